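# Default fluorophore alphabet, in canonical order. All count vectors and
# probability vectors in the package are aligned to the category order
# produced by category_space() for this alphabet.
FLYBOW_COLORS <- c("G", "R", "Y", "B")

SIMPLEX_TOL <- 1e-9

#' The canonical color-category space
#'
#' Every image displays a non-empty subset of the fluorophore alphabet; with
#' four colors there are \eqn{2^4 - 1 = 15} such subsets. Categories are
#' ordered by subset size and, within a size, lexicographically by position in
#' the alphabet, giving the fixed order G, R, Y, B, GR, GY, GB, RY, RB, YB,
#' GRY, GRB, GYB, RYB, GRYB. Count vectors, category-probability vectors and
#' file columns all use this order.
#'
#' @param colors character vector of 2 to 6 distinct single-character labels;
#'   defaults to the four-color flybow alphabet `c("G","R","Y","B")`.
#' @return A `category_space` object: a character vector of category names,
#'   with the member sets in attribute `members` (a list of integer index
#'   vectors into `colors`) and the alphabet in attribute `colors`.
#' @examples
#' sp <- category_space()
#' length(sp)            # 15
#' sp[5:10]              # the six two-color categories
#' @export
category_space <- function(colors = FLYBOW_COLORS) {
  if (anyDuplicated(colors) || length(colors) < 2L || length(colors) > 6L) {
    stop("`colors` must be 2-6 distinct labels", call. = FALSE)
  }
  m <- length(colors)
  members <- unlist(
    lapply(seq_len(m), function(sz) {
      combos <- utils::combn(m, sz, simplify = FALSE)
      combos
    }),
    recursive = FALSE
  )
  names_ <- vapply(members, function(ix) paste(colors[ix], collapse = ""), "")
  structure(names_, members = members, colors = colors,
            class = "category_space")
}

#' @export
print.category_space <- function(x, ...) {
  cat(sprintf("<category_space: %d categories over {%s}>\n",
              length(unclass(x)), paste(attr(x, "colors"), collapse = ",")))
  print(as.character(x))
  invisible(x)
}

# number of colors behind a category space
n_colors <- function(space) length(attr(space, "colors"))

validate_simplex <- function(p, n = 4L, tol = SIMPLEX_TOL) {
  if (!is.numeric(p) || length(p) != n || anyNA(p)) {
    stop(sprintf("`p` must be a numeric %d-vector of color frequencies", n),
         call. = FALSE)
  }
  if (any(p < -tol) || any(p > 1 + tol) || abs(sum(p) - 1) > tol) {
    stop("`p` is off the probability simplex (components in [0,1] summing to 1)",
         call. = FALSE)
  }
  p <- pmin(pmax(p, 0), 1)
  p / sum(p)
}

#' Category probabilities for a known clone number
#'
#' Probability that `k` clones, independently colored with frequencies `p`,
#' display exactly each color set. Computed in closed form by
#' inclusion-exclusion over subsets:
#' \deqn{f_S(p, k) = \sum_{T \subseteq S} (-1)^{|S|-|T|}
#'   \Big(\sum_{c \in T} p_c\Big)^k .}
#'
#' @param p color frequencies; numeric vector on the simplex, one entry per
#'   color of `space`.
#' @param k positive integer number of clones.
#' @param space a [category_space()]; defaults to the four-color space.
#' @return Named numeric vector of probabilities in canonical category order,
#'   summing to 1.
#' @seealso [category_probs_brute_force()] for the enumeration oracle.
#' @examples
#' category_probs_given_k(rep(0.25, 4), k = 2)
#' @export
category_probs_given_k <- function(p, k, space = category_space()) {
  if (length(k) != 1L || is.na(k) || k < 1 || k != round(k)) {
    stop("`k` must be a single integer >= 1", call. = FALSE)
  }
  p <- validate_simplex(p, n_colors(space))
  members <- attr(space, "members")
  probs <- vapply(members, function(S) {
    s <- length(S)
    total <- 0
    # sum over sub-subsets T of S, including the empty set (term 0 unless k=0)
    for (mask in 0:(2^s - 1L)) {
      Tix <- S[bitwAnd(mask, 2^(seq_len(s) - 1L)) > 0L]
      sgn <- (-1)^(s - length(Tix))
      total <- total + sgn * sum(p[Tix])^k
    }
    total
  }, 0)
  probs <- pmax(probs, 0)  # clear negative round-off
  names(probs) <- as.character(space)
  probs
}

#' Category probabilities by exhaustive enumeration
#'
#' Enumerates all \eqn{m^k} ordered color assignments of `k` clones and tallies
#' the probability of each displayed color set. Identical contract to
#' [category_probs_given_k()]; quadratically slower, kept as the independent
#' oracle for tests (hence the `k <= 8` guard).
#'
#' @inheritParams category_probs_given_k
#' @return Named numeric vector in canonical category order.
#' @export
category_probs_brute_force <- function(p, k, space = category_space()) {
  if (length(k) != 1L || is.na(k) || k < 1 || k != round(k)) {
    stop("`k` must be a single integer >= 1", call. = FALSE)
  }
  if (k > 8) stop("enumeration oracle limited to k <= 8", call. = FALSE)
  m <- n_colors(space)
  p <- validate_simplex(p, m)
  assignments <- as.matrix(expand.grid(rep(list(seq_len(m)), k)))
  probs <- stats::setNames(numeric(length(space)), as.character(space))
  key <- vapply(attr(space, "members"), paste, "", collapse = ",")
  for (i in seq_len(nrow(assignments))) {
    cols <- sort(unique(assignments[i, ]))
    w <- prod(p[assignments[i, ]])
    probs[match(paste(cols, collapse = ","), key)] <-
      probs[match(paste(cols, collapse = ","), key)] + w
  }
  probs
}
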