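# Zero-truncated Poisson mixture over color categories and its multinomial
# log-likelihood. theta = (mu, p): mu is the mean number of founder clones per
# image (before discarding empty images), p the four color-induction
# frequencies.

MU_FLOOR <- 1e-8

#' Model parameters
#'
#' @param mu positive real; mean founder clones per image under the (untruncated)
#'   Poisson law.
#' @param p color frequencies on the simplex, canonical color order (G, R, Y, B
#'   by default).
#' @param space the [category_space()] the parameters refer to.
#' @return A `model_params` object (list with `mu`, `p`, `space`).
#' @examples
#' model_params(2, c(0.4, 0.2, 0.2, 0.2))
#' @export
model_params <- function(mu, p, space = category_space()) {
  if (!is.numeric(mu) || length(mu) != 1L || is.na(mu) || mu <= 0) {
    stop("`mu` must be a single positive number", call. = FALSE)
  }
  p <- validate_simplex(p, n_colors(space))
  names(p) <- attr(space, "colors")
  structure(list(mu = as.numeric(mu), p = p, space = space),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf("<model_params: mu = %.6g; p = (%s)>\n", x$mu,
              paste(sprintf("%s=%.4f", names(x$p), x$p), collapse = ", ")))
  invisible(x)
}

#' Per-dataset category counts
#'
#' The data vector n: integer counts of images over the 15 canonical
#' categories, plus the design metadata identifying the dataset within the
#' 3 induction-times x 2 stages x 2 image-classes experiment grid.
#'
#' @param counts non-negative integer vector in canonical category order
#'   (named vectors are checked against the canonical names).
#' @param dataset_id character scalar.
#' @param induction_min heat-shock induction time in minutes (30, 60 or 120
#'   in the reference design; any positive value accepted).
#' @param stage `"early"` (<= 5 days post-induction) or `"late"` (>= 20 dpi).
#' @param image_class `"tumor"` or `"clone"`.
#' @param space the [category_space()].
#' @return A `category_counts` object.
#' @export
category_counts <- function(counts, dataset_id = "dataset",
                            induction_min = NA_real_,
                            stage = NA_character_,
                            image_class = NA_character_,
                            space = category_space()) {
  nc <- length(space)
  if (!is.numeric(counts) || length(counts) != nc || anyNA(counts) ||
      any(counts < 0) || any(counts != round(counts))) {
    stop(sprintf("`counts` must be %d non-negative integers in canonical category order", nc),
         call. = FALSE)
  }
  if (!is.null(names(counts)) && !identical(names(counts), as.character(space))) {
    stop("`counts` names do not match the canonical category order", call. = FALSE)
  }
  if (sum(counts) < 1) stop("at least one image is required", call. = FALSE)
  if (!is.na(stage) && !stage %in% c("early", "late")) {
    stop('`stage` must be "early" or "late"', call. = FALSE)
  }
  if (!is.na(image_class) && !image_class %in% c("tumor", "clone")) {
    stop('`image_class` must be "tumor" or "clone"', call. = FALSE)
  }
  counts <- stats::setNames(as.integer(round(counts)), as.character(space))
  structure(list(counts = counts, n_images = sum(counts),
                 meta = list(dataset_id = as.character(dataset_id),
                             induction_min = as.numeric(induction_min),
                             stage = as.character(stage),
                             image_class = as.character(image_class)),
                 space = space),
            class = "category_counts")
}

#' @export
print.category_counts <- function(x, ...) {
  cat(sprintf("<category_counts %s: %d images (induction %s min, %s, %s)>\n",
              x$meta$dataset_id, x$n_images, format(x$meta$induction_min),
              x$meta$stage, x$meta$image_class))
  print(x$counts)
  invisible(x)
}

#' Zero-truncated Poisson probability mass
#'
#' Probability of `k` clones in a retained image when the untruncated clone
#' number is Poisson(`mu`) and images with zero clones are discarded:
#' \deqn{P(k \mid k \ge 1) = \frac{\mu^k e^{-\mu} / k!}{1 - e^{-\mu}}.}
#'
#' @param k positive integer (vectorized); `k = 0` is rejected because the
#'   truncation removes it.
#' @param mu positive real.
#' @return Numeric vector of probabilities.
#' @examples
#' truncated_poisson_pmf(2, 2)   # 0.31304
#' @export
truncated_poisson_pmf <- function(k, mu) {
  if (any(is.na(k)) || any(k < 1) || any(k != round(k))) {
    stop("`k` must be integer >= 1 (zero-clone images are discarded)", call. = FALSE)
  }
  if (!is.numeric(mu) || length(mu) != 1L || is.na(mu) || mu <= 0) {
    stop("`mu` must be a single positive number", call. = FALSE)
  }
  # expm1 keeps the normalizer accurate as mu -> 0
  exp(k * log(mu) - mu - lgamma(k + 1)) / (-expm1(-mu))
}

#' Mixture category probabilities (series form)
#'
#' The category frequencies actually observed across retained images:
#' a truncated-Poisson-weighted average of the known-k probabilities,
#' \deqn{F(\mu, p) = \frac{1}{1 - P(0,\mu)} \sum_{k > 0} P(k,\mu)\, f(p, k),}
#' summed until the residual Poisson tail mass drops below `tail_tol`
#' (hard cap at k = 1000).
#'
#' @param params a [model_params()].
#' @param tail_tol series truncation tolerance in (0, 1e-6].
#' @return Named probability vector over the 15 categories.
#' @seealso [mixture_category_probs_closed_form()], the exact product form
#'   used as the production fast path.
#' @export
mixture_category_probs <- function(params, tail_tol = 1e-12) {
  stopifnot(inherits(params, "model_params"))
  if (!is.numeric(tail_tol) || tail_tol <= 0 || tail_tol > 1e-6) {
    stop("`tail_tol` must be in (0, 1e-6]", call. = FALSE)
  }
  mu <- params$mu
  space <- params$space
  acc <- stats::setNames(numeric(length(space)), as.character(space))
  # untruncated Poisson tail mass beyond k terms, tracked by recursion
  pk <- exp(-mu)                       # P(0, mu)
  tail_mass <- 1 - pk
  norm <- -expm1(-mu)
  for (k in seq_len(1000L)) {
    pk <- pk * mu / k                  # P(k, mu)
    acc <- acc + pk * category_probs_given_k(params$p, k, space)
    tail_mass <- tail_mass - pk
    if (tail_mass < tail_tol) {
      return(acc / norm)
    }
  }
  stop("series did not converge within k <= 1000 (mu too large for the series path)",
       call. = FALSE)
}

#' Mixture category probabilities (closed form)
#'
#' Exact product form of the truncated mixture, by Poisson thinning: clones of
#' color c arrive as independent Poisson(\eqn{\mu p_c}) streams, so color c is
#' present with probability \eqn{1 - e^{-\mu p_c}} independently across colors,
#' and conditioning on a non-empty image divides by \eqn{1 - e^{-\mu}}:
#' \deqn{F_S = \frac{\prod_{c \in S} (1 - e^{-\mu p_c})
#'   \prod_{c \notin S} e^{-\mu p_c}}{1 - e^{-\mu}}.}
#' Equals the series of [mixture_category_probs()] to float precision; used as
#' the default fast path throughout fitting and as its cross-check oracle.
#'
#' @inheritParams mixture_category_probs
#' @return Named probability vector over the 15 categories.
#' @export
mixture_category_probs_closed_form <- function(params) {
  stopifnot(inherits(params, "model_params"))
  space <- params$space
  members <- attr(space, "members")
  present <- -expm1(-params$mu * params$p)   # 1 - exp(-mu p_c)
  absent <- exp(-params$mu * params$p)
  m <- length(params$p)
  probs <- vapply(members, function(S) {
    prod(present[S]) * prod(absent[setdiff(seq_len(m), S)])
  }, 0)
  probs <- probs / (-expm1(-params$mu))
  names(probs) <- as.character(space)
  probs
}

LOGLIK_SENTINEL <- -Inf

#' Multinomial log-likelihood of category counts
#'
#' \eqn{\ell(\theta \mid n) = \log M(n, F(\theta))}: the multinomial
#' log-probability of the observed category counts under the mixture
#' frequencies. The multinomial coefficient is included so the value is a true
#' log-probability (it is constant in \eqn{\theta} and cancels in all
#' deviances and intervals). If some category has positive count but zero
#' probability under \eqn{\theta}, the likelihood is zero and `-Inf` is
#' returned rather than an error.
#'
#' @param counts a [category_counts()].
#' @param params a [model_params()].
#' @return Scalar log-likelihood (possibly `-Inf`).
#' @export
log_likelihood <- function(counts, params) {
  stopifnot(inherits(counts, "category_counts"), inherits(params, "model_params"))
  f <- mixture_category_probs_closed_form(params)
  n <- counts$counts
  pos <- n > 0
  if (any(pos & f <= 0)) return(LOGLIK_SENTINEL)
  lgamma(sum(n) + 1) - sum(lgamma(n + 1)) + sum(n[pos] * log(f[pos]))
}

#' Parameter transforms for unconstrained optimization
#'
#' `to_unconstrained` maps interior parameters to
#' \eqn{\eta = (\log \mu,\; \log p_G/p_B,\; \log p_R/p_B,\; \log p_Y/p_B)}
#' (log for the Poisson mean, additive-log-ratio with the last color as
#' reference for the simplex; a smooth bijection onto the open simplex, so any
#' finite \eqn{\eta} back-maps to valid parameters and the optimizer never
#' leaves the feasible set). `from_unconstrained` inverts it, flooring
#' \eqn{\mu} at `1e-8` against underflow in the truncation factor.
#'
#' @param params a [model_params()] with all components strictly interior.
#' @return `to_unconstrained`: numeric 4-vector; `from_unconstrained`: a
#'   [model_params()].
#' @export
to_unconstrained <- function(params) {
  stopifnot(inherits(params, "model_params"))
  p <- params$p
  if (any(p <= 0) || any(p >= 1)) {
    stop("transform requires interior p (no component exactly 0 or 1)", call. = FALSE)
  }
  m <- length(p)
  c(log(params$mu), log(p[-m] / p[m]))
}

#' @rdname to_unconstrained
#' @param eta finite numeric 4-vector (1 coordinate for log mu, 3 free simplex
#'   coordinates).
#' @param space the [category_space()].
#' @export
from_unconstrained <- function(eta, space = category_space()) {
  m <- n_colors(space)
  if (!is.numeric(eta) || length(eta) != m || anyNA(eta) || any(!is.finite(eta))) {
    stop(sprintf("`eta` must be a finite numeric %d-vector", m), call. = FALSE)
  }
  mu <- max(exp(eta[1]), MU_FLOOR)
  z <- c(eta[-1], 0)
  z <- z - max(z)                      # overflow-safe softmax
  p <- exp(z) / sum(exp(z))
  model_params(mu, p, space)
}
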