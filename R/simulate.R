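# Seeded simulator of flybow-style experiments with exactly the sampling
# structure the model assumes: per image a Poisson(mu) number of founder
# clones, each clone independently colored from p, empty images discarded,
# readout = the set of colors present.

#' Simulate one lineage-tracing experiment
#'
#' Draws images one at a time: \eqn{k \sim} Poisson(`mu`); when `discard_empty`
#' is on, zero-clone draws are rejected (and counted in `n_discarded`) exactly
#' as empty images are dropped from real datasets, which makes the retained
#' clone numbers zero-truncated Poisson by construction. Each of the `k`
#' clones gets an i.i.d. color from `p`; the image's category is the set of
#' distinct colors present. Fully determined by `seed`.
#'
#' @param mu positive real; mean clones per image before truncation.
#' @param p color frequencies (simplex, canonical color order).
#' @param n_images number of retained (non-empty) images to generate.
#' @param seed integer seed.
#' @param discard_empty reject zero-clone images (default `TRUE`). When off,
#'   empty draws still yield no category and are tallied in `n_discarded`,
#'   but are not redrawn, so fewer than `n_images` categorized images result.
#' @param dataset_id,induction_min,stage,image_class metadata passed through
#'   to the embedded [category_counts()].
#' @param space the [category_space()].
#' @return A `sim_experiment`: `images` (list of per-clone color vectors, one
#'   per retained image), `counts` (a [category_counts()]), `n_discarded`,
#'   and the generating `config` (`mu`, `p`, `n_images`, `seed`).
#' @examples
#' sim <- simulate_experiment(mu = 2, p = rep(0.25, 4), n_images = 100, seed = 7)
#' sim$counts
#' @export
simulate_experiment <- function(mu, p, n_images, seed,
                                discard_empty = TRUE,
                                dataset_id = "sim",
                                induction_min = NA_real_,
                                stage = NA_character_,
                                image_class = NA_character_,
                                space = category_space()) {
  if (!is.numeric(mu) || length(mu) != 1L || mu <= 0) {
    stop("`mu` must be a single positive number", call. = FALSE)
  }
  p <- validate_simplex(p, n_colors(space))
  if (!is.numeric(n_images) || length(n_images) != 1L || n_images < 1 ||
      n_images != round(n_images)) {
    stop("`n_images` must be a positive integer", call. = FALSE)
  }
  colors <- attr(space, "colors")
  m <- length(colors)

  drawn <- with_local_seed(seed, {
    images <- vector("list", n_images)
    kept <- 0L
    discarded <- 0L
    attempts <- 0L
    # rejection sampling mirrors the experimental discarding of empty images;
    # without rejection, n_images is the number of attempts instead
    while (if (discard_empty) kept < n_images else attempts < n_images) {
      attempts <- attempts + 1L
      k <- stats::rpois(1L, mu)
      if (k == 0L) {
        discarded <- discarded + 1L
        next
      }
      kept <- kept + 1L
      images[[kept]] <- colors[sample.int(m, k, replace = TRUE, prob = p)]
    }
    list(images = images[seq_len(kept)], discarded = discarded)
  })

  key <- vapply(attr(space, "members"), function(ix)
    paste(colors[ix], collapse = ""), "")
  cat_of <- vapply(drawn$images, function(cl) {
    present <- colors[sort(match(unique(cl), colors))]
    match(paste(present, collapse = ""), key)
  }, 0L)
  counts <- stats::setNames(tabulate(cat_of, nbins = length(space)), key)
  structure(list(
    images = drawn$images,
    counts = category_counts(counts, dataset_id = dataset_id,
                             induction_min = induction_min, stage = stage,
                             image_class = image_class, space = space),
    n_discarded = drawn$discarded,
    config = list(mu = mu, p = p, n_images = length(drawn$images),
                  seed = as.integer(seed), discard_empty = discard_empty)
  ), class = "sim_experiment")
}

#' @export
print.sim_experiment <- function(x, ...) {
  cat(sprintf("<sim_experiment: %d images, %d empty draws discarded, mu = %g, seed = %d>\n",
              length(x$images), x$n_discarded, x$config$mu, x$config$seed))
  print(x$counts$counts)
  invisible(x)
}

# the reference 3 induction-times x 2 stages x 2 classes design
grid_conditions <- function() {
  g <- expand.grid(induction_min = c(30, 60, 120),
                   stage = c("early", "late"),
                   image_class = c("clone", "tumor"),
                   stringsAsFactors = FALSE)
  g <- g[order(g$induction_min, match(g$stage, c("early", "late")),
               g$image_class), ]
  rownames(g) <- NULL
  g
}

#' Default study conditions for the simulated experiment grid
#'
#' Mean founder-clone numbers by condition and color frequencies by induction
#' time used by [simulate_paper_grid()] when no maps are supplied. Late tumors
#' center on eight founders; clone-control images are near-single-lineage.
#' GFP dominates heavily at 30-min induction (the cassette's default state)
#' and the frequencies flatten — while staying GFP-heavy — at 60 and 120 min.
#'
#' @return A list with `mu_by_condition` (named by
#'   `"<induction>_<stage>_<class>"`) and `p_by_induction` (named by minutes).
#' @export
default_grid_conditions <- function() {
  mu <- c("30_early_clone" = 1.5, "30_early_tumor" = 6,
          "30_late_clone" = 1.2, "30_late_tumor" = 8,
          "60_early_clone" = 1.5, "60_early_tumor" = 6,
          "60_late_clone" = 1.2, "60_late_tumor" = 8,
          "120_early_clone" = 1.5, "120_early_tumor" = 6,
          "120_late_clone" = 1.2, "120_late_tumor" = 8)
  p <- list("30" = c(0.94, 0.02, 0.02, 0.02),
            "60" = c(0.70, 0.10, 0.10, 0.10),
            "120" = c(0.55, 0.15, 0.15, 0.15))
  list(mu_by_condition = as.list(mu), p_by_induction = p)
}

#' Simulate the full 12-dataset experiment grid
#'
#' One dataset per cell of the 3 induction-times (30/60/120 min) x 2 stages
#' (early/late) x 2 image-classes (tumor/clone) design, each generated by
#' [simulate_experiment()] with condition-specific parameters and its own
#' seed stream derived from (`seed`, dataset index), so any cell is
#' reproducible in isolation.
#'
#' @param mu_by_condition named list/vector of true \eqn{\mu} keyed
#'   `"<induction>_<stage>_<class>"`, covering all 12 cells.
#' @param p_by_induction named list of color-frequency vectors keyed by
#'   induction minutes (`"30"`, `"60"`, `"120"`).
#' @param n_images_per_dataset retained images per dataset.
#' @param seed master integer seed.
#' @return List of 12 [category_counts()] with metadata filled in.
#' @export
simulate_paper_grid <- function(mu_by_condition = default_grid_conditions()$mu_by_condition,
                                p_by_induction = default_grid_conditions()$p_by_induction,
                                n_images_per_dataset = 150L,
                                seed = 1L) {
  grid <- grid_conditions()
  keys <- sprintf("%d_%s_%s", grid$induction_min, grid$stage, grid$image_class)
  missing_mu <- setdiff(keys, names(mu_by_condition))
  if (length(missing_mu)) {
    stop("`mu_by_condition` is missing grid cells: ",
         paste(missing_mu, collapse = ", "), call. = FALSE)
  }
  missing_p <- setdiff(as.character(unique(grid$induction_min)),
                       names(p_by_induction))
  if (length(missing_p)) {
    stop("`p_by_induction` is missing induction times: ",
         paste(missing_p, collapse = ", "), call. = FALSE)
  }
  lapply(seq_len(nrow(grid)), function(i) {
    simulate_experiment(
      mu = mu_by_condition[[keys[i]]],
      p = p_by_induction[[as.character(grid$induction_min[i])]],
      n_images = n_images_per_dataset,
      seed = derive_seed(seed, i),
      dataset_id = keys[i],
      induction_min = grid$induction_min[i],
      stage = grid$stage[i],
      image_class = grid$image_class[i]
    )$counts
  })
}

#' Theoretical clone size after synchronous divisions
#'
#' Cell count of a single founder clone after `division_events` synchronous
#' binary divisions: \eqn{2^d}. Fifteen division events give 32,768 cells —
#' the growth arithmetic showing that slow division alone cannot explain why
#' tumors are never monoclonal.
#'
#' @param division_events non-negative integer (vectorized).
#' @return Numeric cell counts.
#' @examples
#' theoretical_clone_size(15)  # 32768
#' @export
theoretical_clone_size <- function(division_events) {
  if (any(is.na(division_events)) || any(division_events < 0) ||
      any(division_events != round(division_events))) {
    stop("`division_events` must be non-negative integers", call. = FALSE)
  }
  2^division_events
}
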