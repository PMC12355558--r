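# Maximum-likelihood estimation of (mu, p) from category counts, profile
# likelihood confidence intervals, and the per-condition results table.
#
# With the product (Poisson-thinning) form of the mixture, the multinomial
# log-likelihood depends on the data only through N (total images) and the
# per-color presence counts m_c = sum over categories containing c:
#   l(t) = sum_c [ m_c log(1 - e^{-t_c}) - (N - m_c) t_c ] - N log(1 - e^{-mu})
# with t_c = mu p_c, mu = sum_c t_c (plus the multinomial constant). This
# gives cheap exact gradients in the unconstrained parameterization.

GRAD_TOL <- 1e-6
BOUNDARY_TOL <- 1e-4

suff_stats <- function(counts) {
  members <- attr(counts$space, "members")
  m <- n_colors(counts$space)
  occ <- vapply(seq_len(m), function(c) {
    sum(counts$counts[vapply(members, function(S) c %in% S, TRUE)])
  }, 0)
  list(occ = occ, N = counts$n_images,
       const = lgamma(counts$n_images + 1) - sum(lgamma(counts$counts + 1)))
}

# log-likelihood (incl. multinomial constant) from sufficient statistics,
# as a function of t = mu * p; returns -Inf if impossible
loglik_t <- function(t, ss) {
  mu <- sum(t)
  a <- log1p(-exp(-t))                         # log(1 - e^{-t_c})
  if (any(ss$occ > 0 & !is.finite(a))) return(-Inf)
  terms <- ifelse(ss$occ > 0, ss$occ * a, 0)
  ss$const + sum(terms - (ss$N - ss$occ) * t) - ss$N * log1p(-exp(-mu))
}

# d l / d t_c
dloglik_dt <- function(t, ss) {
  mu <- sum(t)
  r <- exp(-t) / pmax(-expm1(-t), 1e-300)      # e^{-t}/(1-e^{-t})
  ss$occ * r - (ss$N - ss$occ) - ss$N * exp(-mu) / (-expm1(-mu))
}

#' Deterministic starting values for the optimizer
#'
#' Color frequencies start at the normalized per-color occurrence shares
#' (with a pseudo-count of 0.5 per color, so no start sits on the simplex
#' boundary). The clone-number mean starts at the method-of-moments solve of
#' the expected number of distinct colors per retained image,
#' \eqn{\sum_c (1 - e^{-\mu p_c}) / (1 - e^{-\mu})}, against its observed
#' value, clamped to \eqn{[0.1, 20]}.
#'
#' @param counts a [category_counts()].
#' @return A [model_params()] start point; deterministic in the input.
#' @export
initial_guess <- function(counts) {
  stopifnot(inherits(counts, "category_counts"))
  ss <- suff_stats(counts)
  p0 <- (ss$occ + 0.5) / sum(ss$occ + 0.5)
  sizes <- vapply(attr(counts$space, "members"), length, 0L)
  mean_colors <- sum(counts$counts * sizes) / ss$N
  ecolors <- function(mu) sum(-expm1(-mu * p0)) / (-expm1(-mu))
  mu0 <- if (mean_colors <= ecolors(0.05)) {
    0.1
  } else if (mean_colors >= ecolors(20)) {
    20
  } else {
    max(0.1, stats::uniroot(function(mu) ecolors(mu) - mean_colors,
                            c(0.05, 20), tol = 1e-8)$root)
  }
  model_params(mu0, p0, counts$space)
}

# Objective/gradient in unconstrained space. `fixed` optionally pins mu
# (fixed$mu), one color (fixed$color index + value), or the whole p
# (fixed$p). Free coordinates are always (log mu if free) then alr coords
# of the free part of the simplex.
make_objective <- function(counts, fixed = list()) {
  ss <- suff_stats(counts)
  m <- n_colors(counts$space)

  expand <- function(eta) {
    i <- 1L
    if (is.null(fixed$mu)) { mu <- exp(eta[i]); i <- i + 1L } else mu <- fixed$mu
    mu <- max(min(mu, 1e6), MU_FLOOR)
    if (!is.null(fixed$p)) {
      p <- fixed$p
    } else if (!is.null(fixed$color)) {
      v <- fixed$value
      free <- setdiff(seq_len(m), fixed$color)
      z <- c(eta[seq.int(i, length.out = length(free) - 1L)], 0)
      z <- z - max(z)
      s <- exp(z) / sum(exp(z))
      p <- numeric(m)
      p[fixed$color] <- v
      p[free] <- (1 - v) * s
    } else {
      z <- c(eta[seq.int(i, length.out = m - 1L)], 0)
      z <- z - max(z)
      p <- exp(z) / sum(exp(z))
    }
    list(mu = mu, p = p, t = mu * p)
  }

  nll <- function(eta) {
    if (anyNA(eta) || any(!is.finite(eta))) return(1e10)
    ll <- loglik_t(expand(eta)$t, ss)
    if (!is.finite(ll)) 1e10 else -ll
  }

  ngr <- function(eta) {
    th <- expand(eta)
    g <- dloglik_dt(th$t, ss)                    # d l / d t_c
    out <- numeric(length(eta))
    i <- 1L
    if (is.null(fixed$mu)) {                     # d l / d log mu
      out[i] <- sum(g * th$t)
      i <- i + 1L
    }
    if (is.null(fixed$p)) {
      if (!is.null(fixed$color)) {
        free <- setdiff(seq_len(m), fixed$color)
        s <- th$p[free] / (1 - fixed$value)
        gs <- g[free]
        j <- seq_len(length(free) - 1L)
        out[i - 1L + j] <- th$mu * (1 - fixed$value) *
          s[j] * (gs[j] - sum(gs * s))
      } else {
        j <- seq_len(m - 1L)
        out[i - 1L + j] <- th$mu * th$p[j] * (g[j] - sum(g * th$p))
      }
    }
    -out
  }

  n_free <- (if (is.null(fixed$mu)) 1L else 0L) +
    (if (!is.null(fixed$p)) 0L else if (!is.null(fixed$color)) m - 2L else m - 1L)

  list(nll = nll, ngr = ngr, expand = expand, n_free = n_free, ss = ss)
}

# run BFGS from one start, then Newton-polish until the gradient norm is small
optimize_from <- function(obj, eta0, max_rounds = 3L) {
  eta <- eta0
  val <- obj$nll(eta)
  for (round in seq_len(max_rounds)) {
    res <- tryCatch(
      stats::optim(eta, obj$nll, obj$ngr, method = "BFGS",
                   control = list(maxit = 500L, reltol = 1e-14)),
      error = function(e) NULL
    )
    if (!is.null(res) && res$value <= val) { eta <- res$par; val <- res$value }
    if (sqrt(sum(obj$ngr(eta)^2)) < GRAD_TOL) break
    # Newton steps on the stationarity condition (finite-difference Jacobian
    # of the analytic gradient); BFGS alone stalls just short of GRAD_TOL
    for (it in seq_len(10L)) {
      g <- obj$ngr(eta)
      if (sqrt(sum(g^2)) < GRAD_TOL * 0.1) break
      d <- length(eta)
      h <- 1e-5
      H <- vapply(seq_len(d), function(j) {
        ej <- eta; ej[j] <- ej[j] + h
        ej2 <- eta; ej2[j] <- ej2[j] - h
        (obj$ngr(ej) - obj$ngr(ej2)) / (2 * h)
      }, numeric(d))
      step <- tryCatch(solve((H + t(H)) / 2, g), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) break
      cand <- eta - step
      vc <- obj$nll(cand)
      if (!is.finite(vc) || vc > val + 1e-8) break
      eta <- cand; val <- vc
    }
    if (sqrt(sum(obj$ngr(eta)^2)) < GRAD_TOL) break
  }
  list(eta = eta, value = val, grad_norm = sqrt(sum(obj$ngr(eta)^2)))
}

#' Fit the clone-number model by maximum likelihood
#'
#' Maximizes the multinomial likelihood of the observed category counts under
#' the zero-truncated Poisson mixture, with a quasi-Newton (BFGS) optimizer and
#' analytic gradients on the unconstrained scale (log \eqn{\mu},
#' additive-log-ratio simplex coordinates). One deterministic start from
#' [initial_guess()] plus `n_starts - 1` jittered starts (normal jitter,
#' SD 0.5 in unconstrained space, seeded); the best optimum wins, with ties
#' within 1e-9 resolved by lowest start index.
#'
#' @param counts a [category_counts()].
#' @param n_starts total optimizer starts (>= 1).
#' @param seed integer seed for the jittered starts.
#' @param fix_p optional color frequencies to hold fixed (for example, taken
#'   from a paired control dataset); then only \eqn{\mu} is estimated.
#' @return A `fit_result`: `params_hat`, `loglik` (a true log-probability,
#'   multinomial coefficient included), `converged` (gradient norm below 1e-6
#'   in unconstrained space), `grad_norm`, `n_starts_used`, `boundary_flags`
#'   (\eqn{\hat\mu} or a \eqn{\hat p_c} within 1e-4 of the boundary),
#'   `degenerate` (fewer than 2 distinct categories observed), `counts_ref`.
#' @examples
#' sim <- simulate_experiment(mu = 3, p = c(0.4, 0.2, 0.2, 0.2),
#'                            n_images = 200, seed = 1)
#' fit <- fit_mle(sim$counts, seed = 1)
#' fit$params_hat
#' @export
fit_mle <- function(counts, n_starts = 5L, seed = 1L, fix_p = NULL) {
  stopifnot(inherits(counts, "category_counts"), n_starts >= 1L)
  degenerate <- sum(counts$counts > 0) < 2L
  sizes <- vapply(attr(counts$space, "members"), length, 0L)
  if (is.null(fix_p) && sum(counts$counts[sizes >= 2L]) == 0L) {
    # no color co-occurrence at all: the likelihood supremum sits on the
    # mu -> 0 boundary (single-clone images), where it attains the saturated
    # multinomial bound with p at the empirical singleton frequencies
    p_hat <- counts$counts[sizes == 1L] / counts$n_images
    params_hat <- model_params(MU_FLOOR, p_hat, counts$space)
    flags <- c(mu = TRUE,
               stats::setNames(unname(p_hat) <= BOUNDARY_TOL,
                               paste0("p_", attr(counts$space, "colors"))))
    return(structure(list(
      params_hat = params_hat,
      loglik = log_likelihood(counts, params_hat),
      converged = FALSE, grad_norm = NA_real_, n_starts_used = 0L,
      boundary_flags = flags, degenerate = degenerate, fix_p = FALSE,
      eta_hat = NULL, counts_ref = counts$meta$dataset_id, counts = counts
    ), class = "fit_result"))
  }
  fixed <- list()
  if (!is.null(fix_p)) {
    fixed$p <- validate_simplex(fix_p, n_colors(counts$space))
  }
  obj <- make_objective(counts, fixed)
  guess <- initial_guess(counts)
  eta_full <- to_unconstrained(guess)
  eta0 <- if (is.null(fix_p)) eta_full else eta_full[1L]

  starts <- list(eta0)
  if (n_starts > 1L) {
    jit <- with_local_seed(seed, {
      lapply(seq_len(n_starts - 1L), function(i) {
        eta0 + stats::rnorm(length(eta0), 0, 0.5)
      })
    })
    starts <- c(starts, jit)
  }

  sols <- lapply(starts, function(s) optimize_from(obj, s))
  vals <- vapply(sols, `[[`, 0, "value")
  best <- which(vals <= min(vals) + 1e-9)[1L]   # tie -> lowest start index
  sol <- sols[[best]]

  th <- obj$expand(sol$eta)
  params_hat <- model_params(th$mu, th$p, counts$space)
  flags <- c(mu = th$mu <= BOUNDARY_TOL,
             stats::setNames(th$p <= BOUNDARY_TOL,
                             paste0("p_", attr(counts$space, "colors"))))
  structure(list(
    params_hat = params_hat,
    loglik = -sol$value,
    converged = is.finite(sol$value) && sol$grad_norm < GRAD_TOL && !degenerate,
    grad_norm = sol$grad_norm,
    n_starts_used = length(starts),
    boundary_flags = flags,
    degenerate = degenerate,
    fix_p = !is.null(fix_p),
    eta_hat = sol$eta,
    counts_ref = counts$meta$dataset_id,
    counts = counts
  ), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result %s: mu_hat = %.4g, loglik = %.4f, %s>\n",
              x$counts_ref, x$params_hat$mu, x$loglik,
              if (x$converged) "converged" else "NOT converged"))
  cat(sprintf("  p_hat = (%s)\n",
              paste(sprintf("%s=%.4f", names(x$params_hat$p), x$params_hat$p),
                    collapse = ", ")))
  if (any(x$boundary_flags)) {
    cat("  boundary:", paste(names(which(x$boundary_flags)), collapse = ", "), "\n")
  }
  invisible(x)
}

# profile log-likelihood at a fixed value of one parameter, warm-started;
# returns -Inf on inner-optimizer failure
profile_loglik <- function(counts, parameter, value, fit, warm = NULL) {
  m <- n_colors(counts$space)
  colors <- attr(counts$space, "colors")
  if (parameter == "mu") {
    fixed <- list(mu = value)
    if (fit$fix_p) fixed$p <- fit$params_hat$p
    start <- if (fit$fix_p) numeric(0) else {
      p <- pmin(pmax(fit$params_hat$p, 1e-8), 1 - 1e-8)
      log(p[-m] / p[m])
    }
  } else {
    ci <- match(sub("^p_", "", parameter), colors)
    fixed <- list(color = ci, value = value)
    free <- setdiff(seq_len(m), ci)
    s <- pmin(pmax(fit$params_hat$p[free], 1e-8), 1)
    s <- s / sum(s)
    start <- c(log(fit$params_hat$mu), log(s[-length(s)] / s[length(s)]))
  }
  if (!is.null(warm) && length(warm) == length(start)) start <- warm
  obj <- make_objective(counts, fixed)
  if (obj$n_free == 0L) {
    return(list(loglik = -obj$nll(numeric(0)), eta = numeric(0)))
  }
  sol <- tryCatch(optimize_from(obj, start, max_rounds = 2L),
                  error = function(e) NULL)
  if (is.null(sol) || !is.finite(sol$value)) {
    return(list(loglik = -Inf, eta = start))
  }
  list(loglik = -sol$value, eta = sol$eta)
}

#' Profile-likelihood confidence interval
#'
#' For one parameter, the profile log-likelihood re-maximizes over all other
#' parameters at each fixed value; the confidence set is where the profile
#' deviance \eqn{2[\ell(\hat\theta) - \ell_{\mathrm{profile}}(v)]} stays below
#' the \eqn{\chi^2_1} quantile at `level` (3.841 at 95%). Endpoints are
#' bracketed by geometric expansion away from the estimate (on the log scale
#' for \eqn{\mu}, logit scale for frequencies) and then refined by bisection to
#' absolute tolerance 1e-4 on the parameter scale (log scale for \eqn{\mu}).
#' If the deviance never crosses the threshold before the parameter bound, the
#' endpoint is set to the bound and flagged.
#'
#' @param counts a [category_counts()].
#' @param fit the [fit_mle()] result for `counts`.
#' @param parameter one of `"mu"`, `"p_G"`, `"p_R"`, `"p_Y"`, `"p_B"`.
#' @param level confidence level in (0, 1).
#' @return A `profile_ci`: `parameter`, `level`, `estimate`, `lower`, `upper`,
#'   `lower_at_boundary`, `upper_at_boundary`.
#' @export
profile_ci <- function(counts, fit, parameter = "mu", level = 0.95) {
  stopifnot(inherits(counts, "category_counts"), inherits(fit, "fit_result"))
  if (level <= 0 || level >= 1) stop("`level` must be in (0,1)", call. = FALSE)
  colors <- attr(counts$space, "colors")
  valid <- c("mu", paste0("p_", colors))
  if (!parameter %in% valid) {
    stop("`parameter` must be one of: ", paste(valid, collapse = ", "), call. = FALSE)
  }
  thresh <- stats::qchisq(level, df = 1)
  ll_hat <- fit$loglik

  is_mu <- parameter == "mu"
  est <- if (is_mu) fit$params_hat$mu else {
    fit$params_hat$p[[match(sub("^p_", "", parameter), colors)]]
  }
  # search scale: log for mu, logit for p; bisection tolerance applied on the
  # reporting scale (log-mu / natural p)
  to_s <- if (is_mu) log else stats::qlogis
  from_s <- if (is_mu) exp else stats::plogis
  bound_lo <- if (is_mu) log(MU_FLOOR) else stats::qlogis(1e-8)
  bound_hi <- if (is_mu) log(1e4) else stats::qlogis(1 - 1e-8)
  tol_scale <- if (is_mu) log else identity

  warm <- new.env(parent = emptyenv())
  warm$eta <- NULL
  deviance_at <- function(x_s) {
    pr <- profile_loglik(counts, parameter, from_s(x_s), fit, warm = warm$eta)
    if (is.finite(pr$loglik)) warm$eta <- pr$eta
    d <- 2 * (ll_hat - pr$loglik)
    if (is.finite(d) && d < -1e-6) {
      warning("profile log-likelihood exceeded the fit optimum (deviance ",
              format(d), "); treating as 0", call. = FALSE)
    }
    max(d, 0)
  }

  one_side <- function(dir) {                     # dir = -1 lower, +1 upper
    x0 <- min(max(to_s(est), bound_lo), bound_hi)
    bound <- if (dir < 0) bound_lo else bound_hi
    h <- 0.25
    inner <- x0
    repeat {
      x <- x0 + dir * h
      hit_bound <- (dir < 0 && x <= bound) || (dir > 0 && x >= bound)
      if (hit_bound) x <- bound
      d <- deviance_at(x)
      if (d > thresh) { outer <- x; break }
      inner <- x
      if (hit_bound) return(list(value = from_s(bound), at_boundary = TRUE))
      h <- h * 2
    }
    # bisection between inner (inside CI) and outer (outside)
    while (abs(tol_scale(from_s(outer)) - tol_scale(from_s(inner))) > 1e-4) {
      mid <- (inner + outer) / 2
      if (deviance_at(mid) > thresh) outer <- mid else inner <- mid
    }
    list(value = from_s((inner + outer) / 2), at_boundary = FALSE)
  }

  warm$eta <- NULL
  lo <- one_side(-1)
  warm$eta <- NULL
  hi <- one_side(+1)
  structure(list(parameter = parameter, level = level, estimate = est,
                 lower = lo$value, upper = hi$value,
                 lower_at_boundary = lo$at_boundary,
                 upper_at_boundary = hi$at_boundary),
            class = "profile_ci")
}

#' @export
print.profile_ci <- function(x, ...) {
  cat(sprintf("<profile_ci %s: %.4g [%.4g, %.4g] at %.0f%%%s>\n",
              x$parameter, x$estimate, x$lower, x$upper, 100 * x$level,
              if (x$lower_at_boundary || x$upper_at_boundary) ", boundary" else ""))
  invisible(x)
}

#' Fit every dataset of an experiment grid
#'
#' Independent maximum-likelihood fit and \eqn{\mu} profile interval per
#' dataset; rows ordered by (induction time, stage, image class). Per-dataset
#' failures are recorded in the row's `status` and never abort the batch.
#'
#' @param datasets non-empty list of [category_counts()].
#' @param seed integer; per-dataset optimizer seeds are derived from it, so a
#'   given seed and input reproduce the table exactly.
#' @param level confidence level for the \eqn{\mu} interval.
#' @param fix_p_from optional `dataset_id`: that dataset (typically a clone
#'   control) is fitted first and its \eqn{\hat p} is held fixed when fitting
#'   all other datasets. Default: every dataset fitted independently.
#' @return A `condition_table` data frame: metadata, `n_images`, `mu_hat`,
#'   `mu_lo`, `mu_hi` (and boundary flags), \eqn{\hat p}, `loglik`,
#'   `converged`, `status`.
#' @export
fit_all <- function(datasets, seed = 1L, level = 0.95, fix_p_from = NULL) {
  if (!is.list(datasets) || length(datasets) == 0L ||
      !all(vapply(datasets, inherits, TRUE, "category_counts"))) {
    stop("`datasets` must be a non-empty list of category_counts", call. = FALSE)
  }
  ids <- vapply(datasets, function(d) d$meta$dataset_id, "")
  seeds <- with_local_seed(seed, sample.int(.Machine$integer.max - 1L,
                                            length(datasets)))
  p_fixed <- NULL
  if (!is.null(fix_p_from)) {
    ref <- match(fix_p_from, ids)
    if (is.na(ref)) stop("`fix_p_from` dataset_id not found", call. = FALSE)
    p_fixed <- fit_mle(datasets[[ref]], seed = seeds[ref])$params_hat$p
  }

  rows <- lapply(seq_along(datasets), function(i) {
    d <- datasets[[i]]
    colors <- attr(d$space, "colors")
    base <- data.frame(dataset_id = d$meta$dataset_id,
                       induction_min = d$meta$induction_min,
                       stage = d$meta$stage,
                       image_class = d$meta$image_class,
                       n_images = d$n_images,
                       stringsAsFactors = FALSE)
    res <- tryCatch({
      fp <- if (!is.null(p_fixed) && ids[i] != fix_p_from) p_fixed else NULL
      fit <- fit_mle(d, seed = seeds[i], fix_p = fp)
      ci <- profile_ci(d, fit, "mu", level = level)
      cbind(base,
            data.frame(mu_hat = fit$params_hat$mu,
                       mu_lo = ci$lower, mu_hi = ci$upper,
                       mu_lo_boundary = ci$lower_at_boundary,
                       mu_hi_boundary = ci$upper_at_boundary,
                       as.list(stats::setNames(fit$params_hat$p,
                                               paste0("p_", colors))),
                       loglik = fit$loglik, converged = fit$converged,
                       status = "ok", stringsAsFactors = FALSE))
    }, error = function(e) {
      cbind(base,
            data.frame(mu_hat = NA_real_, mu_lo = NA_real_, mu_hi = NA_real_,
                       mu_lo_boundary = NA, mu_hi_boundary = NA,
                       p_G = NA_real_, p_R = NA_real_, p_Y = NA_real_,
                       p_B = NA_real_, loglik = NA_real_, converged = FALSE,
                       status = paste0("error: ", conditionMessage(e)),
                       stringsAsFactors = FALSE))
    })
    res
  })
  tab <- do.call(rbind, rows)
  ord <- order(tab$induction_min,
               match(tab$stage, c("early", "late")),
               tab$image_class)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "seed") <- as.integer(seed)
  attr(tab, "level") <- level
  class(tab) <- c("condition_table", "data.frame")
  tab
}
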