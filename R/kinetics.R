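#' Detect bound ligand-receptor pairs
#'
#' A ligand-receptor pair is bound when its interaction energy is below
#' `-threshold_fraction * epsilon` of its pair potential. Each ligand is
#' matched to at most one receptor and vice versa; when several candidates
#' compete, the lowest-energy pair wins (ties broken by particle index).
#'
#' @param state A `cg_system`.
#' @param threshold_fraction Energy threshold as a fraction of epsilon,
#'   in (0, 1); default 0.5.
#' @return A tibble with columns `ligand`, `receptor` (particle indices),
#'   `pair` (species pair label, e.g. `"AE-AER"`), `energy`.
#' @export
detect_bound_pairs <- function(state, threshold_fraction = 0.5) {
  if (threshold_fraction <= 0 || threshold_fraction >= 1)
    abort("threshold_fraction must lie in (0, 1)")
  en <- encode_system(state)
  res <- cg_detect_cpp(state$pos, en$species, en$sp_sigma, en$sp_mass,
                       en$sp_gamma, en$sp_is2d, en$sp_frozen,
                       en$pair_kind, en$pair_eps, en$pair_sigma, en$pair_rcut,
                       en$pair_n, en$pair_thetac, en$pair_recsp,
                       en$bond_idx, en$bond_L0, en$bond_lp,
                       state$box$lx, state$box$ly, state$box$lz,
                       state$temperature, threshold_fraction)
  lab <- paste0(en$spn[res$type_ligand + 1], "-", en$spn[res$type_receptor + 1])
  tibble(ligand = res$ligand, receptor = res$receptor,
         pair = lab[res$type], energy = res$energy)
}

#' Bound-complex time series
#'
#' Extracts the per-frame bound-complex count for one ligand-receptor pair
#' type from one or several replicate runs (or from a list of system
#' snapshots) and averages across replicates.
#'
#' @param x A `cg_run`, a list of `cg_run` replicates, or a list of
#'   `cg_system` snapshots (then `times` must be given).
#' @param pair Pair type label, e.g. `"L-R"` or `"AE-AER"`. Defaults to the
#'   first angular pair type present.
#' @param times Sample times when `x` is a list of snapshots.
#' @param threshold_fraction Binding threshold for snapshot input.
#' @return A `cg_series`: a tibble with columns `time` and `count`
#'   (replicate-averaged, real-valued), with attributes `n_replicates` and
#'   `replicates` (the per-replicate count matrix).
#' @export
complex_timeseries <- function(x, pair = NULL, times = NULL,
                               threshold_fraction = 0.5) {
  if (inherits(x, "cg_run")) x <- list(x)
  if (!length(x)) abort("empty trajectory")
  if (inherits(x[[1]], "cg_system")) {
    if (length(x) < 2) abort("need at least 2 frames")
    counts <- vapply(x, function(st) {
      bp <- detect_bound_pairs(st, threshold_fraction)
      if (!is.null(pair)) bp <- bp[bp$pair == pair, , drop = FALSE]
      nrow(bp)
    }, numeric(1))
    times <- times %||% seq_along(x) - 1
    return(new_series(times, counts, matrix(counts, ncol = 1), 1L))
  }
  stopifnot(all(vapply(x, inherits, logical(1), "cg_run")))
  pt <- x[[1]]$pair_types
  if (nrow(pt) == 0) abort("run has no angular (binding) pair type")
  lab <- paste0(pt$ligand, "-", pt$receptor)
  pair <- pair %||% lab[1]
  col <- paste0("bound_", sub("-", "_", pair))
  if (!col %in% colnames(x[[1]]$counts))
    abort(sprintf("pair type '%s' not present (have: %s)", pair,
                  paste(lab, collapse = ", ")))
  reps <- vapply(x, function(r) as.numeric(r$counts[, col]),
                 numeric(nrow(x[[1]]$counts)))
  reps <- matrix(reps, ncol = length(x))
  new_series(x[[1]]$samples$time, rowMeans(reps), reps, length(x))
}

new_series <- function(times, counts, replicates, n_replicates, meta = NULL) {
  if (any(diff(times) <= 0)) abort("times must be strictly increasing")
  if (any(counts < 0)) abort("counts must be non-negative")
  s <- tibble(time = times, count = counts)
  class(s) <- c("cg_series", class(s))
  attr(s, "replicates") <- replicates
  attr(s, "n_replicates") <- n_replicates
  attr(s, "meta") <- meta
  s
}

#' A fitted rate constant
#'
#' Container for one estimated rate: point value, standard error, the fit
#' model and window, and the goodness of fit. `tidy()` and `glance()`
#' methods give broom-style summaries.
#'
#' @param value Rate value (1/tau for koff, sigma^3/tau for kon).
#' @param stderr Standard error, same units.
#' @param fit_model `"exp_decay"`, `"short_time_linear"` or `"equilibrium"`.
#' @param fit_window Numeric length-2: (t_min, t_max) of the fitted window.
#' @param gof R-squared of the fit (NA where not applicable).
#' @param n Number of points used.
#' @return An object of class `cg_rate`.
#' @export
rate_estimate <- function(value, stderr, fit_model, fit_window, gof = NA_real_,
                          n = NA_integer_) {
  stopifnot(value >= 0, stderr >= 0 || is.na(stderr))
  structure(list(value = value, stderr = stderr, fit_model = fit_model,
                 fit_window = fit_window, gof = gof, n = n),
            class = "cg_rate")
}

#' @export
print.cg_rate <- function(x, ...) {
  cat(sprintf("<cg_rate> %s: %.4g +/- %.3g (R^2 = %.4f, n = %d, window [%.3g, %.3g])\n",
              x$fit_model, x$value, x$stderr, x$gof, x$n,
              x$fit_window[1], x$fit_window[2]))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname rate_estimate
#' @param x A `cg_rate`.
#' @param ... Unused.
#' @export
tidy.cg_rate <- function(x, ...) {
  tibble(term = "rate", estimate = x$value, std.error = x$stderr)
}

#' @rdname rate_estimate
#' @export
glance.cg_rate <- function(x, ...) {
  tibble(r.squared = x$gof, fit.model = x$fit_model, nobs = x$n,
         window.min = x$fit_window[1], window.max = x$fit_window[2])
}

r_squared <- function(obs, fitted) {
  sst <- sum((obs - mean(obs))^2)
  if (sst == 0) return(1)
  1 - sum((obs - fitted)^2) / sst
}

# leave-one-replicate-out jackknife standard error of an estimator applied
# to the ensemble-averaged series; falls back to NA with < 3 replicates
jackknife_stderr <- function(series, estimator) {
  reps <- attr(series, "replicates")
  if (is.null(reps) || ncol(reps) < 3) return(NA_real_)
  n <- ncol(reps)
  vals <- vapply(seq_len(n), function(k) {
    m <- rowMeans(reps[, -k, drop = FALSE])
    # single-column replicate matrix so the estimator does not re-jackknife
    sub <- new_series(series$time, m, matrix(m, ncol = 1), n - 1L)
    tryCatch(suppressWarnings(estimator(sub)), error = function(e) NA_real_)
  }, numeric(1))
  vals <- vals[is.finite(vals)]
  if (length(vals) < 3) return(NA_real_)
  sqrt((length(vals) - 1) / length(vals) * sum((vals - mean(vals))^2))
}

#' Dissociation rate from an exponential decay
#'
#' Fits `C(t) = C0 * exp(-koff * t)` to a dissociation time series with `C0`
#' fixed to the initial count, by nonlinear least squares. Points after the
#' count first drops below the shot-noise floor (5 complexes) are excluded
#' from the fit.
#'
#' @param series A `cg_series` from a dissociation protocol
#'   (`counts[1] > 0`).
#' @param floor Shot-noise floor: fit uses points until the count falls
#'   below this value (default 5, never excludes the first two points).
#' @return A `cg_rate` with `fit_model = "exp_decay"`.
#' @export
estimate_koff <- function(series, floor = 5) {
  t <- series$time - series$time[1]
  y <- series$count
  if (all(y == 0)) abort("all-zero series: no complexes to fit")
  C0 <- y[1]
  if (C0 <= 0) abort("counts[1] must be positive for a dissociation fit")
  below <- which(y < min(floor, C0))
  keep <- if (length(below)) seq_len(max(2, below[1] - 1)) else seq_along(y)
  tf <- t[keep]; yf <- y[keep]
  if (mean(diff(yf)) >= 0 && yf[length(yf)] >= C0) {
    warn("series does not decay; koff ~ 0")
    return(rate_estimate(0, NA_real_, "exp_decay",
                         range(series$time[keep]), r_squared(yf, yf), length(yf)))
  }
  # log-linear start value on the positive part
  pos <- yf > 0
  k0 <- if (sum(pos) >= 2) {
    sl <- coef(lm(log(yf[pos]) ~ tf[pos]))[2]
    max(-sl, 1e-8)
  } else 1e-3
  fit <- tryCatch(
    nls(yf ~ C0 * exp(-k * tf), start = list(k = k0),
        control = list(maxiter = 200, warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    k <- k0; se <- NA_real_; pred <- C0 * exp(-k * tf)
  } else {
    k <- max(coef(fit)[["k"]], 0)
    se <- tryCatch(sqrt(vcov(fit)[1, 1]), error = function(e) NA_real_)
    pred <- C0 * exp(-k * tf)
  }
  # replicate-level (jackknife) spread dominates the fit covariance
  # whenever an ensemble is available
  sj <- jackknife_stderr(series, function(s) estimate_koff(s, floor)$value)
  se <- suppressWarnings(max(se, sj, na.rm = TRUE))
  rate_estimate(k, if (is.finite(se)) se else NA_real_, "exp_decay",
                range(series$time[keep]), r_squared(yf, pred), length(yf))
}

#' Affinity rate from short-time association kinetics
#'
#' At short times, before dissociation and depletion matter, complex
#' formation grows linearly: `C(t) ~ kon * [L]0 * R_total * t`. The fit is
#' through the origin, restricted to the window where the count stays at or
#' below `window_occupancy` of the total receptor number. Because the true
#' curve already bends towards its plateau inside any finite window, a pure
#' straight line underestimates the initial slope by up to tens of percent;
#' the estimator therefore fits `a*t + b*t^2` through the origin and
#' reports the linear coefficient, which recovers the t = 0 slope to
#' second order (set `curvature = FALSE` for the uncorrected line).
#'
#' @param series A `cg_series` from an association protocol.
#' @param ligand_conc Initial ligand concentration `[L]0` (1/sigma^3).
#' @param receptor_count Total receptor count `R_total` (equivalently
#'   `R_s0 * A`, the surface density times the membrane area).
#' @param window_occupancy Fit window cap as a fraction of `R_total`,
#'   default 0.2.
#' @param curvature Apply the quadratic curvature correction (default TRUE).
#' @return A `cg_rate` with `fit_model = "short_time_linear"`; the rate is
#'   in volume units, sigma^3/tau.
#' @export
estimate_kon_short_time <- function(series, ligand_conc, receptor_count,
                                    window_occupancy = 0.2,
                                    curvature = TRUE) {
  stopifnot(ligand_conc >= 0, receptor_count > 0)
  t <- series$time - series$time[1]
  y <- series$count
  over <- which(y > window_occupancy * receptor_count)
  keep <- if (length(over)) seq_len(max(over[1] - 1, 0)) else seq_along(y)
  if (length(keep) < 3) abort("fewer than 3 points in the short-time window")
  tf <- t[keep]; yf <- y[keep]
  if (curvature && length(keep) >= 5) {
    tf2 <- tf^2
    fit <- lm(yf ~ 0 + tf + tf2)
    slope <- unname(coef(fit)[1])
    se <- sqrt(vcov(fit)[1, 1])
  } else {
    fit <- lm(yf ~ 0 + tf)
    slope <- unname(coef(fit)[1])
    se <- sqrt(vcov(fit)[1, 1])
  }
  denom <- ligand_conc * receptor_count
  kon <- if (denom > 0) max(slope, 0) / denom else 0
  se <- if (denom > 0) se / denom else 0
  sj <- jackknife_stderr(series, function(s)
    estimate_kon_short_time(s, ligand_conc, receptor_count,
                            window_occupancy, curvature)$value)
  se <- suppressWarnings(max(se, sj, na.rm = TRUE))
  rate_estimate(kon, if (is.finite(se)) se else 0, "short_time_linear",
                range(series$time[keep]), r_squared(yf, fitted(fit)),
                length(keep))
}

# plateau check on the final quartile; returns list(ok, c_eq, se)
plateau_stats <- function(series) {
  n <- nrow(series)
  q <- series[series$time >= series$time[1] + 0.75 * (series$time[n] - series$time[1]), ]
  if (nrow(q) < 3) return(list(ok = FALSE, c_eq = NA_real_, se = NA_real_))
  fit <- lm(count ~ time, data = q)
  sl <- coef(fit)[2]; sls <- sqrt(vcov(fit)[2, 2])
  span <- diff(range(q$time))
  m <- mean(q$count)
  ok <- is.finite(sl) && (abs(sl) <= 2 * sls || abs(sl * span) <= 0.1 * max(m, 1))
  # replicate-level uncertainty when available, else autocorrelation-deflated
  reps <- attr(series, "replicates")
  se <- if (!is.null(reps) && ncol(reps) > 1) {
    idx <- series$time >= q$time[1]
    rm <- colMeans(reps[idx, , drop = FALSE])
    sd(rm) / sqrt(length(rm))
  } else sd(q$count) / sqrt(max(nrow(q) / 4, 1))
  list(ok = ok, c_eq = m, se = se)
}

#' Affinity rate from the equilibrium condition
#'
#' At steady state the mass-action balance `kon [L] (R_total - C_eq) =
#' koff C_eq` inverts to `kon = koff * C_eq / ([L] (R_total - C_eq))`.
#' The equilibrium count is the mean over the final quartile of the series,
#' accepted only if that quartile is consistent with a plateau.
#'
#' @param series A `cg_series` that has reached steady state.
#' @param koff A `cg_rate` (or numeric) dissociation rate.
#' @param ligand_conc Free-ligand concentration at equilibrium (1/sigma^3);
#'   at high ligand excess the initial concentration.
#' @param receptor_count Total receptor count.
#' @return A `cg_rate` with `fit_model = "equilibrium"`.
#' @export
estimate_kon_equilibrium <- function(series, koff, ligand_conc,
                                     receptor_count) {
  ps <- plateau_stats(series)
  if (!ps$ok) abort("no plateau detected in the final quartile")
  kv <- if (inherits(koff, "cg_rate")) koff$value else koff
  ks <- if (inherits(koff, "cg_rate")) koff$stderr else NA_real_
  c_eq <- ps$c_eq
  if (c_eq <= 0)
    return(rate_estimate(0, 0, "equilibrium", range(series$time), NA_real_,
                         nrow(series)))
  free <- receptor_count - c_eq
  if (free <= 0) abort("equilibrium count >= total receptors: cannot invert")
  kon <- kv * c_eq / (ligand_conc * free)
  rel2 <- (ps$se * receptor_count / (c_eq * free))^2
  if (is.finite(ks) && kv > 0) rel2 <- rel2 + (ks / kv)^2
  rate_estimate(kon, kon * sqrt(rel2), "equilibrium",
                range(series$time), NA_real_, nrow(series))
}

#' Linear dependence of a rate on the diffusion coefficient
#'
#' Weighted least-squares line through rate-versus-diffusion measurements;
#' in the diffusion-limited regime both affinity and dissociation rates grow
#' linearly with D.
#'
#' @param results A data frame with columns `D` and `value` and optionally
#'   `stderr` (used as inverse-variance weights), or a list of
#'   `(D, cg_rate)` pairs.
#' @return A tibble with `slope`, `slope_stderr`, `intercept`, `r_squared`.
#' @export
rate_vs_diffusion <- function(results) {
  if (!is.data.frame(results)) {
    results <- dplyr::bind_rows(lapply(results, function(p)
      tibble(D = p[[1]], value = p[[2]]$value, stderr = p[[2]]$stderr)))
  }
  if (length(unique(results$D)) < 3)
    abort("need at least 3 distinct diffusion coefficients")
  w <- if ("stderr" %in% names(results) &&
           all(is.finite(results$stderr)) && all(results$stderr > 0))
    1 / results$stderr^2 else rep(1, nrow(results))
  fit <- lm(value ~ D, data = results, weights = w)
  tibble(slope = unname(coef(fit)[2]),
         slope_stderr = sqrt(vcov(fit)[2, 2]),
         intercept = unname(coef(fit)[1]),
         r_squared = summary(fit)$r.squared)
}

#' Intrinsic rate from the transport-limited composition
#'
#' Measured rates compose the intrinsic (reaction) rate with a transport
#' rate `k_T` proportional to the ligand diffusion coefficient:
#' `1/k_meas = 1/k_int + 1/k_T`. This inverts the composition; `k_int >=
#' k_meas` always, diverging in the diffusion-limited limit `k_meas -> k_T`.
#'
#' @param k_meas Measured rate(s), with `0 < k_meas < k_T`.
#' @param k_T Transport rate constant(s).
#' @return Intrinsic rate(s).
#' @export
transport_decomposition <- function(k_meas, k_T) {
  if (any(k_meas <= 0)) abort("k_meas must be positive")
  if (any(k_meas >= k_T))
    abort("k_meas >= k_T is unphysical for the transport composition")
  1 / (1 / k_meas - 1 / k_T)
}
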