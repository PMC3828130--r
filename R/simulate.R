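#' Run replicate simulations for an experiment
#'
#' Builds the experiment's initial configuration and propagates it, once per
#' replicate, each replicate seeded deterministically from the experiment
#' seed (`seed + replicate - 1`). Bound-complex counts are ensemble-averaged
#' into a [complex_timeseries()].
#'
#' @param spec A `cg_experiment`.
#' @param pair Pair type to extract (default: first angular pair).
#' @param record_bonds Record WLC bond extensions (chimera runs).
#' @param ... Passed to [run_dynamics()].
#' @return A list with `series` (a `cg_series`), `runs` metadata tibble
#'   (per replicate: seed, overstretch count, max bond extension), and the
#'   experiment `spec`.
#' @export
simulate_experiment <- function(spec, pair = NULL, record_bonds = FALSE, ...) {
  runs <- vector("list", spec$n_replicates)
  meta <- vector("list", spec$n_replicates)
  for (k in seq_len(spec$n_replicates)) {
    sk <- spec$seed + k - 1
    set.seed(sk)
    st <- switch(spec$protocol,
                 dissociation = build_dissociation(spec),
                 association = build_association(spec),
                 chimera = build_chimera(spec))
    if (spec$equilibration > 0) {
      st <- langevin_step(st, dt = spec$dt, n_steps = spec$equilibration)
      st$time <- 0
    }
    r <- run_dynamics(st, n_steps = spec$n_steps, dt = spec$dt,
                      sample_every = spec$sample_interval,
                      bind_threshold = spec$bind_threshold,
                      record_bonds = record_bonds, ...)
    runs[[k]] <- r
    meta[[k]] <- tibble(replicate = k, seed = sk,
                        n_overstretch = r$n_overstretch,
                        max_bond_x = r$max_bond_x)
  }
  series <- complex_timeseries(runs, pair = pair)
  attr(series, "meta") <- spec
  out <- list(series = series, runs_meta = dplyr::bind_rows(meta),
              spec = spec)
  if (record_bonds) out$bond_r <- lapply(runs, `[[`, "bond_r")
  out
}

#' Dissociation experiment and rate estimate
#'
#' Convenience driver: replicate dissociation runs, ensemble-averaged decay
#' curve, and the exponential-fit dissociation rate.
#'
#' @inheritParams simulate_experiment
#' @return A list with `series`, `koff` (a `cg_rate`) and `spec`.
#' @export
simulate_dissociation <- function(spec, ...) {
  stopifnot(spec$protocol == "dissociation")
  out <- simulate_experiment(spec, ...)
  out$koff <- estimate_koff(out$series)
  out
}

#' Association experiment and rate estimates
#'
#' Replicate association runs plus the short-time (linear-growth) affinity
#' estimate; the equilibrium estimate is added when a plateau is reached and
#' a `koff` is supplied.
#'
#' @inheritParams simulate_experiment
#' @param koff Optional `cg_rate` for the equilibrium estimator.
#' @return A list with `series`, `kon_short`, optionally `kon_equilibrium`,
#'   and `spec`.
#' @export
simulate_association <- function(spec, koff = NULL, ...) {
  stopifnot(spec$protocol == "association")
  out <- simulate_experiment(spec, ...)
  out$kon_short <- estimate_kon_short_time(out$series, spec$ligand_conc,
                                           spec$n_receptors)
  if (!is.null(koff)) {
    out$kon_equilibrium <- tryCatch(
      estimate_kon_equilibrium(out$series, koff, spec$ligand_conc,
                               spec$n_receptors),
      error = function(e) { warn(conditionMessage(e)); NULL })
  }
  out
}

#' Chimera experiment
#'
#' Replicate chimeric-ligand runs; returns the AE-AER occupancy series (the
#' activity readout) and the TE-TER series.
#'
#' @inheritParams simulate_experiment
#' @return A list with `series_ae`, `series_te`, `runs_meta`, `spec`.
#' @export
simulate_chimera <- function(spec, ...) {
  stopifnot(spec$protocol == "chimera")
  runs <- vector("list", spec$n_replicates)
  meta <- vector("list", spec$n_replicates)
  for (k in seq_len(spec$n_replicates)) {
    sk <- spec$seed + k - 1
    set.seed(sk)
    st <- build_chimera(spec)
    if (spec$equilibration > 0) {
      st <- langevin_step(st, dt = spec$dt, n_steps = spec$equilibration)
      st$time <- 0
    }
    r <- run_dynamics(st, n_steps = spec$n_steps, dt = spec$dt,
                      sample_every = spec$sample_interval,
                      bind_threshold = spec$bind_threshold, ...)
    runs[[k]] <- r
    meta[[k]] <- tibble(replicate = k, seed = sk,
                        n_overstretch = r$n_overstretch,
                        max_bond_x = r$max_bond_x)
  }
  series_ae <- complex_timeseries(runs, pair = "AE-AER")
  attr(series_ae, "meta") <- spec
  series_te <- if (spec$n_ter > 0) complex_timeseries(runs, pair = "TE-TER")
               else NULL
  list(series_ae = series_ae, series_te = series_te,
       runs_meta = dplyr::bind_rows(meta), spec = spec)
}
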