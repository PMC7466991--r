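# Exact Gillespie stochastic counterpart: per-genotype birth and death
# events, replicate ensembles and outcome tallies.

#' Event propensities of an integer population
#'
#' Twelve propensities: births per genotype
#' `omega_g * V_g * N * max(0, 1 - N/K)` (with `V_g` from
#' [zygote_production()] on the count vector) and deaths `d_g * n_g`.  The
#' empty population has total propensity zero (absorbing).  Pure-R
#' reference; the simulation loop uses an equivalent compiled kernel tested
#' against it.
#'
#' @param counts per-genotype integer counts (length 6).
#' @param traits trait table from [scenario_traits()].
#' @param scenario a [gdrive_scenario()].
#' @return Named numeric vector of length 12
#'   (`birth_00 ... birth_BB, death_00 ... death_BB`).
#' @export
ssa_propensities <- function(counts, traits, scenario) {
  counts <- .as_state(counts)
  nm <- c(paste0("birth_", gd_genotypes), paste0("death_", gd_genotypes))
  N <- sum(counts)
  if (N <= 0) return(setNames(numeric(12), nm))
  traits <- .as_traits(traits)
  V <- zygote_production(counts, traits, scenario$timing,
                         scenario$c_D, scenario$c_B)
  growth <- N * max(0, 1 - N / scenario$K)
  setNames(c(traits$omega * V * growth, traits$d * counts), nm)
}

#' Run one exact stochastic replicate
#'
#' Gillespie simulation from the rounded wild-type-equilibrium counts plus
#' `drive_intro` drive heterozygotes.  Events are chosen with probability
#' proportional to their propensity and waiting times are exponential in the
#' total rate, with propensities recomputed after every event (exact SSA).
#' The brake release adds `N0B` 0B individuals at the first event boundary
#' where the drive frequency reaches `f_I`; a run ends at extinction or
#' `tmax`.  Counts are integers, so no critical density is needed.
#'
#' @param scenario a [gdrive_scenario()].
#' @param seed RNG seed (one replicate is bitwise reproducible given its
#'   seed); `NULL` uses the current RNG state.
#' @param init optional integer initial counts.
#' @param record_dt if positive, thin a trajectory at this time resolution.
#' @param tmax optional override of the scenario horizon.
#' @param brake logical: allow the brake release event.
#' @return A `gdrive_replicate` list: `seed`, `outcome`, `t_end`,
#'   `brake_time`, `final` counts, `n_events`, and optionally `trajectory`.
#' @export
run_replicate <- function(scenario, seed = NULL, init = NULL,
                          record_dt = 0, tmax = NULL, brake = TRUE) {
  stopifnot(inherits(scenario, "gdrive_scenario"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (is.null(init)) {
    init <- c(round(wt_equilibrium_density(scenario)),
              round(scenario$drive_intro), 0L, 0L, 0L, 0L)
  }
  init <- as.integer(round(init))
  if (any(init < 0)) stop("counts must be non-negative", call. = FALSE)
  if (is.null(tmax)) tmax <- scenario$tmax
  a <- .sc_args(scenario)
  res <- ssa_run_cpp(init, a$omega, a$d, a$beta, a$zygote_timing, a$cD,
                     a$cB, a$K, tmax, brake, scenario$f_I,
                     as.integer(round(scenario$N0B)), record_dt, 4e9)
  final <- setNames(as.numeric(res$final), gd_genotypes)
  out <- list(seed = seed,
              outcome = factor(.classify_final(final, isTRUE(res$brake_fired)),
                               levels = gd_outcomes),
              t_end = res$t_end,
              brake_fired = res$brake_fired,
              brake_time = if (isTRUE(res$brake_fired)) res$brake_time else NA,
              final = final, n_events = res$n_events, reason = res$reason)
  if (record_dt > 0) {
    st <- res$trajectory$states
    colnames(st) <- paste0("n_", gd_genotypes)
    out$trajectory <- data.frame(t = res$trajectory$t, st)
  }
  class(out) <- "gdrive_replicate"
  out
}

#' @export
print.gdrive_replicate <- function(x, ...) {
  cat(sprintf("Stochastic replicate (seed %s): %s at t = %.4g\n",
              if (is.null(x$seed)) "<current RNG>" else x$seed,
              as.character(x$outcome), x$t_end))
  cat("  final counts:", paste(sprintf("%s=%d", gd_genotypes,
                                       as.integer(x$final)), collapse = " "),
      "\n")
  invisible(x)
}

#' Simulate a replicate ensemble of a scenario
#'
#' Independent exact-SSA replicates with per-replicate seeds derived as
#' `seed + replicate - 1`, so a given `(scenario, seed)` pair yields an
#' identical ensemble on every run regardless of execution order.
#'
#' @param object a [gdrive_scenario()].
#' @param nsim number of replicates.
#' @param seed base seed; defaults to the scenario's `seed` field, or a
#'   random one drawn from the current RNG.
#' @param tmax,record_dt,brake passed to [run_replicate()].
#' @param ... unused.
#' @return A `gdrive_ensemble`: data frame of per-replicate results
#'   (`replicate`, `seed`, `outcome`, `t_end`, `brake_time`, final counts)
#'   with the outcome tally in attribute `tally`.
#' @examples
#' sc <- gdrive_scenario(N_star = 200, tmax = 50)
#' ens <- simulate(sc, nsim = 5, seed = 1)
#' outcome_tally(ens)
#' @export
simulate.gdrive_scenario <- function(object, nsim = 1, seed = NULL,
                                     tmax = NULL, record_dt = 0,
                                     brake = TRUE, ...) {
  if (is.null(seed)) seed <- object$seed
  if (is.null(seed)) seed <- sample.int(2^30, 1)
  seed <- as.integer(seed)
  stopifnot(nsim >= 1)
  reps <- vector("list", nsim)
  for (i in seq_len(nsim))
    reps[[i]] <- run_replicate(object, seed = seed + i - 1L,
                               record_dt = record_dt, tmax = tmax,
                               brake = brake)
  fin <- do.call(rbind, lapply(reps, function(r) r$final))
  colnames(fin) <- paste0("n_", gd_genotypes)
  out <- data.frame(replicate = seq_len(nsim),
                    seed = seed + seq_len(nsim) - 1L,
                    outcome = factor(vapply(reps, function(r)
                      as.character(r$outcome), character(1)),
                      levels = gd_outcomes),
                    t_end = vapply(reps, `[[`, numeric(1), "t_end"),
                    brake_time = vapply(reps, function(r)
                      as.numeric(r$brake_time), numeric(1)),
                    fin)
  if (record_dt > 0)
    attr(out, "trajectories") <- lapply(reps, `[[`, "trajectory")
  attr(out, "scenario") <- object
  attr(out, "base_seed") <- seed
  attr(out, "tally") <- table(out$outcome) / nsim
  class(out) <- c("gdrive_ensemble", "data.frame")
  out
}

#' Outcome tally of an ensemble
#'
#' @param ensemble a `gdrive_ensemble` from [simulate.gdrive_scenario()].
#' @return Data frame with columns `outcome`, `count`, `frequency`
#'   (frequencies sum to 1).
#' @export
outcome_tally <- function(ensemble) {
  stopifnot(inherits(ensemble, "gdrive_ensemble"))
  tab <- table(ensemble$outcome)
  data.frame(outcome = names(tab), count = as.integer(tab),
             frequency = as.numeric(tab) / nrow(ensemble))
}

#' @export
print.gdrive_ensemble <- function(x, ...) {
  cat(sprintf("Stochastic ensemble: %d replicates (base seed %d)\n",
              nrow(x), attr(x, "base_seed")))
  tl <- outcome_tally(x)
  tl <- tl[tl$count > 0, ]
  for (i in seq_len(nrow(tl)))
    cat(sprintf("  %-24s %5d  (%.3f)\n", tl$outcome[i], tl$count[i],
                tl$frequency[i]))
  invisible(x)
}
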