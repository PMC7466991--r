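# Deterministic genotype-density dynamics and outcome classification.

#' Right-hand side of the genotype-density dynamics
#'
#' `dN_g/dt = omega_g V_g N (1 - N/K) - d_g N_g`, with the zygote production
#' terms `V_g` from [zygote_production()].  The birth term is clamped at zero
#' when `N >= K` (negative birth rates are unphysical and would break the
#' stochastic analogue); the empty population is absorbing (all-zero
#' derivative).  This is the pure-R reference implementation; the integrator
#' uses an equivalent compiled kernel which is tested against it.
#'
#' @param state per-genotype densities (length 6, genotype order).
#' @param traits trait table from [scenario_traits()].
#' @param scenario a [gdrive_scenario()] supplying `timing`, `c_D`, `c_B`
#'   and `K`.
#' @return Named derivative vector of length 6.
#' @export
ode_rhs <- function(state, traits, scenario) {
  state <- .as_state(state)
  N <- sum(state)
  if (N <= 0) return(setNames(numeric(6), gd_genotypes))
  traits <- .as_traits(traits)
  V <- zygote_production(state, traits, scenario$timing,
                         scenario$c_D, scenario$c_B)
  growth <- N * max(0, 1 - N / scenario$K)
  setNames(traits$omega * V * growth - traits$d * state, gd_genotypes)
}

#' Allele frequencies and Hardy-Weinberg deviations of a state
#'
#' `p_D = (N_DD + N_0D/2 + N_DB/2)/N` and analogously for `p_B`;
#' `delta_0D = N_0D/N - 2 p_D p_0` and analogously for the other
#' heterozygotes.
#'
#' @param state per-genotype densities or counts (length 6).
#' @return Named vector `N, p_0, p_D, p_B, delta_0D, delta_0B, delta_DB`.
#' @export
summarize_state <- function(state) {
  state <- .as_state(state)
  N <- sum(state)
  if (N <= 0)
    stop("allele frequencies are undefined for an extinct population; ",
         "branch on extinction before summarising", call. = FALSE)
  p <- drop(state %*% .allele_copies) / (2 * N)
  c(N = N, p_0 = p[["0"]], p_D = p[["D"]], p_B = p[["B"]],
    delta_0D = state[["0D"]] / N - 2 * p[["D"]] * p[["0"]],
    delta_0B = state[["0B"]] / N - 2 * p[["B"]] * p[["0"]],
    delta_DB = state[["DB"]] / N - 2 * p[["D"]] * p[["B"]])
}

#' Integrate a scenario's deterministic dynamics
#'
#' Fixed-step explicit Euler advance of the genotype-density system.  After
#' every step, any genotype density below the critical value `thr` is set to
#' zero (with `thr = 0` the truncation is disabled and the run is the pure
#' infinite-population model).  The brake release fires once, at the first
#' step boundary where the drive allele frequency reaches `f_I`, instantly
#' adding `N0B` wild-type/brake heterozygotes.  The run ends at `tmax` or at
#' total extinction.
#'
#' @param scenario a [gdrive_scenario()].
#' @param init optional initial state; defaults to [initial_state()].
#' @param dt,thr,tmax optional overrides of the scenario's integrator
#'   settings.
#' @param record_every record every this many steps (default: about one
#'   record per 0.5 time units, at least every step).
#' @param brake logical: allow the brake release event (default `TRUE`).
#' @return A `gdrive_trajectory`: data frame with columns `t`, the six
#'   genotype densities `N_00 ... N_BB`, `N`, `p_D`, `p_B`, `delta_0D`,
#'   `delta_0B`, `delta_DB` (frequency columns are `NA` after extinction),
#'   with the event log in attributes `events` (brake time, first-zero times
#'   per genotype, stop reason) and the scenario in attribute `scenario`.
#' @examples
#' sc <- gdrive_scenario(N_star = 1000, tmax = 100)
#' tr <- run_deterministic(sc)
#' tail(tr, 2)
#' @export
run_deterministic <- function(scenario, init = NULL, dt = NULL, thr = NULL,
                              tmax = NULL, record_every = NULL, brake = TRUE) {
  stopifnot(inherits(scenario, "gdrive_scenario"))
  if (is.null(init)) init <- initial_state(scenario)
  init <- .as_state(init)
  dt <- if (is.null(dt)) scenario$dt else dt
  thr <- if (is.null(thr)) scenario$thr else thr
  tmax <- if (is.null(tmax)) scenario$tmax else tmax
  if (is.null(record_every)) record_every <- max(1L, round(0.5 / dt))
  a <- .sc_args(scenario)
  res <- euler_integrate_cpp(init, a$omega, a$d, a$beta, a$zygote_timing,
                             a$cD, a$cB, a$K, dt, thr, tmax,
                             brake, scenario$f_I, scenario$N0B,
                             as.integer(record_every))
  if (res$reason == "nonfinite")
    stop("integration produced non-finite densities; reduce `dt`",
         call. = FALSE)
  st <- res$states
  colnames(st) <- paste0("N_", gd_genotypes)
  N <- rowSums(st)
  pos <- N > 0
  p <- matrix(NA_real_, nrow(st), 3, dimnames = list(NULL, gd_alleles))
  p[pos, ] <- (st[pos, , drop = FALSE] %*% .allele_copies) / (2 * N[pos])
  delta_0D <- delta_0B <- delta_DB <- rep(NA_real_, nrow(st))
  delta_0D[pos] <- st[pos, "N_0D"] / N[pos] - 2 * p[pos, "D"] * p[pos, "0"]
  delta_0B[pos] <- st[pos, "N_0B"] / N[pos] - 2 * p[pos, "B"] * p[pos, "0"]
  delta_DB[pos] <- st[pos, "N_DB"] / N[pos] - 2 * p[pos, "D"] * p[pos, "B"]
  out <- data.frame(t = res$t, st, N = N, p_D = p[, "D"], p_B = p[, "B"],
                    delta_0D = delta_0D, delta_0B = delta_0B,
                    delta_DB = delta_DB)
  attr(out, "events") <- list(
    brake_fired = res$brake_fired,
    brake_time = res$brake_time,
    first_zero = setNames(as.numeric(res$first_zero), gd_genotypes),
    reason = res$reason,
    final = setNames(as.numeric(res$final), gd_genotypes),
    t_end = res$t_end)
  attr(out, "scenario") <- scenario
  class(out) <- c("gdrive_trajectory", "data.frame")
  out
}

#' @export
print.gdrive_trajectory <- function(x, ...) {
  ev <- attr(x, "events")
  cat(sprintf("Deterministic trajectory: %d records, t in [%g, %g]\n",
              nrow(x), x$t[1], ev$t_end))
  if (isTRUE(ev$brake_fired))
    cat(sprintf("  brake released at t = %g\n", ev$brake_time))
  else cat("  brake never released\n")
  cat(sprintf("  end: %s; outcome: %s\n", ev$reason,
              classify_outcome(x)))
  invisible(x)
}

#' @export
summary.gdrive_trajectory <- function(object, ...) {
  ev <- attr(object, "events")
  fin <- ev$final
  out <- list(outcome = classify_outcome(object),
              brake_time = if (isTRUE(ev$brake_fired)) ev$brake_time else NA,
              t_end = ev$t_end, final_state = fin,
              final_N = sum(fin))
  cat("Outcome:", as.character(out$outcome), "\n")
  cat("Final state (densities):\n")
  print(round(fin, 4))
  invisible(out)
}

#' Plot allele frequencies and scaled population size along a trajectory
#'
#' @param x a `gdrive_trajectory`.
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.gdrive_trajectory <- function(x, ...) {
  sc <- attr(x, "scenario")
  Nstar <- wt_equilibrium_density(sc)
  graphics::matplot(x$t, cbind(1 - x$p_D - x$p_B, x$p_D, x$p_B, x$N / Nstar),
                    type = "l", lty = c(1, 1, 1, 2),
                    col = c("steelblue", "firebrick", "darkorange", "black"),
                    xlab = "time", ylab = "allele frequency / scaled N", ...)
  ev <- attr(x, "events")
  if (isTRUE(ev$brake_fired)) graphics::abline(v = ev$brake_time, lty = 3)
  graphics::legend("topright", c("p_0", "p_D", "p_B", "N / N*"),
                   lty = c(1, 1, 1, 2),
                   col = c("steelblue", "firebrick", "darkorange", "black"),
                   bty = "n")
  invisible(x)
}

# shared decision tree on a final state + brake flag (densities or counts)
.classify_final <- function(final, fired) {
  tot <- sum(final)
  if (tot == 0)
    return(if (fired) "extinction_after_brake" else "extinction_before_brake")
  drive <- (final[["0D"]] + final[["DD"]] + final[["DB"]]) > 0
  brake <- (final[["0B"]] + final[["DB"]] + final[["BB"]]) > 0
  wt <- (final[["00"]] + final[["0D"]] + final[["0B"]]) > 0
  if (!drive && !brake && wt)
    return(if (fired) "wt_recovery" else "drive_loss_before_brake")
  if (!drive && brake && wt) return("coexist_wt_brake")
  if (drive && brake && wt) return("coexist_wt_drive_brake")
  "undetermined_at_tmax"
}

#' Classify the terminal outcome of a run
#'
#' Decision tree on the final state and the event log: total extinction maps
#' to `extinction_before_brake`/`extinction_after_brake` depending on whether
#' the brake was released; a wild-type-only final state maps to
#' `wt_recovery` (or `drive_loss_before_brake` if the drive vanished before
#' the release); wild type plus brake without drive is `coexist_wt_brake`;
#' all three alleles present is `coexist_wt_drive_brake`; anything else is
#' reported honestly as `undetermined_at_tmax`.
#'
#' @param traj a `gdrive_trajectory` (or an object with the same `events`
#'   attribute contract).
#' @return A factor of length 1 with levels `gd_outcomes`.
#' @export
classify_outcome <- function(traj) {
  ev <- attr(traj, "events")
  if (is.null(ev) || nrow(traj) == 0)
    stop("`traj` must be a non-empty trajectory with an event log",
         call. = FALSE)
  factor(.classify_final(ev$final, isTRUE(ev$brake_fired)),
         levels = gd_outcomes)
}
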