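# The factorial scenario grid and introduction-frequency sweeps.

#' Enumerate the factorial scenario grid
#'
#' Full factorial over conversion timing, targeted trait, dominance and
#' brake kind; the default levels give the 24 standard combinations
#' (2 timings x 3 traits x 2 dominance values x 2 brake kinds).  Ordering is
#' stable: timing-major, then trait, dominance, brake kind.  A combination
#' whose standardisation is infeasible is returned as an error entry rather
#' than silently dropped.
#'
#' @param base a [gdrive_scenario()] supplying every non-factorial
#'   parameter; default [gdrive_scenario()].
#' @param timings,traits,dominance,brake_kinds factor levels.
#' @return A named list of `gdrive_scenario` objects (or `try-error`
#'   entries), names being scenario ids such as
#'   `"germline_omega_h0_universal"`.
#' @export
scenario_grid <- function(base = gdrive_scenario(),
                          timings = c("germline", "zygote"),
                          traits = c("omega", "d", "beta"),
                          dominance = c(0, 0.5),
                          brake_kinds = c("universal", "specific")) {
  stopifnot(inherits(base, "gdrive_scenario"))
  out <- list()
  for (ti in timings) for (tr in traits) for (h in dominance)
    for (bk in brake_kinds) {
      id <- sprintf("%s_%s_h%s_%s", ti, tr, format(h), bk)
      out[[id]] <- tryCatch(
        .sc_modify(base, timing = ti, targeted_trait = tr, h = h,
                   brake_kind = bk),
        error = function(e) structure(conditionMessage(e),
                                      class = "try-error"))
    }
  out
}

#' Sweep the brake-introduction frequency of a scenario
#'
#' For each value of `f_I`, runs a stochastic ensemble and (optionally) one
#' deterministic integration, and reports the outcome frequencies in long
#' form.  Deterministic and stochastic runs share the scenario but not
#' randomness.
#'
#' @param scenario a [gdrive_scenario()].
#' @param f_I introduction frequencies in `(0, 1)` (default
#'   `seq(0.1, 0.9, by = 0.1)`).
#' @param n_reps stochastic replicates per `f_I`.
#' @param base_seed base RNG seed; per-`f_I` blocks use
#'   `base_seed + (block - 1) * n_reps`.
#' @param deterministic also run the thresholded integrator per `f_I`.
#' @param tmax optional horizon override.
#' @return Data frame with columns `scenario_id`, `timing`, `trait`, `h`,
#'   `brake_kind`, `f_I`, `outcome`, `count`, `frequency`,
#'   `deterministic_label`, `n_reps`, `base_seed`.
#' @export
sweep_introduction <- function(scenario, f_I = seq(0.1, 0.9, by = 0.1),
                               n_reps = 100, base_seed = 1,
                               deterministic = TRUE, tmax = NULL) {
  stopifnot(inherits(scenario, "gdrive_scenario"))
  if (any(f_I <= 0 | f_I >= 1)) stop("`f_I` values must lie in (0, 1)",
                                     call. = FALSE)
  id <- sprintf("%s_%s_h%s_%s", scenario$timing, scenario$targeted_trait,
                format(scenario$h), scenario$brake_kind)
  rows <- vector("list", length(f_I))
  for (i in seq_along(f_I)) {
    sc <- .sc_modify(scenario, f_I = f_I[i])
    if (!is.null(tmax)) sc$tmax <- tmax
    ens <- simulate(sc, nsim = n_reps,
                    seed = base_seed + (i - 1L) * n_reps)
    tl <- outcome_tally(ens)
    det <- NA_character_
    if (deterministic)
      det <- as.character(classify_outcome(run_deterministic(sc)))
    rows[[i]] <- data.frame(scenario_id = id, timing = scenario$timing,
                            trait = scenario$targeted_trait, h = scenario$h,
                            brake_kind = scenario$brake_kind, f_I = f_I[i],
                            outcome = tl$outcome, count = tl$count,
                            frequency = tl$frequency,
                            deterministic_label = det, n_reps = n_reps,
                            base_seed = base_seed)
  }
  do.call(rbind, rows)
}

#' Trend of wild-type recovery with introduction frequency
#'
#' Sign of the Spearman rank correlation between `f_I` and the wild-type
#' recovery frequency, per scenario.  A descriptive summary: recovery often,
#' but not universally, becomes less likely the later the brake is
#' introduced.
#'
#' @param rows output of [sweep_introduction()] (possibly several scenarios
#'   row-bound together).
#' @return Data frame with columns `scenario_id`, `trend`
#'   (`"decreasing"`, `"increasing"` or `"flat"`), `rho`.
#' @export
wt_recovery_trend <- function(rows) {
  stopifnot(all(c("scenario_id", "f_I", "outcome", "frequency")
                %in% names(rows)))
  out <- lapply(split(rows, rows$scenario_id), function(d) {
    rec <- d[d$outcome == "wt_recovery", c("f_I", "frequency")]
    if (length(unique(rec$f_I)) < 2)
      stop("need at least two f_I values per scenario", call. = FALSE)
    rho <- suppressWarnings(cor(rec$f_I, rec$frequency, method = "spearman"))
    trend <- if (is.na(rho) || rho == 0) "flat"
             else if (rho < 0) "decreasing" else "increasing"
    data.frame(scenario_id = d$scenario_id[1], trend = trend, rho = rho)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
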