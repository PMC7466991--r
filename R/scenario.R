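# Scenario configuration: the full parameter bundle of a drive/brake run.

#' Define a drive/brake scenario
#'
#' Bundles every parameter of a run: conversion probabilities, dominance,
#' conversion timing, the fitness trait targeted by drive and brake, the
#' brake type, demographic baseline, carrying capacity, introduction
#' settings and integrator settings.  The drive homozygote's value of the
#' targeted trait is standardised so that
#' `d_DD / (omega_DD * beta_DD^2) = drive_ratio`; with `drive_ratio > 1` a
#' 100% drive population is not viable (an eradication drive).
#'
#' @param c_D,c_B probabilities of successful gene conversion by the drive
#'   and the brake, in `[0, 1]`.
#' @param h shared dominance coefficient of drive and brake costs.
#' @param timing `"germline"` or `"zygote"` gene conversion.
#' @param targeted_trait the fitness component carried by the drive cost:
#'   `"omega"` (zygote survival), `"d"` (adult death rate) or `"beta"`
#'   (fecundity).
#' @param brake_kind `"universal"` (no fitness restoration: the brake
#'   homozygote has the drive homozygote's traits) or `"specific"`
#'   (a recoded cargo restores a fraction `restoration` of the drive's
#'   deficit on the targeted trait, leaving a small residual cost).
#' @param omega00,d00,beta00 wild-type homozygote traits.
#' @param drive_ratio standardised eradication strength
#'   `d_DD / (omega_DD * beta_DD^2)`; must exceed 1.
#' @param restoration fraction in `(0, 1)` of the wild-type/drive trait gap
#'   recovered by a specific brake (ignored for universal brakes).
#' @param K carrying capacity of the logistic birth term.  Default `NULL`
#'   derives `K` from `N_star` so that the wild-type-only equilibrium
#'   `K (1 - d00 / (omega00 beta00^2))` equals `N_star`.
#' @param N_star target wild-type equilibrium density used when `K` is
#'   `NULL` (default 10000).
#' @param f_I drive allele frequency at which the brake release is
#'   triggered, in `(0, 1)`.
#' @param N0B number of wild-type/brake heterozygotes released at the
#'   trigger (default 100).
#' @param drive_intro number of drive heterozygotes added to the wild-type
#'   equilibrium at time 0 (default 100).
#' @param dt fixed integration step of the deterministic solver.
#' @param thr critical density below which a genotype is set to zero in the
#'   deterministic solver (`0` disables truncation).
#' @param tmax time horizon.
#' @param seed optional default RNG seed for stochastic runs.
#' @return An object of class `gdrive_scenario`.
#' @examples
#' sc <- gdrive_scenario()
#' scenario_traits(sc)
#' @export
gdrive_scenario <- function(c_D = 0.95, c_B = 0.95, h = 0,
                            timing = c("germline", "zygote"),
                            targeted_trait = c("omega", "d", "beta"),
                            brake_kind = c("universal", "specific"),
                            omega00 = 1, d00 = 0.1, beta00 = 1,
                            drive_ratio = 1.1, restoration = 0.95,
                            K = NULL, N_star = 10000,
                            f_I = 0.5, N0B = 100, drive_intro = 100,
                            dt = 0.005, thr = 0.01, tmax = 25000,
                            seed = NULL) {
  .check_prob(c_D, "c_D")
  .check_prob(c_B, "c_B")
  .check_prob(h, "h")
  timing <- match.arg(timing)
  targeted_trait <- match.arg(targeted_trait)
  brake_kind <- match.arg(brake_kind)
  num1 <- function(x, name, lo = -Inf, strict = TRUE) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
        (strict && x <= lo) || (!strict && x < lo))
      stop(sprintf("`%s` must be a single number %s %s", name,
                   if (strict) ">" else ">=", lo), call. = FALSE)
    as.numeric(x)
  }
  omega00 <- num1(omega00, "omega00", 0)
  if (omega00 > 1) stop("`omega00` must lie in (0, 1]", call. = FALSE)
  d00 <- num1(d00, "d00", 0)
  beta00 <- num1(beta00, "beta00", 0)
  drive_ratio <- num1(drive_ratio, "drive_ratio", 1)
  restoration <- num1(restoration, "restoration", 0)
  if (restoration >= 1)
    stop("`restoration` must lie in (0, 1): a specific brake keeps a small ",
         "residual cost relative to wild type", call. = FALSE)
  wt_growth <- 1 - d00 / (omega00 * beta00^2)
  if (wt_growth <= 0)
    stop("wild-type population not viable: need d00 < omega00 * beta00^2",
         call. = FALSE)
  if (is.null(K)) {
    N_star <- num1(N_star, "N_star", 0)
    K <- N_star / wt_growth
  } else {
    K <- num1(K, "K", 0)
  }
  f_I <- num1(f_I, "f_I", 0)
  if (f_I >= 1) stop("`f_I` must lie in (0, 1)", call. = FALSE)
  N0B <- num1(N0B, "N0B", 0, strict = FALSE)
  drive_intro <- num1(drive_intro, "drive_intro", 0, strict = FALSE)
  dt <- num1(dt, "dt", 0)
  thr <- num1(thr, "thr", 0, strict = FALSE)
  tmax <- num1(tmax, "tmax", 0)
  if (!is.null(seed)) seed <- as.integer(seed)

  sc <- list(c_D = c_D, c_B = c_B, h = h, timing = timing,
             targeted_trait = targeted_trait, brake_kind = brake_kind,
             omega00 = omega00, d00 = d00, beta00 = beta00,
             drive_ratio = drive_ratio, restoration = restoration,
             K = K, f_I = f_I, N0B = N0B, drive_intro = drive_intro,
             dt = dt, thr = thr, tmax = tmax, seed = seed)
  class(sc) <- "gdrive_scenario"
  # fail early if the standardisation is infeasible
  scenario_traits(sc)
  sc
}

#' Wild-type-only equilibrium density of a scenario
#'
#' Closed form `K (1 - d00 / (omega00 * beta00^2))`.
#'
#' @param scenario a [gdrive_scenario()].
#' @return A single density.
#' @export
wt_equilibrium_density <- function(scenario) {
  stopifnot(inherits(scenario, "gdrive_scenario"))
  scenario$K * (1 - scenario$d00 / (scenario$omega00 * scenario$beta00^2))
}

#' Trait table implied by a scenario
#'
#' Solves the eradication standardisation for the drive homozygote on the
#' targeted trait (all other traits equal across genotypes), sets the brake
#' homozygote according to the brake kind, and fills heterozygotes via
#' [heterozygote_traits()].
#'
#' @param scenario a [gdrive_scenario()].
#' @return Data frame with columns `genotype`, `omega`, `d`, `beta`.
#' @export
scenario_traits <- function(scenario) {
  stopifnot(inherits(scenario, "gdrive_scenario"))
  base <- c(omega = scenario$omega00, d = scenario$d00, beta = scenario$beta00)
  r <- scenario$drive_ratio
  dd <- base
  dd[[scenario$targeted_trait]] <- switch(scenario$targeted_trait,
    omega = scenario$d00 / (r * scenario$beta00^2),
    d     = r * scenario$omega00 * scenario$beta00^2,
    beta  = sqrt(scenario$d00 / (r * scenario$omega00)))
  if (scenario$targeted_trait == "omega" &&
      (dd[["omega"]] <= 0 || dd[["omega"]] > 1))
    stop("infeasible standardisation: required omega_DD outside (0, 1]",
         call. = FALSE)
  bb <- dd
  if (scenario$brake_kind == "specific") {
    tt <- scenario$targeted_trait
    bb[[tt]] <- dd[[tt]] + scenario$restoration * (base[[tt]] - dd[[tt]])
  }
  heterozygote_traits(base, dd, bb, scenario$h)
}

#' Default initial state of a scenario
#'
#' The wild-type-only equilibrium density plus `drive_intro` drive
#' heterozygotes.
#'
#' @param scenario a [gdrive_scenario()].
#' @return Named density vector in genotype order.
#' @export
initial_state <- function(scenario) {
  stopifnot(inherits(scenario, "gdrive_scenario"))
  n <- setNames(numeric(6), gd_genotypes)
  n[["00"]] <- wt_equilibrium_density(scenario)
  n[["0D"]] <- scenario$drive_intro
  n
}

#' @export
print.gdrive_scenario <- function(x, ...) {
  cat("Drive/brake scenario\n")
  cat(sprintf("  conversion: c_D = %.3g, c_B = %.3g (%s timing)\n",
              x$c_D, x$c_B, x$timing))
  cat(sprintf("  costs on %s, dominance h = %.3g, %s brake",
              x$targeted_trait, x$h, x$brake_kind))
  if (x$brake_kind == "specific")
    cat(sprintf(" (restoration %.3g)", x$restoration))
  cat("\n")
  cat(sprintf("  eradication ratio d_DD/(omega_DD beta_DD^2) = %.3g\n",
              x$drive_ratio))
  cat(sprintf("  K = %.6g, WT equilibrium N* = %.6g\n",
              x$K, wt_equilibrium_density(x)))
  cat(sprintf("  introductions: %g 0D at t = 0; %g 0B when p_D >= %.3g\n",
              x$drive_intro, x$N0B, x$f_I))
  cat(sprintf("  numerics: dt = %g, thr = %g, tmax = %g\n",
              x$dt, x$thr, x$tmax))
  invisible(x)
}

#' @export
summary.gdrive_scenario <- function(object, ...) {
  tr <- scenario_traits(object)
  print(object)
  cat("Genotype traits:\n")
  print(tr, row.names = FALSE, digits = 4)
  invisible(list(scenario = object, traits = tr))
}

# internal: numeric argument bundle for the C++ kernels
.sc_args <- function(scenario, traits = NULL) {
  if (is.null(traits)) traits <- scenario_traits(scenario)
  list(omega = traits$omega, d = traits$d, beta = traits$beta,
       zygote_timing = scenario$timing == "zygote",
       cD = scenario$c_D, cB = scenario$c_B, K = scenario$K)
}

# internal: shallow-modify a scenario with revalidation
.sc_modify <- function(scenario, ...) {
  args <- scenario[setdiff(names(scenario), character())]
  class(args) <- NULL
  args <- modifyList(args, list(...))
  do.call(gdrive_scenario, args)
}
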