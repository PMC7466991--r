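# Boundary equilibria, numerical Jacobian stability, drive classification
# and the invasion-threshold finder.
#
# The model is re-expressed in total density N, allele frequencies and
# Hardy-Weinberg deviations; the reduced right-hand sides are obtained from
# the density system by the chain rule, so no symbolic algebra is needed.

# frequencies of (00, 0D, DD) implied by reduced coordinates (p_D, delta_0D)
.freqs2 <- function(pD, delta) {
  pD <- unname(pD); delta <- unname(delta)
  c(f00 = (1 - pD)^2 - delta / 2,
    f0D = 2 * pD * (1 - pD) + delta,
    fDD = pD^2 - delta / 2)
}

# reduced two-allele RHS in u = (N, p_D, delta_0D); brake classes absent
.reduced_rhs2 <- function(u, traits, scenario) {
  u <- unname(u)
  N <- u[1]; pD <- u[2]; delta <- u[3]
  f <- .freqs2(pD, delta)
  n <- c(f[["f00"]], f[["f0D"]], f[["fDD"]], 0, 0, 0) * N
  dn <- density_rhs_cpp(n, traits$omega, traits$d, traits$beta,
                        scenario$timing == "zygote", scenario$c_D,
                        scenario$c_B, scenario$K)
  dN <- sum(dn)
  dpD <- ((dn[3] + 0.5 * dn[2]) - pD * dN) / N
  df0D <- (dn[2] - f[["f0D"]] * dN) / N
  ddelta <- df0D - 2 * (dpD * (1 - pD) + pD * (-dpD))
  c(dN, dpD, ddelta)
}

# two-allele frequency dynamics in the vanishing-density limit (N -> 0, the
# logistic factor tends to 1); coordinates v = (p_D, delta_0D).  This is the
# system in which the drive-only boundary of an eradication drive lives.
.freq_rhs2 <- function(v, traits, scenario) {
  f <- .freqs2(v[1], v[2])
  n <- c(f[["f00"]], f[["f0D"]], f[["fDD"]], 0, 0, 0)
  # per-capita rates with the logistic factor effectively 1 (N = 1, K huge)
  g <- density_rhs_cpp(n, traits$omega, traits$d, traits$beta,
                       scenario$timing == "zygote", scenario$c_D,
                       scenario$c_B, 1e12)
  dn <- g - n * sum(g)
  dpD <- dn[3] + 0.5 * dn[2]
  ddelta <- dn[2] - 2 * (dpD * (1 - v[1]) + v[1] * (-dpD))
  c(dpD, ddelta)
}

# reduced three-allele RHS in u = (N, p_D, p_B, d_0D, d_0B, d_DB)
.reduced_rhs3 <- function(u, traits, scenario) {
  u <- unname(u)
  N <- u[1]; pD <- u[2]; pB <- u[3]
  d0D <- u[4]; d0B <- u[5]; dDB <- u[6]
  p0 <- 1 - pD - pB
  f0D <- 2 * p0 * pD + d0D
  f0B <- 2 * p0 * pB + d0B
  fDB <- 2 * pD * pB + dDB
  fDD <- pD - f0D / 2 - fDB / 2
  fBB <- pB - f0B / 2 - fDB / 2
  f00 <- 1 - f0D - f0B - fDB - fDD - fBB
  n <- c(f00, f0D, fDD, f0B, fDB, fBB) * N
  dn <- density_rhs_cpp(n, traits$omega, traits$d, traits$beta,
                        scenario$timing == "zygote", scenario$c_D,
                        scenario$c_B, scenario$K)
  dN <- sum(dn)
  dpD <- ((dn[3] + 0.5 * dn[2] + 0.5 * dn[5]) - pD * dN) / N
  dpB <- ((dn[6] + 0.5 * dn[4] + 0.5 * dn[5]) - pB * dN) / N
  dp0 <- -dpD - dpB
  dd0D <- (dn[2] - f0D * dN) / N - 2 * (dpD * p0 + pD * dp0)
  dd0B <- (dn[4] - f0B * dN) / N - 2 * (dpB * p0 + pB * dp0)
  ddDB <- (dn[5] - fDB * dN) / N - 2 * (dpD * pB + pD * dpB)
  c(dN, dpD, dpB, dd0D, dd0B, ddDB)
}

# central-difference Jacobian
.num_jacobian <- function(fn, u, h = NULL) {
  m <- length(fn(u))
  J <- matrix(0, m, length(u))
  for (j in seq_along(u)) {
    hj <- if (is.null(h)) 1e-6 * max(1, abs(u[j])) else h
    up <- u; up[j] <- up[j] + hj
    um <- u; um[j] <- um[j] - hj
    J[, j] <- (fn(up) - fn(um)) / (2 * hj)
  }
  J
}

.stability_verdict <- function(ev, eps = 1e-7) {
  re <- Re(ev)
  if (all(re < -eps)) "stable"
  else if (any(re > eps)) "unstable"
  else "marginal"
}

.stability_report <- function(ev, eps = 1e-7, resolved_by = "jacobian") {
  out <- list(eigenvalues = ev,
              verdict = .stability_verdict(ev, eps),
              eps = eps, resolved_by = resolved_by)
  out$stable <- out$verdict == "stable"
  class(out) <- "stability_report"
  out
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Stability: %s (resolved by %s)\n", x$verdict, x$resolved_by))
  cat("  eigenvalue real parts:",
      paste(signif(Re(x$eigenvalues), 4), collapse = ", "), "\n")
  invisible(x)
}

#' Boundary equilibria of the two-allele (no brake) model
#'
#' The wild-type-only equilibrium `(N = K (1 - d00/(omega00 beta00^2)),
#' p_D = 0, delta_0D = 0)` and, for an eradication drive, the drive-only
#' equilibrium `(N = 0, p_D = 1, delta_0D = 0)`.  Residual norms of the
#' reduced right-hand side are reported (the drive-only point is checked in
#' the vanishing-density frequency system, where its coordinates are
#' well defined).
#'
#' @param scenario a [gdrive_scenario()] (its brake fields are ignored).
#' @return List with elements `wt` and `drive`, each a list with `N`, `p_D`,
#'   `delta_0D` and `residual`.
#' @export
boundary_equilibria <- function(scenario) {
  stopifnot(inherits(scenario, "gdrive_scenario"))
  traits <- scenario_traits(scenario)
  Nstar <- wt_equilibrium_density(scenario)
  if (Nstar <= 0)
    stop("wild-type equilibrium non-positive: base population not viable",
         call. = FALSE)
  res_wt <- sqrt(sum(.reduced_rhs2(c(Nstar, 0, 0), traits, scenario)^2))
  res_dr <- sqrt(sum(.freq_rhs2(c(1, 0), traits, scenario)^2))
  list(wt = list(N = Nstar, p_D = 0, delta_0D = 0, residual = res_wt),
       drive = list(N = 0, p_D = 1, delta_0D = 0, residual = res_dr))
}

# integrate the two-allele density model from an initial Hardy-Weinberg drive
# frequency p0 at the wild-type equilibrium; returns final p_D (NA only if
# the state went fully extinct with no defined frequency, which cannot occur
# with thr = 0)
.two_allele_fate <- function(scenario, p0, tmax = 3000, dt = 0.01) {
  traits <- scenario_traits(scenario)
  Nstar <- wt_equilibrium_density(scenario)
  f <- .freqs2(p0, 0)
  init <- c(f[["f00"]], f[["f0D"]], f[["fDD"]], 0, 0, 0) * Nstar
  a <- .sc_args(scenario, traits)
  res <- euler_integrate_cpp(init, a$omega, a$d, a$beta, a$zygote_timing,
                             a$cD, a$cB, a$K, dt, 0, tmax,
                             FALSE, scenario$f_I, 0, 1000L)
  st <- res$states
  Nrow <- rowSums(st)
  # read the fate off the last record with a physically meaningful density:
  # once the population has collapsed many orders of magnitude below the
  # wild-type equilibrium, eradication is settled and deeper records only
  # accumulate floating-point underflow
  ok <- which(Nrow > Nstar * 1e-12)
  if (!length(ok)) return(NA_real_)
  nr <- max(ok)
  (st[nr, 3] + 0.5 * st[nr, 2] + 0.5 * st[nr, 5]) / Nrow[nr]
}

# resolve a marginal boundary verdict by perturbation + integration
.resolve_wt_by_integration <- function(scenario, p0 = 0.01, tmax = 3000) {
  pf <- .two_allele_fate(scenario, p0, tmax = tmax)
  if (is.na(pf)) return("marginal")
  if (pf > max(10 * p0, 0.5)) "unstable"
  else if (pf < p0 / 10) "stable"
  else "marginal"
}

.resolve_drive_by_integration <- function(scenario, p0 = 1 - 1e-4,
                                          tmax = 2e5, dt = 0.01) {
  # local probe: seed a trace of wild type (Hardy-Weinberg at p0 close to 1)
  # into the collapsing drive population and follow the vanishing-density
  # frequency dynamics; the long horizon resolves second-order (neutral to
  # first order) invasions
  traits <- scenario_traits(scenario)
  f <- .freqs2(p0, 0)
  res <- freq2_integrate_cpp(unname(f), traits$omega, traits$d, traits$beta,
                             scenario$timing == "zygote", scenario$c_D,
                             scenario$c_B, dt, tmax, 0.5)
  if (isTRUE(res$escaped)) "unstable"
  else if (res$p_D > 1 - 10 * (1 - p0)) "stable"
  else "marginal"
}

#' Jacobian stability of the two-allele boundary equilibria
#'
#' Central-difference Jacobian of the reduced system at the wild-type-only
#' equilibrium, and of the vanishing-density frequency system at the
#' drive-only boundary (where the reduced frequency coordinates remain well
#' defined as the population collapses).  An equilibrium is stable when all
#' eigenvalue real parts are below `-eps`; verdicts within `eps` of zero are
#' reported as `"marginal"` and, when `resolve_marginal = TRUE`, settled by
#' a perturbation-integration oracle (noted in the report).
#'
#' @param scenario a [gdrive_scenario()].
#' @param which `"wt"` or `"drive"` boundary.
#' @param eps stability tolerance on eigenvalue real parts.
#' @param resolve_marginal settle marginal verdicts by integration.
#' @param resolve_tmax horizon of the resolving integration (long horizons
#'   are needed when selection is second order, e.g. a fully recessive cost
#'   with no conversion).
#' @return A `stability_report`: eigenvalues, `verdict`, `stable`,
#'   `resolved_by`.
#' @export
jacobian_stability <- function(scenario, which = c("wt", "drive"),
                               eps = 1e-7, resolve_marginal = TRUE,
                               resolve_tmax = 3000) {
  which <- match.arg(which)
  traits <- scenario_traits(scenario)
  if (which == "wt") {
    Nstar <- wt_equilibrium_density(scenario)
    J <- .num_jacobian(function(u) .reduced_rhs2(u, traits, scenario),
                       c(Nstar, 0, 0))
    rep <- .stability_report(eigen(J, only.values = TRUE)$values, eps)
    if (rep$verdict == "marginal" && resolve_marginal) {
      rep$verdict <- .resolve_wt_by_integration(scenario, tmax = resolve_tmax)
      rep$stable <- rep$verdict == "stable"
      rep$resolved_by <- "integration"
    }
  } else {
    J <- .num_jacobian(function(v) .freq_rhs2(v, traits, scenario), c(1, 0))
    rep <- .stability_report(eigen(J, only.values = TRUE)$values, eps)
    if (rep$verdict == "marginal" && resolve_marginal) {
      rep$verdict <- .resolve_drive_by_integration(scenario, tmax = resolve_tmax)
      rep$stable <- rep$verdict == "stable"
      rep$resolved_by <- "integration"
    }
  }
  cond <- tryCatch(kappa(J), error = function(e) NA_real_)
  if (is.finite(cond) && cond > 1e12)
    rep$warning <- "ill-conditioned Jacobian"
  rep
}

#' Classify a drive into the four homing-drive categories
#'
#' Combines the stability of the two boundary equilibria of the two-allele
#' model: loss (wild-type boundary stable, drive boundary unstable),
#' coexistence (both unstable), fixation (wild-type unstable, drive stable)
#' and bistability (both stable).  A drive is threshold-dependent exactly
#' when it is bistable; the invasion threshold is then located by
#' [invasion_threshold()].
#'
#' @param scenario a [gdrive_scenario()].
#' @param find_threshold also locate `p_star` for bistable drives.
#' @param ... passed to [jacobian_stability()].
#' @return A `drive_category` list: `category`, `threshold_dependent`,
#'   `p_star` (or `NA`), and the two stability reports.
#' @export
classify_drive <- function(scenario, find_threshold = TRUE, ...) {
  wt <- jacobian_stability(scenario, "wt", ...)
  dr <- jacobian_stability(scenario, "drive", ...)
  if (wt$verdict == "marginal" || dr$verdict == "marginal") {
    category <- "marginal"
  } else if (wt$stable && !dr$stable) category <- "loss"
  else if (!wt$stable && !dr$stable) category <- "coexistence"
  else if (!wt$stable && dr$stable) category <- "fixation"
  else category <- "bistability"
  out <- list(category = category,
              threshold_dependent = identical(category, "bistability"),
              p_star = NA_real_, wt = wt, drive = dr)
  class(out) <- "drive_category"
  if (find_threshold && out$threshold_dependent)
    out$p_star <- invasion_threshold(scenario, .category = out)
  out
}

#' @export
print.drive_category <- function(x, ...) {
  cat(sprintf("Drive category: %s%s\n", x$category,
              if (x$threshold_dependent) " (threshold-dependent)" else ""))
  if (!is.na(x$p_star))
    cat(sprintf("  invasion threshold p* = %.4f\n", x$p_star))
  cat(sprintf("  WT boundary: %s; drive boundary: %s\n",
              x$wt$verdict, x$drive$verdict))
  invisible(x)
}

#' Invasion threshold of a threshold-dependent drive
#'
#' Bisection on the initial drive frequency (introduced at Hardy-Weinberg
#' proportions into the wild-type equilibrium): the smallest introduction
#' frequency from which long-run integration fixes the drive.  Returns `NA`
#' for non-bistable scenarios.
#'
#' @param scenario a [gdrive_scenario()].
#' @param tol bracket tolerance on the threshold frequency.
#' @param tmax integration horizon of each probe.
#' @param .category optional precomputed [classify_drive()] result.
#' @return The threshold frequency `p_star`, or `NA_real_`.
#' @export
invasion_threshold <- function(scenario, tol = 1e-3, tmax = 4000,
                               .category = NULL) {
  if (is.null(.category))
    .category <- classify_drive(scenario, find_threshold = FALSE)
  if (!isTRUE(.category$threshold_dependent)) return(NA_real_)
  fate_fix <- function(p0) {
    pf <- .two_allele_fate(scenario, p0, tmax = tmax)
    !is.na(pf) && pf > 0.5
  }
  lo <- 1e-3; hi <- 1 - 1e-3
  if (fate_fix(lo) || !fate_fix(hi))
    return(NA_real_)  # integration disagrees with bistability verdict
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (fate_fix(mid)) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Stability of the wild-type-only equilibrium in the full three-allele model
#'
#' Numerical Jacobian of the six-dimensional reduced system (total density,
#' two allele frequencies, three Hardy-Weinberg deviations) at
#' `(N*, 0, 0, 0, 0, 0)`.  The `agreement` flag records whether the verdict
#' coincides with the two-allele wild-type boundary verdict — brake
#' parameters never flip the local stability of the wild-type-only
#' equilibrium.
#'
#' @param scenario a full [gdrive_scenario()].
#' @param eps stability tolerance on eigenvalue real parts.
#' @return A `stability_report` with an extra `agreement` element.
#' @export
wt_stability_three_allele <- function(scenario, eps = 1e-7) {
  traits <- scenario_traits(scenario)
  Nstar <- wt_equilibrium_density(scenario)
  J <- .num_jacobian(function(u) .reduced_rhs3(u, traits, scenario),
                     c(Nstar, 0, 0, 0, 0, 0))
  rep3 <- .stability_report(eigen(J, only.values = TRUE)$values, eps)
  rep2 <- jacobian_stability(scenario, "wt", eps = eps,
                             resolve_marginal = FALSE)
  rep3$two_allele <- rep2
  rep3$agreement <- identical(rep3$verdict, rep2$verdict)
  rep3
}

#' Interior equilibria of the two-allele reduced system
#'
#' Quasi-Newton refinement of the squared reduced right-hand side, started
#' from the best points of a coarse deterministic grid over scaled density
#' and drive frequency (Hardy-Weinberg deviation started at zero).  Minima
#' with scaled residual norm below `tol` and positive density are reported,
#' deduplicated.  For coexistence drives this locates the polymorphic
#' attractor; eradication-drive bistability typically has no
#' positive-density interior equilibrium (the separatrix meets the
#' extinction boundary), in which case no rows are returned.
#'
#' @param scenario a [gdrive_scenario()].
#' @param n_starts number of grid starting points refined.
#' @param tol residual-norm acceptance tolerance (scaled units).
#' @return Data frame with columns `N`, `p_D`, `delta_0D`, `residual`.
#' @export
interior_equilibria <- function(scenario, n_starts = 30, tol = 1e-8) {
  traits <- scenario_traits(scenario)
  Nstar <- wt_equilibrium_density(scenario)
  # scaled coordinates (N/N*, p_D, delta) keep the objective comparably
  # conditioned in every direction
  scaled_rhs <- function(v) {
    r <- .reduced_rhs2(c(v[1] * Nstar, v[2], v[3]), traits, scenario)
    c(r[1] / Nstar, r[2], r[3])
  }
  obj <- function(v) sum(scaled_rhs(v)^2)
  starts <- expand.grid(n = seq(0.02, 1.2, length.out = 13),
                        p = seq(0.05, 0.95, length.out = 13))
  starts$val <- apply(starts, 1, function(r) obj(c(r[[1]], r[[2]], 0)))
  starts <- starts[order(starts$val), ][seq_len(min(n_starts, nrow(starts))), ]
  found <- list()
  for (i in seq_len(nrow(starts))) {
    v0 <- c(starts$n[i], starts$p[i], 0)
    fit <- tryCatch(stats::optim(v0, obj, method = "BFGS",
                                 control = list(maxit = 2000,
                                                reltol = 1e-18)),
                    error = function(e) NULL)
    if (is.null(fit)) next
    v <- fit$par
    # Newton polish on the root system itself (BFGS on the squared norm
    # stalls well above root accuracy)
    for (k in 1:25) {
      r <- scaled_rhs(v)
      if (sqrt(sum(r^2)) < 1e-13) break
      J <- .num_jacobian(scaled_rhs, v)
      step <- tryCatch(solve(J, r), error = function(e) NULL)
      if (is.null(step) || any(!is.finite(step))) break
      v <- v - step
    }
    res <- sqrt(obj(v))
    if (res < tol && v[1] > 1e-6 && v[2] > 1e-4 && v[2] < 1 - 1e-4) {
      dup <- any(vapply(found, function(w) max(abs(w[1:3] - v)) < 1e-4,
                        logical(1)))
      if (!dup) found[[length(found) + 1]] <- c(v, res)
    }
  }
  if (!length(found))
    return(data.frame(N = numeric(), p_D = numeric(), delta_0D = numeric(),
                      residual = numeric()))
  m <- do.call(rbind, found)
  data.frame(N = m[, 1] * Nstar, p_D = m[, 2], delta_0D = m[, 3],
             residual = m[, 4])
}
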