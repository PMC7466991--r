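test_that("the density RHS matches direct substitution and is absorbing", {
  sc <- gdrive_scenario(K = 1)
  tr <- scenario_traits(sc)
  # all-WT, omega = beta = 1, d = 0.1, K = 1, N = 0.5:
  # dN00/dt = 1 * 1 * 0.5 * (1 - 0.5) - 0.1 * 0.5 = 0.2
  st <- setNames(c(0.5, 0, 0, 0, 0, 0), gd_genotypes)
  expect_equal(ode_rhs(st, tr, sc)[["00"]], 0.2)
  # extinction is absorbing
  expect_equal(ode_rhs(setNames(numeric(6), gd_genotypes), tr, sc),
               setNames(numeric(6), gd_genotypes))
  # all-WT equilibrium density is stationary
  sc2 <- gdrive_scenario()
  st2 <- setNames(c(wt_equilibrium_density(sc2), 0, 0, 0, 0, 0),
                  gd_genotypes)
  expect_equal(ode_rhs(st2, scenario_traits(sc2), sc2)[["00"]], 0,
               tolerance = 1e-9)
})

test_that("the compiled RHS kernel agrees with the R reference", {
  set.seed(50)
  for (i in 1:200) {
    sc <- random_scenario()
    tr <- scenario_traits(sc)
    st <- random_state() * 50
    expect_equal(
      as.numeric(drivebrake:::density_rhs_cpp(
        st, tr$omega, tr$d, tr$beta, sc$timing == "zygote",
        sc$c_D, sc$c_B, sc$K)),
      unname(ode_rhs(st, tr, sc)), tolerance = 1e-12)
  }
})

test_that("a compiled Euler step agrees with the R reference step", {
  set.seed(51)
  sc <- gdrive_scenario(N_star = 1000)
  tr <- scenario_traits(sc)
  st <- setNames(c(900, 100, 5, 30, 2, 0.005), gd_genotypes)
  res <- drivebrake:::euler_integrate_cpp(
    st, tr$omega, tr$d, tr$beta, FALSE, sc$c_D, sc$c_B, sc$K,
    0.005, 0.01, 0.005, FALSE, sc$f_I, 0, 1L)
  expect_equal(unname(res$states[2, ]),
               unname(r_euler_step(st, tr, sc, 0.005, 0.01)),
               tolerance = 1e-12)
})

test_that("state summaries reproduce allele frequencies and HW deviations", {
  st <- setNames(c(50, 50, 0, 0, 0, 0), gd_genotypes)
  s <- summarize_state(st)
  expect_equal(s[["p_D"]], 0.25)
  expect_equal(s[["delta_0D"]], 0.125)
  # Hardy-Weinberg state has all deltas zero
  p <- c(0.5, 0.3, 0.2)
  hw <- setNames(100 * c(p[1]^2, 2 * p[1] * p[2], p[2]^2,
                         2 * p[1] * p[3], 2 * p[2] * p[3], p[3]^2),
                 gd_genotypes)
  shw <- summarize_state(hw)
  expect_equal(unname(shw[c("delta_0D", "delta_0B", "delta_DB")]),
               c(0, 0, 0), tolerance = 1e-12)
  expect_equal(unname(shw[c("p_0", "p_D", "p_B")]), p)
  # frequencies sum to one
  expect_equal(sum(shw[c("p_0", "p_D", "p_B")]), 1, tolerance = 1e-9)
  alldd <- setNames(c(0, 0, 7, 0, 0, 0), gd_genotypes)
  expect_equal(summarize_state(alldd)[["p_D"]], 1)
  expect_error(summarize_state(setNames(numeric(6), gd_genotypes)),
               "undefined")
})

test_that("an all-wild-type run converges to the closed-form equilibrium", {
  sc <- gdrive_scenario()
  init <- setNames(c(1000, 0, 0, 0, 0, 0), gd_genotypes)
  tr <- run_deterministic(sc, init = init, tmax = 500, record_every = 1000)
  Nstar <- wt_equilibrium_density(sc)
  expect_equal(Nstar, 10000)
  expect_equal(tail(tr$N, 1) / Nstar, 1, tolerance = 1e-6)
})

test_that("trait-neutral alleles drift nowhere in the deterministic model", {
  # all six genotypes identical, no conversion: allele frequencies frozen,
  # total density approaches K (1 - d / (omega beta^2))
  om <- rep(1, 6); dd <- rep(0.1, 6); bb <- rep(1, 6)
  init <- c(300, 200, 100, 150, 50, 25)
  res <- drivebrake:::euler_integrate_cpp(
    init, om, dd, bb, FALSE, 0, 0, 2000, 0.005, 0, 600, FALSE, 0.5, 0, 200L)
  st <- res$states
  N <- rowSums(st)
  pD <- (st[, 3] + 0.5 * st[, 2] + 0.5 * st[, 5]) / N
  pB <- (st[, 6] + 0.5 * st[, 4] + 0.5 * st[, 5]) / N
  expect_lt(max(abs(pD - pD[1])), 1e-9)
  expect_lt(max(abs(pB - pB[1])), 1e-9)
  expect_equal(tail(N, 1), 2000 * 0.9, tolerance = 1e-6)
})

test_that("halving the step changes the trajectory negligibly", {
  sc <- gdrive_scenario()
  init <- setNames(c(1000, 0, 0, 0, 0, 0), gd_genotypes)
  a <- run_deterministic(sc, init = init, dt = 0.005, tmax = 100,
                         record_every = 20000)
  b <- run_deterministic(sc, init = init, dt = 0.0025, tmax = 100,
                         record_every = 40000)
  expect_equal(tail(a$N, 1), tail(b$N, 1), tolerance = 1e-3)
})

test_that("densities stay non-negative along oscillatory trajectories", {
  sc <- gdrive_scenario(tmax = 1500)
  for (thr in c(0, 0.01)) {
    d <- as.data.frame(run_deterministic(sc, thr = thr))
    expect_gte(min(as.matrix(d[, paste0("N_", gd_genotypes)])), 0)
  }
})

test_that("the critical density removes a trace drive introduction", {
  sc <- gdrive_scenario(drive_intro = 0.005, tmax = 50)  # below thr = 0.01
  tr <- run_deterministic(sc)
  expect_equal(as.character(classify_outcome(tr)), "drive_loss_before_brake")
  expect_equal(attr(tr, "events")$first_zero[["0D"]], 0.005)
})

test_that("the brake fires at the first step where p_D reaches f_I", {
  sc <- gdrive_scenario(f_I = 0.004, tmax = 10)  # initial p_D ~ 0.005
  tr <- run_deterministic(sc)
  expect_equal(attr(tr, "events")$brake_time, 0)
  # unreachable trigger: the event never fires
  sc2 <- gdrive_scenario(c_D = 0, f_I = 0.9, tmax = 100)
  tr2 <- run_deterministic(sc2)
  expect_false(attr(tr2, "events")$brake_fired)
})

test_that("outcome classification follows the decision tree", {
  # threshold-independent eradication drive, universal brake: extinction
  # after the brake release under the default critical density
  sc <- gdrive_scenario(tmax = 2500)
  tr <- run_deterministic(sc)
  expect_true(attr(tr, "events")$brake_fired)
  expect_true(as.character(classify_outcome(tr)) %in%
                c("wt_recovery", "extinction_after_brake",
                  "coexist_wt_brake", "coexist_wt_drive_brake"))
  # fitness-restoring brake: the drive is lost and wild type persists
  scs <- gdrive_scenario(brake_kind = "specific", tmax = 2500)
  trs <- run_deterministic(scs)
  expect_true(as.character(classify_outcome(trs)) %in%
                c("wt_recovery", "coexist_wt_brake"))
  # no drive introduced: p_D never reaches f_I, WT persists
  sc0 <- gdrive_scenario(drive_intro = 0, tmax = 50)
  expect_equal(as.character(classify_outcome(run_deterministic(sc0))),
               "drive_loss_before_brake")
  expect_error(classify_outcome(data.frame()), "event log|non-empty")
})

test_that("trajectories serialise to CSV with a JSON event sidecar", {
  sc <- gdrive_scenario(N_star = 500, tmax = 100)
  tr <- run_deterministic(sc)
  tmp <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, tmp)
  back <- read.csv(tmp)
  expect_true(all(c("t", paste0("N_", gd_genotypes), "N", "p_D", "p_B",
                    "delta_0D", "delta_0B", "delta_DB") %in% names(back)))
  ev <- jsonlite::read_json(paste0(tmp, ".events.json"))
  expect_true(ev$outcome %in% gd_outcomes)
})
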