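test_that("gamete distributions follow conversion rules and normalise", {
  # homozygotes transmit their single allele whatever the timing
  expect_equal(gamete_distribution("00", "germline", c_D = 0.9, c_B = 0.5),
               c(`0` = 1, D = 0, B = 0))
  # germline drive conversion: P(D) = 1/2 + c_D/2
  expect_equal(gamete_distribution("0D", "germline", c_D = 0.9),
               c(`0` = 0.05, D = 0.95, B = 0))
  # the brake leaves the wild-type allele unaffected
  expect_equal(gamete_distribution("0B", "germline", c_B = 1),
               c(`0` = 0.5, D = 0, B = 0.5))
  expect_equal(gamete_distribution("DB", "germline", c_B = 1),
               c(`0` = 0, D = 0, B = 1))
  # zygote timing: Mendelian gametes for every heterozygote
  expect_equal(gamete_distribution("0D", "zygote", c_D = 1),
               c(`0` = 0.5, D = 0.5, B = 0))
  for (g in gd_genotypes) for (ti in c("germline", "zygote"))
    for (cc in c(0, 0.25, 0.5, 0.75, 1)) {
      p <- gamete_distribution(g, ti, c_D = cc, c_B = cc)
      expect_gte(min(p), 0)
      expect_equal(sum(p), 1, tolerance = 1e-12)
    }
  expect_error(gamete_distribution("0D", "germline", c_D = 1.2), "probability")
})

test_that("gamete flux sums to the fecundity-weighted mean fecundity", {
  tr <- heterozygote_traits(c(omega = 1, d = 0.1, beta = 1),
                            c(omega = 0.5, d = 0.1, beta = 1),
                            c(omega = 0.5, d = 0.1, beta = 1), h = 0.5)
  allwt <- setNames(c(80, 0, 0, 0, 0, 0), gd_genotypes)
  expect_equal(gamete_flux(allwt, tr, "germline"), c(`0` = 1, D = 0, B = 0))
  # half 00, half 0D, c_D = 1: all 0D gametes carry D
  st <- setNames(c(50, 50, 0, 0, 0, 0), gd_genotypes)
  expect_equal(gamete_flux(st, tr, "germline", c_D = 1),
               c(`0` = 0.5, D = 0.5, B = 0))
  set.seed(41)
  for (i in 1:20) {
    trr <- random_traits()
    stt <- random_state()
    x <- gamete_flux(stt, trr, "zygote", runif(1), runif(1))
    expect_equal(sum(x), sum(trr$beta * stt) / sum(stt), tolerance = 1e-12)
  }
  expect_error(gamete_flux(setNames(numeric(6), gd_genotypes), tr, "germline"),
               "empty population")
})

test_that("x_D is non-decreasing in c_D under germline conversion", {
  set.seed(42)
  for (i in 1:20) {
    tr <- random_traits()
    st <- random_state()
    st[["0D"]] <- st[["0D"]] + 1  # ensure some heterozygotes
    xD <- vapply(seq(0, 1, by = 0.1), function(cd)
      gamete_flux(st, tr, "germline", c_D = cd, c_B = 0.3)[["D"]],
      numeric(1))
    expect_true(all(diff(xD) >= -1e-14))
  }
})

test_that("zygote production matches hand-worked conversions", {
  tr <- heterozygote_traits(c(omega = 1, d = 0.1, beta = 1),
                            c(omega = 0.5, d = 0.1, beta = 1),
                            c(omega = 0.5, d = 0.1, beta = 1), h = 0)
  allwt <- setNames(c(10, 0, 0, 0, 0, 0), gd_genotypes)
  expect_equal(zygote_production(allwt, tr, "germline"),
               setNames(c(1, 0, 0, 0, 0, 0), gd_genotypes))
  # half 00 / half 0D under zygote timing with complete conversion:
  # Mendelian x = (0.75, 0.25) gives raw V = (0.5625, 0.375, 0.0625); every
  # 0D zygote is then converted to DD
  st <- setNames(c(50, 50, 0, 0, 0, 0), gd_genotypes)
  V <- zygote_production(st, tr, "zygote", c_D = 1)
  expect_equal(unname(V[1:3]), c(0.5625, 0, 0.4375), tolerance = 1e-12)
})

test_that("total zygote production is conserved by the conversion transfer", {
  set.seed(43)
  for (i in 1:1000) {
    tr <- random_traits()
    st <- random_state()
    ti <- sample(c("germline", "zygote"), 1)
    cd <- runif(1); cb <- runif(1)
    V <- zygote_production(st, tr, ti, cd, cb)
    x <- gamete_flux(st, tr, ti, cd, cb)
    expect_gte(min(V), 0)
    expect_equal(sum(V), sum(x)^2, tolerance = 1e-9)
  }
})

test_that("without conversion both timings reduce to the same Mendelian V", {
  set.seed(44)
  for (i in 1:50) {
    tr <- random_traits()
    st <- random_state()
    expect_equal(zygote_production(st, tr, "germline", 0, 0),
                 zygote_production(st, tr, "zygote", 0, 0),
                 tolerance = 1e-12)
  }
})

test_that("zygote production agrees with the 36-pair brute-force oracle", {
  set.seed(45)
  for (i in 1:100) {
    tr <- random_traits()
    st <- random_state()
    ti <- sample(c("germline", "zygote"), 1)
    cd <- runif(1); cb <- runif(1)
    expect_equal(zygote_production(st, tr, ti, cd, cb),
                 brute_force_V(st, tr, ti, cd, cb), tolerance = 1e-9)
  }
})

test_that("heterozygote traits interpolate homozygotes through h", {
  tr0 <- heterozygote_traits(c(omega = 1, d = 0.1, beta = 1),
                             c(omega = 0.2, d = 0.1, beta = 1),
                             c(omega = 0.9, d = 0.1, beta = 1), h = 0)
  expect_equal(tr0["0D", "omega"], 1)       # complete recessivity
  tr5 <- heterozygote_traits(c(omega = 1, d = 0.1, beta = 1),
                             c(omega = 0.2, d = 0.1, beta = 1),
                             c(omega = 0.9, d = 0.1, beta = 1), h = 0.5)
  expect_equal(tr5["0D", "omega"], 0.6)     # codominant midpoint
  expect_equal(tr5["DB", "omega"], 0.55)    # (1-h) omega_BB + h omega_DD
  expect_equal(tr5["0B", "omega"], 0.95)
  expect_error(heterozygote_traits(c(omega = 1, d = 0.1, beta = 1),
                                   c(omega = 0.2, d = 0.1, beta = 1),
                                   c(omega = 0.9, d = 0.1, beta = 1),
                                   h = 1.5), "probability|h")
})

test_that("scenario traits satisfy the eradication standardisation", {
  sc_d <- gdrive_scenario(targeted_trait = "d")
  expect_equal(scenario_traits(sc_d)["DD", "d"], 1.1)
  sc_w <- gdrive_scenario(targeted_trait = "omega")
  expect_equal(scenario_traits(sc_w)["DD", "omega"], 0.1 / 1.1)
  sc_b <- gdrive_scenario(targeted_trait = "beta")
  tr <- scenario_traits(sc_b)
  expect_equal(tr["DD", "d"] / (tr["DD", "omega"] * tr["DD", "beta"]^2), 1.1)
  # universal brake: brake homozygote has drive-level traits
  expect_equal(scenario_traits(sc_w)["BB", "omega"],
               scenario_traits(sc_w)["DD", "omega"])
  # specific brake: strictly between drive and wild type on the target
  sp <- gdrive_scenario(targeted_trait = "omega", brake_kind = "specific",
                        restoration = 0.95)
  om <- scenario_traits(sp)
  expect_gt(om["BB", "omega"], om["DD", "omega"])
  expect_lt(om["BB", "omega"], om["00", "omega"])
  # and only the targeted trait differs across genotypes
  expect_equal(unique(om$d), 0.1)
  expect_equal(unique(om$beta), 1)
})

test_that("trait tables export as CSV", {
  tmp <- tempfile(fileext = ".csv")
  write_traits_csv(scenario_traits(gdrive_scenario()), tmp)
  back <- read.csv(tmp)
  expect_equal(names(back), c("genotype", "omega", "d", "beta"))
  expect_equal(back$genotype, gd_genotypes)
})
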