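# Shared fixtures and independent oracles for the suite.

# random positive state with some structural zeros
random_state <- function() {
  n <- runif(6, 0, 100)
  n[sample(6, sample(0:3, 1))] <- 0
  if (sum(n) == 0) n[1] <- 1
  setNames(n, gd_genotypes)
}

random_traits <- function() {
  heterozygote_traits(
    c(omega = runif(1, 0.5, 1), d = runif(1, 0.05, 0.5),
      beta = runif(1, 0.5, 2)),
    c(omega = runif(1, 0.05, 1), d = runif(1, 0.05, 1),
      beta = runif(1, 0.1, 2)),
    c(omega = runif(1, 0.05, 1), d = runif(1, 0.05, 1),
      beta = runif(1, 0.1, 2)),
    h = runif(1))
}

random_scenario <- function(...) {
  gdrive_scenario(c_D = runif(1), c_B = runif(1), h = runif(1),
                  timing = sample(c("germline", "zygote"), 1),
                  targeted_trait = sample(c("omega", "d", "beta"), 1),
                  brake_kind = sample(c("universal", "specific"), 1),
                  drive_ratio = runif(1, 1.05, 3),
                  restoration = runif(1, 0.5, 0.99), ...)
}

# Brute-force zygote production: enumerate all 36 ordered parental genotype
# pairs with fecundity-weighted mating probabilities, all gamete draws, and
# per-zygote conversion.  Independent of the gamete-flux implementation.
brute_force_V <- function(state, traits, timing, c_D, c_B) {
  N <- sum(state)
  w <- traits$beta * state / N  # fecundity-weighted parental shares
  gam <- function(g) {
    # per-genotype gamete distribution written out longhand
    switch(g,
      "00" = c(`0` = 1, D = 0, B = 0),
      "0D" = if (timing == "germline")
        c(`0` = (1 - c_D) / 2, D = (1 + c_D) / 2, B = 0)
      else c(`0` = 0.5, D = 0.5, B = 0),
      "DD" = c(`0` = 0, D = 1, B = 0),
      "0B" = c(`0` = 0.5, D = 0, B = 0.5),
      "DB" = if (timing == "germline")
        c(`0` = 0, D = (1 - c_B) / 2, B = (1 + c_B) / 2)
      else c(`0` = 0, D = 0.5, B = 0.5),
      "BB" = c(`0` = 0, D = 0, B = 1))
  }
  geno_of <- function(a, b) {
    pair <- sort(factor(c(a, b), levels = gd_alleles))
    paste0(ifelse(pair == "0", "0", as.character(pair)), collapse = "")
  }
  canon <- c("00" = "00", "0D" = "0D", "DD" = "DD", "0B" = "0B",
             "DB" = "DB", "BB" = "BB")
  V <- setNames(numeric(6), gd_genotypes)
  for (i in gd_genotypes) for (j in gd_genotypes) {
    wij <- w[[i]] * w[[j]]
    if (wij == 0) next
    gi <- gam(i); gj <- gam(j)
    for (a in gd_alleles) for (b in gd_alleles) {
      p <- wij * gi[[a]] * gj[[b]]
      if (p == 0) next
      z <- canon[[geno_of(a, b)]]
      if (timing == "zygote" && z == "0D") {
        V[["DD"]] <- V[["DD"]] + p * c_D
        V[["0D"]] <- V[["0D"]] + p * (1 - c_D)
      } else if (timing == "zygote" && z == "DB") {
        V[["BB"]] <- V[["BB"]] + p * c_B
        V[["DB"]] <- V[["DB"]] + p * (1 - c_B)
      } else {
        V[[z]] <- V[[z]] + p
      }
    }
  }
  V
}

# one explicit-Euler reference step in plain R (mirrors the compiled kernel)
r_euler_step <- function(state, traits, scenario, dt, thr) {
  dn <- ode_rhs(state, traits, scenario)
  nxt <- pmax(state + dt * dn, 0)
  if (thr > 0) nxt[nxt < thr] <- 0
  nxt
}
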