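# Gamete production, fecundity-weighted random mating and trait tables.

.check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(sprintf("`%s` must be a single probability in [0, 1]", name),
         call. = FALSE)
  invisible(x)
}

.check_timing <- function(timing) {
  match.arg(timing, c("germline", "zygote"))
}

.as_state <- function(state) {
  if (length(state) != 6L || any(!is.finite(state)) || any(state < 0))
    stop("a population state is a vector of 6 non-negative finite densities ",
         "in genotype order ", paste(gd_genotypes, collapse = ", "),
         call. = FALSE)
  x <- as.numeric(state)
  names(x) <- gd_genotypes
  x
}

.as_traits <- function(traits) {
  if (is.data.frame(traits)) {
    stopifnot(all(c("omega", "d", "beta") %in% names(traits)),
              nrow(traits) == 6L)
    traits
  } else stop("`traits` must be a 6-row data frame with columns omega, d, beta")
}

#' Gamete allele distribution of a genotype
#'
#' Probability that a gamete produced by an individual of genotype `g`
#' carries each allele.  With germline conversion, `0D` heterozygotes
#' transmit the drive with probability `(1 + c_D)/2` (the wild-type copy is
#' converted with probability `c_D` before Mendelian segregation) and `DB`
#' heterozygotes transmit the brake with probability `(1 + c_B)/2`.  The
#' brake never cuts the wild-type allele, so `0B` heterozygotes always
#' segregate 50:50.  With zygote-timing conversion gametes are Mendelian
#' (conversion acts on newly formed zygotes, see [zygote_production()]).
#'
#' @param g genotype label, one of `gd_genotypes`.
#' @param timing `"germline"` or `"zygote"`.
#' @param c_D,c_B conversion probabilities of drive and brake.
#' @return Named numeric vector of length 3 (alleles `0`, `D`, `B`)
#'   summing to 1.
#' @examples
#' gamete_distribution("0D", "germline", c_D = 0.9)
#' @export
gamete_distribution <- function(g, timing = c("germline", "zygote"),
                                c_D = 0, c_B = 0) {
  timing <- .check_timing(timing)
  .check_prob(c_D, "c_D")
  .check_prob(c_B, "c_B")
  g <- match.arg(g, gd_genotypes)
  M <- .gamete_matrix(timing, c_D, c_B)
  M[g, ]
}

.gamete_matrix <- function(timing, c_D, c_B) {
  M <- matrix(0, 6, 3, dimnames = list(gd_genotypes, gd_alleles))
  M["00", "0"] <- 1
  M["DD", "D"] <- 1
  M["BB", "B"] <- 1
  M["0B", c("0", "B")] <- 0.5
  if (timing == "germline") {
    M["0D", c("0", "D")] <- c(1 - c_D, 1 + c_D) / 2
    M["DB", c("D", "B")] <- c(1 - c_B, 1 + c_B) / 2
  } else {
    M["0D", c("0", "D")] <- 0.5
    M["DB", c("D", "B")] <- 0.5
  }
  M
}

#' Fecundity-weighted gamete flux of a population
#'
#' `x_a = sum_g beta_g (N_g / N) * P(gamete a | g)`.  The fluxes sum to the
#' fecundity-weighted mean fecundity of the population.
#'
#' @param state per-genotype densities (length 6, genotype order).
#' @param traits trait table as returned by [heterozygote_traits()] or
#'   [scenario_traits()].
#' @inheritParams gamete_distribution
#' @return Named numeric vector of length 3.
#' @export
gamete_flux <- function(state, traits, timing = c("germline", "zygote"),
                        c_D = 0, c_B = 0) {
  timing <- .check_timing(timing)
  state <- .as_state(state)
  traits <- .as_traits(traits)
  N <- sum(state)
  if (N <= 0) stop("empty population: gamete flux undefined", call. = FALSE)
  M <- .gamete_matrix(timing, c_D, c_B)
  drop((traits$beta * state / N) %*% M)
}

#' Zygote production terms V_g
#'
#' Production of genotype-`g` zygotes by random union of fecundity-weighted
#' gametes: `V_aa = x_a^2`, `V_ab = 2 x_a x_b`.  With germline timing the
#' conversion bias is already inside the gamete fluxes; with zygote timing
#' the gametes are Mendelian and converted heterozygous zygotes are
#' transferred to the corresponding homozygote class (`0D -> DD` with
#' probability `c_D`, `DB -> BB` with probability `c_B`), so they express the
#' homozygote's traits from the zygote stage on.  The transfer conserves
#' `sum_g V_g = (sum_a x_a)^2`.
#'
#' @inheritParams gamete_flux
#' @return Named numeric vector of length 6 (genotype order).
#' @export
zygote_production <- function(state, traits, timing = c("germline", "zygote"),
                              c_D = 0, c_B = 0) {
  timing <- .check_timing(timing)
  .check_prob(c_D, "c_D")
  .check_prob(c_B, "c_B")
  x <- gamete_flux(state, traits, timing, c_D, c_B)
  V <- c(`00` = x[["0"]]^2,
         `0D` = 2 * x[["0"]] * x[["D"]],
         `DD` = x[["D"]]^2,
         `0B` = 2 * x[["0"]] * x[["B"]],
         `DB` = 2 * x[["D"]] * x[["B"]],
         `BB` = x[["B"]]^2)
  if (timing == "zygote") {
    V[["DD"]] <- V[["DD"]] + c_D * V[["0D"]]
    V[["0D"]] <- (1 - c_D) * V[["0D"]]
    V[["BB"]] <- V[["BB"]] + c_B * V[["DB"]]
    V[["DB"]] <- (1 - c_B) * V[["DB"]]
  }
  V
}

#' Build the six-genotype trait table from homozygote traits
#'
#' Heterozygote traits are linear in the dominance coefficient `h` of the
#' cost-carrying allele: `0D = (1-h) 00 + h DD`, `0B = (1-h) 00 + h BB`,
#' `DB = (1-h) BB + h DD`, applied independently to zygote survival `omega`,
#' adult death rate `d` and fecundity `beta`.
#'
#' @param base00,homoDD,homoBB named numeric triples with elements
#'   `omega`, `d`, `beta` for the respective homozygote.
#' @param h dominance coefficient in `[0, 1]` (`0` = costs fully recessive,
#'   `0.5` = codominant, `1` = costs fully dominant).
#' @return Data frame with columns `genotype`, `omega`, `d`, `beta`
#'   in genotype order.
#' @examples
#' heterozygote_traits(c(omega = 1, d = 0.1, beta = 1),
#'                     c(omega = 0.2, d = 0.1, beta = 1),
#'                     c(omega = 0.2, d = 0.1, beta = 1), h = 0.5)
#' @export
heterozygote_traits <- function(base00, homoDD, homoBB, h) {
  .check_prob(h, "h")
  trip <- function(x, nm) {
    if (!all(c("omega", "d", "beta") %in% names(x)))
      stop(sprintf("`%s` must have named elements omega, d, beta", nm),
           call. = FALSE)
    x[c("omega", "d", "beta")]
  }
  t00 <- trip(base00, "base00")
  tDD <- trip(homoDD, "homoDD")
  tBB <- trip(homoBB, "homoBB")
  t0D <- (1 - h) * t00 + h * tDD
  t0B <- (1 - h) * t00 + h * tBB
  tDB <- (1 - h) * tBB + h * tDD
  tab <- rbind(t00, t0D, tDD, t0B, tDB, tBB)
  out <- data.frame(genotype = gd_genotypes, omega = tab[, "omega"],
                    d = tab[, "d"], beta = tab[, "beta"],
                    row.names = gd_genotypes)
  if (any(out$omega < 0 | out$omega > 1))
    stop("zygote survival omega must lie in [0, 1] for all genotypes",
         call. = FALSE)
  if (any(out$d <= 0))
    stop("adult death rates must be positive for all genotypes", call. = FALSE)
  if (any(out$beta < 0))
    stop("fecundities must be non-negative", call. = FALSE)
  out
}

#' Export a trait table as CSV
#'
#' @param traits trait table (data frame with columns `genotype`, `omega`,
#'   `d`, `beta`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_traits_csv <- function(traits, path) {
  traits <- .as_traits(traits)
  write.csv(traits[, c("genotype", "omega", "d", "beta")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}
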