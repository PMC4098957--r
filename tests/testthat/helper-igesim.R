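# Shared test helpers: random pedigrees and tiny unselected populations.

# Random discrete-generation pedigree: n0 base animals, then `gens` cohorts
# of `per_gen` with parents drawn from the previous cohort.
random_pedigree <- function(n0 = 10L, gens = 4L, per_gen = 30L) {
  sire <- rep(0L, n0); dam <- rep(0L, n0); gen <- rep(0L, n0)
  sex <- rep(c("M", "F"), length.out = n0)
  prev <- seq_len(n0)
  for (g in seq_len(gens)) {
    males <- prev[sex[prev] == "M"]; females <- prev[sex[prev] == "F"]
    s <- sample(males, per_gen, replace = TRUE)
    d <- sample(females, per_gen, replace = TRUE)
    sire <- c(sire, s); dam <- c(dam, d); gen <- c(gen, rep(g, per_gen))
    sex <- c(sex, sample(c("M", "F"), per_gen, replace = TRUE))
    prev <- seq_along(sire)[gen == g]
  }
  pedigree(sire, dam, gen, sex)
}

# One unselected progeny generation in two-family groups: returns the
# population state after generation 1 of a random-selection replicate.
unselected_generation <- function(cfg, seed, gp = derive_components(cfg)) {
  cfg1 <- scenario_config(
    ige_magnitude = cfg$ige_magnitude, h2_direct = cfg$h2_direct,
    h2_indirect = cfg$h2_indirect, r_ADS = cfg$r_ADS, r_EDS = cfg$r_EDS,
    generations = 1L, burn_in_generation = 0L)
  run_replicate(cfg1, seed, gp = gp, random_selection = TRUE)$pop
}

expect_symmetric_psd <- function(M, tol = 1e-10) {
  expect_lt(max(abs(M - t(M))), tol)
  expect_gte(min(eigen(M, symmetric = TRUE, only.values = TRUE)$values),
             -tol)
}
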