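# Closed-nucleus population simulator.
#
# A population is a plain list of parallel vectors (one slot per
# individual, ids dense 1..N): sire, dam, generation, sex, the true direct
# and indirect breeding values aD/aS, the non-genetic effects eD/eS, group
# id, phenotype and inbreeding F.  Base animals are generation 0, are never
# grouped or phenotyped, and act as the generation-1 parents.

# Draw n rows from a bivariate normal with 2x2 covariance S (allows
# singular S, e.g. no indirect variance).
rbvn <- function(n, S) {
  ev <- eigen(S, symmetric = TRUE)
  lam <- pmax(ev$values, 0)
  Z <- matrix(stats::rnorm(2L * n), n, 2L)
  Z %*% (t(ev$vectors) * sqrt(lam))
}

new_population <- function(n_alloc) {
  list(
    sire = integer(n_alloc), dam = integer(n_alloc),
    generation = integer(n_alloc), sex = character(n_alloc),
    aD = numeric(n_alloc), aS = numeric(n_alloc),
    eD = numeric(n_alloc), eS = numeric(n_alloc),
    group = rep(NA_integer_, n_alloc), phenotype = rep(NA_real_, n_alloc),
    F = numeric(n_alloc), n = 0L
  )
}

#' Initialise the unrelated base population
#'
#' Draws `n_males + n_females` unrelated base animals (generation 0,
#' F = 0).  Genetic effects (A_D, A_S) are bivariate normal with covariance
#' `gp$G0`; non-genetic effects (E_D, E_S) with covariance `gp$E0`.  Base
#' animals are not grouped and carry no phenotype: selection starts on their
#' progeny.
#'
#' @param gp a [derive_components()] result.
#' @param n_males,n_females base animal counts (default: the scenario's
#'   sire and dam numbers).
#' @return a population state list (see [run_replicate()]); slots filled for
#'   individuals `1..(n_males + n_females)`.
#' @export
init_base_population <- function(gp, n_males = gp$config$n_sires,
                                 n_females = gp$config$n_dams) {
  cfg <- gp$config
  n_alloc <- n_males + n_females +
    cfg$generations * cfg$n_dams * cfg$progeny_per_dam
  pop <- new_population(n_alloc)
  nb <- n_males + n_females
  idx <- seq_len(nb)
  A <- rbvn(nb, gp$G0)
  E <- rbvn(nb, gp$E0)
  pop$aD[idx] <- A[, 1]; pop$aS[idx] <- A[, 2]
  pop$eD[idx] <- E[, 1]; pop$eS[idx] <- E[, 2]
  pop$sex[idx] <- rep(c("M", "F"), c(n_males, n_females))
  pop$n <- nb
  pop
}

#' Simulate one offspring of a sire-dam pair
#'
#' Breeding values are midparent plus a Mendelian sampling deviation drawn
#' from a bivariate normal with covariance
#' \eqn{\tfrac12\,(1 - (F_s + F_d)/2)\, G_0}; non-genetic effects are drawn
#' fresh from the base distribution; sex is a fair coin.
#'
#' This scalar version documents the sampling model; [run_replicate()] uses
#' the vectorised equivalent internally.
#'
#' @param sire,dam indices of the parents in `pop`.
#' @param pop population state holding the parents.
#' @param gp a [derive_components()] result.
#' @param generation generation index of the offspring.
#' @return `pop` with one more individual appended.
#' @export
make_offspring <- function(sire, dam, pop, gp, generation) {
  i <- pop$n + 1L
  mid <- 0.5 * c(pop$aD[sire] + pop$aD[dam], pop$aS[sire] + pop$aS[dam])
  k <- 0.5 * (1 - (pop$F[sire] + pop$F[dam]) / 2)
  m <- drop(rbvn(1L, k * gp$G0))
  E <- drop(rbvn(1L, gp$E0))
  pop$sire[i] <- sire; pop$dam[i] <- dam
  pop$generation[i] <- generation
  pop$sex[i] <- if (stats::runif(1) < 0.5) "M" else "F"
  pop$aD[i] <- mid[1] + m[1]; pop$aS[i] <- mid[2] + m[2]
  pop$eD[i] <- E[1]; pop$eS[i] <- E[2]
  pop$n <- i
  pop
}

# Vectorised progeny generation: one call per generation.
# matings: data.frame(sire, dam); each mating produces `progeny_per_dam`
# offspring.  Returns pop with the cohort appended (F not yet filled).
make_progeny_cohort <- function(matings, pop, gp, generation,
                                progeny_per_dam) {
  nm <- nrow(matings)
  nk <- nm * progeny_per_dam
  s <- rep(matings$sire, each = progeny_per_dam)
  d <- rep(matings$dam, each = progeny_per_dam)
  idx <- pop$n + seq_len(nk)
  k <- 0.5 * (1 - (pop$F[s] + pop$F[d]) / 2)  # Mendelian scaling per kid
  M <- rbvn(nk, gp$G0) * sqrt(k)              # scales covariance by k
  E <- rbvn(nk, gp$E0)
  pop$sire[idx] <- s; pop$dam[idx] <- d
  pop$generation[idx] <- generation
  pop$sex[idx] <- ifelse(stats::runif(nk) < 0.5, "M", "F")
  pop$aD[idx] <- 0.5 * (pop$aD[s] + pop$aD[d]) + M[, 1]
  pop$aS[idx] <- 0.5 * (pop$aS[s] + pop$aS[d]) + M[, 2]
  pop$eD[idx] <- E[, 1]; pop$eS[idx] <- E[, 2]
  pop$n <- pop$n + nk
  pop
}

#' Assign a generation to groups of two full-sib families
#'
#' Each full-sib family of 8 is split at random into two quartets; quartets
#' are then paired at random under the constraint that the two quartets of
#' a group come from different families, giving 50 groups of 8.  A family's
#' two quartets may meet different partner families.
#'
#' @param ids integer ids of the generation's individuals.
#' @param family integer family label per id (same sire and dam).
#' @param n_group group size (default 8).
#' @return integer vector of group labels (1-based, dense), parallel to
#'   `ids`.
#' @export
assign_groups <- function(ids, family, n_group = 8L) {
  half <- n_group %/% 2L
  fams <- split(ids, family)
  if (any(lengths(fams) != n_group)) {
    stop("every full-sib family must have exactly ", n_group, " progeny")
  }
  quartets <- list(); qfam <- integer(0)
  for (fi in seq_along(fams)) {
    mem <- sample(fams[[fi]])
    quartets <- c(quartets, list(mem[seq_len(half)], mem[half + seq_len(half)]))
    qfam <- c(qfam, fi, fi)
  }
  if (length(fams) < 2L) {
    stop("at least two families are needed for two-family groups")
  }
  nq <- length(quartets)
  # uniform random perfect matching of quartets, rejecting pairings that
  # put a family's two quartets together (rarely more than a few tries)
  for (try in seq_len(10000L)) {
    ord <- sample.int(nq)
    ok <- all(qfam[ord[seq(1L, nq, 2L)]] != qfam[ord[seq(2L, nq, 2L)]])
    if (ok) break
  }
  if (!ok) stop("could not pair quartets from distinct families")
  grp_of_q <- integer(nq)
  grp_of_q[ord] <- rep(seq_len(nq %/% 2L), each = 2L)
  grp <- integer(length(ids))
  for (q in seq_len(nq)) grp[match(quartets[[q]], ids)] <- grp_of_q[q]
  grp
}

#' Construct phenotypes from direct and indirect effects
#'
#' For individual i in a group of n,
#' \deqn{P_i = A_{D,i} + E_{D,i} + \sum_{j \ne i} (A_{S,j} + E_{S,j}),}
#' the sum running over the n-1 group mates.  With no indirect effects this
#' reduces to the classical P = A + E.
#'
#' @param pop population state.
#' @param ids ids of a fully grouped generation.
#' @return `pop` with `phenotype[ids]` filled.
#' @export
construct_phenotypes <- function(pop, ids) {
  grp <- pop$group[ids]
  if (anyNA(grp)) stop("phenotype requested before group assignment")
  s_tot <- tapply(pop$aS[ids] + pop$eS[ids], grp, sum)
  pop$phenotype[ids] <- pop$aD[ids] + pop$eD[ids] +
    (s_tot[as.character(grp)] - (pop$aS[ids] + pop$eS[ids]))
  pop
}

# True total breeding value A_D + (n-1) A_S for given ids.
true_tbv <- function(pop, ids, n_group) {
  pop$aD[ids] + (n_group - 1) * pop$aS[ids]
}

#' Extract the pedigree of a population state
#'
#' @param pop population state.
#' @return a [pedigree()] covering individuals `1..pop$n`.
#' @export
population_pedigree <- function(pop) {
  idx <- seq_len(pop$n)
  pedigree(pop$sire[idx], pop$dam[idx], pop$generation[idx], pop$sex[idx])
}

#' Dump a population state as a delimited text table
#'
#' One row per individual with pedigree fields, sex, group, true effects,
#' phenotype and inbreeding; intended for debugging and test fixtures.
#'
#' @param pop population state.
#' @param path output path.
#' @export
write_population <- function(pop, path) {
  idx <- seq_len(pop$n)
  tab <- data.frame(id = idx, sire = pop$sire[idx], dam = pop$dam[idx],
                    generation = pop$generation[idx], sex = pop$sex[idx],
                    group = pop$group[idx], aD = pop$aD[idx],
                    aS = pop$aS[idx], eD = pop$eD[idx], eS = pop$eS[idx],
                    phenotype = pop$phenotype[idx], F = pop$F[idx])
  utils::write.table(tab, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}
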