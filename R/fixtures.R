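# Deterministic toy worlds and the independent oracle code paths used to
# validate the production machinery.  The oracles (tabular relationship
# matrix, dense GLS BLUP, brute-force loops) are deliberately naive O(N^2)
# or dense implementations and are never called by the production code.

#' Tabular (recursive) numerator relationship matrix
#'
#' Dense O(N^2) tabular-method construction of A; the independent oracle
#' for [a_inverse()] and [inbreeding_coefficients()] (F = diag(A) - 1).
#'
#' @param ped a [pedigree()].
#' @return dense numeric matrix of order `nrow(ped)`.
#' @export
tabular_relationship_matrix <- function(ped) {
  n <- nrow(ped)
  A <- matrix(0, n, n)
  at <- function(i, j) if (i == 0L || j == 0L) 0 else A[i, j]
  for (i in seq_len(n)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    if (i > 1L) {
      for (j in seq_len(i - 1L)) {
        A[j, i] <- A[i, j] <- 0.5 * (at(j, s) + at(j, d))
      }
    }
    A[i, i] <- 1 + 0.5 * at(s, d)
  }
  A
}

#' Dense GLS/BLUP oracle
#'
#' Textbook mixed-model solution on dense matrices: with
#' \eqn{V = Z G Z' + R}, the GLS fixed effects are
#' \eqn{\hat\beta = (X'V^{-1}X)^{-1} X'V^{-1} y} and the BLUP of the random
#' effects is \eqn{\hat u = G Z' V^{-1}(y - X\hat\beta)}.  Used as the
#' independent check of the sparse mixed-model equations on toy data.
#'
#' @param y numeric response vector.
#' @param X dense fixed-effect design matrix.
#' @param Z dense random-effect design matrix.
#' @param G prior covariance of the random effects.
#' @param R residual covariance.
#' @return list with `beta` and `u`.
#' @export
dense_blup <- function(y, X, Z, G, R) {
  V <- Z %*% G %*% t(Z) + R
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  u <- G %*% t(Z) %*% Vi %*% (y - X %*% beta)
  list(beta = drop(beta), u = drop(u))
}

# Compound-symmetric residual covariance for grouped records.
block_residual_covariance <- function(rec_group, sigma_e2, sigma_g2) {
  n <- length(rec_group)
  R <- matrix(0, n, n)
  for (g in unique(rec_group)) {
    m <- which(rec_group == g)
    R[m, m] <- sigma_g2
  }
  diag(R) <- sigma_e2 + sigma_g2
  R
}

#' Build a named deterministic toy world
#'
#' Small fixed populations with every derived expectation computed by the
#' independent oracle paths, for testing each production stage in seconds:
#' \describe{
#'   \item{`"trio"`}{two unrelated base animals and their offspring; known
#'     3x3 A and F.}
#'   \item{`"two_groups"`}{two full-sib families of 8 with fixed
#'     (non-sampled) effect values, two 4+4 groups, phenotypes from the
#'     brute-force double loop, and the dense-oracle BLUP solution under
#'     the intermediate-IGE neutral scenario.}
#'   \item{`"full_sib_line"`}{five generations of repeated full-sib
#'     mating; F sequence 0, 0.25, 0.375, ... from the tabular method.}
#' }
#'
#' @param name one of `"trio"`, `"two_groups"`, `"full_sib_line"`.
#' @return list with fields depending on the fixture; always includes
#'   `ped`, `A` (tabular oracle) and `F` (its diagonal minus 1).
#' @export
make_toy_world <- function(name = c("trio", "two_groups", "full_sib_line")) {
  name <- match.arg(name)
  if (name == "trio") {
    ped <- pedigree(sire = c(0L, 0L, 1L), dam = c(0L, 0L, 2L),
                    generation = c(0L, 0L, 1L))
    A <- tabular_relationship_matrix(ped)
    return(list(ped = ped, A = A, F = diag(A) - 1))
  }
  if (name == "full_sib_line") {
    # two base animals, then two full sibs per generation mated together
    sire <- c(0L, 0L); dam <- c(0L, 0L); gen <- c(0L, 0L)
    for (t in 1:5) {
      p <- c(2L * t - 1L, 2L * t)
      sire <- c(sire, p[1], p[1]); dam <- c(dam, p[2], p[2])
      gen <- c(gen, t, t)
    }
    ped <- pedigree(sire, dam, gen)
    A <- tabular_relationship_matrix(ped)
    return(list(ped = ped, A = A, F = diag(A) - 1,
                F_by_generation = tapply(diag(A) - 1, gen, unique)))
  }
  # two_groups: 4 unrelated base parents, families (1x3) and (2x4),
  # 8 progeny each, two 4+4 groups mixing the families.
  sire <- c(rep(0L, 4L), rep(c(1L, 2L), each = 8L))
  dam <- c(rep(0L, 4L), rep(c(3L, 4L), each = 8L))
  gen <- c(rep(0L, 4L), rep(1L, 16L))
  ped <- pedigree(sire, dam, gen,
                  sex = c("M", "M", "F", "F",
                          rep(c("M", "F"), 8L)))
  A <- tabular_relationship_matrix(ped)
  ids <- 5:20
  # fixed, asymmetric effect values (no sampling involved)
  aD <- c(0.5, -0.2, 0.1, 0.4, -0.3, 0.2, 0.0, 0.6,
          -0.5, 0.3, 0.25, -0.1, 0.05, -0.4, 0.35, 0.15)
  aS <- c(0.05, -0.02, 0.01, 0.04, -0.03, 0.02, 0.00, 0.06,
          -0.05, 0.03, 0.025, -0.01, 0.005, -0.04, 0.035, 0.015)
  eD <- c(0.2, 0.1, -0.1, 0.3, -0.2, 0.15, 0.05, -0.25,
          0.12, -0.18, 0.22, 0.02, -0.08, 0.28, -0.12, 0.08)
  eS <- c(0.02, 0.01, -0.01, 0.03, -0.02, 0.015, 0.005, -0.025,
          0.012, -0.018, 0.022, 0.002, -0.008, 0.028, -0.012, 0.008)
  # interleave the families into two 4+4 groups
  group <- c(rep(1L, 4L), rep(2L, 4L), rep(1L, 4L), rep(2L, 4L))
  # brute-force phenotype oracle: explicit double loop over group mates
  P <- numeric(16L)
  for (i in seq_len(16L)) {
    P[i] <- aD[i] + eD[i]
    for (j in seq_len(16L)) {
      if (j != i && group[j] == group[i]) P[i] <- P[i] + aS[j] + eS[j]
    }
  }
  cfg <- scenario_config(ige_magnitude = 1, h2_direct = 0.3,
                         h2_indirect = 0.3)
  gp <- derive_components(cfg)
  # dense-oracle BLUP of (aD over all 20, aS over all 20) from the records
  N <- 20L
  X <- matrix(1, 16L, 1L)
  ZD <- matrix(0, 16L, N); ZD[cbind(seq_len(16L), ids)] <- 1
  ZS <- matrix(0, 16L, N)
  for (i in seq_len(16L)) {
    mates <- ids[group == group[i] & ids != ids[i]]
    ZS[i, mates] <- 1
  }
  G <- kronecker(gp$G0, A)
  R <- block_residual_covariance(group, gp$sigma_e2, gp$sigma_g2)
  oracle <- dense_blup(P, X, cbind(ZD, ZS), G, R)
  list(ped = ped, A = A, F = diag(A) - 1, ids = ids,
       aD = aD, aS = aS, eD = eD, eS = eS, group = group, y = P,
       gp = gp, config = cfg,
       oracle_mu = oracle$beta,
       oracle_aD = oracle$u[seq_len(N)],
       oracle_aS = oracle$u[N + seq_len(N)],
       oracle_etbv = oracle$u[seq_len(N)] +
         (cfg$n_group - 1) * oracle$u[N + seq_len(N)])
}
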