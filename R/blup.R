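# BLUP of direct and indirect breeding values with known (true) variance
# components, by exact sparse solution of the mixed-model equations for
#
#   y = mu + Z_D a_D + Z_S a_S + V g + e
#
# var(a_D, a_S) = G0 (x) A, var(g) = I sigma_g2, var(e) = I sigma_e2.
# Each row of Z_S carries a 1 for each of the record's n-1 group mates.
#
# The group term only models the non-genetic covariance sigma_g2 among
# group members, so the model can equivalently be written without g, with a
# block-diagonal residual covariance (per group: diagonal
# sigma_e2 + sigma_g2, off-diagonal sigma_g2).  The block form is the only
# valid one when sigma_g2 < 0 (competitive non-genetic correlations) and is
# therefore the default; with sigma_g2 >= 0 both forms give identical
# solutions for mu, a_D and a_S.

#' Assemble evaluation data from a population state
#'
#' Collects phenotypes of all grouped-and-phenotyped individuals up to a
#' generation, their design structure, and the pedigree-derived inverse
#' relationship matrix.
#'
#' @param pop population state (see [run_replicate()]).
#' @param up_to_generation last generation whose records enter.
#' @param from_generation first generation whose records enter (default 1:
#'   all accumulated records).
#' @param Ainv optional precomputed [a_inverse()] for `1..pop$n`.
#' @return an `evaluation_data` list: `y`, `rec_id` (individual of each
#'   record), `rec_group` (dense group index of each record), `n_ind`,
#'   `Ainv`.
#' @export
evaluation_data <- function(pop, up_to_generation = max(pop$generation),
                            from_generation = 1L, Ainv = NULL) {
  idx <- seq_len(pop$n)
  keep <- idx[pop$generation[idx] >= from_generation &
                pop$generation[idx] <= up_to_generation &
                !is.na(pop$phenotype[idx])]
  if (length(keep) == 0L) stop("no phenotyped records up to generation ",
                               up_to_generation)
  # group ids are only unique within a generation; make them global
  gkey <- paste(pop$generation[keep], pop$group[keep])
  rec_group <- as.integer(factor(gkey, levels = unique(gkey)))
  if (is.null(Ainv)) {
    ped <- population_pedigree(pop)
    Ainv <- a_inverse(ped, inbreeding_coefficients(ped))
  }
  structure(list(y = pop$phenotype[keep], rec_id = keep,
                 rec_group = rec_group, n_ind = pop$n, Ainv = Ainv),
            class = "evaluation_data")
}

# 2x2 inverse of G0 with a ridge only if numerically singular.
g0_inverse <- function(G0) {
  det <- G0[1, 1] * G0[2, 2] - G0[1, 2]^2
  scale <- max(G0[1, 1], G0[2, 2])
  if (det <= 1e-12 * scale^2) {
    eps <- 1e-8 * max(scale, 1)
    warning("G0 numerically singular; adding ridge ", signif(eps, 3),
            " to its diagonal")
    G0 <- G0 + diag(eps, 2)
  }
  solve(G0)
}

#' Build the mixed-model equations
#'
#' Assembles the sparse symmetric normal equations for the overall mean and
#' the direct and indirect breeding values of every pedigree member
#' (indirect equations and group structure are dropped when the scenario
#' has no indirect effects, collapsing to the standard animal model).
#'
#' @param data an [evaluation_data()] object.
#' @param gp a [derive_components()] result.
#' @param group_model `"block"` (default) folds the within-group covariance
#'   \eqn{\sigma^2_g} into a block-diagonal residual; `"explicit"` fits
#'   group effects as a random term with variance \eqn{\sigma^2_g}
#'   (requires \eqn{\sigma^2_g > 0}).
#' @return an `mme_system` list with the coefficient matrix `C`, right-hand
#'   side `rhs`, and an index map for unpacking solutions.
#' @export
build_mme <- function(data, gp, group_model = c("block", "explicit")) {
  group_model <- match.arg(group_model)
  nrec <- length(data$y)
  N <- data$n_ind
  social <- gp$sigma_PS2 > 0
  ZD <- Matrix::sparseMatrix(i = seq_len(nrec), j = data$rec_id, x = 1,
                             dims = c(nrec, N))
  if (!social) {
    W <- cbind(rep(1, nrec), ZD)
    C <- Matrix::crossprod(W) / gp$sigma_e2
    pad <- Matrix::bdiag(Matrix::Matrix(0, 1, 1), data$Ainv / gp$sigma_AD2)
    C <- C + pad
    rhs <- Matrix::crossprod(W, data$y) / gp$sigma_e2
    map <- list(mu = 1L, aD = 1L + seq_len(N), aS = NULL, g = NULL)
    return(structure(list(C = Matrix::forceSymmetric(C), rhs = rhs,
                          map = map, social = FALSE,
                          group_model = "none", gp = gp),
                     class = "mme_system"))
  }
  ngrp <- max(data$rec_group)
  Vrec <- Matrix::sparseMatrix(i = seq_len(nrec), j = data$rec_group, x = 1,
                               dims = c(nrec, ngrp))
  # membership of each individual in each group (records are one-per-
  # individual, so Z_S falls out of the group membership):
  M <- Matrix::sparseMatrix(i = data$rec_id, j = data$rec_group, x = 1,
                            dims = c(N, ngrp))
  ZS <- Vrec %*% Matrix::t(M) - ZD
  G0inv <- g0_inverse(gp$G0)
  Gpart <- Matrix::bdiag(Matrix::Matrix(0, 1, 1),
                         kronecker(G0inv, data$Ainv))
  n <- gp$n_group
  if (group_model == "explicit") {
    if (gp$sigma_g2 <= 0) {
      stop("explicit group effects need sigma_g2 > 0; use the block form")
    }
    W <- cbind(rep(1, nrec), ZD, ZS, Vrec)
    C <- Matrix::crossprod(W) / gp$sigma_e2 +
      Matrix::bdiag(Gpart, Matrix::Diagonal(ngrp) / gp$sigma_g2)
    rhs <- Matrix::crossprod(W, data$y) / gp$sigma_e2
    map <- list(mu = 1L, aD = 1L + seq_len(N), aS = 1L + N + seq_len(N),
                g = 1L + 2L * N + seq_len(ngrp))
  } else {
    # R = I sigma_e2 + J_group sigma_g2 per group;
    # R^{-1} = alpha I + beta J_group with
    alpha <- 1 / gp$sigma_e2
    beta <- -gp$sigma_g2 / (gp$sigma_e2 * (gp$sigma_e2 + n * gp$sigma_g2))
    W <- cbind(rep(1, nrec), ZD, ZS)
    WtV <- Matrix::crossprod(W, Vrec)
    C <- alpha * Matrix::crossprod(W) + beta * Matrix::tcrossprod(WtV) +
      Gpart
    ysum <- Matrix::crossprod(Vrec, data$y)  # group sums of y
    rhs <- alpha * Matrix::crossprod(W, data$y) + beta * (WtV %*% ysum)
    map <- list(mu = 1L, aD = 1L + seq_len(N), aS = 1L + N + seq_len(N),
                g = NULL)
  }
  structure(list(C = Matrix::forceSymmetric(C), rhs = rhs, map = map,
                 social = TRUE, group_model = group_model, gp = gp),
            class = "mme_system")
}

#' Solve assembled mixed-model equations
#'
#' Sparse Cholesky solution of the normal equations, verified against the
#' stated relative-residual tolerance.  Estimated total breeding values are
#' \eqn{\widehat{TBV} = \hat a_D + (n-1) \hat a_S}
#' (just \eqn{\hat a_D} without indirect effects).
#'
#' @param system an [build_mme()] result.
#' @param tol relative residual tolerance.
#' @return an `mme_solution` list: `mu`, `aD`, `aS`, `g` (explicit
#'   formulation only), `etbv` for every pedigree member, and `residual`
#'   (the achieved relative residual of the normal equations).
#' @export
solve_mme <- function(system, tol = 1e-10) {
  C <- system$C
  sol <- tryCatch(
    as.numeric(Matrix::solve(C, system$rhs)),
    error = function(e) {
      # fall back to a regularised solve; report if even that drifts
      as.numeric(Matrix::solve(C + Matrix::Diagonal(nrow(C), 1e-10),
                               system$rhs))
    }
  )
  res <- sqrt(sum((as.numeric(C %*% sol) - as.numeric(system$rhs))^2)) /
    max(sqrt(sum(as.numeric(system$rhs)^2)), .Machine$double.eps)
  if (res > tol * 1e4) {
    stop("mixed-model solve did not converge (relative residual ",
         signif(res, 3), ")")
  }
  map <- system$map
  aD <- sol[map$aD]
  aS <- if (is.null(map$aS)) rep(0, length(aD)) else sol[map$aS]
  n <- system$gp$n_group
  structure(list(mu = sol[map$mu], aD = aD, aS = aS,
                 g = if (!is.null(map$g)) sol[map$g],
                 etbv = aD + (n - 1) * aS,
                 residual = res),
            class = "mme_solution")
}

#' BLUP evaluation of the current generation's candidates
#'
#' Fits the model on all phenotypes accumulated in generations
#' `1..generation` with the full pedigree and a single overall mean, and
#' returns the solution together with the estimated total breeding values
#' of the generation's candidates.
#'
#' @param pop population state.
#' @param gp a [derive_components()] result.
#' @param generation candidate generation (defaults to the newest).
#' @param Ainv optional precomputed [a_inverse()].
#' @param group_model passed to [build_mme()]; default uses the block
#'   residual (valid for any feasible \eqn{\sigma^2_g}).
#' @param cumulative if `TRUE` (default) all records of generations
#'   `1..generation` enter the fit; if `FALSE`, only the candidate
#'   generation's records (still with the full pedigree).
#' @return list with `solution` (an `mme_solution`), `candidates` (ids) and
#'   `etbv` (their estimated total breeding values).
#' @export
evaluate_generation <- function(pop, gp,
                                generation = max(pop$generation[seq_len(pop$n)]),
                                Ainv = NULL, group_model = "block",
                                cumulative = TRUE) {
  data <- evaluation_data(pop, up_to_generation = generation,
                          from_generation = if (cumulative) 1L
                                            else generation,
                          Ainv = Ainv)
  system <- build_mme(data, gp, group_model = group_model)
  solution <- solve_mme(system)
  idx <- seq_len(pop$n)
  candidates <- idx[pop$generation[idx] == generation]
  list(solution = solution, candidates = candidates,
       etbv = solution$etbv[candidates])
}

#' Export an assembled system or an EBV report as delimited text
#'
#' `write_mme_system()` writes the coefficient matrix in coordinate form
#' (columns `row`, `col`, `value`; the right-hand side follows as rows
#' with `col = 0`).  `write_ebv_report()` writes one row per pedigree
#' member with the estimated direct and indirect breeding values and the
#' estimated total breeding value.
#'
#' @param system an [build_mme()] result.
#' @param solution an [solve_mme()] result.
#' @param path output file path.
#' @param ids optional subset of individual ids to report.
#' @return the path, invisibly.
#' @export
write_mme_system <- function(system, path) {
  tri <- Matrix::mat2triplet(Matrix::triu(system$C))
  tab <- data.frame(row = c(tri$i, seq_along(as.numeric(system$rhs))),
                    col = c(tri$j, rep(0L, length(as.numeric(system$rhs)))),
                    value = c(tri$x, as.numeric(system$rhs)))
  utils::write.table(tab, path, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mme_system
#' @export
write_ebv_report <- function(solution, path, ids = seq_along(solution$aD)) {
  tab <- data.frame(id = ids, aD_hat = solution$aD[ids],
                    aS_hat = solution$aS[ids], etbv = solution$etbv[ids])
  utils::write.table(tab, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}
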