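# Turn a toy world into a population-state list for evaluation.
toy_population <- function(w) {
  nb <- min(w$ids) - 1L
  list(sire = w$ped$sire, dam = w$ped$dam, generation = w$ped$generation,
       sex = w$ped$sex,
       aD = c(rep(0, nb), w$aD), aS = c(rep(0, nb), w$aS),
       eD = c(rep(0, nb), w$eD), eS = c(rep(0, nb), w$eS),
       group = c(rep(NA_integer_, nb), w$group),
       phenotype = c(rep(NA_real_, nb), w$y),
       F = rep(0, nrow(w$ped)), n = nrow(w$ped))
}

test_that("sparse MME solution equals the dense GLS oracle on the toy set", {
  w <- make_toy_world("two_groups")
  pop <- toy_population(w)
  ev <- evaluate_generation(pop, w$gp, generation = 1L)
  expect_equal(ev$solution$mu, w$oracle_mu, tolerance = 1e-8)
  expect_equal(ev$solution$aD, w$oracle_aD, tolerance = 1e-8)
  expect_equal(ev$solution$aS, w$oracle_aS, tolerance = 1e-8)
  expect_equal(ev$solution$etbv, w$oracle_etbv, tolerance = 1e-8)
  expect_lt(ev$solution$residual, 1e-10)
  # unphenotyped base parents still receive EBVs via relationship ties
  expect_gt(max(abs(ev$solution$etbv[1:4])), 0)
})

test_that("explicit-group and block-residual formulations agree when sigma_g2 >= 0", {
  w <- make_toy_world("two_groups")
  pop <- toy_population(w)
  b <- evaluate_generation(pop, w$gp, generation = 1L,
                           group_model = "block")
  e <- evaluate_generation(pop, w$gp, generation = 1L,
                           group_model = "explicit")
  expect_equal(b$solution$etbv, e$solution$etbv, tolerance = 1e-8)
  expect_equal(b$solution$mu, e$solution$mu, tolerance = 1e-8)
  expect_length(e$solution$g, 2L)  # one effect per group
})

test_that("negative group covariance is handled by the block residual only", {
  cfg <- scenario_config(ige_magnitude = 0.25, h2_direct = 0.1,
                         r_ADS = -0.8, r_EDS = -0.8)
  gp <- derive_components(cfg)
  expect_lt(gp$sigma_g2, 0)
  w <- make_toy_world("two_groups")
  pop <- toy_population(w)
  data <- evaluation_data(pop)
  expect_error(build_mme(data, gp, group_model = "explicit"),
               "sigma_g2 > 0")
  sol <- solve_mme(build_mme(data, gp, group_model = "block"))
  expect_lt(sol$residual, 1e-10)
  # cross-check against the dense oracle under the same components
  A <- w$A
  X <- matrix(1, 16, 1)
  ZD <- matrix(0, 16, 20); ZD[cbind(1:16, w$ids)] <- 1
  ZS <- matrix(0, 16, 20)
  for (i in 1:16) {
    ZS[i, w$ids[w$group == w$group[i]]] <- 1
    ZS[i, w$ids[i]] <- 0
  }
  G <- kronecker(gp$G0, A)
  R <- diag(gp$sigma_e2, 16)
  for (g in 1:2) {
    m <- which(w$group == g)
    R[m, m] <- R[m, m] + gp$sigma_g2
  }
  oracle <- dense_blup(w$y, X, cbind(ZD, ZS), G, R)
  expect_equal(sol$aD, oracle$u[1:20], tolerance = 1e-8)
  expect_equal(sol$aS, oracle$u[21:40], tolerance = 1e-8)
})

test_that("the base scenario collapses to the single-trait animal model", {
  gp0 <- derive_components(scenario_config(ige_magnitude = 0,
                                           h2_direct = 0.3))
  w <- make_toy_world("two_groups")
  pop <- toy_population(w)
  data <- evaluation_data(pop)
  sys <- build_mme(data, gp0)
  expect_false(sys$social)
  expect_null(sys$map$aS)
  expect_equal(nrow(sys$C), 1L + 20L)  # mean + one equation per animal
  sol <- solve_mme(sys)
  # matches a dense single-trait animal-model oracle on the same records
  X <- matrix(1, 16, 1)
  ZD <- matrix(0, 16, 20); ZD[cbind(1:16, w$ids)] <- 1
  oracle <- dense_blup(w$y, X, ZD, gp0$sigma_AD2 * w$A,
                       diag(gp0$sigma_e2, 16))
  expect_equal(sol$aD, oracle$u, tolerance = 1e-8)
  expect_equal(sol$etbv, oracle$u, tolerance = 1e-8)  # TBV = A_D here
})

test_that("vanishing genetic variance shrinks all EBVs to zero", {
  cfg <- scenario_config(ige_magnitude = 1, h2_direct = 1e-8,
                         h2_indirect = 1e-8)
  gp <- derive_components(cfg)
  w <- make_toy_world("two_groups")
  pop <- toy_population(w)
  sol <- solve_mme(build_mme(evaluation_data(pop), gp))
  expect_lt(max(abs(sol$etbv)), 1e-4)
})

test_that("record order does not affect the solution", {
  w <- make_toy_world("two_groups")
  pop <- toy_population(w)
  data <- evaluation_data(pop)
  perm <- c(9, 3, 16, 1, 12, 5, 7, 14, 2, 11, 6, 4, 15, 10, 8, 13)
  data2 <- data
  data2$y <- data$y[perm]
  data2$rec_id <- data$rec_id[perm]
  data2$rec_group <- data$rec_group[perm]
  s1 <- solve_mme(build_mme(data, w$gp))
  s2 <- solve_mme(build_mme(data2, w$gp))
  expect_equal(s1$etbv, s2$etbv, tolerance = 1e-10)
})

test_that("BLUP with true components is unbiased and gains accuracy with h2", {
  set.seed(53)
  reg <- c(); acc <- list(lo = c(), hi = c())
  for (k in 1:4) {
    for (h2 in c(0.1, 0.5)) {
      cfg <- scenario_config(ige_magnitude = 1, h2_direct = h2)
      pop <- unselected_generation(cfg, 300 + k)
      gp <- derive_components(cfg)
      ev <- evaluate_generation(pop, gp, generation = 1L)
      tbv <- pop$aD[ev$candidates] + 7 * pop$aS[ev$candidates]
      if (h2 == 0.5) {
        reg <- c(reg, coef(lm(tbv ~ ev$etbv))[2])
      }
      key <- if (h2 == 0.1) "lo" else "hi"
      acc[[key]] <- c(acc[[key]], cor(tbv, ev$etbv))
    }
  }
  # regression of true on estimated TBV ~ 1 (BLUP property)
  expect_equal(mean(reg), 1, tolerance = 0.2)
  # accuracy increases with heritability at fixed IGE magnitude
  expect_gt(mean(acc$hi), mean(acc$lo))
})

test_that("system and EBV exports round-trip through text", {
  w <- make_toy_world("two_groups")
  pop <- toy_population(w)
  sys <- build_mme(evaluation_data(pop), w$gp)
  sol <- solve_mme(sys)
  f1 <- withr::local_tempfile(fileext = ".txt")
  write_mme_system(sys, f1)
  tab <- read.table(f1, header = TRUE)
  C <- as.matrix(sys$C)
  rhs_rows <- tab[tab$col == 0, ]
  expect_equal(rhs_rows$value, as.numeric(sys$rhs))
  coef_rows <- tab[tab$col != 0, ]
  expect_equal(coef_rows$value,
               C[cbind(coef_rows$row, coef_rows$col)])
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_ebv_report(sol, f2, ids = w$ids)
  rep <- read.table(f2, header = TRUE, sep = "\t")
  expect_equal(rep$etbv, sol$etbv[w$ids])
})
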