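test_that("component derivation reproduces the intermediate-IGE scenario", {
  gp <- derive_components(scenario_config(ige_magnitude = 1,
                                          h2_direct = 0.3))
  expect_equal(gp$sigma_PS2, 1 / 7)
  expect_equal(gp$sigma_AS2, 0.3 / 7)
  expect_equal(gp$sigma_ES2, 0.1)
  expect_equal(gp$sigma_g2, 0.6)
  expect_equal(gp$sigma_e2, 0.8)
  expect_equal(gp$G0, matrix(c(0.3, 0, 0, 0.3 / 7), 2, 2,
                             dimnames = dimnames(gp$G0)))
})

test_that("no IGE collapses every derived quantity to the classical case", {
  gp <- derive_components(scenario_config(ige_magnitude = 0,
                                          h2_direct = 0.3))
  expect_equal(gp$sigma_AS2, 0)
  expect_equal(gp$sigma_ES2, 0)
  expect_equal(gp$sigma_g2, 0)
  expect_equal(gp$sigma_e2, gp$sigma_ED2)
  expect_equal(phenotypic_variance_two_family_groups(gp), 1)
  expect_equal(classical_heritability(gp), 0.3)
  expect_equal(total_heritable_ratio(gp)$T2, 0.3)
})

test_that("group covariance can be negative under competitive non-genetic effects", {
  gp <- derive_components(scenario_config(ige_magnitude = 0.25,
                                          h2_direct = 0.1, r_EDS = -0.8))
  expect_equal(gp$sigma_g2,
               2 * (-0.8) * sqrt(0.9 * 0.9 * 0.25 / 7) + 6 * 0.9 * 0.25 / 7,
               tolerance = 1e-12)
  expect_lt(gp$sigma_g2, 0)
  # the block residual stays positive definite nonetheless
  expect_gt(gp$sigma_e2 + gp$n_group * gp$sigma_g2, 0)
})

test_that("knobs round-trip through the derived components", {
  grid <- expand.grid(m = c(0.25, 1, 4), h2 = c(0.1, 0.3, 0.5),
                      r = c(-0.8, -0.4, 0, 0.4, 0.8))
  for (k in seq_len(nrow(grid))) {
    cfg <- scenario_config(ige_magnitude = grid$m[k],
                           h2_direct = grid$h2[k],
                           h2_indirect = grid$h2[k],
                           r_ADS = grid$r[k], r_EDS = grid$r[k])
    gp <- derive_components(cfg)
    n <- cfg$n_group
    expect_equal((n - 1) * (gp$sigma_AS2 + gp$sigma_ES2), cfg$ige_magnitude,
                 tolerance = 1e-12)
    expect_equal(gp$sigma_AD2 / (gp$sigma_AD2 + gp$sigma_ED2),
                 cfg$h2_direct, tolerance = 1e-12)
    expect_equal(gp$sigma_AS2 / gp$sigma_PS2, cfg$h2_indirect,
                 tolerance = 1e-12)
    expect_equal(gp$sigma_ADS / sqrt(gp$sigma_AD2 * gp$sigma_AS2),
                 cfg$r_ADS, tolerance = 1e-12)
    expect_symmetric_psd(gp$G0)
  }
})

test_that("analytic quantities match direct hand evaluation", {
  gp1 <- derive_components(scenario_config(ige_magnitude = 0.25,
                                           h2_direct = 0.3))
  expect_equal(phenotypic_variance_two_family_groups(gp1), 1.3464286,
               tolerance = 1e-6)
  expect_equal(expected_neutral_deltaF(100, 200), 0.001875)
  expect_equal(expected_neutral_deltaF(40, 40), 1 / 160)
  expect_error(expected_neutral_deltaF(0, 50), "positive")
})

test_that("infeasible residual structure is rejected", {
  # perfectly correlated non-genetic effects of equal variance leave no
  # residual variance (sigma_ES2 = sigma_ED2 = 0.7 here)
  expect_error(
    derive_components(scenario_config(ige_magnitude = 7, h2_direct = 0.3,
                                      r_EDS = 1)),
    "positive definite")
})

test_that("fixing the classical heritability adjusts only the direct split", {
  cfg <- scenario_config(ige_magnitude = 1, h2_direct = 0.3)
  gp <- derive_components(cfg)
  # default convention: direct phenotypic variance stays 1
  gfix <- solve_fixed_classical_h2(0.3, gp)
  expect_equal(gfix$sigma_AD2,
               0.3 * phenotypic_variance_two_family_groups(gp),
               tolerance = 1e-10)
  expect_equal(gfix$sigma_AD2 + gfix$sigma_ED2, 1, tolerance = 1e-10)
  expect_equal(classical_heritability(gfix), 0.3, tolerance = 1e-10)
  expect_equal(gfix$sigma_AS2, gp$sigma_AS2)
  expect_equal(gfix$sigma_ES2, gp$sigma_ES2)
  # strong IGE needs a direct heritability above 1: infeasible
  g3 <- derive_components(scenario_config(ige_magnitude = 4,
                                          h2_direct = 0.3))
  expect_error(solve_fixed_classical_h2(0.3, g3), "exceeds 1")
  # alternative convention: sigma_ED2 held, phenotypic variance grows
  galt <- solve_fixed_classical_h2(0.3, gp, keep = "sigma_ED2")
  expect_equal(galt$sigma_AD2, 0.3 * (0.7 + 16 * 0.3 / 7 + 7 * 0.1) / 0.7,
               tolerance = 1e-10)
  expect_equal(galt$sigma_ED2, gp$sigma_ED2)
  expect_equal(classical_heritability(galt), 0.3, tolerance = 1e-10)
  # base scenario at its own heritability is a fixed point
  gb <- derive_components(scenario_config(ige_magnitude = 0,
                                          h2_direct = 0.3))
  expect_equal(solve_fixed_classical_h2(0.3, gb)$sigma_AD2, gb$sigma_AD2,
               tolerance = 1e-10)
})

test_that("fixed-heritability root finder agrees with a brute-force grid", {
  cfg <- scenario_config(ige_magnitude = 0.25, h2_direct = 0.3,
                         r_ADS = 0.4, r_EDS = 0)
  gp <- derive_components(cfg)
  for (keep in c("sigma_PD2", "sigma_ED2")) {
    gfix <- solve_fixed_classical_h2(0.3, gp, keep = keep)
    expect_equal(classical_heritability(gfix), 0.3, tolerance = 1e-10)
    # brute force: scan sigma_AD2, keep the best
    grid <- seq(0.01, if (keep == "sigma_PD2") 0.999 else 2, by = 1e-4)
    h2g <- vapply(grid, function(s) {
      sED2 <- if (keep == "sigma_PD2") 1 - s else gp$sigma_ED2
      sADS <- cfg$r_ADS * sqrt(s * gp$sigma_AS2)
      sP2 <- s + sED2 + 7 * (gp$sigma_AS2 + gp$sigma_ES2) +
        2 * 3 * 0.5 * sADS + 2 * 9 * 0.5 * gp$sigma_AS2
      s / sP2
    }, numeric(1))
    best <- grid[which.min(abs(h2g - 0.3))]
    expect_equal(gfix$sigma_AD2, best, tolerance = 1e-3)
  }
})

test_that("Monte-Carlo covariance of simulated group mates matches sigma_g2", {
  # all-environmental scenario: phenotype = own E_D + mates' E_S
  set.seed(41)
  cfg <- scenario_config(ige_magnitude = 1, h2_direct = 0, h2_indirect = 0,
                         r_EDS = 0.4)
  gp <- derive_components(cfg)
  pop <- unselected_generation(cfg, 99, gp = gp)
  ids <- which(pop$generation[seq_len(pop$n)] == 1L)
  ph <- pop$phenotype[ids]; grp <- pop$group[ids]; dams <- pop$dam[ids]
  # pairs of *unrelated* group mates (different families)
  xs <- c(); ys <- c()
  for (g in unique(grp)) {
    m <- ids[grp == g]
    for (i in seq_along(m)) for (j in seq_along(m)) {
      if (i != j && dams[match(m[i], ids)] != dams[match(m[j], ids)]) {
        xs <- c(xs, ph[match(m[i], ids)]); ys <- c(ys, ph[match(m[j], ids)])
      }
    }
  }
  # double-entered pairs; MC tolerance ~3 SE of a covariance of ~1600 pairs
  emp <- mean(xs * ys) - mean(xs) * mean(ys)
  expect_equal(emp, gp$sigma_g2, tolerance = 0.12)
  # total non-genetic variance of a record
  expect_equal(stats::var(ph), gp$sigma_g2 + gp$sigma_e2, tolerance = 0.2)
})

test_that("scenario grids load from YAML with defaults", {
  path <- system.file("extdata", "scenarios.yaml", package = "igesim")
  grid <- read_scenario_grid(path)
  expect_true(all(vapply(grid, inherits, logical(1), "scenario_config")))
  expect_true("base_h2_0.3" %in% names(grid))
  expect_equal(grid[["scenario2_neutral_h2_0.3"]]$ige_magnitude, 1)
  tab <- derived_quantities_table(grid)
  expect_equal(tab$h2_classical[tab$scenario == "scenario2_neutral_h2_0.3"],
               0.3 / 2.3857143, tolerance = 1e-6)
})
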