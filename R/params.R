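#' Scenario configuration for a social-breeding simulation
#'
#' Bundles the four knobs that define a scenario point -- the magnitude of
#' the indirect effect, the direct and indirect heritabilities and the
#' direct-indirect correlations -- together with the population design
#' (25 sires, 50 dams mated 1:2, 8 progeny per dam, groups of 8 made of two
#' full-sib families, 20 generations).
#'
#' The magnitude of the indirect effect is expressed as its contribution to
#' phenotypic variance among unrelated group mates, \eqn{(n-1)\sigma^2_{PS}},
#' so `ige_magnitude = 0` is the classical single-trait model and
#' `ige_magnitude = 1` means indirect effects contribute as much variance as
#' the whole direct phenotypic variance.
#'
#' @param ige_magnitude contribution of indirect effects to phenotypic
#'   variance among unrelated group mates, \eqn{(n-1)\sigma^2_{PS}}.
#'   The study grid uses 0 (base), 0.25, 1 and 4.
#' @param h2_direct direct heritability \eqn{\sigma^2_{AD}/\sigma^2_{PD}}.
#' @param h2_indirect indirect heritability
#'   \eqn{\sigma^2_{AS}/\sigma^2_{PS}}; ignored when `ige_magnitude = 0`.
#' @param r_ADS genetic direct-indirect correlation, in \eqn{[-1, 1]}.
#' @param r_EDS non-genetic direct-indirect correlation, in \eqn{[-1, 1]}.
#' @param sigma_PD2 direct phenotypic variance (the study fixes it at 1).
#' @param n_group group size (8: two full-sib families of four).
#' @param n_sires,n_dams numbers of selected parents per generation.
#' @param progeny_per_dam full-sib family size.
#' @param generations number of discrete generations of selection.
#' @param burn_in_generation generation whose mean inbreeding starts the
#'   rate-of-inbreeding window (the window ends at `generations`).
#' @param replicates default number of Monte-Carlo replicates.
#' @param seed default master seed for [run_experiment()].
#' @return An object of class `"scenario_config"` (a validated list).
#' @seealso [derive_components()], [run_replicate()]
#' @export
#' @examples
#' cfg <- scenario_config(ige_magnitude = 1, h2_direct = 0.3, h2_indirect = 0.3)
#' derive_components(cfg)
scenario_config <- function(ige_magnitude = 0,
                            h2_direct = 0.3,
                            h2_indirect = h2_direct,
                            r_ADS = 0,
                            r_EDS = 0,
                            sigma_PD2 = 1,
                            n_group = 8L,
                            n_sires = 25L,
                            n_dams = 50L,
                            progeny_per_dam = 8L,
                            generations = 20L,
                            burn_in_generation = 10L,
                            replicates = 100L,
                            seed = 1L) {
  cfg <- list(
    ige_magnitude = as.numeric(ige_magnitude),
    h2_direct = as.numeric(h2_direct),
    h2_indirect = as.numeric(h2_indirect),
    r_ADS = as.numeric(r_ADS),
    r_EDS = as.numeric(r_EDS),
    sigma_PD2 = as.numeric(sigma_PD2),
    n_group = as.integer(n_group),
    n_sires = as.integer(n_sires),
    n_dams = as.integer(n_dams),
    progeny_per_dam = as.integer(progeny_per_dam),
    generations = as.integer(generations),
    burn_in_generation = as.integer(burn_in_generation),
    replicates = as.integer(replicates),
    seed = as.integer(seed)
  )
  class(cfg) <- "scenario_config"
  validate_scenario_config(cfg)
  cfg
}

validate_scenario_config <- function(cfg) {
  stopifnot(
    cfg$ige_magnitude >= 0,
    cfg$sigma_PD2 > 0,
    cfg$h2_direct >= 0, cfg$h2_direct <= 1,
    cfg$h2_indirect >= 0, cfg$h2_indirect <= 1,
    abs(cfg$r_ADS) <= 1, abs(cfg$r_EDS) <= 1,
    cfg$n_group >= 2L, cfg$n_group %% 2L == 0L,
    cfg$n_sires >= 1L,
    cfg$n_dams == 2L * cfg$n_sires,
    cfg$progeny_per_dam >= 1L,
    (cfg$progeny_per_dam * cfg$n_dams) %% cfg$n_group == 0L,
    cfg$generations >= 1L,
    cfg$burn_in_generation >= 0L,
    cfg$burn_in_generation < cfg$generations
  )
  invisible(cfg)
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Scenario configuration\n")
  cat(sprintf("  IGE magnitude (n-1)sPS2 : %g\n", x$ige_magnitude))
  cat(sprintf("  h2 direct / indirect    : %g / %g\n", x$h2_direct, x$h2_indirect))
  cat(sprintf("  r_ADS / r_EDS           : %g / %g\n", x$r_ADS, x$r_EDS))
  cat(sprintf("  design: %d sires x %d dams, %d progeny/dam, groups of %d\n",
              x$n_sires, x$n_dams, x$progeny_per_dam, x$n_group))
  cat(sprintf("  %d generations, dF window %d..%d, %d replicates\n",
              x$generations, x$burn_in_generation, x$generations, x$replicates))
  invisible(x)
}

#' Derive all simulation and evaluation (co)variance components
#'
#' Expands a scenario point into the full set of direct and indirect genetic
#' and non-genetic (co)variances.  The indirect phenotypic variance is
#' \eqn{\sigma^2_{PS} = m/(n-1)} where m is the IGE magnitude; heritabilities
#' split each phenotypic variance into genetic and non-genetic parts, and
#' the correlations set the covariances.  Two quantities of the fitted model
#' follow from the non-genetic decomposition:
#' \itemize{
#'   \item the within-group non-genetic covariance (the "group effect"
#'     variance) \eqn{\sigma^2_g = 2\sigma_{EDS} + (n-2)\sigma^2_{ES}};
#'   \item the i.i.d. residual
#'     \eqn{\sigma^2_e = \sigma^2_{ED} - 2\sigma_{EDS} + \sigma^2_{ES}},
#'     i.e. the total non-genetic variance of a record,
#'     \eqn{\sigma^2_{ED} + (n-1)\sigma^2_{ES}}, minus \eqn{\sigma^2_g}.
#' }
#' \eqn{\sigma^2_g} can be negative under competitive non-genetic
#' correlations; the BLUP module then absorbs it into a block-structured
#' residual instead of a non-negative group variance component.
#'
#' @param config a [scenario_config()].
#' @return An object of class `"genetic_parameters"`: a list with elements
#'   `sigma_AD2`, `sigma_ED2`, `sigma_PS2`, `sigma_AS2`, `sigma_ES2`,
#'   `sigma_ADS`, `sigma_EDS`, `sigma_g2`, `sigma_e2`, the 2x2 genetic
#'   covariance matrix `G0` of (A_D, A_S), the matching non-genetic matrix
#'   `E0`, plus `n_group` and a back-reference `config`.
#' @export
derive_components <- function(config) {
  validate_scenario_config(config)
  n <- config$n_group
  sigma_AD2 <- config$h2_direct * config$sigma_PD2
  sigma_ED2 <- (1 - config$h2_direct) * config$sigma_PD2
  sigma_PS2 <- config$ige_magnitude / (n - 1)
  sigma_AS2 <- config$h2_indirect * sigma_PS2
  sigma_ES2 <- (1 - config$h2_indirect) * sigma_PS2
  sigma_ADS <- config$r_ADS * sqrt(sigma_AD2 * sigma_AS2)
  sigma_EDS <- config$r_EDS * sqrt(sigma_ED2 * sigma_ES2)
  gp <- build_genetic_parameters(sigma_AD2, sigma_ED2, sigma_PS2,
                                 sigma_AS2, sigma_ES2, sigma_ADS, sigma_EDS,
                                 n, config)
  gp
}

# Assemble a genetic_parameters object from raw components and check that
# the within-group non-genetic covariance block is positive definite.
build_genetic_parameters <- function(sigma_AD2, sigma_ED2, sigma_PS2,
                                     sigma_AS2, sigma_ES2, sigma_ADS,
                                     sigma_EDS, n, config) {
  sigma_g2 <- 2 * sigma_EDS + (n - 2) * sigma_ES2
  sigma_e2 <- sigma_ED2 - 2 * sigma_EDS + sigma_ES2
  G0 <- matrix(c(sigma_AD2, sigma_ADS, sigma_ADS, sigma_AS2), 2, 2,
               dimnames = list(c("AD", "AS"), c("AD", "AS")))
  E0 <- matrix(c(sigma_ED2, sigma_EDS, sigma_EDS, sigma_ES2), 2, 2,
               dimnames = list(c("ED", "ES"), c("ED", "ES")))
  # Non-genetic covariance block among the n records of one group is
  # compound symmetric: diagonal sigma_e2 + sigma_g2, off-diagonal sigma_g2.
  # Its eigenvalues are sigma_e2 (n-1 times) and sigma_e2 + n * sigma_g2.
  if (sigma_e2 <= 0 || sigma_e2 + n * sigma_g2 <= 0) {
    stop("infeasible parameter combination: within-group non-genetic ",
         "covariance block is not positive definite (sigma_e2 = ",
         signif(sigma_e2, 6), ", sigma_e2 + n*sigma_g2 = ",
         signif(sigma_e2 + n * sigma_g2, 6), ")")
  }
  if (min(eigen(G0, symmetric = TRUE, only.values = TRUE)$values) < -1e-12) {
    stop("G0 is not positive semidefinite")
  }
  gp <- list(sigma_AD2 = sigma_AD2, sigma_ED2 = sigma_ED2,
             sigma_PS2 = sigma_PS2, sigma_AS2 = sigma_AS2,
             sigma_ES2 = sigma_ES2, sigma_ADS = sigma_ADS,
             sigma_EDS = sigma_EDS, sigma_g2 = sigma_g2,
             sigma_e2 = sigma_e2, G0 = G0, E0 = E0,
             n_group = n, config = config)
  class(gp) <- "genetic_parameters"
  gp
}

#' @export
print.genetic_parameters <- function(x, ...) {
  cat("Genetic parameters (direct / indirect)\n")
  cat(sprintf("  sigma_AD2 = %.6g  sigma_AS2 = %.6g  sigma_ADS = %.6g\n",
              x$sigma_AD2, x$sigma_AS2, x$sigma_ADS))
  cat(sprintf("  sigma_ED2 = %.6g  sigma_ES2 = %.6g  sigma_EDS = %.6g\n",
              x$sigma_ED2, x$sigma_ES2, x$sigma_EDS))
  cat(sprintf("  group sigma_g2 = %.6g, residual sigma_e2 = %.6g\n",
              x$sigma_g2, x$sigma_e2))
  invisible(x)
}

#' Phenotypic variance in groups of two full-sib families
#'
#' Variance of a phenotype when each group of size n holds two full-sib
#' families of n/2 (sib relationship r = 1/2).  Beyond the unrelated-mates
#' terms \eqn{\sigma^2_{AD} + \sigma^2_{ED} + (n-1)(\sigma^2_{AS} +
#' \sigma^2_{ES})}, relatedness adds (i) the covariance between an
#' individual's direct value and the indirect values of its n/2 - 1 sib
#' group mates, and (ii) the covariances among indirect values of the p
#' related pairs within its n-1 mates.  For n = 8 the mates are 3 own sibs
#' and 4 members of the partner family, so p = choose(3,2) + choose(4,2) = 9.
#'
#' @param gp a [derive_components()] result.
#' @param config optional scenario; defaults to `gp$config`.
#' @return the phenotypic variance (a scalar).
#' @export
phenotypic_variance_two_family_groups <- function(gp, config = gp$config) {
  n <- config$n_group
  r <- 0.5
  half <- n / 2
  p <- choose(half - 1, 2) + choose(half, 2)  # related pairs among n-1 mates
  gp$sigma_AD2 + gp$sigma_ED2 +
    (n - 1) * (gp$sigma_AS2 + gp$sigma_ES2) +
    2 * (half - 1) * r * gp$sigma_ADS +
    2 * p * r * gp$sigma_AS2
}

#' Classical (direct) heritability under the two-family group design
#'
#' \eqn{\sigma^2_{AD}/\sigma^2_P} with the phenotypic variance of
#' [phenotypic_variance_two_family_groups()].  With indirect effects in the
#' phenotype this is smaller than the input direct heritability.
#'
#' @inheritParams phenotypic_variance_two_family_groups
#' @return the heritability ratio.
#' @export
classical_heritability <- function(gp, config = gp$config) {
  gp$sigma_AD2 / phenotypic_variance_two_family_groups(gp, config)
}

#' Total heritable variance ratio T2
#'
#' The variance of the total breeding value
#' \eqn{TBV = A_D + (n-1) A_S}, i.e.
#' \eqn{\sigma^2_{TBV} = \sigma^2_{AD} + 2(n-1)\sigma_{ADS} +
#' (n-1)^2 \sigma^2_{AS}}, divided by the two-family-group phenotypic
#' variance.  T2 is the analogue of heritability for socially affected
#' traits and can exceed 1.
#'
#' @inheritParams phenotypic_variance_two_family_groups
#' @return list with `sigma_TBV2` and `T2`.
#' @export
total_heritable_ratio <- function(gp, config = gp$config) {
  n <- config$n_group
  sigma_TBV2 <- gp$sigma_AD2 + 2 * (n - 1) * gp$sigma_ADS +
    (n - 1)^2 * gp$sigma_AS2
  list(sigma_TBV2 = sigma_TBV2,
       T2 = sigma_TBV2 / phenotypic_variance_two_family_groups(gp, config))
}

#' Expected no-selection rate of inbreeding
#'
#' Classical prediction \eqn{\Delta F = 1/(8 N_m) + 1/(8 N_f)} for an
#' idealised population with `n_sires` male and `n_dams` female parents per
#' generation and random selection.
#'
#' @param n_sires,n_dams numbers of male and female parents (> 0).
#' @return the expected rate of inbreeding per generation.
#' @export
#' @examples
#' expected_neutral_deltaF(25, 50)  # 0.0075
expected_neutral_deltaF <- function(n_sires, n_dams) {
  if (n_sires <= 0 || n_dams <= 0) stop("parent counts must be positive")
  1 / (8 * n_sires) + 1 / (8 * n_dams)
}

#' Rescale the direct genetic variance to fix the classical heritability
#'
#' Returns parameters in which \eqn{\sigma^2_{AD}} is increased so that the
#' classical heritability under the two-family group design equals
#' `target_h2`, while all indirect components (genetic and non-genetic)
#' stay at their original values.  Two conventions for the non-genetic
#' direct variance are supported:
#' \describe{
#'   \item{`keep = "sigma_PD2"` (default)}{\eqn{\sigma^2_{ED}} shrinks so
#'     that the direct phenotypic variance
#'     \eqn{\sigma^2_{PD} = \sigma^2_{AD} + \sigma^2_{ED}} stays at its
#'     original value (1 in the study grid).  The target is then
#'     infeasible as soon as the required \eqn{\sigma^2_{AD}} exceeds
#'     \eqn{\sigma^2_{PD}}, i.e. as soon as the required direct
#'     heritability exceeds 1 -- which is exactly the situation for the
#'     strong-IGE scenario at a target of 0.3.}
#'   \item{`keep = "sigma_ED2"`}{\eqn{\sigma^2_{ED}} stays at its original
#'     value and the direct phenotypic variance grows.}
#' }
#' Solved in closed form when the direct-indirect correlations are zero,
#' otherwise by 1-D root finding (the covariances track
#' \eqn{r\sqrt{\cdot}}).
#'
#' @param target_h2 classical heritability to attain, in (0, 1).
#' @param gp starting [derive_components()] result.
#' @param config optional scenario; defaults to `gp$config`.
#' @param keep which non-genetic convention to hold fixed (see above).
#' @return a new `genetic_parameters` object whose
#'   [classical_heritability()] equals `target_h2` to 1e-10.
#' @export
solve_fixed_classical_h2 <- function(target_h2, gp, config = gp$config,
                                     keep = c("sigma_PD2", "sigma_ED2")) {
  stopifnot(target_h2 > 0, target_h2 < 1)
  keep <- match.arg(keep)
  n <- config$n_group
  r <- 0.5
  half <- n / 2
  p <- choose(half - 1, 2) + choose(half, 2)
  sigma_PD2 <- gp$sigma_AD2 + gp$sigma_ED2
  # indirect-effect part of sigma_P2, independent of the direct split
  indir <- (n - 1) * (gp$sigma_AS2 + gp$sigma_ES2) +
    2 * p * r * gp$sigma_AS2
  rebuild <- function(sAD2) {
    sED2 <- if (keep == "sigma_PD2") sigma_PD2 - sAD2 else gp$sigma_ED2
    if (sED2 < 0) stop("target classical heritability not attainable: ",
                       "required direct heritability exceeds 1")
    sADS <- config$r_ADS * sqrt(sAD2 * gp$sigma_AS2)
    sEDS <- config$r_EDS * sqrt(sED2 * gp$sigma_ES2)
    build_genetic_parameters(sAD2, sED2, gp$sigma_PS2,
                             gp$sigma_AS2, gp$sigma_ES2, sADS, sEDS,
                             n, config)
  }
  neutral <- config$r_ADS == 0 && (config$r_EDS == 0 || keep == "sigma_ED2")
  if (neutral || gp$sigma_AS2 == 0) {
    sAD2 <- if (keep == "sigma_PD2") {
      # sigma_P2 = sigma_PD2 + indir regardless of the split
      target_h2 * (sigma_PD2 + indir)
    } else {
      # target = sAD2 / (sAD2 + sigma_ED2 + indir)
      target_h2 * (gp$sigma_ED2 + indir) / (1 - target_h2)
    }
    if (keep == "sigma_PD2" && sAD2 > sigma_PD2) {
      stop("target classical heritability not attainable: required direct ",
           "heritability ", signif(sAD2 / sigma_PD2, 4), " exceeds 1")
    }
  } else {
    f <- function(sAD2) classical_heritability(rebuild(sAD2)) - target_h2
    upper <- if (keep == "sigma_PD2") sigma_PD2 else max(1, gp$sigma_AD2)
    if (keep == "sigma_ED2") {
      while (f(upper) < 0 && upper < 1e8) upper <- upper * 2
    }
    if (f(upper) < 0) {
      stop("target classical heritability not attainable",
           if (keep == "sigma_PD2") ": required direct heritability exceeds 1")
    }
    sAD2 <- stats::uniroot(f, c(1e-12, upper), tol = 1e-14)$root
  }
  out <- rebuild(sAD2)
  if (abs(classical_heritability(out) - target_h2) > 1e-10) {
    stop("fixed-heritability solve did not converge")
  }
  out
}

#' Read a scenario grid from a YAML configuration file
#'
#' The file maps scenario names to knob values understood by
#' [scenario_config()]; a top-level `defaults:` block applies to every
#' scenario.  See `system.file("extdata", "scenarios.yaml", package =
#' "igesim")` for the study grid layout.
#'
#' @param path path to a YAML file.
#' @return named list of [scenario_config()] objects.
#' @export
read_scenario_grid <- function(path) {
  raw <- yaml::read_yaml(path)
  defaults <- raw$defaults
  raw$defaults <- NULL
  lapply(raw, function(knobs) {
    do.call(scenario_config, utils::modifyList(as.list(defaults),
                                               as.list(knobs)))
  })
}

#' Tabulate derived quantities for a list of scenarios
#'
#' @param scenarios named list of [scenario_config()] objects.
#' @return data.frame with one row per scenario: the knobs, all derived
#'   components and the analytic summary quantities (two-family phenotypic
#'   variance, classical heritability, T2, neutral delta-F).
#' @export
derived_quantities_table <- function(scenarios) {
  rows <- lapply(names(scenarios), function(nm) {
    cfg <- scenarios[[nm]]
    gp <- derive_components(cfg)
    tt <- total_heritable_ratio(gp)
    data.frame(
      scenario = nm,
      ige_magnitude = cfg$ige_magnitude,
      h2_direct = cfg$h2_direct, h2_indirect = cfg$h2_indirect,
      r_ADS = cfg$r_ADS, r_EDS = cfg$r_EDS,
      sigma_AD2 = gp$sigma_AD2, sigma_AS2 = gp$sigma_AS2,
      sigma_ADS = gp$sigma_ADS, sigma_ED2 = gp$sigma_ED2,
      sigma_ES2 = gp$sigma_ES2, sigma_EDS = gp$sigma_EDS,
      sigma_g2 = gp$sigma_g2, sigma_e2 = gp$sigma_e2,
      sigma_P2_two_family = phenotypic_variance_two_family_groups(gp),
      h2_classical = classical_heritability(gp),
      sigma_TBV2 = tt$sigma_TBV2, T2 = tt$T2,
      deltaF_neutral = expected_neutral_deltaF(cfg$n_sires, cfg$n_dams),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
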