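# Orchestration of the closed-nucleus selection program: per generation,
# evaluate all candidates by BLUP of total breeding value, truncate within
# sex, mate the selected parents in a nested 1 sire : 2 dams design, and
# track pedigree inbreeding.  The rate of inbreeding is taken over the
# post-burn-in window (generations 10 to 20 by default) so that the Bulmer
# effect and the buildup of pedigree information have equilibrated.

#' Truncation selection of parents on estimated total breeding value
#'
#' Selects the top `n_sires` males and `n_dams` females by ETBV, ties
#' broken by lowest id (deterministic).
#'
#' @param candidates integer ids of the selection candidates.
#' @param sex character vector (`"M"`/`"F"`) parallel to `candidates`.
#' @param etbv numeric vector of estimated total breeding values, parallel
#'   to `candidates`.
#' @param n_sires,n_dams numbers to select.
#' @return list with sorted integer vectors `sires` and `dams`.
#' @export
select_parents <- function(candidates, sex, etbv, n_sires, n_dams) {
  pick <- function(which_sex, k) {
    sel <- sex == which_sex
    if (sum(sel) < k) {
      stop("only ", sum(sel), " candidates of sex ", which_sex,
           " for ", k, " slots")
    }
    ids <- candidates[sel]
    ord <- order(-etbv[sel], ids)
    sort(ids[ord[seq_len(k)]])
  }
  list(sires = pick("M", n_sires), dams = pick("F", n_dams))
}

#' Random nested 1:2 mating
#'
#' Dams are randomly permuted and assigned two per sire; every dam is used
#' exactly once, every sire exactly twice.
#'
#' @param sires,dams integer id vectors with `length(dams) == 2 *
#'   length(sires)`.
#' @return data.frame with columns `sire`, `dam`, one row per mating.
#' @export
mate_nested <- function(sires, dams) {
  if (length(dams) != 2L * length(sires)) {
    stop("nested 1:2 design needs exactly twice as many dams as sires")
  }
  data.frame(sire = rep(sires, each = 2L), dam = sample(dams))
}

#' Run one replicate of the breeding program
#'
#' Simulates the full program: unrelated base parents (generation 0), then
#' per generation BLUP evaluation on all accumulated records, truncation
#' selection of 25 sires and 50 dams on estimated total breeding value,
#' nested random mating, 8 progeny per dam, random two-family groups of 8
#' and phenotype construction.  Inbreeding is tracked from the pedigree and
#' the rate of inbreeding is computed from the mean coefficients of the
#' burn-in and final generations.
#'
#' @param config a [scenario_config()].
#' @param seed integer seed for this replicate.
#' @param gp genetic parameters; defaults to [derive_components()] of
#'   `config`, but can be overridden (e.g. by
#'   [solve_fixed_classical_h2()]).
#' @param group_model passed to [build_mme()].
#' @param track_sib_cor if `TRUE`, per-generation full- and half-sib
#'   correlations of estimated total breeding values are recorded for the
#'   post-burn-in generations.
#' @param random_selection if `TRUE`, parents are chosen at random instead
#'   of on ETBV (no-selection control; BLUP evaluation is skipped).
#' @param cumulative passed to [evaluate_generation()].  The default
#'   (`FALSE`) fits each generation's records with the full pedigree, which
#'   is how the reproduced selection program behaves; `TRUE` accumulates
#'   all records across generations.
#' @return a `replicate_result` list: `F_bar` (mean inbreeding per
#'   generation 0..G), `delta_F`, `sib_cor` (data.frame or `NULL`),
#'   `seed`, and the final `pop`ulation state.
#' @export
run_replicate <- function(config, seed, gp = derive_components(config),
                          group_model = "block", track_sib_cor = FALSE,
                          random_selection = FALSE, cumulative = FALSE) {
  validate_scenario_config(config)
  set.seed(seed)
  G <- config$generations
  pop <- init_base_population(gp)
  sires <- seq_len(config$n_sires)
  dams <- config$n_sires + seq_len(config$n_dams)
  F_bar <- numeric(G + 1L)  # index t+1 = generation t
  sib_rows <- list()
  for (t in seq_len(G)) {
    matings <- mate_nested(sires, dams)
    first_new <- pop$n + 1L
    pop <- make_progeny_cohort(matings, pop, gp, t, config$progeny_per_dam)
    cohort <- first_new:pop$n
    # inbreeding of the new cohort given all earlier coefficients
    pop$F[seq_len(pop$n)] <- ml_inbreeding_cpp(
      pop$sire[seq_len(pop$n)], pop$dam[seq_len(pop$n)],
      pop$F[seq_len(pop$n)], first_new)
    F_bar[t + 1L] <- mean(pop$F[cohort])
    # two-family groups (families are dam-defined under nested mating)
    pop$group[cohort] <- assign_groups(cohort, pop$dam[cohort],
                                       config$n_group)
    pop <- construct_phenotypes(pop, cohort)
    if (random_selection) {
      males <- cohort[pop$sex[cohort] == "M"]
      females <- cohort[pop$sex[cohort] == "F"]
      if (length(males) < config$n_sires ||
          length(females) < config$n_dams) {
        stop("replicate aborted: fewer candidates of a sex than parents ",
             "needed in generation ", t)
      }
      sires <- sort(sample(males, config$n_sires))
      dams <- sort(sample(females, config$n_dams))
    } else {
      ped <- population_pedigree(pop)
      Ainv <- a_inverse(ped, pop$F[seq_len(pop$n)])
      ev <- evaluate_generation(pop, gp, generation = t, Ainv = Ainv,
                                group_model = group_model,
                                cumulative = cumulative)
      sel <- select_parents(ev$candidates, pop$sex[ev$candidates],
                            ev$etbv, config$n_sires, config$n_dams)
      sires <- sel$sires
      dams <- sel$dams
      if (track_sib_cor && t >= config$burn_in_generation) {
        sc <- sib_classes(ped, t)
        etbv_all <- ev$solution$etbv
        sib_rows[[length(sib_rows) + 1L]] <- data.frame(
          generation = t,
          full = sib_pair_correlation(etbv_all, sc$full),
          half = sib_pair_correlation(etbv_all, sc$half))
      }
    }
  }
  dF <- delta_F(F_bar[config$burn_in_generation + 1L], F_bar[G + 1L],
                G - config$burn_in_generation)
  structure(list(F_bar = F_bar, delta_F = dF,
                 sib_cor = if (length(sib_rows)) do.call(rbind, sib_rows),
                 seed = seed, pop = pop),
            class = "replicate_result")
}

# Intra-class (double-entry) Pearson correlation over a pair list.
sib_pair_correlation <- function(values, pairs) {
  if (is.null(pairs) || nrow(pairs) < 2L) return(NA_real_)
  x <- c(values[pairs[, 1]], values[pairs[, 2]])
  y <- c(values[pairs[, 2]], values[pairs[, 1]])
  stats::cor(x, y)
}

#' Correlations of estimated total breeding values between sibs
#'
#' Averages the per-generation full-sib and half-sib ETBV correlations
#' stored by [run_replicate()] (`track_sib_cor = TRUE`) over generations
#' and replicates.
#'
#' @param results list of `replicate_result` objects.
#' @return list with mean `full` and `half` correlations.
#' @export
sib_etbv_correlations <- function(results) {
  tabs <- Filter(Negate(is.null), lapply(results, `[[`, "sib_cor"))
  if (length(tabs) == 0L) stop("no sib correlations were tracked")
  tab <- do.call(rbind, tabs)
  list(full = mean(tab$full, na.rm = TRUE),
       half = mean(tab$half, na.rm = TRUE))
}

# Deterministic per-replicate seed from (master seed, scenario index,
# replicate index); kept within 32-bit integer range.
replicate_seed <- function(master, scenario_index, replicate) {
  as.integer((as.double(master) * 7919 + scenario_index * 104729 +
                replicate * 7907) %% 2147483587)
}

#' Run a replicated scenario grid
#'
#' Maps [run_replicate()] over scenarios and replicates with independent
#' per-replicate seeds, and aggregates the rate of inbreeding (mean and
#' standard error over replicates) and, optionally, the sib-ETBV
#' correlations.  Failed replicates are dropped with a warning and the
#' surviving count is reported.
#'
#' @param scenarios named list; each element either a [scenario_config()]
#'   or a list `list(config = , gp = )` to override the derived components.
#' @param reps replicates per scenario (default: each scenario's own
#'   `replicates` field).
#' @param seed master seed.
#' @param track_sib_cor,group_model passed to [run_replicate()].
#' @param verbose print one line per scenario as it completes.
#' @return data.frame with one row per scenario: mean ΔF, its standard
#'   error, replicate count, and mean sib correlations when tracked.  The
#'   per-replicate ΔF values are attached as attribute `"replicates"`.
#' @export
run_experiment <- function(scenarios, reps = NULL, seed = 1L,
                           track_sib_cor = FALSE, group_model = "block",
                           verbose = FALSE) {
  rows <- list(); per_rep <- list()
  for (si in seq_along(scenarios)) {
    sc <- scenarios[[si]]
    nm <- names(scenarios)[si]
    if (inherits(sc, "scenario_config")) sc <- list(config = sc)
    cfg <- sc$config
    gp <- if (!is.null(sc$gp)) sc$gp else derive_components(cfg)
    R <- if (is.null(reps)) cfg$replicates else reps
    res <- vector("list", R)
    for (r in seq_len(R)) {
      res[[r]] <- tryCatch(
        run_replicate(cfg, replicate_seed(seed, si, r), gp = gp,
                      group_model = group_model,
                      track_sib_cor = track_sib_cor),
        error = function(e) {
          warning("replicate ", r, " of scenario ", nm, " failed: ",
                  conditionMessage(e))
          NULL
        })
    }
    ok <- Filter(Negate(is.null), res)
    dF <- vapply(ok, `[[`, numeric(1), "delta_F")
    row <- data.frame(
      scenario = nm,
      mean_delta_F = mean(dF),
      se_delta_F = if (length(dF) > 1L) stats::sd(dF) / sqrt(length(dF))
                   else NA_real_,
      replicates = length(dF),
      stringsAsFactors = FALSE)
    if (track_sib_cor) {
      sc_cor <- sib_etbv_correlations(ok)
      row$cor_full_sib <- sc_cor$full
      row$cor_half_sib <- sc_cor$half
    }
    rows[[si]] <- row
    per_rep[[nm]] <- dF
    if (verbose) {
      message(sprintf("%-24s dF = %.4f%% (SE %.4f%%, %d reps)", nm,
                      100 * row$mean_delta_F, 100 * row$se_delta_F,
                      row$replicates))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "replicates") <- per_rep
  out
}
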