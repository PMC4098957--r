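#' Construct a pedigree
#'
#' A pedigree is a data.frame with integer columns `id` (1..N, dense),
#' `sire`, `dam` (0 = unknown), `generation` and optionally `sex`
#' (`"M"`/`"F"`).  Parents must precede offspring (`sire < id`,
#' `dam < id`), which also rules out cycles.
#'
#' @param sire,dam integer vectors of parent ids (0 for unknown).
#' @param generation integer vector of generation indices (base = 0).
#' @param sex optional character vector (`"M"`/`"F"`).
#' @return a data.frame of class `"pedigree"`.
#' @export
pedigree <- function(sire, dam, generation = rep(0L, length(sire)),
                     sex = NULL) {
  n <- length(sire)
  stopifnot(length(dam) == n, length(generation) == n)
  ped <- data.frame(id = seq_len(n), sire = as.integer(sire),
                    dam = as.integer(dam),
                    generation = as.integer(generation))
  if (!is.null(ped$sire) && n > 0) {
    bad <- ped$sire >= ped$id | ped$dam >= ped$id |
      ped$sire < 0L | ped$dam < 0L
    if (any(bad)) {
      stop("pedigree not ordered parents-before-offspring (first bad id: ",
           ped$id[which(bad)[1]], ")")
    }
    one_parent <- xor(ped$sire == 0L, ped$dam == 0L)
    if (any(one_parent)) {
      stop("individuals with exactly one known parent are not supported")
    }
  }
  if (!is.null(sex)) ped$sex <- as.character(sex)
  class(ped) <- c("pedigree", "data.frame")
  ped
}

#' Pedigree inbreeding coefficients
#'
#' Wright's inbreeding coefficient for every individual, computed with the
#' Meuwissen-Luo recursion (equivalent to the tabular method, but linear in
#' the size of each individual's ancestor set).  Base individuals (both
#' parents unknown) have F = 0.
#'
#' @param ped a [pedigree()].
#' @param f_known optional numeric vector of already-known coefficients for
#'   the first `start - 1` individuals of a growing pedigree.
#' @param start first id whose coefficient must be (re)computed.
#' @return numeric vector of inbreeding coefficients, one per individual.
#' @export
#' @examples
#' # offspring of two full sibs
#' ped <- pedigree(sire = c(0, 0, 1, 1, 3), dam = c(0, 0, 2, 2, 4))
#' inbreeding_coefficients(ped)[5]  # 0.25
inbreeding_coefficients <- function(ped, f_known = numeric(0), start = 1L) {
  stopifnot(inherits(ped, "pedigree"))
  start <- as.integer(start)
  if (start > 1L && length(f_known) < start - 1L) {
    stop("f_known must cover individuals 1..(start-1)")
  }
  ml_inbreeding_cpp(ped$sire, ped$dam,
                    c(f_known, numeric(max(0L, nrow(ped) - length(f_known)))),
                    start)
}

#' Inverse of the numerator relationship matrix
#'
#' Builds the sparse inverse of the additive (numerator) relationship
#' matrix A directly from the pedigree using Henderson's rules, with
#' Mendelian-sampling variances adjusted for parental inbreeding:
#' for individual i with parents s and d the sampling variance on the
#' relationship scale is 1/2 - (F_s + F_d)/4 (terms for unknown parents
#' replaced by the base value).
#'
#' @param ped a [pedigree()].
#' @param F inbreeding coefficients, as from [inbreeding_coefficients()];
#'   computed if missing.
#' @return a sparse symmetric matrix (`Matrix::dsCMatrix`) of order
#'   `nrow(ped)`.
#' @export
a_inverse <- function(ped, F = inbreeding_coefficients(ped)) {
  stopifnot(inherits(ped, "pedigree"), length(F) == nrow(ped))
  n <- nrow(ped)
  id <- ped$id; s <- ped$sire; d <- ped$dam
  Fs <- ifelse(s > 0L, F[pmax(s, 1L)], -1)
  Fd <- ifelse(d > 0L, F[pmax(d, 1L)], -1)
  alpha <- 1 / (0.5 - 0.25 * (Fs + Fd))  # inverse Mendelian variance
  ii <- id; jj <- id; xx <- alpha
  ks <- s > 0L
  ii <- c(ii, id[ks], s[ks]); jj <- c(jj, s[ks], s[ks])
  xx <- c(xx, -alpha[ks] / 2, alpha[ks] / 4)
  kd <- d > 0L
  ii <- c(ii, id[kd], d[kd]); jj <- c(jj, d[kd], d[kd])
  xx <- c(xx, -alpha[kd] / 2, alpha[kd] / 4)
  kb <- ks & kd
  ii <- c(ii, pmin(s, d)[kb]); jj <- c(jj, pmax(s, d)[kb])
  xx <- c(xx, alpha[kb] / 4)
  keep <- ii <= jj
  lower <- !keep
  Ainv <- Matrix::sparseMatrix(
    i = c(ii[keep], jj[lower]), j = c(jj[keep], ii[lower]),
    x = c(xx[keep], xx[lower]), dims = c(n, n), symmetric = TRUE
  )
  Ainv
}

#' Rate of inbreeding between two generation means
#'
#' \deqn{\Delta F = 1 - \left(\frac{1 - \bar F_{end}}
#'   {1 - \bar F_{start}}\right)^{1/span}}
#' the per-generation proportional loss of remaining heterozygosity between
#' two mean inbreeding levels `span` generations apart.
#'
#' @param F_bar_start,F_bar_end mean inbreeding coefficients, each in
#'   \eqn{[0, 1)}.
#' @param span number of generations between the two means (> 0).
#' @return the rate of inbreeding per generation (dimensionless).
#' @export
#' @examples
#' delta_F(0.1, 0.2, 10)
delta_F <- function(F_bar_start, F_bar_end, span) {
  if (any(c(F_bar_start, F_bar_end) < 0) ||
      any(c(F_bar_start, F_bar_end) >= 1)) {
    stop("mean inbreeding must lie in [0, 1)")
  }
  if (span <= 0) stop("span must be positive")
  1 - ((1 - F_bar_end) / (1 - F_bar_start))^(1 / span)
}

#' Enumerate sib pairs within one generation
#'
#' Lists all full-sib pairs (same sire and same dam) and half-sib pairs
#' (exactly one shared parent) among the individuals of a generation.
#' Under the nested 1 sire : 2 dams mating design all half sibs are
#' paternal.  Pairs are unordered and returned once each.
#'
#' @param ped a [pedigree()].
#' @param generation generation index to scan.
#' @return list with two 2-column integer matrices, `full` and `half`
#'   (columns `i`, `j`, `i < j`).
#' @export
sib_classes <- function(ped, generation) {
  ids <- ped$id[ped$generation == generation & ped$sire > 0L]
  s <- ped$sire[ids]; d <- ped$dam[ids]
  pairs_within <- function(members) {
    if (length(members) < 2L) return(NULL)
    t(utils::combn(sort(members), 2L))
  }
  full <- do.call(rbind, lapply(split(ids, paste(s, d)), pairs_within))
  # all pairs sharing a sire, minus the full-sib pairs
  same_sire <- do.call(rbind, lapply(split(ids, s), pairs_within))
  same_dam <- do.call(rbind, lapply(split(ids, d), pairs_within))
  key <- function(m) if (is.null(m)) character(0) else paste(m[, 1], m[, 2])
  fk <- key(full)
  half <- rbind(same_sire[!(key(same_sire) %in% fk), , drop = FALSE],
                same_dam[!(key(same_dam) %in% c(fk, key(same_sire))), ,
                         drop = FALSE])
  shape <- function(m) {
    if (is.null(m) || nrow(m) == 0L) {
      m <- matrix(integer(0), 0, 2)
    }
    dimnames(m) <- list(NULL, c("i", "j"))
    m[order(m[, 1], m[, 2]), , drop = FALSE]
  }
  list(full = shape(full), half = shape(half))
}

#' Read or write a pedigree as 4-column delimited text
#'
#' The layout is the de-facto pedigree exchange format: whitespace-separated
#' columns `id sire dam generation`, with 0 for an unknown parent, one
#' individual per line, a header line.
#'
#' @param ped a [pedigree()].
#' @param path file path.
#' @return `read_pedigree` returns a [pedigree()]; `write_pedigree` is
#'   called for its side effect.
#' @export
write_pedigree <- function(ped, path) {
  utils::write.table(ped[, c("id", "sire", "dam", "generation")], path,
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) {
  tab <- utils::read.table(path, header = TRUE)
  stopifnot(all(c("id", "sire", "dam", "generation") %in% names(tab)))
  tab <- tab[order(tab$id), ]
  if (!identical(as.integer(tab$id), seq_len(nrow(tab)))) {
    stop("pedigree ids must be dense 1..N")
  }
  pedigree(tab$sire, tab$dam, tab$generation)
}
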