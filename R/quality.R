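#' Per-SNP imputation-quality measures
#'
#' All measures are computed from one SNP's genotype-probability triplets
#' (an `n x 3` matrix, one row per individual), as produced by [gp_col()].
#' With \eqn{e_i = p_{i1} + 2 p_{i2}} (dosage),
#' \eqn{f_i = p_{i1} + 4 p_{i2}} and
#' \eqn{\hat\theta = \sum_i e_i / (2N)} (estimated alternative-allele
#' frequency):
#'
#' * `impute_info()` is the IMPUTE info score, the estimated ratio of
#'   observed to expected statistical information for the allele-frequency
#'   estimate: \eqn{1 - \sum_i (f_i - e_i^2) / (2N \hat\theta(1-\hat\theta))},
#'   set to 1 when \eqn{\hat\theta \in \{0,1\}} (monomorphic convention) and
#'   clipped to `[0, 1]` (negative raw values are possible and logged).
#' * `mach_r2()` is the MaCH R2-style ratio of the population variance of the
#'   dosages to the binomial variance \eqn{2\hat\theta(1-\hat\theta)}; it may
#'   exceed 1 and is 0 for a monomorphic frequency estimate.
#' * `beagle_dr2()` is a Beagle-style dosage R2, implemented as the squared
#'   Pearson correlation between the dosage and the best-guess genotype; 0
#'   when either vector is constant.
#' * `iam_scores()` returns surrogate Iam accuracy scores: `iam_chance` is
#'   the mean normalized total-variation distance of the triplets from the
#'   uniform triplet (low = imputation close to random), `iam_hwe` the mean
#'   normalized total-variation distance from the Hardy-Weinberg triplet at
#'   \eqn{\hat\theta} (low = imputation driven by allele frequency alone),
#'   clamped so `iam_hwe <= iam_chance`, and
#'   `iam_combined = iam_hwe - iam_chance + 1`.
#' * `hiq()` is a surrogate heterogeneity score: with \eqn{m_j} the mean of
#'   \eqn{p_{ij}} over individuals, \eqn{(1 - \sum_j m_j^2) / (2/3)}; low for
#'   largely monomorphic imputation.
#'
#' The Iam and hiQ formulas are documented surrogates: they reproduce the
#' qualitative behaviour the scores are defined by (uniform triplets score
#' low on `iam_chance`, HWE-driven triplets low on `iam_hwe`, the ordering
#' and combined range hold, monomorphic imputation scores low on `hiq`), but
#' their numeric values are not comparable to published Iam/hiQ thresholds.
#'
#' @param gp_column An `n x 3` matrix of genotype-probability triplets.
#' @return A single numeric score (`iam_scores()` returns a named list with
#'   `iam_chance`, `iam_hwe`, `iam_combined`).
#' @name quality_measures
NULL

check_gp_column <- function(gp_column, min_n = 1L) {
  if (is.null(dim(gp_column)) && length(gp_column) == 3L) {
    gp_column <- matrix(gp_column, ncol = 3L)
  }
  if (!is.matrix(gp_column) || ncol(gp_column) != 3L ||
      nrow(gp_column) < min_n) {
    abort(sprintf("Expected an n x 3 matrix of triplets with n >= %d.", min_n))
  }
  gp_column
}

col_dosage <- function(gp_column) gp_column[, 2L] + 2 * gp_column[, 3L]

#' @rdname quality_measures
#' @export
impute_info <- function(gp_column) {
  gp_column <- check_gp_column(gp_column)
  e <- col_dosage(gp_column)
  f <- gp_column[, 2L] + 4 * gp_column[, 3L]
  n <- length(e)
  theta <- sum(e) / (2 * n)
  if (theta <= 0 || theta >= 1) return(1)
  raw <- 1 - sum(f - e^2) / (2 * n * theta * (1 - theta))
  if (raw < 0) {
    rlang::inform(sprintf("Negative raw IMPUTE info (%.4f); clipped to 0.", raw),
                  .frequency = "once", .frequency_id = "impute_info_clip")
  }
  min(max(raw, 0), 1)
}

#' @rdname quality_measures
#' @export
mach_r2 <- function(gp_column) {
  gp_column <- check_gp_column(gp_column)
  e <- col_dosage(gp_column)
  n <- length(e)
  theta <- sum(e) / (2 * n)
  if (theta <= 0 || theta >= 1) return(0)
  pop_var <- sum((e - mean(e))^2) / n
  pop_var / (2 * theta * (1 - theta))
}

#' @rdname quality_measures
#' @export
beagle_dr2 <- function(gp_column) {
  gp_column <- check_gp_column(gp_column, min_n = 2L)
  e <- col_dosage(gp_column)
  g <- best_guess_col(gp_column)
  if (var(e) == 0 || var(g) == 0) return(0)
  cor(e, g)^2
}

# total-variation distance of each triplet row from a fixed triplet q,
# normalized by the maximum attainable distance (1 - min(q))
norm_tv_distance <- function(gp_column, q) {
  tv <- 0.5 * (abs(gp_column[, 1L] - q[1L]) + abs(gp_column[, 2L] - q[2L]) +
                 abs(gp_column[, 3L] - q[3L]))
  tv / (1 - min(q))
}

#' @rdname quality_measures
#' @export
iam_scores <- function(gp_column) {
  gp_column <- check_gp_column(gp_column)
  iam_chance <- mean(norm_tv_distance(gp_column, rep(1 / 3, 3L)))
  theta <- sum(col_dosage(gp_column)) / (2 * nrow(gp_column))
  hwe <- c((1 - theta)^2, 2 * theta * (1 - theta), theta^2)
  raw_hwe <- mean(norm_tv_distance(gp_column, hwe))
  iam_hwe <- min(raw_hwe, iam_chance)
  list(iam_chance = iam_chance, iam_hwe = iam_hwe,
       iam_combined = iam_hwe - iam_chance + 1)
}

#' @rdname quality_measures
#' @export
hiq <- function(gp_column) {
  gp_column <- check_gp_column(gp_column)
  m <- colMeans(gp_column)
  (1 - sum(m^2)) / (2 / 3)
}

quality_one_group <- function(gp) {
  m <- n_snps(gp)
  rows <- lapply(seq_len(m), function(j) {
    col <- gp_col(gp, j)
    iam <- iam_scores(col)
    tibble::tibble(
      snp_index = j,
      theta = sum(col_dosage(col)) / (2 * nrow(col)),
      impute_info = impute_info(col),
      mach_r2 = mach_r2(col),
      beagle_dr2 = beagle_dr2(col),
      iam_chance = iam$iam_chance,
      iam_hwe = iam$iam_hwe,
      iam_combined = iam$iam_combined,
      hiq = hiq(col)
    )
  })
  dplyr::bind_rows(rows)
}

#' Per-SNP quality table for a case-control study
#'
#' Computes every quality measure separately for cases and controls — the
#' per-group scores are the informative quantity when the two groups were
#' imputed separately (or when a joint imputation is re-checked per group) —
#' and combines the two group scores per SNP under `group_combine`. The
#' minimum (default) is the conservative choice: low quality in even one
#' group reduces confidence in the association at that SNP.
#'
#' @param study A [cohort_study()].
#' @param group_combine `"min"` (default), `"mean"` or `"max"`.
#' @return A tibble with one row per SNP: `snp_index`, `chrom`, `pos`,
#'   `typed`, per-measure `<measure>_cases` / `<measure>_controls` columns,
#'   and combined columns named after each measure.
#' @export
quality_table <- function(study, group_combine = c("min", "mean", "max")) {
  group_combine <- match.arg(group_combine)
  if (n_individuals(study$cases) < 1L || n_individuals(study$controls) < 1L) {
    abort("Both study groups must contain at least one individual.")
  }
  qc <- quality_one_group(study$cases)
  qt <- quality_one_group(study$controls)
  combine <- switch(group_combine, min = pmin, max = pmax,
                    mean = function(a, b) (a + b) / 2)
  measures <- c("impute_info", "mach_r2", "beagle_dr2", "iam_chance",
                "iam_hwe", "iam_combined", "hiq")
  out <- tibble::tibble(
    snp_index = qc$snp_index,
    chrom = study$variants$chrom,
    pos = study$variants$pos,
    typed = study$variants$typed,
    theta_cases = qc$theta,
    theta_controls = qt$theta
  )
  for (ms in measures) {
    out[[paste0(ms, "_cases")]] <- qc[[ms]]
    out[[paste0(ms, "_controls")]] <- qt[[ms]]
    out[[ms]] <- combine(qc[[ms]], qt[[ms]])
  }
  attr(out, "group_combine") <- group_combine
  out
}
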