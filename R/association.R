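#' Case-control association scan
#'
#' Per-SNP logistic regression of case/control status on genotype, in either
#' the dosage or the best-guess format, optionally adjusted for the study's
#' covariates (e.g. sex, age, principal components):
#' \deqn{logit P(Y = 1) = \beta_0 + \beta_1 SNP + \sum_k \gamma_k C_k}
#' Each SNP is fit by maximum likelihood (IRLS via [stats::glm.fit()], at
#' most 100 iterations, deviance tolerance 1e-12) and tested with the Wald
#' statistic on
#' \eqn{\beta_1}. Fits that do not converge or show complete separation
#' (diverging `|beta| > 15`) are flagged, not fabricated; constant genotype
#' columns are flagged untestable.
#'
#' @param study A [cohort_study()].
#' @param format `"dosage"` or `"best_guess"`.
#' @param use_covariates Include `study$covariates` when present.
#' @param snp_subset Optional integer vector of SNP indices to test; others
#'   are returned with `NA` P-values and `note = "not_tested"`.
#' @return A tibble with one row per SNP: `snp_index`, `chrom`, `pos`,
#'   `typed`, `format`, `beta`, `se`, `p`, `converged`, `note`.
#' @export
assoc_scan <- function(study, format = c("dosage", "best_guess"),
                       use_covariates = TRUE, snp_subset = NULL) {
  format <- match.arg(format)
  geno <- study_genotypes(study, format)
  y <- study_phenotype(study)
  covar <- NULL
  if (use_covariates && !is.null(study$covariates)) {
    covar <- as.matrix(study$covariates)
  }
  m <- ncol(geno)
  snp_subset <- snp_subset %||% seq_len(m)

  beta <- se <- p <- rep(NA_real_, m)
  converged <- rep(FALSE, m)
  note <- rep(NA_character_, m)
  note[setdiff(seq_len(m), snp_subset)] <- "not_tested"

  base_x <- cbind(`(Intercept)` = rep(1, length(y)), snp = 0, covar)
  for (j in snp_subset) {
    g <- geno[, j]
    if (var(g) == 0) {
      note[j] <- "constant_genotype"
      next
    }
    base_x[, 2L] <- g
    fit <- suppressWarnings(
      glm.fit(base_x, y, family = binomial(),
              control = list(maxit = 100, epsilon = 1e-12))
    )
    b <- fit$coefficients[2L]
    if (!fit$converged || !is.finite(b) || abs(b) > 15) {
      note[j] <- if (is.finite(b) && abs(b) > 15) "separation" else "not_converged"
      next
    }
    # Wald SE from the observed information at the converged coefficients
    # (the fit's stored QR reflects the penultimate IRLS weights)
    mu <- fit$fitted.values
    info <- crossprod(base_x * (mu * (1 - mu)), base_x)
    s <- tryCatch(sqrt(chol2inv(chol(info))[2L, 2L]), error = function(e) NA)
    if (!is.finite(s)) {
      note[j] <- "not_converged"
      next
    }
    beta[j] <- b
    se[j] <- s
    p[j] <- 2 * pnorm(-abs(b / s))
    converged[j] <- TRUE
  }
  tibble::tibble(
    snp_index = seq_len(m),
    chrom = study$variants$chrom,
    pos = study$variants$pos,
    typed = study$variants$typed,
    format = format,
    beta = beta, se = se, p = p,
    converged = converged, note = note
  )
}

#' Significant and suggestive SNP sets
#'
#' Splits an association table into the nested significant
#' (`p < significance`) and suggestive (`p < suggestive`) sets. The
#' suggestive set is the one spikes are built from: SNPs just short of
#' genome-wide significance still support an association signal in close
#' physical proximity.
#'
#' @param assoc An [assoc_scan()] tibble (one format, or several stacked).
#' @param significance Genome-wide threshold (default `5e-8`).
#' @param suggestive Suggestive threshold (default `5e-7`); must be >=
#'   `significance`.
#' @return `assoc` with logical columns `significant` and `suggestive`
#'   (significant implies suggestive).
#' @export
significant_set <- function(assoc, significance = 5e-8, suggestive = 5e-7) {
  stopifnot(suggestive >= significance)
  assoc$significant <- !is.na(assoc$p) & assoc$p < significance
  assoc$suggestive <- !is.na(assoc$p) & assoc$p < suggestive
  assoc
}
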