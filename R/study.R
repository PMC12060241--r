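#' Variant table
#'
#' Per-SNP metadata aligned 1:1 with the columns of the study's genotype
#' matrices. Positions are 1-based (VCF convention) and must be strictly
#' increasing within each chromosome. The `typed` flag separates directly
#' genotyped scaffold SNPs from imputed ones.
#'
#' @param chrom Chromosome labels (character or coercible).
#' @param pos 1-based base-pair positions.
#' @param ref,alt Allele strings (defaults `"A"`/`"G"` for synthetic data).
#' @param typed Logical, directly genotyped vs imputed.
#' @return A tibble with columns `snp_index`, `chrom`, `pos`, `ref`, `alt`,
#'   `typed`.
#' @export
variant_table <- function(chrom, pos, ref = "A", alt = "G", typed = TRUE) {
  vt <- tibble::tibble(
    snp_index = seq_along(pos),
    chrom = as.character(chrom),
    pos = as.integer(pos),
    ref = ref,
    alt = alt,
    typed = typed
  )
  validate_variant_table(vt)
  vt
}

validate_variant_table <- function(vt) {
  stopifnot(all(c("snp_index", "chrom", "pos", "typed") %in% names(vt)))
  bad <- vt |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(ok = all(diff(.data$pos) > 0), .groups = "drop")
  if (!all(bad$ok)) {
    abort("Positions must be strictly increasing within each chromosome.")
  }
  invisible(vt)
}

#' Case-control cohort study
#'
#' Bundles the case and control genotype-probability matrices with their
#' shared variant table and optional per-individual covariates (for example
#' sex, age, principal components). Cases and controls must cover the
#' identical variant set; covariate rows are ordered cases first, then
#' controls.
#'
#' @param cases,controls [gp_matrix()] objects over the same SNPs.
#' @param variants A [variant_table()] with one row per SNP column.
#' @param covariates Optional numeric data frame with
#'   `n_cases + n_controls` rows.
#' @return An object of class `cohort_study`.
#' @export
cohort_study <- function(cases, controls, variants, covariates = NULL) {
  stopifnot(inherits(cases, "gp_matrix"), inherits(controls, "gp_matrix"))
  if (n_snps(cases) != n_snps(controls)) {
    abort("Cases and controls must share the identical variant set.")
  }
  validate_variant_table(variants)
  if (nrow(variants) != n_snps(cases)) {
    abort("`variants` must have one row per SNP column.")
  }
  n_total <- n_individuals(cases) + n_individuals(controls)
  if (!is.null(covariates)) {
    covariates <- tibble::as_tibble(covariates)
    if (nrow(covariates) != n_total) {
      abort(sprintf(
        "`covariates` has %d rows but the study has %d individuals.",
        nrow(covariates), n_total
      ))
    }
  }
  structure(
    list(cases = cases, controls = controls, variants = variants,
         covariates = covariates),
    class = "cohort_study"
  )
}

#' @export
print.cohort_study <- function(x, ...) {
  cat(sprintf(
    "<cohort_study: %d cases, %d controls, %d SNPs (%d typed), %s>\n",
    n_individuals(x$cases), n_individuals(x$controls), nrow(x$variants),
    sum(x$variants$typed),
    if (is.null(x$covariates)) "no covariates"
    else paste0(ncol(x$covariates), " covariates")
  ))
  invisible(x)
}

#' Case/control phenotype vector of a study
#' @param study A [cohort_study()].
#' @return Integer vector, 1 for cases then 0 for controls.
#' @export
study_phenotype <- function(study) {
  c(rep(1L, n_individuals(study$cases)), rep(0L, n_individuals(study$controls)))
}

#' Combined genotype matrix of a study in one format
#' @param study A [cohort_study()].
#' @param format `"dosage"` or `"best_guess"`.
#' @return An `n_total x m` numeric matrix, cases stacked above controls.
#' @export
study_genotypes <- function(study, format = c("dosage", "best_guess")) {
  format <- match.arg(format)
  gp <- gp_rbind(study$cases, study$controls)
  if (format == "dosage") gp_to_dosage(gp) else gp_to_best_guess(gp)
}
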