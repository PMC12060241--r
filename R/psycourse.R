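#' Load the packaged PsyCourse top-SNP table
#'
#' The published summary of the PsyCourse case-control GWAS (1,121 cases on
#' the affective-to-psychotic spectrum vs 404 controls, jointly imputed,
#' Beagle R2 quality): the 80 SNPs with a P-value below 5e-6 in the dosage
#' or best-guess format, with the imputation quality as reported by the
#' imputation service ("initial") and the minimum of the quality
#' recalculated separately for the three diagnosis groups ("min"). P-values
#' are stored on the x1e-6 scale exactly as published and converted here;
#' one best-guess P-value censored above 1e-4 in the source is stored as
#' `NA`. Directly genotyped SNPs carry `typed = TRUE` and no quality.
#'
#' @return A validated tibble: `chrom`, `pos`, `p_dosage`, `p_best_guess`,
#'   `quality_initial`, `quality_min`, `typed`.
#' @export
load_psycourse_top_snps <- function() {
  path <- system.file("extdata", "psycourse_top_snps.tsv",
                      package = "midrangeqc", mustWork = TRUE)
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  fx <- tibble::tibble(
    chrom = as.character(raw$chrom),
    pos = as.integer(raw$pos),
    p_dosage = raw$p_dosage_e6 * 1e-6,
    p_best_guess = raw$p_best_guess_e6 * 1e-6,
    quality_initial = raw$quality_initial,
    quality_min = raw$quality_min,
    typed = raw$typed
  )
  if (nrow(fx) != 80L) abort("Fixture corrupted: expected 80 rows.")
  if (sum(fx$typed) != 3L) abort("Fixture corrupted: expected 3 typed rows.")
  best <- pmin(fx$p_dosage, fx$p_best_guess, na.rm = TRUE)
  if (!all(best < 5e-6)) {
    abort("Fixture corrupted: every row must reach P < 5e-6 in some format.")
  }
  fx
}

#' Apply the Midrange Filter to the PsyCourse top-SNP table
#'
#' Reproduces the published real-data workflow on [load_psycourse_top_snps()]: the table
#' is treated as precomputed association and quality results; positions
#' suggestive in either format are chained into spikes; spikes are annotated
#' and classified with the Midrange Filter on the chosen quality column.
#' This GWAS has no genome-wide significant SNP, so the exploratory 5e-6
#' level serves as presence and typed-anchor threshold, as in the published
#' analysis.
#'
#' @param fixture The table from [load_psycourse_top_snps()] (or a compatible tibble).
#' @param lower,upper Quality thresholds (defaults 0.3 / 0.8).
#' @param quality_column `"quality_min"` (default, the per-group minimum the
#'   filter is designed for) or `"quality_initial"`.
#' @param presence_threshold P-value level for spike membership and format
#'   presence (default 5e-6).
#' @param gap_limit Spike chaining distance (default 2 Mb).
#' @return A list: `decisions` (classified spikes), `assoc` (the stacked
#'   long-format association tibble), `kept_snps` (rows of the fixture in
#'   kept spikes).
#' @export
filter_psycourse <- function(fixture = load_psycourse_top_snps(), lower = 0.3, upper = 0.8,
                          quality_column = c("quality_min", "quality_initial"),
                          presence_threshold = 5e-6, gap_limit = 2e6) {
  quality_column <- match.arg(quality_column)
  assoc <- tidyr::pivot_longer(
    dplyr::select(fixture, "chrom", "pos", "typed",
                  dosage = "p_dosage", best_guess = "p_best_guess"),
    cols = c("dosage", "best_guess"),
    names_to = "format", values_to = "p"
  )
  quality <- dplyr::select(fixture, "chrom", "pos", "typed",
                           quality = dplyr::all_of(quality_column))

  sugg <- assoc[!is.na(assoc$p) & assoc$p < presence_threshold,
                c("chrom", "pos")]
  spikes <- aggregate_spikes(sugg, gap_limit = gap_limit)
  spikes <- annotate_spikes(
    spikes, assoc, quality, measure = "quality",
    presence_threshold = presence_threshold,
    significance = presence_threshold
  )
  config <- filter_config(
    lower = lower, upper = upper,
    significance = presence_threshold, suggestive = presence_threshold,
    presence_threshold = presence_threshold, gap_limit = gap_limit
  )
  decisions <- classify_spikes(spikes, config)

  kept <- decisions[decisions$verdict == "keep", , drop = FALSE]
  kept_pos <- tibble::tibble(
    chrom = rep(kept$chrom, lengths(kept$members)),
    pos = unlist(kept$members) %||% integer()
  )
  kept_snps <- dplyr::semi_join(fixture, kept_pos, by = c("chrom", "pos"))
  list(decisions = decisions, assoc = assoc, kept_snps = kept_snps)
}
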