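#' Midrange Filter configuration
#'
#' The Midrange Filter classifies whole spikes with two imputation-quality
#' thresholds: `lower` is the minimum acceptable quality and `upper` the
#' high-confidence bar. For IMPUTE info both are established conventions
#' (0.3 and 0.8) and delimit the "midrange" in which per-SNP filtering cannot
#' separate true from false associations. "Does not meet" a threshold is
#' strict: a value exactly at the threshold passes.
#'
#' @param lower,upper Quality thresholds, `0 <= lower < upper <= 1`
#'   (defaults 0.3 and 0.8).
#' @param measure Combined quality column the filter consumes:
#'   `"impute_info"` (default), `"mach_r2"` or `"beagle_dr2"`.
#' @param group_combine How per-group scores are combined: `"min"`
#'   (default), `"mean"` or `"max"`.
#' @param significance,suggestive Association thresholds (defaults 5e-8 and
#'   5e-7).
#' @param presence_threshold P-value bound for format presence (defaults to
#'   `suggestive`).
#' @param gap_limit Spike chaining distance in bp (default 2 Mb).
#' @return A `filter_config` list.
#' @export
filter_config <- function(lower = 0.3, upper = 0.8,
                          measure = c("impute_info", "mach_r2", "beagle_dr2"),
                          group_combine = c("min", "mean", "max"),
                          significance = 5e-8, suggestive = 5e-7,
                          presence_threshold = suggestive,
                          gap_limit = 2e6) {
  measure <- match.arg(measure)
  group_combine <- match.arg(group_combine)
  if (!(lower >= 0 && lower < upper && upper <= 1)) {
    abort("Thresholds must satisfy 0 <= lower < upper <= 1.")
  }
  structure(
    list(lower = lower, upper = upper, measure = measure,
         group_combine = group_combine, significance = significance,
         suggestive = suggestive, presence_threshold = presence_threshold,
         gap_limit = gap_limit),
    class = "filter_config"
  )
}

#' Classify annotated spikes with the Midrange Filter
#'
#' Decision rules, in precedence order:
#' 1. A spike containing a significant typed SNP is regarded as true and
#'    kept (`typed_anchor`).
#' 2. Any spike whose lowest member quality does not meet the lower
#'    threshold is discarded (`q_min_below_lower`).
#' 3. A best-guess-specific spike whose highest member quality does not meet
#'    the upper threshold is discarded (`bg_specific_q_max_below_upper`) —
#'    dosage has more power, so a signal only best guess can see needs
#'    high-confidence imputation.
#' 4. Otherwise the spike is kept (`passed`).
#'
#' Spikes detectable at least in the dosage format are case
#' `dosage_detectable`; best-guess-specific spikes are case `bestguess_only`;
#' typed-anchored spikes are case `typed`.
#'
#' @param spikes An [annotate_spikes()] tibble.
#' @param config A [filter_config()].
#' @return `spikes` with `case`, `verdict` (`"keep"`/`"discard"`) and
#'   `reason` columns.
#' @export
classify_spikes <- function(spikes, config = filter_config()) {
  needed <- c("dosage_present", "best_guess_present", "has_typed_significant",
              "q_min", "q_max")
  if (!all(needed %in% names(spikes))) {
    abort("Spikes must be annotated (annotate_spikes) before classification.")
  }
  bg_only <- !spikes$dosage_present & spikes$best_guess_present
  spikes$case <- dplyr::case_when(
    spikes$has_typed_significant ~ "typed",
    bg_only ~ "bestguess_only",
    TRUE ~ "dosage_detectable"
  )
  # NA extremes (e.g. all members typed) impose no quality constraint
  q_min <- ifelse(is.na(spikes$q_min), Inf, spikes$q_min)
  q_max <- ifelse(is.na(spikes$q_max), Inf, spikes$q_max)
  spikes$reason <- dplyr::case_when(
    spikes$has_typed_significant ~ "typed_anchor",
    q_min < config$lower ~ "q_min_below_lower",
    bg_only & q_max < config$upper ~ "bg_specific_q_max_below_upper",
    TRUE ~ "passed"
  )
  spikes$verdict <- ifelse(
    spikes$reason %in% c("typed_anchor", "passed"), "keep", "discard"
  )
  spikes
}

#' Run the Midrange Filter end to end
#'
#' The full practical workflow on an imputed case-control study:
#' per-group quality table; initial association scans (both formats)
#' restricted to SNPs whose combined quality meets the lower threshold;
#' follow-up dosage testing of the surrounding low-quality SNPs
#' ([complete_spikes()]); aggregation of all suggestive positions into
#' spikes; annotation; and a keep/discard decision per spike. The filtered
#' association table keeps every suggestive SNP of kept spikes and drops all
#' SNPs of discarded spikes — the filter decides whole spikes, never parts
#' of them.
#'
#' @param study An imputed [cohort_study()].
#' @param config A [filter_config()].
#' @param truth Optional [make_truth()] tibble; when given, spikes carry a
#'   `true_spike` label.
#' @param restrict_initial Restrict the initial scans to SNPs whose combined
#'   quality meets the lower threshold (the practical workflow, default).
#'   Set `FALSE` to test every SNP up front -- the design used when
#'   evaluating filters against a gold standard, where low-quality
#'   association signals must be observable rather than skipped.
#' @return An object of class `midrange_filter`: a list with `decisions`
#'   (classified spike tibble), `assoc` (stacked association results),
#'   `filtered_assoc` (suggestive rows of kept spikes), `quality`, `config`.
#' @export
run_midrange_filter <- function(study, config = filter_config(),
                                truth = NULL, restrict_initial = TRUE) {
  quality <- quality_table(study, group_combine = config$group_combine)
  eligible <- if (restrict_initial) {
    which(quality$typed | quality[[config$measure]] >= config$lower)
  } else {
    seq_len(nrow(quality))
  }
  assoc <- dplyr::bind_rows(
    assoc_scan(study, "dosage", snp_subset = eligible),
    assoc_scan(study, "best_guess", snp_subset = eligible)
  )
  sugg <- assoc[!is.na(assoc$p) & assoc$p < config$suggestive,
                c("chrom", "pos")]
  spikes <- aggregate_spikes(sugg, gap_limit = config$gap_limit)
  completed <- complete_spikes(spikes, study, assoc,
                               suggestive = config$suggestive,
                               gap_limit = config$gap_limit)
  assoc <- completed$assoc
  spikes <- completed$spikes
  spikes <- annotate_spikes(
    spikes, assoc, quality, measure = config$measure,
    presence_threshold = config$presence_threshold,
    significance = config$significance
  )
  # only spikes containing a significant SNP are discovered association
  # signals; suggestive-only clusters are not reported and not decided
  spikes <- spikes[spikes$has_significant, , drop = FALSE]
  decisions <- classify_spikes(spikes, config)
  if (!is.null(truth)) decisions <- label_spike_truth(decisions, truth)

  kept <- decisions[decisions$verdict == "keep", , drop = FALSE]
  kept_pos <- tibble::tibble(
    chrom = rep(kept$chrom, lengths(kept$members)),
    pos = unlist(kept$members) %||% integer()
  )
  filtered_assoc <- dplyr::semi_join(
    assoc[!is.na(assoc$p) & assoc$p < config$suggestive, , drop = FALSE],
    kept_pos, by = c("chrom", "pos")
  )
  structure(
    list(decisions = decisions, assoc = assoc,
         filtered_assoc = filtered_assoc, quality = quality,
         config = config),
    class = "midrange_filter"
  )
}

#' @export
print.midrange_filter <- function(x, ...) {
  cat(sprintf(
    "<midrange_filter: %d spikes, %d kept, %d discarded (measure %s, thresholds %.2f/%.2f)>\n",
    nrow(x$decisions), sum(x$decisions$verdict == "keep"),
    sum(x$decisions$verdict == "discard"),
    x$config$measure, x$config$lower, x$config$upper
  ))
  invisible(x)
}

#' @rdname run_midrange_filter
#' @param x A `midrange_filter` object.
#' @param ... Unused.
#' @export
tidy.midrange_filter <- function(x, ...) {
  dplyr::select(x$decisions, -"members")
}

#' @rdname run_midrange_filter
#' @export
glance.midrange_filter <- function(x, ...) {
  d <- x$decisions
  tibble::tibble(
    n_spikes = nrow(d),
    n_kept = sum(d$verdict == "keep"),
    n_discarded = sum(d$verdict == "discard"),
    n_typed_anchor = sum(d$reason == "typed_anchor"),
    n_bg_specific = sum(d$case == "bestguess_only"),
    n_snps_kept = nrow(x$filtered_assoc),
    lower = x$config$lower,
    upper = x$config$upper,
    measure = x$config$measure
  )
}

#' Per-SNP single-threshold filtering (compatibility mode)
#'
#' Plain per-SNP quality thresholding, the practice the spike-level filter
#' is compared against: a SNP is discarded when its combined quality does
#' not meet `threshold` (strict `<`; typed SNPs always pass). Applied to a
#' spike set it produces full, partial or no deletion of each spike.
#'
#' @param quality A [quality_table()].
#' @param threshold Quality threshold.
#' @param measure Combined quality column.
#' @return `quality` with a logical `kept` column.
#' @export
threshold_filter_snps <- function(quality, threshold,
                                  measure = "impute_info") {
  quality$kept <- quality$typed | !(quality[[measure]] < threshold)
  quality
}
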