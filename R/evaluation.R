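#' False-association percentage
#'
#' The ratio between false-positive and total counts, in percent, rounded
#' half-up to 2 decimals (printed-table style).
#'
#' @param false_count Number of false positives, `0 <= false_count <= total`.
#' @param total Total count, `> 0`.
#' @return A single number, e.g. `false_percent(52, 107)` is `48.60`.
#' @export
false_percent <- function(false_count, total) {
  if (any(total <= 0)) abort("`total` must be positive.")
  if (any(false_count < 0 | false_count > total)) {
    abort("`false_count` must lie in [0, total].")
  }
  round_half_up(100 * false_count / total, 2L)
}

round_half_up <- function(x, digits) {
  scale <- 10^digits
  floor(x * scale + 0.5) / scale
}

confusion_row <- function(stratum, is_false) {
  total <- length(is_false)
  fp <- sum(is_false)
  tibble::tibble(
    stratum = stratum, total = total, false = fp, true = total - fp,
    false_percent = if (total > 0) false_percent(fp, total) else NA_real_
  )
}

#' Per-SNP confusion strata for quality filtering
#'
#' Cross-tabulates the significant SNPs of one format against the truth
#' labels, stratified by combined imputation quality: all SNPs, those
#' meeting the upper threshold, those meeting the lower threshold, and the
#' midrange in between (`lower <= q < upper`; boundary values follow the
#' filter's strict-below-fails rule, so the two threshold strata nest and
#' the midrange is their set difference).
#'
#' @param assoc A [significant_set()] tibble for one format.
#' @param truth A [make_truth()] tibble.
#' @param quality A [quality_table()].
#' @param lower,upper Quality thresholds (defaults 0.3 / 0.8).
#' @param measure Combined quality column.
#' @return A tibble of confusion rows (`stratum`, `total`, `false`, `true`,
#'   `false_percent`).
#' @export
snp_confusion <- function(assoc, truth, quality, lower = 0.3, upper = 0.8,
                          measure = "impute_info") {
  sig <- assoc[assoc$significant, , drop = FALSE]
  sig <- dplyr::left_join(
    sig,
    dplyr::select(truth, "snp_index", "significant_gold"),
    by = "snp_index"
  )
  sig <- dplyr::left_join(
    sig,
    dplyr::select(quality, "snp_index", q = dplyr::all_of(measure)),
    by = "snp_index"
  )
  is_false <- !sig$significant_gold
  q <- ifelse(sig$typed, Inf, sig$q)   # typed SNPs pass any threshold
  dplyr::bind_rows(
    confusion_row("all", is_false),
    confusion_row(paste0(">", upper), is_false[q >= upper]),
    confusion_row(paste0(">", lower), is_false[q >= lower]),
    confusion_row("midrange", is_false[q >= lower & q < upper])
  )
}

# spike-level retention under per-SNP thresholding: a spike survives when
# any suggestive member passes; partial = survives but lost members
spike_threshold_outcome <- function(decisions, quality, threshold, measure) {
  q_by_pos <- setNames(
    ifelse(quality$typed, Inf, quality[[measure]]),
    paste0(quality$chrom, ":", quality$pos)
  )
  purrr::map2_dfr(decisions$chrom, decisions$members, function(ch, mem) {
    q <- q_by_pos[paste0(ch, ":", mem)]
    q <- q[!is.na(q)]
    kept <- sum(!(q < threshold))
    tibble::tibble(retained = kept > 0, partial = kept > 0 && kept < length(q))
  })
}

#' Spike-level confusion for threshold filters and the Midrange Filter
#'
#' Counts retained true and false spikes under no filtering, per-SNP
#' thresholding at the upper and lower quality thresholds (a spike counts as
#' retained when at least one member survives; partially deleted but still
#' present spikes are tallied separately), and the Midrange Filter's whole-
#' spike decisions.
#'
#' @param decisions A classified, truth-labelled spike tibble (from
#'   [run_midrange_filter()] with `truth`, or [classify_spikes()] +
#'   [label_spike_truth()]).
#' @param quality A [quality_table()].
#' @param lower,upper Quality thresholds.
#' @param measure Combined quality column.
#' @return A tibble with one row per filter (`stratum` of `"unfiltered"`,
#'   `">upper"`, `">lower"`, `"midrange_filter"`): retained totals, false and
#'   true counts, `false_percent`, and `n_partial` for the threshold rows.
#' @export
spike_confusion <- function(decisions, quality, lower = 0.3, upper = 0.8,
                            measure = "impute_info") {
  if (nrow(decisions) == 0L) {
    return(tibble::tibble(
      stratum = c("unfiltered", ">upper", ">lower", "midrange_filter"),
      total = 0L, false = 0L, true = 0L, false_percent = NA_real_,
      n_partial = 0L
    ))
  }
  stopifnot("true_spike" %in% names(decisions))
  is_false <- !decisions$true_spike
  upper_out <- spike_threshold_outcome(decisions, quality, upper, measure)
  lower_out <- spike_threshold_outcome(decisions, quality, lower, measure)
  mf_kept <- decisions$verdict == "keep"
  out <- dplyr::bind_rows(
    cbind(confusion_row("unfiltered", is_false), n_partial = 0L),
    cbind(confusion_row(paste0(">", upper), is_false[upper_out$retained]),
          n_partial = sum(upper_out$partial)),
    cbind(confusion_row(paste0(">", lower), is_false[lower_out$retained]),
          n_partial = sum(lower_out$partial)),
    cbind(confusion_row("midrange_filter", is_false[mf_kept]), n_partial = 0L)
  )
  tibble::as_tibble(out)
}

#' ROC of a quality measure as a false-association classifier
#'
#' Sweeps a discard rule (discard iff quality `< t`, consistent with the
#' filter) over the sorted unique quality values plus infinite endpoints.
#' Sensitivity is the fraction of false associations correctly discarded;
#' specificity the fraction of true associations correctly kept. The AUC is
#' the trapezoid area over (1 - specificity, sensitivity), which equals the
#' probability that a random false association scores below a random true
#' one (ties counting half).
#'
#' @param quality_values Numeric vector of per-item quality scores.
#' @param is_false Logical vector: `TRUE` for false associations.
#' @return A `quality_roc` list: `points` tibble
#'   (`threshold`, `sensitivity`, `specificity`) and `auc`.
#' @export
roc_quality <- function(quality_values, is_false) {
  stopifnot(length(quality_values) == length(is_false))
  keep <- !is.na(quality_values) & !is.na(is_false)
  quality_values <- quality_values[keep]
  is_false <- is_false[keep]
  if (!any(is_false) || all(is_false)) {
    abort("ROC needs at least one false and one true association.")
  }
  thresholds <- c(-Inf, sort(unique(quality_values)), Inf)
  pts <- purrr::map_dfr(thresholds, function(t) {
    discard <- quality_values < t
    tibble::tibble(
      threshold = t,
      sensitivity = mean(discard[is_false]),
      specificity = mean(!discard[!is_false])
    )
  })
  x <- 1 - pts$specificity
  y <- pts$sensitivity
  ord <- order(x, y)
  auc <- sum(diff(x[ord]) * (head(y[ord], -1) + tail(y[ord], -1)) / 2)
  structure(list(points = pts, auc = auc), class = "quality_roc")
}

#' @export
print.quality_roc <- function(x, ...) {
  cat(sprintf("<quality_roc: %d points, AUC %.3f>\n", nrow(x$points), x$auc))
  invisible(x)
}

#' Quality threshold at a target specificity
#'
#' Picks the largest discard threshold whose specificity (fraction of true
#' associations kept) still meets the target, and reports its sensitivity.
#' The discard-all endpoint (threshold `Inf`) is excluded by convention. An
#' unreachable target is reported as threshold 0 with `reachable = FALSE`.
#'
#' @param roc A [roc_quality()] result.
#' @param target_specificity Required specificity in `[0, 1]`.
#' @return A tibble: `threshold`, `sensitivity`, `specificity`, `reachable`.
#' @export
threshold_at_specificity <- function(roc, target_specificity) {
  pts <- roc$points[is.finite(roc$points$threshold) |
                      roc$points$threshold == -Inf, , drop = FALSE]
  ok <- pts[pts$specificity >= target_specificity, , drop = FALSE]
  if (nrow(ok) == 0L) {
    return(tibble::tibble(threshold = 0, sensitivity = NA_real_,
                          specificity = NA_real_, reachable = FALSE))
  }
  best <- ok[which.max(ok$threshold), , drop = FALSE]
  tibble::tibble(threshold = best$threshold, sensitivity = best$sensitivity,
                 specificity = best$specificity, reachable = TRUE)
}
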