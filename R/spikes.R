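#' Aggregate SNP positions into spikes
#'
#' Chains suggestive SNPs into association "spikes" by physical proximity:
#' two SNPs belong to the same spike when they are fewer than `gap_limit`
#' base pairs apart, or connected by a chain of SNPs with every
#' neighbour-to-neighbour gap below `gap_limit` (single linkage with a strict
#' inequality, so a gap of exactly `gap_limit` splits). The algorithm uses
#' only positions, never P-values, and spikes never span chromosomes.
#'
#' @param x A data frame with `chrom` and `pos` columns, or a numeric vector
#'   of positions (then `chrom` applies to all of them).
#' @param gap_limit Chaining distance in base pairs (default 2,000,000).
#' @param chrom Chromosome label used when `x` is a bare position vector.
#' @return A tibble ordered by (chrom, start): `spike_id`, `chrom`, `start`,
#'   `end`, `n_members`, and a `members` list-column of sorted member
#'   positions.
#' @examples
#' aggregate_spikes(c(100, 1900000, 3700000))   # one chained spike
#' aggregate_spikes(c(100, 2000100))            # two spikes
#' @export
aggregate_spikes <- function(x, gap_limit = 2e6, chrom = "1") {
  if (is.numeric(x)) {
    x <- tibble::tibble(chrom = chrom, pos = x)
  }
  x <- tibble::as_tibble(x)[c("chrom", "pos")]
  x <- dplyr::distinct(dplyr::arrange(x, .data$chrom, .data$pos))
  if (nrow(x) == 0L) {
    return(tibble::tibble(
      spike_id = character(), chrom = character(), start = integer(),
      end = integer(), n_members = integer(), members = list()
    ))
  }
  out <- x |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(block = cumsum(c(1, diff(.data$pos) >= gap_limit))) |>
    dplyr::group_by(.data$chrom, .data$block) |>
    dplyr::summarise(
      start = min(.data$pos), end = max(.data$pos),
      n_members = dplyr::n(), members = list(sort(.data$pos)),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::select(-"block")
  out$spike_id <- sprintf("%s:%d-%d", out$chrom, out$start, out$end)
  dplyr::relocate(out, "spike_id")
}

spike_member_rows <- function(spike_chrom, spike_members, table) {
  table[table$chrom == spike_chrom & table$pos %in% spike_members, ,
        drop = FALSE]
}

#' Annotate spikes with format presence, typed anchors and quality extremes
#'
#' For each spike: which genotype formats detect it (a format is present
#' when at least one member SNP passes `presence_threshold` in that format),
#' whether it contains a typed SNP significant at `significance` (a typed
#' anchor), and the extremes of the combined imputation-quality measure over
#' its suggestive imputed members. Spikes present in exactly one format are
#' format specific.
#'
#' @param spikes An [aggregate_spikes()] tibble.
#' @param assoc A stacked association tibble covering both formats (columns
#'   `chrom`, `pos`, `format`, `p`, `typed`), e.g. two [assoc_scan()] results
#'   bound together.
#' @param quality A [quality_table()] (or any tibble with `chrom`, `pos` and
#'   the `measure` column holding the group-combined quality).
#' @param measure Name of the quality column to take extremes of (default
#'   `"impute_info"`).
#' @param presence_threshold P-value bound defining format presence
#'   (default the suggestive 5e-7).
#' @param significance Threshold for the typed-anchor rule (default 5e-8).
#' @return `spikes` with columns `dosage_present`, `best_guess_present`,
#'   `format_specific` (`"dosage"`, `"best_guess"` or `"both"`),
#'   `has_significant` (at least one member reaches `significance` in some
#'   format -- only such spikes constitute discovered association signals),
#'   `has_typed_significant`, `q_min`, `q_max`.
#' @export
annotate_spikes <- function(spikes, assoc, quality,
                            measure = "impute_info",
                            presence_threshold = 5e-7,
                            significance = 5e-8) {
  if (!measure %in% names(quality)) {
    abort(sprintf("Quality table has no column `%s`.", measure))
  }
  if (nrow(spikes) == 0L) {
    return(dplyr::mutate(
      spikes,
      dosage_present = logical(), best_guess_present = logical(),
      has_significant = logical(), has_typed_significant = logical(),
      q_min = numeric(), q_max = numeric(), format_specific = character()
    ))
  }
  ann <- purrr::pmap(
    list(spikes$chrom, spikes$members),
    function(ch, mem) {
      rows <- spike_member_rows(ch, mem, assoc)
      hit <- !is.na(rows$p) & rows$p < presence_threshold
      dosage_present <- any(hit & rows$format == "dosage")
      bg_present <- any(hit & rows$format == "best_guess")
      typed_anchor <- any(!is.na(rows$p) & rows$p < significance & rows$typed)
      has_significant <- any(!is.na(rows$p) & rows$p < significance)
      q_rows <- spike_member_rows(ch, rows$pos[hit], quality)
      q_rows <- q_rows[!q_rows$typed & !is.na(q_rows[[measure]]), , drop = FALSE]
      missing_q <- setdiff(unique(rows$pos[hit & !rows$typed]),
                           quality$pos[quality$chrom == ch])
      if (length(missing_q)) {
        abort(sprintf("Spike member SNP(s) missing from the quality table: %s",
                      paste0(ch, ":", missing_q, collapse = ", ")))
      }
      qv <- q_rows[[measure]]
      tibble::tibble(
        dosage_present = dosage_present,
        best_guess_present = bg_present,
        has_significant = has_significant,
        has_typed_significant = typed_anchor,
        q_min = if (length(qv)) min(qv) else NA_real_,
        q_max = if (length(qv)) max(qv) else NA_real_
      )
    }
  )
  out <- dplyr::bind_cols(spikes, dplyr::bind_rows(ann))
  out$format_specific <- dplyr::case_when(
    out$dosage_present & out$best_guess_present ~ "both",
    out$dosage_present ~ "dosage",
    out$best_guess_present ~ "best_guess",
    TRUE ~ "none"
  )
  out
}

#' Complete spikes by follow-up association of surrounding SNPs
#'
#' The practical workflow first tests only SNPs above the lower quality
#' threshold. Once initial spikes are found, the SNPs surrounding them that
#' were excluded by the quality restriction are association-tested in the
#' dosage format and, when suggestive, merged into spike membership — so a
#' low-quality member can later pull a spike's `q_min` below the lower
#' threshold. Follow-up never removes members.
#'
#' @param spikes Initial [aggregate_spikes()] tibble.
#' @param study The [cohort_study()] to run follow-up tests on.
#' @param assoc The stacked association tibble from the initial scans; rows
#'   with `note == "not_tested"` are candidates for follow-up.
#' @param suggestive P-value bound for joining a spike (default 5e-7).
#' @param gap_limit Neighbourhood radius and re-chaining distance.
#' @return A list: `assoc` (with follow-up dosage results merged) and
#'   `spikes` (re-aggregated membership).
#' @export
complete_spikes <- function(spikes, study, assoc, suggestive = 5e-7,
                            gap_limit = 2e6) {
  if (nrow(spikes) == 0L) {
    return(list(assoc = assoc, spikes = spikes))
  }
  untested <- assoc[!is.na(assoc$note) & assoc$note == "not_tested" &
                      assoc$format == "dosage", , drop = FALSE]
  near <- purrr::map_lgl(seq_len(nrow(untested)), function(i) {
    sp <- spikes[spikes$chrom == untested$chrom[i], , drop = FALSE]
    nrow(sp) > 0 && any(untested$pos[i] > sp$start - gap_limit &
                          untested$pos[i] < sp$end + gap_limit)
  })
  followup_idx <- untested$snp_index[near]
  if (length(followup_idx)) {
    extra <- assoc_scan(study, format = "dosage", snp_subset = followup_idx)
    extra <- extra[extra$snp_index %in% followup_idx, , drop = FALSE]
    keep <- !(assoc$format == "dosage" & assoc$snp_index %in% followup_idx)
    assoc <- dplyr::bind_rows(assoc[keep, , drop = FALSE], extra)
  }
  sugg <- assoc[!is.na(assoc$p) & assoc$p < suggestive, c("chrom", "pos")]
  new_spikes <- aggregate_spikes(sugg, gap_limit = gap_limit)
  list(assoc = assoc, spikes = new_spikes)
}
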