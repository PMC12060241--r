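#' Read genotype probabilities from a VCF
#'
#' Reads a VCF 4.x file (via \pkg{vcfR}) carrying per-sample genotype
#' probabilities. The GP FORMAT field is preferred; if only DS is present,
#' triplets are reconstructed with [gp_from_dosage()] (lossy, documented
#' there). A file with neither GP nor DS is rejected. Non-biallelic records
#' are skipped with a warning; the toolkit operates on biallelic SNPs only.
#'
#' Typed/imputed status is taken from INFO flags: a record is typed when
#' `typed_key` is present, imputed when `imputed_key` is present; records with
#' neither flag default to `default_typed`.
#'
#' @param path Path to a VCF (plain or gzipped).
#' @param typed_key,imputed_key INFO flag keys (defaults `"TYPED"`, `"IMP"`).
#' @param default_typed Status assumed when neither flag is present.
#' @return A list with elements `gp` ([gp_matrix()]), `variants`
#'   ([variant_table()]) and `samples` (character vector).
#' @export
read_vcf <- function(path, typed_key = "TYPED", imputed_key = "IMP",
                     default_typed = TRUE) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT %||% "")
  if (any(multi)) {
    warn(sprintf("Skipping %d non-biallelic record(s).", sum(multi)))
    vcf <- vcf[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  if (nrow(fix) == 0L) abort("No biallelic records in VCF.")

  fmt <- unique(unlist(strsplit(vcf@gt[, "FORMAT"], ":")))
  if (!any(c("GP", "DS") %in% fmt)) {
    abort(paste0("VCF carries neither GP nor DS FORMAT fields; cannot build ",
                 "genotype probabilities (found: ",
                 paste(fmt, collapse = ", "), ")."))
  }

  if ("GP" %in% fmt) {
    gp_chr <- vcfR::extract.gt(vcf, element = "GP")
    if (anyNA(gp_chr)) abort("Missing GP entries in VCF.")
    m <- nrow(gp_chr); n <- ncol(gp_chr)
    vals <- as.numeric(unlist(strsplit(t(gp_chr), ","), use.names = FALSE))
    # vals ordered individual-fastest within SNP after the transpose
    probs <- aperm(array(vals, dim = c(3L, n, m)), c(2L, 3L, 1L))
    # triplets may carry rounding error from fixed-precision storage
    sums <- probs[, , 1L] + probs[, , 2L] + probs[, , 3L]
    probs <- probs / as.vector(sums)
    gp <- gp_matrix(probs)
  } else {
    ds <- vcfR::extract.gt(vcf, element = "DS", as.numeric = TRUE)
    gp <- gp_from_dosage(t(ds))
  }

  info <- fix$INFO %||% rep("", nrow(fix))
  has_flag <- function(key) {
    grepl(paste0("(^|;)", key, "($|;|=)"), info)
  }
  typed <- ifelse(has_flag(typed_key), TRUE,
                  ifelse(has_flag(imputed_key), FALSE, default_typed))
  variants <- variant_table(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT, typed = as.logical(typed)
  )
  list(gp = gp, variants = variants, samples = colnames(vcf@gt)[-1])
}

#' Write genotype probabilities to a VCF
#'
#' Emits a minimal, deterministic VCF 4.2 file with GT, DS and GP FORMAT
#' fields (GP and DS rounded to 4 decimals) and TYPED/IMP INFO flags, so that
#' `read_vcf(write_vcf(x))` round-trips GP values to 4 decimals.
#'
#' @param x A [cohort_study()] (cases written first, sample names
#'   `case_*`/`ctrl_*`) or a list with elements `gp`, `variants` and
#'   optionally `samples`.
#' @param path Output path.
#' @param typed_key,imputed_key INFO flag keys to emit.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path, typed_key = "TYPED", imputed_key = "IMP") {
  if (inherits(x, "cohort_study")) {
    samples <- c(
      sprintf("case_%04d", seq_len(n_individuals(x$cases))),
      sprintf("ctrl_%04d", seq_len(n_individuals(x$controls)))
    )
    x <- list(gp = gp_rbind(x$cases, x$controls), variants = x$variants,
              samples = samples)
  }
  gp <- x$gp; variants <- x$variants
  samples <- x$samples %||% sprintf("sample_%04d", seq_len(n_individuals(gp)))

  con <- tryCatch(file(path, open = "wt"),
                  error = function(e) abort(paste0("Cannot write to ", path)))
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=midrangeqc",
    sprintf("##INFO=<ID=%s,Number=0,Type=Flag,Description=\"Directly genotyped\">", typed_key),
    sprintf("##INFO=<ID=%s,Number=0,Type=Flag,Description=\"Imputed\">", imputed_key),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Best-guess genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Alternative allele dosage\">",
    "##FORMAT=<ID=GP,Number=G,Type=Float,Description=\"Genotype probabilities for 0/1/2 copies\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  ), con)

  gt_codes <- c("0/0", "0/1", "1/1")
  bg <- gp_to_best_guess(gp)
  ds <- gp_to_dosage(gp)
  for (j in seq_len(nrow(variants))) {
    fields <- sprintf(
      "%s:%s:%s", gt_codes[bg[, j] + 1L], fmt_num(ds[, j]),
      paste(fmt_num(gp[, j, 1L]), fmt_num(gp[, j, 2L]), fmt_num(gp[, j, 3L]),
            sep = ",")
    )
    writeLines(paste(c(
      variants$chrom[j], variants$pos[j], ".", variants$ref[j],
      variants$alt[j], ".", "PASS",
      if (variants$typed[j]) typed_key else imputed_key,
      "GT:DS:GP", fields
    ), collapse = "\t"), con)
  }
  invisible(path)
}

fmt_num <- function(x) formatC(round(x, 4), format = "fg", digits = 8)

#' Write a tibble as a deterministic TSV report
#'
#' Thin wrapper over [readr::write_tsv()] that keeps the column order of the
#' input and writes a header-only file for empty tables.
#'
#' @param table A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(table, path) {
  readr::write_tsv(table, path, progress = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
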