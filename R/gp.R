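#' Genotype-probability matrix
#'
#' The universal genotype representation of the package: for each of `n`
#' individuals and `m` biallelic SNPs, a probability triplet
#' \eqn{(p_0, p_1, p_2)} giving the posterior probability of carrying 0, 1 or
#' 2 copies of the alternative allele. Directly genotyped (or fully certain)
#' SNPs are represented by degenerate triplets with one probability equal to 1.
#'
#' @param probs A numeric array of dimension `n x m x 3`, or an `n x 3` matrix
#'   for a single SNP. Each triplet must be non-negative and sum to 1 within
#'   `tol`.
#' @param tol Tolerance on the triplet sums (default `1e-6`).
#'
#' @return A `gp_matrix`: a 3-D array of class `"gp_matrix"` with dimensions
#'   individuals x SNPs x genotype (0/1/2 copies).
#' @examples
#' gp <- gp_matrix(array(c(0.1, 0.2, 0.7), dim = c(1, 1, 3)))
#' gp_to_dosage(gp, 1)
#' @export
gp_matrix <- function(probs, tol = 1e-6) {
  if (is.matrix(probs) && ncol(probs) == 3L) {
    probs <- array(probs, dim = c(nrow(probs), 1L, 3L))
  }
  if (!is.array(probs) || length(dim(probs)) != 3L || dim(probs)[3] != 3L) {
    abort("`probs` must be an n x m x 3 array of genotype probabilities.")
  }
  if (dim(probs)[1] < 1L || dim(probs)[2] < 1L) {
    abort("A gp_matrix needs at least one individual and one SNP.")
  }
  if (anyNA(probs) || any(probs < -tol)) {
    abort("Genotype probabilities must be non-negative and non-missing.")
  }
  sums <- probs[, , 1L, drop = FALSE] + probs[, , 2L, drop = FALSE] +
    probs[, , 3L, drop = FALSE]
  if (any(abs(sums - 1) > tol)) {
    abort(sprintf(
      "Genotype-probability triplets must sum to 1 (max deviation %.3g).",
      max(abs(sums - 1))
    ))
  }
  dimnames(probs) <- list(NULL, NULL, c("g0", "g1", "g2"))
  structure(probs, class = c("gp_matrix", "array"))
}

#' @export
print.gp_matrix <- function(x, ...) {
  cat(sprintf(
    "<gp_matrix: %d individuals x %d SNPs>\n", n_individuals(x), n_snps(x)
  ))
  invisible(x)
}

#' @rdname gp_matrix
#' @param gp A `gp_matrix`.
#' @export
n_individuals <- function(gp) dim(gp)[1]

#' @rdname gp_matrix
#' @export
n_snps <- function(gp) dim(gp)[2]

#' Extract one SNP's probability triplets
#'
#' @param gp A [gp_matrix()].
#' @param snp_index Column index of the SNP.
#' @return An `n x 3` numeric matrix of triplets.
#' @export
gp_col <- function(gp, snp_index) {
  check_snp_index(gp, snp_index)
  matrix(gp[, snp_index, ], ncol = 3L,
         dimnames = list(NULL, c("g0", "g1", "g2")))
}

check_snp_index <- function(gp, snp_index) {
  if (length(snp_index) != 1L || is.na(snp_index) ||
      snp_index < 1L || snp_index > n_snps(gp)) {
    abort(sprintf(
      "`snp_index` must be a single index in 1..%d (got %s).",
      n_snps(gp), paste(snp_index, collapse = ",")
    ))
  }
  invisible(TRUE)
}

#' Collapse genotype probabilities to dosage
#'
#' The dosage of an individual is the expected count of alternative alleles,
#' \eqn{e = p_1 + 2 p_2}. Dosage preserves the uncertainty of imputation in a
#' single number per genotype.
#'
#' @param gp A [gp_matrix()].
#' @param snp_index SNP column to collapse; `NULL` (default) collapses all
#'   SNPs at once.
#' @return A numeric vector of length `n` (one SNP) or an `n x m` matrix, with
#'   values in `[0, 2]`.
#' @export
gp_to_dosage <- function(gp, snp_index = NULL) {
  if (is.null(snp_index)) {
    return(matrix(gp[, , 2L] + 2 * gp[, , 3L], n_individuals(gp), n_snps(gp)))
  }
  check_snp_index(gp, snp_index)
  gp[, snp_index, 2L] + 2 * gp[, snp_index, 3L]
}

#' Collapse genotype probabilities to best-guess genotypes
#'
#' The best guess is the hard genotype with the highest posterior probability;
#' all imputation uncertainty is discarded. Ties are broken deterministically
#' towards the lowest genotype (0 before 1 before 2).
#'
#' @inheritParams gp_to_dosage
#' @return An integer vector (one SNP) or `n x m` matrix with values in
#'   `{0, 1, 2}`.
#' @export
gp_to_best_guess <- function(gp, snp_index = NULL) {
  if (is.null(snp_index)) {
    out <- vapply(seq_len(n_snps(gp)), function(j) best_guess_col(gp_col(gp, j)),
                  integer(n_individuals(gp)))
    return(matrix(out, nrow = n_individuals(gp)))
  }
  check_snp_index(gp, snp_index)
  best_guess_col(gp_col(gp, snp_index))
}

best_guess_col <- function(triplets) {
  # max.col with ties.method = "first" implements the lowest-index tie-break,
  # but is sensitive to floating noise; snap near-ties first.
  tr <- round(triplets, 12)
  max.col(tr, ties.method = "first") - 1L
}

#' Reconstruct probability triplets from dosages
#'
#' Used when a VCF carries only the DS FORMAT field. The dosage mass is
#' assigned to the two nearest integer genotypes (for example a dosage of 1.6
#' becomes the triplet `(0, 0.4, 0.6)`). This reconstruction is lossy: it
#' recovers the dosage exactly but represents the least-uncertain triplet
#' consistent with it.
#'
#' @param dosage A numeric vector or `n x m` matrix of dosages in `[0, 2]`.
#' @return A [gp_matrix()].
#' @export
gp_from_dosage <- function(dosage) {
  if (is.null(dim(dosage))) dosage <- matrix(dosage, ncol = 1L)
  if (anyNA(dosage) || any(dosage < 0) || any(dosage > 2)) {
    abort("Dosages must be non-missing and within [0, 2].")
  }
  lo <- pmin(floor(dosage), 1)   # dosage 2 maps to genotypes 1/2 with mass on 2
  frac <- dosage - lo
  n <- nrow(dosage); m <- ncol(dosage)
  probs <- array(0, dim = c(n, m, 3L))
  idx <- cbind(c(row(dosage)), c(col(dosage)))
  probs[cbind(idx, c(lo) + 1L)] <- 1 - c(frac)
  probs[cbind(idx, c(lo) + 2L)] <- probs[cbind(idx, c(lo) + 2L)] + c(frac)
  gp_matrix(probs)
}

#' Build a degenerate gp_matrix from hard genotypes
#'
#' Complete (unimputed) data are represented by triplets that put probability
#' 1 on the observed genotype.
#'
#' @param genotypes An `n x m` integer matrix with values in `{0, 1, 2}`.
#' @return A [gp_matrix()].
#' @export
gp_from_genotypes <- function(genotypes) {
  if (is.null(dim(genotypes))) genotypes <- matrix(genotypes, ncol = 1L)
  if (anyNA(genotypes) || !all(genotypes %in% 0:2)) {
    abort("Genotypes must be 0, 1 or 2 with no missing values.")
  }
  n <- nrow(genotypes); m <- ncol(genotypes)
  probs <- array(0, dim = c(n, m, 3L))
  probs[cbind(c(row(genotypes)), c(col(genotypes)), c(genotypes) + 1L)] <- 1
  gp_matrix(probs)
}

#' Bind two gp_matrix objects by individuals
#' @param a,b `gp_matrix` objects over the same SNPs.
#' @return A `gp_matrix` stacking the individuals of `a` over those of `b`.
#' @export
gp_rbind <- function(a, b) {
  if (n_snps(a) != n_snps(b)) abort("gp matrices cover different SNP sets.")
  out <- array(0, dim = c(n_individuals(a) + n_individuals(b), n_snps(a), 3L))
  out[seq_len(n_individuals(a)), , ] <- a
  out[n_individuals(a) + seq_len(n_individuals(b)), , ] <- b
  gp_matrix(out)
}
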