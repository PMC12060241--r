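small_cfg <- function(...) {
  defaults <- list(n_snps = 60, n_cases = 40, n_controls = 40,
                   panel_size = 50, mean_spacing = 75000, seed = 2024)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

test_that("pool generation is bit-identical under a fixed seed", {
  p1 <- simulate_haplotype_pool(small_cfg())
  p2 <- simulate_haplotype_pool(small_cfg())
  expect_identical(p1$test, p2$test)
  expect_identical(p1$ref, p2$ref)
  expect_identical(p1$variants, p2$variants)
  p3 <- simulate_haplotype_pool(small_cfg(seed = 2025))
  expect_false(identical(p1$test, p3$test))
})

test_that("the copying process hits its LD limit cases", {
  # ld_decay = 0: the first allele is carried across the whole chromosome
  pool <- simulate_haplotype_pool(small_cfg(ld_decay = 0))
  expect_true(all(apply(pool$test, 1, function(h) length(unique(h)) == 1L)))
  # ld_decay = 1: adjacent SNPs uncorrelated over many haplotypes
  cfg1 <- sim_config(n_snps = 40, n_cases = 2500, n_controls = 2500,
                     panel_size = 10, ld_decay = 1, seed = 99)
  pool1 <- simulate_haplotype_pool(cfg1)
  cors <- vapply(seq_len(39), function(j) {
    a <- pool1$test[, j]; b <- pool1$test[, j + 1]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) 0 else stats::cor(a, b)
  }, numeric(1))
  expect_lt(max(abs(cors)), 0.05)
})

test_that("case-control sampling respects the disease model", {
  # null model: equal allele frequencies across groups at the locus
  cfg0 <- small_cfg(n_cases = 300, n_controls = 300,
                    disease_loci = tibble::tibble(snp_index = 10L,
                                                  odds_ratio = 1,
                                                  model = "additive"))
  pool0 <- simulate_haplotype_pool(cfg0)
  samp0 <- sample_case_control(pool0)
  fc <- mean(gp_to_dosage(samp0$study$cases, 10)) / 2
  fk <- mean(gp_to_dosage(samp0$study$controls, 10)) / 2
  se <- sqrt(fc * (1 - fc) / (2 * 300) + fk * (1 - fk) / (2 * 300))
  expect_lt(abs(fc - fk), 3 * se + 1e-9)
  # complete-data triplets are degenerate
  expect_true(all(unclass(samp0$study$cases) %in% c(0, 1)))
  # dominant coding gives genotypes 1 and 2 identical risk by construction
  expect_identical(midrangeqc:::genotype_risk_code(1L, "dominant"),
                   midrangeqc:::genotype_risk_code(2L, "dominant"))
  expect_identical(midrangeqc:::genotype_risk_code(1L, "recessive"), 0L)
})

test_that("a strong additive locus is detected in the gold standard", {
  hits <- 0L
  for (i in 1:20) {
    cfg <- sim_config(n_snps = 30, n_cases = 1000, n_controls = 1000,
                      panel_size = 10, mean_spacing = 75000,
                      maf_range = c(0.25, 0.35),
                      disease_loci = tibble::tibble(snp_index = NA_integer_,
                                                    odds_ratio = 3,
                                                    model = "additive"),
                      seed = 5000 + i)
    pool <- simulate_haplotype_pool(cfg)
    samp <- sample_case_control(pool)
    locus <- pool$config$disease_loci$snp_index[1]
    res <- assoc_scan(samp$study, "dosage", snp_subset = locus)
    if (!is.na(res$p[locus]) && res$p[locus] < 5e-8) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("deletion masks behave in both modes", {
  cfg <- sim_config(n_snps = 1000, n_cases = 30, n_controls = 30,
                    panel_size = 20, seed = 7,
                    deletion = list(mode = "uniform", fraction = 0.8))
  pool <- simulate_haplotype_pool(cfg)
  samp <- sample_case_control(pool)
  masked <- apply_deletion_mask(samp)
  n_typed <- sum(masked$study$variants$typed)
  expect_gte(n_typed, 150)
  expect_lte(n_typed, 250)

  # scaffold_fraction = 1: identity, nothing deleted
  cfg2 <- small_cfg(deletion = list(mode = "scaffold", fraction = 1))
  pool2 <- simulate_haplotype_pool(cfg2)
  samp2 <- sample_case_control(pool2)
  masked2 <- apply_deletion_mask(samp2)
  expect_true(all(masked2$study$variants$typed))
  expect_equal(unclass(masked2$study$cases), unclass(samp2$study$cases))

  # disease loci enjoy no protection from deletion (flag is just a draw)
  locus <- pool$config$disease_loci$snp_index
  expect_true(is.logical(masked$study$variants$typed[locus]))
  # over-aggressive masks are rejected
  expect_error(
    apply_deletion_mask(samp, sim_config(
      n_snps = 1000, n_cases = 30, n_controls = 30, panel_size = 20,
      seed = 7, deletion = list(mode = "uniform", fraction = 0.9999)
    )),
    "fewer than 2"
  )
})

test_that("surrogate imputation is exact in the perfect-LD limit", {
  # constructed perfect-LD study: every individual's genotype is constant
  # along the chromosome, and the panel covers all three genotype classes
  # deeply, so the evidence term dominates the frequency shrinkage
  g_ind <- c(0L, 1L, 2L, 1L, 0L, 2L)
  geno <- matrix(rep(g_ind, 4), ncol = 4)
  variants <- variant_table("1", c(1e3, 5e5, 1e6, 1.5e6),
                            typed = c(TRUE, FALSE, TRUE, FALSE))
  study <- cohort_study(gp_from_genotypes(geno[1:3, , drop = FALSE]),
                        gp_from_genotypes(geno[4:6, , drop = FALSE]),
                        variants)
  masked <- apply_deletion_mask(study, sim_config(
    n_snps = 4, n_cases = 3, n_controls = 3, panel_size = 10,
    deletion = list(mode = "scaffold", fraction = 1), seed = 1
  ))
  masked$study$variants$typed <- variants$typed
  panel <- matrix(rep(rep(0:2, each = 10), 4), ncol = 4)
  imputed <- surrogate_impute(masked$study, panel = panel, k_window = 2,
                              alpha = 0.1)
  imp_dose <- gp_to_dosage(gp_rbind(imputed$cases, imputed$controls))
  expect_lt(max(abs(imp_dose[, c(2, 4)] - geno[, c(2, 4)])), 0.1)
})

test_that("typed SNPs are never altered by imputation", {
  cfg <- small_cfg()
  sim <- simulate_cohort(cfg)
  typed <- sim$study$variants$typed
  expect_equal(unclass(sim$study$cases)[, typed, ],
               unclass(sim$complete$cases)[, typed, ])
  expect_equal(unclass(sim$study$controls)[, typed, ],
               unclass(sim$complete$controls)[, typed, ])
})

test_that("a reference panel of one individual collapses onto its genotype", {
  cfg <- small_cfg(panel_size = 1)
  pool <- simulate_haplotype_pool(cfg)
  samp <- sample_case_control(pool)
  masked <- apply_deletion_mask(samp)
  imputed <- surrogate_impute(masked, k_window = 2, alpha = 0.5)
  untyped <- which(!masked$study$variants$typed)
  # both the evidence and the frequency shrinkage derive from the single
  # panel pair, so the best guess is that pair's genotype everywhere
  for (grp in c("cases", "controls")) {
    bg <- gp_to_best_guess(imputed$study[[grp]])
    pg <- samp$panel[[grp]][1, ]
    expect_true(all(bg[, untyped] == matrix(pg[untyped], nrow(bg),
                                            length(untyped), byrow = TRUE)))
  }
})

test_that("the standard seeded scenario spans the quality regimes", {
  q <- std_quality()
  qi <- q$impute_info[!q$typed]
  expect_true(any(qi > 0.3 & qi < 0.8))   # midrange occupied
  expect_true(any(qi >= 0.8))             # high-confidence tail
  expect_true(any(qi < 0.5))              # low/mid tail
})

test_that("pooled allele frequencies track the pool at neutral loci", {
  # a null disease model keeps every SNP neutral, including LD partners of
  # the (inactive) locus
  cfg <- small_cfg(n_cases = 200, n_controls = 200,
                   disease_loci = tibble::tibble(snp_index = NA_integer_,
                                                 odds_ratio = 1,
                                                 model = "additive"))
  pool <- simulate_haplotype_pool(cfg)
  samp <- sample_case_control(pool)
  loci <- pool$config$disease_loci$snp_index
  pool_freq <- colMeans(pool$test)
  study_dose <- gp_to_dosage(gp_rbind(samp$study$cases, samp$study$controls))
  study_freq <- colMeans(study_dose) / 2
  se <- sqrt(pool_freq * (1 - pool_freq) / (2 * 400))
  neutral <- setdiff(seq_len(cfg$n_snps), loci)
  # allow a few 3-SE misses by chance across 59 SNPs
  expect_lt(mean(abs(study_freq - pool_freq)[neutral] > 3 * se[neutral]), 0.1)
})

test_that("denser scaffolds do not degrade median imputation quality", {
  meds <- vapply(c(0.1, 0.3, 0.6), function(f) {
    qs <- vapply(1:5, function(i) {
      cfg <- sim_config(n_snps = 120, n_cases = 60, n_controls = 60,
                        panel_size = 300, mean_spacing = 75000,
                        deletion = list(mode = "scaffold", fraction = f),
                        seed = 31400 + i)
      sim <- simulate_cohort(cfg)
      q <- quality_table(sim$study)
      stats::median(q$impute_info[!q$typed])
    }, numeric(1))
    mean(qs)
  }, numeric(1))
  expect_gte(meds[2], meds[1] - 0.05)
  expect_gte(meds[3], meds[2] - 0.05)
})

test_that("truth labels follow the gold-standard definition", {
  sim <- std_sim()
  expect_identical(sim$truth$significant_gold,
                   !is.na(sim$gold$p) & sim$gold$p < 5e-8)
  # spike truth: one true member suffices
  spikes <- tibble::tibble(
    spike_id = c("a", "b"), chrom = "1",
    start = c(1L, 10L), end = c(2L, 11L), n_members = 2L,
    members = list(c(1L, 2L), c(10L, 11L))
  )
  truth <- tibble::tibble(chrom = "1", pos = c(1L, 2L, 10L, 11L),
                          significant_gold = c(TRUE, FALSE, FALSE, FALSE))
  lab <- label_spike_truth(spikes, truth)
  expect_identical(lab$true_spike, c(TRUE, FALSE))
  # empty significant set: no spike is true
  truth$significant_gold <- FALSE
  expect_false(any(label_spike_truth(spikes, truth)$true_spike))
})

test_that("identical config and seed reproduce the whole cohort", {
  s1 <- simulate_cohort(small_cfg())
  s2 <- simulate_cohort(small_cfg())
  expect_equal(unclass(s1$study$cases), unclass(s2$study$cases))
  expect_equal(s1$truth, s2$truth)
})
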