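test_that("classification follows the rule precedence", {
  cfg <- filter_config()
  # typed anchor wins even over terrible quality
  d <- classify_spikes(make_spike(0.1, 0.1, typed_sig = TRUE), cfg)
  expect_identical(d$verdict, "keep")
  expect_identical(d$reason, "typed_anchor")
  expect_identical(d$case, "typed")
  # q_min below lower discards any spike
  d <- classify_spikes(make_spike(0.2, 0.95), cfg)
  expect_identical(d$verdict, "discard")
  expect_identical(d$reason, "q_min_below_lower")
  # best-guess-only spikes additionally need the upper threshold
  d <- classify_spikes(make_spike(0.5, 0.7, dosage = FALSE), cfg)
  expect_identical(d$verdict, "discard")
  expect_identical(d$reason, "bg_specific_q_max_below_upper")
  expect_identical(d$case, "bestguess_only")
  # the same quality profile passes when dosage can see the spike
  d <- classify_spikes(make_spike(0.5, 0.7, dosage = TRUE), cfg)
  expect_identical(d$verdict, "keep")
  # values exactly at a threshold pass (strict "does not meet")
  d <- classify_spikes(make_spike(0.3, 0.8, dosage = FALSE), cfg)
  expect_identical(d$verdict, "keep")
  expect_error(classify_spikes(tibble::tibble(q_min = 1), cfg), "annotated")
})

test_that("published application decisions are reproduced", {
  res <- filter_psycourse()
  d <- res$decisions
  # chromosome 20: dosage-detectable, per-group minima 0.518/0.514 >= 0.3
  chr20 <- d[d$chrom == "20", ]
  expect_identical(chr20$verdict, "keep")
  expect_identical(sum(lengths(chr20$members[chr20$verdict == "keep"])), 2L)
  # 6:130733300 falls to 0.238 on the per-group minimum: discarded low
  s6 <- d[d$chrom == "6" & d$start == 130733300, ]
  expect_identical(s6$verdict, "discard")
  expect_identical(s6$reason, "q_min_below_lower")
  # 1:210978952 is best-guess specific at 0.603 < 0.8: discarded
  s1 <- d[d$chrom == "1" & d$start == 210978952, ]
  expect_identical(s1$verdict, "discard")
  expect_identical(s1$reason, "bg_specific_q_max_below_upper")
  expect_identical(s1$case, "bestguess_only")
  # nothing else is discarded
  expect_identical(sum(d$verdict == "discard"), 2L)
  expect_identical(nrow(res$kept_snps), 78L)
})

test_that("initial-quality filtering keeps the chr20 signal only via the filter", {
  # under the plain 0.8 threshold both chr20 SNPs (0.518/0.514) would go;
  # the whole-spike rule preserves them
  res <- filter_psycourse()
  chr20 <- res$kept_snps[res$kept_snps$chrom == "20", ]
  expect_identical(nrow(chr20), 2L)
  expect_true(all(chr20$quality_min < 0.8 & chr20$quality_min >= 0.3))
})

test_that("threshold monotonicity: raising thresholds never revives a spike", {
  set.seed(77)
  spikes <- dplyr::bind_rows(lapply(1:60, function(i) {
    make_spike(runif(1), NA, dosage = runif(1) < 0.7, bg = runif(1) < 0.7,
               typed_sig = runif(1) < 0.15)
  }))
  spikes$q_max <- pmin(1, spikes$q_min + runif(60, 0, 0.5))
  spikes$dosage_present[!spikes$dosage_present & !spikes$best_guess_present] <- TRUE
  grid <- expand.grid(lower = c(0.1, 0.3, 0.5), upper = c(0.6, 0.8, 0.95))
  for (i in seq_len(nrow(grid))) for (j in seq_len(nrow(grid))) {
    gi <- grid[i, ]; gj <- grid[j, ]
    if (gi$lower <= gj$lower && gi$upper <= gj$upper) {
      di <- classify_spikes(spikes, filter_config(gi$lower, gi$upper))
      dj <- classify_spikes(spikes, filter_config(gj$lower, gj$upper))
      expect_true(all(!(di$verdict == "discard" & dj$verdict == "keep")))
    }
  }
})

test_that("dominance over single thresholds holds on random spikes", {
  set.seed(78)
  spikes <- dplyr::bind_rows(lapply(1:80, function(i) {
    q1 <- runif(1); q2 <- runif(1)
    make_spike(min(q1, q2), max(q1, q2), dosage = runif(1) < 0.6,
               bg = runif(1) < 0.6, typed_sig = FALSE)
  }))
  spikes$dosage_present[!spikes$dosage_present & !spikes$best_guess_present] <- TRUE
  cfg <- filter_config()
  d <- classify_spikes(spikes, cfg)
  # discarded by the lower rule alone => discarded by the Midrange Filter
  lower_discard <- spikes$q_min < cfg$lower
  expect_true(all(d$verdict[lower_discard] == "discard"))
  # all members meet the upper threshold => kept (no typed anchors present)
  upper_keep <- spikes$q_min >= cfg$upper
  expect_true(all(d$verdict[upper_keep] == "keep"))
})

test_that("the full pipeline is deterministic and honours whole-spike deletion", {
  sim <- std_sim()
  mf1 <- run_midrange_filter(sim$study, truth = sim$truth)
  mf2 <- run_midrange_filter(sim$study, truth = sim$truth)
  expect_equal(mf1$decisions, mf2$decisions)
  expect_equal(mf1$filtered_assoc, mf2$filtered_assoc)
  # every suggestive SNP of a kept spike survives; discarded spikes vanish
  kept_pos <- unlist(mf1$decisions$members[mf1$decisions$verdict == "keep"])
  drop_pos <- unlist(mf1$decisions$members[mf1$decisions$verdict == "discard"])
  expect_true(all(mf1$filtered_assoc$pos %in% kept_pos))
  expect_false(any(mf1$filtered_assoc$pos %in% setdiff(drop_pos, kept_pos)))
  expect_s3_class(glance(mf1), "tbl_df")
  expect_identical(nrow(tidy(mf1)), nrow(mf1$decisions))
})

test_that("a study with no significant SNPs yields empty decisions", {
  sim <- std_sim()
  st <- sim$complete
  # permute the phenotype by swapping equal-sized case/control halves:
  # build a null study from control genotypes only
  n <- n_individuals(st$controls)
  half <- floor(n / 2)
  null_study <- cohort_study(
    cases = gp_matrix(unclass(st$controls)[1:half, , , drop = FALSE]),
    controls = gp_matrix(unclass(st$controls)[(half + 1):n, , , drop = FALSE]),
    variants = st$variants
  )
  mf <- run_midrange_filter(null_study)
  expect_identical(nrow(mf$decisions), 0L)
  expect_identical(nrow(mf$filtered_assoc), 0L)
})

test_that("group_combine mean and max still give valid decisions", {
  sim <- std_sim()
  for (rule in c("mean", "max")) {
    mf <- run_midrange_filter(sim$study, filter_config(group_combine = rule),
                              truth = sim$truth)
    expect_true(all(mf$decisions$verdict %in% c("keep", "discard")))
    expect_true(all(mf$decisions$q_min <= mf$decisions$q_max | is.na(mf$decisions$q_min)))
  }
})

test_that("plot methods return ggplot objects", {
  sim <- std_sim()
  mf <- run_midrange_filter(sim$study, truth = sim$truth)
  expect_s3_class(autoplot(mf), "ggplot")
  expect_s3_class(plot_manhattan(mf$assoc), "ggplot")
})
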