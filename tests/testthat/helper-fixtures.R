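# shared fixtures, built once per test run and memoized

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, builder(), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# a moderate, well-matched imputed cohort used across quality/association/
# filter tests: 300 SNPs on a ~22 Mb chromosome, 150 + 150 individuals,
# deep per-group panels, 20% scaffold
std_sim <- function() {
  memo("std_sim", function() {
    cfg <- sim_config(
      n_snps = 300, n_cases = 150, n_controls = 150, panel_size = 1200,
      mean_spacing = 75000,
      deletion = list(mode = "scaffold", fraction = 0.2),
      seed = 4242
    )
    simulate_cohort(cfg)
  })
}

std_quality <- function() {
  memo("std_quality", function() quality_table(std_sim()$study))
}

# n x 3 triplet matrix shorthand
tri <- function(...) {
  matrix(c(...), ncol = 3L, byrow = TRUE)
}

# independent logistic-regression oracle: direct likelihood maximization
# over (b0, b1) with numerical Hessian for the Wald SE
logit_oracle <- function(y, g) {
  nll <- function(b) {
    eta <- b[1] + b[2] * g
    -sum(y * eta - log1p(exp(eta)))
  }
  fit <- stats::optim(c(0, 0), nll, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-12))
  # polish to machine precision with analytic Newton steps
  b <- fit$par
  x <- cbind(1, g)
  for (i in 1:50) {
    mu <- stats::plogis(drop(x %*% b))
    grad <- drop(crossprod(x, y - mu))
    hess <- crossprod(x * (mu * (1 - mu)), x)
    step <- solve(hess, grad)
    b <- b + step
    if (max(abs(step)) < 1e-13) break
  }
  mu <- stats::plogis(drop(x %*% b))
  hess <- crossprod(x * (mu * (1 - mu)), x)
  se <- sqrt(diag(solve(hess)))[2]
  z <- b[2] / se
  list(beta = unname(b[2]), se = unname(se),
       p = unname(2 * stats::pnorm(-abs(z))))
}

# brute-force spike chaining: transitive closure over the all-pairs
# "closer than gap_limit" relation
chain_oracle <- function(pos, gap_limit = 2e6) {
  pos <- sort(unique(pos))
  n <- length(pos)
  if (n == 0) return(list())
  adj <- abs(outer(pos, pos, "-")) < gap_limit
  comp <- rep(NA_integer_, n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    frontier <- i
    comp[i] <- cid
    while (length(frontier)) {
      nxt <- which(apply(adj[frontier, , drop = FALSE], 2, any) & is.na(comp))
      comp[nxt] <- cid
      frontier <- nxt
    }
  }
  unname(split(pos, comp))
}

# exhaustive pair-counting AUC oracle: P(q_false < q_true) + 0.5 P(tie)
auc_oracle <- function(quality, is_false) {
  qf <- quality[is_false]
  qt <- quality[!is_false]
  pairs <- outer(qf, qt, function(a, b) (a < b) + 0.5 * (a == b))
  mean(pairs)
}

# minimal annotated spike tibble for classifier tests
make_spike <- function(q_min, q_max, dosage = TRUE, bg = TRUE,
                       typed_sig = FALSE, chrom = "1") {
  tibble::tibble(
    spike_id = sprintf("%s:%d", chrom, sample.int(1e6, 1)),
    chrom = chrom, start = 1L, end = 2L, n_members = 2L,
    members = list(c(1L, 2L)),
    dosage_present = dosage, best_guess_present = bg,
    has_significant = TRUE, has_typed_significant = typed_sig,
    q_min = q_min, q_max = q_max,
    format_specific = if (dosage && bg) "both" else if (dosage) "dosage"
      else "best_guess"
  )
}
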