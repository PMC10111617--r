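test_that("select_by_pvalue filters strictly and errors usefully when empty", {
  rec <- make_records(n = 3, pval = c(1e-9, 1e-7, 1e-3))
  expect_equal(nrow(select_by_pvalue(rec, 5e-8)), 1L)
  expect_equal(nrow(select_by_pvalue(rec, 1e-5)), 2L)
  expect_equal(nrow(select_by_pvalue(rec, 1.0)), 3L)
  expect_error(select_by_pvalue(rec, 1e-12), "relaxed threshold")
  expect_error(select_by_pvalue(rec, 0), "probability")
})

test_that("clump keeps the best SNP of a correlated pair and everything under identity LD", {
  rec <- make_records(n = 2, pval = c(1e-10, 1e-9))
  ld <- diag(2); dimnames(ld) <- list(rec$snp_id, rec$snp_id)
  ld[1, 2] <- ld[2, 1] <- sqrt(0.5)
  kept <- clump(rec, ld, r2_threshold = 0.001)
  expect_equal(kept$snp_id, "rs0001")

  ld_id <- diag(2); dimnames(ld_id) <- list(rec$snp_id, rec$snp_id)
  expect_equal(nrow(clump(rec, ld_id)), 2L)
  expect_equal(nrow(clump(rec, ld = NULL)), 2L)  # no LD info -> independent
})

test_that("clump resolves LD blocks to the per-block minimum-p SNP", {
  # 10 SNPs in 2 blocks of 5, within-block r2 = 0.9
  withr::with_seed(41, {
    rec <- make_records(n = 10, pval = runif(10, 1e-12, 1e-8),
                        pos = c(1:5 * 1000, 1:5 * 1000 + 5e6))
    block <- rep(1:2, each = 5)
    ld <- diag(10)
    for (i in 1:10) for (j in 1:10)
      if (i != j && block[i] == block[j]) ld[i, j] <- sqrt(0.9)
    dimnames(ld) <- list(rec$snp_id, rec$snp_id)

    kept <- clump(rec, ld, r2_threshold = 0.001, window_kb = 10000)
    # independent reference: iterative which.min over a worklist
    reference <- {
      left <- seq_len(10); acc <- integer(0)
      while (length(left)) {
        i <- left[which.min(rec$pval[left])]
        acc <- c(acc, i)
        drop <- vapply(left, function(j)
          block[j] == block[i] && ld[i, j]^2 >= 0.001, logical(1))
        left <- left[!drop]
      }
      sort(rec$snp_id[acc])
    }
    expect_equal(sort(kept$snp_id), reference)
    expect_equal(nrow(kept), 2L)
    per_block_best <- vapply(1:2, function(b) {
      ix <- which(block == b)
      rec$snp_id[ix][which.min(rec$pval[ix])]
    }, character(1))
    expect_setequal(kept$snp_id, per_block_best)
  })
})

test_that("clump output is invariant to input row order and commutes with selection", {
  withr::with_seed(42, {
    rec <- make_records(n = 12, pval = 10^runif(12, -12, -6),
                        pos = rep(1:4 * 1000, 3),
                        chrom = as.character(rep(1:3, each = 4)))
    ld <- diag(12)
    for (i in 1:12) for (j in 1:12)
      if (i != j && rec$chrom[i] == rec$chrom[j]) ld[i, j] <- 0.6
    dimnames(ld) <- list(rec$snp_id, rec$snp_id)

    base <- clump(rec, ld)
    for (perm in list(12:1, sample(12))) {
      expect_identical(clump(rec[perm, ], ld)$snp_id, base$snp_id)
    }
    thr <- 1e-8
    a <- clump(select_by_pvalue(rec, thr), ld)
    b <- select_by_pvalue(clump(rec, ld), thr)
    expect_identical(a$snp_id, b$snp_id)
  })
})

test_that("f_statistic is (beta/se)^2 and matches the variance-explained identity", {
  expect_equal(f_statistic(0.1, 0.01), 100)
  expect_equal(f_statistic(sqrt(10) * 0.02, 0.02), 10)  # weak-instrument boundary
  withr::with_seed(43, {
    beta <- rnorm(20, 0, 0.1); se <- runif(20, 0.01, 0.05); n <- 5000
    t2 <- (beta / se)^2
    r2 <- t2 / (t2 + n - 2)
    expect_equal(f_from_r2(r2, n), f_statistic(beta, se), tolerance = 1e-12)
  })
  expect_error(f_statistic(0.1, 0), "positive")
})

test_that("steiger_filter keeps exposure-dominant SNPs and removes reverse-direction SNPs", {
  h <- make_harmonized(beta_exp = c(0.10, 0.01), beta_out = c(0.01, 0.10),
                       se_exp = c(0.01, 0.01), se_out = c(0.01, 0.01))
  expect_message(out <- steiger_filter(h, n_exp = 1e5, n_out = 1e5),
                 "removed 1")
  expect_equal(out$snp_id, "rs0001")
  detail <- attr(out, "steiger")
  expect_true(detail$retained[1] && !detail$retained[2])
  # all reverse -> hard error
  h_rev <- make_harmonized(beta_exp = 0.01, beta_out = 0.10)
  expect_error(steiger_filter(h_rev, n_exp = 1e5, n_out = 1e5), "removed all")
})

test_that("steiger_filter removes simulated reverse-causal SNPs at high rate", {
  st <- simulate_gwas(simulation_config(
    seed = 404, n_snp_causal = 20, n_snp_mediator = 0, n_snp_null = 0,
    reverse_causal_snps = 30, n_exp = 1e5, n_case = 5e4, n_control = 5e4))
  h <- harmonize(st$exposure, st$outcome)
  filt <- suppressMessages(steiger_filter(h, alpha = 0.05))
  removed <- setdiff(h$snp_id, filt$snp_id)
  frac_rev_removed <- mean(st$truth$reverse_ids %in% removed)
  expect_gte(frac_rev_removed, 0.9)
  # forward instruments largely survive
  expect_gte(mean(st$truth$causal_ids %in% filt$snp_id), 0.8)
})

test_that("default scenario yields strong instruments (min F > 10) across seeds", {
  ok <- vapply(1:20, function(s) {
    st <- simulate_gwas(simulation_config(seed = 500 + s))
    sel <- select_by_pvalue(st$exposure, 5e-8)
    min(f_statistic(sel$beta, sel$se)) > 10
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("LD matrix round-trips through its TSV representation", {
  st <- simulate_gwas(simulation_config(seed = 77, n_snp_causal = 5,
                                        n_snp_mediator = 0, n_snp_null = 0,
                                        ld_blocks = list(list(size = 3, r2 = 0.8))))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ld_matrix(st$ld, path)
  back <- read_ld_matrix(path)
  expect_equal(back, st$ld, tolerance = 1e-12)
})
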