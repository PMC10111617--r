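test_that("read_summary_stats parses TSV/CSV, maps headers and handles optional columns", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("SNP,EA,OA,BETA,SE,P",
               "rs1,A,G,0.10,0.01,1.524e-23",
               "rs2,t,c,-0.20,0.02,1.524e-23",
               "rs3,G,A,0.05,0.04,0.2113"), path)
  rec <- read_summary_stats(path)
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$beta, c(0.10, -0.20, 0.05))
  expect_equal(rec$effect_allele[2], "T")  # uppercased
  expect_true(all(is.na(rec$eaf)))         # absent -> missing
  expect_true(all(is.na(rec$n)))

  # custom header mapping
  path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("variant\tallele1\tallele2\tb\tstderr\tpvalue",
               "rs1\tA\tG\t0.1\t0.01\t1.524e-23"), path2)
  rec2 <- read_summary_stats(path2, column_map = c(
    snp_id = "variant", effect_allele = "allele1", other_allele = "allele2",
    beta = "b", se = "stderr", pval = "pvalue"))
  expect_equal(rec2$beta, 0.1)
})

test_that("read_summary_stats rejects bad rows and reports the count", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\tEA\tOA\tBETA\tSE\tP",
               "rs1\tA\tG\t0.1\t0.01\t1.524e-23",
               "rs2\tA\tG\tNA\t0.01\t1e-10",       # unparsable beta
               "rs3\tAT\tG\t0.1\t0.01\t1e-10",     # indel
               "rs4\tA\tA\t0.1\t0.01\t1e-10"),     # degenerate alleles
             path)
  expect_message(rec <- read_summary_stats(path), "rejected 3 of 4")
  expect_equal(nrow(rec), 1L)
  expect_equal(attr(rec, "n_rejected"), 3L)
})

test_that("read_summary_stats errors on missing mandatory columns, naming them", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\tEA\tOA\tBETA\tP", "rs1\tA\tG\t0.1\t1e-10"), path)
  expect_error(read_summary_stats(path), "mandatory column 'se'")
})

test_that("missing p-values are reconstituted from beta/se; inconsistent ones warn", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("SNP\tEA\tOA\tBETA\tSE\tP",
               "rs1\tA\tG\t0.1\t0.05\tNA",
               "rs2\tA\tG\t0.1\t0.05\t1e-30"), path)
  expect_warning(
    expect_message(rec <- read_summary_stats(path), "reconstituted 1"),
    "inconsistent")
  expect_equal(rec$pval[1], 2 * pnorm(-2), tolerance = 1e-12)
})

test_that("write -> read round-trips values and write -> read -> write is byte-identical", {
  rec <- withr::with_seed(11, make_records(
    n = 8, beta = rnorm(8, 0, 0.1), se = runif(8, 0.005, 0.02),
    eaf = runif(8), nn = sample(1e4:1e6, 8)))
  rec$eaf[3] <- NA  # missing eaf serialized as NA
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_summary_stats(rec, f1)
  expect_true(is.na(read_summary_stats(f1)$eaf[3]))
  back <- read_summary_stats(f1)
  expect_equal(back$beta, rec$beta)
  expect_equal(back$se, rec$se)
  write_summary_stats(back, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_error(write_summary_stats(rec[0, ], f1), "no records")
})

test_that("gzip-compressed input is read transparently", {
  rec <- make_records(n = 3)
  plain <- withr::local_tempfile(fileext = ".tsv")
  gz <- withr::local_tempfile(fileext = ".tsv.gz")
  write_summary_stats(rec, plain)
  con <- gzfile(gz, "wt"); writeLines(readLines(plain), con); close(con)
  expect_equal(read_summary_stats(gz)$beta, rec$beta)
})

test_that("harmonize keeps matches, flips swaps, complements strands and drops palindromes", {
  exp <- make_records(n = 5, ea = c("A", "A", "A", "A", "A"),
                      oa = c("G", "G", "G", "T", "G"),
                      beta = c(0.1, 0.1, 0.1, 0.1, 0.1))
  out <- make_records(n = 5, ea = c("A", "G", "T", "A", "C"),
                      oa = c("G", "A", "C", "T", "G"),
                      beta = c(0.2, 0.2, 0.2, 0.2, 0.2))
  # rs1 direct; rs2 swapped; rs3 strand-complement of A/G (T/C -> direct);
  # rs4 palindromic A/T; rs5 irreconcilable (C/G is palindromic too - swap in
  # a genuinely incompatible pair instead)
  out$effect_allele[5] <- "A"; out$other_allele[5] <- "C"
  expect_warning(h <- harmonize(exp, out), "irreconcilable")
  expect_equal(h$snp_id, c("rs0001", "rs0002", "rs0003"))
  expect_equal(h$beta_out, c(0.2, -0.2, 0.2))
  expect_equal(attr(h, "n_flipped"), 1L)
  expect_equal(attr(h, "n_dropped_palindromic"), 1L)
  expect_equal(attr(h, "n_dropped_incompatible"), 1L)
})

test_that("harmonize flips complement-swapped alleles and errors with zero overlap", {
  exp <- make_records(n = 1, ea = "A", oa = "G", beta = 0.1)
  out <- make_records(n = 1, ea = "C", oa = "T", beta = 0.2)  # comp of G/A
  h <- harmonize(exp, out)
  expect_equal(h$beta_out, -0.2)
  expect_equal(attr(h, "n_flipped"), 1L)

  out2 <- make_records(n = 1, ids = "rsX")
  expect_error(harmonize(exp, out2), "no shared SNPs")
})

test_that("harmonize is idempotent on an already-aligned pair", {
  st <- simulate_gwas(simulation_config(seed = 301, n_snp_causal = 20,
                                        n_snp_mediator = 0, n_snp_null = 10,
                                        frac_palindromic = 0.2))
  h1 <- harmonize(st$exposure, st$outcome)
  # rebuild outcome records from the harmonized (aligned) set
  realigned <- data.frame(snp_id = h1$snp_id, chrom = h1$chrom, pos = h1$pos,
                          effect_allele = h1$effect_allele,
                          other_allele = h1$other_allele, eaf = h1$eaf_out,
                          beta = h1$beta_out, se = h1$se_out,
                          pval = h1$pval_out, n = h1$n_out,
                          stringsAsFactors = FALSE)
  exp_aligned <- st$exposure[st$exposure$snp_id %in% h1$snp_id, ]
  h2 <- harmonize(exp_aligned, realigned)
  expect_equal(h2$beta_out, h1$beta_out)
  expect_equal(attr(h2, "n_flipped"), 0L)
  expect_equal(attr(h2, "n_dropped_palindromic"), 0L)
})

test_that("flipping every exposure effect allele negates beta_exp but leaves causal estimates invariant", {
  st <- simulate_gwas(simulation_config(seed = 302, n_snp_causal = 25,
                                        n_snp_mediator = 0, n_snp_null = 0))
  sel <- select_by_pvalue(st$exposure, 5e-8)
  h1 <- harmonize(sel, st$outcome)

  flipped <- sel
  flipped$effect_allele <- sel$other_allele
  flipped$other_allele <- sel$effect_allele
  flipped$beta <- -sel$beta
  flipped$eaf <- 1 - sel$eaf
  h2 <- harmonize(flipped, st$outcome)

  expect_equal(h2$beta_exp, -h1$beta_exp)
  expect_equal(h2$beta_out, -h1$beta_out)
  expect_equal(mr_ivw(h2)$beta, mr_ivw(h1)$beta, tolerance = 1e-12)
  expect_equal(mr_egger(h2)$beta, mr_egger(h1)$beta, tolerance = 1e-12)
  wm1 <- mr_weighted_median(h1, n_boot = 200, seed = 5)
  wm2 <- mr_weighted_median(h2, n_boot = 200, seed = 5)
  expect_equal(wm2$beta, wm1$beta, tolerance = 1e-12)
})

test_that("palindromic drop count equals the configured fraction exactly", {
  st <- simulate_gwas(simulation_config(seed = 303, n_snp_causal = 40,
                                        n_snp_mediator = 0, n_snp_null = 60,
                                        frac_palindromic = 0.2))
  h <- harmonize(st$exposure, st$outcome)
  expect_equal(attr(h, "n_dropped_palindromic") / nrow(st$exposure), 0.2)
})
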