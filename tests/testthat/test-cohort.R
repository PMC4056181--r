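test_that("Hardy-Weinberg genotype frequencies are correct and normalized", {
  expect_equal(hwe_genotype_freqs(0.5), c(g0 = 0.25, g1 = 0.50, g2 = 0.25))
  expect_equal(hwe_genotype_freqs(0.0), c(g0 = 1, g1 = 0, g2 = 0))
  expect_equal(hwe_genotype_freqs(0.3), c(g0 = 0.49, g1 = 0.42, g2 = 0.09))
  m <- hwe_genotype_freqs(seq(0, 1, by = 0.1))
  expect_equal(unname(rowSums(m)), rep(1, 11))
  expect_error(hwe_genotype_freqs(1.2), "raf")
})

test_that("genotype sampling is deterministic and matches HWE frequencies", {
  pan <- random_panel(4, seed = 11)
  g1 <- sample_genotypes(pan, 5000, rng_seed = 7)
  g2 <- sample_genotypes(pan, 5000, rng_seed = 7)
  expect_identical(g1, g2)
  expect_identical(colnames(g1), pan$snp_id)
  expect_true(all(g1 %in% 0:2))

  # monomorphic edge: raf 0 gives an all-zero column
  mono <- data.frame(snp_id = "rs0", raf = 0, or_allele = 1)
  expect_true(all(sample_genotypes(mono, 1000, rng_seed = 1) == 0L))

  # empirical genotype proportions within 4 binomial SEs at n = 100,000
  n <- 100000
  half <- snp_panel("rs1", raf = 0.5, or_allele = 1.2)
  g <- sample_genotypes(half, n, rng_seed = 3)
  props <- tabulate(g[, 1] + 1L, 3L) / n
  expected <- c(0.25, 0.5, 0.25)
  se <- sqrt(expected * (1 - expected) / n)
  expect_true(all(abs(props - expected) < 4 * se))
})

test_that("baseline-risk solver reproduces prevalence and LR identities", {
  # null SNP: every genotype at the population risk
  p0 <- solve_baseline_risk(0.4, 1, d = 0.2)
  expect_equal(unname(p0$geno_risks), rep(0.2, 3), tolerance = 1e-10)
  expect_equal(unname(p0$lrs), rep(1, 3), tolerance = 1e-9)

  # frozen oracle values for OR = 2, raf = 0.5, d = 0.2
  pr <- solve_baseline_risk(0.5, 2, d = 0.2)
  expect_equal(unname(pr$geno_risks), c(0.104320, 0.188931, 0.317817),
               tolerance = 1e-5)
  expect_equal(unname(pr$lrs), c(0.465882, 0.931765, 1.863530),
               tolerance = 1e-5)

  # algebraic identities on random parameter draws
  set.seed(42)
  for (i in 1:20) {
    raf <- runif(1, 0.02, 0.98)
    or <- exp(runif(1, 0, 1.5))
    d <- runif(1, 0.002, 0.4)
    pr <- solve_baseline_risk(raf, or, d)
    expect_equal(sum(pr$geno_freqs), 1, tolerance = 1e-12)
    expect_equal(sum(pr$geno_freqs * pr$geno_risks), d, tolerance = 1e-10)
    expect_equal(pr$lrs[2] / pr$lrs[1], or, tolerance = 1e-9)
    expect_equal(pr$lrs[3] / pr$lrs[1], or^2, tolerance = 1e-9)
    ctrl <- pr$geno_freqs * (1 - pr$geno_risks) / (1 - d)
    expect_equal(sum(ctrl * pr$lrs), 1, tolerance = 1e-9)
  }
})

test_that("posterior risks follow Bayes' theorem", {
  d <- 0.2
  pr <- solve_baseline_risk(0.5, 2, d)

  # single SNP: the posterior for genotype i is exactly the solved risk p_i
  geno <- matrix(0:2, ncol = 1, dimnames = list(NULL, "rs1"))
  expect_equal(posterior_risks(geno, list(pr), d), unname(pr$geno_risks),
               tolerance = 1e-12)

  # null panel: every individual sits at the prior
  nullp <- null_panel(3)
  study <- study_spec("null", nullp, d = d, n_sim = 500)
  cohort <- simulate_cohort(study, rng_seed = 5)
  expect_equal(cohort$posterior_risk, rep(d, 500), tolerance = 1e-9)

  # law of total probability: mean posterior risk near d for a real panel
  study <- godarts_study(n_sim = 100000L)
  cohort <- simulate_cohort(study, rng_seed = 9)
  mc_se <- sd(cohort$posterior_risk) / sqrt(length(cohort$posterior_risk))
  expect_lt(abs(mean(cohort$posterior_risk) - 0.2), 4 * mc_se + 1e-3)
  expect_true(all(cohort$posterior_risk > 0 & cohort$posterior_risk < 1))
})

test_that("status assignment is Bernoulli in each individual's risk", {
  expect_error(assign_status(c(0.2, 1.2)), "strictly")
  expect_true(all(assign_status(rep(1 - 1e-12, 200), rng_seed = 1) == 1L))
  expect_true(all(assign_status(rep(1e-12, 200), rng_seed = 1) == 0L))
  r <- 0.3; n <- 50000
  st <- assign_status(rep(r, n), rng_seed = 2)
  expect_lt(abs(mean(st) - r), 4 * sqrt(r * (1 - r) / n))
})

test_that("cohort simulation is reproducible and recovers its parameters", {
  study <- godarts_study(n_sim = 20000L)
  c1 <- simulate_cohort(study, rng_seed = 123)
  c2 <- simulate_cohort(study, rng_seed = 123)
  expect_identical(c1$genotypes, c2$genotypes)
  expect_identical(c1$status, c2$status)
  expect_equal(c1$posterior_risk, c2$posterior_risk)
  expect_equal(c1$seed, 123L)

  # prevalence within 4 binomial SEs of d
  expect_lt(abs(mean(c1$status) - 0.2), 4 * sqrt(0.2 * 0.8 / 20000))

  # per-SNP allele frequency within 4 binomial SEs of the input raf;
  # assessed across seeds since a lone 4-SE excursion has probability ~1e-4
  # per SNP-seed pair and 180 pairs are drawn here
  se <- sqrt(study$snps$raf * (1 - study$snps$raf) / (2 * 20000))
  within <- vapply(1:10, function(seed) {
    emp <- colMeans(simulate_cohort(study, rng_seed = seed)$genotypes) / 2
    abs(emp - study$snps$raf) < 4 * se
  }, logical(18))
  expect_gte(mean(within), 0.96)
})

test_that("cohorts export to delimited text in both layouts", {
  study <- study_spec("toy", random_panel(3, 2), d = 0.1, n_sim = 50)
  cohort <- simulate_cohort(study, rng_seed = 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(cohort, path)
  back <- read.delim(path)
  expect_equal(nrow(back), 50)
  expect_equal(back$status, cohort$status)
  expect_equal(back$posterior_risk, cohort$posterior_risk, tolerance = 1e-12)

  write_cohort(cohort, path, panel_major = TRUE)
  tr <- read.delim(path)
  expect_equal(nrow(tr), 3)
  expect_equal(ncol(tr), 51)
})
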