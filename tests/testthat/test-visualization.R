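make_cohort <- function(panel, d = 0.2, n = 8000, seed = 12) {
  simulate_cohort(study_spec("viz", panel, d = d, n_sim = n), rng_seed = seed)
}

test_that("allele-count histogram gives two normalized distributions", {
  cohort <- make_cohort(random_panel(4, 41))
  h <- allele_count_histogram(cohort)
  expect_equal(h$allele_count, 0:8)
  expect_equal(sum(h$prop_patients), 1)
  expect_equal(sum(h$prop_nonpatients), 1)

  # strong panel: patient counts stochastically dominate nonpatient counts
  strong <- snp_panel(paste0("rs", 1:4), raf = rep(0.4, 4),
                      or_allele = rep(2.5, 4))
  hs <- allele_count_histogram(make_cohort(strong))
  expect_true(all(cumsum(hs$prop_patients) <=
                    cumsum(hs$prop_nonpatients) + 1e-9))

  # null panel: the two distributions agree within sampling error
  hn <- allele_count_histogram(make_cohort(null_panel(4), n = 20000))
  expect_lt(max(abs(hn$prop_patients - hn$prop_nonpatients)), 0.03)
})

test_that("ROC polyline area equals the Mann-Whitney AUC", {
  cohort <- make_cohort(random_panel(3, 43))
  score <- bayes_score(cohort)
  roc <- roc_points(score, cohort$status)
  expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
  expect_equal(roc$fpr[1], 0)
  expect_equal(utils::tail(roc$tpr, 1), 1)
  expect_equal(attr(roc, "auc"),
               auc_mann_whitney(score, cohort$status)$auc, tolerance = 1e-12)

  # heavy integer ties, small instances, against brute force
  set.seed(3)
  for (i in 1:10) {
    n <- sample(20:120, 1)
    sc <- sample(0:5, n, replace = TRUE)
    st <- rbinom(n, 1, 0.5)
    if (!sum(st) || !sum(1 - st)) next
    expect_equal(attr(roc_points(sc, st), "auc"), brute_force_auc(sc, st),
                 tolerance = 1e-12)
  }

  # degenerate cases
  expect_equal(attr(roc_points(rep(1, 10), rep(0:1, 5)), "auc"), 0.5)
  perfect <- roc_points(c(1, 1, 9, 9), c(0, 0, 1, 1))
  expect_true(any(perfect$fpr == 0 & perfect$tpr == 1))
})

test_that("quintile odds ratios are computed against the lowest fifth", {
  cohort <- make_cohort(random_panel(6, 47), n = 20000)
  qt <- quintile_or_table(bayes_score(cohort), cohort$status)
  expect_equal(sum(qt$n_cases + qt$n_controls), 20000)
  expect_equal(qt$or_vs_reference[1], 1)
  expect_true(all(is.na(qt$ci_low[1])))
  # internal thresholds give ~20% occupancy per quintile
  occupancy <- (qt$n_cases + qt$n_controls) / 20000
  expect_true(all(abs(occupancy - 0.2) < 0.01))
  # risk-ordered scores: monotone increasing quintile ORs
  expect_true(all(diff(qt$or_vs_reference) > 0))

  # external thresholds are honored
  thr <- quantile(bayes_score(cohort), c(0.1, 0.3, 0.6, 0.9))
  qt2 <- quintile_or_table(bayes_score(cohort), cohort$status,
                           thresholds = unname(thr))
  expect_equal(sum(qt2$n_cases + qt2$n_controls), 20000)
  expect_gt(qt2$n_cases[3] + qt2$n_controls[3],
            qt2$n_cases[1] + qt2$n_controls[1])

  # null cohort by unweighted score: ORs flat around 1 (a wide panel keeps
  # the count percentiles distinct)
  nullc <- make_cohort(null_panel(12), n = 30000)
  qtn <- quintile_or_table(unweighted_score(nullc$genotypes), nullc$status)
  expect_true(all(qtn$or_vs_reference[-1] > 0.85 &
                    qtn$or_vs_reference[-1] < 1.15))
  expect_true(all(qtn$ci_low[-1] < 1 & qtn$ci_high[-1] > 1))

  # tied internal percentiles (few discrete score values) surface as the
  # empty-cell error, never a silent correction
  narrow <- make_cohort(null_panel(6), n = 30000)
  expect_error(
    quintile_or_table(unweighted_score(narrow$genotypes), narrow$status),
    "empty")

  # fewer than 5 distinct scores cannot define internal quintiles
  single <- make_cohort(snp_panel("rs1", 0.5, 1.5), n = 3000)
  expect_error(quintile_or_table(bayes_score(single), single$status),
               "distinct")
})

test_that("risk-versus-allele-count scatter reports squared correlation", {
  single <- make_cohort(snp_panel("rs1", 0.5, 2), n = 3000)
  sc <- risk_vs_allele_scatter(single)
  expect_equal(length(unique(sc$points$allele_count)), 3L)
  agg <- aggregate(posterior_risk ~ allele_count, sc$points, unique)
  expect_true(all(diff(agg$posterior_risk) > 0))

  # equal ORs: risk is a deterministic increasing function of the count,
  # so R^2 reflects only the logistic nonlinearity and sits close to 1
  eq <- make_cohort(snp_panel(paste0("rs", 1:5), raf = rep(0.4, 5),
                              or_allele = rep(1.6, 5)), n = 5000)
  sc_eq <- risk_vs_allele_scatter(eq)
  risk_by_count <- tapply(sc_eq$points$posterior_risk,
                          sc_eq$points$allele_count, function(x)
                            max(x) - min(x))
  expect_true(all(risk_by_count < 1e-12))
  expect_gt(sc_eq$r_squared, 0.9)
  expect_lt(sc_eq$r_squared, 1)

  # null cohort: constant risks, R^2 undefined
  nullc <- make_cohort(null_panel(3), n = 2000)
  expect_error(risk_vs_allele_scatter(nullc), "undefined")
})

test_that("the four-panel cohort plot renders without error", {
  cohort <- make_cohort(random_panel(4, 53), n = 4000)
  tmp <- withr::local_tempfile(fileext = ".png")
  grDevices::png(tmp, width = 900, height = 700)
  expect_silent(plot(cohort))
  grDevices::dev.off()
  expect_true(file.exists(tmp))
})
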