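test_that("median and range follow the midpoint convention", {
  expect_equal(median_range(c(1, 3, 2)), c(median = 2, min = 1, max = 3))
  expect_equal(median_range(c(1, 2, 3, 4))[["median"]], 2.5)
  expect_equal(median_range(c(NA, 5, NA))[["median"]], 5)
  expect_true(all(is.na(median_range(c(NA_real_, NA_real_)))))
})

test_that("rank-sum test matches hand-derived exact cases", {
  # all 20 assignments of {1..6} into 3+3; only U=0 and U=9 are as extreme
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$method, "exact")
  expect_equal(unname(r$statistic), 0)
  expect_equal(r$p, 0.1)
  # identical groups: no evidence at all
  r2 <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r2$p, 1)
  expect_error(mann_whitney(numeric(0), 1:3), "at least one")
})

test_that("exact rank-sum p-values equal exhaustive enumeration", {
  set.seed(41)
  for (na in 2:5) for (nb in 2:5) {
    a <- sample(seq_len(50), na)
    b <- sample(setdiff(seq_len(50), a), nb)
    r <- mann_whitney(a, b)
    expect_equal(r$method, "exact")
    expect_equal(r$p, enumerate_mw_p(a, b), tolerance = 1e-12,
                 info = sprintf("na=%d nb=%d", na, nb))
  }
})

test_that("rank-sum invariances hold: label swap and U_a + U_b = n_a n_b", {
  set.seed(43)
  for (i in 1:10) {
    a <- rnorm(sample(3:12, 1))
    b <- rnorm(sample(3:12, 1))
    ra <- mann_whitney(a, b)
    rb <- mann_whitney(b, a)
    expect_equal(ra$p, rb$p)
    expect_equal(unname(ra$statistic + rb$statistic),
                 length(a) * length(b))
  }
})

test_that("ties push the test to the corrected normal approximation", {
  a <- c(1, 2, 2, 3); b <- c(2, 3, 3, 4)
  r <- mann_whitney(a, b)
  expect_match(r$method, "approximation")
  expect_true(r$p > 0 && r$p <= 1)
})

test_that("2x2 chi-square equals the closed form and handles edge tables", {
  set.seed(47)
  for (i in 1:10) {
    m <- matrix(sample(1:30, 4, replace = TRUE), 2)
    r <- chi_square_2x2(m)
    expect_equal(unname(r$statistic), chisq_closed_form(m))
  }
  # perfectly proportional table: statistic 0, p 1
  r0 <- chi_square_2x2(matrix(c(10, 5, 20, 10), 2))
  expect_equal(unname(r0$statistic), 0)
  expect_equal(r0$p, 1)
  expect_equal(unname(chi_square_2x2(matrix(c(10, 0, 0, 10), 2))$statistic),
               20)
  expect_error(chi_square_2x2(matrix(c(1, 2, 3), 1)), "2x2")
  expect_error(chi_square_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "marginal")
})

test_that("the printed sex distribution is not a group difference", {
  # 14/30 male patients vs 5/10 male controls
  r <- chi_square_2x2(rbind(c(14, 16), c(5, 5)))
  expect_equal(round(r$p, 3), 0.855)
})

test_that("change scores difference follow-up minus initial with propagation", {
  out <- data.frame(
    id = rep(c("P01", "P02"), each = 2),
    group = "patient",
    visit = rep(c("initial", "follow-up"), 2),
    diaphragm_height_ratio = c(1.19, 1.23, 1.10, NA))
  ch <- change_scores(out, "diaphragm_height_ratio")
  expect_equal(ch$diaphragm_height_ratio[ch$id == "P01"], 0.04)
  expect_true(is.na(ch$diaphragm_height_ratio[ch$id == "P02"]))
})

test_that("curvature change classification is sign-based with a stable zero", {
  expect_equal(classify_change(c(0.04, -0.28, 0, NA)),
               c("deterioration", "improvement", "stable", "unclassified"))
})

test_that("treatment subgroups close the 3-year boundary and keep negatives", {
  status <- c("untreated", "treated", "treated", "treated", NA)
  dur <- c(NA, 3.0, 3.1, -0.1, NA)
  g <- ert_group(status, dur)
  expect_equal(as.character(g), c("untreated", "le3y", "gt3y", "le3y", NA))
})

test_that("subgroup machinery partitions patients and matches the overall test", {
  sim <- simulate_cohort(cohort_sim_spec(n_patients = 12, n_controls = 6,
                                         seed = 53))
  outcomes <- analytic_outcomes(sim)
  cohort <- sim$cohort
  # ERT partition sizes sum to the patient count
  sizes <- vapply(ert_subgroups(), function(sp) {
    subgroup_analysis(outcomes, cohort, sp)$n[1]
  }, numeric(1))
  expect_equal(sum(sizes), 12)
  # weakness partition also sums to the patient count
  wsizes <- vapply(weakness_subgroups(1.4), function(sp) {
    subgroup_analysis(outcomes, cohort, sp)$n[1]
  }, numeric(1))
  expect_equal(sum(wsizes), 12)
  # an all-patient subgroup reproduces the overall comparison
  all_spec <- subgroup_spec("all patients", function(df) rep(TRUE, nrow(df)))
  r_all <- subgroup_analysis(outcomes, cohort, all_spec)
  ch <- change_scores(outcomes)
  r_direct <- mann_whitney(ch$diaphragm_height_ratio[ch$group == "patient"],
                           ch$diaphragm_height_ratio[ch$group == "control"])
  expect_equal(r_all$p, r_direct$p)
  expect_equal(unname(r_all$statistic), unname(r_direct$statistic))
  expect_error(subgroup_analysis(outcomes, cohort,
                                 subgroup_spec("none", function(df)
                                   rep(FALSE, nrow(df)))),
               "empty subgroup")
})

test_that("cohort reports carry medians, significance marks and classification", {
  sim <- simulate_cohort(cohort_sim_spec(n_patients = 10, n_controls = 5,
                                         seed = 59))
  outcomes <- roundtrip_outcomes_csv(sim)
  rep <- reproduce_tables(outcomes, sim$cohort)
  expect_s3_class(rep, "cohort_report")
  expect_equal(rep$missing_variables, character(0))
  expect_equal(nrow(rep$mri), 8)
  # report medians equal directly computed group medians
  ini <- outcomes[outcomes$visit == "initial", ]
  for (v in outcome_names()) {
    expect_equal(rep$mri$patients_initial_median[rep$mri$variable == v],
                 median(ini[[v]][ini$group == "patient"]))
    expect_equal(rep$mri$controls_initial_median[rep$mri$variable == v],
                 median(ini[[v]][ini$group == "control"]))
  }
  # significance asterisks appear exactly when p <= 0.05
  expect_equal(rep$mri$sig_change, ifelse(rep$mri$p_change <= 0.05, "*", ""))
  # classification covers every patient with consistent labels
  expect_equal(nrow(rep$classification), 10)
  expect_setequal(unique(rep$classification$weakness[
    rep$classification$cc_initial < 1.4]), "moderate-severe")
  expect_equal(rep$classification$change_class,
               classify_change(rep$classification$height_ratio_change))
  # excluding a subject reruns the analysis on n - 1
  worst <- rep$classification$id[
    which.max(rep$classification$height_ratio_change)]
  rep2 <- reproduce_tables(outcomes, sim$cohort, exclude_ids = worst)
  expect_equal(nrow(rep2$classification), 9)
  ch2 <- change_scores(outcomes[outcomes$id != worst, ])
  expect_equal(
    rep2$mri$patients_change_median[
      rep2$mri$variable == "diaphragm_height_ratio"],
    median(ch2$diaphragm_height_ratio[ch2$group == "patient"]))
})
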