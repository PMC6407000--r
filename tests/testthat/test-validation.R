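# Reference oracles (ref_loocv, ref_breslow, ref_foldid) live in
# helper-oracles.R.

test_that("the LOOCV engine reproduces an independent reference loop exactly", {
  d <- small_cohort(25, n_targets = 6, prognostic = 4L, beta = -0.8, seed = 15L)
  expr <- cohort_expr(d)
  mc <- list(folds = 3L, nlambda = 12L, lambda_min_ratio = 0.05,
             max_selected = 3L)
  got <- loocv_prognostic_indices(expr, d$clinical, "dfs",
                                  model_config = mc, seed = 71L)
  want <- ref_loocv(expr, d$clinical, folds = 3L, nlambda = 12L, lmr = 0.05,
                    max_sel = 3L, seed = 71L)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("the median split sends ties and the extra patient to the low group", {
  cl <- data.frame(patient_id = sprintf("P%d", 1:7), stage = "I",
                   dfs_time = c(2, 4, 6, 8, 10, 12, 14),
                   dfs_event = c(1, 1, 1, 1, 0, 0, 0))
  pi_ <- setNames(c(1, 2, 3, 4, 5, 6, 7), cl$patient_id)
  res <- cv_km_and_logrank(pi_, cl, "dfs")
  expect_equal(as.vector(table(res$risk_group)), c(4, 3))  # low gets the extra
  pi_tie <- setNames(c(1, 1, 2, 2, 2, 3, 3), cl$patient_id)
  res2 <- cv_km_and_logrank(pi_tie, cl, "dfs")
  expect_equal(sum(res2$risk_group == "low"), 5L)  # exact-median ties -> low
  expect_error(cv_km_and_logrank(setNames(rep(1, 7), cl$patient_id), cl, "dfs"),
               "degenerate")
})

test_that("the cross-validated log-rank statistic matches a hand computation", {
  # 8 patients, no censoring, indices perfectly ordered with event times
  cl <- data.frame(patient_id = sprintf("P%d", 1:8), stage = "I",
                   dfs_time = 1:8, dfs_event = TRUE)
  pi_ <- setNames(-(1:8), cl$patient_id)  # earliest events = highest risk
  res <- cv_km_and_logrank(pi_, cl, "dfs")
  # hand log-rank: high group = patients 1-4 (die first)
  grp_high <- c(1, 1, 1, 1, 0, 0, 0, 0)
  o <- sum(grp_high)                      # all high-risk deaths observed
  e <- v <- 0
  at_risk <- rep(TRUE, 8)
  for (t in 1:8) {
    n <- sum(at_risk); n1 <- sum(at_risk & grp_high == 1)
    e <- e + n1 / n
    v <- v + n1 / n * (1 - n1 / n)
    at_risk[t] <- FALSE
  }
  expect_equal(res$logrank_chisq, (o - e)^2 / v, tolerance = 1e-10)
})

test_that("the IPCW AUC reduces to the rank-sum AUC without censoring", {
  set.seed(61)
  n <- 30
  cl <- data.frame(patient_id = sprintf("P%d", 1:n), stage = "I",
                   dfs_time = sample(seq(2, 60, 2), n), dfs_event = TRUE)
  pi_ <- setNames(rnorm(n), cl$patient_id)
  t_star <- 30
  res <- cv_time_dependent_roc(pi_, cl, "dfs", t_star = t_star)
  case <- cl$dfs_time <= t_star
  w <- outer(pi_[case], pi_[!case], ">") + 0.5 * outer(pi_[case], pi_[!case], "==")
  expect_equal(res$auc, mean(w), tolerance = 1e-10)
})

test_that("degenerate and perfect classifiers hit the AUC boundary values", {
  n <- 20
  cl <- data.frame(patient_id = sprintf("P%d", 1:n), stage = "I",
                   dfs_time = seq_len(n), dfs_event = TRUE)
  const <- setNames(rep(1, n), cl$patient_id)
  expect_equal(cv_time_dependent_roc(const, cl, "dfs", t_star = 10)$auc, 0.5)
  perfect <- setNames(-seq_len(n), cl$patient_id)
  expect_equal(cv_time_dependent_roc(perfect, cl, "dfs", t_star = 10)$auc, 1.0)
})

test_that("AUC obeys label-flip symmetry at any landmark", {
  set.seed(77)
  n <- 40
  cl <- data.frame(patient_id = sprintf("P%d", 1:n), stage = "I",
                   dfs_time = rexp(n, 1 / 30),
                   dfs_event = runif(n) < 0.7)
  cl$dfs_time <- pmax(cl$dfs_time, 0.5)
  pi_ <- setNames(rnorm(n), cl$patient_id)
  for (ts in c(15, 25)) {
    a <- cv_time_dependent_roc(pi_, cl, "dfs", t_star = ts)$auc
    b <- cv_time_dependent_roc(-pi_, cl, "dfs", t_star = ts)$auc
    expect_equal(a + b, 1, tolerance = 1e-10)
  }
})

test_that("landmarks outside follow-up or without cases are rejected", {
  cl <- data.frame(patient_id = sprintf("P%d", 1:6), stage = "I",
                   dfs_time = c(10, 20, 30, 40, 50, 60),
                   dfs_event = c(0, 0, 0, 1, 1, 1))
  pi_ <- setNames(1:6, cl$patient_id)
  expect_error(cv_time_dependent_roc(pi_, cl, "dfs", t_star = 100), "follow-up")
  expect_error(cv_time_dependent_roc(pi_, cl, "dfs", t_star = 5), "events")
})

test_that("permutation p-values follow the +1 convention at tiny B", {
  d <- small_cohort(22, n_targets = 4, prognostic = 3L, beta = -1.5, seed = 19L)
  expr <- cohort_expr(d)
  res <- suppressWarnings(
    permutation_test_logrank(expr, d$clinical, "dfs", B = 1L, seed = 5L,
                             model_config = fast_mc, t_star = 24))
  expect_true(res$p %in% c(0.5, 1))
  expect_gte(res$p, 1 / (res$B_effective + 1))
})

test_that("identical outcomes make the risk-group statistic undefined", {
  cl <- data.frame(patient_id = sprintf("P%d", 1:6), stage = "I",
                   dfs_time = rep(5, 6), dfs_event = TRUE)
  pi_ <- setNames(1:6, cl$patient_id)
  expect_error(cv_km_and_logrank(pi_, cl, "dfs"), "undefined|degenerate")
})

test_that("duplicated cohorts give held-out indices close to the full-data fit", {
  d <- small_cohort(14, n_targets = 5, prognostic = 3L, beta = -1.2, seed = 23L)
  expr <- cohort_expr(d)
  cl2 <- d$clinical[rep(1:14, 2), ]
  cl2$patient_id <- sprintf("D%02d", 1:28)
  expr2 <- expr[rep(1:14, 2), ]
  rownames(expr2) <- cl2$patient_id
  cv_pi <- suppressWarnings(
    loocv_prognostic_indices(expr2, cl2, "dfs", model_config = fast_mc,
                             seed = 3L))
  full <- fit_elastic_net_cox(expr2, cl2, "dfs", folds = fast_mc$folds,
                              nlambda = fast_mc$nlambda,
                              lambda_min_ratio = fast_mc$lambda_min_ratio,
                              max_selected = fast_mc$max_selected, seed = 3L)
  pi_full <- prognostic_index(full, expr2, cl2)
  keep <- !is.na(cv_pi)
  expect_gte(cor(cv_pi[keep], pi_full[keep], method = "spearman"), 0.8)
})

test_that("a null cohort shows no discrimination", {
  d <- small_cohort(40, n_targets = 5, seed = 29L)
  expr <- cohort_expr(d)
  cv_pi <- suppressWarnings(
    loocv_prognostic_indices(expr, d$clinical, "dfs", model_config = fast_mc,
                             seed = 13L))
  roc <- cv_time_dependent_roc(cv_pi, d$clinical, "dfs", t_star = 24)
  expect_gt(roc$auc, 0.25)
  expect_lt(roc$auc, 0.75)
})
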