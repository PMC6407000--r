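test_that("at the top of the path only the unpenalized clinical terms are fitted", {
  d <- small_cohort(100, n_targets = 8, seed = 4L)
  expr <- cohort_expr(d)
  fit <- fit_elastic_net_cox(expr, d$clinical, "dfs", lambda = "max")
  expect_length(fit$selected_mirnas, 0L)
  cl <- d$clinical
  ref <- survival::coxph(
    survival::Surv(dfs_time, dfs_event) ~ (stage == "II") + (stage == "IIIA"),
    data = cl, ties = "breslow")
  expect_lt(max(abs(fit$beta[c("stageII", "stageIIIA")] - coef(ref))), 1e-3)
})

test_that("with a vanishing penalty the fit matches unpenalized multivariable Cox", {
  d <- small_cohort(40, n_targets = 7, seed = 6L)
  expr <- cohort_expr(d)   # 5 miRNAs after removing the 2 references
  fit <- fit_elastic_net_cox(expr, d$clinical, "dfs", lambda = 1e-7,
                             clinical_covariates = character(0))
  df <- data.frame(expr, check.names = FALSE)
  df$time <- d$clinical$dfs_time; df$event <- d$clinical$dfs_event
  ref <- survival::coxph(survival::Surv(time, event) ~ ., data = df,
                         ties = "breslow")
  expect_equal(unname(fit$beta[colnames(expr)]), unname(coef(ref)),
               tolerance = 1e-3)
})

test_that("the selection cap is respected and clinical terms never count", {
  d <- simulate_cohort(simulation_config(
    n_patients = 120L, n_targets = 20L, n_housekeeping = 2L,
    prognostic_set = c(3L, 4L, 5L, 6L, 7L, 8L, 9L, 10L),
    beta_mirna = rep(c(-0.8, 0.8), 4), stable_set = c(1L, 2L),
    sparse_set = integer(0), detection_limit_ct = 60, seed = 31L))
  expr <- cohort_expr(d)
  fit <- fit_elastic_net_cox(expr, d$clinical, "dfs", max_selected = 5L,
                             folds = 5L, seed = 9L)
  expect_lte(length(fit$selected_mirnas), 5L)
  expect_true(all(c("stageII", "stageIIIA") %in% names(fit$beta)))
  expect_true(all(fit$penalty_factor[fit$clinical_terms] == 0))
  expect_true(all(fit$cv$nonzero[fit$cv$admissible] <= 5L))
})

test_that("coefficients are reported on the -dCt scale", {
  d <- small_cohort(60, n_targets = 8, prognostic = 5L, beta = -1,
                    seed = 12L)
  expr <- cohort_expr(d)
  fit <- fit_elastic_net_cox(expr, d$clinical, "dfs", lambda = 1e-7,
                             clinical_covariates = character(0))
  # rescaling the input rescales the reported coefficient inversely
  expr2 <- expr; expr2[, 1] <- expr2[, 1] * 4
  fit2 <- fit_elastic_net_cox(expr2, d$clinical, "dfs", lambda = 1e-7,
                              clinical_covariates = character(0))
  expect_equal(fit2$beta[1] * 4, fit$beta[1], tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("lambda selection is invariant to patient ordering given the folds", {
  d <- small_cohort(50, n_targets = 6, prognostic = 3L, beta = -0.8,
                    seed = 8L)
  expr <- cohort_expr(d)
  foldid <- rep_len(1:4, 50)
  fit1 <- fit_elastic_net_cox(expr, d$clinical, "dfs", folds = 4L,
                              foldid = foldid, nlambda = 20L)
  set.seed(99); perm <- sample(50)
  fit2 <- fit_elastic_net_cox(expr[perm, , drop = FALSE], d$clinical, "dfs",
                              folds = 4L, foldid = foldid[perm], nlambda = 20L)
  expect_equal(fit1$lambda_selected, fit2$lambda_selected, tolerance = 1e-10)
  expect_equal(fit1$beta, fit2$beta, tolerance = 1e-6)
})

test_that("pure-noise miRNAs rarely enter the CV-selected model", {
  picked <- character(0)
  for (seed in 1:6) {
    d <- small_cohort(60, n_targets = 12, seed = seed)
    expr <- cohort_expr(d)
    fit <- fit_elastic_net_cox(expr, d$clinical, "dfs", folds = 5L,
                               seed = seed, nlambda = 30L)
    picked <- c(picked, fit$selected_mirnas)
  }
  if (length(picked)) expect_lt(max(table(picked)) / 6, 0.5)
  else succeed("no noise miRNA ever selected")
})

test_that("prognostic indices are linear predictors with exact arithmetic", {
  stage_fit <- structure(list(
    endpoint = "dfs", alpha = 0.5, max_selected = 5L, folds = 10L, seed = 1L,
    clinical_covariates = "stage", clinical_terms = c("stageII", "stageIIIA"),
    mirna_ids = character(0), patient_ids = "P1",
    beta = c(stageII = 0.60, stageIIIA = 1.23),
    selected_mirnas = character(0),
    penalty_factor = c(stageII = 0, stageIIIA = 0),
    lambda_path = numeric(0), lambda_selected = NA_real_, cv = NULL,
    center = numeric(0), scale = numeric(0)), class = "pen_cox_fit")
  cl <- data.frame(patient_id = c("A", "B", "C"),
                   stage = c("II", "I", "IIIA"))
  pi_ <- prognostic_index(stage_fit, matrix(numeric(0), 3, 0,
                                            dimnames = list(c("A", "B", "C"), NULL)),
                          cl)
  expect_equal(unname(pi_), c(0.60, 0, 1.23))
})

test_that("prognostic indices are affine-equivariant in the miRNAs", {
  d <- small_cohort(50, n_targets = 6, prognostic = 3L, beta = -0.9, seed = 3L)
  expr <- cohort_expr(d)
  fit <- fit_elastic_net_cox(expr, d$clinical, "dfs", lambda = 1e-6,
                             folds = 4L)
  pi0 <- prognostic_index(fit, expr, d$clinical)
  g <- fit$mirna_ids[2]
  expr_c <- expr; expr_c[, g] <- expr_c[, g] + 1.5
  pi1 <- prognostic_index(fit, expr_c, d$clinical)
  expect_equal(unname(pi1 - pi0), rep(1.5 * fit$beta[[g]], 50),
               tolerance = 1e-10)
})

test_that("an everything-penalized, fully shrunk model yields a constant PI that downstream refuses", {
  d <- small_cohort(30, n_targets = 5, seed = 7L)
  expr <- cohort_expr(d)
  fit <- fit_elastic_net_cox(expr, d$clinical, "dfs", lambda = "max",
                             clinical_covariates = character(0))
  pi_ <- prognostic_index(fit, expr, d$clinical)
  expect_equal(unname(pi_), rep(0, 30))
  expect_error(cv_km_and_logrank(pi_, d$clinical, "dfs"), "degenerate")
})

test_that("error paths: too few events, missing values, feature mismatch", {
  d <- small_cohort(25, n_targets = 5, seed = 5L, censor_max = 60)
  expr <- cohort_expr(d)
  expect_error(fit_elastic_net_cox(expr, d$clinical, "dfs", folds = 30L),
               "fewer events")
  expr_na <- expr; expr_na[1, 1] <- NA
  expect_error(fit_elastic_net_cox(expr_na, d$clinical, "dfs"), "impute")
  fit <- fit_elastic_net_cox(expr, d$clinical, "dfs", folds = 3L)
  expect_error(prognostic_index(fit, expr[, -1, drop = FALSE], d$clinical),
               "lacks")
})
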