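clin_stub <- function(n, events, times = NULL) {
  data.frame(patient_id = sprintf("P%02d", seq_len(n)), histotype = "SCC",
             stage = "I", age_at_surgery = 65, gender = "male",
             smoking = "current", chemo = FALSE, radio = FALSE,
             dfs_time = times %||% seq_len(n), dfs_event = events,
             os_time = times %||% seq_len(n), os_event = events)
}

test_that("sparse-gene exclusion uses a strict >50% rule", {
  ct <- matrix(rnorm(36, 28), 12, 3,
               dimnames = list(sprintf("P%02d", 1:12), c("half", "seven", "full")))
  ct[1:6, "half"] <- NA    # exactly 50%: retained
  ct[1:7, "seven"] <- NA   # 58%: excluded
  res <- exclude_sparse(make_plate(ct))
  expect_setequal(res$plate$target_ids, c("half", "full"))
  expect_equal(res$report$excluded[match(c("half", "seven", "full"),
                                         res$report$gene)],
               c(FALSE, TRUE, FALSE))
})

test_that("the generator's planted sparse targets are exactly the excluded set", {
  d <- simulate_cohort(simulation_config(seed = 21L))
  res <- exclude_sparse(spikein_center(d$plate))
  expect_setequal(res$report$gene[res$report$excluded], d$truth$sparse_ids)
  expect_length(d$truth$sparse_ids, 14L)
})

test_that("differential missingness picks Fisher/chi-square appropriately", {
  n <- 20
  ev <- rep(c(TRUE, FALSE), each = 10)
  ct <- matrix(rnorm(n * 2, 28), n, 2,
               dimnames = list(sprintf("P%02d", 1:n), c("sep", "bal")))
  ct[1:10, "sep"] <- NA                     # undetermined iff event
  ct[c(1:5, 11:15), "bal"] <- NA            # perfectly balanced
  rep_ <- test_differential_missingness(make_plate(ct), clin_stub(n, ev), "dfs")
  sep <- rep_[rep_$gene == "sep", ]
  expect_equal(sep$test, "fisher")
  expect_equal(sep$p_value, 2 / choose(20, 10), tolerance = 1e-10)
  expect_equal(rep_[rep_$gene == "bal", "p_value"], 1, tolerance = 1e-10)
})

test_that("degenerate margins are reported as not applicable", {
  n <- 10
  ct <- matrix(rnorm(n * 2, 28), n, 2,
               dimnames = list(sprintf("P%02d", 1:n), c("g1", "g2")))
  ct[1:4, "g1"] <- NA
  rep_all_events <- test_differential_missingness(
    make_plate(ct), clin_stub(n, rep(TRUE, n)), "dfs")
  expect_true(all(rep_all_events$test == "not applicable"))
  # a gene never undetermined is degenerate too
  rep2 <- test_differential_missingness(
    make_plate(ct), clin_stub(n, rep(c(TRUE, FALSE), 5)), "dfs")
  expect_equal(rep2[rep2$gene == "g2", "test"], "not applicable")
})

test_that("KNN imputation matches an exhaustive hand enumeration", {
  set.seed(31)
  ct <- matrix(round(rnorm(6 * 5, 28, 2), 2), 6, 5)
  ct[1, 2] <- NA; ct[4, 5] <- NA; ct[6, 2] <- NA
  p <- make_plate(ct)
  out <- knn_impute(p, k = 2L)
  # independent enumeration of pairwise RMS distances over shared genes
  dist_jj <- function(i, j) {
    sh <- !is.na(ct[i, ]) & !is.na(ct[j, ])
    sqrt(mean((ct[i, sh] - ct[j, sh])^2))
  }
  for (cell in list(c(1, 2), c(4, 5), c(6, 2))) {
    j <- cell[1]; g <- cell[2]
    donors <- setdiff(which(!is.na(ct[, g])), j)
    dd <- sapply(donors, dist_jj, i = j)
    nearest <- donors[order(dd, donors)][1:2]
    expect_equal(out$ct[j, g], mean(ct[nearest, g]), tolerance = 1e-10)
  }
  # observed wells untouched; no mask remains; idempotent
  expect_equal(out$ct[!is.na(ct)], ct[!is.na(ct)], ignore_attr = TRUE)
  expect_false(any(out$undetermined))
  expect_identical(knn_impute(out, k = 2L)$ct, out$ct)
})

test_that("KNN limiting cases: exact copy with k = 1, gene mean with k = all", {
  ct <- rbind(c(25, 30, 28), c(25, 30, NA), c(27, 33, 26), c(20, 21, 24))
  colnames(ct) <- c("a", "b", "c")
  p <- make_plate(ct)
  one <- knn_impute(p, k = 1L)
  expect_equal(one$ct[2, "c"], 28)  # patient 1 is an exact copy on shared genes
  all_k <- knn_impute(p, k = 3L)
  expect_equal(all_k$ct[2, "c"], mean(ct[-2, "c"]))
})

test_that("imputed values stay within the observed range per gene", {
  d <- simulate_cohort(simulation_config(seed = 13L))
  pl <- exclude_sparse(spikein_center(d$plate))$plate
  out <- knn_impute(pl, k = 5L)
  cells <- attr(out, "imputed")
  for (r in seq_len(nrow(cells))) {
    g <- cells[r, 2]
    obs <- pl$ct[!pl$undetermined[, g], g]
    expect_gte(out$ct[cells[r, 1], g], min(obs))
    expect_lte(out$ct[cells[r, 1], g], max(obs))
  }
})

test_that("KNN refuses genes observed in fewer than k patients", {
  ct <- rbind(c(25, NA), c(26, NA), c(27, 31), c(24, NA))
  colnames(ct) <- c("a", "rare")
  expect_error(knn_impute(make_plate(ct), k = 2L), "rare")
})

test_that("complete-case and imputed univariate Cox agree under MCAR", {
  cfg <- simulation_config(
    n_patients = 500L, n_targets = 8L, n_housekeeping = 2L,
    prognostic_set = 4L, beta_mirna = -0.5, beta_stage = c(0, 0),
    stable_set = c(1L, 2L), sparse_set = integer(0),
    detection_limit_ct = 60, mcar_prob = 0.1, seed = 17L)
  d <- simulate_cohort(cfg)
  centred <- spikein_center(d$plate)
  imputed <- knn_impute(centred, k = 5L)
  g <- "miR-004"
  cc <- !centred$undetermined[, g]
  cl <- d$clinical
  b_cc <- fit_univariate_cox(cl$dfs_time[cc], cl$dfs_event[cc],
                             -centred$ct[cc, g])$beta
  b_imp <- fit_univariate_cox(cl$dfs_time, cl$dfs_event, -imputed$ct[, g])$beta
  expect_lt(abs(b_cc - b_imp), 0.1)
})
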