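# Small in-code fixtures shared across test files.

# Quick plate from a patients x genes matrix; NA cells become undetermined.
make_plate <- function(ct, spike = NULL, hk = character(0)) {
  ct <- as.matrix(ct)
  if (is.null(rownames(ct))) rownames(ct) <- sprintf("P%02d", seq_len(nrow(ct)))
  if (is.null(colnames(ct))) colnames(ct) <- sprintf("g%02d", seq_len(ncol(ct)))
  spike <- spike %||% rep(20, nrow(ct))
  ct_plate(ct, is.na(ct), rownames(ct), setdiff(colnames(ct), hk), hk, spike)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Compact cohort for the resampling engines: few targets, no undetermined
# wells, two designated stable genes, configurable signal.
small_cohort <- function(n, n_targets = 5L, prognostic = integer(0),
                         beta = numeric(0), beta_stage = c(0, 0), seed = 1L,
                         censor_max = 160) {
  simulate_cohort(simulation_config(
    n_patients = n, n_targets = n_targets, n_housekeeping = 2L,
    prognostic_set = prognostic, beta_mirna = beta, beta_stage = beta_stage,
    sparse_set = integer(0), stable_set = c(1L, 2L),
    detection_limit_ct = 60, censor_uniform_max = censor_max,
    seed = seed))
}

# Normalized expression straight from a cohort without undetermined wells.
cohort_expr <- function(cohort) {
  centred <- spikein_center(cohort$plate)
  stab <- rank_stability(centred)
  delta_ct(centred, stab)
}

# Settings that keep the cross-validated engines quick in tests.
fast_mc <- list(folds = 3L, nlambda = 10L, lambda_min_ratio = 0.05,
                max_selected = 2L)
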