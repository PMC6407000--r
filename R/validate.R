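default_model_config <- function(model_config = list()) {
  utils::modifyList(
    list(alpha = 0.5, max_selected = 5L, folds = 10L,
         clinical_covariates = "stage",
         nlambda = 100L, lambda_min_ratio = 0.01),
    model_config)
}

#' Leave-one-out cross-validated prognostic indices
#'
#' For each patient the entire modelling procedure of
#' [fit_elastic_net_cox()] — including internal standardization and k-fold
#' lambda selection, re-seeded deterministically from `(seed, i)` — is refit
#' on the remaining patients, and the held-out patient's linear predictor is
#' computed from that fit. No information from the held-out patient enters
#' the model that scores them. A degenerate inner fit yields `NA` with a
#' warning; such patients are excluded downstream.
#'
#' @param expr Patients x miRNAs matrix (may have zero columns for a
#'   covariate-only model).
#' @param clinical Clinical table.
#' @param endpoint `"dfs"` or `"os"`.
#' @param model_config Named list overriding the modelling defaults
#'   (`alpha = 0.5`, `max_selected = 5`, `folds = 10`,
#'   `clinical_covariates = "stage"`, `nlambda = 100`,
#'   `lambda_min_ratio = 0.01`).
#' @param seed Master seed; fold seeds derive from `(seed, "loocv", i)`.
#' @return Named numeric vector of cross-validated prognostic indices.
#' @export
loocv_prognostic_indices <- function(expr, clinical, endpoint = c("dfs", "os"),
                                     model_config = list(), seed = 1L) {
  endpoint <- match.arg(endpoint)
  mc <- default_model_config(model_config)
  expr <- as.matrix(expr)
  ids <- rownames(expr) %||% clinical$patient_id
  n <- length(ids)
  if (n < 20L) warning("n < 20: leave-one-out estimates will be unstable")
  cv_pi <- stats::setNames(rep(NA_real_, n), ids)
  for (i in seq_len(n)) {
    train <- ids[-i]
    fit_i <- tryCatch(
      fit_elastic_net_cox(expr[train, , drop = FALSE],
                          clinical[clinical$patient_id %in% train, ,
                                   drop = FALSE],
                          endpoint = endpoint,
                          alpha = mc$alpha, max_selected = mc$max_selected,
                          folds = mc$folds,
                          seed = derive_seed(seed, "loocv", i),
                          clinical_covariates = mc$clinical_covariates,
                          nlambda = mc$nlambda,
                          lambda_min_ratio = mc$lambda_min_ratio),
      error = function(e) e)
    if (inherits(fit_i, "error")) {
      warning("inner fit failed for patient ", ids[i], ": ",
              conditionMessage(fit_i))
      next
    }
    cv_pi[i] <- prognostic_index(
      fit_i, expr[ids[i], , drop = FALSE],
      clinical[clinical$patient_id == ids[i], , drop = FALSE])
  }
  cv_pi
}

#' Median split of cross-validated indices with Kaplan-Meier comparison
#'
#' Splits patients at the median cross-validated prognostic index (patients
#' exactly at the median go to the low-risk group, so for odd n the low
#' group gets the extra patient), draws the per-group Kaplan-Meier curves
#' and returns the log-rank chi-square.
#'
#' @param cv_pi Output of [loocv_prognostic_indices()]; `NA` entries are
#'   dropped.
#' @param clinical Clinical table.
#' @param endpoint `"dfs"` or `"os"`.
#' @return A list: `risk_group` (factor low/high), `km` (see
#'   [km_summary()]), `logrank_chisq`, `logrank_p`.
#' @export
cv_km_and_logrank <- function(cv_pi, clinical, endpoint = c("dfs", "os")) {
  endpoint <- match.arg(endpoint)
  cv_pi <- cv_pi[!is.na(cv_pi)]
  if (length(unique(cv_pi)) < 2L)
    stop("all cross-validated indices identical: degenerate risk classifier")
  ids <- names(cv_pi)
  grp <- factor(ifelse(cv_pi > stats::median(cv_pi), "high", "low"),
                levels = c("low", "high"))
  names(grp) <- ids
  if (any(table(grp) == 0L))
    stop("median split produced an empty risk group")
  km <- km_summary(clinical_times(clinical, endpoint, ids),
                   clinical_events(clinical, endpoint, ids), grp)
  if (!is.finite(km$logrank_chisq))
    stop("log-rank statistic undefined (degenerate outcome configuration)")
  list(risk_group = grp, km = km,
       logrank_chisq = km$logrank_chisq, logrank_p = km$logrank_p)
}

# Kaplan-Meier estimate of the censoring distribution G(t) = P(C > t),
# evaluated at t (right-continuous) or just before t (`left = TRUE`).
censor_survival <- function(time, event) {
  sf <- survival::survfit(survival::Surv(time, !as.logical(event)) ~ 1)
  list(time = sf$time, surv = sf$surv)
}

censor_eval <- function(G, t, left = FALSE) {
  vapply(t, function(ti) {
    idx <- if (left) which(G$time < ti) else which(G$time <= ti)
    if (!length(idx)) 1 else G$surv[max(idx)]
  }, numeric(1))
}

# Cumulative-case / dynamic-control IPCW ROC at landmark t_star.
ipcw_roc <- function(pi, time, event, t_star) {
  event <- as.logical(event)
  case <- time <= t_star & event
  ctrl <- time > t_star
  if (!any(case)) stop("no events by the landmark time")
  if (!any(ctrl)) stop("no patients at risk beyond the landmark time")
  G <- censor_survival(time, event)
  w_case <- 1 / censor_eval(G, time[case], left = TRUE)
  w_ctrl <- rep(1 / censor_eval(G, t_star), sum(ctrl))
  if (any(!is.finite(w_case)) || any(!is.finite(w_ctrl)))
    stop("censoring weights undefined at the landmark time")
  pc <- pi[case]; pk <- pi[ctrl]
  # weighted probabilistic index; ties count one half
  gt <- outer(pc, pk, ">") + 0.5 * outer(pc, pk, "==")
  wmat <- outer(w_case, w_ctrl)
  auc <- sum(gt * wmat) / sum(wmat)
  thr <- c(Inf, sort(unique(pi), decreasing = TRUE))
  curve <- data.frame(
    threshold = thr,
    tpr = vapply(thr, function(c) sum(w_case[pc >= c]) / sum(w_case), 0),
    fpr = vapply(thr, function(c) sum(w_ctrl[pk >= c]) / sum(w_ctrl), 0))
  list(auc = auc, curve = curve,
       n_cases = sum(case), n_controls = sum(ctrl))
}

#' Cross-validated time-dependent ROC curve and AUC
#'
#' Cumulative-case / dynamic-control ROC of the cross-validated prognostic
#' indices at a landmark time: patients with an event by `t_star` are cases,
#' patients still event-free past `t_star` are controls, and both are
#' weighted by the inverse of the Kaplan-Meier estimate of the censoring
#' distribution. The AUC is the weighted probabilistic index (ties counted
#' one half), identical to the trapezoidal area under the weighted curve.
#' With `B > 0` a standalone permutation p-value for AUC = 0.5 is computed
#' by shuffling the (time, event) pairs against the indices and recomputing
#' the AUC (two-sided, on |AUC - 0.5|).
#'
#' @param cv_pi Cross-validated prognostic indices (`NA` dropped).
#' @param clinical Clinical table.
#' @param endpoint `"dfs"` or `"os"`.
#' @param t_star Landmark time in months (default 24: two-year relapse).
#' @param B Number of permutations for the standalone test (0 = none).
#' @param seed Seed for the permutations.
#' @return A list: `auc`, `curve` (threshold/tpr/fpr), `t_star`, `n_cases`,
#'   `n_controls`, and when `B > 0` also `p_auc` and `B`.
#' @export
cv_time_dependent_roc <- function(cv_pi, clinical, endpoint = c("dfs", "os"),
                                  t_star = 24, B = 0L, seed = 1L) {
  endpoint <- match.arg(endpoint)
  cv_pi <- cv_pi[!is.na(cv_pi)]
  ids <- names(cv_pi)
  tt <- clinical_times(clinical, endpoint, ids)
  ev <- clinical_events(clinical, endpoint, ids)
  if (t_star <= 0 || t_star >= max(tt))
    stop("t_star must lie within the observed follow-up")
  roc <- ipcw_roc(cv_pi, tt, ev, t_star)
  out <- c(roc, list(t_star = t_star))
  if (B > 0) {
    obs <- abs(roc$auc - 0.5)
    perm <- vapply(seq_len(B), function(b) {
      idx <- with_seed(derive_seed(seed, "auc_perm", b),
                       sample(length(cv_pi)))
      tryCatch(abs(ipcw_roc(cv_pi, tt[idx], ev[idx], t_star)$auc - 0.5),
               error = function(e) NA_real_)
    }, numeric(1))
    perm <- perm[!is.na(perm)]
    out$p_auc <- (1 + sum(perm >= obs - 1e-12)) / (length(perm) + 1)
    out$B <- B
  }
  out
}

# Shared engine: observed cross-validated statistics and their permutation
# distribution. scheme "outcomes" shuffles the (time, event) pairs against
# the joint covariate rows; "outcomes_and_stage" also moves stage with the
# outcomes; "mirna" shuffles only the miRNA rows (added-value null).
cv_perm_engine <- function(expr, clinical, endpoint, B, seed, model_config,
                           t_star, scheme = c("outcomes",
                                              "outcomes_and_stage", "mirna")) {
  scheme <- match.arg(scheme)
  expr <- as.matrix(expr)
  ids <- rownames(expr) %||% clinical$patient_id
  cl <- clinical[match(ids, clinical$patient_id), , drop = FALSE]

  one_run <- function(expr_r, cl_r, run_seed) {
    pi_cv <- suppressWarnings(
      loocv_prognostic_indices(expr_r, cl_r, endpoint,
                               model_config = model_config, seed = run_seed))
    kmr <- cv_km_and_logrank(pi_cv, cl_r, endpoint)
    roc <- cv_time_dependent_roc(pi_cv, cl_r, endpoint, t_star = t_star)
    list(cv_pi = pi_cv, km = kmr, roc = roc,
         logrank = kmr$logrank_chisq, auc = roc$auc)
  }
  observed <- one_run(expr, cl, derive_seed(seed, "observed"))

  stat_lr <- rep(NA_real_, B)
  stat_auc <- rep(NA_real_, B)
  n <- length(ids)
  tcol <- paste0(endpoint, "_time"); ecol <- paste0(endpoint, "_event")
  for (b in seq_len(B)) {
    idx <- with_seed(derive_seed(seed, "shuffle", b), sample(n))
    expr_b <- expr; cl_b <- cl
    if (scheme == "mirna") {
      expr_b <- expr[idx, , drop = FALSE]
      rownames(expr_b) <- ids
    } else {
      cl_b[[tcol]] <- cl[[tcol]][idx]
      cl_b[[ecol]] <- cl[[ecol]][idx]
      if (scheme == "outcomes_and_stage") cl_b$stage <- cl$stage[idx]
    }
    res <- tryCatch(one_run(expr_b, cl_b, derive_seed(seed, "perm", b)),
                    error = function(e) NULL)
    if (!is.null(res)) {
      stat_lr[b] <- res$logrank
      stat_auc[b] <- res$auc
    }
  }
  ok <- !is.na(stat_lr)
  list(observed = observed,
       perm_logrank = stat_lr[ok], perm_auc = stat_auc[ok],
       B = B, B_effective = sum(ok), scheme = scheme)
}

perm_p <- function(perm, obs) (1 + sum(perm >= obs - 1e-12)) / (length(perm) + 1)

#' Permutation test of the cross-validated log-rank statistic
#'
#' The null distribution is built by shuffling the correspondence between
#' the (time, event) pairs and the joint (miRNA, clinical) covariate rows;
#' for every permutation the full pipeline — leave-one-out refits with inner
#' lambda tuning, median split, log-rank — is rerun. The p-value uses the
#' `(1 + exceedances) / (B + 1)` convention; permutations whose pipeline
#' degenerates are skipped and the denominator adjusted.
#'
#' @inheritParams loocv_prognostic_indices
#' @param B Number of permutations (1000 for a definitive run; reduce for
#'   exploration).
#' @param t_star Landmark for the AUC that is tracked alongside.
#' @param shuffle `"outcomes"` (default: stage stays with the miRNAs) or
#'   `"outcomes_and_stage"`.
#' @return A list: `statistic` (observed cross-validated log-rank
#'   chi-square), `p`, the companion `auc`/`p_auc_vs_half` (two-sided, from
#'   the same permutations), `B_effective`, permutation draws, and the
#'   observed run (`observed`).
#' @export
permutation_test_logrank <- function(expr, clinical, endpoint = c("dfs", "os"),
                                     B = 1000L, seed = 1L,
                                     model_config = list(), t_star = 24,
                                     shuffle = c("outcomes",
                                                 "outcomes_and_stage")) {
  endpoint <- match.arg(endpoint)
  shuffle <- match.arg(shuffle)
  stopifnot(B >= 1L)
  eng <- cv_perm_engine(expr, clinical, endpoint, B, seed, model_config,
                        t_star, scheme = shuffle)
  obs_lr <- eng$observed$logrank
  obs_auc <- eng$observed$auc
  list(statistic = obs_lr,
       p = perm_p(eng$perm_logrank, obs_lr),
       auc = obs_auc,
       p_auc_vs_half = perm_p(abs(eng$perm_auc - 0.5), abs(obs_auc - 0.5)),
       B = B, B_effective = eng$B_effective,
       perm_logrank = eng$perm_logrank, perm_auc = eng$perm_auc,
       observed = eng$observed)
}

#' Added-value permutation test: do the miRNAs improve on the covariates?
#'
#' Only the miRNA rows are randomly reassigned to patients; the
#' correspondence between time, event status and clinical covariates is not
#' disrupted. This tests the null hypothesis that survival and covariates
#' are independent of the miRNAs: the observed combined-model
#' cross-validated log-rank statistic and AUC are compared with their
#' distributions under miRNA reassignment (one-sided, `(1 + exceed)/(B+1)`).
#' The covariate-only model's statistics are reported alongside.
#'
#' @inheritParams permutation_test_logrank
#' @return A list: `p_logrank`, `p_auc`, observed combined statistics,
#'   `clinical_only` (log-rank chi-square and AUC of the covariate-only
#'   model), `B_effective`, and the permutation draws.
#' @export
added_value_permutation_test <- function(expr, clinical,
                                         endpoint = c("dfs", "os"),
                                         B = 1000L, seed = 1L,
                                         model_config = list(), t_star = 24) {
  endpoint <- match.arg(endpoint)
  stopifnot(B >= 1L)
  eng <- cv_perm_engine(expr, clinical, endpoint, B, seed, model_config,
                        t_star, scheme = "mirna")
  expr0 <- matrix(numeric(0), nrow(as.matrix(expr)), 0,
                  dimnames = list(rownames(expr), NULL))
  clin_only <- tryCatch({
    pi0 <- suppressWarnings(
      loocv_prognostic_indices(expr0, clinical, endpoint,
                               model_config = model_config,
                               seed = derive_seed(seed, "clinical_only")))
    km0 <- cv_km_and_logrank(pi0, clinical, endpoint)
    roc0 <- cv_time_dependent_roc(pi0, clinical, endpoint, t_star = t_star)
    list(logrank_chisq = km0$logrank_chisq, logrank_p = km0$logrank_p,
         auc = roc0$auc, cv_pi = pi0)
  }, error = function(e) {
    warning("covariate-only model degenerate: ", conditionMessage(e))
    NULL
  })
  list(p_logrank = perm_p(eng$perm_logrank, eng$observed$logrank),
       p_auc = perm_p(eng$perm_auc, eng$observed$auc),
       statistic = eng$observed$logrank, auc = eng$observed$auc,
       clinical_only = clin_only,
       B = B, B_effective = eng$B_effective,
       perm_logrank = eng$perm_logrank, perm_auc = eng$perm_auc,
       observed = eng$observed)
}

#' Full Simon-type validation report for one fitted configuration
#'
#' Convenience wrapper running the leave-one-out engine once and both
#' permutation tests, producing the cross-validated risk groups,
#' Kaplan-Meier curves, time-dependent ROC and all permutation p-values.
#'
#' @inheritParams permutation_test_logrank
#' @return A list of class `validation_report`.
#' @export
validate_model <- function(expr, clinical, endpoint = c("dfs", "os"),
                           B = 1000L, seed = 1L, model_config = list(),
                           t_star = 24) {
  endpoint <- match.arg(endpoint)
  lr <- permutation_test_logrank(expr, clinical, endpoint, B = B, seed = seed,
                                 model_config = model_config, t_star = t_star)
  av <- added_value_permutation_test(expr, clinical, endpoint, B = B,
                                     seed = derive_seed(seed, "added"),
                                     model_config = model_config,
                                     t_star = t_star)
  obs <- lr$observed
  structure(list(
    endpoint = endpoint, t_star = t_star, B = B,
    cv_pi = obs$cv_pi,
    risk_group = obs$km$risk_group,
    cv_km = obs$km$km,
    cv_logrank_stat = lr$statistic,
    p_logrank_perm = lr$p,
    cv_roc = obs$roc$curve,
    cv_auc = obs$roc$auc,
    p_auc_vs_half = lr$p_auc_vs_half,
    p_added_value_logrank = av$p_logrank,
    p_added_value_auc = av$p_auc,
    clinical_only = av$clinical_only
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %s, landmark %g months, B = %d\n",
              toupper(x$endpoint), x$t_star, x$B))
  cat(sprintf("  cross-validated log-rank chi-square %.3f (perm p = %.4g)\n",
              x$cv_logrank_stat, x$p_logrank_perm))
  cat(sprintf("  cross-validated AUC %.3f (p vs 0.5 = %.4g)\n",
              x$cv_auc, x$p_auc_vs_half))
  cat(sprintf("  added value over covariates: p_logrank = %.4g, p_auc = %.4g\n",
              x$p_added_value_logrank, x$p_added_value_auc))
  invisible(x)
}
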