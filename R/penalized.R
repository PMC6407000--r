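# Clinical design block with fixed, level-stable dummy coding.
# Reference levels: stage I, female, never-smoker, no chemo, no radio.
clinical_design <- function(clinical, covariates) {
  n <- nrow(clinical)
  cols <- list()
  if ("stage" %in% covariates) {
    st <- factor(clinical$stage, levels = c("I", "II", "IIIA"))
    cols[["stageII"]] <- as.numeric(st == "II")
    cols[["stageIIIA"]] <- as.numeric(st == "IIIA")
  }
  if ("age" %in% covariates) cols[["age"]] <- as.numeric(clinical$age_at_surgery)
  if ("gender" %in% covariates)
    cols[["gendermale"]] <- as.numeric(clinical$gender == "male")
  if ("smoking" %in% covariates) {
    cols[["smokingex"]] <- as.numeric(clinical$smoking == "ex")
    cols[["smokingcurrent"]] <- as.numeric(clinical$smoking == "current")
  }
  if ("chemo" %in% covariates) cols[["chemo"]] <- as.numeric(clinical$chemo)
  if ("radio" %in% covariates) cols[["radio"]] <- as.numeric(clinical$radio)
  if (!length(cols)) return(matrix(numeric(0), n, 0))
  do.call(cbind, cols)
}

# Breslow Cox partial log-likelihood for each column of a linear-predictor
# matrix (n x L). Used for the cross-validated deviance; matches glmnet's
# internal tie handling.
breslow_loglik <- function(eta, time, event) {
  eta <- as.matrix(eta)
  ord <- order(time, decreasing = TRUE)   # reverse time: cumsum = risk sets
  time <- time[ord]; event <- as.logical(event)[ord]
  eta <- eta[ord, , drop = FALSE]
  vapply(seq_len(ncol(eta)), function(l) {
    e <- eta[, l]
    risk <- cumsum(exp(e))
    # ties: all deaths at time t share the full risk set at t
    risk_at <- stats::ave(risk, time, FUN = max)
    sum(e[event]) - sum(log(risk_at[event]))
  }, numeric(1))
}

# Event-stratified fold assignment, reproducible from seed.
make_foldid <- function(event, folds, seed) {
  event <- as.logical(event)
  foldid <- integer(length(event))
  with_seed(seed, {
    for (grp in list(which(event), which(!event))) {
      if (length(grp))
        foldid[sample(grp)] <- rep_len(seq_len(folds), length(grp))
    }
  })
  foldid
}

#' Elastic-net Cox model with unpenalized clinical covariates
#'
#' Fits the combined multivariable model: all miRNA expression columns under
#' an elastic-net penalty (mixing parameter `alpha`, default 0.5) and the
#' chosen clinical covariates left unpenalized (penalty factor 0). miRNA
#' columns are standardized internally (mean 0, SD 1) before penalization
#' and coefficients are reported back on the -dCt scale. The lambda path is
#' truncated at the first value where the number of nonzero penalized
#' coefficients would exceed `max_selected` (default 5), so the final model
#' never contains more than that many miRNAs; unpenalized covariates never
#' count against the cap. Lambda is selected on this admissible path by
#' k-fold cross-validated partial-likelihood deviance (Verweij-van
#' Houwelingen), with folds stratified by event status and reproducible
#' from `seed`.
#'
#' With zero miRNA columns the model degenerates to an unpenalized Cox fit
#' of the clinical covariates (used as the covariate-only comparator in the
#' validation engine).
#'
#' @param expr Patients x miRNAs matrix of -dCt values (no missing values).
#' @param clinical Clinical table aligned by `patient_id` to `rownames(expr)`.
#' @param endpoint `"dfs"` or `"os"`.
#' @param alpha Elastic-net mixing parameter.
#' @param max_selected Cap on the number of selected miRNAs.
#' @param folds Number of CV folds (requires at least that many events).
#' @param seed Integer seed for the fold assignment.
#' @param clinical_covariates Clinical covariates entered unpenalized; any of
#'   `"stage"`, `"age"`, `"gender"`, `"smoking"`, `"chemo"`, `"radio"`.
#' @param nlambda,lambda_min_ratio Geometric lambda path specification.
#' @param lambda Optional override: `"max"` pins the fit at the top of the
#'   path (all penalized coefficients zero); a number skips CV and evaluates
#'   at that penalty.
#' @param foldid Optional explicit fold assignment (overrides `seed`).
#' @return An object of class `pen_cox_fit`: coefficients on the original
#'   scale (`beta`), `lambda_path`, `lambda_selected`, `penalty_factor`,
#'   `selected_mirnas`, the CV deviance curve (`cv`), and bookkeeping needed
#'   to score new patients.
#' @export
fit_elastic_net_cox <- function(expr, clinical, endpoint = c("dfs", "os"),
                                alpha = 0.5, max_selected = 5L, folds = 10L,
                                seed = 1L,
                                clinical_covariates = "stage",
                                nlambda = 100L, lambda_min_ratio = 0.01,
                                lambda = NULL, foldid = NULL) {
  endpoint <- match.arg(endpoint)
  expr <- as.matrix(expr)
  ids <- rownames(expr)
  stopifnot(!is.null(ids), all(ids %in% clinical$patient_id))
  cl <- clinical[match(ids, clinical$patient_id), , drop = FALSE]
  tt <- clinical_times(cl, endpoint)
  ev <- clinical_events(cl, endpoint)
  if (anyNA(expr)) stop("expression matrix has missing values; impute first")

  xc <- clinical_design(cl, clinical_covariates)
  keep_clin <- apply(xc, 2, function(v) stats::var(v) > 0)
  xc <- xc[, keep_clin, drop = FALSE]
  clin_terms <- colnames(xc)

  const <- apply(expr, 2, function(v) stats::var(v) == 0)
  if (any(const)) {
    warning("dropping all-constant miRNA columns: ",
            paste(colnames(expr)[const], collapse = ", "))
    expr <- expr[, !const, drop = FALSE]
  }
  mirna_ids <- colnames(expr)
  p_mir <- ncol(expr)

  base <- list(endpoint = endpoint, alpha = alpha,
               max_selected = as.integer(max_selected),
               folds = as.integer(folds), seed = as.integer(seed),
               clinical_covariates = clinical_covariates,
               clinical_terms = clin_terms, mirna_ids = mirna_ids,
               patient_ids = ids)

  if (p_mir == 0L) {
    # covariate-only comparator: plain Cox fit, Breslow ties as in glmnet
    if (ncol(xc) == 0L) stop("no covariates to fit")
    cfit <- survival::coxph(survival::Surv(tt, ev) ~ xc, ties = "breslow")
    beta <- stats::setNames(as.numeric(stats::coef(cfit)), clin_terms)
    out <- c(base, list(
      beta = beta, selected_mirnas = character(0),
      penalty_factor = stats::setNames(rep(0, length(clin_terms)), clin_terms),
      lambda_path = numeric(0), lambda_selected = NA_real_, cv = NULL,
      center = numeric(0), scale = numeric(0)))
    class(out) <- "pen_cox_fit"
    return(out)
  }

  if (sum(ev) < folds && is.null(lambda))
    stop("fewer events (", sum(ev), ") than folds (", folds,
         "); use fewer folds")

  ctr <- colMeans(expr)
  scl <- apply(expr, 2, stats::sd)
  xs <- scale(expr, center = ctr, scale = scl)
  x <- cbind(xc, xs)
  pf <- c(rep(0, ncol(xc)), rep(1, p_mir))
  y <- survival::Surv(tt, ev)

  fit <- glmnet::glmnet(x, y, family = "cox", alpha = alpha,
                        penalty.factor = pf, standardize = FALSE,
                        nlambda = nlambda, lambda.min.ratio = lambda_min_ratio)
  path <- fit$lambda
  pen_idx <- which(pf == 1) # rows of coef matrix (no intercept for cox)
  nz_count <- colSums(as.matrix(fit$beta[pen_idx, , drop = FALSE]) != 0)
  over <- which(nz_count > max_selected)
  adm <- if (length(over)) seq_len(min(over) - 1L) else seq_along(path)
  if (!length(adm)) adm <- 1L

  if (!is.null(lambda)) {
    # explicit lambda bypasses both CV and the selection cap
    if (identical(lambda, "max")) {
      lambda_selected <- path[1]
    } else {
      lambda_selected <- as.numeric(lambda)
      if (!any(abs(path - lambda_selected) < 1e-12)) {
        path2 <- sort(unique(c(path[path > lambda_selected], lambda_selected)),
                      decreasing = TRUE)
        fit <- glmnet::glmnet(x, y, family = "cox", alpha = alpha,
                              penalty.factor = pf, standardize = FALSE,
                              lambda = path2)
      }
    }
    cvtab <- NULL
  } else {
    foldid <- foldid %||% make_foldid(ev, folds, seed)
    stopifnot(length(foldid) == length(ev))
    folds <- max(foldid)
    devfold <- matrix(NA_real_, folds, length(path))
    ll_all_cache <- NULL
    for (k in seq_len(folds)) {
      tr <- foldid != k
      fitk <- glmnet::glmnet(x[tr, , drop = FALSE], y[tr, ],
                             family = "cox", alpha = alpha,
                             penalty.factor = pf, standardize = FALSE,
                             lambda = path)
      bk <- as.matrix(fitk$beta)
      # glmnet may drop trailing lambdas on a fold; align by value
      use <- match(signif(path, 10), signif(fitk$lambda, 10))
      eta_all <- x %*% bk
      ll_all <- breslow_loglik(eta_all, tt, ev)
      ll_tr <- breslow_loglik(eta_all[tr, , drop = FALSE], tt[tr], ev[tr])
      dev <- -2 * (ll_all - ll_tr)
      devfold[k, ] <- dev[use]
    }
    cvm <- colMeans(devfold)
    cvsd <- apply(devfold, 2, stats::sd) / sqrt(folds)
    cvtab <- data.frame(lambda = path, cvm = cvm, cvse = cvsd,
                        nonzero = nz_count,
                        admissible = seq_along(path) %in% adm)
    ok <- adm[is.finite(cvm[adm])]
    lambda_selected <- path[ok[which.min(cvm[ok])]]
  }

  bsel <- as.numeric(stats::predict(fit, s = lambda_selected,
                                    type = "coefficients"))
  names(bsel) <- colnames(x)
  # back to the -dCt scale for the standardized block
  bsel[mirna_ids] <- bsel[mirna_ids] / scl
  sel <- mirna_ids[bsel[mirna_ids] != 0]
  out <- c(base, list(
    beta = bsel, selected_mirnas = sel,
    penalty_factor = stats::setNames(pf, colnames(x)),
    lambda_path = path, lambda_selected = lambda_selected, cv = cvtab,
    center = ctr, scale = scl))
  class(out) <- "pen_cox_fit"
  out
}

#' @export
print.pen_cox_fit <- function(x, ...) {
  cat(sprintf(
    "<pen_cox_fit> endpoint %s, alpha %.2f; %d clinical term(s), %d/%d miRNAs selected (cap %d)\n",
    toupper(x$endpoint), x$alpha, length(x$clinical_terms),
    length(x$selected_mirnas), length(x$mirna_ids), x$max_selected))
  nz <- x$beta[x$beta != 0]
  if (length(nz)) print(round(nz, 4))
  invisible(x)
}

#' Prognostic index (linear predictor) of fitted patients or new data
#'
#' `PI = x' beta` at the selected lambda, on the original covariate scales
#' (no baseline hazard needed: only ranks and contrasts of PI are used
#' downstream). Higher PI = higher predicted risk.
#'
#' @param fit A [fit_elastic_net_cox()] result.
#' @param expr Patients x miRNAs matrix covering `fit$mirna_ids`.
#' @param clinical Clinical table covering the patients of `expr`.
#' @return Named numeric vector of prognostic indices.
#' @export
prognostic_index <- function(fit, expr, clinical) {
  stopifnot(inherits(fit, "pen_cox_fit"))
  if (length(fit$mirna_ids)) {
    expr <- as.matrix(expr)
    missing_g <- setdiff(fit$mirna_ids, colnames(expr))
    if (length(missing_g))
      stop("expression matrix lacks model miRNAs: ",
           paste(missing_g, collapse = ", "))
    ids <- rownames(expr)
  } else {
    ids <- clinical$patient_id
  }
  cl <- clinical[match(ids, clinical$patient_id), , drop = FALSE]
  xc <- clinical_design(cl, fit$clinical_covariates)
  xc <- xc[, fit$clinical_terms, drop = FALSE]
  x <- if (length(fit$mirna_ids))
    cbind(xc, expr[, fit$mirna_ids, drop = FALSE]) else xc
  stopifnot(identical(colnames(x), names(fit$beta)))
  stats::setNames(as.numeric(x %*% fit$beta), ids)
}
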