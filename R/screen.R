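#' Univariate Cox regression for one covariate
#'
#' Fits a single-covariate Cox proportional-hazards model (Efron tie
#' handling) and reports hazard ratios with Wald 95% confidence intervals
#' and two-sided Wald p-values. Categorical covariates expand to one row per
#' non-reference level; the reference is the factor's first level (set
#' factors up with stage I, female, never-smoker, no-treatment first).
#' Monotone-likelihood fits (infinite coefficient) are returned as flagged
#' rows with an infinite confidence bound rather than an error.
#'
#' @param times,events Follow-up times (months) and event indicators.
#' @param covariate Numeric vector or factor/character.
#' @param term Label for the covariate in the output.
#' @return Data frame: term, level, hazard_ratio, ci95_low, ci95_high,
#'   p_value, beta, se, monotone (logical flag).
#' @export
fit_univariate_cox <- function(times, events, covariate, term = "x") {
  stopifnot(length(times) == length(events),
            length(covariate) == length(times))
  events <- as.logical(events)
  if (sum(events) < 1L) stop("no events: Cox model undefined")
  if (is.character(covariate)) covariate <- factor(covariate)
  keep <- !is.na(covariate)
  cv <- if (is.factor(covariate)) droplevels(covariate[keep]) else covariate[keep]
  if (length(unique(cv)) < 2L) stop("constant covariate: '", term, "'")
  monotone <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(times[keep], events[keep]) ~ cv,
                    ties = "efron"),
    warning = function(w) {
      if (grepl("infinite|converge|beta may be infinite", conditionMessage(w)))
        monotone <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- stats::coef(fit)
  se <- sqrt(diag(fit$var))
  monotone <- monotone | (abs(beta) > 15) | (se > 1e3)
  lev <- if (is.factor(cv)) levels(cv)[-1] else NA_character_
  data.frame(
    term = term,
    level = if (is.factor(cv)) lev else NA_character_,
    hazard_ratio = exp(unname(beta)),
    ci95_low = exp(unname(beta - 1.96 * se)),
    ci95_high = ifelse(monotone, Inf, exp(unname(beta + 1.96 * se))),
    p_value = 2 * stats::pnorm(-abs(unname(beta / se))),
    beta = unname(beta), se = unname(se),
    monotone = unname(monotone),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg step-up procedure
#'
#' Sorts the p-values ascending (stable: ties keep input order), computes
#' the critical values `(j/m) * delta`, and rejects hypotheses 1..j* where
#' j* is the largest rank whose p-value sits at or below its critical value.
#' `m` may exceed the number of supplied p-values when only the smallest of
#' a larger family are available (the remaining ones then cannot change the
#' decision for the supplied ranks as long as they are larger).
#'
#' @param p_values Numeric vector in \[0, 1\].
#' @param delta FDR level (default 0.05).
#' @param m Family size (default `length(p_values)`).
#' @return Data frame in input order: p_value, rank, critical, rejected.
#' @export
benjamini_hochberg <- function(p_values, delta = 0.05, m = length(p_values)) {
  stopifnot(length(p_values) >= 1L, m >= length(p_values), delta > 0)
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  ord <- order(p_values)           # stable: ties keep input order
  j <- seq_along(p_values)
  critical <- j / m * delta
  ps <- p_values[ord]
  hits <- which(ps <= critical)
  jstar <- if (length(hits)) max(hits) else 0L
  out <- data.frame(p_value = p_values,
                    rank = NA_integer_, critical = NA_real_,
                    rejected = FALSE)
  out$rank[ord] <- j
  out$critical[ord] <- critical
  out$rejected[ord] <- j <= jstar
  out
}

#' Kaplan-Meier summary with median survival and log-rank test
#'
#' Product-limit curves (log-log Greenwood confidence intervals), the median
#' survival time — the earliest time at which the survival curve drops to
#' 0.5 or below, `NA` when never reached — with its 95% CI, and, when a
#' grouping is supplied, the log-rank test across groups.
#'
#' @param times,events Follow-up times and event indicators.
#' @param group Optional grouping factor.
#' @return A list: `curve` (data frame time/surv/lower/upper/group),
#'   `median` (data frame per group: median, ci_low, ci_high, n, events),
#'   and for grouped input `logrank_chisq`, `logrank_df`, `logrank_p`.
#' @export
km_summary <- function(times, events, group = NULL) {
  events <- as.logical(events)
  srv <- survival::Surv(times, events)
  if (is.null(group)) {
    fit <- survival::survfit(srv ~ 1, conf.type = "log-log")
    grp_names <- "all"
  } else {
    group <- as.factor(group)
    if (any(table(group) == 0L) || nlevels(group) < 1L)
      stop("empty group in Kaplan-Meier comparison")
    fit <- survival::survfit(srv ~ group, conf.type = "log-log")
    grp_names <- levels(group)
  }
  smry <- summary(fit)$table
  if (is.null(dim(smry))) smry <- matrix(smry, 1, dimnames = list("all", names(smry)))
  strata <- if (is.null(fit$strata)) rep("all", length(fit$time))
            else rep(grp_names, fit$strata)
  curve <- data.frame(time = fit$time, n_risk = fit$n.risk,
                      surv = fit$surv, lower = fit$lower, upper = fit$upper,
                      group = strata)
  # earliest time at which the curve drops to 0.5 or below; NA if never
  cross <- function(g) {
    idx <- which(curve$group == g & curve$surv <= 0.5 + 1e-12)
    if (length(idx)) curve$time[min(idx)] else NA_real_
  }
  med <- data.frame(group = grp_names,
                    n = smry[, "records"], events = smry[, "events"],
                    median = vapply(grp_names, cross, numeric(1)),
                    ci_low = smry[, "0.95LCL"], ci_high = smry[, "0.95UCL"],
                    row.names = NULL)
  out <- list(curve = curve, median = med)
  if (!is.null(group) && nlevels(droplevels(group)) > 1L) {
    lr <- tryCatch(survival::survdiff(srv ~ group),
                   error = function(e)
                     stop("log-rank statistic undefined: ",
                          conditionMessage(e), call. = FALSE))
    out$logrank_chisq <- unname(lr$chisq)
    out$logrank_df <- length(lr$n) - 1L
    out$logrank_p <- stats::pchisq(lr$chisq, length(lr$n) - 1L,
                                   lower.tail = FALSE)
  }
  out
}

#' Median follow-up time
#'
#' The reverse-of-events convention: the median of the times at risk of the
#' censored patients (even counts use the mean-of-middle convention).
#'
#' @param times,events Follow-up times and event indicators.
#' @return Months; `NA` with a warning when no patient is censored.
#' @export
median_followup <- function(times, events) {
  cens <- times[!as.logical(events)]
  if (!length(cens)) {
    warning("no censored patients: median follow-up undefined")
    return(NA_real_)
  }
  stats::median(cens)
}

#' Univariate screening of every miRNA with FDR control
#'
#' Runs [fit_univariate_cox()] for each expression column against the chosen
#' endpoint and applies [benjamini_hochberg()] across the miRNA family
#' (clinical covariates are never part of the FDR family). The output is
#' shaped like the univariable screening tables such analyses report:
#' HR, 95% CI, p-value and the BH critical column `(j/m) x delta`.
#'
#' @param expr Patients x miRNAs matrix of -dCt values.
#' @param clinical Clinical table (see [read_clinical()]).
#' @param endpoint `"dfs"` or `"os"`.
#' @param delta FDR level.
#' @return Data frame sorted by p-value: gene, hazard_ratio, ci95_low,
#'   ci95_high, p_value, rank, critical, rejected.
#' @export
screen_mirnas <- function(expr, clinical, endpoint = c("dfs", "os"),
                          delta = 0.05) {
  endpoint <- match.arg(endpoint)
  ids <- rownames(expr)
  tt <- clinical_times(clinical, endpoint, ids)
  ev <- clinical_events(clinical, endpoint, ids)
  rows <- lapply(colnames(expr), function(g)
    cbind(gene = g,
          fit_univariate_cox(tt, ev, expr[, g], term = g)[
            , c("hazard_ratio", "ci95_low", "ci95_high", "p_value")]))
  tab <- do.call(rbind, rows)
  bh <- benjamini_hochberg(tab$p_value, delta = delta)
  tab <- cbind(tab, bh[, c("rank", "critical", "rejected")])
  tab[order(tab$rank), , drop = FALSE]
}
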