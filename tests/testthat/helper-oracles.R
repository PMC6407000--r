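# Independent oracle implementations (brute force / plain loops), shared by
# the unit tests and the acceptance suite. These deliberately avoid the
# package's internal code paths.

# Efron partial log-likelihood for a single covariate, evaluated by loops.
efron_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t in unique(time[event])) {
    deaths <- which(time == t & event)
    risk <- which(time >= t)
    d <- length(deaths)
    ll <- ll + beta * sum(x[deaths])
    sr <- sum(exp(beta * x[risk]))
    sd_ <- sum(exp(beta * x[deaths]))
    for (l in seq_len(d) - 1) ll <- ll - log(sr - l / d * sd_)
  }
  ll
}

# Exhaustive search over all BH rejection cut-offs.
brute_bh <- function(p, delta, m) {
  ord <- order(p)
  best <- 0L
  for (j in seq_along(p)) if (p[ord[j]] <= j / m * delta) best <- j
  rej <- rep(FALSE, length(p))
  if (best > 0) rej[ord[seq_len(best)]] <- TRUE
  rej
}

# Two-way means fit by explicit loops; residual SD with the G/(G-1) factor.
brute_stability <- function(m) {
  G <- ncol(m); n <- nrow(m)
  resid <- matrix(0, n, G)
  for (j in seq_len(n)) for (g in seq_len(G))
    resid[j, g] <- m[j, g] - mean(m[, g]) - mean(m[j, ]) + mean(m)
  out <- sapply(seq_len(G), function(g)
    sqrt(G / (G - 1) * sum((resid[, g] - mean(resid[, g]))^2) / (n - 1)))
  names(out) <- colnames(m)
  out
}

# Hand KNN imputation of one masked cell by pairwise-distance enumeration.
brute_knn_cell <- function(ct, j, g, k) {
  donors <- setdiff(which(!is.na(ct[, g])), j)
  dd <- sapply(donors, function(i) {
    sh <- !is.na(ct[i, ]) & !is.na(ct[j, ])
    sqrt(mean((ct[i, sh] - ct[j, sh])^2))
  })
  mean(ct[donors[order(dd, donors)][seq_len(k)], g])
}

# Plain-loop Breslow partial log-likelihood for each linear-predictor column.
ref_breslow <- function(eta, time, event) {
  eta <- as.matrix(eta)
  sapply(seq_len(ncol(eta)), function(l) {
    e <- eta[, l]
    ll <- 0
    for (i in which(as.logical(event)))
      ll <- ll + e[i] - log(sum(exp(e[time >= time[i]])))
    ll
  })
}

# Event-stratified fold assignment reproducing the documented seeding scheme.
ref_foldid <- function(event, folds, seed) {
  event <- as.logical(event)
  foldid <- integer(length(event))
  set.seed(as.integer(seed))
  for (grp in list(which(event), which(!event)))
    if (length(grp)) foldid[sample(grp)] <- rep_len(seq_len(folds), length(grp))
  foldid
}

# Straightforward single-patient-out reference loop written directly against
# glmnet: stage dummies unpenalized, miRNAs standardized on the training set,
# path truncated at the selection cap, Verweij-van Houwelingen CV deviance.
ref_loocv <- function(expr, clinical, folds, nlambda, lmr, max_sel, seed) {
  ids <- rownames(expr)
  out <- setNames(rep(NA_real_, length(ids)), ids)
  for (i in seq_along(ids)) {
    tr <- setdiff(ids, ids[i])
    cl <- clinical[match(tr, clinical$patient_id), ]
    st <- factor(cl$stage, levels = c("I", "II", "IIIA"))
    xc <- cbind(stageII = as.numeric(st == "II"),
                stageIIIA = as.numeric(st == "IIIA"))
    xc <- xc[, apply(xc, 2, var) > 0, drop = FALSE]
    e_tr <- expr[tr, , drop = FALSE]
    ctr <- colMeans(e_tr); scl <- apply(e_tr, 2, sd)
    x <- cbind(xc, scale(e_tr, ctr, scl))
    pf <- c(rep(0, ncol(xc)), rep(1, ncol(e_tr)))
    y <- survival::Surv(cl$dfs_time, cl$dfs_event)
    fit <- glmnet::glmnet(x, y, family = "cox", alpha = 0.5,
                          penalty.factor = pf, standardize = FALSE,
                          nlambda = nlambda, lambda.min.ratio = lmr)
    path <- fit$lambda
    nz <- colSums(as.matrix(fit$beta[pf == 1, , drop = FALSE]) != 0)
    over <- which(nz > max_sel)
    adm <- if (length(over)) seq_len(min(over) - 1L) else seq_along(path)
    if (!length(adm)) adm <- 1L
    foldid <- ref_foldid(cl$dfs_event, folds, derive_seed(seed, "loocv", i))
    dev <- matrix(NA_real_, folds, length(path))
    for (k in seq_len(folds)) {
      trk <- foldid != k
      fk <- glmnet::glmnet(x[trk, , drop = FALSE], y[trk, ], family = "cox",
                           alpha = 0.5, penalty.factor = pf,
                           standardize = FALSE, lambda = path)
      use <- match(signif(path, 10), signif(fk$lambda, 10))
      eta <- x %*% as.matrix(fk$beta)
      d <- -2 * (ref_breslow(eta, cl$dfs_time, cl$dfs_event) -
                   ref_breslow(eta[trk, , drop = FALSE],
                               cl$dfs_time[trk], cl$dfs_event[trk]))
      dev[k, ] <- d[use]
    }
    cvm <- colMeans(dev)
    ok <- adm[is.finite(cvm[adm])]
    lam <- path[ok[which.min(cvm[ok])]]
    b <- as.numeric(predict(fit, s = lam, type = "coefficients"))
    names(b) <- colnames(x)
    b[colnames(e_tr)] <- b[colnames(e_tr)] / scl
    sti <- clinical$stage[clinical$patient_id == ids[i]]
    xi <- c(stageII = as.numeric(sti == "II"),
            stageIIIA = as.numeric(sti == "IIIA"))[colnames(xc)]
    out[i] <- sum(xi * b[colnames(xc)]) + sum(expr[ids[i], ] * b[colnames(e_tr)])
  }
  out
}
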