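#' Configuration of the synthetic cohort generator
#'
#' Defaults emulate a squamous-cell (SCC) early-stage NSCLC cohort: 83
#' patients, stage I/II/IIIA frequencies of roughly 51/33/17%, stage
#' log-hazard ratios 0.60 and 1.23 versus stage I, a Weibull baseline tuned
#' to a median disease-free survival around two years, and administrative
#' plus uniform censoring spreading follow-up over roughly 13 years. Three
#' target miRNAs carry proportional-hazards signal (per unit of latent
#' expression, i.e. per unit of -dCt) of a size comparable to the univariate
#' hazard ratios such panels report. Fourteen designated targets are
#' low-abundance so that more than half of their wells fall beyond the
#' detection limit, and two designated targets are near-noise-free "stable"
#' reference candidates.
#'
#' @param n_patients Number of patients.
#' @param n_targets,n_housekeeping Panel sizes (target miRNAs, snRNAs).
#' @param prognostic_set Integer indices of targets with nonzero log-HR.
#' @param beta_mirna Log-hazard coefficients (per unit of latent expression,
#'   equivalently per unit of -dCt) for `prognostic_set`, same length.
#' @param beta_stage Length-2 log-HRs for stage II and IIIA versus I.
#' @param stage_probs Length-3 simplex of stage I/II/IIIA frequencies.
#' @param weibull_shape,weibull_scale Baseline event-time distribution
#'   (months).
#' @param censor_admin_time Administrative censoring horizon (months); may be
#'   `Inf`.
#' @param censor_uniform_max Upper bound of uniform accrual censoring
#'   (months); may be `Inf`.
#' @param detection_limit_ct Ct above which a well reads "undetermined".
#' @param sigma_gene SD of gene-level abundance (Ct cycles); draws are
#'   clamped to +/- 4 cycles so that ordinary targets never cross the
#'   detection limit in bulk.
#' @param sigma_sample SD of the shared biological sample effect.
#' @param sigma_noise SD of well-level noise for ordinary genes.
#' @param ref_noise_sd Well-level noise SD for the two `stable_set` genes.
#' @param sigma_spike SD of the per-sample technical (extraction) offset
#'   measured by the spike-in.
#' @param stable_set Two target indices designated as stable reference
#'   candidates.
#' @param sparse_set Target indices forced to low abundance (mostly
#'   undetermined); emulates the below-detection targets such panels drop.
#' @param sparse_shift Abundance deficit (cycles) applied to `sparse_set`.
#' @param ct_offset Affine offset mapping latent expression to Ct.
#' @param spikein_mean_ct Mean spike-in Ct.
#' @param mcar_prob Optional probability of independent (MCAR) masking of
#'   observed target wells, for imputation fixtures.
#' @param os_gap_mean Mean (months) of the exponential gap between the
#'   disease-free and overall-survival event times.
#' @param histotype Histotype label stamped on every patient.
#' @param seed Integer seed; identical seeds give byte-identical cohorts.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 83L,
                              n_targets = 84L,
                              n_housekeeping = 6L,
                              prognostic_set = c(5L, 6L, 7L),
                              beta_mirna = c(-0.5, -0.4, 0.3),
                              beta_stage = c(0.60, 1.23),
                              stage_probs = c(0.506, 0.325, 0.169),
                              weibull_shape = 1.1,
                              weibull_scale = 48,
                              censor_admin_time = 170,
                              censor_uniform_max = 160,
                              detection_limit_ct = 35,
                              sigma_gene = 2.5,
                              sigma_sample = 1,
                              sigma_noise = 1,
                              ref_noise_sd = 0.15,
                              sigma_spike = 0.7,
                              stable_set = c(21L, 24L),
                              sparse_set = 71:84,
                              sparse_shift = 10,
                              ct_offset = 28,
                              spikein_mean_ct = 20,
                              mcar_prob = 0,
                              os_gap_mean = 24,
                              histotype = "SCC",
                              seed = 1L) {
  cfg <- as.list(environment())
  validate_simulation_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

validate_simulation_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_patients >= 2, n_targets >= 1, n_housekeeping >= 0)
    if (abs(sum(stage_probs) - 1) > 1e-12)
      stop("stage_probs must sum to 1 within 1e-12")
    if (any(c(sigma_gene, sigma_sample, sigma_noise, ref_noise_sd,
              sigma_spike) < 0))
      stop("all SDs must be >= 0")
    if (weibull_shape <= 0 || weibull_scale <= 0)
      stop("weibull_shape and weibull_scale must be > 0")
    for (s in list(prognostic_set, stable_set, sparse_set)) {
      if (length(s) && (anyDuplicated(s) || any(s < 1L) || any(s > n_targets)))
        stop("target index sets must be distinct, valid target indices")
    }
    stopifnot(length(beta_mirna) == length(prognostic_set),
              length(beta_stage) == 2L, length(stable_set) %in% c(0L, 2L))
  })
  invisible(cfg)
}

#' Simulate a qPCR plate and clinical table with known truth
#'
#' Latent expression of gene g in patient j is
#' `x[g, j] = gene effect + sample effect + well noise`; the two `stable_set`
#' genes carry the small `ref_noise_sd` well noise. Observed Ct is the
#' affine map `ct = ct_offset - x + technical offset`, the technical offset
#' being what the spike-in records. Event times follow a Weibull
#' proportional-hazards model with linear predictor
#' `beta_stage[stage] + sum(beta_mirna * centred x)`; censoring is the
#' minimum of a uniform accrual draw and the administrative horizon. Wells
#' with Ct beyond `detection_limit_ct` are flagged undetermined.
#'
#' @param config A [simulation_config()].
#' @return A list with components `plate` (a [ct_plate()]), `clinical`
#'   (a data frame, see [read_clinical()] for the column contract) and
#'   `truth` (latent expression, linear predictors, true coefficient vector,
#'   uncensored event times).
#' @export
simulate_cohort <- function(config = simulation_config()) {
  validate_simulation_config(config)
  cf <- config
  with_seed(cf$seed, {
    n <- cf$n_patients
    p <- cf$n_targets
    ids <- sprintf("P%03d", seq_len(n))
    targets <- sprintf("miR-%03d", seq_len(p))
    hk <- if (cf$n_housekeeping > 0) sprintf("snRNA-U%d", seq_len(cf$n_housekeeping)) else character(0)

    # gene-level abundance; clamped so ordinary targets stay well detected
    u <- pmin(pmax(stats::rnorm(p, 0, cf$sigma_gene), -4), 4)
    u[cf$sparse_set] <- -cf$sparse_shift
    b <- stats::rnorm(n, 0, cf$sigma_sample)       # biological sample effect
    noise_sd <- rep(cf$sigma_noise, p)
    noise_sd[cf$stable_set] <- cf$ref_noise_sd
    eps <- matrix(stats::rnorm(n * p), n, p) * rep(noise_sd, each = n)
    x <- outer(b, u, function(bj, ug) ug + bj) + eps  # n x p latent expression

    tech <- stats::rnorm(n, 0, cf$sigma_spike)     # extraction/recovery offset
    spike <- cf$spikein_mean_ct + tech
    ct_t <- cf$ct_offset - x + tech

    if (cf$n_housekeeping > 0) {
      u_hk <- stats::rnorm(cf$n_housekeeping, 3, 0.5)
      eps_hk <- matrix(stats::rnorm(n * cf$n_housekeeping, 0, cf$sigma_noise),
                       n, cf$n_housekeeping)
      x_hk <- outer(b, u_hk, function(bj, ug) ug + bj) + eps_hk
      ct_h <- cf$ct_offset - x_hk + tech
    } else ct_h <- matrix(numeric(0), n, 0)

    # clinical covariates
    stage <- factor(sample(c("I", "II", "IIIA"), n, TRUE, cf$stage_probs),
                    levels = c("I", "II", "IIIA"))
    age <- round(pmin(pmax(stats::rnorm(n, 68, 8), 40), 88), 1)
    gender <- factor(sample(c("female", "male"), n, TRUE, c(0.15, 0.85)),
                     levels = c("female", "male"))
    smoking <- factor(sample(c("never", "ex", "current"), n, TRUE,
                             c(0.05, 0.30, 0.65)),
                      levels = c("never", "ex", "current"))
    chemo <- stats::runif(n) < 0.18
    radio <- stats::runif(n) < 0.12

    # proportional-hazards event times (inverse-CDF Weibull sampling)
    z <- sweep(x, 2, colMeans(x))  # centred latent expression
    lp <- cf$beta_stage[1] * (stage == "II") + cf$beta_stage[2] * (stage == "IIIA")
    if (length(cf$prognostic_set))
      lp <- lp + as.vector(z[, cf$prognostic_set, drop = FALSE] %*% cf$beta_mirna)
    lp <- as.numeric(lp)
    u_t <- stats::runif(n)
    t_dfs <- cf$weibull_scale * (-log(u_t) * exp(-lp))^(1 / cf$weibull_shape)
    t_os <- t_dfs + stats::rexp(n, 1 / cf$os_gap_mean)
    cens <- if (is.finite(cf$censor_uniform_max))
      stats::runif(n, 0, cf$censor_uniform_max) else rep(Inf, n)
    cens <- pmin(cens, cf$censor_admin_time)

    dfs_event <- t_dfs <= cens
    dfs_time <- pmin(t_dfs, cens)
    os_event <- t_os <= cens
    os_time <- pmin(t_os, cens)
    if (any(!is.finite(dfs_time)) || any(!is.finite(os_time)))
      stop("non-finite survival draws; config: ",
           paste(utils::capture.output(utils::str(unclass(cf))), collapse = "\n"))
    # infinite censoring bounds => everyone observed at their event time
    ct_all <- cbind(ct_t, ct_h)
    if (any(!is.finite(ct_all)))
      stop("non-finite Ct draws; config: ",
           paste(utils::capture.output(utils::str(unclass(cf))), collapse = "\n"))

    und <- ct_all > cf$detection_limit_ct
    if (cf$mcar_prob > 0) {
      mcar <- matrix(stats::runif(n * p) < cf$mcar_prob, n, p)
      und[, seq_len(p)] <- und[, seq_len(p), drop = FALSE] | mcar
    }
    ct_all[und] <- NA_real_

    plate <- ct_plate(ct_all, und, ids, targets, hk, spike, centered = FALSE)
    clinical <- data.frame(
      patient_id = ids, histotype = cf$histotype, stage = stage,
      age_at_surgery = age, gender = gender, smoking = smoking,
      chemo = chemo, radio = radio,
      dfs_time = dfs_time, dfs_event = dfs_event,
      os_time = os_time, os_event = os_event,
      stringsAsFactors = FALSE
    )
    beta_full <- numeric(p)
    beta_full[cf$prognostic_set] <- cf$beta_mirna
    truth <- list(
      x = `dimnames<-`(x, list(ids, targets)),
      linear_predictor = stats::setNames(lp, ids),
      beta_mirna = stats::setNames(beta_full, targets),
      beta_stage = cf$beta_stage,
      event_time_dfs = stats::setNames(t_dfs, ids),
      event_time_os = stats::setNames(t_os, ids),
      censor_time = stats::setNames(cens, ids),
      stable_ids = targets[cf$stable_set],
      sparse_ids = targets[cf$sparse_set],
      prognostic_ids = targets[cf$prognostic_set]
    )
    list(plate = plate, clinical = clinical, truth = truth)
  })
}
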