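#' Read a Ct plate from CSV
#'
#' Dialect: one row per patient; a `patient_id` column; a `spikein_ct`
#' column (cel-miR-39; must be numeric and present for every patient); one
#' column per gene, housekeeping snRNA columns carrying the prefix `HK_`.
#' Masked wells are the sentinel `Undetermined` (any letter case) or an
#' empty field. Any other non-numeric cell is an error reported with its
#' line number.
#'
#' @param path CSV file path.
#' @return A [ct_plate()].
#' @export
read_plate <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  need <- c("patient_id", "spikein_ct")
  miss <- setdiff(need, names(raw))
  if (length(miss)) stop("plate file lacks column(s): ",
                         paste(miss, collapse = ", "))
  ids <- raw$patient_id
  if (anyDuplicated(ids)) stop("duplicate patient ids in plate file")
  spike <- suppressWarnings(as.numeric(raw$spikein_ct))
  if (any(is.na(spike)))
    stop("non-numeric spike-in Ct at line(s): ",
         paste(which(is.na(spike)) + 1L, collapse = ", "))
  gene_cols <- setdiff(names(raw), need)
  hk <- gene_cols[startsWith(gene_cols, "HK_")]
  targets <- setdiff(gene_cols, hk)
  parse_col <- function(col) {
    v <- raw[[col]]
    masked <- trimws(v) == "" | tolower(trimws(v)) == "undetermined"
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!masked & is.na(num))
    if (length(bad))
      stop("malformed value(s) in column '", col, "' at line(s): ",
           paste(bad + 1L, collapse = ", "))
    num[masked] <- NA_real_
    list(ct = num, masked = masked)
  }
  parsed <- lapply(gene_cols, parse_col)
  ct <- do.call(cbind, lapply(parsed, `[[`, "ct"))
  und <- do.call(cbind, lapply(parsed, `[[`, "masked"))
  colnames(ct) <- colnames(und) <- gene_cols
  ct_plate(ct[, c(targets, hk), drop = FALSE],
           und[, c(targets, hk), drop = FALSE],
           ids, targets, sub("^HK_", "", hk), spike)
}

#' Write a Ct plate to CSV
#'
#' Inverse of [read_plate()]: round-trip stable on values and masks
#' (`Undetermined` sentinel for masked wells).
#'
#' @param plate A [ct_plate()].
#' @param path Output CSV path.
#' @export
write_plate <- function(plate, path) {
  stopifnot(inherits(plate, "ct_plate"))
  fmt <- function(col, mask) ifelse(mask, "Undetermined",
                                    formatC(col, digits = 15, format = "g"))
  df <- data.frame(patient_id = plate$patient_ids,
                   spikein_ct = formatC(plate$spikein_ct, digits = 15,
                                        format = "g"),
                   check.names = FALSE, stringsAsFactors = FALSE)
  for (g in plate$target_ids)
    df[[g]] <- fmt(plate$ct[, g], plate$undetermined[, g])
  for (g in plate$housekeeping_ids)
    df[[paste0("HK_", g)]] <- fmt(plate$ct[, g], plate$undetermined[, g])
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a clinical table from CSV
#'
#' Required columns: `patient_id`, `histotype` (SCC/ADC), `stage` (I, II,
#' IIIA; IA/IB/IIA/IIB are collapsed to their 3-level parent),
#' `age_at_surgery`, `gender`, `smoking` (never/ex/current), `chemo`,
#' `radio`, `dfs_time`, `dfs_event`, `os_time`, `os_event`. Times are
#' months and must be positive; event columns are logical (or 0/1).
#'
#' @param path CSV file path.
#' @param plate Optional [ct_plate()]; patient ids must then match exactly
#'   (the set difference is reported otherwise).
#' @return A data frame with typed columns.
#' @export
read_clinical <- function(path, plate = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "histotype", "stage", "age_at_surgery", "gender",
            "smoking", "chemo", "radio", "dfs_time", "dfs_event",
            "os_time", "os_event")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("clinical file lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$patient_id)) stop("duplicate patient ids in clinical file")
  df$stage <- sub("^(I{1,2})[AB]$", "\\1", df$stage)
  df$stage <- factor(df$stage, levels = c("I", "II", "IIIA"))
  if (anyNA(df$stage)) stop("invalid stage values (expected I/II/IIIA)")
  df$gender <- factor(df$gender, levels = c("female", "male"))
  df$smoking <- factor(df$smoking, levels = c("never", "ex", "current"))
  df$chemo <- as.logical(df$chemo)
  df$radio <- as.logical(df$radio)
  for (col in c("dfs_time", "os_time")) {
    if (any(!is.finite(df[[col]]) | df[[col]] <= 0))
      stop(col, " must be positive and finite")
  }
  for (col in c("dfs_event", "os_event")) df[[col]] <- as.logical(df[[col]])
  if (!is.null(plate)) {
    extra <- setdiff(df$patient_id, plate$patient_ids)
    absent <- setdiff(plate$patient_ids, df$patient_id)
    if (length(extra) || length(absent))
      stop("clinical/plate id mismatch; only in clinical: {",
           paste(extra, collapse = ", "), "}; only in plate: {",
           paste(absent, collapse = ", "), "}")
  }
  df
}

#' Write a clinical table to CSV
#' @param clinical Clinical data frame.
#' @param path Output CSV path.
#' @export
write_clinical <- function(clinical, path) {
  utils::write.csv(clinical, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Run the full per-cohort, per-endpoint analysis
#'
#' Orchestrates the whole pipeline for each requested histotype and
#' endpoint, never pooling cohorts: spike-in centring, sparse-gene
#' exclusion, differential-missingness tests, stability-ranked reference
#' selection (on complete genes only), KNN imputation, reference
#' subtraction, univariate Cox screening with BH control, the combined
#' elastic-net Cox fit, and the Simon-type validation engine. All
#' randomness derives from the master seed. When `out_dir` is given, every
#' stage writes its artifact (CSV/JSON) plus a run manifest.
#'
#' @param plate A [ct_plate()] (or path to one).
#' @param clinical A clinical data frame (or path to one).
#' @param histotypes Histotype cohorts to analyse (default: those present).
#' @param endpoints Endpoints to analyse (`"dfs"`, `"os"`).
#' @param exclusion_threshold Undetermined-fraction exclusion cut-off.
#' @param delta FDR level for the univariate screen.
#' @param alpha,max_selected,folds Elastic-net settings.
#' @param k KNN imputation neighbours.
#' @param t_star ROC landmark (months).
#' @param B Permutations per test.
#' @param seed Master seed.
#' @param out_dir Optional artifact directory.
#' @return Nested list of per-cohort, per-endpoint results, invisibly when
#'   writing artifacts.
#' @export
run_pipeline <- function(plate, clinical, histotypes = NULL,
                         endpoints = c("dfs", "os"),
                         exclusion_threshold = 0.5, delta = 0.05,
                         alpha = 0.5, max_selected = 5L, folds = 10L,
                         k = 5L, t_star = 24, B = 1000L, seed = 1L,
                         nlambda = 100L, lambda_min_ratio = 0.01,
                         out_dir = NULL) {
  if (is.character(plate)) plate <- read_plate(plate)
  if (is.character(clinical)) clinical <- read_clinical(clinical, plate)
  endpoints <- match.arg(endpoints, c("dfs", "os"), several.ok = TRUE)
  histotypes <- histotypes %||% unique(clinical$histotype)
  results <- list()
  for (h in histotypes) {
    ids <- clinical$patient_id[clinical$histotype == h]
    if (!length(ids)) stop("no patients with histotype ", h)
    pl <- plate_subset(plate, patients = ids)
    cl <- clinical[clinical$patient_id %in% ids, , drop = FALSE]

    centred <- spikein_center(pl)
    excl <- exclude_sparse(centred, exclusion_threshold)
    stab <- rank_stability(excl$plate)
    imputed <- knn_impute(excl$plate, k = k)
    expr <- delta_ct(imputed, stab)

    cohort <- list(stability = stab, missingness = excl$report,
                   references = stab$selected_references,
                   n_patients = length(ids),
                   n_tests = ncol(expr))
    for (ep in endpoints) {
      diffmiss <- test_differential_missingness(excl$plate, cl, ep)
      screen <- screen_mirnas(expr, cl, ep, delta = delta)
      fit <- fit_elastic_net_cox(expr, cl, ep, alpha = alpha,
                                 max_selected = max_selected, folds = folds,
                                 seed = derive_seed(seed, h, ep, "fit"),
                                 nlambda = nlambda,
                                 lambda_min_ratio = lambda_min_ratio)
      report <- validate_model(expr, cl, ep, B = B,
                               seed = derive_seed(seed, h, ep, "validate"),
                               model_config = list(alpha = alpha,
                                                   max_selected = max_selected,
                                                   folds = folds,
                                                   nlambda = nlambda,
                                                   lambda_min_ratio = lambda_min_ratio),
                               t_star = t_star)
      fu <- median_followup(clinical_times(cl, ep), clinical_events(cl, ep))
      cohort[[ep]] <- list(differential_missingness = diffmiss,
                           screen = screen, fit = fit, validation = report,
                           median_followup = fu)
    }
    results[[h]] <- cohort
  }
  if (!is.null(out_dir)) {
    write_report(out_dir, results,
                 config = list(histotypes = histotypes, endpoints = endpoints,
                               exclusion_threshold = exclusion_threshold,
                               delta = delta, alpha = alpha,
                               max_selected = max_selected, folds = folds,
                               k = k, t_star = t_star, B = B, seed = seed))
    return(invisible(results))
  }
  results
}

#' Persist a pipeline result tree as CSV/JSON artifacts
#'
#' One subdirectory per histotype: stability ranking and missingness report
#' as CSV; per endpoint the screening table (CSV), the fitted model and the
#' validation report (JSON); plus a top-level `manifest.json` echoing the
#' configuration.
#'
#' @param dir Output directory (created if needed).
#' @param results Return value of [run_pipeline()].
#' @param config Configuration echo stored in the manifest.
#' @export
write_report <- function(dir, results, config = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (h in names(results)) {
    hd <- file.path(dir, h)
    dir.create(hd, showWarnings = FALSE)
    co <- results[[h]]
    utils::write.csv(co$stability$ranking, file.path(hd, "stability.csv"),
                     row.names = FALSE)
    utils::write.csv(co$missingness, file.path(hd, "missingness.csv"),
                     row.names = FALSE)
    for (ep in intersect(c("dfs", "os"), names(co))) {
      res <- co[[ep]]
      utils::write.csv(res$screen,
                       file.path(hd, sprintf("screen_%s.csv", ep)),
                       row.names = FALSE)
      utils::write.csv(res$differential_missingness,
                       file.path(hd, sprintf("missingness_tests_%s.csv", ep)),
                       row.names = FALSE)
      fit <- res$fit
      jsonlite::write_json(
        list(endpoint = fit$endpoint, alpha = fit$alpha,
             max_selected = fit$max_selected,
             lambda_selected = fit$lambda_selected,
             lambda_path = fit$lambda_path,
             beta = as.list(fit$beta[fit$beta != 0]),
             selected_mirnas = fit$selected_mirnas,
             cv = fit$cv),
        file.path(hd, sprintf("fit_%s.json", ep)),
        auto_unbox = TRUE, digits = NA, null = "null")
      v <- res$validation
      jsonlite::write_json(
        list(endpoint = v$endpoint, t_star = v$t_star, B = v$B,
             cv_pi = as.list(v$cv_pi),
             risk_group = as.list(stats::setNames(as.character(v$risk_group),
                                                  names(v$risk_group))),
             cv_logrank_stat = v$cv_logrank_stat,
             p_logrank_perm = v$p_logrank_perm,
             cv_auc = v$cv_auc, p_auc_vs_half = v$p_auc_vs_half,
             p_added_value_logrank = v$p_added_value_logrank,
             p_added_value_auc = v$p_added_value_auc,
             median_followup = res$median_followup),
        file.path(hd, sprintf("validation_%s.json", ep)),
        auto_unbox = TRUE, digits = NA, null = "null")
      utils::write.csv(v$cv_roc, file.path(hd, sprintf("roc_%s.csv", ep)),
                       row.names = FALSE)
      utils::write.csv(v$cv_km$curve, file.path(hd, sprintf("km_%s.csv", ep)),
                       row.names = FALSE)
    }
  }
  jsonlite::write_json(
    list(package = "miRsurv",
         version = as.character(utils::packageVersion("miRsurv")),
         r_version = R.version.string,
         timestamp = format(Sys.time(), tz = "UTC"),
         config = config),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
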