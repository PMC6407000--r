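#' Exclude targets with too many undetermined wells
#'
#' Target miRNAs whose fraction of undetermined wells strictly exceeds the
#' threshold (default 0.5, i.e. ">50%") are removed from the plate.
#' Housekeeping wells are never excluded here.
#'
#' @param plate A [ct_plate()].
#' @param threshold Exclusion threshold in (0, 1); strict inequality.
#' @return A list: `plate` (targets above threshold removed) and `report`
#'   (data frame with per-target undetermined fraction and exclusion flag).
#' @export
exclude_sparse <- function(plate, threshold = 0.5) {
  stopifnot(inherits(plate, "ct_plate"), threshold > 0, threshold < 1)
  frac <- colMeans(plate$undetermined[, plate$target_ids, drop = FALSE])
  excluded <- frac > threshold
  report <- data.frame(gene = plate$target_ids,
                       undetermined_fraction = unname(frac),
                       excluded = unname(excluded), row.names = NULL)
  keep <- c(plate$target_ids[!excluded], plate$housekeeping_ids)
  if (all(excluded)) warning("all target miRNAs excluded")
  list(plate = plate_subset(plate, genes = keep), report = report)
}

#' Test for outcome-associated missingness
#'
#' For each gene, cross-tabulates undetermined status against the event
#' indicator of the chosen endpoint and tests for a different proportion of
#' undetermined wells between patients with and without events: Fisher's
#' exact test when any expected cell count is 5 or below, otherwise
#' Pearson's chi-square without continuity correction. Genes with a degenerate margin
#' (never or always undetermined, or all patients sharing one event status)
#' are reported as not applicable.
#'
#' @param plate A [ct_plate()].
#' @param clinical Clinical table matching the plate's patients.
#' @param endpoint `"dfs"` or `"os"`.
#' @return Data frame: gene, 2x2 counts, test used, statistic, p-value.
#' @export
test_differential_missingness <- function(plate, clinical,
                                          endpoint = c("dfs", "os")) {
  endpoint <- match.arg(endpoint)
  ev <- clinical_events(clinical, endpoint, plate$patient_ids)
  genes <- c(plate$target_ids, plate$housekeeping_ids)
  rows <- lapply(genes, function(g) {
    und <- plate$undetermined[, g]
    n11 <- sum(und & ev); n10 <- sum(und & !ev)
    n01 <- sum(!und & ev); n00 <- sum(!und & !ev)
    out <- data.frame(gene = g, undet_event = n11, undet_noevent = n10,
                      det_event = n01, det_noevent = n00,
                      test = NA_character_, statistic = NA_real_,
                      p_value = NA_real_, stringsAsFactors = FALSE)
    tab <- matrix(c(n11, n01, n10, n00), 2)
    if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
      out$test <- "not applicable"
      return(out)
    }
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected <= 5)) {
      ft <- stats::fisher.test(tab)
      out$test <- "fisher"; out$p_value <- ft$p.value
    } else {
      ch <- stats::chisq.test(tab, correct = FALSE)
      out$test <- "chisq"; out$statistic <- unname(ch$statistic)
      out$p_value <- ch$p.value
    }
    out
  })
  do.call(rbind, rows)
}

#' K-nearest-neighbour imputation of undetermined wells
#'
#' Distances between patients are root-mean-square Ct differences over the
#' genes observed in both (scaling by the number of shared genes, so
#' patients with different missingness patterns remain comparable). Each
#' masked well is filled with the unweighted mean of the k nearest patients
#' in which that gene is observed; observed wells are never altered.
#' Intended to run on spike-in-centred Ct, after sparse-gene exclusion and
#' before reference subtraction.
#'
#' @param plate A [ct_plate()].
#' @param k Number of neighbours (default 5).
#' @return The completed `ct_plate` (no undetermined wells) with attribute
#'   `"imputed"`: a two-column matrix of the filled (patient, gene) cells.
#' @export
knn_impute <- function(plate, k = 5L) {
  stopifnot(inherits(plate, "ct_plate"), k >= 1L)
  obs <- !plate$undetermined
  n_obs <- colSums(obs)
  short <- colnames(obs)[n_obs < k]
  if (length(short))
    stop("genes observed in fewer than k = ", k, " patients: ",
         paste(short, collapse = ", "),
         "; lower k or exclude them first")
  if (!any(plate$undetermined)) return(plate)
  ct <- plate$ct
  n <- nrow(ct)
  # pairwise RMS distance over shared observed genes, computed via masked
  # cross-products: sum_shared (xi - xj)^2 = xi^2.W' + W.xj^2' - 2 xi.xj'
  a <- ct; a[!obs] <- 0
  w <- obs * 1
  a2w <- (a^2) %*% t(w)
  ss <- a2w + t(a2w) - 2 * a %*% t(a)
  shared <- w %*% t(w)
  d <- sqrt(pmax(ss, 0) / shared)  # NaN (0/0) where no shared genes
  d[shared == 0] <- Inf
  diag(d) <- Inf
  cells <- which(plate$undetermined, arr.ind = TRUE)
  filled <- ct
  for (r in seq_len(nrow(cells))) {
    j <- cells[r, 1L]; g <- cells[r, 2L]
    donors <- which(obs[, g])
    ord <- donors[order(d[j, donors], donors)]
    filled[j, g] <- mean(ct[ord[seq_len(k)], g])
  }
  out <- ct_plate(filled, matrix(FALSE, n, ncol(ct)), plate$patient_ids,
                  plate$target_ids, plate$housekeeping_ids, plate$spikein_ct,
                  centered = plate$centered)
  attr(out, "imputed") <- cells
  out
}

# Event indicator of an endpoint, aligned to `ids`.
clinical_events <- function(clinical, endpoint, ids = clinical$patient_id) {
  col <- paste0(endpoint, "_event")
  stopifnot(col %in% names(clinical),
            all(ids %in% clinical$patient_id))
  ev <- clinical[[col]][match(ids, clinical$patient_id)]
  if (anyNA(ev)) stop("every patient needs an event indicator for ", endpoint)
  as.logical(ev)
}

clinical_times <- function(clinical, endpoint, ids = clinical$patient_id) {
  col <- paste0(endpoint, "_time")
  stopifnot(col %in% names(clinical), all(ids %in% clinical$patient_id))
  clinical[[col]][match(ids, clinical$patient_id)]
}
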