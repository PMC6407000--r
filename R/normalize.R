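#' Centre a plate on the exogenous spike-in
#'
#' For each patient the deviation of their cel-miR-39 Ct from the cohort mean
#' is subtracted from every well, correcting technical recovery differences
#' between extractions. The spike-in Ct itself is re-centred as well, so the
#' operation is idempotent. The applied offsets average zero across patients
#' by construction.
#'
#' @param plate A [ct_plate()] with at least two patients.
#' @return The centred `ct_plate` (`centered = TRUE`).
#' @export
spikein_center <- function(plate) {
  stopifnot(inherits(plate, "ct_plate"))
  if (length(plate$patient_ids) < 2L)
    stop("spike-in centring needs >= 2 patients (cohort mean undefined)")
  offset <- plate$spikein_ct - mean(plate$spikein_ct)
  ct <- plate$ct - offset  # recycled by row: offset is per patient
  ct[plate$undetermined] <- NA_real_
  ct_plate(ct, plate$undetermined, plate$patient_ids, plate$target_ids,
           plate$housekeeping_ids, plate$spikein_ct - offset, centered = TRUE)
}

#' Rank candidate reference genes by expression stability
#'
#' A model-based stability score in the NormFinder tradition: the additive
#' two-way model `ct[j, g] = gene[g] + sample[j] + residual` is fitted by
#' row/column means and each gene's score is the standard deviation of its
#' residuals across patients, with the small-sample correction factor
#' `G/(G-1)` applied to the variance (G = number of candidates). Lower
#' scores mean more stable genes; the two minimizers are the selected
#' endogenous references. Candidates with any undetermined well are dropped
#' before fitting.
#'
#' When `groups` is supplied, a grouped variant is computed instead: per
#' gene, the squared group-mean residual (bias) plus the within-group
#' residual sampling variance, averaged over groups.
#'
#' @param plate A [ct_plate()], normally already spike-in centred.
#' @param candidate_ids Genes to rank; default all target miRNAs.
#' @param groups Optional factor (one level per patient) for the grouped
#'   variant.
#' @return A list of class `stability_ranking`: `ranking` (data frame sorted
#'   by stability, ties broken lexicographically by gene id),
#'   `selected_references` (two gene ids), `dropped` (incomplete candidates).
#' @export
rank_stability <- function(plate, candidate_ids = NULL, groups = NULL) {
  stopifnot(inherits(plate, "ct_plate"))
  candidate_ids <- candidate_ids %||% plate$target_ids
  stopifnot(all(candidate_ids %in% colnames(plate$ct)))
  complete <- candidate_ids[colSums(plate$undetermined[, candidate_ids,
                                                       drop = FALSE]) == 0L]
  dropped <- setdiff(candidate_ids, complete)
  if (length(complete) < 3L)
    stop("need >= 3 complete candidate genes; dropped (incomplete): ",
         paste(dropped, collapse = ", "))
  m <- plate$ct[, complete, drop = FALSE]
  G <- ncol(m)
  resid <- m - outer(rowMeans(m), colMeans(m), "+") + mean(m)
  if (is.null(groups)) {
    stability <- sqrt(G / (G - 1) * apply(resid, 2, stats::var))
  } else {
    groups <- as.factor(groups)
    stopifnot(length(groups) == nrow(m))
    stability <- apply(resid, 2, function(r) {
      per <- tapply(r, groups, function(v)
        mean(v)^2 + stats::var(v) / length(v))
      sqrt(mean(per))
    })
  }
  ord <- order(stability, complete)
  ranking <- data.frame(gene = complete[ord],
                        stability = unname(stability[ord]),
                        selected = seq_along(complete) %in% 1:2,
                        row.names = NULL)
  structure(list(ranking = ranking,
                 selected_references = ranking$gene[1:2],
                 dropped = dropped),
            class = "stability_ranking")
}

#' @export
print.stability_ranking <- function(x, ...) {
  cat("<stability_ranking> selected references:",
      paste(x$selected_references, collapse = ", "), "\n")
  print(utils::head(x$ranking, 5))
  invisible(x)
}

#' Reference-gene subtraction: Ct to -dCt expression
#'
#' Subtracts, per patient, the mean Ct of the two selected reference genes
#' from every target Ct (dCt) and returns its negative, the relative
#' expression scale on which all downstream statistics operate (higher
#' -dCt = more abundant). The reference genes are removed from the output;
#' housekeeping snRNA wells are not part of the expression matrix.
#'
#' @param plate A spike-in-centred [ct_plate()].
#' @param refs A [rank_stability()] result or a character vector of two
#'   reference gene ids, unmasked in every patient.
#' @return A patients x miRNAs numeric matrix of -dCt values with attribute
#'   `"references"`; masked target wells stay `NA`.
#' @export
delta_ct <- function(plate, refs) {
  stopifnot(inherits(plate, "ct_plate"))
  if (inherits(refs, "stability_ranking")) refs <- refs$selected_references
  stopifnot(is.character(refs), length(refs) == 2L,
            all(refs %in% colnames(plate$ct)))
  if (!plate$centered)
    warning("plate is not spike-in centred; call spikein_center() first")
  bad <- plate$patient_ids[rowSums(plate$undetermined[, refs, drop = FALSE]) > 0]
  if (length(bad))
    stop("reference gene undetermined for patients: ",
         paste(bad, collapse = ", "))
  ref_mean <- rowMeans(plate$ct[, refs, drop = FALSE])
  keep <- setdiff(plate$target_ids, refs)
  value <- -(plate$ct[, keep, drop = FALSE] - ref_mean)
  attr(value, "references") <- refs
  value
}
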