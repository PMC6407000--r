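#' Construct a Ct plate
#'
#' A `ct_plate` holds raw (or spike-in-centred) qPCR cycle-threshold values
#' for a cohort: one row per patient, one column per assayed gene (target
#' miRNAs followed by housekeeping snRNAs), plus the per-patient Ct of the
#' exogenous spike-in (cel-miR-39). Wells that never crossed the fluorescence
#' threshold ("undetermined") are recorded in a logical mask and carry `NA`
#' in the Ct matrix.
#'
#' @param ct Numeric matrix, patients x genes; `NA` exactly where
#'   `undetermined` is `TRUE`.
#' @param undetermined Logical matrix aligned to `ct`.
#' @param patient_ids,target_ids,housekeeping_ids Character identifiers.
#' @param spikein_ct Numeric vector of spike-in Ct values, one per patient;
#'   must be finite (the spike-in is an extraction control, never missing).
#' @param centered Logical; `TRUE` once [spikein_center()] has been applied.
#' @return An object of class `ct_plate`.
#' @export
ct_plate <- function(ct, undetermined, patient_ids, target_ids,
                     housekeeping_ids = character(0), spikein_ct,
                     centered = FALSE) {
  ct <- as.matrix(ct)
  undetermined <- as.matrix(undetermined)
  gene_ids <- c(target_ids, housekeeping_ids)
  stopifnot(
    nrow(ct) == length(patient_ids),
    ncol(ct) == length(gene_ids),
    identical(dim(ct), dim(undetermined)),
    length(spikein_ct) == length(patient_ids)
  )
  if (anyDuplicated(patient_ids)) stop("duplicate patient ids")
  if (anyDuplicated(gene_ids)) stop("duplicate gene ids")
  if (!all(is.finite(spikein_ct)))
    stop("spike-in Ct must be finite for every patient (extraction control)")
  mode(undetermined) <- "logical"
  if (any(undetermined & !is.na(ct)) || any(!undetermined & !is.finite(ct)))
    stop("ct must be finite where undetermined is FALSE and NA where TRUE")
  dimnames(ct) <- dimnames(undetermined) <- list(patient_ids, gene_ids)
  names(spikein_ct) <- patient_ids
  structure(
    list(ct = ct, undetermined = undetermined,
         patient_ids = as.character(patient_ids),
         target_ids = as.character(target_ids),
         housekeeping_ids = as.character(housekeeping_ids),
         spikein_ct = spikein_ct, centered = isTRUE(centered)),
    class = "ct_plate"
  )
}

#' @export
print.ct_plate <- function(x, ...) {
  cat(sprintf(
    "<ct_plate> %d patients x (%d targets + %d housekeeping); %d undetermined wells (%.1f%%)%s\n",
    length(x$patient_ids), length(x$target_ids), length(x$housekeeping_ids),
    sum(x$undetermined), 100 * mean(x$undetermined),
    if (x$centered) "; spike-in centred" else ""))
  invisible(x)
}

#' Subset a plate by patients and/or genes
#'
#' @param plate A [ct_plate()].
#' @param patients,genes Character vectors of ids to keep (`NULL` keeps all).
#' @return A `ct_plate`.
#' @export
plate_subset <- function(plate, patients = NULL, genes = NULL) {
  patients <- patients %||% plate$patient_ids
  genes <- genes %||% c(plate$target_ids, plate$housekeeping_ids)
  stopifnot(all(patients %in% plate$patient_ids))
  ct_plate(plate$ct[patients, genes, drop = FALSE],
           plate$undetermined[patients, genes, drop = FALSE],
           patients,
           intersect(plate$target_ids, genes),
           intersect(plate$housekeeping_ids, genes),
           plate$spikein_ct[patients],
           centered = plate$centered)
}
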