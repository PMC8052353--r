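#' Compare a patient's cfDNA alteration sets at two timepoints
#'
#' Contrasts the somatic cfDNA alterations detected at initial diagnosis
#' with those detected just before death: alterations found at both
#' timepoints are persistent, those seen only at diagnosis were lost
#' during the clinical course, and those seen only before death were
#' newly gained.
#'
#' @param diagnosis_set,death_set somatic cfDNA \code{variant_set}s of
#'   the same patient.
#' @return object of class \code{longitudinal_summary} with counts
#'   \code{n_diagnosis, n_death, n_persistent, n_lost, n_gained} and
#'   \code{persistence_pct} (= 100 * persistent / diagnosis; \code{NA}
#'   and flagged when no alterations were detected at diagnosis).
#' @export
compare_timepoints <- function(diagnosis_set, death_set) {
  stopifnot(inherits(diagnosis_set, "variant_set"),
            inherits(death_set, "variant_set"))
  if (!is.na(diagnosis_set$patient_id) && !is.na(death_set$patient_id) &&
      diagnosis_set$patient_id != death_set$patient_id)
    .stopf("patient mismatch between timepoints")
  dk <- variant_keys(diagnosis_set)
  xk <- variant_keys(death_set)
  n_persistent <- sum(dk %in% xk)
  structure(
    list(patient_id = diagnosis_set$patient_id,
         n_diagnosis = length(dk), n_death = length(xk),
         n_persistent = n_persistent,
         n_lost = length(dk) - n_persistent,
         n_gained = length(xk) - n_persistent,
         persistence_pct = if (length(dk) > 0) 100 * n_persistent / length(dk)
                           else NA_real_,
         undefined = length(dk) == 0),
    class = "longitudinal_summary"
  )
}

#' @export
print.longitudinal_summary <- function(x, ...) {
  cat(sprintf("<longitudinal_summary> patient %s\n", x$patient_id))
  cat(sprintf("  diagnosis %d | persistent %d | before death %d (lost %d, gained %d)\n",
              x$n_diagnosis, x$n_persistent, x$n_death, x$n_lost, x$n_gained))
  cat(if (x$undefined) "  persistence undefined (no alterations at diagnosis)\n"
      else sprintf("  persistence %.1f%%\n", round_half_up(x$persistence_pct, 1)))
  invisible(x)
}

#' Variants presaging metastasis in diagnosis-time cfDNA
#'
#' Finds the alterations detected in cfDNA at initial diagnosis that at
#' autopsy were present in at least one metastatic lesion but never in
#' the primary tumor — i.e. alterations of (future) metastases that were
#' already circulating at diagnosis.
#'
#' @param cohort a somatic, filtered \code{patient_cohort} with a
#'   diagnosis-timepoint cfDNA set, a primary tumor set, and at least
#'   one metastasis set.
#' @param metastasis_ids optional sample ids restricting which
#'   metastases count as "new" (default: all metastasis sets).
#' @return data.frame with one row per (key, carrying metastasis):
#'   columns \code{key, gene, variant_type, effect, impact, organ,
#'   sample_id, vaf}; zero rows when no variant qualifies.
#' @export
find_presaging_variants <- function(cohort, metastasis_ids = NULL) {
  stopifnot(inherits(cohort, "patient_cohort"))
  if (!"diagnosis" %in% names(cohort$cfdna_sets))
    .stopf("patient '%s' has no diagnosis-timepoint cfDNA set", cohort$patient_id)
  kinds <- vapply(cohort$tumor_sets, function(s) s$kind, character(1))
  if (!any(kinds == "tumor_primary"))
    .stopf("patient '%s' has no primary tumor set", cohort$patient_id)
  mets <- cohort$tumor_sets[kinds == "tumor_metastasis"]
  if (!is.null(metastasis_ids))
    mets <- mets[names(mets) %in% metastasis_ids]
  if (length(mets) == 0)
    .stopf("patient '%s' has no (selected) metastasis set", cohort$patient_id)

  diag_keys <- variant_keys(cohort$cfdna_sets[["diagnosis"]])
  primary_keys <- variant_keys(cohort$tumor_sets[[which(kinds == "tumor_primary")[1]]])
  candidate <- setdiff(intersect(diag_keys,
                                 unlist(lapply(mets, variant_keys),
                                        use.names = FALSE)),
                       primary_keys)
  rows <- do.call(rbind, lapply(mets, function(m) {
    hit <- m$calls[m$calls$key %in% candidate, , drop = FALSE]
    if (nrow(hit) == 0) return(NULL)
    data.frame(key = hit$key, gene = hit$gene, variant_type = hit$variant_type,
               effect = hit$effect, impact = hit$impact,
               organ = m$organ, sample_id = m$sample_id, vaf = hit$vaf,
               stringsAsFactors = FALSE)
  }))
  if (is.null(rows))
    rows <- data.frame(key = character(), gene = character(),
                       variant_type = character(), effect = character(),
                       impact = character(), organ = character(),
                       sample_id = character(), vaf = numeric(),
                       stringsAsFactors = FALSE)
  rows <- rows[order(rows$key, rows$sample_id), , drop = FALSE]
  rownames(rows) <- NULL
  rows
}
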