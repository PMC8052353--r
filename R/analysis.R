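#' Full tumor/cfDNA concordance analysis for one patient
#'
#' Runs the complete single-patient analysis: germline subtraction and
#' confidence filtering, per-lesion tumor/cfDNA overlap counts and
#' detection rates, truncal/shared/individual classification with
#' class-stratified cfDNA detection and pairwise tests, per-lesion VAF
#' stratification of detected versus undetected alterations, the
#' cfDNA-only VAF comparison, and the genes carrying identical
#' alterations in tumor and plasma.
#'
#' @param cohort a \code{patient_cohort} of raw (unfiltered) sets.
#' @param min_tier confidence tier analyses run on; default
#'   \code{"high"}.
#' @param cfdna_timepoint cfDNA sample defining detection; default
#'   \code{"pre_mortem"}.
#' @param rule classification rule, see [classify_mutations()].
#' @param functional_only restrict all sets to protein-altering calls
#'   first (see [functional_filter()]).
#' @return object of class \code{cf_concordance}.
#' @export
cf_concordance <- function(cohort, min_tier = "high",
                           cfdna_timepoint = "pre_mortem",
                           rule = "at_least_two", functional_only = FALSE) {
  stopifnot(inherits(cohort, "patient_cohort"))
  som <- somatic_cohort(cohort, min_tier)
  if (functional_only) {
    som$tumor_sets <- lapply(som$tumor_sets, functional_filter)
    som$cfdna_sets <- lapply(som$cfdna_sets, functional_filter)
  }
  cf <- cfdna_at(som, cfdna_timepoint)
  venns <- lapply(som$tumor_sets, venn, cfdna_set = cf)
  per_sample <- do.call(rbind, lapply(venns, function(v)
    data.frame(patient_id = som$patient_id, sample_id = v$sample_id,
               n_tumor = v$n_tumor, n_both = v$n_common,
               n_tumor_only = v$n_tumor_only, n_cfdna_only = v$n_cfdna_only,
               detection_rate = v$detection_rate, stringsAsFactors = FALSE)))
  rownames(per_sample) <- NULL
  classified <- classify_mutations(som, cfdna_timepoint, rule)
  strata <- lapply(som$tumor_sets, stratify_vaf, cfdna_set = cf)
  structure(
    list(patient_id = som$patient_id,
         n_cfdna = length(cf),
         per_sample = per_sample,
         venns = venns,
         classified = classified,
         class_detection = if (nrow(classified)) per_class_detection(classified),
         vaf_strata = strata,
         cfdna_only = cfdna_only_vaf_comparison(som, cfdna_timepoint),
         genes_shared = genes_shared_tumor_cfdna(som, cfdna_timepoint),
         somatic = som),
    class = "cf_concordance"
  )
}

#' @export
print.cf_concordance <- function(x, ...) {
  cat(sprintf("<cf_concordance> patient %s: %d tumor lesion(s), %d cfDNA alterations\n",
              x$patient_id, nrow(x$per_sample), x$n_cfdna))
  ps <- x$per_sample
  for (i in seq_len(nrow(ps)))
    cat(sprintf("  %-16s tumor %5d | both %4d | cfDNA-only %4d | detection %s\n",
                ps$sample_id[i], ps$n_tumor[i], ps$n_both[i], ps$n_cfdna_only[i],
                if (is.na(ps$detection_rate[i])) "NA" else
                  sprintf("%.1f%%", round_half_up(100 * ps$detection_rate[i], 1))))
  if (!is.null(x$class_detection)) print(x$class_detection)
  co <- x$cfdna_only
  cat(sprintf("  cfDNA-only VAF %s vs tumor-corroborated %s (n=%d/%d)\n",
              .fmt_pct(co$mean_vaf_cfdna_only), .fmt_pct(co$mean_vaf_in_tumor),
              co$n_cfdna_only, co$n_in_tumor))
  invisible(x)
}

.fmt_pct <- function(v) if (is.na(v)) "NA" else
  sprintf("%.1f%%", round_half_up(100 * v, 1))

#' @export
summary.cf_concordance <- function(object, ...) {
  strata <- do.call(rbind, lapply(object$vaf_strata, function(s)
    data.frame(patient_id = object$patient_id, lesion = s$lesion_id,
               n_detected = s$n_detected, n_undetected = s$n_undetected,
               mean_vaf_detected = s$mean_detected,
               ci_lo_detected = s$ci95_detected[1],
               ci_hi_detected = s$ci95_detected[2],
               mean_vaf_undetected = s$mean_undetected,
               ci_lo_undetected = s$ci95_undetected[1],
               ci_hi_undetected = s$ci95_undetected[2],
               u_statistic = s$u_statistic, p_value = s$p_value,
               stringsAsFactors = FALSE)))
  rownames(strata) <- NULL
  list(per_sample = object$per_sample,
       class_summary = if (!is.null(object$class_detection))
         cbind(patient_id = object$patient_id, object$class_detection$summary),
       class_tests = if (!is.null(object$class_detection))
         cbind(patient_id = object$patient_id, object$class_detection$tests),
       vaf_stratification = strata,
       cfdna_only = object$cfdna_only,
       genes_shared = object$genes_shared)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Write one patient's concordance outputs
#'
#' Emits the machine-readable components of a [cf_concordance()] result:
#' per-sample concordance counts, class summary and pairwise tests,
#' per-lesion VAF stratification, and the per-patient Venn counts, each
#' as TSV with a JSON twin.
#'
#' @param x a \code{cf_concordance} object.
#' @param dir output directory (created if needed).
#' @return character vector of files written, invisibly.
#' @export
write_concordance_outputs <- function(x, dir) {
  stopifnot(inherits(x, "cf_concordance"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  s <- summary(x)
  ps <- s$per_sample
  ps$detection_rate_pct <- round_half_up(100 * ps$detection_rate, 1)
  files <- c(
    .write_tsv(ps, file.path(dir, "per_sample_concordance.tsv")),
    .write_tsv(as.data.frame(x$classified),
               file.path(dir, "classified_variants.tsv")),
    .write_tsv(s$vaf_stratification, file.path(dir, "vaf_stratification.tsv"))
  )
  if (!is.null(s$class_summary)) {
    files <- c(files,
               .write_tsv(s$class_summary, file.path(dir, "class_summary.tsv")),
               .write_tsv(s$class_tests, file.path(dir, "class_tests.tsv")))
  }
  venn_json <- file.path(dir, "venn_counts.json")
  jsonlite::write_json(
    lapply(x$venns, function(v) v[c("n_tumor", "n_cfdna", "n_common",
                                    "n_tumor_only", "n_cfdna_only",
                                    "detection_rate")]),
    venn_json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  json_twin <- file.path(dir, "per_sample_concordance.json")
  jsonlite::write_json(ps, json_twin, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(files, venn_json, json_twin))
}

#' Join component outputs into one patient-level report
#'
#' Reads the component TSVs produced by [write_concordance_outputs()]
#' (and optionally a longitudinal summary) from \code{outputs_dir},
#' cross-checks their counts for internal consistency, and writes
#' \code{patient_report.tsv} (with a JSON twin): one row per patient
#' with aggregate concordance, class and VAF numbers. Inconsistent
#' component counts abort with an error; nothing is silently
#' reconciled.
#'
#' @param outputs_dir directory holding the component TSVs.
#' @return the report data.frame, invisibly.
#' @export
assemble_report <- function(outputs_dir) {
  need <- function(f) {
    p <- file.path(outputs_dir, f)
    if (!file.exists(p)) .stopf("missing component file: %s", p)
    utils::read.delim(p, stringsAsFactors = FALSE)
  }
  ps <- need("per_sample_concordance.tsv")
  cl <- need("class_summary.tsv")
  vs <- need("vaf_stratification.tsv")

  # consistency: every report number must be recomputable from components
  bad <- which(ps$n_tumor != ps$n_both + ps$n_tumor_only)
  if (length(bad))
    .stopf("inconsistent per-sample counts for sample '%s'", ps$sample_id[bad[1]])
  rate <- ifelse(ps$n_tumor > 0, ps$n_both / ps$n_tumor, NA)
  if (any(abs(rate - ps$detection_rate) > 1e-9, na.rm = TRUE))
    .stopf("detection_rate disagrees with counts in per_sample_concordance.tsv")
  if (any(cl$n_in_cfdna > cl$n_total))
    .stopf("class_summary.tsv: n_in_cfdna exceeds n_total")
  # VAF strata exclude CNV and VAF-less calls, so per lesion they can
  # never exceed the lesion's somatic total
  strat_n <- vs$n_detected + vs$n_undetected
  tumor_n <- ps$n_tumor[match(vs$lesion, ps$sample_id)]
  if (any(strat_n > tumor_n, na.rm = TRUE))
    .stopf("vaf_stratification.tsv: strata exceed lesion totals for '%s'",
           vs$lesion[which(strat_n > tumor_n)[1]])
  long_path <- file.path(outputs_dir, "longitudinal_summary.tsv")
  lo <- if (file.exists(long_path))
    utils::read.delim(long_path, stringsAsFactors = FALSE)

  rows <- lapply(split(ps, ps$patient_id), function(p) {
    pid <- p$patient_id[1]
    clp <- cl[cl$patient_id == pid, , drop = FALSE]
    data.frame(
      patient_id = pid,
      n_samples = nrow(p),
      n_tumor_alterations = sum(p$n_tumor),
      n_both = sum(p$n_both),
      n_cfdna_only = p$n_cfdna_only[1],
      mean_detection_rate_pct = round_half_up(
        100 * mean(p$detection_rate, na.rm = TRUE), 1),
      n_truncal = .class_n(clp, "TRUNCAL"), n_shared = .class_n(clp, "SHARED"),
      n_individual = .class_n(clp, "INDIVIDUAL"),
      persistence_pct = if (!is.null(lo) && pid %in% lo$patient_id)
        lo$persistence_pct[lo$patient_id == pid][1] else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  .write_tsv(report, file.path(outputs_dir, "patient_report.tsv"))
  jsonlite::write_json(report, file.path(outputs_dir, "patient_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

.class_n <- function(cl, class) {
  v <- cl$n_total[cl$class == class]
  if (length(v)) v[1] else 0L
}
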