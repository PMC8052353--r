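#' Remove germline variants from a sample's calls
#'
#' Somatic calls are obtained by excluding every alteration whose key is
#' also called in the patient's matched germline (whole-blood) DNA. The
#' operation is idempotent and commutes with [filter_confidence()].
#'
#' @param x tumor or cfDNA \code{variant_set}.
#' @param germline germline \code{variant_set} of the same patient, or
#'   \code{NULL} (input returned unchanged).
#' @return \code{variant_set} with germline keys removed.
#' @export
subtract_germline <- function(x, germline) {
  stopifnot(inherits(x, "variant_set"))
  if (is.null(germline)) return(x)
  stopifnot(inherits(germline, "variant_set"))
  if (!is.na(x$patient_id) && !is.na(germline$patient_id) &&
      x$patient_id != germline$patient_id)
    .stopf("patient mismatch: '%s' vs germline '%s'", x$patient_id,
           germline$patient_id)
  x$calls <- x$calls[!x$calls$key %in% germline$calls$key, , drop = FALSE]
  rownames(x$calls) <- NULL
  x
}

#' Keep only calls at or above a confidence tier
#'
#' The upstream caller reports every alteration with high, medium or low
#' confidence; analyses run on high-confidence calls only by default.
#'
#' @param x a \code{variant_set}.
#' @param min_tier minimum tier to retain (\code{low < medium < high}).
#' @return filtered \code{variant_set}.
#' @export
filter_confidence <- function(x, min_tier = "high") {
  stopifnot(inherits(x, "variant_set"))
  min_tier <- match.arg(min_tier, .CONFIDENCE_LEVELS)
  x$calls <- x$calls[.confidence_at_least(x$calls$confidence, min_tier), ,
                     drop = FALSE]
  rownames(x$calls) <- NULL
  x
}

#' Tumor/cfDNA overlap counts for one sample pair
#'
#' Counts the alterations found in the tumor sample, in the cfDNA
#' sample, and in both (exact key matches), and reports the detection
#' rate: the number of tumor alterations also seen in cfDNA divided by
#' the tumor total. The rate is \code{NA} (flagged undefined) when the
#' tumor set is empty.
#'
#' @param tumor_set,cfdna_set somatic, confidence-filtered
#'   \code{variant_set}s.
#' @return object of class \code{venn_counts} with fields
#'   \code{n_tumor}, \code{n_cfdna}, \code{n_common}, \code{n_tumor_only},
#'   \code{n_cfdna_only}, \code{detection_rate},
#'   \code{rate_undefined}.
#' @export
venn <- function(tumor_set, cfdna_set) {
  tk <- variant_keys(tumor_set)
  ck <- variant_keys(cfdna_set)
  n_common <- sum(tk %in% ck)
  structure(
    list(sample_id = tumor_set$sample_id,
         n_tumor = length(tk), n_cfdna = length(ck), n_common = n_common,
         n_tumor_only = length(tk) - n_common,
         n_cfdna_only = length(ck) - n_common,
         detection_rate = if (length(tk) > 0) n_common / length(tk) else NA_real_,
         rate_undefined = length(tk) == 0),
    class = "venn_counts"
  )
}

#' @export
print.venn_counts <- function(x, ...) {
  cat(sprintf("<venn_counts> %s: tumor %d | common %d | cfDNA %d (tumor-only %d, cfDNA-only %d)\n",
              x$sample_id, x$n_tumor, x$n_common, x$n_cfdna, x$n_tumor_only,
              x$n_cfdna_only))
  cat(if (x$rate_undefined) "  detection rate undefined (empty tumor set)\n"
      else sprintf("  detection rate %.1f%%\n",
                   round_half_up(100 * x$detection_rate, 1)))
  invisible(x)
}

#' Classify tumor variants as truncal, shared or individual
#'
#' Every alteration present in at least one tumor lesion of a patient is
#' classified by the breadth of its presence across lesions:
#' \describe{
#'   \item{TRUNCAL}{present in all tumor lesions, primary and metastases;
#'     with exactly two lesions, variants present in both.}
#'   \item{SHARED}{present in more than one lesion but not all (branch
#'     mutations); impossible with only two lesions.}
#'   \item{INDIVIDUAL}{present in exactly one lesion.}
#' }
#' Each variant also records whether its key is present in the
#' designated cfDNA sample.
#'
#' @param cohort a \code{patient_cohort} whose sets are already somatic
#'   and confidence-filtered (see [somatic_cohort()]).
#' @param cfdna_timepoint which cfDNA set defines the
#'   \code{in_cfdna} flag; default \code{"pre_mortem"}.
#' @param rule \code{"at_least_two"} (default): SHARED means present in
#'   >= 2 lesions but not all. \code{"more_than_two"}: the stricter
#'   literal reading under which SHARED requires presence in > 2 lesions
#'   (but not all); two-lesion branch variants then fall to INDIVIDUAL.
#' @return data.frame of class \code{classified_variants}: one row per
#'   unique tumor key with columns \code{key, gene, n_lesions_present,
#'   mclass, in_cfdna} plus a logical presence column per tumor sample;
#'   the lesion sample ids are stored in \code{attr(, "lesions")}.
#' @export
classify_mutations <- function(cohort, cfdna_timepoint = "pre_mortem",
                               rule = c("at_least_two", "more_than_two")) {
  stopifnot(inherits(cohort, "patient_cohort"))
  rule <- match.arg(rule)
  cf <- cfdna_at(cohort, cfdna_timepoint)
  n_sets <- length(cohort$tumor_sets)
  if (n_sets < 2)
    .warnf("patient '%s' has a single tumor set: all variants reported TRUNCAL",
           cohort$patient_id)

  keysets <- lapply(cohort$tumor_sets, variant_keys)
  all_keys <- unique(unlist(keysets, use.names = FALSE))
  presence <- vapply(keysets, function(k) all_keys %in% k,
                     logical(length(all_keys)))
  if (length(all_keys) == 1L) presence <- matrix(presence, nrow = 1)
  if (length(all_keys) == 0L)
    presence <- matrix(logical(0), nrow = 0, ncol = n_sets)
  colnames(presence) <- names(cohort$tumor_sets)
  n_present <- rowSums(presence)

  shared_min <- if (rule == "at_least_two") 2L else 3L
  mclass <- ifelse(n_present == n_sets, "TRUNCAL",
                   ifelse(n_present >= shared_min, "SHARED", "INDIVIDUAL"))

  genes <- unlist(lapply(cohort$tumor_sets, function(s)
    stats::setNames(s$calls$gene, s$calls$key)), use.names = TRUE)
  out <- data.frame(
    key = all_keys,
    gene = unname(genes[match(all_keys, names(genes))]),
    n_lesions_present = as.integer(n_present),
    mclass = mclass,
    in_cfdna = all_keys %in% variant_keys(cf),
    stringsAsFactors = FALSE
  )
  out <- cbind(out, as.data.frame(presence, optional = TRUE))
  attr(out, "lesions") <- names(cohort$tumor_sets)
  attr(out, "patient_id") <- cohort$patient_id
  class(out) <- c("classified_variants", "data.frame")
  out
}

#' Class-stratified cfDNA detection rates with pairwise tests
#'
#' For each mutation class (truncal / shared / individual) reports how
#' many of the class's tumor alterations were also detected in cfDNA,
#' and compares classes pairwise with both a Yates-corrected chi-square
#' test on the 2x2 detected/undetected table and an equal-variance
#' two-sided t-test on the 0/1 detection indicators (the two tests the
#' study protocol names).
#'
#' @param classified output of [classify_mutations()]; may combine
#'   several patients via \code{rbind}.
#' @return object of class \code{class_detection} with a \code{summary}
#'   data.frame (class, n_total, n_in_cfdna, rate) and a \code{tests}
#'   data.frame (comparison, chisq_statistic, chisq_p, t_statistic, t_p).
#' @export
per_class_detection <- function(classified) {
  stopifnot(nrow(classified) > 0)
  classes <- c("TRUNCAL", "SHARED", "INDIVIDUAL")
  n_total <- vapply(classes, function(cl) sum(classified$mclass == cl), integer(1))
  n_det <- vapply(classes, function(cl)
    sum(classified$mclass == cl & classified$in_cfdna), integer(1))
  summary <- data.frame(
    class = classes, n_total = n_total, n_in_cfdna = n_det,
    rate = ifelse(n_total > 0, n_det / n_total, NA_real_),
    stringsAsFactors = FALSE
  )
  pairs <- list(c("TRUNCAL", "INDIVIDUAL"), c("SHARED", "INDIVIDUAL"),
                c("TRUNCAL", "SHARED"))
  tests <- do.call(rbind, lapply(pairs, function(p) {
    a <- p[1]; b <- p[2]
    if (n_total[a] == 0 || n_total[b] == 0)
      return(data.frame(comparison = paste(tolower(a), "vs", tolower(b)),
                        chisq_statistic = NA_real_, chisq_p = NA_real_,
                        t_statistic = NA_real_, t_p = NA_real_))
    tab <- matrix(c(n_det[a], n_total[a] - n_det[a],
                    n_det[b], n_total[b] - n_det[b]), nrow = 2, byrow = TRUE)
    cs <- tryCatch(chi_square_yates(tab),
                   error = function(e) list(statistic = NA_real_, p_value = NA_real_))
    xa <- as.numeric(classified$in_cfdna[classified$mclass == a])
    xb <- as.numeric(classified$in_cfdna[classified$mclass == b])
    tt <- if (length(xa) > 1 && length(xb) > 1 &&
              (stats::sd(xa) > 0 || stats::sd(xb) > 0))
      stats::t.test(xa, xb, var.equal = TRUE)
    else list(statistic = NA_real_, p.value = NA_real_)
    data.frame(comparison = paste(tolower(a), "vs", tolower(b)),
               chisq_statistic = unname(cs$statistic), chisq_p = unname(cs$p_value),
               t_statistic = unname(tt$statistic), t_p = unname(tt$p.value))
  }))
  structure(list(summary = summary, tests = tests), class = "class_detection")
}

#' @export
print.class_detection <- function(x, ...) {
  cat("<class_detection> cfDNA detection by mutation class\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-10s %4d / %4d detected%s\n", tolower(s$class[i]),
                s$n_in_cfdna[i], s$n_total[i],
                if (is.na(s$rate[i])) "" else
                  sprintf(" (%.1f%%)", round_half_up(100 * s$rate[i], 1))))
  t <- x$tests
  for (i in seq_len(nrow(t)))
    cat(sprintf("  %-24s chi-square(Yates) p=%s, t-test p=%s\n", t$comparison[i],
                .fmt_p(t$chisq_p[i]), .fmt_p(t$t_p[i])))
  invisible(x)
}

.fmt_p <- function(p) if (is.na(p)) "NA" else format(signif(p, 3))

#' Restrict a sample to functional (protein-altering) alterations
#'
#' Confines a call set to biologically meaningful alterations by
#' dropping synonymous-coding variants and region annotations (intronic,
#' UTR, upstream/downstream, intergenic): a call is kept when its impact
#' annotation is HIGH or MODERATE, i.e. non-synonymous coding,
#' frameshift, stop gain/loss, splice-site and in-frame indel effects.
#' Gene-level CNV records, which carry no effect annotation, are kept.
#' Calls with a missing annotation are retained and counted in a
#' warning.
#'
#' @param x a \code{variant_set}.
#' @return filtered \code{variant_set}.
#' @export
functional_filter <- function(x) {
  stopifnot(inherits(x, "variant_set"))
  calls <- x$calls
  missing_ann <- !calls$is_cnv &
    (is.na(calls$impact) | !nzchar(calls$impact)) &
    (is.na(calls$effect) | !nzchar(calls$effect))
  if (any(missing_ann))
    .warnf("%d call(s) without effect/impact annotation retained", sum(missing_ann))
  impact <- toupper(.blank(calls$impact))
  effect <- toupper(.blank(calls$effect))
  drop <- !calls$is_cnv & !missing_ann &
    (impact %in% c("LOW", "MODIFIER") |
       grepl("SYNONYMOUS_COD", effect) & !grepl("NON_SYNONYMOUS", effect) |
       effect %in% c("INTRON", "UPSTREAM", "DOWNSTREAM", "INTERGENIC") |
       grepl("^UTR", effect) | grepl("_UTR", effect))
  keep_high_mod <- impact %in% c("HIGH", "MODERATE")
  drop <- drop & !keep_high_mod
  x$calls <- calls[!drop, , drop = FALSE]
  rownames(x$calls) <- NULL
  x
}

#' Alterations shared by the cfDNA of multiple patients
#'
#' Surveys the cfDNA call sets of a patient collection for alteration
#' keys present in at least \code{min_patients} patients.
#'
#' @param cfdna_sets named list (by patient) of cfDNA
#'   \code{variant_set}s, or of \code{patient_cohort}s (the designated
#'   timepoint's cfDNA set is used).
#' @param min_patients minimum number of patients sharing a key.
#' @param cfdna_timepoint used when cohorts are supplied.
#' @return data.frame with columns \code{key, gene, n_patients,
#'   patients}, ordered by chromosome and position.
#' @export
cross_patient_shared <- function(cfdna_sets, min_patients = 2,
                                 cfdna_timepoint = "pre_mortem") {
  stopifnot(length(cfdna_sets) >= 2)
  sets <- lapply(cfdna_sets, function(s) {
    if (inherits(s, "patient_cohort")) cfdna_at(s, cfdna_timepoint) else s
  })
  pids <- names(sets)
  if (is.null(pids)) pids <- vapply(sets, function(s) s$patient_id, character(1))
  keys <- lapply(sets, variant_keys)
  long <- data.frame(
    key = unlist(keys, use.names = FALSE),
    patient = rep(pids, lengths(keys)),
    stringsAsFactors = FALSE
  )
  long <- long[!duplicated(long), , drop = FALSE]
  tab <- table(long$key)
  shared <- names(tab)[tab >= min_patients]
  genes <- unlist(lapply(sets, function(s)
    stats::setNames(s$calls$gene, s$calls$key)))
  out <- data.frame(
    key = shared,
    gene = unname(genes[match(shared, names(genes))]),
    n_patients = as.integer(tab[shared]),
    patients = vapply(shared, function(k)
      paste(sort(long$patient[long$key == k]), collapse = ","), character(1)),
    stringsAsFactors = FALSE
  )
  chrom <- sub(":.*$", "", out$key)
  pos <- suppressWarnings(as.numeric(sub("^[^:]+:([^:]+):.*$", "\\1", out$key)))
  pos[is.na(pos)] <- Inf  # CNV keys sort last
  out <- out[order(.chrom_rank(chrom), pos, out$key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genes with identical alterations in tumor and cfDNA
#'
#' Lists the genes carrying at least one alteration key found in both
#' any tumor lesion and the cfDNA of the patient, with the alteration
#' types involved. Sharing is at key level: the same gene altered at
#' different nucleotides in tumor and cfDNA does not qualify.
#'
#' @param cohort a somatic, filtered \code{patient_cohort}.
#' @param cfdna_timepoint cfDNA set used; default \code{"pre_mortem"}.
#' @return data.frame with columns \code{gene, n_keys, types}.
#' @export
genes_shared_tumor_cfdna <- function(cohort, cfdna_timepoint = "pre_mortem") {
  stopifnot(inherits(cohort, "patient_cohort"))
  cf <- cfdna_at(cohort, cfdna_timepoint)
  tumor_calls <- do.call(rbind, lapply(cohort$tumor_sets, function(s) s$calls))
  shared <- tumor_calls[tumor_calls$key %in% variant_keys(cf), , drop = FALSE]
  shared <- shared[!duplicated(shared$key), , drop = FALSE]
  if (nrow(shared) == 0)
    return(data.frame(gene = character(), n_keys = integer(),
                      types = character(), stringsAsFactors = FALSE))
  sp <- split(shared, shared$gene)
  out <- data.frame(
    gene = names(sp),
    n_keys = vapply(sp, nrow, integer(1)),
    types = vapply(sp, function(d)
      paste(sort(unique(d$variant_type)), collapse = "/"), character(1)),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$n_keys, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Correlation between cfDNA detectability and tumor size
#'
#' Computes, over tumor lesions with a recorded size, the correlation
#' between the per-lesion cfDNA detection rate and the lesion's maximal
#' diameter. Spearman's rank correlation is primary; Pearson's is
#' reported alongside. Lesions whose detection rate is undefined (empty
#' somatic set) are excluded.
#'
#' @param cohorts list of somatic, filtered \code{patient_cohort}s (or a
#'   single cohort).
#' @param cfdna_timepoint cfDNA set used per patient.
#' @return object of class \code{size_correlation} with the paired data
#'   and both coefficients; \code{insufficient} / \code{degenerate}
#'   flags are set when fewer than 3 pairs exist or the ranks carry no
#'   variation.
#' @export
detectability_vs_size <- function(cohorts, cfdna_timepoint = "pre_mortem") {
  if (inherits(cohorts, "patient_cohort")) cohorts <- list(cohorts)
  pairs <- do.call(rbind, lapply(cohorts, function(co) {
    cf <- cfdna_at(co, cfdna_timepoint)
    do.call(rbind, lapply(co$tumor_sets, function(ts) {
      if (is.na(ts$tumor_size_mm)) return(NULL)
      v <- venn(ts, cf)
      if (v$rate_undefined) return(NULL)
      data.frame(patient_id = co$patient_id, sample_id = ts$sample_id,
                 detection_rate = v$detection_rate, size_mm = ts$tumor_size_mm,
                 stringsAsFactors = FALSE)
    }))
  }))
  res <- list(pairs = pairs, n = if (is.null(pairs)) 0L else nrow(pairs),
              insufficient = FALSE, degenerate = FALSE,
              spearman_rho = NA_real_, spearman_p = NA_real_,
              pearson_r = NA_real_, pearson_p = NA_real_)
  if (res$n < 3) {
    res$insufficient <- TRUE
    return(structure(res, class = "size_correlation"))
  }
  if (stats::sd(pairs$size_mm) == 0 || stats::sd(pairs$detection_rate) == 0) {
    res$degenerate <- TRUE
    return(structure(res, class = "size_correlation"))
  }
  sp <- suppressWarnings(stats::cor.test(pairs$detection_rate, pairs$size_mm,
                                         method = "spearman"))
  pe <- stats::cor.test(pairs$detection_rate, pairs$size_mm, method = "pearson")
  res$spearman_rho <- unname(sp$estimate); res$spearman_p <- sp$p.value
  res$pearson_r <- unname(pe$estimate); res$pearson_p <- pe$p.value
  structure(res, class = "size_correlation")
}

#' @export
print.size_correlation <- function(x, ...) {
  cat(sprintf("<size_correlation> %d lesion(s) with size and defined detection rate\n", x$n))
  if (x$insufficient) cat("  insufficient data (< 3 pairs)\n")
  else if (x$degenerate) cat("  degenerate (no variation in ranks)\n")
  else cat(sprintf("  Spearman rho=%.3f (p=%s); Pearson r=%.3f (p=%s)\n",
                   x$spearman_rho, .fmt_p(x$spearman_p), x$pearson_r,
                   .fmt_p(x$pearson_p)))
  invisible(x)
}

#' Reduce a cohort to somatic, confidence-filtered sets
#'
#' Applies [subtract_germline()] (tumors and cfDNA alike, using the
#' cohort's matched germline set) and [filter_confidence()] to every
#' member sample.
#'
#' @param cohort a \code{patient_cohort}.
#' @param min_tier confidence tier passed to [filter_confidence()].
#' @return a \code{patient_cohort} of somatic filtered sets.
#' @export
somatic_cohort <- function(cohort, min_tier = "high") {
  stopifnot(inherits(cohort, "patient_cohort"))
  g <- cohort$germline_set
  prep <- function(s) filter_confidence(subtract_germline(s, g), min_tier)
  cohort$tumor_sets <- lapply(cohort$tumor_sets, prep)
  cohort$cfdna_sets <- lapply(cohort$cfdna_sets, prep)
  cohort
}
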