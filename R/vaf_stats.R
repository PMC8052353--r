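#' Variant allele frequency from allele depths
#'
#' VAF = (allele coverage of the variant call) / (reference coverage +
#' variant coverage).
#'
#' @param ref_depth,alt_depth non-negative read counts; total must be
#'   positive.
#' @return fraction in \[0,1\]. Vectorized.
#' @examples
#' compute_vaf(70, 30)  # 0.30
#' @export
compute_vaf <- function(ref_depth, alt_depth) {
  if (any(ref_depth < 0 | alt_depth < 0, na.rm = TRUE))
    .stopf("negative allele depth")
  tot <- ref_depth + alt_depth
  if (any(is.na(tot) | tot <= 0))
    .stopf("undefined VAF: zero total depth")
  alt_depth / tot
}

#' Mann-Whitney U test (exact or approximate)
#'
#' Two-sided rank-sum comparison of two samples. In \code{"auto"} mode
#' the exact null distribution is used when the combined sample size is
#' at most \code{exact_max} and there are no ties; otherwise the normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y non-empty numeric vectors.
#' @param mode \code{"auto"}, \code{"exact"} or \code{"approx"}.
#' @param exact_max combined-size threshold for the exact branch.
#' @return list with \code{U} (number of (x, y) pairs with x > y, i.e.
#'   the rank-sum statistic for \code{x}), \code{p_value}, and the
#'   \code{method} used.
#' @export
mann_whitney_u <- function(x, y, mode = c("auto", "exact", "approx"),
                           exact_max = 12) {
  mode <- match.arg(mode)
  if (length(x) == 0 || length(y) == 0)
    .stopf("mann_whitney_u: empty sample")
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- switch(mode,
                  auto = (length(x) + length(y) <= exact_max) && !ties,
                  exact = TRUE,
                  approx = FALSE)
  if (exact && ties)
    .stopf("exact Mann-Whitney p is unavailable with ties")
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  p <- wt$p.value
  # fully tied pooled sample: zero rank variance, no evidence either way
  if (is.nan(p)) p <- 1
  list(U = unname(wt$statistic), p_value = p,
       method = if (exact) "exact" else "normal_approx")
}

#' Chi-square test with Yates continuity correction
#'
#' For a 2x2 table of counts \eqn{[[a,b],[c,d]]} with total \eqn{N}, the
#' statistic is \eqn{N(|ad-bc|-N/2)^2} divided by the product of the row
#' and column margins, clamped at zero when \eqn{|ad-bc| \le N/2}; the
#' p-value comes from the chi-square distribution with one degree of
#' freedom.
#'
#' @param table 2x2 matrix (or length-4 vector, row-major) of
#'   non-negative counts; no margin may be zero.
#' @return list with \code{statistic} and \code{p_value}.
#' @export
chi_square_yates <- function(table) {
  if (is.vector(table) && length(table) == 4)
    table <- matrix(table, nrow = 2, byrow = TRUE)
  if (!all(dim(table) == c(2, 2)) || any(table < 0) || any(is.na(table)))
    .stopf("chi_square_yates needs a 2x2 table of non-negative counts")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    .stopf("degenerate table: zero row or column margin")
  ct <- suppressWarnings(stats::chisq.test(table, correct = TRUE))
  list(statistic = unname(ct$statistic), p_value = ct$p.value)
}

#' Mean with 95% confidence interval
#'
#' @param values numeric vector; at least one value.
#' @param method \code{"t"} (default) for a t-distribution interval or
#'   \code{"normal"} for the large-sample normal approximation.
#' @return list with \code{mean}, \code{lower}, \code{upper}, \code{n},
#'   and \code{degenerate} (TRUE when n = 1, in which case the interval
#'   collapses to the point).
#' @export
mean_ci95 <- function(values, method = c("t", "normal")) {
  method <- match.arg(method)
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0) .stopf("mean_ci95: empty input")
  m <- mean(values)
  if (n == 1)
    return(list(mean = m, lower = m, upper = m, n = 1L, degenerate = TRUE))
  se <- stats::sd(values) / sqrt(n)
  q <- if (method == "t") stats::qt(0.975, df = n - 1) else stats::qnorm(0.975)
  list(mean = m, lower = m - q * se, upper = m + q * se, n = as.integer(n),
       degenerate = FALSE)
}

#' VAF stratification of one lesion by cfDNA detectability
#'
#' Splits a tumor lesion's somatic alterations into those whose key is
#' also detected in the patient's cfDNA and those that are not, and
#' compares the two VAF distributions (two-sided Mann-Whitney U test,
#' means with 95% CIs). CNV records, which carry no conventional VAF,
#' are excluded, as are calls without a VAF.
#'
#' @param lesion_set somatic, filtered tumor \code{variant_set}.
#' @param cfdna_set somatic, filtered cfDNA \code{variant_set}.
#' @param ci_method passed to [mean_ci95()].
#' @return object of class \code{vaf_stratification}; \code{p_value} is
#'   \code{NA} and \code{flagged} is \code{TRUE} when either stratum is
#'   empty.
#' @export
stratify_vaf <- function(lesion_set, cfdna_set, ci_method = "t") {
  calls <- lesion_set$calls
  calls <- calls[!calls$is_cnv & !is.na(calls$vaf), , drop = FALSE]
  detected <- calls$key %in% variant_keys(cfdna_set)
  vd <- calls$vaf[detected]
  vu <- calls$vaf[!detected]
  res <- list(lesion_id = lesion_set$sample_id,
              vafs_detected = vd, vafs_undetected = vu,
              n_detected = length(vd), n_undetected = length(vu),
              mean_detected = NA_real_, ci95_detected = c(NA_real_, NA_real_),
              mean_undetected = NA_real_, ci95_undetected = c(NA_real_, NA_real_),
              u_statistic = NA_real_, p_value = NA_real_, flagged = FALSE)
  if (length(vd)) {
    ci <- mean_ci95(vd, ci_method)
    res$mean_detected <- ci$mean; res$ci95_detected <- c(ci$lower, ci$upper)
  }
  if (length(vu)) {
    ci <- mean_ci95(vu, ci_method)
    res$mean_undetected <- ci$mean; res$ci95_undetected <- c(ci$lower, ci$upper)
  }
  if (length(vd) && length(vu)) {
    mw <- mann_whitney_u(vd, vu)
    res$u_statistic <- mw$U; res$p_value <- mw$p_value
  } else res$flagged <- TRUE
  structure(res, class = "vaf_stratification")
}

#' @export
print.vaf_stratification <- function(x, ...) {
  cat(sprintf("<vaf_stratification> %s\n", x$lesion_id))
  fmt <- function(m, ci, n) {
    if (is.na(m)) return(sprintf("(empty stratum, n=%d)", n))
    sprintf("mean VAF %.1f%% (95%% CI %.1f-%.1f), n=%d",
            100 * m, 100 * ci[1], 100 * ci[2], n)
  }
  cat("  detected in cfDNA:     ", fmt(x$mean_detected, x$ci95_detected, x$n_detected), "\n")
  cat("  not detected in cfDNA: ", fmt(x$mean_undetected, x$ci95_undetected, x$n_undetected), "\n")
  cat(if (x$flagged) "  Mann-Whitney test not applicable (empty stratum)\n"
      else sprintf("  Mann-Whitney U=%g, two-sided p=%s\n", x$u_statistic,
                   .fmt_p(x$p_value)))
  invisible(x)
}

#' Mean VAF of cfDNA-only versus tumor-corroborated cfDNA alterations
#'
#' Stratifies the cfDNA sample's somatic alterations by whether their
#' key is present in any tumor lesion of the same patient, and reports
#' the mean cfDNA-side VAF of each stratum. An empty stratum yields an
#' absent (NA) mean.
#'
#' @param cohort somatic, filtered \code{patient_cohort}.
#' @param cfdna_timepoint cfDNA set used; default \code{"pre_mortem"}.
#' @return list with \code{mean_vaf_cfdna_only},
#'   \code{mean_vaf_in_tumor}, \code{n_cfdna_only}, \code{n_in_tumor}.
#' @export
cfdna_only_vaf_comparison <- function(cohort, cfdna_timepoint = "pre_mortem") {
  stopifnot(inherits(cohort, "patient_cohort"))
  cf <- cfdna_at(cohort, cfdna_timepoint)
  tumor_keys <- unique(unlist(lapply(cohort$tumor_sets, variant_keys),
                              use.names = FALSE))
  calls <- cf$calls
  calls <- calls[!calls$is_cnv & !is.na(calls$vaf), , drop = FALSE]
  in_tumor <- calls$key %in% tumor_keys
  list(
    mean_vaf_cfdna_only = if (any(!in_tumor)) mean(calls$vaf[!in_tumor]) else NA_real_,
    mean_vaf_in_tumor = if (any(in_tumor)) mean(calls$vaf[in_tumor]) else NA_real_,
    n_cfdna_only = sum(!in_tumor), n_in_tumor = sum(in_tumor)
  )
}
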