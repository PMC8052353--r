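# in-code fixtures and independent statistical oracles used across tests

# a variant_set from bare positions on chr1 (SNP A>G), all high confidence
mk_set <- function(pos, sample_id = "S", patient_id = "P1",
                   kind = "tumor_primary", vaf = 0.5, confidence = "high",
                   organ = NA_character_, timepoint = NA,
                   tumor_size_mm = NA_real_, effect = "NON_SYNONYMOUS_CODING",
                   impact = "MODERATE") {
  calls <- if (length(pos) == 0) NULL else {
    depth <- 1000L
    alt <- as.integer(round(rep_len(vaf, length(pos)) * depth))
    variant_calls(chrom = "chr1", pos = pos, ref = "A", alt = "G",
                  variant_type = "SNP", gene = "TP53",
                  effect = effect, impact = impact,
                  ref_depth = depth - alt, alt_depth = alt,
                  confidence = confidence)
  }
  if (is.null(calls)) {
    variant_set(sample_id, patient_id, kind, organ = organ,
                timepoint = timepoint, tumor_size_mm = tumor_size_mm)
  } else {
    variant_set(sample_id, patient_id, kind, calls, organ = organ,
                timepoint = timepoint, tumor_size_mm = tumor_size_mm)
  }
}

# cohort whose lesions contain the given position vectors and whose cfDNA
# contains cf_pos
mk_cohort <- function(lesion_pos, cf_pos, patient_id = "P1",
                      germline_pos = NULL) {
  tumor_sets <- lapply(seq_along(lesion_pos), function(i)
    mk_set(lesion_pos[[i]], sample_id = paste0("T", i),
           patient_id = patient_id,
           kind = if (i == 1) "tumor_primary" else "tumor_metastasis",
           organ = if (i == 1) "lung" else paste0("met", i)))
  cfdna <- mk_set(cf_pos, sample_id = "CF", patient_id = patient_id,
                  kind = "cfdna", timepoint = "pre_mortem")
  germ <- if (!is.null(germline_pos))
    mk_set(germline_pos, sample_id = "GL", patient_id = patient_id,
           kind = "germline")
  patient_cohort(patient_id, tumor_sets, list(cfdna), germ)
}

# exhaustive rank-assignment Mann-Whitney oracle: enumerates every way the
# pooled ranks can be assigned to x, builds the exact null distribution of
# U, and doubles the smaller tail (the distribution is symmetric)
mw_exact_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(nx + ny, nx)
  all_u <- apply(combs, 2, function(idx) sum(seq_len(nx + ny)[idx]) - nx * (nx + 1) / 2)
  lo <- min(u_obs, nx * ny - u_obs)
  hi <- max(u_obs, nx * ny - u_obs)
  # two-sided p doubles the smaller tail, capped at 1 (when U sits at the
  # center the two tails overlap in the central atom)
  list(U = u_obs, p = min(1, mean(all_u <= lo) + mean(all_u >= hi)))
}

# closed-form Yates-corrected chi-square for [[a,b],[c,d]]
yates_oracle <- function(a, b, c, d) {
  n <- a + b + c + d
  num <- abs(a * d - b * c) - n / 2
  if (num <= 0) return(list(statistic = 0, p = 1))
  stat <- n * num^2 / ((a + b) * (c + d) * (a + c) * (b + d))
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}
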