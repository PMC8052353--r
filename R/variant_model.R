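#' Normalize a variant into its cross-sample identity key
#'
#' Variants are matched across samples at nucleotide-change resolution:
#' two calls are the same alteration only when chromosome, position,
#' reference allele and alternate allele all agree exactly. Copy-number
#' events carry no single nucleotide change, so CNV records are keyed by
#' gene symbol alone.
#'
#' Chromosome labels are canonicalized to the \code{"chrN"} form
#' (\code{"7"} and \code{"chr7"} both become \code{"chr7"}); alleles are
#' uppercased. Coordinates are 1-based on the reference build of the
#' input tables and are never shifted.
#'
#' @param chrom chromosome label, with or without the \code{"chr"} prefix.
#' @param pos 1-based position (ignored for CNV records).
#' @param ref,alt reference and alternate allele strings (ignored for CNV).
#' @param variant_type one of \code{"SNP"}, \code{"DEL"}, \code{"INS"},
#'   \code{"MNP"}, \code{"CNV"}.
#' @param gene gene symbol; required (and used for identity) when
#'   \code{variant_type} is \code{"CNV"}.
#' @param line optional input line number used in error messages.
#' @return character key, \code{"chrom:pos:REF:ALT"} for sequence variants
#'   and \code{"CNV:gene"} for copy-number events. Vectorized.
#' @examples
#' normalize_key("7", 140434607, "g", "a", "SNP", "BRAF")
#' normalize_key(NA, NA, "", "", "CNV", "EGFR")
#' @export
normalize_key <- function(chrom, pos, ref, alt, variant_type = "SNP",
                          gene = NA_character_, line = NULL) {
  n <- max(length(chrom), length(pos), length(ref), length(alt),
           length(variant_type), length(gene))
  chrom <- rep_len(as.character(chrom), n)
  pos <- rep_len(pos, n)
  ref <- rep_len(toupper(trimws(as.character(ref))), n)
  alt <- rep_len(toupper(trimws(as.character(alt))), n)
  variant_type <- rep_len(as.character(variant_type), n)
  gene <- rep_len(as.character(gene), n)

  bad_type <- !variant_type %in% .VARIANT_TYPES
  if (any(bad_type))
    .stopf("unknown variant_type '%s'", variant_type[which(bad_type)[1]])

  is_cnv <- variant_type == "CNV"
  if (any(is_cnv & (is.na(gene) | !nzchar(gene))))
    .stopf("CNV record without a gene symbol%s", .line_tag(line, is_cnv))

  snv <- !is_cnv
  if (any(snv & (is.na(ref) | is.na(alt) | !nzchar(ref) | !nzchar(alt))))
    .stopf("malformed record: empty allele on non-CNV variant%s",
           .line_tag(line, snv & (is.na(ref) | is.na(alt) | !nzchar(ref) | !nzchar(alt))))
  if (any(snv & ref == alt))
    .stopf("malformed record: ref equals alt%s", .line_tag(line, snv & ref == alt))
  pos_num <- suppressWarnings(as.numeric(pos))
  if (any(snv & (is.na(pos_num) | pos_num < 1)))
    .stopf("malformed record: position must be >= 1%s",
           .line_tag(line, snv & (is.na(pos_num) | pos_num < 1)))

  chrom <- ifelse(grepl("^chr", chrom, ignore.case = TRUE),
                  paste0("chr", sub("^chr", "", chrom, ignore.case = TRUE)),
                  paste0("chr", chrom))

  out <- character(n)
  out[snv] <- paste(chrom[snv], format(pos_num[snv], scientific = FALSE, trim = TRUE),
                    ref[snv], alt[snv], sep = ":")
  out[is_cnv] <- paste("CNV", gene[is_cnv], sep = ":")
  out
}

.line_tag <- function(line, which_bad) {
  if (is.null(line)) return("")
  idx <- which(which_bad)[1]
  sprintf(" (line %s)", rep_len(line, max(idx, length(line)))[idx])
}

.empty_calls <- function() {
  data.frame(
    key = character(), chrom = character(), pos = integer(),
    ref = character(), alt = character(), is_cnv = logical(),
    variant_type = character(), gene = character(), transcript = character(),
    codon_change = character(), aa_change = character(),
    dbsnp_id = character(), cosmic_id = character(),
    effect = character(), impact = character(),
    ref_depth = integer(), alt_depth = integer(), vaf = numeric(),
    confidence = character(), stringsAsFactors = FALSE
  )
}

#' Construct a table of variant calls
#'
#' Builds the canonical call table used throughout the package from
#' parallel vectors, computing keys with [normalize_key()] and VAFs from
#' depths where both are available. Duplicate keys are collapsed keeping
#' the higher-confidence record.
#'
#' @param chrom,pos,ref,alt,variant_type,gene see [normalize_key()].
#' @param transcript,codon_change,aa_change,dbsnp_id,cosmic_id annotation
#'   strings (may be empty).
#' @param effect effect annotation (e.g. \code{NON_SYNONYMOUS_CODING}).
#' @param impact one of \code{HIGH}, \code{MODERATE}, \code{LOW},
#'   \code{MODIFIER} (may be \code{NA}).
#' @param ref_depth,alt_depth non-negative read counts.
#' @param vaf variant allele fraction in \[0,1\]; recomputed from depths
#'   when total depth is positive.
#' @param confidence \code{"high"}, \code{"medium"} or \code{"low"}.
#' @return data.frame with one row per unique variant key.
#' @export
variant_calls <- function(chrom, pos, ref, alt, variant_type = "SNP",
                          gene = NA_character_, transcript = "",
                          codon_change = "", aa_change = "",
                          dbsnp_id = "", cosmic_id = "",
                          effect = NA_character_, impact = NA_character_,
                          ref_depth = NA_integer_, alt_depth = NA_integer_,
                          vaf = NA_real_, confidence = "high") {
  key <- normalize_key(chrom, pos, ref, alt, variant_type, gene)
  n <- length(key)
  vt <- rep_len(as.character(variant_type), n)
  cnv <- vt == "CNV"
  df <- data.frame(
    key = key,
    chrom = ifelse(cnv, NA_character_, sub(":.*$", "", key)),
    pos = ifelse(cnv, NA_integer_,
                 suppressWarnings(as.integer(rep_len(pos, n)))),
    ref = ifelse(cnv, NA_character_, toupper(rep_len(as.character(ref), n))),
    alt = ifelse(cnv, NA_character_, toupper(rep_len(as.character(alt), n))),
    is_cnv = cnv,
    variant_type = vt,
    gene = rep_len(as.character(gene), n),
    transcript = rep_len(as.character(transcript), n),
    codon_change = rep_len(as.character(codon_change), n),
    aa_change = rep_len(as.character(aa_change), n),
    dbsnp_id = rep_len(as.character(dbsnp_id), n),
    cosmic_id = rep_len(as.character(cosmic_id), n),
    effect = rep_len(as.character(effect), n),
    impact = rep_len(as.character(impact), n),
    ref_depth = rep_len(suppressWarnings(as.integer(ref_depth)), n),
    alt_depth = rep_len(suppressWarnings(as.integer(alt_depth)), n),
    vaf = rep_len(as.numeric(vaf), n),
    confidence = rep_len(as.character(confidence), n),
    stringsAsFactors = FALSE
  )
  bad_conf <- !df$confidence %in% .CONFIDENCE_LEVELS
  if (any(bad_conf))
    .stopf("unknown confidence tier '%s'", df$confidence[which(bad_conf)[1]])

  # VAF is defined as alt / (ref + alt); recompute whenever depths exist
  tot <- df$ref_depth + df$alt_depth
  have_depth <- !is.na(tot) & tot > 0
  df$vaf[have_depth] <- df$alt_depth[have_depth] / tot[have_depth]
  if (any(!is.na(df$vaf) & (df$vaf < 0 | df$vaf > 1)))
    .stopf("VAF outside [0,1]")

  .dedup_calls(df)
}

# duplicate keys collapse to the single highest-confidence record
.dedup_calls <- function(df) {
  if (!anyDuplicated(df$key)) return(df)
  ord <- order(match(df$key, unique(df$key)),
               -match(df$confidence, .CONFIDENCE_LEVELS))
  df <- df[ord, , drop = FALSE]
  df <- df[!duplicated(df$key), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' One sample's filtered variant calls
#'
#' Container for the calls of a single sample together with its role in
#' the patient: tumor (primary or metastasis), plasma cfDNA, or matched
#' germline. Tumor samples may carry a size (maximal diameter, mm).
#'
#' @param sample_id,patient_id identifiers.
#' @param kind one of \code{"tumor_primary"}, \code{"tumor_metastasis"},
#'   \code{"cfdna"}, \code{"germline"}.
#' @param calls data.frame from [variant_calls()] (or compatible).
#' @param organ free-text organ/site label.
#' @param timepoint \code{"diagnosis"}, \code{"pre_mortem"},
#'   \code{"autopsy"}, or an integer number of days before death.
#' @param tumor_size_mm optional positive tumor diameter; tumor kinds only.
#' @return object of class \code{variant_set}.
#' @export
variant_set <- function(sample_id, patient_id, kind, calls = .empty_calls(),
                        organ = NA_character_, timepoint = NA,
                        tumor_size_mm = NA_real_) {
  kind <- match.arg(kind, .SAMPLE_KINDS)
  if (!is.na(tumor_size_mm)) {
    if (!kind %in% c("tumor_primary", "tumor_metastasis"))
      .stopf("tumor_size_mm given for non-tumor sample '%s'", sample_id)
    if (tumor_size_mm <= 0)
      .stopf("tumor_size_mm must be positive ('%s')", sample_id)
  }
  if (anyDuplicated(calls$key))
    calls <- .dedup_calls(calls)
  rownames(calls) <- NULL
  structure(
    list(sample_id = sample_id, patient_id = patient_id, kind = kind,
         organ = organ, timepoint = timepoint,
         tumor_size_mm = tumor_size_mm, calls = calls),
    class = "variant_set"
  )
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("<variant_set> %s (%s, patient %s%s)\n", x$sample_id, x$kind,
              x$patient_id,
              if (!is.na(x$organ)) paste0(", ", x$organ) else ""))
  cat(sprintf("  %d calls; confidence: %s\n", nrow(x$calls),
              paste(sprintf("%s=%d", .CONFIDENCE_LEVELS,
                            tabulate(match(x$calls$confidence, .CONFIDENCE_LEVELS),
                                     nbins = 3L)), collapse = " ")))
  invisible(x)
}

#' @export
length.variant_set <- function(x) nrow(x$calls)

#' Variant keys of a sample
#' @param x a \code{variant_set}.
#' @return character vector of variant keys.
#' @export
variant_keys <- function(x) {
  stopifnot(inherits(x, "variant_set"))
  x$calls$key
}

#' All samples of one patient wired to their roles
#'
#' @param patient_id identifier shared by all member sets.
#' @param tumor_sets list of tumor \code{variant_set}s (>= 1, at most one
#'   primary).
#' @param cfdna_sets list of cfDNA \code{variant_set}s, named by timepoint
#'   (>= 1).
#' @param germline_set optional matched-germline \code{variant_set}.
#' @return object of class \code{patient_cohort}.
#' @export
patient_cohort <- function(patient_id, tumor_sets, cfdna_sets,
                           germline_set = NULL) {
  stopifnot(length(tumor_sets) >= 1, length(cfdna_sets) >= 1)
  all_sets <- c(tumor_sets, cfdna_sets,
                if (!is.null(germline_set)) list(germline_set))
  pids <- vapply(all_sets, function(s) s$patient_id, character(1))
  if (!all(pids == patient_id))
    .stopf("all member sets must share patient_id '%s'", patient_id)
  kinds <- vapply(tumor_sets, function(s) s$kind, character(1))
  if (!all(kinds %in% c("tumor_primary", "tumor_metastasis")))
    .stopf("tumor_sets must be tumor kinds")
  if (sum(kinds == "tumor_primary") > 1)
    .stopf("patient '%s' has more than one primary tumor set", patient_id)
  if (!all(vapply(cfdna_sets, function(s) s$kind, character(1)) == "cfdna"))
    .stopf("cfdna_sets must have kind 'cfdna'")
  sids <- vapply(all_sets, function(s) s$sample_id, character(1))
  if (anyDuplicated(sids))
    .stopf("duplicate sample_id '%s'", sids[duplicated(sids)][1])
  names(tumor_sets) <- vapply(tumor_sets, function(s) s$sample_id, character(1))
  names(cfdna_sets) <- vapply(cfdna_sets, function(s) as.character(s$timepoint),
                              character(1))
  structure(
    list(patient_id = patient_id, tumor_sets = tumor_sets,
         cfdna_sets = cfdna_sets, germline_set = germline_set),
    class = "patient_cohort"
  )
}

#' @export
print.patient_cohort <- function(x, ...) {
  cat(sprintf("<patient_cohort> %s: %d tumor set(s), %d cfDNA set(s), germline %s\n",
              x$patient_id, length(x$tumor_sets), length(x$cfdna_sets),
              if (is.null(x$germline_set)) "absent" else "present"))
  for (s in x$tumor_sets)
    cat(sprintf("  tumor  %-12s %-16s %5d calls%s\n", s$sample_id,
                paste0(s$kind, if (!is.na(s$organ)) paste0("/", s$organ) else ""),
                nrow(s$calls),
                if (!is.na(s$tumor_size_mm)) sprintf(" (%.0f mm)", s$tumor_size_mm) else ""))
  for (s in x$cfdna_sets)
    cat(sprintf("  cfDNA  %-12s t=%-14s %5d calls\n", s$sample_id,
                as.character(s$timepoint), nrow(s$calls)))
  invisible(x)
}

#' Pick a cohort's cfDNA set by timepoint
#'
#' @param cohort a \code{patient_cohort}.
#' @param timepoint timepoint label; defaults to \code{"pre_mortem"}, the
#'   sample drawn before death that the tumor/cfDNA comparisons use. If
#'   the cohort holds exactly one cfDNA set it is returned regardless.
#' @return a \code{variant_set}.
#' @export
cfdna_at <- function(cohort, timepoint = "pre_mortem") {
  stopifnot(inherits(cohort, "patient_cohort"))
  if (length(cohort$cfdna_sets) == 1L) return(cohort$cfdna_sets[[1]])
  tp <- as.character(timepoint)
  hit <- names(cohort$cfdna_sets) == tp
  if (!any(hit))
    .stopf("patient '%s' has no cfDNA set at timepoint '%s' (available: %s)",
           cohort$patient_id, tp, paste(names(cohort$cfdna_sets), collapse = ", "))
  cohort$cfdna_sets[[which(hit)[1]]]
}
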