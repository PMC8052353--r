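.TSV_COLUMNS <- c("Chr", "Pos_GRCh37", "Ref", "Variant", "Gene_Name",
                  "Variant_Type", "Transcript_ID", "Codon_Change", "AA_Change",
                  "dbSNP_ID", "COSMIC_ID", "snpEff_Effect", "snpEff_Impact",
                  "Ref_Depth", "Alt_Depth", "VAF", "Confidence")

#' Read a per-sample variant table
#'
#' Reads one sample's calls from either a VCF (v4.x) or the annotated
#' tab-separated dialect whose columns follow the layout
#' \code{Chr, Pos_GRCh37, Ref, Variant, Gene_Name, Variant_Type,
#' Transcript_ID, Codon_Change, AA_Change, dbSNP_ID, COSMIC_ID,
#' snpEff_Effect, snpEff_Impact, Ref_Depth, Alt_Depth, VAF, Confidence}.
#' Duplicate keys are collapsed keeping the higher-confidence record and
#' VAF is recomputed from depths whenever both depths are present.
#'
#' For VCF input, multi-allelic records are split into one call per
#' alternate allele before keying, allele depths are taken from the
#' per-sample \code{AD} field, and the confidence tier is derived from
#' \code{FILTER} (\code{PASS} maps to \code{high}; a literal
#' \code{medium}/\code{low} filter string maps to that tier; anything
#' else to \code{low}) unless \code{confidence_info_key} names an INFO
#' key carrying the tier. Symbolic \code{<CNV>} alternate alleles are
#' read as gene-level copy-number events.
#'
#' @param path file to read.
#' @param dialect \code{"annotated_tsv"} or \code{"vcf"}; default guesses
#'   from the file extension.
#' @param sample_id,patient_id,kind,organ,timepoint,tumor_size_mm sample
#'   metadata; see [variant_set()].
#' @param confidence_info_key optional INFO key naming the confidence
#'   tier in VCF input.
#' @return a \code{variant_set}.
#' @export
read_variant_table <- function(path, dialect = c("auto", "annotated_tsv", "vcf"),
                               sample_id = basename(path),
                               patient_id = NA_character_,
                               kind = "tumor_primary", organ = NA_character_,
                               timepoint = NA, tumor_size_mm = NA_real_,
                               confidence_info_key = NULL) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf"
               else "annotated_tsv"
  calls <- switch(dialect,
                  annotated_tsv = .read_annotated_tsv(path),
                  vcf = .read_vcf(path, confidence_info_key))
  variant_set(sample_id = sample_id, patient_id = patient_id, kind = kind,
              calls = calls, organ = organ, timepoint = timepoint,
              tumor_size_mm = tumor_size_mm)
}

.read_annotated_tsv <- function(path) {
  df <- tryCatch(
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                      colClasses = "character", na.strings = c("NA", "")),
    error = function(e) .stopf("cannot parse %s: %s", path, conditionMessage(e)))
  missing <- setdiff(.TSV_COLUMNS, names(df))
  if (length(missing))
    .stopf("%s: missing mandatory column(s): %s", path,
           paste(missing, collapse = ", "))
  if (nrow(df) == 0) return(.empty_calls())
  vt <- toupper(df$Variant_Type)
  pos <- suppressWarnings(as.numeric(df$Pos_GRCh37))
  bad <- (vt != "CNV") & (is.na(pos) | !nzchar(ifelse(is.na(df$Ref), "", df$Ref)) |
                            !nzchar(ifelse(is.na(df$Variant), "", df$Variant)))
  if (any(bad))
    .stopf("%s: unparseable row %d (missing position or allele)", path,
           which(bad)[1] + 1L)  # +1 for the header row
  variant_calls(
    chrom = df$Chr, pos = pos, ref = df$Ref, alt = df$Variant,
    variant_type = vt, gene = df$Gene_Name, transcript = .blank(df$Transcript_ID),
    codon_change = .blank(df$Codon_Change), aa_change = .blank(df$AA_Change),
    dbsnp_id = .blank(df$dbSNP_ID), cosmic_id = .blank(df$COSMIC_ID),
    effect = df$snpEff_Effect, impact = df$snpEff_Impact,
    ref_depth = suppressWarnings(as.integer(df$Ref_Depth)),
    alt_depth = suppressWarnings(as.integer(df$Alt_Depth)),
    vaf = suppressWarnings(as.numeric(df$VAF)),
    confidence = tolower(df$Confidence)
  )
}

.blank <- function(x) ifelse(is.na(x), "", x)

.read_vcf <- function(path, confidence_info_key = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0) return(.empty_calls())
  info_field <- function(key) {
    val <- vcfR::extract.info(v, element = key)
    if (is.null(val)) rep(NA_character_, nrow(fix)) else val
  }
  gene <- info_field("GENE")
  effect <- info_field("EFFECT")
  impact <- info_field("IMPACT")
  vtype <- info_field("TYPE")
  conf <- if (!is.null(confidence_info_key)) tolower(info_field(confidence_info_key))
          else .filter_to_confidence(fix[, "FILTER"])
  ad <- if ("AD" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID)
    vcfR::extract.gt(v, element = "AD")[, 1] else rep(NA_character_, nrow(fix))

  rows <- lapply(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    ads <- suppressWarnings(as.integer(strsplit(
      ifelse(is.na(ad[i]), "", ad[i]), ",", fixed = TRUE)[[1]]))
    lapply(seq_along(alts), function(j) {
      alt <- alts[j]
      is_cnv <- alt %in% c("<CNV>", "<DUP>", "<DEL:CNV>")
      list(chrom = fix[i, "CHROM"], pos = as.numeric(fix[i, "POS"]),
           ref = if (is_cnv) "" else fix[i, "REF"],
           alt = if (is_cnv) "" else alt,
           variant_type = if (is_cnv) "CNV" else
             .infer_variant_type(fix[i, "REF"], alt),
           gene = gene[i], effect = effect[i], impact = impact[i],
           vtype_override = vtype[i],
           dbsnp = if (fix[i, "ID"] %in% c(".", NA)) "" else fix[i, "ID"],
           ref_depth = if (length(ads) >= 1 && !is.na(ads[1])) ads[1] else NA_integer_,
           alt_depth = if (length(ads) >= j + 1 && !is.na(ads[j + 1])) ads[j + 1] else NA_integer_,
           confidence = conf[i])
    })
  })
  rows <- unlist(rows, recursive = FALSE)
  chrom <- vapply(rows, function(r) r$chrom, character(1))
  vt <- vapply(rows, function(r)
    if (!is.na(r$vtype_override) && nzchar(r$vtype_override)) r$vtype_override
    else r$variant_type, character(1))
  variant_calls(
    chrom = chrom,
    pos = vapply(rows, function(r) r$pos, numeric(1)),
    ref = vapply(rows, function(r) r$ref, character(1)),
    alt = vapply(rows, function(r) r$alt, character(1)),
    variant_type = vt,
    gene = vapply(rows, function(r) as.character(r$gene), character(1)),
    dbsnp_id = vapply(rows, function(r) r$dbsnp, character(1)),
    effect = vapply(rows, function(r) as.character(r$effect), character(1)),
    impact = vapply(rows, function(r) as.character(r$impact), character(1)),
    ref_depth = vapply(rows, function(r) as.integer(r$ref_depth), integer(1)),
    alt_depth = vapply(rows, function(r) as.integer(r$alt_depth), integer(1)),
    confidence = vapply(rows, function(r) r$confidence, character(1))
  )
}

.filter_to_confidence <- function(filter) {
  f <- tolower(ifelse(is.na(filter), ".", filter))
  ifelse(f %in% c("pass", "."), "high",
         ifelse(f %in% c("medium", "low"), f, "low"))
}

.infer_variant_type <- function(ref, alt) {
  if (nchar(ref) == 1 && nchar(alt) == 1) "SNP"
  else if (nchar(ref) > nchar(alt)) "DEL"
  else if (nchar(ref) < nchar(alt)) "INS"
  else "MNP"
}

#' Write a per-sample variant table
#'
#' Writes a \code{variant_set} back to disk in either dialect so that
#' \code{read_variant_table(write_variant_table(x))} reproduces the keys,
#' depths and annotations. VCF output is minimal v4.2 with the gene,
#' effect, impact and variant-type annotations in INFO and allele depths
#' in the per-sample \code{AD} field; the confidence tier is carried in
#' \code{FILTER} (\code{high} as \code{PASS}).
#'
#' @param x a \code{variant_set}.
#' @param path output path.
#' @param dialect \code{"annotated_tsv"} or \code{"vcf"}.
#' @return \code{path}, invisibly.
#' @export
write_variant_table <- function(x, path, dialect = c("annotated_tsv", "vcf")) {
  stopifnot(inherits(x, "variant_set"))
  dialect <- match.arg(dialect)
  ok <- tryCatch({
    if (dialect == "annotated_tsv") .write_annotated_tsv(x$calls, path)
    else .write_vcf(x, path)
    TRUE
  }, error = function(e) .stopf("cannot write %s: %s", path, conditionMessage(e)))
  invisible(path)
}

.write_annotated_tsv <- function(calls, path) {
  out <- data.frame(
    Chr = .blank(calls$chrom), Pos_GRCh37 = .blank(as.character(calls$pos)),
    Ref = .blank(calls$ref), Variant = .blank(calls$alt),
    Gene_Name = .blank(calls$gene), Variant_Type = calls$variant_type,
    Transcript_ID = .blank(calls$transcript),
    Codon_Change = .blank(calls$codon_change),
    AA_Change = .blank(calls$aa_change), dbSNP_ID = .blank(calls$dbsnp_id),
    COSMIC_ID = .blank(calls$cosmic_id), snpEff_Effect = .blank(calls$effect),
    snpEff_Impact = .blank(calls$impact),
    Ref_Depth = .blank(as.character(calls$ref_depth)),
    Alt_Depth = .blank(as.character(calls$alt_depth)),
    VAF = .blank(as.character(calls$vaf)), Confidence = calls$confidence,
    stringsAsFactors = FALSE, check.names = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.write_vcf <- function(x, path) {
  calls <- x$calls
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=EFFECT,Number=1,Type=String,Description=\"Effect annotation\">",
    "##INFO=<ID=IMPACT,Number=1,Type=String,Description=\"Impact class\">",
    "##INFO=<ID=TYPE,Number=1,Type=String,Description=\"Variant type\">",
    "##FILTER=<ID=medium,Description=\"Medium-confidence call\">",
    "##FILTER=<ID=low,Description=\"Low-confidence call\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", x$sample_id, sep = "\t")
  )
  if (nrow(calls)) {
    info <- paste0(
      ifelse(is.na(calls$gene) | !nzchar(calls$gene), "",
             paste0("GENE=", calls$gene, ";")),
      ifelse(is.na(calls$effect) | !nzchar(calls$effect), "",
             paste0("EFFECT=", calls$effect, ";")),
      ifelse(is.na(calls$impact) | !nzchar(calls$impact), "",
             paste0("IMPACT=", calls$impact, ";")),
      "TYPE=", calls$variant_type)
    ad <- ifelse(is.na(calls$ref_depth) | is.na(calls$alt_depth), ".",
                 paste(calls$ref_depth, calls$alt_depth, sep = ","))
    body <- paste(
      ifelse(calls$is_cnv, "chr1", calls$chrom),
      ifelse(calls$is_cnv, "1", as.character(calls$pos)),
      ifelse(nzchar(.blank(calls$dbsnp_id)), calls$dbsnp_id, "."),
      ifelse(calls$is_cnv, "N", calls$ref),
      ifelse(calls$is_cnv, "<CNV>", calls$alt),
      ".",
      ifelse(calls$confidence == "high", "PASS", calls$confidence),
      info, "GT:AD",
      paste0("0/1:", ad),
      sep = "\t")
  } else body <- character()
  writeLines(c(header, body), path)
}

#' Read a cohort manifest
#'
#' The manifest is a tab-separated table with one row per sample and
#' columns \code{patient_id, sample_id, kind, organ, timepoint,
#' tumor_size_mm, path}.
#'
#' @param path manifest file.
#' @return data.frame of manifest rows.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) .stopf("no such manifest: %s", path)
  m <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                         na.strings = c("NA", ""))
  required <- c("patient_id", "sample_id", "kind", "organ", "timepoint",
                "tumor_size_mm", "path")
  missing <- setdiff(required, names(m))
  if (length(missing))
    .stopf("manifest %s: missing column(s): %s", path,
           paste(missing, collapse = ", "))
  m
}

#' Assemble one patient's cohort from a manifest
#'
#' Reads every sample file referenced by the manifest rows of a single
#' patient and wires the resulting \code{variant_set}s into a
#' [patient_cohort()]. Relative paths in the manifest are resolved
#' against \code{base_dir}.
#'
#' @param manifest data.frame as returned by [read_manifest()] (or a path
#'   to a manifest file); must contain exactly one patient.
#' @param base_dir directory against which relative sample paths are
#'   resolved; defaults to the manifest's directory when \code{manifest}
#'   is a path, else the working directory.
#' @param dialect passed to [read_variant_table()].
#' @return a \code{patient_cohort}.
#' @export
build_cohort <- function(manifest, base_dir = NULL, dialect = "auto") {
  if (is.character(manifest)) {
    if (is.null(base_dir)) base_dir <- dirname(manifest)
    manifest <- read_manifest(manifest)
  }
  if (is.null(base_dir)) base_dir <- "."
  if (length(unique(manifest$patient_id)) != 1L)
    .stopf("manifest error: build_cohort expects exactly one patient, got %d",
           length(unique(manifest$patient_id)))
  if (anyDuplicated(manifest$sample_id))
    .stopf("manifest error: duplicate sample_id '%s'",
           manifest$sample_id[duplicated(manifest$sample_id)][1])
  if (!any(manifest$kind == "cfdna"))
    .stopf("manifest error: patient '%s' has no cfDNA sample",
           manifest$patient_id[1])
  if (sum(manifest$kind == "tumor_primary") > 1)
    .stopf("manifest error: patient '%s' has two primary tumor samples",
           manifest$patient_id[1])
  sets <- lapply(seq_len(nrow(manifest)), function(i) {
    r <- manifest[i, ]
    p <- if (grepl("^(/|[A-Za-z]:)", r$path)) r$path else file.path(base_dir, r$path)
    read_variant_table(p, dialect = dialect, sample_id = r$sample_id,
                       patient_id = r$patient_id, kind = r$kind,
                       organ = r$organ, timepoint = r$timepoint,
                       tumor_size_mm = suppressWarnings(as.numeric(r$tumor_size_mm)))
  })
  kinds <- manifest$kind
  patient_cohort(
    patient_id = manifest$patient_id[1],
    tumor_sets = sets[kinds %in% c("tumor_primary", "tumor_metastasis")],
    cfdna_sets = sets[kinds == "cfdna"],
    germline_set = if (any(kinds == "germline")) sets[[which(kinds == "germline")[1]]]
  )
}

#' Assemble every patient in a manifest
#'
#' @inheritParams build_cohort
#' @return named list of \code{patient_cohort}s, one per patient.
#' @export
build_cohorts <- function(manifest, base_dir = NULL, dialect = "auto") {
  if (is.character(manifest)) {
    if (is.null(base_dir)) base_dir <- dirname(manifest)
    manifest <- read_manifest(manifest)
  }
  pids <- unique(manifest$patient_id)
  out <- lapply(pids, function(p)
    build_cohort(manifest[manifest$patient_id == p, , drop = FALSE],
                 base_dir = base_dir, dialect = dialect))
  names(out) <- pids
  out
}
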