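# internal helpers shared across modules

.CONFIDENCE_LEVELS <- c("low", "medium", "high")
.VARIANT_TYPES <- c("SNP", "DEL", "INS", "MNP", "CNV")
.IMPACT_LEVELS <- c("HIGH", "MODERATE", "LOW", "MODIFIER")
.SAMPLE_KINDS <- c("tumor_primary", "tumor_metastasis", "cfdna", "germline")

#' Round half away from zero
#'
#' Rounding used for all printed percentages; base \code{round()} rounds
#' half to even, which does not match the conventional half-up style of
#' clinical reports.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# natural ordering rank for chromosome labels ("chr1" < ... < "chr22" < "chrX" < "chrY" < "chrM")
.chrom_rank <- function(chrom) {
  body <- sub("^chr", "", chrom)
  r <- suppressWarnings(as.numeric(body))
  r[body == "X"] <- 23
  r[body == "Y"] <- 24
  r[body %in% c("M", "MT")] <- 25
  r[is.na(r)] <- 26
  r
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.confidence_at_least <- function(conf, min_tier) {
  match(conf, .CONFIDENCE_LEVELS) >= match(min_tier, .CONFIDENCE_LEVELS)
}

#' Panel gene symbols bundled with the package
#'
#' Symbols of the 160 oncogenes and tumor-suppressor genes of a
#' comprehensive cancer panel; the simulator draws gene labels from this
#' list so that simulated tables look like panel output.
#'
#' @return character vector of gene symbols.
#' @export
panel_genes <- function() {
  readLines(system.file("extdata", "panel_genes.txt", package = "cfconcord"))
}
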