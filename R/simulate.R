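#' Configuration for the clonal-evolution / cfDNA-shedding simulator
#'
#' Defaults describe a patient of the kind the analysis targets: an
#' autopsied cancer patient with a primary tumor plus metastases, a
#' targeted panel sequenced to ~1400x in tissue and ~5000x in plasma,
#' and a somatic burden of around 200 alterations dominated by
#' single-lesion (individual) variants.
#'
#' @param n_lesions number of tumor lesions (>= 2; >= 3 for shared
#'   variants to be plantable).
#' @param n_truncal,n_shared,n_individual planted somatic variant counts
#'   per class.
#' @param n_germline germline heterozygous polymorphisms present in
#'   every sample (true VAF 0.5).
#' @param depth mean tissue sequencing depth.
#' @param depth_dispersion negative-binomial size parameter for per-site
#'   depth (larger = less overdispersed).
#' @param purity tumor-cell fraction per lesion, recycled to
#'   \code{n_lesions}.
#' @param prevalence_range range of the carrying-clone prevalence drawn
#'   for each non-truncal somatic variant (truncal variants are clonal,
#'   prevalence 1).
#' @param cfdna_weights non-negative per-lesion contributions to plasma
#'   DNA, normalized to sum to 1; default equal.
#' @param shedding_vaf_exponent strength of the VAF dependence of cfDNA
#'   detection: a variant with plasma mixture VAF v survives an extra
#'   Bernoulli thinning with probability \code{min(1, (2v)^exponent)}.
#'   0 disables the thinning.
#' @param cfdna_depth mean plasma sequencing depth.
#' @param min_alt_reads,min_vaf calling thresholds applied to every
#'   observed sample.
#' @param n_cfdna_noise plasma-only low-VAF artifact variants.
#' @param noiseless when TRUE, depths are deterministic, thresholds are
#'   ignored and shedding is certain: every planted somatic variant is
#'   called in every carrier lesion and in cfDNA (the exact-recovery
#'   limit).
#' @param diagnosis_cfdna also emit a diagnosis-timepoint cfDNA sample
#'   containing circulating truncal variants (plus any planted
#'   presaging variants and the germline polymorphisms).
#' @param n_presaging variants planted in one metastasis (never the
#'   primary) and injected into the diagnosis cfDNA sample; requires
#'   \code{diagnosis_cfdna = TRUE}.
#' @param pos_offset constant added to every simulated genomic position;
#'   [simulate_cohort()] uses disjoint offsets to keep patients'
#'   variant keys unique across the cohort.
#' @param seed integer seed making the whole patient reproducible.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(n_lesions = 3, n_truncal = 20, n_shared = 50,
                       n_individual = 130, n_germline = 50,
                       depth = 1400, depth_dispersion = 8,
                       purity = 0.6, prevalence_range = c(0.1, 1),
                       cfdna_weights = NULL, shedding_vaf_exponent = 1,
                       cfdna_depth = 5000, min_alt_reads = 4, min_vaf = 0.01,
                       n_cfdna_noise = 30, noiseless = FALSE,
                       diagnosis_cfdna = FALSE, n_presaging = 0,
                       pos_offset = 0, seed = 1L) {
  if (n_lesions < 2) .stopf("infeasible config: n_lesions must be >= 2")
  if (n_shared > 0 && n_lesions < 3)
    .stopf("infeasible config: shared variants need n_lesions >= 3")
  if (n_presaging > 0 && !diagnosis_cfdna)
    .stopf("infeasible config: presaging variants need diagnosis_cfdna = TRUE")
  stopifnot(n_truncal >= 0, n_shared >= 0, n_individual >= 0, n_germline >= 0,
            min_alt_reads >= 0, min_vaf >= 0, depth > 0, cfdna_depth > 0)
  purity <- rep_len(purity, n_lesions)
  stopifnot(all(purity > 0), all(purity <= 1))
  if (is.null(cfdna_weights)) cfdna_weights <- rep(1, n_lesions)
  cfdna_weights <- rep_len(cfdna_weights, n_lesions)
  stopifnot(all(cfdna_weights >= 0), sum(cfdna_weights) > 0)
  cfdna_weights <- cfdna_weights / sum(cfdna_weights)
  structure(
    list(n_lesions = n_lesions, n_truncal = n_truncal, n_shared = n_shared,
         n_individual = n_individual, n_germline = n_germline, depth = depth,
         depth_dispersion = depth_dispersion, purity = purity,
         prevalence_range = prevalence_range, cfdna_weights = cfdna_weights,
         shedding_vaf_exponent = shedding_vaf_exponent,
         cfdna_depth = cfdna_depth, min_alt_reads = min_alt_reads,
         min_vaf = min_vaf, n_cfdna_noise = n_cfdna_noise,
         noiseless = noiseless, diagnosis_cfdna = diagnosis_cfdna,
         n_presaging = n_presaging, pos_offset = pos_offset,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# deterministic substream seed for (seed, label); keeps per-sample draws
# independent of how many other samples exist
.substream <- function(seed, label) {
  h <- sum(utf8ToInt(label) * (seq_len(nchar(label)) * 131)) %% 1000003L
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587)
}

.EFFECT_POOL <- data.frame(
  effect = c("INTRON", "UPSTREAM", "DOWNSTREAM", "UTR_3_PRIME",
             "SYNONYMOUS_CODING", "NON_SYNONYMOUS_CODING", "STOP_GAINED",
             "FRAME_SHIFT"),
  impact = c("MODIFIER", "MODIFIER", "MODIFIER", "MODIFIER",
             "LOW", "MODERATE", "HIGH", "HIGH"),
  prob = c(0.35, 0.10, 0.05, 0.05, 0.15, 0.22, 0.04, 0.04),
  stringsAsFactors = FALSE
)

.random_keys <- function(n, pos_offset = 0) {
  if (n == 0)
    return(data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), stringsAsFactors = FALSE))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  data.frame(
    chrom = paste0("chr", sample(1:22, n, replace = TRUE)),
    pos = pos_offset + sample.int(9000000L, n, replace = FALSE),
    ref = ref, alt = unname(alt), stringsAsFactors = FALSE
  )
}

.annotate <- function(n) {
  idx <- sample.int(nrow(.EFFECT_POOL), n, replace = TRUE,
                    prob = .EFFECT_POOL$prob)
  .EFFECT_POOL[idx, c("effect", "impact")]
}

.rdepth <- function(n, mean, size) {
  pmax(1L, stats::rnbinom(n, mu = mean, size = size))
}

# observe a vector of true VAFs in one sample: returns data.frame with
# depth, alt, called
.observe <- function(true_vaf, cfg, depth_mean, thinning_prob = NULL) {
  n <- length(true_vaf)
  if (cfg$noiseless) {
    depth <- rep(10000L, n)
    alt <- as.integer(round(true_vaf * depth))
    called <- true_vaf > 0
  } else {
    depth <- .rdepth(n, depth_mean, cfg$depth_dispersion)
    alt <- stats::rbinom(n, depth, true_vaf)
    called <- alt >= cfg$min_alt_reads & alt / depth >= cfg$min_vaf
    if (!is.null(thinning_prob))
      called <- called & stats::runif(n) < thinning_prob
  }
  data.frame(depth = depth, alt = alt, called = called)
}

#' Simulate one patient's multi-lesion cohort with known ground truth
#'
#' Plants truncal, shared and individual somatic variants plus germline
#' heterozygous polymorphisms; draws per-site tissue depths
#' (negative-binomial) and binomial alt reads at a true VAF of
#' \code{0.5 * purity * clone prevalence}; mixes the lesions into plasma
#' with the configured weights; and applies the calling thresholds plus
#' a VAF-dependent shedding thinning to decide which variants are
#' detected in cfDNA. All randomness derives from \code{config$seed}
#' through per-sample substreams, so the output is fully reproducible
#' and adding a sample does not perturb the others.
#'
#' @param config a [sim_config()].
#' @param patient_id identifier for the simulated patient.
#' @return list with \code{cohort} (a \code{patient_cohort} including a
#'   germline set) and \code{truth}, a data.frame with one row per
#'   planted variant: \code{key, gene, class, germline, presaging,
#'   prevalence, cfdna_true_vaf}, one \code{vaf_<lesion>} column per
#'   lesion (0 when absent) and one \code{in_<lesion>} presence column.
#' @export
simulate_patient <- function(config, patient_id = "SIM1") {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  L <- cfg$n_lesions
  lesion_ids <- c(paste0(patient_id, "_P"),
                  if (L > 1) paste0(patient_id, "_M", seq_len(L - 1)))

  set.seed(.substream(cfg$seed, paste0(patient_id, ":plant")))
  n_som <- cfg$n_truncal + cfg$n_shared + cfg$n_individual + cfg$n_presaging
  keys <- .random_keys(n_som + cfg$n_germline + cfg$n_cfdna_noise,
                       pos_offset = cfg$pos_offset)
  som <- keys[seq_len(n_som), , drop = FALSE]
  germ <- keys[n_som + seq_len(cfg$n_germline), , drop = FALSE]
  noise <- keys[n_som + cfg$n_germline + seq_len(cfg$n_cfdna_noise), , drop = FALSE]

  cls <- rep(c("TRUNCAL", "SHARED", "INDIVIDUAL", "PRESAGING"),
             c(cfg$n_truncal, cfg$n_shared, cfg$n_individual, cfg$n_presaging))
  presence <- matrix(FALSE, nrow = n_som, ncol = L,
                     dimnames = list(NULL, lesion_ids))
  pick1 <- function(x) x[sample.int(length(x), 1)]  # sample() scalar-safe
  presence[cls == "TRUNCAL", ] <- TRUE
  for (i in which(cls == "SHARED")) {
    k <- pick1(2:(L - 1))
    presence[i, sample.int(L, k)] <- TRUE
  }
  for (i in which(cls == "INDIVIDUAL"))
    presence[i, sample.int(L, 1)] <- TRUE
  # presaging variants live in exactly one metastasis, never the primary
  for (i in which(cls == "PRESAGING"))
    presence[i, pick1(2:L)] <- TRUE

  prevalence <- ifelse(cls == "TRUNCAL", 1,
                       stats::runif(n_som, cfg$prevalence_range[1],
                                    cfg$prevalence_range[2]))
  lesion_vaf <- presence *
    outer(0.5 * prevalence, cfg$purity[seq_len(L)])  # true VAF per lesion
  colnames(lesion_vaf) <- lesion_ids
  cfdna_vaf <- as.numeric(lesion_vaf %*% cfg$cfdna_weights)

  genes <- sample(panel_genes(), n_som + cfg$n_germline + cfg$n_cfdna_noise,
                  replace = TRUE)
  ann <- .annotate(n_som + cfg$n_germline + cfg$n_cfdna_noise)
  som_genes <- genes[seq_len(n_som)]
  som_ann <- ann[seq_len(n_som), , drop = FALSE]
  germ_genes <- genes[n_som + seq_len(cfg$n_germline)]
  germ_ann <- ann[n_som + seq_len(cfg$n_germline), , drop = FALSE]
  noise_genes <- genes[n_som + cfg$n_germline + seq_len(cfg$n_cfdna_noise)]
  noise_ann <- ann[n_som + cfg$n_germline + seq_len(cfg$n_cfdna_noise), , drop = FALSE]

  som_keys <- normalize_key(som$chrom, som$pos, som$ref, som$alt, "SNP", som_genes)
  germ_keys <- if (cfg$n_germline) normalize_key(germ$chrom, germ$pos, germ$ref,
                                                 germ$alt, "SNP", germ_genes)
               else character()

  make_calls <- function(tbl, gene, ann, obs, vaf_true) {
    sel <- obs$called
    variant_calls(
      chrom = tbl$chrom[sel], pos = tbl$pos[sel], ref = tbl$ref[sel],
      alt = tbl$alt[sel], variant_type = "SNP", gene = gene[sel],
      effect = ann$effect[sel], impact = ann$impact[sel],
      ref_depth = obs$depth[sel] - obs$alt[sel], alt_depth = obs$alt[sel],
      confidence = "high"
    )
  }

  set.seed(.substream(cfg$seed, paste0(patient_id, ":sizes")))
  sizes <- round(stats::runif(L, 10, 80))

  tumor_sets <- lapply(seq_len(L), function(l) {
    set.seed(.substream(cfg$seed, paste0(patient_id, ":lesion", l)))
    truth_vaf <- c(lesion_vaf[, l], rep(0.5, cfg$n_germline))
    obs <- .observe(truth_vaf, cfg, cfg$depth)
    tbl <- rbind(som[, c("chrom", "pos", "ref", "alt")],
                 germ[, c("chrom", "pos", "ref", "alt")])
    calls <- make_calls(tbl, c(som_genes, germ_genes),
                        rbind(som_ann, germ_ann), obs, truth_vaf)
    variant_set(sample_id = lesion_ids[l], patient_id = patient_id,
                kind = if (l == 1) "tumor_primary" else "tumor_metastasis",
                calls = calls,
                organ = if (l == 1) "lung" else paste0("metastasis_", l - 1),
                timepoint = "autopsy", tumor_size_mm = sizes[l])
  })

  # plasma sample before death: lesion mixture + germline + artifact noise
  set.seed(.substream(cfg$seed, paste0(patient_id, ":cfdna_pre")))
  thin <- if (cfg$shedding_vaf_exponent > 0)
    pmin(1, (2 * cfdna_vaf)^cfg$shedding_vaf_exponent) else NULL
  obs_som <- .observe(cfdna_vaf, cfg, cfg$cfdna_depth, thinning_prob = thin)
  obs_germ <- .observe(rep(0.5, cfg$n_germline), cfg, cfg$cfdna_depth)
  noise_vaf <- stats::runif(cfg$n_cfdna_noise, 0.005, 0.05)
  noise_depth <- if (cfg$noiseless) rep(10000L, cfg$n_cfdna_noise)
                 else .rdepth(cfg$n_cfdna_noise, cfg$cfdna_depth, cfg$depth_dispersion)
  noise_alt <- pmax(cfg$min_alt_reads, as.integer(round(noise_vaf * noise_depth)))
  obs_noise <- data.frame(depth = noise_depth, alt = noise_alt,
                          called = rep(cfg$n_cfdna_noise > 0, cfg$n_cfdna_noise))
  cf_tbl <- rbind(som[, c("chrom", "pos", "ref", "alt")],
                  germ[, c("chrom", "pos", "ref", "alt")],
                  noise[, c("chrom", "pos", "ref", "alt")])
  cf_calls <- make_calls(cf_tbl, c(som_genes, germ_genes, noise_genes),
                         rbind(som_ann, germ_ann, noise_ann),
                         rbind(obs_som, obs_germ, obs_noise),
                         c(cfdna_vaf, rep(0.5, cfg$n_germline), noise_vaf))
  cfdna_sets <- list(variant_set(
    sample_id = paste0(patient_id, "_cfDNA_pre"), patient_id = patient_id,
    kind = "cfdna", calls = cf_calls, organ = "plasma", timepoint = "pre_mortem"))

  if (cfg$diagnosis_cfdna) {
    # at diagnosis only trunk-derived DNA circulates, except for planted
    # presaging variants released by an occult metastasis
    set.seed(.substream(cfg$seed, paste0(patient_id, ":cfdna_dx")))
    dx_sel <- cls %in% c("TRUNCAL", "PRESAGING")
    dx_vaf <- ifelse(cls == "TRUNCAL", cfdna_vaf,
                     ifelse(cls == "PRESAGING", pmax(cfdna_vaf, 0.05), 0))
    obs_dx <- .observe(ifelse(dx_sel, dx_vaf, 0), cfg, cfg$cfdna_depth)
    obs_dx$called <- obs_dx$called | cls == "PRESAGING"  # planted: always present
    obs_dx$alt <- pmax(obs_dx$alt, ifelse(cls == "PRESAGING", cfg$min_alt_reads + 1L, 0L))
    obs_dxg <- .observe(rep(0.5, cfg$n_germline), cfg, cfg$cfdna_depth)
    dx_tbl <- rbind(som[, c("chrom", "pos", "ref", "alt")],
                    germ[, c("chrom", "pos", "ref", "alt")])
    dx_calls <- make_calls(dx_tbl, c(som_genes, germ_genes),
                           rbind(som_ann, germ_ann),
                           rbind(obs_dx, obs_dxg),
                           c(dx_vaf, rep(0.5, cfg$n_germline)))
    cfdna_sets <- c(cfdna_sets, list(variant_set(
      sample_id = paste0(patient_id, "_cfDNA_dx"), patient_id = patient_id,
      kind = "cfdna", calls = dx_calls, organ = "plasma",
      timepoint = "diagnosis")))
  }

  germline_set <- variant_set(
    sample_id = paste0(patient_id, "_germline"), patient_id = patient_id,
    kind = "germline",
    calls = if (cfg$n_germline) variant_calls(
      chrom = germ$chrom, pos = germ$pos, ref = germ$ref, alt = germ$alt,
      variant_type = "SNP", gene = germ_genes, effect = germ_ann$effect,
      impact = germ_ann$impact,
      ref_depth = 500L, alt_depth = 500L, confidence = "high"
    ) else .empty_calls()
  )

  truth <- data.frame(
    key = c(som_keys, germ_keys),
    gene = c(som_genes, germ_genes),
    # presaging variants sit in exactly one metastasis: INDIVIDUAL by definition
    class = c(ifelse(cls == "PRESAGING", "INDIVIDUAL", cls),
              rep("GERMLINE", cfg$n_germline)),
    germline = c(rep(FALSE, n_som), rep(TRUE, cfg$n_germline)),
    presaging = c(cls == "PRESAGING", rep(FALSE, cfg$n_germline)),
    prevalence = c(prevalence, rep(NA_real_, cfg$n_germline)),
    cfdna_true_vaf = c(cfdna_vaf, rep(0.5, cfg$n_germline)),
    stringsAsFactors = FALSE
  )
  for (l in seq_len(L)) {
    truth[[paste0("vaf_", lesion_ids[l])]] <-
      c(lesion_vaf[, l], rep(0.5, cfg$n_germline))
    truth[[paste0("in_", lesion_ids[l])]] <-
      c(presence[, l], rep(TRUE, cfg$n_germline))
  }

  list(
    cohort = patient_cohort(patient_id, tumor_sets, cfdna_sets, germline_set),
    truth = truth
  )
}

#' Simulate a multi-patient cohort with optionally planted shared keys
#'
#' Simulates \code{n_patients} independent patients (disjoint position
#' ranges keep their variant keys patient-unique) and injects the given
#' keys into the pre-mortem cfDNA sample of the selected patients, for
#' testing cross-patient sharing surveys against a known answer.
#'
#' @param n_patients number of patients (>= 2).
#' @param config a [sim_config()] applied to every patient (each patient
#'   gets its own substream of \code{config$seed}).
#' @param planted_shared_keys character vector of variant keys in
#'   \code{"chrN:pos:REF:ALT"} form to inject.
#' @param planted_in integer vector of patient indices receiving the
#'   planted keys (default: patients 1 and 2).
#' @return named list of simulation results as returned by
#'   [simulate_patient()].
#' @export
simulate_cohort <- function(n_patients, config, planted_shared_keys = character(),
                            planted_in = if (n_patients >= 2) 1:2 else 1) {
  stopifnot(n_patients >= 2, inherits(config, "sim_config"))
  sims <- lapply(seq_len(n_patients), function(i) {
    cfg <- config
    cfg$seed <- .substream(config$seed, paste0("patient", i))
    cfg$pos_offset <- config$pos_offset + (i - 1) * 10000000
    simulate_patient(cfg, patient_id = sprintf("SIM%d", i))
  })
  names(sims) <- sprintf("SIM%d", seq_len(n_patients))
  if (length(planted_shared_keys)) {
    parts <- strsplit(planted_shared_keys, ":", fixed = TRUE)
    for (i in planted_in) {
      co <- sims[[i]]$cohort
      tp <- which(vapply(co$cfdna_sets, function(s)
        identical(as.character(s$timepoint), "pre_mortem"), logical(1)))[1]
      cf <- co$cfdna_sets[[tp]]
      extra <- variant_calls(
        chrom = vapply(parts, `[[`, character(1), 1),
        pos = as.numeric(vapply(parts, `[[`, character(1), 2)),
        ref = vapply(parts, `[[`, character(1), 3),
        alt = vapply(parts, `[[`, character(1), 4),
        variant_type = "SNP", gene = "TP53",
        effect = "NON_SYNONYMOUS_CODING", impact = "MODERATE",
        ref_depth = 900L, alt_depth = 100L, confidence = "high")
      cf$calls <- .dedup_calls(rbind(cf$calls, extra))
      co$cfdna_sets[[tp]] <- cf
      sims[[i]]$cohort <- co
    }
  }
  sims
}

#' Deterministic fixture cohort with exact set sizes
#'
#' Builds a synthetic single-patient cohort whose variant sets reproduce
#' specified totals and intersections exactly, so printed worked
#' examples of the set algebra can be checked without any sequencing
#' model. Two layouts are supported:
#' \itemize{
#'   \item \code{list(tumor = , cfdna = , common = )}: one tumor lesion
#'     and one pre-mortem cfDNA sample with the given totals sharing
#'     exactly \code{common} keys. Tumor VAFs are 0.6 for shared keys
#'     and 0.1 for tumor-only keys.
#'   \item \code{list(diagnosis = , death = , common = )}: two cfDNA
#'     timepoints sharing exactly \code{common} keys (a minimal tumor
#'     set is included to satisfy cohort invariants).
#' }
#'
#' @param venn_spec named list as above.
#' @param patient_id identifier of the synthetic patient.
#' @return a \code{patient_cohort}.
#' @export
generate_fixture <- function(venn_spec, patient_id = "FIX1") {
  nm <- sort(names(venn_spec))
  mk_calls <- function(pos, vaf = 0.5) {
    n <- length(pos)
    if (n == 0) return(.empty_calls())
    depth <- 1000L
    alt <- as.integer(round(rep_len(vaf, n) * depth))
    variant_calls(chrom = "chr1", pos = pos, ref = "A", alt = "G",
                  variant_type = "SNP", gene = "TP53",
                  effect = "NON_SYNONYMOUS_CODING", impact = "MODERATE",
                  ref_depth = depth - alt, alt_depth = alt,
                  confidence = "high")
  }
  if (identical(nm, sort(c("tumor", "cfdna", "common")))) {
    nt <- venn_spec$tumor; nc <- venn_spec$cfdna; k <- venn_spec$common
    if (k > min(nt, nc))
      .stopf("infeasible venn spec: common (%d) exceeds min(tumor, cfdna) = %d",
             k, min(nt, nc))
    common_pos <- seq_len(k)
    tumor_pos <- c(common_pos, k + seq_len(nt - k))
    cfdna_pos <- c(common_pos, nt + seq_len(nc - k))
    tumor <- variant_set(paste0(patient_id, "_T"), patient_id, "tumor_primary",
                         mk_calls(tumor_pos, c(rep(0.6, k), rep(0.1, nt - k))),
                         organ = "lung", timepoint = "autopsy")
    cfdna <- variant_set(paste0(patient_id, "_cf"), patient_id, "cfdna",
                         mk_calls(cfdna_pos, 0.3), organ = "plasma",
                         timepoint = "pre_mortem")
    return(patient_cohort(patient_id, list(tumor), list(cfdna)))
  }
  if (identical(nm, sort(c("diagnosis", "death", "common")))) {
    nd <- venn_spec$diagnosis; nx <- venn_spec$death; k <- venn_spec$common
    if (k > min(nd, nx))
      .stopf("infeasible venn spec: common (%d) exceeds min(diagnosis, death) = %d",
             k, min(nd, nx))
    common_pos <- seq_len(k)
    dx_pos <- c(common_pos, k + seq_len(nd - k))
    death_pos <- c(common_pos, nd + seq_len(nx - k))
    dx <- variant_set(paste0(patient_id, "_cf_dx"), patient_id, "cfdna",
                      mk_calls(dx_pos, 0.3), organ = "plasma",
                      timepoint = "diagnosis")
    death <- variant_set(paste0(patient_id, "_cf_pre"), patient_id, "cfdna",
                         mk_calls(death_pos, 0.3), organ = "plasma",
                         timepoint = "pre_mortem")
    tumor <- variant_set(paste0(patient_id, "_T"), patient_id, "tumor_primary",
                         mk_calls(10000000 + 1:2, 0.5), organ = "lung",
                         timepoint = "autopsy")
    return(patient_cohort(patient_id, list(tumor), list(dx, death)))
  }
  .stopf("venn_spec must name either {tumor, cfdna, common} or {diagnosis, death, common}")
}

#' Write a simulated patient to disk as pipeline input
#'
#' Emits per-sample variant tables (annotated TSV or VCF), the ground
#' truth table, and a cohort manifest, so the complete file-based
#' pipeline can run end-to-end on simulator output.
#'
#' @param sim result of [simulate_patient()].
#' @param dir output directory (created if needed).
#' @param dialect \code{"annotated_tsv"} or \code{"vcf"}.
#' @return path of the manifest file, invisibly.
#' @export
write_simulated_patient <- function(sim, dir, dialect = "annotated_tsv") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  co <- sim$cohort
  ext <- if (dialect == "vcf") ".vcf" else ".tsv"
  sets <- c(co$tumor_sets, co$cfdna_sets,
            if (!is.null(co$germline_set)) list(co$germline_set))
  rows <- lapply(sets, function(s) {
    fn <- paste0(s$sample_id, ext)
    write_variant_table(s, file.path(dir, fn), dialect)
    data.frame(patient_id = s$patient_id, sample_id = s$sample_id,
               kind = s$kind, organ = s$organ,
               timepoint = as.character(s$timepoint),
               tumor_size_mm = s$tumor_size_mm, path = fn,
               stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file.path(dir, "manifest.tsv"))
}
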