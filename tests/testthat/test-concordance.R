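test_that("germline subtraction removes exactly the germline keys", {
  x <- mk_set(1:3, "T")
  g <- mk_set(2, "GL", kind = "germline")
  expect_equal(variant_keys(subtract_germline(x, g)),
               paste0("chr1:", c(1, 3), ":A:G"))
  # empty germline is the identity; subtraction is idempotent
  expect_equal(variant_keys(subtract_germline(x, mk_set(integer(0), "GL0", kind = "germline"))),
               variant_keys(x))
  expect_equal(subtract_germline(subtract_germline(x, g), g),
               subtract_germline(x, g))
  expect_error(subtract_germline(x, mk_set(1, "GLX", patient_id = "P2",
                                           kind = "germline")),
               "patient mismatch")
})

test_that("germline hets vanish from every sample of a simulated patient", {
  sim <- simulate_patient(sim_config(seed = 21))
  g <- sim$cohort$germline_set
  gkeys <- sim$truth$key[sim$truth$germline]
  expect_setequal(variant_keys(g), gkeys)
  for (s in c(sim$cohort$tumor_sets, sim$cohort$cfdna_sets)) {
    som <- subtract_germline(s, g)
    expect_equal(sum(variant_keys(som) %in% gkeys), 0L)
    # nothing non-germline was removed
    expect_setequal(variant_keys(som), setdiff(variant_keys(s), gkeys))
  }
})

test_that("confidence filtering respects the tier order and commutes with subtraction", {
  calls <- variant_calls(chrom = "1", pos = 1:3, ref = "A", alt = "G",
                         ref_depth = 50L, alt_depth = 50L,
                         confidence = c("high", "medium", "low"))
  s <- variant_set("S", "P1", "tumor_primary", calls)
  expect_equal(length(filter_confidence(s, "high")), 1L)
  expect_equal(length(filter_confidence(s, "medium")), 2L)
  expect_equal(length(filter_confidence(s, "low")), 3L)
  g <- mk_set(2, "GL", kind = "germline")
  expect_equal(filter_confidence(subtract_germline(s, g), "medium"),
               subtract_germline(filter_confidence(s, "medium"), g))
})

test_that("venn counts satisfy exact conservation and reproduce worked overlaps", {
  # primary lesion with 891 alterations, 9 of them in a 119-alteration cfDNA
  co <- generate_fixture(list(tumor = 891, cfdna = 119, common = 9))
  v <- venn(co$tumor_sets[[1]], co$cfdna_sets[[1]])
  expect_equal(v$n_tumor_only, 882)
  expect_equal(v$n_cfdna_only, 110)
  expect_equal(v$n_common + v$n_tumor_only, v$n_tumor)
  expect_equal(v$n_common + v$n_cfdna_only, v$n_cfdna)
  expect_equal(round_half_up(100 * v$detection_rate, 1), 1.0)

  # 97-alteration lesion sharing 34 with an 87-alteration cfDNA
  co2 <- generate_fixture(list(tumor = 97, cfdna = 87, common = 34))
  v2 <- venn(co2$tumor_sets[[1]], co2$cfdna_sets[[1]])
  expect_equal(v2$n_tumor_only, 63)
  expect_equal(v2$n_cfdna_only, 53)
  expect_equal(v2$detection_rate, 34 / 97, tolerance = 1e-12)

  v3 <- venn(mk_set(1:5), mk_set(11:15, "CF", kind = "cfdna"))
  expect_equal(v3$n_common, 0L)
  expect_equal(v3$detection_rate, 0)
  v4 <- venn(mk_set(integer(0)), mk_set(1:3, "CF", kind = "cfdna"))
  expect_true(v4$rate_undefined)
  expect_true(is.na(v4$detection_rate))
})

test_that("classification follows the breadth definitions including the two-lesion rule", {
  co <- mk_cohort(list(c(1, 2, 3), c(1, 2, 9), c(1, 10, 11)), cf_pos = c(1, 10))
  cl <- classify_mutations(co)
  got <- setNames(cl$mclass, sub("chr1:(\\d+):A:G", "\\1", cl$key))
  expect_equal(got[["1"]], "TRUNCAL")     # in all three lesions
  expect_equal(got[["2"]], "SHARED")      # in two of three
  expect_equal(got[["3"]], "INDIVIDUAL")  # in one
  expect_equal(unname(got[c("9", "10", "11")]), rep("INDIVIDUAL", 3))
  expect_equal(cl$in_cfdna, cl$key %in% c("chr1:1:A:G", "chr1:10:A:G"))
  # partition: class counts sum to the union of tumor keys
  expect_equal(nrow(cl), 6L)

  # two lesions: both -> TRUNCAL, never SHARED
  co2 <- mk_cohort(list(c(1, 2), c(1, 3)), cf_pos = 1)
  cl2 <- classify_mutations(co2)
  expect_setequal(unique(cl2$mclass), c("TRUNCAL", "INDIVIDUAL"))
  expect_equal(cl2$mclass[cl2$key == "chr1:1:A:G"], "TRUNCAL")

  # literal "more than two sites" reading demotes two-of-three variants
  cl3 <- classify_mutations(co, rule = "more_than_two")
  expect_equal(cl3$mclass[cl3$key == "chr1:2:A:G"], "INDIVIDUAL")
  expect_equal(cl3$mclass[cl3$key == "chr1:1:A:G"], "TRUNCAL")
})

test_that("classification is invariant under tumor-set reordering", {
  co <- mk_cohort(list(c(1, 2, 3), c(1, 2, 9), c(1, 10, 11)), cf_pos = 1)
  co_rev <- patient_cohort("P1", rev(co$tumor_sets), co$cfdna_sets)
  a <- classify_mutations(co)
  b <- classify_mutations(co_rev)
  a <- a[order(a$key), c("key", "mclass", "n_lesions_present")]
  b <- b[order(b$key), c("key", "mclass", "n_lesions_present")]
  expect_equal(a, b, ignore_attr = TRUE)
})

test_that("single-tumor cohorts classify everything truncal with a warning", {
  co <- mk_cohort(list(1:4), cf_pos = 1:2)
  expect_warning(cl <- classify_mutations(co), "single tumor")
  expect_equal(unique(cl$mclass), "TRUNCAL")
})

test_that("per-class detection reports rates and limit cases", {
  co <- mk_cohort(list(c(1:10), c(1:10, 21:25), c(1:10, 31:35)),
                  cf_pos = c(1:10))
  s <- per_class_detection(classify_mutations(co))$summary
  expect_equal(s$rate[s$class == "TRUNCAL"], 1.0)
  expect_equal(s$rate[s$class == "INDIVIDUAL"], 0.0)
  expect_true(is.na(s$rate[s$class == "SHARED"]))  # empty class flagged absent

  # noiseless full-shedding simulation: every class fully detected
  sim <- simulate_patient(sim_config(seed = 5, noiseless = TRUE,
                                     n_cfdna_noise = 0))
  pcd <- per_class_detection(classify_mutations(somatic_cohort(sim$cohort)))
  expect_equal(pcd$summary$rate, c(1, 1, 1))
  expect_true(all(pcd$summary$n_in_cfdna <= pcd$summary$n_total))
})

test_that("functional filter keeps protein-altering calls and drops region/synonymous ones", {
  calls <- variant_calls(
    chrom = "1", pos = 1:6, ref = "A", alt = "G",
    effect = c("NON_SYNONYMOUS_CODING", "SYNONYMOUS_CODING", "INTRON",
               "UPSTREAM", "UTR_3_PRIME", "STOP_GAINED"),
    impact = c("MODERATE", "LOW", "MODIFIER", "MODIFIER", "MODIFIER", "HIGH"),
    ref_depth = 50L, alt_depth = 50L)
  s <- variant_set("S", "P1", "tumor_primary", calls)
  kept <- functional_filter(s)
  expect_setequal(kept$calls$effect, c("NON_SYNONYMOUS_CODING", "STOP_GAINED"))
  # CNVs carry no annotation and are kept; unannotated SNVs warn but stay
  cnv <- variant_calls(chrom = "1", pos = 1, ref = "", alt = "",
                       variant_type = "CNV", gene = "EGFR")
  s2 <- variant_set("S2", "P1", "tumor_primary", cnv)
  expect_equal(length(functional_filter(s2)), 1L)
  unann <- variant_calls(chrom = "1", pos = 7, ref = "A", alt = "G",
                         ref_depth = 50L, alt_depth = 50L)
  s3 <- variant_set("S3", "P1", "tumor_primary", unann)
  expect_warning(k3 <- functional_filter(s3), "without effect")
  expect_equal(length(k3), 1L)
})

test_that("cross-patient survey recovers exactly the planted shared keys", {
  planted <- sprintf("chr9:%d:A:G", 600000001:600000010)
  sims <- simulate_cohort(6, sim_config(seed = 13, n_truncal = 10,
                                        n_shared = 10, n_individual = 20,
                                        n_germline = 5, n_cfdna_noise = 3),
                          planted_shared_keys = planted, planted_in = 1:2)
  sets <- lapply(sims, function(s)
    cfdna_at(somatic_cohort(s$cohort)))
  shared <- cross_patient_shared(sets, min_patients = 2)
  expect_setequal(shared$key, planted)
  expect_equal(unique(shared$n_patients), 2L)
  expect_equal(unique(shared$patients), "SIM1,SIM2")
  # deterministic ordering by position
  expect_equal(shared$key, planted[order(as.integer(sub("chr9:(\\d+):.*", "\\1", planted)))])

  # disjoint cfDNA sets -> empty survey
  none <- cross_patient_shared(sets[3:6], min_patients = 2)
  expect_equal(nrow(none), 0L)
  # planted everywhere -> each key lists all patients
  sims2 <- simulate_cohort(3, sim_config(seed = 14, n_truncal = 5, n_shared = 5,
                                         n_individual = 5, n_germline = 0,
                                         n_cfdna_noise = 0),
                           planted_shared_keys = planted[1], planted_in = 1:3)
  sets2 <- lapply(sims2, function(s) cfdna_at(somatic_cohort(s$cohort)))
  sh2 <- cross_patient_shared(sets2)
  expect_equal(sh2$key, planted[1])
  expect_equal(sh2$n_patients, 3L)
})

test_that("gene-level tumor/cfDNA sharing requires identical keys", {
  t1 <- variant_set("T1", "P1", "tumor_primary", variant_calls(
    chrom = c("7", "7"), pos = c(55259515, 55249071), ref = "T", alt = c("G", "C"),
    gene = c("EGFR", "EGFR"), ref_depth = 50L, alt_depth = 50L))
  cf_same <- variant_set("CF", "P1", "cfdna", variant_calls(
    chrom = "7", pos = 55259515, ref = "T", alt = "G", gene = "EGFR",
    ref_depth = 60L, alt_depth = 40L), timepoint = "pre_mortem")
  co <- patient_cohort("P1", list(t1), list(cf_same))
  g <- genes_shared_tumor_cfdna(co)
  expect_equal(g$gene, "EGFR")
  expect_equal(g$types, "SNP")

  # same gene, different nucleotide: not shared at key level
  cf_diff <- variant_set("CF", "P1", "cfdna", variant_calls(
    chrom = "7", pos = 55242465, ref = "G", alt = "A", gene = "EGFR",
    ref_depth = 60L, alt_depth = 40L), timepoint = "pre_mortem")
  co2 <- patient_cohort("P1", list(t1), list(cf_diff))
  expect_equal(nrow(genes_shared_tumor_cfdna(co2)), 0L)
  co3 <- patient_cohort("P1", list(t1),
                        list(mk_set(integer(0), "CF", kind = "cfdna")))
  expect_equal(nrow(genes_shared_tumor_cfdna(co3)), 0L)
})

test_that("detectability-vs-size handles degenerate, perfect and simulated inputs", {
  mk_size_cohort <- function(sizes, rates, pid) {
    # one lesion per (size, rate): rate achieved by n detected of 10
    lesions <- lapply(seq_along(sizes), function(i)
      mk_set(100 * i + 1:10, paste0(pid, "_T", i), patient_id = pid,
             kind = if (i == 1) "tumor_primary" else "tumor_metastasis",
             tumor_size_mm = sizes[i]))
    cf_pos <- unlist(lapply(seq_along(sizes), function(i)
      100 * i + seq_len(round(10 * rates[i]))))
    patient_cohort(pid, lesions,
                   list(mk_set(cf_pos, paste0(pid, "_CF"), patient_id = pid,
                               kind = "cfdna", timepoint = "pre_mortem")))
  }
  perfect <- mk_size_cohort(c(10, 20, 30, 40), c(0.1, 0.3, 0.6, 0.9), "P1")
  r <- detectability_vs_size(perfect)
  expect_equal(r$spearman_rho, 1.0)
  flat <- mk_size_cohort(c(25, 25, 25), c(0.1, 0.5, 0.9), "P2")
  expect_true(detectability_vs_size(flat)$degenerate)
  small <- mk_size_cohort(c(10, 20), c(0.2, 0.4), "P3")
  expect_true(detectability_vs_size(small)$insufficient)

  # size-independent shedding: correlation should typically be weak
  sims <- lapply(1:8, function(s) simulate_patient(sim_config(seed = 300 + s)))
  rs <- detectability_vs_size(lapply(sims, function(s) somatic_cohort(s$cohort)))
  expect_equal(rs$n, 24L)
  expect_lt(abs(rs$spearman_rho), 0.5)
})

test_that("somatic_cohort applies subtraction and filtering to every member", {
  sim <- simulate_patient(sim_config(seed = 17))
  co <- somatic_cohort(sim$cohort)
  gkeys <- variant_keys(sim$cohort$germline_set)
  for (s in c(co$tumor_sets, co$cfdna_sets)) {
    expect_equal(sum(variant_keys(s) %in% gkeys), 0L)
    expect_true(all(s$calls$confidence == "high"))
  }
})
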