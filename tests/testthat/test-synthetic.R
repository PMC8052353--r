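test_that("simulation is fully reproducible from its seed", {
  a <- simulate_patient(sim_config(seed = 11))
  b <- simulate_patient(sim_config(seed = 11))
  expect_identical(a, b)
  c <- simulate_patient(sim_config(seed = 12))
  expect_false(identical(a$truth$key, c$truth$key))
})

test_that("planted structure matches the configured counts and definitions", {
  cfg <- sim_config(seed = 2, n_truncal = 15, n_shared = 25, n_individual = 40,
                    n_germline = 12, n_lesions = 4)
  sim <- simulate_patient(cfg)
  tr <- sim$truth
  expect_equal(sum(tr$class == "TRUNCAL"), 15)
  expect_equal(sum(tr$class == "SHARED"), 25)
  expect_equal(sum(tr$class == "INDIVIDUAL"), 40)
  expect_equal(sum(tr$germline), 12)
  pres <- as.matrix(tr[, grep("^in_", names(tr))])
  n_present <- rowSums(pres)
  expect_true(all(n_present[tr$class == "TRUNCAL" & !tr$germline] == 4))
  expect_true(all(n_present[tr$class == "SHARED"] %in% 2:3))
  expect_true(all(n_present[tr$class == "INDIVIDUAL"] == 1))
  # true VAF = 0.5 * purity * prevalence in carrier lesions, 0 elsewhere
  vafs <- as.matrix(tr[, grep("^vaf_", names(tr))])
  som <- !tr$germline
  expect_equal(vafs[som, ] > 0, pres[som, ], ignore_attr = TRUE)
  expect_true(all(vafs[som, ][pres[som, ]] <= 0.5 * max(cfg$purity)))
  truncal_vaf <- vafs[tr$class == "TRUNCAL" & !tr$germline, 1]
  expect_equal(unique(truncal_vaf), 0.5 * cfg$purity[1])  # clonal trunk
})

test_that("noiseless limit calls every planted variant everywhere it exists", {
  sim <- simulate_patient(sim_config(seed = 5, noiseless = TRUE,
                                     n_cfdna_noise = 0))
  tr <- sim$truth[!sim$truth$germline, ]
  co <- somatic_cohort(sim$cohort)
  for (l in seq_along(co$tumor_sets)) {
    want <- tr$key[tr[[paste0("in_", names(co$tumor_sets)[l])]]]
    expect_setequal(variant_keys(co$tumor_sets[[l]]), want)
  }
  expect_setequal(variant_keys(cfdna_at(co)), tr$key)
  cl <- classify_mutations(co)
  m <- merge(cl[, c("key", "mclass")], tr[, c("key", "class")], by = "key")
  expect_equal(nrow(m), nrow(tr))
  expect_equal(mean(m$mclass == m$class), 1)
})

test_that("deeper cfDNA sequencing increases detection in expectation", {
  rate_at <- function(depth, seeds) {
    mean(vapply(seeds, function(s) {
      sim <- simulate_patient(sim_config(seed = s, cfdna_depth = depth))
      cl <- classify_mutations(somatic_cohort(sim$cohort))
      mean(cl$in_cfdna)
    }, numeric(1)))
  }
  # depths chosen inside the depth-limited regime (below them the
  # min_alt_reads threshold dominates; far above, min_vaf saturates gains)
  seeds <- 1:12
  shallow <- rate_at(30, seeds)
  mid <- rate_at(150, seeds)
  deep <- rate_at(600, seeds)
  expect_lt(shallow, mid)
  expect_lt(mid, deep)
})

test_that("fixture generator meets specified set sizes exactly and rejects infeasible specs", {
  co <- generate_fixture(list(tumor = 50, cfdna = 20, common = 5))
  v <- venn(co$tumor_sets[[1]], co$cfdna_sets[[1]])
  expect_equal(c(v$n_tumor, v$n_cfdna, v$n_common), c(50, 20, 5))
  expect_error(generate_fixture(list(tumor = 10, cfdna = 5, common = 7)),
               "infeasible")
  expect_error(generate_fixture(list(a = 1)), "venn_spec")
})

test_that("simulated cohort files drive the full file-based pipeline", {
  sim <- simulate_patient(sim_config(seed = 19, diagnosis_cfdna = TRUE))
  for (dialect in c("annotated_tsv", "vcf")) {
    d <- withr::local_tempdir()
    write_simulated_patient(sim, d, dialect)
    co <- build_cohort(file.path(d, "manifest.tsv"))
    expect_setequal(names(co$cfdna_sets), c("pre_mortem", "diagnosis"))
    for (nm in names(co$tumor_sets))
      expect_setequal(variant_keys(co$tumor_sets[[nm]]),
                      variant_keys(sim$cohort$tumor_sets[[nm]]))
    truth <- utils::read.delim(file.path(d, "truth.tsv"))
    expect_setequal(truth$key, sim$truth$key)
  }
})
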