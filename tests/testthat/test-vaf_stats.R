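test_that("VAF is alt over total depth, scale-invariant, with limits", {
  expect_equal(compute_vaf(50, 50), 0.5)
  expect_equal(compute_vaf(70, 30), 0.30)
  expect_equal(compute_vaf(0, 40), 1.0)
  for (k in c(1, 2, 7, 100))
    expect_equal(compute_vaf(k * 70, k * 30), 0.30)
  expect_error(compute_vaf(0, 0), "zero total depth")
  expect_error(compute_vaf(-1, 5), "negative")
})

test_that("Mann-Whitney agrees with exhaustive rank-assignment enumeration", {
  r <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 0.1)  # 2/20 rank assignments as extreme
  expect_equal(r$method, "exact")

  set.seed(99)
  for (i in 1:20) {
    nx <- sample(2:5, 1); ny <- sample(2:5, 1)
    x <- round(rnorm(nx), 6); y <- round(rnorm(ny, 0.5), 6)
    got <- mann_whitney_u(x, y)
    want <- mw_exact_oracle(x, y)
    expect_equal(got$U, want$U)
    expect_equal(got$p_value, want$p, tolerance = 1e-12)
  }
  expect_error(mann_whitney_u(numeric(0), 1), "empty")
})

test_that("identical single values give p = 1 and large samples match the closed form", {
  expect_equal(mann_whitney_u(1, 1)$p_value, 1, tolerance = 1e-9)
  # independent normal-approximation formula with tie and continuity correction
  approx_oracle <- function(x, y) {
    nx <- length(x); ny <- length(y); r <- rank(c(x, y))
    u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
    ties <- table(r)
    sigma <- sqrt(nx * ny / 12 * ((nx + ny + 1) -
                                    sum(ties^3 - ties) / ((nx + ny) * (nx + ny - 1))))
    z <- (u - nx * ny / 2 - sign(u - nx * ny / 2) * 0.5) / sigma
    2 * stats::pnorm(-abs(z))
  }
  set.seed(4)
  for (i in 1:10) {
    x <- rnorm(30); y <- rnorm(30, 0.3)
    expect_equal(mann_whitney_u(x, y, mode = "approx")$p_value,
                 approx_oracle(x, y), tolerance = 1e-8)
  }
})

test_that("exact and approximate Mann-Whitney p agree closely for small tie-free samples", {
  set.seed(11)
  for (i in 1:200) {
    x <- rnorm(5); y <- rnorm(5)
    pe <- mann_whitney_u(x, y, mode = "exact")$p_value
    pa <- mann_whitney_u(x, y, mode = "approx")$p_value
    expect_lt(abs(pe - pa), 0.02)
  }
})

test_that("Yates chi-square matches the clamped closed form and its symmetries", {
  got <- chi_square_yates(matrix(c(10, 90, 40, 60), 2, byrow = TRUE))
  want <- yates_oracle(10, 90, 40, 60)
  expect_equal(got$statistic, want$statistic, tolerance = 1e-12)
  expect_equal(got$p_value, want$p, tolerance = 1e-12)

  even <- chi_square_yates(c(5, 5, 5, 5))
  expect_equal(even$statistic, 0)
  expect_equal(even$p_value, 1)
  # |ad-bc| <= N/2 clamps to zero
  expect_equal(chi_square_yates(c(5, 5, 5, 6))$statistic, 0)

  m <- matrix(c(12, 7, 3, 21), 2, byrow = TRUE)
  base <- chi_square_yates(m)$statistic
  expect_equal(chi_square_yates(t(m))$statistic, base)
  expect_equal(chi_square_yates(m[2:1, ])$statistic, base)
  expect_equal(chi_square_yates(m[, 2:1])$statistic, base)

  expect_error(chi_square_yates(c(0, 0, 3, 4)), "zero row or column")
})

test_that("mean_ci95 covers the truth at the nominal rate and handles edge cases", {
  z <- mean_ci95(c(0.5, 0.5, 0.5))
  expect_equal(z$mean, 0.5)
  expect_equal(z$upper - z$lower, 0)
  s <- mean_ci95(c(0, 1))
  expect_equal(s$mean, 0.5)
  expect_equal(s$upper - s$mean, s$mean - s$lower)
  one <- mean_ci95(0.3)
  expect_true(one$degenerate)
  expect_equal(c(one$lower, one$upper), c(0.3, 0.3))
  expect_error(mean_ci95(numeric(0)), "empty")

  set.seed(7)
  hits <- vapply(1:400, function(i) {
    x <- rnorm(10, mean = 2)
    ci <- mean_ci95(x)
    ci$lower <= 2 && 2 <= ci$upper
  }, logical(1))
  expect_gt(mean(hits), 0.91)
  expect_lt(mean(hits), 0.99)
})

test_that("VAF stratification partitions the lesion and flags empty strata", {
  lesion <- mk_set(1:4, "T", vaf = c(0.6, 0.6, 0.1, 0.1))
  cf <- mk_set(1:2, "CF", kind = "cfdna")
  st <- stratify_vaf(lesion, cf)
  expect_equal(st$mean_detected, 0.6)
  expect_equal(st$mean_undetected, 0.1)
  expect_equal(st$n_detected + st$n_undetected, length(lesion))
  expect_true(st$mean_detected >= st$ci95_detected[1] &&
                st$mean_detected <= st$ci95_detected[2])

  # cfDNA superset of lesion: undetected stratum empty, p absent
  st2 <- stratify_vaf(lesion, mk_set(1:10, "CF", kind = "cfdna"))
  expect_equal(st2$n_undetected, 0L)
  expect_true(st2$flagged)
  expect_true(is.na(st2$p_value))

  # CNV records are excluded from VAF analyses
  cnv <- variant_calls(chrom = "1", pos = 1, ref = "", alt = "",
                       variant_type = "CNV", gene = "MET")
  lesion_cnv <- variant_set("T2", "P1", "tumor_primary",
                            rbind(lesion$calls, cnv))
  st3 <- stratify_vaf(lesion_cnv, cf)
  expect_equal(st3$n_detected + st3$n_undetected, 4L)
})

test_that("VAF-dependent shedding raises the detected stratum's mean VAF", {
  set.seed(1)
  ok <- vapply(1:40, function(s) {
    sim <- simulate_patient(sim_config(seed = 5000 + s))
    co <- somatic_cohort(sim$cohort)
    cf <- cfdna_at(co)
    st <- stratify_vaf(co$tumor_sets[[1]], cf)
    if (st$flagged) return(NA)
    st$mean_detected > st$mean_undetected
  }, logical(1))
  expect_gt(mean(ok, na.rm = TRUE), 0.9)
})

test_that("cfDNA-only variants have lower VAF than tumor-corroborated ones", {
  sim <- simulate_patient(sim_config(seed = 31))
  co <- somatic_cohort(sim$cohort)
  cmp <- cfdna_only_vaf_comparison(co)
  expect_equal(cmp$n_cfdna_only + cmp$n_in_tumor, length(cfdna_at(co)))
  expect_lt(cmp$mean_vaf_cfdna_only, cmp$mean_vaf_in_tumor)

  # disjoint / subset limit cases
  co2 <- mk_cohort(list(1:3), cf_pos = 11:13)
  cmp2 <- suppressWarnings(cfdna_only_vaf_comparison(co2))
  expect_true(is.na(cmp2$mean_vaf_in_tumor))
  co3 <- mk_cohort(list(1:5), cf_pos = 1:3)
  cmp3 <- suppressWarnings(cfdna_only_vaf_comparison(co3))
  expect_true(is.na(cmp3$mean_vaf_cfdna_only))
})
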