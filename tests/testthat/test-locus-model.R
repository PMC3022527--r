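test_that("Hardy-Weinberg expansion handles fixation, symmetry and domain errors", {
  expect_equal(unname(genotype_distribution(0)), c(1, 0, 0))
  expect_equal(unname(genotype_distribution(0.5)), c(0.25, 0.5, 0.25))
  g <- genotype_distribution(0.04)
  expect_equal(unname(g), c(0.96^2, 2 * 0.04 * 0.96, 0.04^2))
  expect_equal(sum(g), 1)
  expect_error(genotype_distribution(-0.1), "maf")
  expect_error(genotype_distribution(1.2), "maf")
})

test_that("compound carrier frequency matches joint-genotype enumeration", {
  expect_identical(compound_carrier_frequency(locus_model(list())), 0)
  m1 <- locus_model(list(risk_variant("v", 0.03, 2)))
  expect_equal(compound_carrier_frequency(m1), 1 - 0.97^2)
  mafs <- c(0.04, 0.01, 0.02)
  m3 <- locus_model(mapply(function(i, p) risk_variant(paste0("v", i), p, 2),
                           1:3, mafs, SIMPLIFY = FALSE))
  expect_equal(compound_carrier_frequency(m3), carrier_freq_enum(mafs),
               tolerance = 1e-12)
})

test_that("odds-ratio calibration reproduces its targets through the penetrance table", {
  expect_equal(unname(calibrate_relative_risks(1, 1, 0.02, 0.01)), c(1, 1))

  # rare-disease limit at small maf: OR targets converge to relative-risk
  # targets (the carrier target is a het/hom mixture, so grr_het approaches 3
  # only as the homozygote weight p/(2-p) vanishes)
  g <- calibrate_relative_risks(3, 38, 0.001, 1e-6)
  expect_equal(unname(g), c(3, 38), tolerance = 0.01)
  w_hom <- 0.001 / (2 - 0.001)
  expect_equal(g[["grr_het"]], (3 - w_hom * 38) / (1 - w_hom), tolerance = 1e-3)

  # full-table case: recompute both odds ratios from the implied penetrances
  f0 <- 0.01; maf <- 0.02
  g <- calibrate_relative_risks(3, 38, maf, f0)
  f1 <- f0 * g[["grr_het"]]; f2 <- f0 * g[["grr_hom"]]
  hw <- genotype_distribution(maf)
  f_car <- (hw[["het"]] * f1 + hw[["hom"]] * f2) / (hw[["het"]] + hw[["hom"]])
  odds <- function(x) x / (1 - x)
  expect_equal(odds(f_car) / odds(f0), 3, tolerance = 1e-10)
  expect_equal(odds(f2) / odds(f0), 38, tolerance = 1e-10)

  # implied heterozygote penetrance <= 0: carrier target below the hom share
  expect_error(calibrate_relative_risks(0.5, 38, 0.4, 0.3), "infeasible")
  # implied heterozygote penetrance >= 1
  expect_error(calibrate_relative_risks(1e4, 1, 0.01, 0.5), "infeasible")
})

test_that("familial risks: null locus, enumeration-oracle grid, and orderings", {
  null <- familial_risks(locus_model(list()))
  expect_equal(c(null$lambda_o, null$lambda_m, null$lambda_s), c(1, 1, 1))

  for (f0 in c(0.001, 0.01, 0.05)) {
    for (p in c(0.005, 0.01, 0.04)) {
      prev_ls <- -Inf
      for (g1 in c(1, 2, 3, 5)) {
        m <- locus_model(list(risk_variant("v", p, g1)),
                         baseline_penetrance = f0)
        fr <- familial_risks(m)
        expect_equal(fr$lambda_s, lambda_s_enum(p, g1, g1^2, f0),
                     tolerance = 1e-10)
        expect_equal(fr$lambda_o, lambda_o_enum(p, g1, g1^2, f0),
                     tolerance = 1e-10)
        # lambda_s non-decreasing in the heterozygote risk; 1 at the null
        expect_gte(fr$lambda_s, max(1, prev_ls))
        if (g1 == 1) expect_equal(fr$lambda_s, 1)
        expect_gte(fr$lambda_m, fr$lambda_s)
        expect_gte(fr$lambda_s, fr$lambda_o)
        expect_gte(fr$lambda_o, 1)
        prev_ls <- fr$lambda_s
      }
    }
  }
})

test_that("locus-level risks with one variant equal the single-variant formula", {
  v <- risk_variant("v", 0.01, 3, 11) # deliberately non-multiplicative
  single <- familial_risks(locus_model(list(v)))
  expect_equal(single$lambda_s, single$per_variant$lambda_s[1])
  expect_equal(single$lambda_s, lambda_s_enum(0.01, 3, 11), tolerance = 1e-10)
})

test_that("locus model config round-trips and rejects malformed input", {
  m <- nod2_model()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_locus_model(m, path)
  m2 <- read_locus_model(path)
  expect_equal(variant_ids <- vapply(m2$variants, `[[`, "", "id"),
               vapply(m$variants, `[[`, "", "id"))
  for (i in 1:3) {
    expect_equal(m2$variants[[i]]$maf, m$variants[[i]]$maf)
    expect_equal(m2$variants[[i]]$grr_het, m$variants[[i]]$grr_het)
    expect_equal(m2$variants[[i]]$grr_hom, m$variants[[i]]$grr_hom)
  }
  expect_equal(m2$baseline_penetrance, m$baseline_penetrance)

  expect_error(locus_model(list(risk_variant("a", 0.7, 2))), "maf")
  expect_error(risk_variant("a", 0.1, -1), "non-negative")
  expect_error(locus_model(list(risk_variant("a", 0.1, 2),
                                risk_variant("a", 0.2, 2))), "unique")
})

test_that("prevalence and penetrance behave under the multiplicative joint model", {
  m <- nod2_model()
  K <- prevalence(m)
  expect_gt(K, m$baseline_penetrance) # risk-increasing model
  expect_lt(K, 1)
  # non-carriers sit at baseline; penetrance clamps at 1 for extreme dosage
  f <- synthassoc:::penetrance_from_dosage(m, matrix(c(0, 0, 0, 2, 2, 2),
                                                     2, 3, byrow = TRUE))
  expect_equal(f[1], m$baseline_penetrance)
  expect_lte(f[2], 1)
})
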