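test_that("trend test: balanced table gives zero statistic, worked example matches closed form", {
  v <- table_to_vectors(c(10, 20, 10), c(10, 20, 10))
  res <- trend_test(v$dosage, v$phenotype)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  # frozen value computed from the closed-form oracle:
  # T = 10, Var = 8.75, chi2 = 100 / 8.75
  cases <- c(10, 20, 10); controls <- c(20, 20, 0)
  expect_equal(trend_stat_oracle(cases, controls), 100 / 8.75)
  v <- table_to_vectors(cases, controls)
  res <- trend_test(v$dosage, v$phenotype)
  expect_equal(res$statistic, 100 / 8.75, tolerance = 1e-12)
  expect_equal(res$p_value, stats::pchisq(100 / 8.75, 1, lower.tail = FALSE))
})

test_that("trend test equals the contingency-table closed form on random small tables", {
  set.seed(202)
  for (i in 1:400) {
    cases <- c(sample(0:30, 1), sample(0:30, 1), sample(0:30, 1))
    controls <- c(sample(0:30, 1), sample(0:30, 1), sample(0:30, 1))
    n <- cases + controls
    if (sum(n > 0) < 2 || sum(cases) == 0 || sum(controls) == 0) next
    oracle <- trend_stat_oracle(cases, controls)
    if (!is.finite(oracle)) next # degenerate margin: all-case or all-control
    v <- table_to_vectors(cases, controls)
    expect_equal(trend_test(v$dosage, v$phenotype)$statistic, oracle,
                 tolerance = 1e-10)
  }
})

test_that("monomorphic sites yield a flagged not-testable result, not an error", {
  res <- trend_test(rep(1L, 10), rep(c(0L, 1L), 5))
  expect_false(res$testable)
  expect_true(is.na(res$p_value))
  expect_error(trend_test(rep(1L, 10), rep(1L, 10)), "phenotype")
})

test_that("logistic LRT agrees with the trend test across a scanned region", {
  m <- nod2_model()
  pool <- build_pool(m, seed = 21)
  co <- sample_case_control(pool, m, 1000, 1000, seed = 22)
  lg <- logistic_scan(co)
  tr <- trend_scan(co)
  ok <- lg$converged & !is.na(tr)
  expect_gt(sum(ok), 15)
  expect_gt(stats::cor(-log10(lg$p_value[ok]), -log10(tr[ok]),
                       method = "spearman"), 0.99)
  # and the P-values themselves are close in the bulk
  expect_lt(stats::median(abs(log10(lg$p_value[ok]) - log10(tr[ok]))), 0.1)
})

test_that("logistic LRT is invariant to affine recoding of the dosage covariate", {
  set.seed(31)
  n <- 400
  d <- sample(0:2, n, replace = TRUE, prob = c(0.5, 0.4, 0.1))
  y <- rbinom(n, 1, plogis(-0.5 + 0.4 * d))
  co1 <- make_cohort(cbind(site = d), y)
  co2 <- make_cohort(cbind(site = 2 * d - 3), y)
  p1 <- logistic_scan(co1, sites = "site")
  p2 <- logistic_scan(co2, sites = "site")
  expect_equal(p1$statistic, p2$statistic, tolerance = 1e-6)
  expect_equal(p1$effect / 1, p2$effect * 2, tolerance = 1e-6)
})

test_that("conditioning on an irrelevant covariate leaves P-values unchanged", {
  mn <- locus_model(list())
  pool <- null_pool(n_common = 10, seed = 23)
  co <- sample_case_control(pool, mn, 2500, 2500, seed = 24)
  set.seed(99)
  noise <- stats::rbinom(5000, 1, 0.3) # independent of genotype and phenotype
  p0 <- logistic_scan(co)
  p1 <- logistic_scan(co, covariates = noise)
  ok <- p0$converged & p1$converged
  expect_lt(max(abs(log10(p0$p_value[ok]) - log10(p1$p_value[ok]))), 0.05)
})

test_that("rank-deficient covariates raise a degenerate-design error", {
  co <- make_cohort(cbind(s = rep(0:1, 50)), rep(0:1, each = 50))
  expect_error(logistic_scan(co, covariates = cbind(rep(1, 100), rep(2, 100))),
               "rank deficient")
})

test_that("compound carrier status collapses rare sites correctly", {
  g <- rbind(c(0L, 0L, 0L), c(0L, 1L, 0L), c(2L, 0L, 1L))
  colnames(g) <- c("r1", "r2", "c1")
  co <- make_cohort(g, c(1L, 0L, 1L), causal = c(TRUE, TRUE, FALSE))
  cc <- compound_carrier(co, c("r1", "r2"))
  expect_identical(cc, c(0L, 1L, 1L))
  expect_error(compound_carrier(co, character(0)), "no rare sites")
  expect_error(compound_carrier(co, "c1"), "causal")

  m <- nod2_model()
  pool <- build_pool(m, seed = 25)
  ctrl_only <- sample_case_control(pool, m, 0, 4000, seed = 26)
  f <- mean(compound_carrier(ctrl_only))
  f_pop <- compound_carrier_frequency(m)
  expect_lt(abs(f - f_pop), 4 * sqrt(f_pop * (1 - f_pop) / 4000))
})

test_that("conditional scan ablates a synthetic association by orders of magnitude", {
  m <- nod2_model()
  pool <- build_pool(m, seed = 11)
  co <- sample_case_control(pool, m, 2000, 3000, seed = 27)
  sc <- conditional_scan(co)
  expect_setequal(unique(sc$model_tag), c("unconditional", "conditional"))
  expect_identical(attr(sc, "conditioning_sites"),
                   pool$sites$id[pool$sites$causal])
  s <- summary(sc)
  min_u <- s$min_p[s$model_tag == "unconditional"]
  min_c <- s$min_p[s$model_tag == "conditional"]
  expect_lt(min_u, 1e-4)
  # signal collapses by orders of magnitude at the region level
  expect_gt(log10(min_c) - log10(min_u), 2)
  # per-site view at the top SNP
  u <- sc[sc$model_tag == "unconditional", ]
  top <- u$site_id[which.min(u$p_value)]
  p_top <- sc$p_value[sc$model_tag == "conditional" & sc$site_id == top]
  expect_gt(p_top, 1e-3)
  # separate-indicator conditioning is also supported
  sc2 <- conditional_scan(co, mode = "separate")
  expect_identical(attr(sc2, "mode"), "separate")
  expect_gt(min(sc2$p_value[sc2$model_tag == "conditional"], na.rm = TRUE),
            min_u)
})

test_that("conditioning on rare sites does not disturb a truly common causal SNP", {
  # common causal variant plus two null rare variants: the contrast experiment
  vars <- list(risk_variant("cv", 0.2, 1.4),
               risk_variant("r1", 0.01, 1), risk_variant("r2", 0.02, 1))
  m <- locus_model(vars, baseline_penetrance = 0.05)
  pool <- build_pool(m, n_common = 8, common_freq_range = c(0.25, 0.45),
                     seed = 28)
  co <- sample_case_control(pool, m, 2500, 2500, seed = 29)
  sc <- conditional_scan(co, rare_sites = c("r1", "r2"),
                         scan_sites = c("cv", pool$sites$id[!pool$sites$causal]))
  pu <- sc$p_value[sc$model_tag == "unconditional" & sc$site_id == "cv"]
  pc <- sc$p_value[sc$model_tag == "conditional" & sc$site_id == "cv"]
  expect_lt(pu, 1e-4) # the common variant is genuinely associated
  expect_lt(abs(log10(pc) - log10(pu)), 1)
})

test_that("null cohorts produce uniform scan P-values", {
  mn <- locus_model(list())
  pool <- null_pool(n_common = 5, seed = 30)
  ps <- vapply(1:300, function(r) {
    co <- sample_case_control(pool, mn, 300, 300,
                              seed = child_seed(31, paste0("u", r)))
    trend_test(co$genotypes[, 1], co$phenotype)$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})
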