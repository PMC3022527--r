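test_that("null-model case-control cohorts are exchangeable across phenotype", {
  mn <- locus_model(list())
  pool <- null_pool(n_common = 6, seed = 2)
  # per-site two-proportion z over replicates: |z| > 1.96 at ~5% rate
  zs <- unlist(lapply(1:40, function(r) {
    co <- sample_case_control(pool, mn, 500, 500,
                              seed = child_seed(3, paste0("ex", r)))
    vapply(seq_len(6), function(s) {
      pc <- mean(co$genotypes[co$phenotype == 1, s]) / 2
      pu <- mean(co$genotypes[co$phenotype == 0, s]) / 2
      pb <- (pc + pu) / 2
      (pc - pu) / sqrt(pb * (1 - pb) * (1 / 1000 + 1 / 1000))
    }, numeric(1))
  }))
  rate <- mean(abs(zs) > 1.96)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / length(zs)) + 0.01)
})

test_that("risk models enrich compound carriers in cases, controls track the population", {
  m <- nod2_model()
  pool <- build_pool(m, seed = 11)
  co <- sample_case_control(pool, m, 2000, 2000, seed = 12)
  cc <- compound_carrier(co)
  f_case <- mean(cc[co$phenotype == 1])
  f_ctrl <- mean(cc[co$phenotype == 0])
  f_pop <- compound_carrier_frequency(m)
  expect_gt(f_case, f_ctrl + 0.05)
  expect_lt(abs(f_ctrl - f_pop), 4 * sqrt(f_pop * (1 - f_pop) / 2000) + 0.005)
})

test_that("empirical allelic OR at the best tag matches the Bayes-inversion expectation", {
  m <- nod2_model()
  pool <- build_pool(m, seed = 11)
  ef <- expected_site_frequencies(pool, m)
  common <- ef[!ef$causal, ]
  best <- common[which.max(abs(log(common$allelic_or))), ]
  co <- sample_case_control(pool, m, 20000, 20000, seed = 13)
  s <- match(best$id, co$sites$id)
  pc <- mean(co$genotypes[co$phenotype == 1, s]) / 2
  pu <- mean(co$genotypes[co$phenotype == 0, s]) / 2
  or_emp <- (pc / (1 - pc)) / (pu / (1 - pu))
  # large-sample empirical OR within ~4 SE of the expected induced OR
  se_log <- sqrt(1 / (pc * (1 - pc) * 40000) + 1 / (pu * (1 - pu) * 40000))
  expect_lt(abs(log(or_emp) - log(best$allelic_or)), 4 * se_log)
  expect_gt(best$allelic_or, 1.1) # the cluster induces a synthetic association
})

test_that("ASP cohorts: Mendelian IBD prior under the null, analytic sharing under risk", {
  mn <- locus_model(list())
  pool <- null_pool(n_common = 4, seed = 5)
  coh <- sample_asp_pairs(pool, mn, 20000, seed = 6)
  expect_true(all(coh$phenotype == 1L))
  z <- table(factor(coh$pedigree$ibd, 0:2)) / 20000
  expect_lt(abs(z[[1]] - 0.25), 4 * sqrt(0.25 * 0.75 / 20000))
  expect_lt(abs(z[[2]] - 0.50), 4 * sqrt(0.5 * 0.5 / 20000))

  m <- locus_model(list(risk_variant("rv", 0.01, 5)))
  p1 <- build_pool(m, n_common = 4, seed = 5)
  coh2 <- sample_asp_pairs(p1, m, 30000, seed = 7)
  sh <- sharing_probabilities(familial_risks(m))
  y_hat <- mean(coh2$pedigree$ibd) / 2
  se <- sqrt((sh$z1 * 0.25 + sh$z2 - sh$y^2) / 30000)
  expect_lt(abs(y_hat - sh$y), 3 * se)
})

test_that("risk-increasing multi-variant models show excess sharing at study scale", {
  m <- fig3_model(3, 3)
  pool <- build_pool(m, n_common = 4, seed = 8)
  coh <- sample_asp_pairs(pool, m, 2658, seed = 9)
  expect_gt(mean(coh$pedigree$ibd) / 2, 0.5)
})

test_that("cohort sampling is deterministic and ids are stable", {
  m <- nod2_model()
  pool <- build_pool(m, seed = 1)
  a <- sample_case_control(pool, m, 100, 100, seed = 2)
  b <- sample_case_control(pool, m, 100, 100, seed = 2)
  expect_identical(a, b)
  expect_identical(rownames(a$genotypes)[1], "S00001")
})

test_that("VCF round-trip reproduces dosages, flags and phenotypes exactly", {
  g <- matrix(c(0L, 1L, 2L, 0L), 2, 2,
              dimnames = list(c("A1", "A2"), c("s1", "s2")))
  co <- make_cohort(g, c(1L, 0L))
  vcf <- withr::local_tempfile(fileext = ".vcf")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(co, vcf, tsv)
  lines <- readLines(vcf)
  records <- grep("^[^#]", lines, value = TRUE)
  expect_length(records, 2)
  expect_length(strsplit(records[1], "\t")[[1]], 9 + 2)
  # GT emitted unphased by convention
  expect_false(any(grepl("\\|", records)))
  co2 <- read_cohort(vcf, tsv)
  expect_identical(unname(co2$genotypes), unname(g))
  expect_identical(co2$phenotype, c(1L, 0L))

  m <- nod2_model()
  pool <- build_pool(m, seed = 3)
  big <- sample_case_control(pool, m, 30, 30, seed = 4)
  write_cohort(big, vcf, tsv)
  lines <- readLines(vcf)
  expect_equal(sum(grepl("\tCAUSAL\t", lines)), 3)
  co3 <- read_cohort(vcf, tsv)
  expect_identical(unname(co3$genotypes), unname(big$genotypes))
  expect_identical(sum(co3$sites$causal), 3L)
})

test_that("sample mismatch between VCF and phenotype table names the offenders", {
  g <- matrix(0:1, 2, 1, dimnames = list(c("A1", "A2"), "s1"))
  co <- make_cohort(g, c(1L, 0L))
  vcf <- withr::local_tempfile(fileext = ".vcf")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_cohort(co, vcf, tsv)
  ph <- utils::read.delim(tsv)
  ph$sample_id[2] <- "GHOST"
  utils::write.table(ph, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_cohort(vcf, tsv), "GHOST")
})

test_that("simulate() method produces cohorts of both designs from a model", {
  m <- fig3_model(2, 2, maf = 0.02)
  cc <- simulate(m, seed = 4, n_cases = 50, n_controls = 50)
  expect_s3_class(cc, "sa_cohort")
  expect_equal(sum(cc$phenotype), 50)
  asp <- simulate(m, seed = 4, design = "asp", n_pairs = 40)
  expect_equal(nrow(asp$pedigree), 40)
})
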