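# Independent oracles used across the suite. These deliberately share no code
# with the package internals they check.

# Sibling relative risk by exhaustive enumeration of parental mating types and
# the joint sib genotype distribution: lambda_s = P(both sibs affected) / K^2.
lambda_s_enum <- function(p, grr_het, grr_hom, f0 = 0.01) {
  f <- f0 * c(1, grr_het, grr_hom)
  hw <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  transmit <- c(0, 0.5, 1) # P(parent transmits risk allele | genotype)
  K <- sum(hw * f)
  p_both <- 0
  for (gm in 0:2) for (gp in 0:2) {
    tm <- transmit[gm + 1]; tp <- transmit[gp + 1]
    child <- c((1 - tm) * (1 - tp), tm * (1 - tp) + (1 - tm) * tp, tm * tp)
    p_aff <- sum(child * f) # sibs iid given parents
    p_both <- p_both + hw[gm + 1] * hw[gp + 1] * p_aff^2
  }
  p_both / K^2
}

# Offspring relative risk by the same enumeration: parent affected, one child.
lambda_o_enum <- function(p, grr_het, grr_hom, f0 = 0.01) {
  f <- f0 * c(1, grr_het, grr_hom)
  hw <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  transmit <- c(0, 0.5, 1)
  K <- sum(hw * f)
  p_both <- 0
  for (gm in 0:2) for (gp in 0:2) {
    tm <- transmit[gm + 1]; tp <- transmit[gp + 1]
    child <- c((1 - tm) * (1 - tp), tm * (1 - tp) + (1 - tm) * tp, tm * tp)
    p_both <- p_both + hw[gm + 1] * hw[gp + 1] * f[gm + 1] * sum(child * f)
  }
  p_both / K^2
}

# Cochran-Armitage trend statistic from a 2x3 table, closed form with scores
# (0, 1, 2); rows are (cases, controls) counts per genotype class.
trend_stat_oracle <- function(cases, controls) {
  w <- 0:2
  n <- cases + controls
  N <- sum(n)
  pbar <- sum(cases) / N
  num <- sum(w * (cases - n * pbar))^2
  den <- pbar * (1 - pbar) * (sum(n * w^2) - sum(n * w)^2 / N)
  num / den
}

# Expand a 2x3 count table into dosage/phenotype vectors.
table_to_vectors <- function(cases, controls) {
  dosage <- c(rep(0:2, times = cases), rep(0:2, times = controls))
  phenotype <- c(rep(1L, sum(cases)), rep(0L, sum(controls)))
  list(dosage = dosage, phenotype = phenotype)
}

# Compound-carrier frequency by direct enumeration of the joint genotype
# classes of all variants (3^k cells).
carrier_freq_enum <- function(mafs) {
  if (!length(mafs)) return(0)
  grids <- do.call(expand.grid, rep(list(0:2), length(mafs)))
  pr <- apply(grids, 1, function(g)
    prod(mapply(function(gi, p) c((1 - p)^2, 2 * p * (1 - p), p^2)[gi + 1],
                g, mafs)))
  sum(pr[rowSums(grids) > 0])
}

# Small null pool shared by calibration-style tests.
null_pool <- function(n_common = 5, seed = 1)
  build_pool(locus_model(list()), n_common = n_common, seed = seed)

# Build an sa_cohort directly from a dosage matrix (for tests that need full
# control over the genotypes).
make_cohort <- function(genotypes, phenotype, causal = NULL) {
  m <- ncol(genotypes)
  if (is.null(causal)) causal <- rep(FALSE, m)
  if (is.null(colnames(genotypes)))
    colnames(genotypes) <- sprintf("s%02d", seq_len(m))
  if (is.null(rownames(genotypes)))
    rownames(genotypes) <- sprintf("I%04d", seq_len(nrow(genotypes)))
  sites <- data.frame(id = colnames(genotypes), position = seq_len(m) * 100L,
                      causal = causal, stringsAsFactors = FALSE)
  synthassoc:::new_cohort(genotypes, phenotype, sites)
}
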