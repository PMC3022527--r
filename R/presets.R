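#' NOD2-like locus model
#'
#' Three low-frequency coding variants (MAFs 0.04, 0.01, 0.02), each
#' calibrated through the penetrance table so that its carrier and homozygote
#' odds ratios versus non-carriers are 3 and 38. Variants combine
#' multiplicatively across the locus.
#'
#' @param baseline_penetrance Baseline penetrance `f0` (default 0.01).
#' @param carrier_or,hom_or Odds-ratio targets per variant.
#' @return A [locus_model()].
#' @examples
#' summary(nod2_model())
#' @export
nod2_model <- function(baseline_penetrance = 0.01, carrier_or = 3, hom_or = 38) {
  mafs <- c(G881R = 0.04, R675W = 0.01, L980fs = 0.02)
  vars <- lapply(names(mafs), function(id) {
    g <- calibrate_relative_risks(carrier_or, hom_or, mafs[[id]],
                                  baseline_penetrance)
    risk_variant(id, mafs[[id]], g[["grr_het"]], g[["grr_hom"]])
  })
  locus_model(vars, baseline_penetrance = baseline_penetrance)
}

#' Multi-rare-variant locus model with a shared per-allele odds ratio
#'
#' `n_variants` independent risk alleles, each at frequency `maf`, each with
#' per-allele (heterozygote) odds ratio `per_allele_or` interpreted as the
#' heterozygote genotype relative risk under a within-variant multiplicative
#' model (`grr_hom = grr_het^2`) in the rare-disease limit. This is the model
#' family used for the linkage-versus-GWAS power comparison (N = 3, 5 or 9
#' risk alleles at frequency 0.01).
#'
#' @param n_variants Number of independent risk variants.
#' @param per_allele_or Per-allele odds ratio (heterozygote GRR).
#' @param maf Shared risk-allele frequency (default 0.01).
#' @param baseline_penetrance Baseline penetrance `f0` (default 0.01).
#' @return A [locus_model()].
#' @export
fig3_model <- function(n_variants, per_allele_or, maf = 0.01,
                       baseline_penetrance = 0.01) {
  stopifnot(n_variants >= 0)
  vars <- lapply(seq_len(n_variants), function(i)
    risk_variant(sprintf("rv%02d", i), maf, per_allele_or))
  locus_model(vars, baseline_penetrance = baseline_penetrance)
}
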