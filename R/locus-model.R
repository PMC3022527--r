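#' Hardy-Weinberg genotype frequencies
#'
#' Expands an allele frequency into the three genotype frequencies
#' (non-carrier, heterozygote, homozygote) under random mating.
#'
#' @param maf Allele frequency in `[0, 1]`.
#' @return Named numeric vector `c(nn, het, hom)` summing to 1.
#' @examples
#' genotype_distribution(0.04)
#' @export
genotype_distribution <- function(maf) {
  if (!is.numeric(maf) || length(maf) != 1L || is.na(maf) || maf < 0 || maf > 1)
    stop("`maf` must be a single number in [0, 1]", call. = FALSE)
  c(nn = (1 - maf)^2, het = 2 * maf * (1 - maf), hom = maf^2)
}

#' Define a single low-frequency risk variant
#'
#' A risk variant is parameterised by its allele frequency and the genotype
#' relative risks (penetrance ratios) of heterozygotes and homozygotes
#' relative to non-carriers. The default homozygote risk is multiplicative
#' within the variant (`grr_hom = grr_het^2`); pass `grr_hom` explicitly for
#' non-multiplicative patterns such as the NOD2 carrier/homozygote contrast.
#'
#' @param id Character variant identifier.
#' @param maf Risk-allele frequency in `[0, 0.5]`.
#' @param grr_het Genotype relative risk of heterozygotes (>= 0).
#' @param grr_hom Genotype relative risk of homozygotes (>= 0); defaults to
#'   `grr_het^2`.
#' @return An object of class `risk_variant`.
#' @export
risk_variant <- function(id, maf, grr_het, grr_hom = grr_het^2) {
  stopifnot(is.character(id), length(id) == 1L)
  if (!is.numeric(maf) || maf < 0 || maf > 0.5)
    stop("`maf` must lie in [0, 0.5]", call. = FALSE)
  if (grr_het < 0 || grr_hom < 0)
    stop("genotype relative risks must be non-negative", call. = FALSE)
  structure(list(id = id, maf = maf, grr_het = grr_het, grr_hom = grr_hom),
            class = "risk_variant")
}

#' Define a locus carrying one or more independent risk variants
#'
#' Variants are assumed pairwise in linkage equilibrium; penetrance combines
#' multiplicatively across variants on a baseline penetrance `f0` for carriers
#' of zero risk alleles. With zero variants the locus is null.
#'
#' @param variants A list of [risk_variant()] objects (possibly empty).
#' @param baseline_penetrance Baseline penetrance `f0` in `(0, 1)`.
#' @return An object of class `locus_model`.
#' @examples
#' m <- locus_model(list(risk_variant("v1", 0.01, 3)), baseline_penetrance = 0.01)
#' summary(m)
#' @export
locus_model <- function(variants = list(), baseline_penetrance = 0.01) {
  if (inherits(variants, "risk_variant")) variants <- list(variants)
  stopifnot(is.list(variants))
  for (v in variants)
    if (!inherits(v, "risk_variant"))
      stop("all elements of `variants` must be risk_variant objects", call. = FALSE)
  ids <- vapply(variants, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("variant ids must be unique", call. = FALSE)
  f0 <- baseline_penetrance
  if (!is.numeric(f0) || f0 <= 0 || f0 >= 1)
    stop("`baseline_penetrance` must lie in (0, 1)", call. = FALSE)
  m <- structure(list(variants = variants, baseline_penetrance = f0),
                 class = "locus_model")
  K <- prevalence(m)
  if (K <= 0 || K >= 1)
    stop("model implies a prevalence outside (0, 1)", call. = FALSE)
  m
}

n_variants <- function(model) length(model$variants)

variant_ids <- function(model) vapply(model$variants, `[[`, character(1), "id")

variant_mafs <- function(model) vapply(model$variants, `[[`, numeric(1), "maf")

# per-variant relative-risk lookup: rows = variants, cols = dosage 0/1/2
grr_table <- function(model) {
  t(vapply(model$variants,
           function(v) c(1, v$grr_het, v$grr_hom), numeric(3)))
}

#' Disease prevalence implied by a locus model
#'
#' Marginal probability of disease, `K = f0 * prod_i E[grr_i]`, under
#' Hardy-Weinberg genotype frequencies and linkage equilibrium across
#' variants.
#'
#' @param model A [locus_model()].
#' @return Prevalence in `(0, 1)`.
#' @export
prevalence <- function(model) {
  stopifnot(inherits(model, "locus_model"))
  e <- vapply(model$variants, function(v) {
    g <- genotype_distribution(v$maf)
    sum(g * c(1, v$grr_het, v$grr_hom))
  }, numeric(1))
  min(1, model$baseline_penetrance * prod(e))
}

#' Probability of carrying at least one risk allele at a locus
#'
#' The compound-carrier frequency: the probability that an individual carries
#' one or more risk alleles at any of the locus's variants, assuming
#' Hardy-Weinberg proportions and linkage equilibrium. Returns 0 for a locus
#' with no variants.
#'
#' @param model A [locus_model()].
#' @return A probability in `[0, 1]`.
#' @examples
#' compound_carrier_frequency(nod2_model())
#' @export
compound_carrier_frequency <- function(model) {
  stopifnot(inherits(model, "locus_model"))
  if (n_variants(model) == 0L) return(0)
  1 - prod((1 - variant_mafs(model))^2)
}

#' Calibrate genotype relative risks from odds-ratio targets
#'
#' Finds the heterozygote and homozygote genotype relative risks whose implied
#' penetrance table reproduces target carrier-vs-non-carrier and
#' homozygote-vs-non-carrier odds ratios exactly. "Carrier" pools
#' heterozygotes and homozygotes with Hardy-Weinberg weights. The conversion
#' goes through the full penetrance table, not the rare-disease approximation,
#' so the result depends on the baseline penetrance.
#'
#' @param target_carrier_or Target odds ratio of carriers vs non-carriers (> 0).
#' @param target_hom_or Target odds ratio of homozygotes vs non-carriers (> 0).
#' @param maf Risk-allele frequency.
#' @param baseline_penetrance Baseline penetrance `f0`.
#' @return Named numeric vector `c(grr_het, grr_hom)`.
#' @examples
#' calibrate_relative_risks(3, 38, maf = 0.02, baseline_penetrance = 0.01)
#' @export
calibrate_relative_risks <- function(target_carrier_or, target_hom_or, maf,
                                     baseline_penetrance) {
  if (target_carrier_or <= 0 || target_hom_or <= 0)
    stop("odds-ratio targets must be positive", call. = FALSE)
  f0 <- baseline_penetrance
  if (f0 <= 0 || f0 >= 1) stop("`baseline_penetrance` must lie in (0,1)", call. = FALSE)
  odds0 <- f0 / (1 - f0)
  inv_odds <- function(o) o / (1 + o)
  f_hom <- inv_odds(target_hom_or * odds0)
  f_car <- inv_odds(target_carrier_or * odds0)
  g <- genotype_distribution(maf)
  w_het <- g["het"] / (g["het"] + g["hom"])
  f_het <- (f_car - (1 - w_het) * f_hom) / w_het
  if (f_het <= 0)
    stop("infeasible targets: implied heterozygote penetrance <= 0", call. = FALSE)
  if (f_het >= 1 || f_hom >= 1)
    stop("infeasible model: implied penetrance >= 1; lower the baseline penetrance",
         call. = FALSE)
  c(grr_het = unname(f_het / f0), grr_hom = unname(f_hom / f0))
}

# Additive/dominance variance decomposition of a single-variant penetrance
# triple (on any scale; lambdas are scale-invariant).
single_variant_lambdas <- function(maf, grr_het, grr_hom) {
  p <- maf; q <- 1 - p
  f <- c(1, grr_het, grr_hom)
  K <- q^2 * f[1] + 2 * p * q * f[2] + p^2 * f[3]
  if (K <= 0) stop("degenerate model: zero prevalence", call. = FALSE)
  a <- p * (f[3] - f[2]) + q * (f[2] - f[1]) # average allele-substitution effect
  VA <- 2 * p * q * a^2
  VD <- (p * q)^2 * (f[3] - 2 * f[2] + f[1])^2
  c(lambda_o = 1 + (VA / 2) / K^2,
    lambda_m = 1 + (VA + VD) / K^2,
    lambda_s = 1 + (VA / 2 + VD / 4) / K^2)
}

#' Familial relative risks of a locus model
#'
#' Computes the offspring (`lambda_o`), monozygotic-twin (`lambda_m`) and
#' sibling (`lambda_s`) relative risks attributable to the locus, in the
#' Risch-Merikangas variance-components framework. Per-variant values use the
#' additive/dominance decomposition of the single-variant penetrance triple;
#' locus-level values for several fully linked variants in linkage equilibrium
#' combine by conditioning on the sib pair's shared-haplotype count:
#' `lambda_o = prod(lambda_o_i)`, `lambda_m = prod(lambda_m_i)` and
#' `lambda_s = (lambda_m + 2 * lambda_o + 1) / 4`.
#'
#' @param model A [locus_model()].
#' @return An object of class `familial_risks`: a list with `lambda_o`,
#'   `lambda_m`, `lambda_s` and a `per_variant` data frame.
#' @examples
#' familial_risks(fig3_model(9, 3))
#' @export
familial_risks <- function(model) {
  stopifnot(inherits(model, "locus_model"))
  if (n_variants(model) == 0L) {
    pv <- data.frame(id = character(), lambda_o = numeric(),
                     lambda_m = numeric(), lambda_s = numeric())
    out <- list(lambda_o = 1, lambda_m = 1, lambda_s = 1, per_variant = pv)
    return(structure(out, class = "familial_risks"))
  }
  pv <- t(vapply(model$variants, function(v)
    single_variant_lambdas(v$maf, v$grr_het, v$grr_hom), numeric(3)))
  lo <- prod(pv[, "lambda_o"])
  lm_ <- prod(pv[, "lambda_m"])
  ls <- (lm_ + 2 * lo + 1) / 4
  per_variant <- data.frame(id = variant_ids(model),
                            lambda_o = pv[, "lambda_o"],
                            lambda_m = pv[, "lambda_m"],
                            lambda_s = pv[, "lambda_s"],
                            row.names = NULL)
  structure(list(lambda_o = lo, lambda_m = lm_, lambda_s = ls,
                 per_variant = per_variant),
            class = "familial_risks")
}

#' @export
print.familial_risks <- function(x, ...) {
  cat(sprintf("Familial relative risks (locus level, %d variant%s)\n",
              nrow(x$per_variant), if (nrow(x$per_variant) == 1) "" else "s"))
  cat(sprintf("  lambda_o = %.6g  lambda_m = %.6g  lambda_s = %.6g\n",
              x$lambda_o, x$lambda_m, x$lambda_s))
  invisible(x)
}

# Penetrance of individuals from their variant dosage matrix (n x n_variants).
# Multiplicative across variants on the baseline; clamped at 1 (only reachable
# for astronomically rare multi-homozygote combinations under strong models).
penetrance_from_dosage <- function(model, dosage) {
  f0 <- model$baseline_penetrance
  nv <- n_variants(model)
  if (nv == 0L) return(rep(f0, NROW(dosage)))
  dosage <- matrix(as.integer(dosage), ncol = nv)
  gt <- grr_table(model)
  rr <- rep(1, nrow(dosage))
  for (j in seq_len(nv)) rr <- rr * gt[j, dosage[, j] + 1L]
  pmin(1, f0 * rr)
}

#' @export
print.risk_variant <- function(x, ...) {
  cat(sprintf("risk_variant %s: maf = %g, grr(het) = %g, grr(hom) = %g\n",
              x$id, x$maf, x$grr_het, x$grr_hom))
  invisible(x)
}

#' @export
print.locus_model <- function(x, ...) {
  cat(sprintf("Locus model: %d risk variant%s, baseline penetrance f0 = %g\n",
              n_variants(x), if (n_variants(x) == 1) "" else "s",
              x$baseline_penetrance))
  for (v in x$variants)
    cat(sprintf("  %-10s maf = %-6g grr_het = %-8.4g grr_hom = %.4g\n",
                v$id, v$maf, v$grr_het, v$grr_hom))
  invisible(x)
}

#' @export
summary.locus_model <- function(object, ...) {
  fr <- familial_risks(object)
  out <- list(model = object,
              prevalence = prevalence(object),
              carrier_frequency = compound_carrier_frequency(object),
              familial_risks = fr)
  class(out) <- "summary.locus_model"
  out
}

#' @export
print.summary.locus_model <- function(x, ...) {
  print(x$model)
  cat(sprintf("Prevalence K = %.6g\n", x$prevalence))
  cat(sprintf("Compound-carrier frequency = %.6g\n", x$carrier_frequency))
  print(x$familial_risks)
  invisible(x)
}

#' Write a locus model to a structured config file
#'
#' Serialises the model as a YAML block (list of variants with id, maf,
#' grr_het, grr_hom, plus the baseline penetrance). [read_locus_model()]
#' round-trips it.
#'
#' @param model A [locus_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_locus_model <- function(model, path) {
  stopifnot(inherits(model, "locus_model"))
  cfg <- list(baseline_penetrance = model$baseline_penetrance,
              variants = lapply(model$variants, function(v)
                list(id = v$id, maf = v$maf,
                     grr_het = v$grr_het, grr_hom = v$grr_hom)))
  yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}

#' Read a locus model from a structured config file
#'
#' @param path Path written by [write_locus_model()] (or hand-authored with
#'   the same keys).
#' @return A [locus_model()].
#' @export
read_locus_model <- function(path) {
  cfg <- yaml::read_yaml(path)
  locus_model_from_config(cfg)
}

locus_model_from_config <- function(cfg) {
  allowed <- c("baseline_penetrance", "variants", "preset")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown model config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(cfg$preset)) {
    f0 <- if (is.null(cfg$baseline_penetrance)) 0.01 else cfg$baseline_penetrance
    return(switch(cfg$preset,
                  nod2 = nod2_model(baseline_penetrance = f0),
                  null = locus_model(list(), baseline_penetrance = f0),
                  stop("unknown model preset: ", cfg$preset, call. = FALSE)))
  }
  vars <- lapply(cfg$variants, function(v) {
    need <- c("id", "maf", "grr_het")
    if (!all(need %in% names(v)))
      stop("variant config requires id, maf, grr_het", call. = FALSE)
    if (is.null(v$grr_hom)) v$grr_hom <- v$grr_het^2
    risk_variant(v$id, v$maf, v$grr_het, v$grr_hom)
  })
  f0 <- if (is.null(cfg$baseline_penetrance)) 0.01 else cfg$baseline_penetrance
  locus_model(vars, baseline_penetrance = f0)
}
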