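#' IBD sharing probabilities of affected sib pairs
#'
#' Converts the familial relative risks of a locus into the probabilities that
#' an affected sib pair shares 0, 1 or 2 haplotypes identical by descent:
#' `z0 = 0.25 / lambda_s`, `z1 = 0.5 * lambda_o / lambda_s`,
#' `z2 = 0.25 * lambda_m / lambda_s`, with mean sharing proportion
#' `Y = z2 + z1 / 2`. The null locus gives (1/4, 1/2, 1/4) and `Y = 0.5`.
#'
#' @param risks A [familial_risks()] object (or a [locus_model()], which is
#'   converted first).
#' @return An object of class `sharing_probs`: list with `z0`, `z1`, `z2`,
#'   `y`.
#' @examples
#' sharing_probabilities(familial_risks(fig3_model(9, 3)))
#' @export
sharing_probabilities <- function(risks) {
  if (inherits(risks, "locus_model")) risks <- familial_risks(risks)
  stopifnot(inherits(risks, "familial_risks"))
  z0 <- 0.25 / risks$lambda_s
  z1 <- 0.5 * risks$lambda_o / risks$lambda_s
  z2 <- 0.25 * risks$lambda_m / risks$lambda_s
  if (any(c(z0, z1, z2) < 0) || any(c(z0, z1, z2) > 1) ||
      abs(z0 + z1 + z2 - 1) > 1e-9)
    stop("inconsistent familial risks: IBD probabilities outside [0, 1]",
         call. = FALSE)
  structure(list(z0 = z0, z1 = z1, z2 = z2, y = z2 + z1 / 2),
            class = "sharing_probs")
}

#' @export
print.sharing_probs <- function(x, ...) {
  cat(sprintf("ASP IBD sharing: z0 = %.5f, z1 = %.5f, z2 = %.5f, Y = %.5f\n",
              x$z0, x$z1, x$z2, x$y))
  invisible(x)
}

#' Analytic power of the ASP mean-sharing linkage test
#'
#' One-sided mean test of the allele-sharing proportion among affected sib
#' pairs at a fully informative marker, under the normal approximation: the
#' per-pair sharing proportion has null variance 1/8 and alternative mean `Y`
#' with variance from the IBD-state second moment. Power is
#' `Phi(((Y - 1/2) sqrt(n) - z_{1-alpha} sigma_0) / sigma_alt)`.
#'
#' @param sharing A [sharing_probabilities()] object (or a [locus_model()]).
#' @param n_pairs Number of affected sib pairs (>= 1).
#' @param alpha One-sided significance level in (0, 1).
#' @return A one-row `power_point` data frame (`method`, `n`, `alpha`,
#'   `power`, `mc_se = NA`).
#' @examples
#' linkage_power(sharing_probabilities(fig3_model(9, 3)), 2658, 1e-4)
#' @export
linkage_power <- function(sharing, n_pairs, alpha) {
  if (inherits(sharing, "locus_model"))
    sharing <- sharing_probabilities(familial_risks(sharing))
  stopifnot(inherits(sharing, "sharing_probs"), n_pairs >= 1,
            alpha > 0, alpha < 1)
  y <- sharing$y
  var_alt <- sharing$z1 * 0.25 + sharing$z2 - y^2
  if (var_alt <= 0)
    stop("degenerate sharing distribution: zero variance", call. = FALSE)
  s0 <- sqrt(1 / 8)
  pow <- stats::pnorm(((y - 0.5) * sqrt(n_pairs) -
                         stats::qnorm(1 - alpha) * s0) / sqrt(var_alt))
  power_point("linkage", n = n_pairs, alpha = alpha, power = pow)
}

power_point <- function(method, n, alpha, power, mc_se = NA_real_) {
  out <- data.frame(method = method, n = n, alpha = alpha, power = power,
                    mc_se = mc_se)
  class(out) <- c("power_point", "data.frame")
  out
}

#' ASP mean-sharing linkage test on a simulated cohort
#'
#' One-sided test that the mean IBD sharing proportion of the cohort's
#' affected sib pairs exceeds 1/2, using the null variance 1/8 per pair
#' (fully informative marker).
#'
#' @param x An `sa_cohort` with a pedigree, or an integer vector of IBD
#'   states (0/1/2).
#' @return List with `y_hat` (mean sharing proportion), `z` and one-sided
#'   `p_value`.
#' @export
asp_mean_test <- function(x) {
  ibd <- if (inherits(x, "sa_cohort")) {
    if (is.null(x$pedigree)) stop("cohort has no sib-pair pedigree", call. = FALSE)
    x$pedigree$ibd
  } else x
  s <- ibd / 2
  n <- length(s)
  z <- (mean(s) - 0.5) / sqrt(1 / (8 * n))
  list(y_hat = mean(s), z = z,
       p_value = stats::pnorm(z, lower.tail = FALSE))
}

#' Analytic power of the case-control trend test at a single SNP
#'
#' Two-sided one-degree-of-freedom power from the noncentrality implied by
#' case and control allele frequencies. Control frequency is the risk-allele
#' frequency `raf` (rare-disease assumption) and the case frequency follows
#' from the allelic odds ratio: `p_case = raf * OR / (1 - raf + raf * OR)`.
#'
#' @param raf Risk-allele frequency in (0, 1).
#' @param allelic_or Allelic odds ratio (> 0).
#' @param n_cases,n_controls Sample sizes.
#' @param alpha Two-sided significance level.
#' @return A one-row `power_point` data frame.
#' @examples
#' gwas_power_analytic(0.52, 1.52, 2000, 3000, alpha = 5e-8)
#' @export
gwas_power_analytic <- function(raf, allelic_or, n_cases, n_controls, alpha) {
  stopifnot(raf > 0, raf < 1, allelic_or > 0, n_cases >= 1, n_controls >= 1,
            alpha > 0, alpha < 1)
  p_ctrl <- raf
  p_case <- raf * allelic_or / (1 - raf + raf * allelic_or)
  if (p_case <= 0 || p_case >= 1)
    stop("implied case allele frequency outside (0, 1)", call. = FALSE)
  ncp <- (p_case - p_ctrl)^2 /
    (p_case * (1 - p_case) / (2 * n_cases) +
       p_ctrl * (1 - p_ctrl) / (2 * n_controls))
  crit <- stats::qchisq(1 - alpha, df = 1)
  pow <- stats::pchisq(crit, df = 1, ncp = ncp, lower.tail = FALSE)
  power_point("gwas_analytic", n = n_cases + n_controls, alpha = alpha,
              power = pow)
}

#' Empirical GWAS power to detect a synthetic association
#'
#' Monte-Carlo power: the fraction of replicate ascertained case-control
#' cohorts in which the trend-test P-value falls below `alpha`. By default a
#' hit is declared on the minimum P over all common SNPs in the region (how a
#' GWAS region is declared significant); `site = "best_tag"` instead tests
#' only the single common SNP with the largest expected induced odds ratio,
#' matching what the analytic single-SNP power refers to.
#'
#' @inheritParams sample_case_control
#' @param alpha Per-scan significance threshold.
#' @param n_reps Number of replicate cohorts (>= 1).
#' @param site `"min_p"` or `"best_tag"`.
#' @return A one-row `power_point` data frame with the binomial Monte-Carlo
#'   standard error.
#' @export
gwas_power_empirical <- function(pool, model, n_cases, n_controls, alpha,
                                 n_reps, seed = NULL,
                                 site = c("min_p", "best_tag")) {
  site <- match.arg(site)
  stopifnot(n_reps >= 1)
  scan_sites <- pool$sites$id[!pool$sites$causal]
  if (site == "best_tag") {
    ef <- expected_site_frequencies(pool, model)
    common <- ef[!ef$causal, ]
    scan_sites <- common$id[which.max(abs(log(common$allelic_or)))]
  }
  root <- if (is.null(seed)) sample.int(2^31 - 2, 1) else seed
  hits <- vapply(seq_len(n_reps), function(r) {
    coh <- sample_case_control(pool, model, n_cases, n_controls,
                               seed = child_seed(root, paste0("gwasrep", r)))
    p <- trend_scan(coh, scan_sites)
    isTRUE(min(p, na.rm = TRUE) < alpha)
  }, logical(1))
  phat <- mean(hits)
  power_point("gwas_empirical", n = n_cases + n_controls, alpha = alpha,
              power = phat, mc_se = sqrt(phat * (1 - phat) / n_reps))
}

#' Comparative linkage-versus-GWAS power over a model grid
#'
#' For every combination of per-allele odds ratio and number of independent
#' risk variants (risk-allele frequency `maf`), computes analytic ASP linkage
#' power, analytic single-tag GWAS power (at the induced odds ratio of the
#' best common tag of a simulated haplotype pool) and empirical GWAS power
#' (min-P over the region), in a long-format table. A crossover summary —
#' the smallest odds ratio at which linkage power reaches the empirical GWAS
#' power, per variant count — is attached as an attribute.
#'
#' @param or_grid Per-allele odds ratios to evaluate.
#' @param n_variants_list Numbers of independent risk variants.
#' @param linkage List: `n_pairs`, `alpha`.
#' @param gwas List: `n_cases`, `n_controls`, `alpha`, `n_reps`, and optional
#'   pool settings `n_common`, `common_freq_range`, `region_length`.
#' @param maf Risk-allele frequency (default 0.01).
#' @param baseline_penetrance Baseline penetrance `f0`.
#' @param seed Root seed for pools and replicate cohorts.
#' @return A `power_curve` data frame: `method`, `n_variants`, `or`, `n`,
#'   `alpha`, `power`, `mc_se`; attribute `crossover` is a data frame with
#'   one row per `n_variants`.
#' @export
power_curve <- function(or_grid, n_variants_list,
                        linkage = list(n_pairs = 2658, alpha = 1e-4),
                        gwas = list(n_cases = 3000, n_controls = 3000,
                                    alpha = 5e-8, n_reps = 100),
                        maf = 0.01, baseline_penetrance = 0.01, seed = 1) {
  stopifnot(length(or_grid) >= 1, length(n_variants_list) >= 1)
  gw_pool <- function(model, s)
    build_pool(model,
               n_common = gwas$n_common %||% 20,
               common_freq_range = gwas$common_freq_range %||% c(0.1, 0.5),
               region_length = gwas$region_length %||% 200000,
               seed = s)
  rows <- list()
  for (N in n_variants_list) for (or in or_grid) {
    model <- fig3_model(N, or, maf = maf,
                        baseline_penetrance = baseline_penetrance)
    lab <- sprintf("N%d_or%g", N, or)
    lp <- linkage_power(sharing_probabilities(familial_risks(model)),
                        linkage$n_pairs, linkage$alpha)
    pool <- gw_pool(model, child_seed(seed, paste0("pool_", lab)))
    ef <- expected_site_frequencies(pool, model)
    common <- ef[!ef$causal, ]
    best <- common[which.max(abs(log(common$allelic_or))), ]
    ga <- gwas_power_analytic(best$freq_control, best$allelic_or,
                              gwas$n_cases, gwas$n_controls, gwas$alpha)
    ge <- gwas_power_empirical(pool, model, gwas$n_cases, gwas$n_controls,
                               gwas$alpha, gwas$n_reps,
                               seed = child_seed(seed, paste0("emp_", lab)))
    blk <- rbind(lp, ga, ge)
    blk$n_variants <- N
    blk$or <- or
    rows[[lab]] <- blk
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[, c("method", "n_variants", "or", "n", "alpha", "power", "mc_se")]
  cross <- do.call(rbind, lapply(n_variants_list, function(N) {
    sub <- out[out$n_variants == N, ]
    ors <- sort(unique(sub$or))
    hit <- ors[vapply(ors, function(o) {
      l <- sub$power[sub$method == "linkage" & sub$or == o]
      g <- sub$power[sub$method == "gwas_empirical" & sub$or == o]
      l >= g
    }, logical(1))]
    data.frame(n_variants = N,
               crossover_or = if (length(hit)) min(hit) else NA_real_)
  }))
  attr(out, "crossover") <- cross
  class(out) <- c("power_curve", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.power_curve <- function(x, ...) {
  cat("Linkage vs GWAS power curve\n")
  print.data.frame(x, digits = 4)
  cross <- attr(x, "crossover")
  if (!is.null(cross)) {
    cat("Crossover (smallest OR with linkage power >= empirical GWAS power):\n")
    for (i in seq_len(nrow(cross)))
      cat(sprintf("  N = %d: %s\n", cross$n_variants[i],
                  if (is.na(cross$crossover_or[i])) "none"
                  else format(cross$crossover_or[i])))
  }
  invisible(x)
}

#' Plot a power curve
#'
#' Power against per-allele odds ratio; solid lines for linkage, dashed for
#' empirical GWAS, one colour per variant count.
#'
#' @param x A [power_curve()] result.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.power_curve <- function(x, ...) {
  Ns <- sort(unique(x$n_variants))
  cols <- grDevices::hcl.colors(max(3, length(Ns)), "Dark 3")[seq_along(Ns)]
  graphics::plot(range(x$or), c(0, 1), type = "n", xlab = "per-allele OR",
                 ylab = "power", ...)
  for (i in seq_along(Ns)) {
    sub <- x[x$n_variants == Ns[i], ]
    l <- sub[sub$method == "linkage", ]
    g <- sub[sub$method == "gwas_empirical", ]
    graphics::lines(l$or[order(l$or)], l$power[order(l$or)], col = cols[i])
    graphics::lines(g$or[order(g$or)], g$power[order(g$or)], col = cols[i],
                    lty = 2)
  }
  graphics::legend("bottomright",
                   legend = c(paste0("N = ", Ns), "linkage", "GWAS (empirical)"),
                   col = c(cols, "black", "black"),
                   lty = c(rep(1, length(Ns)), 1, 2), bty = "n")
  invisible(x)
}
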