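#' Cochran-Armitage trend test for one SNP
#'
#' One-degree-of-freedom trend test of allele dosage against case status with
#' equal scores (0, 1, 2), computed as the proportion trend score test
#' ([stats::prop.trend.test()]); this is asymptotically the score test of the
#' per-allele logistic model. Monomorphic sites yield a flagged not-testable
#' result rather than an error. The effect column is the allelic log odds
#' ratio from the 2x2 allele table (Haldane 0.5 correction when a cell is
#' empty).
#'
#' @param dosage Integer vector of genotype dosages (0/1/2).
#' @param phenotype Binary vector (1 = case, 0 = control).
#' @return A one-row data frame: `statistic`, `p_value`, `effect`, `se`,
#'   `testable`.
#' @examples
#' trend_test(c(0, 1, 2, 0, 1, 0), c(1, 1, 1, 0, 0, 0))
#' @export
trend_test <- function(dosage, phenotype) {
  stopifnot(length(dosage) == length(phenotype))
  phenotype <- as.integer(phenotype)
  if (length(unique(phenotype)) < 2L)
    stop("both phenotype classes must be present", call. = FALSE)
  x <- vapply(0:2, function(d) sum(phenotype == 1L & dosage == d), numeric(1))
  n <- vapply(0:2, function(d) sum(dosage == d), numeric(1))
  keep <- n > 0
  eff <- allelic_log_or(dosage, phenotype)
  if (sum(keep) < 2L)
    return(data.frame(statistic = NA_real_, p_value = NA_real_,
                      effect = NA_real_, se = NA_real_, testable = FALSE))
  pt <- suppressWarnings(stats::prop.trend.test(x[keep], n[keep],
                                                score = (0:2)[keep]))
  stat <- unname(pt$statistic)
  p <- unname(pt$p.value)
  if (!is.finite(stat)) { # all cases or all controls in every class
    stat <- 0; p <- 1
  }
  data.frame(statistic = stat, p_value = p,
             effect = eff[["logor"]], se = eff[["se"]], testable = TRUE)
}

allelic_log_or <- function(dosage, phenotype) {
  a_case <- sum(dosage[phenotype == 1L]); n_case <- 2 * sum(phenotype == 1L)
  a_ctrl <- sum(dosage[phenotype == 0L]); n_ctrl <- 2 * sum(phenotype == 0L)
  tab <- c(a_case, n_case - a_case, a_ctrl, n_ctrl - a_ctrl)
  if (any(tab == 0)) tab <- tab + 0.5
  c(logor = log(tab[1] * tab[4] / (tab[2] * tab[3])),
    se = sqrt(sum(1 / tab)))
}

# IRLS logistic fit via glm.fit; epsilon 1e-8, maxit 50. Returns coefficients,
# SEs, deviance and a convergence/separation flag.
logit_fit <- function(X, y) {
  fit <- suppressWarnings(stats::glm.fit(
    X, y, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-8, maxit = 50)))
  p <- fit$rank
  se <- rep(NA_real_, ncol(X))
  if (p > 0) {
    Rmat <- fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]
    Rmat[lower.tri(Rmat)] <- 0
    covu <- chol2inv(Rmat)
    se[fit$qr$pivot[seq_len(p)]] <- sqrt(diag(covu))
  }
  coefs <- fit$coefficients
  ok <- fit$converged && all(is.finite(coefs)) &&
    max(abs(coefs)) < 15 && all(is.finite(se))
  list(coef = coefs, se = se, deviance = fit$deviance, rank = p,
       converged = ok)
}

#' Per-site logistic association scan
#'
#' Fits, for each scanned site, the logistic regression of case status on
#' allele dosage (plus optional covariates) by iteratively reweighted least
#' squares, and reports the likelihood-ratio test of the dosage term.
#' Complete or quasi-complete separation is flagged (`converged = FALSE`,
#' P set to `NA`) rather than raised; a rank-deficient covariate design is an
#' error.
#'
#' @param cohort An `sa_cohort`.
#' @param covariates Optional numeric vector or matrix of covariates.
#' @param sites Site ids to scan; defaults to all non-causal (common) sites.
#' @return An `assoc_scan` data frame: `site_id`, `position`, `model_tag`,
#'   `effect`, `se`, `statistic` (LRT chi-square), `p_value`, `converged`.
#' @export
logistic_scan <- function(cohort, covariates = NULL, sites = NULL) {
  stopifnot(inherits(cohort, "sa_cohort"))
  y <- cohort$phenotype
  if (length(unique(y)) < 2L)
    stop("both phenotype classes must be present", call. = FALSE)
  if (is.null(sites)) sites <- cohort$sites$id[!cohort$sites$causal]
  idx <- match(sites, cohort$sites$id)
  if (anyNA(idx)) stop("unknown site id(s): ",
                       paste(sites[is.na(idx)], collapse = ", "), call. = FALSE)
  X0 <- cbind(intercept = rep(1, length(y)))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    X0 <- cbind(X0, covariates)
    if (qr(X0)$rank < ncol(X0))
      stop("degenerate design: covariates are rank deficient", call. = FALSE)
  }
  null_fit <- logit_fit(X0, y)
  tag <- if (is.null(covariates)) "unconditional" else "conditional"
  rows <- lapply(idx, function(s) {
    d <- cohort$genotypes[, s]
    if (length(unique(d)) < 2L)
      return(data.frame(site_id = cohort$sites$id[s],
                        position = cohort$sites$position[s], model_tag = tag,
                        effect = NA_real_, se = NA_real_, statistic = NA_real_,
                        p_value = NA_real_, converged = FALSE))
    fit <- logit_fit(cbind(X0, dosage = d), y)
    j <- ncol(X0) + 1L
    lrt <- null_fit$deviance - fit$deviance
    ok <- fit$converged && fit$rank == ncol(X0) + 1L
    data.frame(site_id = cohort$sites$id[s],
               position = cohort$sites$position[s], model_tag = tag,
               effect = unname(fit$coef[j]), se = fit$se[j],
               statistic = if (ok) lrt else NA_real_,
               p_value = if (ok) stats::pchisq(lrt, 1, lower.tail = FALSE)
                         else NA_real_,
               converged = ok)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("assoc_scan", "data.frame")
  out
}

#' Compound rare-variant carrier status
#'
#' Binary indicator that an individual carries at least one alternate allele
#' at any of the listed rare causal sites; the conditioning covariate of the
#' ablation analysis.
#'
#' @param cohort An `sa_cohort`.
#' @param sites Rare site ids; defaults to all sites flagged causal. The
#'   listed sites must exist and be flagged causal. An empty list is an error.
#' @return Integer 0/1 vector, one element per individual.
#' @export
compound_carrier <- function(cohort, sites = NULL) {
  stopifnot(inherits(cohort, "sa_cohort"))
  if (is.null(sites)) sites <- cohort$sites$id[cohort$sites$causal]
  if (!length(sites)) stop("no rare sites to collapse", call. = FALSE)
  idx <- match(sites, cohort$sites$id)
  if (anyNA(idx)) stop("unknown site id(s): ",
                       paste(sites[is.na(idx)], collapse = ", "), call. = FALSE)
  if (!all(cohort$sites$causal[idx]))
    stop("all listed sites must be flagged causal/rare", call. = FALSE)
  as.integer(rowSums(cohort$genotypes[, idx, drop = FALSE] > 0) > 0)
}

#' Paired unconditional/conditional association scan
#'
#' Reproduces the diagnostic ablation analysis of a synthetic association:
#' every common site is scanned by logistic regression twice, without and
#' with conditioning on rare-variant carrier status. In `"compound"` mode the
#' conditioning covariate is the single compound-carrier indicator; in
#' `"separate"` mode one carrier indicator per rare site is used. Rare sites
#' are excluded from the scanned set unless `scan_sites` names them
#' explicitly.
#'
#' @param cohort An `sa_cohort`.
#' @param rare_sites Rare causal site ids to condition on (default: all sites
#'   flagged causal).
#' @param mode `"compound"` (default) or `"separate"`.
#' @param scan_sites Sites to scan (default: all non-causal sites).
#' @return An `assoc_scan` data frame with both `model_tag` blocks, sorted by
#'   position within block; the conditioning sites and mode are attached as
#'   attributes.
#' @examples
#' m <- nod2_model()
#' pool <- build_pool(m, seed = 1)
#' coh <- sample_case_control(pool, m, 500, 500, seed = 2)
#' sc <- conditional_scan(coh)
#' summary(sc)
#' @export
conditional_scan <- function(cohort, rare_sites = NULL,
                             mode = c("compound", "separate"),
                             scan_sites = NULL) {
  mode <- match.arg(mode)
  if (is.null(rare_sites)) rare_sites <- cohort$sites$id[cohort$sites$causal]
  if (!length(rare_sites)) stop("no rare sites to condition on", call. = FALSE)
  cov <- if (mode == "compound") compound_carrier(cohort, rare_sites) else {
    idx <- match(rare_sites, cohort$sites$id)
    m <- (cohort$genotypes[, idx, drop = FALSE] > 0) + 0L
    colnames(m) <- rare_sites
    m
  }
  uncond <- logistic_scan(cohort, covariates = NULL, sites = scan_sites)
  cond <- logistic_scan(cohort, covariates = cov, sites = scan_sites)
  out <- rbind(uncond[order(uncond$position), ], cond[order(cond$position), ])
  rownames(out) <- NULL
  attr(out, "conditioning_sites") <- rare_sites
  attr(out, "mode") <- mode
  class(out) <- c("assoc_scan", "data.frame")
  out
}

#' @export
summary.assoc_scan <- function(object, ...) {
  tags <- unique(object$model_tag)
  out <- data.frame(model_tag = tags,
                    n_sites = vapply(tags, function(t)
                      sum(object$model_tag == t), numeric(1)),
                    min_p = vapply(tags, function(t)
                      suppressWarnings(min(object$p_value[object$model_tag == t],
                                           na.rm = TRUE)), numeric(1)))
  rownames(out) <- NULL
  out
}

#' @export
print.assoc_scan <- function(x, ...) {
  s <- summary(x)
  cat("Association scan\n")
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-14s %3d sites, min P = %.3g\n",
                s$model_tag[i], s$n_sites[i], s$min_p[i]))
  cs <- attr(x, "conditioning_sites")
  if (!is.null(cs))
    cat("  conditioned on:", paste(cs, collapse = ", "),
        sprintf("(%s mode)\n", attr(x, "mode")))
  invisible(x)
}

#' Plot an association scan
#'
#' Base-graphics plot of -log10 P against position; unconditional results in
#' grey, conditional in black, causal positions (if supplied) as red
#' triangles on the axis.
#'
#' @param x An `assoc_scan`.
#' @param causal_positions Optional positions to mark.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.assoc_scan <- function(x, causal_positions = NULL, ...) {
  lp <- -log10(x$p_value)
  cols <- ifelse(x$model_tag == "conditional", "black", "grey60")
  graphics::plot(x$position, lp, col = cols, pch = 16,
                 xlab = "position (bp)", ylab = expression(-log[10](P)), ...)
  if (!is.null(causal_positions))
    graphics::points(causal_positions, rep(0, length(causal_positions)),
                     pch = 17, col = "red")
  if (any(x$model_tag == "conditional"))
    graphics::legend("topright", legend = c("unconditional", "conditional"),
                     col = c("grey60", "black"), pch = 16, bty = "n")
  invisible(x)
}

#' Scan every common site with the trend test
#'
#' Fast scan used by the empirical power machinery: per-site Cochran-Armitage
#' trend P-values over the given sites.
#'
#' @param cohort An `sa_cohort`.
#' @param sites Site ids (default: all non-causal sites).
#' @return Numeric vector of P-values named by site id (`NA` when not
#'   testable).
#' @export
trend_scan <- function(cohort, sites = NULL) {
  if (is.null(sites)) sites <- cohort$sites$id[!cohort$sites$causal]
  idx <- match(sites, cohort$sites$id)
  y <- cohort$phenotype
  p <- vapply(idx, function(s)
    trend_test(cohort$genotypes[, s], y)$p_value, numeric(1))
  names(p) <- sites
  p
}
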