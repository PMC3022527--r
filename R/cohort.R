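new_cohort <- function(genotypes, phenotype, sites, pedigree = NULL,
                       population = NULL) {
  stopifnot(is.matrix(genotypes), length(phenotype) == nrow(genotypes))
  structure(list(genotypes = genotypes, phenotype = as.integer(phenotype),
                 sites = sites, pedigree = pedigree, population = population),
            class = "sa_cohort")
}

#' @export
print.sa_cohort <- function(x, ...) {
  cat(sprintf("Cohort: %d individuals x %d sites (%d causal)\n",
              nrow(x$genotypes), ncol(x$genotypes), sum(x$sites$causal)))
  if (!is.null(x$pedigree))
    cat(sprintf("  %d affected sib pairs (IBD recorded)\n", nrow(x$pedigree)))
  else
    cat(sprintf("  %d cases / %d controls\n", sum(x$phenotype == 1L),
                sum(x$phenotype == 0L)))
  invisible(x)
}

# Map haplotype-class index pairs to a dosage matrix over all pool sites.
dosage_from_class_pairs <- function(pool, h1, h2) {
  g <- pool$classes[h1, , drop = FALSE] + pool$classes[h2, , drop = FALSE]
  storage.mode(g) <- "integer"
  g
}

# Penetrance of every ordered haplotype-class pair (C x C matrix, row = hap 1).
class_pair_penetrance <- function(pool, model) {
  C <- nrow(pool$classes)
  rare <- which(pool$sites$causal)
  ids <- pool$sites$variant_id[rare]
  ord <- match(variant_ids(model), ids)
  if (anyNA(ord))
    stop("model variants do not all correspond to pool causal sites", call. = FALSE)
  rare <- rare[ord]
  hap_r <- pool$classes[, rare, drop = FALSE]
  i <- rep(seq_len(C), times = C)
  j <- rep(seq_len(C), each = C)
  D <- hap_r[i, , drop = FALSE] + hap_r[j, , drop = FALSE]
  matrix(penetrance_from_dosage(model, D), C, C)
}

#' Sample an ascertained case-control cohort
#'
#' Individuals are formed from two haplotypes drawn independently from the
#' pool (no recombination within the region); affection follows the joint
#' penetrance of the model's causal variants. Ascertainment is exact: cases
#' are drawn from `P(haplotype pair | affected)` and controls from
#' `P(haplotype pair | unaffected)`, which is the stationary distribution a
#' rejection sampler would produce, without its unbounded runtime.
#'
#' @param pool A [build_pool()] result whose causal sites match `model`.
#' @param model A [locus_model()].
#' @param n_cases,n_controls Ascertainment quotas.
#' @param seed Optional integer seed.
#' @return An `sa_cohort` (cases first, phenotype 1; then controls,
#'   phenotype 0).
#' @examples
#' m <- nod2_model()
#' pool <- build_pool(m, seed = 1)
#' coh <- sample_case_control(pool, m, 100, 100, seed = 2)
#' @export
sample_case_control <- function(pool, model, n_cases, n_controls, seed = NULL) {
  stopifnot(inherits(pool, "haplotype_pool"), inherits(model, "locus_model"),
            n_cases >= 0, n_controls >= 0)
  C <- nrow(pool$classes)
  f <- class_pair_penetrance(pool, model)
  prior <- tcrossprod(pool$freq)  # P(h1) P(h2)
  w_case <- as.numeric(prior * f)
  w_ctrl <- as.numeric(prior * (1 - f))
  if (n_cases > 0 && sum(w_case) <= 0)
    stop("ascertainment failure: no genotype has positive penetrance", call. = FALSE)
  if (n_controls > 0 && sum(w_ctrl) <= 0)
    stop("ascertainment failure: every genotype is fully penetrant", call. = FALSE)
  with_seed(seed, {
    draw <- function(n, w) {
      k <- sample.int(C * C, n, replace = TRUE, prob = w)
      cbind(h1 = (k - 1L) %% C + 1L, h2 = (k - 1L) %/% C + 1L)
    }
    cases <- draw(n_cases, w_case)
    ctrls <- draw(n_controls, w_ctrl)
    g <- dosage_from_class_pairs(pool, c(cases[, 1], ctrls[, 1]),
                                 c(cases[, 2], ctrls[, 2]))
    rownames(g) <- sprintf("S%05d", seq_len(n_cases + n_controls))
    new_cohort(g, rep(c(1L, 0L), c(n_cases, n_controls)), pool$sites)
  })
}

#' Sample affected sib pairs with IBD bookkeeping
#'
#' Families (two parents, two children) are generated with Mendelian
#' transmission of whole haplotypes and ascertained on both children being
#' affected. Sampling is exact under the locus model's assumptions (linkage
#' equilibrium across variants, multiplicative penetrance): because the
#' double-affection weight factorises over variants given the four
#' transmission choices, the transmission pattern and the per-variant
#' parental alleles are drawn from their exact conditional distributions.
#' Common-SNP backgrounds are then filled in from the pool conditional on
#' each haplotype's rare-allele content — penetrance does not depend on them,
#' so this decoration leaves the ascertained distribution untouched. The true
#' IBD state (0/1/2 shared parental haplotypes) of every pair is recorded.
#'
#' @inheritParams sample_case_control
#' @param n_pairs Number of affected sib pairs.
#' @return An `sa_cohort` with a `pedigree` data frame (`pair`, `sib1`,
#'   `sib2`, `ibd`); all phenotypes are 1.
#' @export
sample_asp_pairs <- function(pool, model, n_pairs, seed = NULL) {
  stopifnot(inherits(pool, "haplotype_pool"), inherits(model, "locus_model"),
            n_pairs >= 1)
  rare <- which(pool$sites$causal)
  ids <- pool$sites$variant_id[rare]
  ord <- match(variant_ids(model), ids)
  if (anyNA(ord))
    stop("model variants do not all correspond to pool causal sites", call. = FALSE)
  rare <- rare[ord]
  nv <- n_variants(model)
  if (prevalence(model) <= 0)
    stop("ascertainment failure: no family can produce two affected children",
         call. = FALSE)

  # 16 transmission patterns: which maternal/paternal haplotype each child gets
  tp <- expand.grid(t1m = 1:2, t1p = 1:2, t2m = 1:2, t2p = 1:2)
  # 16 parental allele configurations per variant: (a1, a2) maternal, (b1, b2)
  # paternal carrier indicators
  ac <- as.matrix(expand.grid(a1 = 0:1, a2 = 0:1, b1 = 0:1, b2 = 0:1))
  # per-variant weight tensors W[t, allele config]; the double-affection
  # weight is prod_v gamma_v(c1) * gamma_v(c2) given transmissions
  gt <- grr_table(model)
  W <- vector("list", nv)
  for (v in seq_len(nv)) {
    p <- model$variants[[v]]$maf
    pa <- p^rowSums(ac) * (1 - p)^(4 - rowSums(ac))
    Wv <- matrix(0, 16, 16)
    for (t in 1:16) {
      c1 <- ac[, tp$t1m[t]] + ac[, 2 + tp$t1p[t]]
      c2 <- ac[, tp$t2m[t]] + ac[, 2 + tp$t2p[t]]
      Wv[t, ] <- pa * gt[v, c1 + 1L] * gt[v, c2 + 1L]
    }
    W[[v]] <- Wv
  }
  wt <- rep(1, 16)
  for (v in seq_len(nv)) wt <- wt * rowSums(W[[v]])

  with_seed(seed, {
    t_draw <- sample.int(16, n_pairs, replace = TRUE, prob = wt)
    # parental rare contents per haplotype slot (m1, m2, p1, p2)
    hapr <- array(0L, dim = c(n_pairs, 4, max(nv, 1)))
    for (v in seq_len(nv)) for (t in unique(t_draw)) {
      sel <- which(t_draw == t)
      cfg <- sample.int(16, length(sel), replace = TRUE, prob = W[[v]][t, ])
      hapr[sel, , v] <- ac[cfg, ]
    }
    ibd <- (tp$t1m[t_draw] == tp$t2m[t_draw]) +
      (tp$t1p[t_draw] == tp$t2p[t_draw])

    # transmitted haplotype rare contents for the two sibs
    slot <- function(mat_t, pat_t) {
      mi <- cbind(seq_len(n_pairs), mat_t)
      pi_ <- cbind(seq_len(n_pairs), 2L + pat_t)
      list(mat = mi, pat = pi_)
    }
    take <- function(idx) {
      out <- matrix(0L, n_pairs, nv)
      for (v in seq_len(nv)) out[, v] <- hapr[cbind(idx, v)]
      out
    }
    s1 <- slot(tp$t1m[t_draw], tp$t1p[t_draw])
    s2 <- slot(tp$t2m[t_draw], tp$t2p[t_draw])

    # decorate every transmitted haplotype with a common-SNP background from
    # the pool, conditional on its rare content
    common_idx <- which(!pool$sites$causal)
    carrier_class <- vapply(seq_len(nv), function(v) {
      w <- which(pool$classes[, rare[v]] == 1L)
      w[1]
    }, integer(1))
    noncarrier <- which(rowSums(pool$classes[, rare, drop = FALSE]) == 0)
    assign_background <- function(rmat) {
      nr <- rowSums(rmat)
      cls <- integer(n_pairs)
      sel0 <- nr == 0L
      if (any(sel0))
        cls[sel0] <- if (length(noncarrier) == 1L) noncarrier else
          sample(noncarrier, sum(sel0), replace = TRUE,
                 prob = pool$freq[noncarrier])
      sel1 <- which(nr >= 1L)
      if (length(sel1)) {
        first_v <- max.col(rmat[sel1, , drop = FALSE], ties.method = "random")
        cls[sel1] <- carrier_class[first_v]
      }
      cls
    }
    hap_vec <- function(rmat, cls) {
      h <- matrix(0L, n_pairs, ncol(pool$classes))
      h[, common_idx] <- pool$classes[cls, common_idx, drop = FALSE]
      h[, rare] <- rmat
      h
    }
    build_sib <- function(sl) {
      rm_ <- take(sl$mat); rp <- take(sl$pat)
      hm <- hap_vec(rm_, assign_background(rm_))
      hp <- hap_vec(rp, assign_background(rp))
      g <- hm + hp
      storage.mode(g) <- "integer"
      g
    }
    g <- rbind(build_sib(s1), build_sib(s2))
    colnames(g) <- pool$sites$id
    sib1 <- sprintf("F%05d_1", seq_len(n_pairs))
    sib2 <- sprintf("F%05d_2", seq_len(n_pairs))
    rownames(g) <- c(sib1, sib2)
    ped <- data.frame(pair = seq_len(n_pairs), sib1 = sib1, sib2 = sib2,
                      ibd = as.integer(ibd))
    new_cohort(g, rep(1L, 2 * n_pairs), pool$sites, pedigree = ped)
  })
}

#' Expected case/control allele frequencies and induced allelic odds ratios
#'
#' Computes, for every pool site, the expected allele frequency among cases
#' and among controls by Bayes inversion of the penetrance model over the
#' exact haplotype-pair distribution, together with the induced allelic odds
#' ratio. At common SNPs this quantifies the synthetic association the rare
#' causal cluster induces.
#'
#' @inheritParams sample_case_control
#' @return The pool's site table with columns `freq_pop`, `freq_case`,
#'   `freq_control` and `allelic_or`.
#' @export
expected_site_frequencies <- function(pool, model) {
  C <- nrow(pool$classes)
  f <- class_pair_penetrance(pool, model)
  prior <- tcrossprod(pool$freq)
  w_case <- prior * f
  w_ctrl <- prior * (1 - f)
  # P(first haplotype is class c | status); alleles of an individual are
  # exchangeable so this equals the expected allele frequency
  hap_case <- rowSums(w_case) / sum(w_case)
  hap_ctrl <- rowSums(w_ctrl) / sum(w_ctrl)
  out <- pool$sites
  out$freq_pop <- as.numeric(crossprod(pool$classes, pool$freq))
  out$freq_case <- as.numeric(crossprod(pool$classes, hap_case))
  out$freq_control <- as.numeric(crossprod(pool$classes, hap_ctrl))
  out$allelic_or <- (out$freq_case / (1 - out$freq_case)) /
    (out$freq_control / (1 - out$freq_control))
  out
}

#' Simulate cohorts from a locus model
#'
#' `simulate()` method dispatching to the ascertained samplers: one call
#' produces a list of `nsim` cohorts from a shared haplotype pool.
#'
#' @param object A [locus_model()].
#' @param nsim Number of cohorts.
#' @param seed Integer root seed (stage streams are derived from it).
#' @param pool A [build_pool()] result; built from `object` with defaults
#'   when `NULL`.
#' @param design `"case_control"` or `"asp"`.
#' @param n_cases,n_controls,n_pairs Cohort sizes.
#' @param ... Unused.
#' @return A list of `sa_cohort` objects (a single cohort when `nsim = 1`).
#' @export
simulate.locus_model <- function(object, nsim = 1, seed = 1, pool = NULL,
                                 design = c("case_control", "asp"),
                                 n_cases = 1000, n_controls = 1000,
                                 n_pairs = 1000, ...) {
  design <- match.arg(design)
  if (is.null(pool)) pool <- build_pool(object, seed = child_seed(seed, "pool"))
  out <- lapply(seq_len(nsim), function(i) {
    s <- child_seed(seed, paste0("cohort", i))
    if (design == "case_control")
      sample_case_control(pool, object, n_cases, n_controls, seed = s)
    else sample_asp_pairs(pool, object, n_pairs, seed = s)
  })
  if (nsim == 1) out[[1]] else out
}

#' Write a cohort as VCF plus a phenotype table
#'
#' Emits a minimal VCF v4.2 (GT field only, unphased `/` separator, one sample
#' column per individual) with causal sites flagged by the `CAUSAL` INFO key,
#' and a two-column tab-delimited phenotype file (`sample_id`, `status` 0/1).
#' [read_cohort()] reproduces the dosage matrix exactly.
#'
#' @param cohort An `sa_cohort`.
#' @param vcf_path,pheno_path Output paths.
#' @return `vcf_path`, invisibly.
#' @export
write_cohort <- function(cohort, vcf_path, pheno_path) {
  stopifnot(inherits(cohort, "sa_cohort"))
  g <- cohort$genotypes
  sites <- cohort$sites
  gt <- matrix(c("0/0", "0/1", "1/1")[g + 1L], nrow(g), ncol(g))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=synthassoc",
    sprintf("##contig=<ID=1,length=%d>",
            max(sites$position) + 1L),
    "##INFO=<ID=CAUSAL,Number=0,Type=Flag,Description=\"Simulated low-frequency causal variant\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(g)), collapse = "\t"))
  ord <- order(sites$position)
  body <- vapply(ord, function(s) {
    paste(c("1", sites$position[s], sites$id[s], "A", "G", ".", ".",
            if (sites$causal[s]) "CAUSAL" else ".", "GT", gt[, s]),
          collapse = "\t")
  }, character(1))
  con <- file(vcf_path, "wb")  # binary mode: fixed newlines for byte determinism
  on.exit(close(con))
  writeLines(c(header, body), con)
  pheno <- data.frame(sample_id = rownames(g), status = cohort$phenotype)
  utils::write.table(pheno, pheno_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
  invisible(vcf_path)
}

#' Read a cohort from VCF plus a phenotype table
#'
#' Reads back files written by [write_cohort()] (or any GT-only VCF with the
#' `CAUSAL` INFO flag convention) through the `vcfR` parser. The sample sets
#' of the two files must coincide; offenders are listed otherwise.
#'
#' @param vcf_path,pheno_path Input paths.
#' @return An `sa_cohort`.
#' @export
read_cohort <- function(vcf_path, pheno_path) {
  if (!file.exists(vcf_path)) stop("VCF file not found: ", vcf_path, call. = FALSE)
  if (!file.exists(pheno_path))
    stop("phenotype file not found: ", pheno_path, call. = FALSE)
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dosage <- matrix(NA_integer_, nrow = ncol(gt), ncol = nrow(gt),
                   dimnames = list(colnames(gt), rownames(gt)))
  clean <- gsub("\\|", "/", t(gt))
  dosage[] <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)[clean]
  fix <- v@fix
  sites <- data.frame(id = fix[, "ID"],
                      position = as.integer(fix[, "POS"]),
                      causal = grepl("(^|;)CAUSAL(;|$)", fix[, "INFO"]),
                      stringsAsFactors = FALSE)
  pheno <- utils::read.delim(pheno_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "status") %in% names(pheno)))
    stop("phenotype table must have columns sample_id and status", call. = FALSE)
  only_vcf <- setdiff(rownames(dosage), pheno$sample_id)
  only_ph <- setdiff(pheno$sample_id, rownames(dosage))
  if (length(only_vcf) || length(only_ph))
    stop("sample mismatch between VCF and phenotype table; VCF-only: [",
         paste(only_vcf, collapse = ", "), "], phenotype-only: [",
         paste(only_ph, collapse = ", "), "]", call. = FALSE)
  pheno <- pheno[match(rownames(dosage), pheno$sample_id), ]
  new_cohort(dosage, pheno$status, sites)
}
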