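#' Build an exact haplotype pool with rare causal alleles on common backgrounds
#'
#' Constructs a population of distinct haplotype classes over `n_common`
#' common SNPs plus one site per risk variant of `model`. Common alleles are
#' laid down by successive random bipartition refinement of the class set
#' (an infinite-sites, no-recombination construction), so every configured
#' allele frequency is reproduced exactly by the pool rather than sampled.
#' Each rare causal allele is then placed on exactly one common-SNP background
#' class (a single mutational origin), chosen with probability proportional to
#' class frequency among classes large enough to host it; the hosting class is
#' split so that the rare allele's marginal frequency equals its variant MAF
#' exactly.
#'
#' @param model A [locus_model()] whose variants become the causal sites.
#' @param n_common Number of common SNP sites (>= 1).
#' @param common_freq_range Length-2 range from which common allele
#'   frequencies are drawn uniformly.
#' @param region_length Region size in base pairs; positions are drawn
#'   uniformly without replacement.
#' @param seed Integer seed (optional; the current RNG stream is used when
#'   `NULL`).
#' @return An object of class `haplotype_pool`: a list with `classes`
#'   (classes x sites 0/1 matrix), `freq`, and a `sites` data frame
#'   (id, position, causal, target_freq, variant_id).
#' @examples
#' pool <- build_pool(nod2_model(), n_common = 20, seed = 1)
#' pool
#' @export
build_pool <- function(model, n_common = 20, common_freq_range = c(0.1, 0.5),
                       region_length = 200000, seed = NULL) {
  stopifnot(inherits(model, "locus_model"), n_common >= 1,
            length(common_freq_range) == 2, region_length >= n_common)
  lo <- min(common_freq_range); hi <- max(common_freq_range)
  if (lo <= 0 || hi >= 1) stop("common frequencies must lie in (0, 1)", call. = FALSE)
  nv <- n_variants(model)
  mafs <- variant_mafs(model)
  min_common_maf <- min(lo, 1 - hi)
  if (nv > 0 && max(mafs) >= min_common_maf)
    stop("all rare variant MAFs must be below the smallest common-SNP MAF",
         call. = FALSE)
  with_seed(seed, {
    # construct in descending frequency order: every derived allele arises on
    # a single existing haplotype class (infinite-sites, no recombination), so
    # allele sets are nested and the four-gamete condition holds exactly
    q_common <- sort(stats::runif(n_common, lo, hi), decreasing = TRUE)
    n_sites <- n_common + nv
    positions <- sort(sample.int(region_length, n_sites))
    rare_pos_idx <- if (nv > 0) sort(sample.int(n_sites, nv)) else integer()

    freq <- 1
    alleles <- matrix(0L, nrow = 1, ncol = 0)
    eps <- 1e-12
    for (q in q_common) {
      feasible <- which(freq >= q - eps)
      if (!length(feasible))
        stop(sprintf(paste0(
          "infeasible common-SNP frequencies: no haplotype class can host a ",
          "derived allele of frequency %.3f; use fewer common SNPs or a ",
          "narrower frequency range"), q), call. = FALSE)
      host <- if (length(feasible) == 1L) feasible else
        sample(feasible, 1L, prob = freq[feasible])
      alleles <- cbind(alleles, 0L)
      alleles <- rbind(alleles, alleles[host, ])
      alleles[nrow(alleles), ncol(alleles)] <- 1L
      freq <- c(freq, q)
      freq[host] <- freq[host] - q
    }
    keep0 <- freq > eps
    alleles <- alleles[keep0, , drop = FALSE]
    freq <- freq[keep0]
    colnames(alleles) <- NULL

    # place each rare allele on one background class
    rare_host <- rep(NA_integer_, nv)
    carries_rare <- rep(FALSE, nrow(alleles))
    rare_cols <- matrix(0L, nrow = nrow(alleles), ncol = nv)
    for (i in seq_len(nv)) {
      feasible <- which(freq >= mafs[i] - eps & !carries_rare)
      if (!length(feasible))
        stop(sprintf(
          "infeasible placement: no background haplotype class can host variant %s (maf %g)",
          variant_ids(model)[i], mafs[i]), call. = FALSE)
      host <- if (length(feasible) == 1L) feasible else
        sample(feasible, 1L, prob = freq[feasible])
      # split host: carrier piece of mass exactly maf
      alleles <- rbind(alleles, alleles[host, ])
      rare_cols <- rbind(rare_cols, rare_cols[host, ])
      carries_rare <- c(carries_rare, TRUE)
      new_i <- nrow(alleles)
      rare_cols[new_i, i] <- 1L
      freq <- c(freq, mafs[i])
      freq[host] <- freq[host] - mafs[i]
      rare_host[i] <- new_i
    }
    keep <- freq > eps
    alleles <- alleles[keep, , drop = FALSE]
    rare_cols <- rare_cols[keep, , drop = FALSE]
    freq <- freq[keep]

    # interleave columns by genomic position
    classes <- matrix(0L, nrow = nrow(alleles), ncol = n_sites)
    common_ids <- sprintf("snp%02d", seq_len(n_common))
    site_id <- character(n_sites)
    causal <- logical(n_sites)
    target_freq <- numeric(n_sites)
    var_id <- rep(NA_character_, n_sites)
    ci <- 0L; ri <- 0L
    for (s in seq_len(n_sites)) {
      if (s %in% rare_pos_idx) {
        ri <- ri + 1L
        classes[, s] <- rare_cols[, ri]
        site_id[s] <- variant_ids(model)[ri]
        causal[s] <- TRUE
        target_freq[s] <- mafs[ri]
        var_id[s] <- variant_ids(model)[ri]
      } else {
        ci <- ci + 1L
        classes[, s] <- alleles[, ci]
        site_id[s] <- common_ids[ci]
        target_freq[s] <- q_common[ci]
      }
    }
    colnames(classes) <- site_id
    pool <- structure(list(
      classes = classes, freq = freq,
      sites = data.frame(id = site_id, position = positions, causal = causal,
                         target_freq = target_freq, variant_id = var_id,
                         stringsAsFactors = FALSE),
      region_length = region_length),
      class = "haplotype_pool")
    validate_pool(pool)
    pool
  })
}

validate_pool <- function(pool, tol = 1e-9) {
  stopifnot(inherits(pool, "haplotype_pool"))
  if (abs(sum(pool$freq) - 1) > 1e-12)
    stop("haplotype class frequencies do not sum to 1", call. = FALSE)
  realized <- as.numeric(crossprod(pool$classes, pool$freq))
  if (any(abs(realized - pool$sites$target_freq) > tol))
    stop("pool marginal allele frequencies drift from their targets", call. = FALSE)
  rare <- which(pool$sites$causal)
  for (s in rare) {
    backgrounds <- unique(pool$classes[pool$classes[, s] == 1L,
                                       !pool$sites$causal, drop = FALSE])
    if (nrow(backgrounds) > 1)
      stop("a rare allele spans more than one common-SNP background class",
           call. = FALSE)
  }
  invisible(pool)
}

#' Per-site allele frequencies of a pool
#'
#' @param pool A [build_pool()] result.
#' @return The pool's `sites` data frame with a `freq` column of realised
#'   allele frequencies.
#' @export
pool_site_frequencies <- function(pool) {
  out <- pool$sites
  out$freq <- as.numeric(crossprod(pool$classes, pool$freq))
  out
}

#' Pairwise linkage disequilibrium between two pool sites
#'
#' Exact D, D' and r^2 computed from the haplotype class frequencies.
#'
#' @param pool A [build_pool()] result.
#' @param site_a,site_b Site ids (or column indices).
#' @return Named numeric vector `c(D, Dprime, r2)`.
#' @export
pool_ld <- function(pool, site_a, site_b) {
  idx <- function(s) if (is.character(s)) match(s, pool$sites$id) else s
  a <- idx(site_a); b <- idx(site_b)
  if (is.na(a) || is.na(b)) stop("unknown site id", call. = FALSE)
  pA <- sum(pool$freq[pool$classes[, a] == 1L])
  pB <- sum(pool$freq[pool$classes[, b] == 1L])
  pAB <- sum(pool$freq[pool$classes[, a] == 1L & pool$classes[, b] == 1L])
  D <- pAB - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), pB * (1 - pA)) else
    min(pA * pB, (1 - pA) * (1 - pB))
  c(D = D,
    Dprime = if (dmax == 0) NA_real_ else abs(D) / dmax,
    r2 = D^2 / (pA * (1 - pA) * pB * (1 - pB)))
}

#' Split a pool into two diverged populations
#'
#' Population A is the input pool unchanged. Population B shares the common
#' SNPs, with class frequencies perturbed by log-normal reweighting of
#' magnitude `divergence_noise` (0 leaves frequencies untouched); when
#' `privacy` is set the rare causal alleles are removed from population B
#' entirely (frequency exactly 0), emulating population-private low-frequency
#' variation.
#'
#' @param pool A [build_pool()] result.
#' @param privacy Logical; make rare causal alleles private to population A.
#' @param divergence_noise Standard deviation of the per-class log-normal
#'   frequency perturbation applied to population B.
#' @param seed Optional integer seed for the perturbation.
#' @return A list with elements `pop_a` and `pop_b`, both `haplotype_pool`s.
#' @export
split_two_populations <- function(pool, privacy = TRUE, divergence_noise = 0,
                                  seed = NULL) {
  stopifnot(inherits(pool, "haplotype_pool"))
  pop_b <- pool
  if (privacy) {
    rare <- which(pop_b$sites$causal)
    pop_b$classes[, rare] <- 0L
    pop_b$sites$target_freq[rare] <- 0
    key <- apply(pop_b$classes, 1, paste, collapse = "")
    if (anyDuplicated(key)) {
      freq <- tapply(pop_b$freq, key, sum)
      first <- !duplicated(key)
      classes <- pop_b$classes[first, , drop = FALSE]
      pop_b$freq <- as.numeric(freq[key[first]])
      pop_b$classes <- classes
    }
  }
  if (divergence_noise > 0) {
    with_seed(seed, {
      w <- exp(stats::rnorm(length(pop_b$freq), 0, divergence_noise))
      pop_b$freq <- pop_b$freq * w / sum(pop_b$freq * w)
    })
    pop_b$sites$target_freq <- as.numeric(crossprod(pop_b$classes, pop_b$freq))
  }
  validate_pool(pop_b)
  list(pop_a = pool, pop_b = pop_b)
}

#' @export
print.haplotype_pool <- function(x, ...) {
  ns <- nrow(x$sites)
  cat(sprintf("Haplotype pool: %d classes over %d sites (%d common, %d causal), region %g bp\n",
              nrow(x$classes), ns, sum(!x$sites$causal), sum(x$sites$causal),
              x$region_length))
  invisible(x)
}

#' Serialise a haplotype pool (config + frequency table)
#'
#' Writes a YAML config with the site table and region length, and a
#' tab-delimited frequency table with one row per haplotype class (`freq`
#' column followed by one 0/1 allele column per site).
#'
#' @param pool A [build_pool()] result.
#' @param config_path,freq_path Output paths.
#' @return `config_path`, invisibly.
#' @export
write_pool <- function(pool, config_path, freq_path) {
  cfg <- list(region_length = pool$region_length,
              sites = lapply(seq_len(nrow(pool$sites)), function(i)
                as.list(pool$sites[i, c("id", "position", "causal",
                                        "target_freq", "variant_id")])))
  yaml::write_yaml(cfg, config_path, precision = 15)
  tab <- data.frame(freq = pool$freq, pool$classes, check.names = FALSE)
  utils::write.table(tab, freq_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(config_path)
}

#' Read a haplotype pool written by [write_pool()]
#'
#' @param config_path,freq_path Paths written by [write_pool()].
#' @return A `haplotype_pool`.
#' @export
read_pool <- function(config_path, freq_path) {
  cfg <- yaml::read_yaml(config_path)
  sites <- do.call(rbind, lapply(cfg$sites, function(s)
    data.frame(id = s$id, position = s$position, causal = s$causal,
               target_freq = s$target_freq,
               variant_id = if (is.null(s$variant_id)) NA_character_ else s$variant_id,
               stringsAsFactors = FALSE)))
  tab <- utils::read.delim(freq_path, check.names = FALSE)
  classes <- as.matrix(tab[, -1, drop = FALSE])
  storage.mode(classes) <- "integer"
  pool <- structure(list(classes = classes, freq = tab$freq, sites = sites,
                         region_length = cfg$region_length),
                    class = "haplotype_pool")
  validate_pool(pool)
  pool
}
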