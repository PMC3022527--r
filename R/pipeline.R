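#' Read and validate a run configuration
#'
#' Configurations are YAML with nested blocks `model`, `pool`, `cohort`,
#' `scan` and `power`, plus top-level `seed` and `out_dir`. Unknown keys are
#' rejected with an actionable message. Two presets ship with the package
#' (`system.file("extdata", "nod2.yaml", package = "synthassoc")` and
#' `"fig3.yaml"`).
#'
#' @param x Path to a YAML file, or an already-parsed list.
#' @return A validated `run_config` list.
#' @export
run_config <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  schema <- list(
    seed = NULL, out_dir = NULL,
    model = c("preset", "baseline_penetrance", "variants"),
    pool = c("n_common", "freq_min", "freq_max", "region_length"),
    cohort = c("design", "n_cases", "n_controls", "n_pairs"),
    scan = c("condition", "mode"),
    power = c("or_grid", "n_variants", "n_pairs", "alpha_linkage",
              "n_cases", "n_controls", "alpha_gwas", "reps",
              "n_common", "freq_min", "freq_max", "maf"))
  unknown <- setdiff(names(cfg), names(schema))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "; allowed: ", paste(names(schema), collapse = ", "), call. = FALSE)
  for (blk in c("model", "pool", "cohort", "scan", "power")) {
    if (is.null(cfg[[blk]])) next
    bad <- setdiff(names(cfg[[blk]]), schema[[blk]])
    if (length(bad))
      stop(sprintf("unknown key(s) in `%s` block: %s; allowed: %s", blk,
                   paste(bad, collapse = ", "),
                   paste(schema[[blk]], collapse = ", ")), call. = FALSE)
  }
  if (is.null(cfg$seed)) cfg$seed <- 1L
  if (!is.numeric(cfg$seed)) stop("`seed` must be an integer", call. = FALSE)
  if (is.null(cfg$out_dir)) cfg$out_dir <- "."
  if (!is.null(cfg$cohort$design) &&
      !cfg$cohort$design %in% c("case_control", "asp"))
    stop("cohort design must be 'case_control' or 'asp'", call. = FALSE)
  class(cfg) <- "run_config"
  cfg
}

config_model <- function(cfg) locus_model_from_config(cfg$model %||% list(preset = "null"))

config_pool <- function(cfg, model) {
  p <- cfg$pool %||% list()
  build_pool(model,
             n_common = p$n_common %||% 20,
             common_freq_range = c(p$freq_min %||% 0.1, p$freq_max %||% 0.5),
             region_length = p$region_length %||% 200000,
             seed = child_seed(cfg$seed, "pool"))
}

write_manifest <- function(cfg, out_dir, stage) {
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(unclass(cfg), cfg_path, precision = 15)
  manifest <- list(stage = stage,
                   seed = as.integer(cfg$seed),
                   config_md5 = unname(tools::md5sum(cfg_path)),
                   package = "synthassoc",
                   package_version = as.character(utils::packageVersion("synthassoc")))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}

tsv_with_metadata <- function(df, path, meta) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(paste0("# ", names(meta), " = ", unlist(meta)), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) {
    lines <- do.call(paste, c(lapply(df, function(col) {
      out <- as.character(col)
      out[is.na(out)] <- "."
      out
    }), sep = "\t"))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Pipeline stage: simulate a cohort to VCF + phenotype table
#'
#' Builds the configured locus model and haplotype pool, samples the
#' ascertained cohort, and writes `cohort.vcf`, `phenotypes.tsv`, a pool site
#' summary, the serialised model, a copy of the configuration and a manifest
#' into the output directory. Deterministic under a fixed seed: repeated runs
#' produce byte-identical files.
#'
#' @param config A [run_config()] (or a path to one).
#' @param out_dir Output directory (default: the config's `out_dir`).
#' @return Invisibly, a list of the written paths.
#' @export
cmd_simulate <- function(config, out_dir = NULL) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  out_dir <- out_dir %||% cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  model <- config_model(cfg)
  pool <- config_pool(cfg, model)
  co <- cfg$cohort %||% list()
  design <- co$design %||% "case_control"
  message(sprintf("INFO simulate: %d variants, %d pool classes, design %s",
                  n_variants(model), nrow(pool$classes), design))
  cohort <- if (design == "asp")
    sample_asp_pairs(pool, model, co$n_pairs %||% 1000,
                     seed = child_seed(cfg$seed, "cohort"))
  else
    sample_case_control(pool, model, co$n_cases %||% 1000,
                        co$n_controls %||% 1000,
                        seed = child_seed(cfg$seed, "cohort"))
  paths <- list(vcf = file.path(out_dir, "cohort.vcf"),
                pheno = file.path(out_dir, "phenotypes.tsv"),
                pool = file.path(out_dir, "pool_sites.tsv"),
                model = file.path(out_dir, "model.yaml"))
  write_cohort(cohort, paths$vcf, paths$pheno)
  tsv_with_metadata(pool_site_frequencies(pool), paths$pool,
                    list(seed = cfg$seed, stage = "simulate"))
  write_locus_model(model, paths$model)
  if (!is.null(cohort$pedigree))
    tsv_with_metadata(cohort$pedigree,
                      file.path(out_dir, "pedigree.tsv"),
                      list(seed = cfg$seed, stage = "simulate"))
  write_manifest(cfg, out_dir, "simulate")
  invisible(paths)
}

#' Pipeline stage: association scan of a VCF + phenotype cohort
#'
#' Runs the per-site logistic scan; when the VCF flags causal sites (and the
#' config does not disable conditioning) the paired unconditional/conditional
#' ablation scan is run instead, and a summary line with the minimum
#' unconditional and conditional P-values is reported.
#'
#' @param config A [run_config()] (or path).
#' @param vcf_path,pheno_path Cohort inputs.
#' @param out_dir Output directory.
#' @return Invisibly, the `assoc_scan` data frame (also written as
#'   `scan_results.tsv`).
#' @export
cmd_scan <- function(config, vcf_path, pheno_path, out_dir = NULL) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  out_dir <- out_dir %||% cfg$out_dir
  cohort <- read_cohort(vcf_path, pheno_path)  # errors before anything is written
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sc <- cfg$scan %||% list()
  condition <- (sc$condition %||% TRUE) && any(cohort$sites$causal)
  res <- if (condition)
    conditional_scan(cohort, mode = sc$mode %||% "compound")
  else logistic_scan(cohort)
  meta <- list(seed = cfg$seed, stage = "scan",
               conditioning = if (condition)
                 paste(attr(res, "conditioning_sites"), collapse = ",")
               else "none")
  if (condition) {
    s <- summary(res)
    meta$min_unconditional_p <- s$min_p[s$model_tag == "unconditional"]
    meta$min_conditional_p <- s$min_p[s$model_tag == "conditional"]
    message(sprintf("INFO scan: min unconditional P = %.3g, min conditional P = %.3g",
                    meta$min_unconditional_p, meta$min_conditional_p))
  }
  if (any(!res$converged))
    message(sprintf("WARN scan: %d site(s) not testable or non-converged",
                    sum(!res$converged)))
  tsv_with_metadata(res, file.path(out_dir, "scan_results.tsv"), meta)
  write_manifest(cfg, out_dir, "scan")
  invisible(res)
}

#' Pipeline stage: linkage-versus-GWAS power table
#'
#' Evaluates [power_curve()] on the configured grids and writes the long
#' table (`power.tsv`) and the per-N crossover summary (`crossover.tsv`),
#' with run metadata (seed, replicate count, significance levels) in
#' commented header lines.
#'
#' @param config A [run_config()] (or path).
#' @param out_dir Output directory.
#' @return Invisibly, the `power_curve` data frame.
#' @export
cmd_power <- function(config, out_dir = NULL) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  out_dir <- out_dir %||% cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pw <- cfg$power %||% list()
  curve <- power_curve(
    or_grid = pw$or_grid %||% c(2, 3, 5),
    n_variants_list = pw$n_variants %||% c(3, 5, 9),
    linkage = list(n_pairs = pw$n_pairs %||% 2658,
                   alpha = pw$alpha_linkage %||% 1e-4),
    gwas = list(n_cases = pw$n_cases %||% 3000,
                n_controls = pw$n_controls %||% 3000,
                alpha = pw$alpha_gwas %||% 5e-8,
                n_reps = pw$reps %||% 100,
                n_common = pw$n_common %||% 20,
                common_freq_range = c(pw$freq_min %||% 0.1,
                                      pw$freq_max %||% 0.5)),
    maf = pw$maf %||% 0.01,
    baseline_penetrance = (cfg$model$baseline_penetrance) %||% 0.01,
    seed = child_seed(cfg$seed, "power"))
  meta <- list(seed = cfg$seed, stage = "power",
               reps = pw$reps %||% 100,
               alpha_linkage = pw$alpha_linkage %||% 1e-4,
               alpha_gwas = pw$alpha_gwas %||% 5e-8)
  tsv_with_metadata(as.data.frame(curve), file.path(out_dir, "power.tsv"), meta)
  cross <- attr(curve, "crossover")
  cross$crossover_or <- ifelse(is.na(cross$crossover_or), "none",
                               as.character(cross$crossover_or))
  tsv_with_metadata(cross, file.path(out_dir, "crossover.tsv"), meta)
  write_manifest(cfg, out_dir, "power")
  invisible(curve)
}
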