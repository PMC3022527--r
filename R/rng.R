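#' Derive a child RNG seed from a root seed and a stage label
#'
#' Every stochastic stage of the pipeline draws its seed from the run's root
#' seed and a fixed text label, so that adding or reordering stages never
#' perturbs the random stream of an existing stage.
#'
#' @param root_seed Integer root seed for the whole run.
#' @param label Character stage label (e.g. `"pool"`, `"cohort"`).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(root_seed, label) {
  stopifnot(is.numeric(root_seed), length(root_seed) == 1L,
            is.character(label), length(label) == 1L)
  # FNV-style multiplicative hash over the label bytes (kept below 2^31 so
  # base bitwXor stays in integer range), folded with the root seed
  h <- 21661362
  for (b in utf8ToInt(label)) {
    h <- bitwXor(as.integer(h), as.integer(b))
    h <- (as.double(h) * 16777619) %% 2147483648
  }
  h <- (h + (as.double(root_seed) %% 2147483647) * 2654435761) %% 2147483647
  as.integer(h)
}

# Evaluate `expr` under a fixed seed, restoring the caller's RNG state.
# seed = NULL uses (and advances) the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}
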