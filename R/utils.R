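#' Derive a reproducible child seed from a global seed and a stage name
#'
#' Every stochastic stage of the pipeline draws its own seed from the single
#' global seed in the configuration, keyed by a stage label, so that stages
#' are individually reproducible and inserting a new stage does not perturb
#' the random streams of the others.
#'
#' @param seed Integer global seed.
#' @param stage Character scalar naming the stage (e.g. `"split"`,
#'   `"gsea:half1:lnc0001"`).
#' @return An integer in `[0, 2^31 - 2]` usable with [set.seed()].
#' @export
#' @examples
#' derive_seed(1L, "split")
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.character(stage), length(stage) == 1L)
  m <- 2147483647 # 2^31 - 1, keeps the polynomial hash exact in doubles
  h <- as.double(seed %% m)
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% m
  as.integer(h)
}

# internal: stop() with call. = FALSE everywhere for clean user-facing errors
.fail <- function(...) stop(..., call. = FALSE)

# internal: check a probability-like scalar
.check_frac <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi)
    .fail(sprintf("'%s' must be a single number in [%g, %g]", name, lo, hi))
  invisible(x)
}

# internal: deterministic TSV writer (fixed column order, no quoting)
.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

.read_tsv <- function(path, ...) {
  utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}
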