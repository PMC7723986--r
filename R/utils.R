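#' @importFrom stats cor optimize p.adjust pt rbinom rnbinom rnorm rpois runif
#'   setNames quantile sd var dnbinom dbinom phyper dhyper
#' @importFrom utils read.delim write.table head tail
NULL

# Deterministic per-stage seed derived from the master seed, so that adding a
# generator stage never perturbs the draws of earlier stages.  Plain
# polynomial string hash folded into [0, 2^31 - 2].
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.double(seed %% m)
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% m
  as.integer(h)
}

# Evaluate expr with a temporary RNG state seeded from (seed, stage); the
# caller's RNG state is untouched.
with_stage_seed <- function(seed, stage, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(stage_seed(seed, stage))
  expr
}

logsumexp <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Deterministic TSV writers: fixed column order, no quoting surprises,
# "." decimal, \n line endings -- byte-identical across runs.
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
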