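# Internal helpers shared across pipeline stages.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Benjamini-Hochberg adjusted p-values
#'
#' Thin wrapper over [stats::p.adjust()] with `method = "BH"`, kept as a named
#' surface so every stage adjusts p-values the same way.
#'
#' @param p numeric vector of p-values.
#' @return numeric vector of FDR-adjusted p-values.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

# Deterministic child seed derived from a user seed and a stream label; keeps
# every stochastic stage independently reproducible under one master seed.
child_seed <- function(seed, stream) {
  u <- utf8ToInt(stream)
  h <- sum(u * seq_along(u)) %% 104729
  # double arithmetic: products stay exact below 2^53, result below 2^31
  as.integer((as.numeric(seed) * 1009 + h * 97) %% 2147483000)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
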