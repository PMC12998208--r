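# Internal helpers shared across modules.

# Run an expression with a locally-set RNG seed, restoring the caller's
# RNG state afterwards so library code never perturbs user simulations.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a reproducible 31-bit sub-seed from a parent seed and an index,
# so per-analyte / per-replicate streams are decoupled but deterministic.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 16807) %% 2147483647)
}

# Weighted mean and weighted (population) SD.
wtd_mean <- function(x, w) sum(w * x) / sum(w)
wtd_sd <- function(x, w) {
  m <- wtd_mean(x, w)
  sqrt(sum(w * (x - m)^2) / sum(w))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_pfasmix <- function(..., class = "pfasmix_error") {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}
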