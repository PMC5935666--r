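`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr with a temporary RNG state; NULL seed leaves the global
# stream untouched (still consumed).
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

# Polynomial rolling hash over the deparsed object; cheap provenance
# fingerprint (not cryptographic).
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# Robust noise floor from first differences; immune to smooth signal.
noise_from_diff <- function(intensity) {
  stats::mad(diff(intensity)) / sqrt(2)
}
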