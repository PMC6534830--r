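# Small shared utilities.

# Deterministic 31-bit seed derived from arbitrary components (integers or
# strings). Keeps every derived seed in [1, 2^31 - 2] so it is always a valid
# R RNG seed.
derive_seed <- function(...) {
  parts <- unlist(lapply(list(...), as.character))
  # multiplier kept small enough that acc * mult stays below 2^53, so the
  # modular arithmetic is exact in double precision
  acc <- 12345
  for (p in parts) {
    for (code in utf8ToInt(p)) {
      acc <- (acc * 69069 + code) %% 2147483647
    }
    acc <- (acc * 31 + 7) %% 2147483647
  }
  as.integer(max(1, acc))
}

# Evaluate an expression with a local RNG seed, restoring global RNG state.
with_rng <- function(seed, expr) {
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
  expr
}

msg <- function(fmt, ..., verbose = getOption("molprep.verbose", FALSE)) {
  if (isTRUE(verbose)) message(sprintf(fmt, ...))
  invisible(NULL)
}
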