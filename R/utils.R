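# Small internal helpers.

# Run `expr` under a private RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards.  All stochastic functions in the package
# take an explicit seed and route through this.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(
        rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a per-stage child seed from a root seed, kept inside 32-bit range.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 7919 + 104729 * as.double(k)) %% 2147483647)
}

check_dna <- function(x, what = "sequence", allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    stop(what, " contains characters outside ",
         if (allow_n) "{A,C,G,T,N}" else "{A,C,G,T}")
  }
  invisible(x)
}

# Sentinel used by yn00-style tools for Ka/Ks when Ks = 0 and Ka > 0.
RATIO_SENTINEL <- 99

`%||%` <- function(a, b) if (is.null(a)) b else a
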