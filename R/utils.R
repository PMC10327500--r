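# Internal helpers shared across modules.

# Classed error so callers can distinguish failure modes programmatically.
# All conditions also carry the umbrella class "plasmidhost_error".
ph_stop <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "plasmidhost_error")))
}

# Reverse complement of an ACGTN character string.
revcomp_string <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Evaluate `code` under a fixed RNG seed, then restore the caller's RNG
# state, so seeded generators compose without clobbering the session.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
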