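## Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
## The expression is lazily evaluated in the calling frame, so assignments
## made inside the block land in the caller.
withr_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

## integer Phred scores of a QualityScaledDNAStringSet, as a plain list
phredScores <- function(reads) {
  as.list(methods::as(Biostrings::quality(reads), "IntegerList"))
}
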