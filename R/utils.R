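## Evaluate `expr` under a fixed RNG seed without disturbing the caller's
## random stream.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Stable cross-platform ordering of file names: zero-pad every digit run so
## "s2" sorts before "s10", then order lexicographically (C collation via
## method = "radix").
naturalOrder <- function(x) {
  key <- vapply(x, .padDigits, character(1), USE.NAMES = FALSE)
  order(key, method = "radix")
}

.padDigits <- function(s) {
  m <- gregexpr("[0-9]+", s)
  runs <- regmatches(s, m)[[1]]
  if (length(runs) == 0) return(s)
  regmatches(s, m) <- list(sprintf("%020.0f", as.numeric(runs)))
  s
}
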