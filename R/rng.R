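## Deterministic per-operation RNG substreams.
##
## One top-level seed drives the whole pipeline; each operation derives its
## own substream seed from (seed, tag) so stages can be re-run independently
## and still reproduce bit-identically.  The mix is a small multiplicative
## hash kept exact in double arithmetic and below 2^31 - 1.

substream_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647  # 2^31 - 1
  h <- (abs(seed) %% m)
  for (b in utf8ToInt(as.character(tag))) {
    h <- (h * 131 + b) %% m
  }
  as.integer(h)
}

with_substream <- function(seed, tag, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(substream_seed(seed, tag))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}
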