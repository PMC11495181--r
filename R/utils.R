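# Internal helpers shared across modules.

# Evaluate expr with a local RNG state seeded by `seed`, restoring the
# caller's .Random.seed afterwards. Used so that per-neuron generator
# streams do not perturb each other or the caller.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic 31-bit stream seed from a base seed and a string key.
# Keeps generated streams stable when unrelated entities are added.
streamSeed <- function(seed, key) {
  h <- 0
  for (cc in utf8ToInt(paste0(key))) h <- (h * 131 + cc) %% 1977326743
  as.integer((as.numeric(seed) * 7919 + h + 1) %% 2147483647)
}

# Centred moving average with width in samples (odd forced); edges padded
# by repeating the first/last value so the output has the input length.
movingAverage <- function(x, width) {
  width <- max(1L, as.integer(width))
  if (width %% 2L == 0L) width <- width + 1L
  if (width == 1L || length(x) < width) return(x)
  half <- (width - 1L) %/% 2L
  xp <- c(rep(x[1], half), x, rep(x[length(x)], half))
  as.numeric(stats::filter(xp, rep(1 / width, width), sides = 2))[
    (half + 1L):(half + length(x))]
}

# Runs of TRUE in a logical vector -> data.frame(start, end) of indices.
trueRuns <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
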