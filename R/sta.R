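# Core STA: mean of signal samples at sample-spaced lags around trigger
# indices. Triggers without full window coverage are excluded.
staCore <- function(x, fs, start, triggers, half) {
  idx0 <- round((triggers - start) * fs) + 1L
  ok <- idx0 - half >= 1L & idx0 + half <= length(x)
  idx0 <- idx0[ok]
  if (!length(idx0))
    return(list(trace = NULL, n = 0L, excluded = sum(!ok)))
  trace <- vapply(-half:half, function(k) sum(x[idx0 + k]), numeric(1)) /
    length(idx0)
  list(trace = trace, n = length(idx0), excluded = sum(!ok))
}

#' Spike-triggered average of a (rectified) continuous signal
#'
#' Averages the signal around every trigger spike. With `rectify = TRUE`
#' the signal is full-wave rectified about its baseline first
#' (`|x - median(x)|`), as is conventional for nerve recordings with a
#' DC offset. Triggers whose window extends beyond the signal are
#' excluded and counted.
#'
#' @param signal a [ContinuousSignal-class] spanning the triggers.
#' @param trigger a [SpikeTrain-class].
#' @param window half-window (s); lags span `[-window, +window]` at the
#'   signal's sample spacing.
#' @param rectify full-wave rectify about the median baseline first.
#' @return a [SpikeTriggeredAverage-class].
#' @export
spikeTriggeredAverage <- function(signal, trigger, window = 0.1,
                                  rectify = TRUE) {
  x <- signal@samples
  if (rectify) x <- abs(x - stats::median(x))
  half <- as.integer(round(window * signal@fs))
  res <- staCore(x, signal@fs, signal@start, trigger@times, half)
  if (res$n == 0L)
    stop("no trigger of ", trigger@neuronId,
         " has full window coverage in signal ", signal@name)
  new("SpikeTriggeredAverage", triggerId = trigger@neuronId,
      signalName = signal@name, lags = (-half:half) / signal@fs,
      meanTrace = res$trace, nTriggers = res$n,
      nExcluded = res$excluded)
}

#' Detect significant features in a spike-triggered average
#'
#' Surrogate STAs are built by triggering on gamma-ISI surrogate trains
#' (rate- and dispersion-matched but uncorrelated with the signal);
#' candidate features are runs of at least 2 consecutive lags outside the
#' pointwise 2.5/97.5 percentile band after subtracting a running-median
#' background (which removes slow respiratory co-modulation), with a
#' max-statistic Monte Carlo p-value and a detectability index from
#' out-of-feature residuals, as for correlograms. A significant offset
#' peak at positive lag carries a `premotor` flag; a significant offset
#' trough at positive lag carries an `inhibitory` flag.
#'
#' @param sta a [SpikeTriggeredAverage-class].
#' @param signal,trigger the inputs used to compute it.
#' @param config an [analysisConfig()] list (`di_threshold`,
#'   `alpha_cth` as the significance level, `sta_n_surrogates` via
#'   `n_surrogates`, capped at 200 for cost).
#' @param n_surrogates surrogate count override.
#' @param rectify must match the original computation.
#' @param seed integer seed.
#' @return the STA with surrogate bands and a `features` data.frame
#'   (`kind`, `position`, `extremum_lag`, `lag_lo`, `lag_hi`, `di`,
#'   `p_mc`, `significant`, `premotor`, `inhibitory`).
#' @export
detectStaFeatures <- function(sta, signal, trigger, config = NULL,
                              n_surrogates = NULL, rectify = TRUE,
                              seed = NULL) {
  cfg <- asConfig(config)
  if (is.null(n_surrogates))
    n_surrogates <- min(cfg$n_surrogates, 200L)
  if (is.null(seed))
    seed <- streamSeed(cfg$rng_seed, paste0(sta@triggerId, "sta"))
  x <- signal@samples
  if (rectify) x <- abs(x - stats::median(x))
  half <- (length(sta@lags) - 1L) %/% 2L
  fit <- fitGammaSurrogates(trigger, n_surrogates, seed)
  S <- matrix(NA_real_, n_surrogates, 2L * half + 1L)
  for (s in seq_len(n_surrogates)) {
    r <- staCore(x, signal@fs, signal@start, fit$surrogates[[s]], half)
    S[s, ] <- if (is.null(r$trace)) 0 else r$trace
  }
  bg_k <- round(half / 2) * 2 + 1             # background window ~ half the STA
  detr <- function(v) v - stats::runmed(v, bg_k)
  obsD <- detr(sta@meanTrace)
  Sd <- t(apply(S, 1, detr))
  mu <- colMeans(Sd)
  lo <- apply(Sd, 2, stats::quantile, probs = 0.025, names = FALSE)
  hi <- apply(Sd, 2, stats::quantile, probs = 0.975, names = FALSE)
  bgTrend <- sta@meanTrace - obsD
  sta@surrogateMean <- bgTrend + mu
  sta@surrogateLo <- bgTrend + lo
  sta@surrogateHi <- bgTrend + hi

  d <- obsD - mu
  dep <- sweep(Sd, 2, mu)
  maxPos <- apply(dep, 1, max)
  maxNeg <- apply(-dep, 1, max)
  runsWithSign <- function(flag, sgn) {
    r <- trueRuns(flag); r$sign <- rep(sgn, nrow(r)); r
  }
  cand <- rbind(runsWithSign(obsD > hi, 1), runsWithSign(obsD < lo, -1))
  cand <- cand[cand$end - cand$start >= 1L, , drop = FALSE]
  feats <- data.frame(kind = character(0), position = character(0),
                      extremum_lag = numeric(0), lag_lo = numeric(0),
                      lag_hi = numeric(0), di = numeric(0),
                      p_mc = numeric(0), significant = logical(0),
                      premotor = logical(0), inhibitory = logical(0),
                      stringsAsFactors = FALSE)
  inExt <- rep(FALSE, length(d))
  for (i in seq_len(nrow(cand))) inExt[cand$start[i]:cand$end[i]] <- TRUE
  noiseSd <- stats::sd(d[!inExt])
  if (!is.finite(noiseSd) || noiseSd == 0) {
    sta@features <- feats
    attr(sta@features, "degenerate") <- "zero STA noise variance"
    return(sta)
  }
  dt <- 1 / signal@fs
  for (i in seq_len(nrow(cand))) {
    idx <- cand$start[i]:cand$end[i]
    sgn <- cand$sign[i]
    depv <- sgn * d[idx]
    best <- which.max(depv)
    obs <- depv[best]
    surrMax <- if (sgn > 0) maxPos else maxNeg
    p_mc <- (1 + sum(surrMax >= obs)) / (n_surrogates + 1)
    lag_lo <- sta@lags[idx[1]] - dt / 2
    lag_hi <- sta@lags[idx[length(idx)]] + dt / 2
    pos <- if (lag_lo <= 0 && lag_hi >= 0) "central" else "offset"
    di <- obs / noiseSd
    sig <- (p_mc <= cfg$alpha_cth) && (di >= cfg$di_threshold)
    elag <- sta@lags[idx[best]]
    feats <- rbind(feats, data.frame(
      kind = if (sgn > 0) "peak" else "trough", position = pos,
      extremum_lag = elag, lag_lo = lag_lo, lag_hi = lag_hi, di = di,
      p_mc = p_mc, significant = sig,
      premotor = sig && pos == "offset" && sgn > 0 && elag > 0,
      inhibitory = sig && pos == "offset" && sgn < 0 && elag > 0,
      stringsAsFactors = FALSE))
  }
  sta@features <- feats
  sta
}
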