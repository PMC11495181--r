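#' Cross-correlogram of two spike trains
#'
#' Counts target spikes at signed lags relative to every reference spike:
#' `counts[b] = #{(i, j): target_j - ref_i` in bin `b}` with half-open bins
#' centred at integer multiples of `bin_width`. A positive lag means the
#' target spike follows the reference spike. The rate normalization is
#' `counts / (n_ref * bin_width)` in spikes/s.
#'
#' @param ref,target [SpikeTrain-class] objects (both non-empty).
#' @param bin_width bin width in seconds (default 0.5 ms).
#' @param window half-window in seconds; lags span `[-window, +window]`.
#' @return a [Correlogram-class] (surrogate bands and features empty until
#'   [detectFeatures()] is run).
#' @examples
#' a <- spikeTrain("a", c(1.0), c(0, 2))
#' b <- spikeTrain("b", c(1.002), c(0, 2))
#' computeCorrelogram(a, b)  # single count at lag +2 ms
#' @export
computeCorrelogram <- function(ref, target, bin_width = 0.0005,
                               window = 0.05) {
  if (!length(ref@times))
    stop("empty reference train: ", ref@neuronId)
  if (!length(target@times))
    stop("empty target train: ", target@neuronId)
  nhalf <- as.integer(round(window / bin_width))
  counts <- .corrCounts(ref@times, target@times, bin_width, nhalf)
  lags <- (-nhalf:nhalf) * bin_width
  new("Correlogram", refId = ref@neuronId, targetId = target@neuronId,
      binWidth = bin_width, lags = lags, counts = counts,
      rate = counts / (length(ref@times) * bin_width),
      nRef = length(ref@times))
}

#' Gamma ISI model and surrogate spike trains
#'
#' Estimates the shape parameter of a gamma interspike-interval (ISI)
#' distribution from the data by the method of moments,
#' `k = mean(ISI)^2 / var(ISI)` (clipped to `[0.05, 100]`; a Poisson train
#' has `k = 1`), and generates surrogate trains with i.i.d. gamma ISIs of
#' the same overall mean, laid end-to-end from the original first spike
#' time and truncated at the interval end. Surrogates preserve each
#' train's rate and ISI dispersion while destroying all correlation
#' structure.
#'
#' The shape is fitted on pause-excluded ISIs (those not exceeding 10
#' times the median ISI): for phasic respiratory and burst-firing cells
#' the silent-phase pauses otherwise dominate the variance and drive the
#' fit to absurd overdispersion, misrepresenting the within-activity
#' renewal process the surrogate is meant to emulate. For a stationary
#' train the exclusion is negligible (0.1% of exponential ISIs). The
#' scale uses the mean of all ISIs, so the surrogate rate matches the
#' recorded rate.
#'
#' @param train a [SpikeTrain-class] with at least 2 spikes.
#' @param n_surrogates number of surrogate trains to generate (0 for the
#'   fit only).
#' @param seed integer seed (reproducible surrogates).
#' @return list with `shape`, `scale`, `mean_isi`, and `surrogates` (a
#'   list of numeric spike-time vectors).
#' @export
fitGammaSurrogates <- function(train, n_surrogates = 0L, seed = 1L) {
  isi <- diff(train@times)
  if (length(isi) < 1L)
    stop("need at least 2 spikes to fit ISIs: ", train@neuronId)
  if (length(isi) < 50L)
    warning("fewer than 50 ISIs for gamma fit: ", train@neuronId)
  m <- mean(isi)
  core <- isi[isi <= 10 * stats::median(isi)]    # exclude silent-phase pauses
  if (length(core) < 2L) core <- isi
  v <- stats::var(core)
  shape <- if (!is.finite(v) || v <= 0) 100 else mean(core)^2 / v
  shape <- min(100, max(0.05, shape))
  scale <- m / shape
  surr <- list()
  if (n_surrogates > 0L) {
    t_first <- train@times[1]
    t_end <- train@interval[2]
    surr <- withSeed(seed, lapply(seq_len(n_surrogates), function(i)
      .gammaTrain(t_first, t_end, shape, scale)))
  }
  list(shape = shape, scale = scale, mean_isi = m, surrogates = surr)
}

# Remove the slow correlogram background with a running median. Neurons
# sharing the respiratory rhythm co-modulate over hundreds of
# milliseconds, which raises (or tilts) the whole +/-50 ms correlogram
# relative to an ISI-surrogate null; features of interest are
# millisecond-scale departures FROM that background, so both the
# observed and every surrogate correlogram are detrended identically
# before band construction and departure measurement.
detrendCounts <- function(v, k) .detrendVec(as.numeric(v), as.integer(k))

# Band statistics from a surrogate count matrix (n_surr x nbins):
# detrended per-bin mean and 2.5/97.5 percentiles, and per-surrogate
# signed max departures for the max-statistic p-value.
bandsFromSurrogates <- function(S, k) {
  sb <- .surrogateBandStats(S, as.integer(k))
  sb$k <- k
  sb
}

# Build the surrogate count matrix for a pair by fresh gamma-ISI draws.
surrogateBands <- function(ref, target, bin_width, nhalf, n_surr, seed,
                           background_width) {
  fr <- suppressWarnings(fitGammaSurrogates(ref))
  ft <- suppressWarnings(fitGammaSurrogates(target))
  S <- withSeed(seed, .surrogateCorrCounts(
    ref@times[1], ref@interval[2], fr$shape, fr$scale,
    target@times[1], target@interval[2], ft$shape, ft$scale,
    n_surr, bin_width, nhalf))
  k <- round(background_width / bin_width / 2) * 2 + 1
  bandsFromSurrogates(S, k)
}

#' Detect significant peak and trough features in a correlogram
#'
#' Surrogate correlograms are built from `n_surrogates` independent
#' gamma-ISI surrogate pairs; the per-bin 2.5/97.5 percentiles form a
#' pointwise null band. A candidate feature is a maximal run of at least 2
#' consecutive bins outside the band on the same side. The detectability
#' index (DI) is the extremum departure divided by the standard deviation
#' of the observed residuals over bins outside all candidate extents
#' ("correlogram noise"). The feature's Monte Carlo p-value compares its
#' DI with each surrogate's own maximum studentized departure over all
#' bins in that sign — a max-statistic correction within the pair;
#' studentizing both sides keeps the test calibrated when cycle-locked
#' co-modulation overdisperses the observed correlogram relative to the
#' renewal surrogates. Features whose
#' extent spans lag 0 are `central` (shared-influence signature); others
#' are `offset` (paucisynaptic excitation/inhibition signature) and are
#' canonicalized to a positive lag by swapping the reference/target roles
#' in the reported `source`/`target` when the extremum lies at negative
#' lag.
#'
#' @param corr a [Correlogram-class] from [computeCorrelogram()].
#' @param ref,target the [SpikeTrain-class] pair the correlogram was
#'   computed from (needed for the ISI fits).
#' @param config an [analysisConfig()] list (uses `n_surrogates`,
#'   `di_threshold`, `fdr_q`).
#' @param seed integer seed for the surrogate draw; defaults to a stream
#'   derived from `config$rng_seed` and the pair ids.
#' @return the correlogram with `surrogateMean`/`surrogateLo`/
#'   `surrogateHi` and a `features` data.frame filled in (columns `kind`,
#'   `position`, `source`, `target`, `extremum_lag`, `lag_lo`, `lag_hi`,
#'   `di`, `p_mc`, `significant`). The provisional `significant` flag uses
#'   `p_mc <= fdr_q`; [screenPairs()] replaces it with the
#'   Benjamini-Hochberg decision across all pairs.
#' @export
detectFeatures <- function(corr, ref, target, config = NULL, seed = NULL) {
  cfg <- asConfig(config)
  if (is.null(seed))
    seed <- streamSeed(cfg$rng_seed,
                       paste(corr@refId, corr@targetId, "xcorr"))
  nhalf <- (length(corr@lags) - 1L) %/% 2L
  sb <- surrogateBands(ref, target, corr@binWidth, nhalf,
                       cfg$n_surrogates, seed, cfg$corr_background)
  featureCore(corr, sb, cfg)
}

# Shared feature extraction given precomputed surrogate band statistics.
featureCore <- function(corr, sb, cfg) {
  n_surr <- length(sb$maxPos)
  obsD <- detrendCounts(as.numeric(corr@counts), sb$k)
  bgTrend <- as.numeric(corr@counts) - obsD
  corr@surrogateMean <- bgTrend + sb$mu
  corr@surrogateLo <- bgTrend + sb$lo
  corr@surrogateHi <- bgTrend + sb$hi

  d <- obsD - sb$mu
  above <- obsD > sb$hi
  below <- obsD < sb$lo
  feats <- emptyFeatures()
  runsWithSign <- function(flag, sgn) {
    r <- trueRuns(flag)
    r$sign <- rep(sgn, nrow(r))
    r
  }
  cand <- rbind(runsWithSign(above, 1), runsWithSign(below, -1))
  cand <- cand[cand$end - cand$start >= 1L, , drop = FALSE]   # >= 2 bins

  # the running-median background is estimated from a truncated window
  # within half a background width of the correlogram edge, so departures
  # peaking there are unreliable; such candidates are discarded
  nbin <- length(obsD)
  margin <- (sb$k - 1L) %/% 2L
  if (nrow(cand)) {
    extremumIn <- function(i) {
      idx <- cand$start[i]:cand$end[i]
      dep <- cand$sign[i] * d[idx]
      idx[which.max(dep)]
    }
    ext <- vapply(seq_len(nrow(cand)), extremumIn, integer(1))
    cand <- cand[ext > margin & ext <= nbin - margin, , drop = FALSE]
  }

  inExtent <- rep(FALSE, length(d))
  for (i in seq_len(nrow(cand)))
    inExtent[cand$start[i]:cand$end[i]] <- TRUE
  noiseSd <- stats::sd(d[!inExtent])
  if (!is.finite(noiseSd) || noiseSd == 0 || all(sb$hi == sb$lo)) {
    corr@features <- feats
    attr(corr@features, "degenerate") <-
      "zero correlogram noise variance; feature detection aborted"
    return(corr)
  }

  bin <- corr@binWidth
  for (i in seq_len(nrow(cand))) {
    idx <- cand$start[i]:cand$end[i]
    sgn <- cand$sign[i]
    dep <- sgn * d[idx]
    best <- which(dep == max(dep))
    if (length(best) > 1L)                       # tie: smallest |lag| wins
      best <- best[which.min(abs(corr@lags[idx][best]))]
    ext_bin <- idx[best]
    obs <- dep[best]
    di <- obs / noiseSd
    # Monte Carlo p-value of the detectability index: the candidate's
    # studentized extremum against each surrogate's own maximum
    # studentized departure (max-statistic correction; studentizing
    # keeps the test calibrated when cycle-locked co-modulation
    # overdisperses the observed correlogram relative to renewal
    # surrogates)
    surrMax <- if (sgn > 0) sb$maxPos else sb$maxNeg
    p_mc <- (1 + sum(surrMax >= di)) / (n_surr + 1)
    lag_lo <- corr@lags[idx[1]] - bin / 2
    lag_hi <- corr@lags[idx[length(idx)]] + bin / 2
    position <- if (lag_lo <= 0 && lag_hi >= 0) "central" else "offset"
    src <- corr@refId; tgt <- corr@targetId
    ext_lag <- corr@lags[ext_bin]
    if (position == "offset" && ext_lag < 0) {   # canonical positive lag
      src <- corr@targetId; tgt <- corr@refId
      ext_lag <- -ext_lag
      tmp <- lag_lo; lag_lo <- -lag_hi; lag_hi <- -tmp
    }
    feats <- rbind(feats, data.frame(
      kind = if (sgn > 0) "peak" else "trough",
      position = position, source = src, target = tgt,
      extremum_lag = ext_lag, lag_lo = lag_lo, lag_hi = lag_hi,
      di = obs / noiseSd, p_mc = p_mc,
      significant = (obs / noiseSd >= cfg$di_threshold) &
        (p_mc <= cfg$fdr_q),
      stringsAsFactors = FALSE))
  }
  corr@features <- feats
  corr
}

emptyFeatures <- function() {
  data.frame(kind = character(0), position = character(0),
             source = character(0), target = character(0),
             extremum_lag = numeric(0), lag_lo = numeric(0),
             lag_hi = numeric(0), di = numeric(0), p_mc = numeric(0),
             significant = logical(0), stringsAsFactors = FALSE)
}

#' Screen all neuron pairs for functional connectivity
#'
#' Computes a cross-correlogram and its surrogate-based features for every
#' unordered pair of usable trains, pools each pair's evidence as the
#' minimum feature p-value (1 when no candidate feature), applies
#' Benjamini-Hochberg false-discovery-rate control across pairs at
#' `fdr_q`, and keeps a feature as a significant edge only if its pair
#' survives BH and its detectability index is at least `di_threshold`.
#'
#' @param session a [Session-class] with at least 2 trains.
#' @param config an [analysisConfig()] list.
#' @param pairs optional 2-column character matrix/data.frame of neuron-id
#'   pairs to assess (defaults to all unordered pairs).
#' @param keep_correlograms logical; retain the per-pair
#'   [Correlogram-class] objects in the result (memory-heavy for large
#'   populations).
#' @return list with `edges` (one row per significant feature: `source`,
#'   `target`, `sign`, `position`, `extremum_lag_s`, `di`, `p_mc`,
#'   `q_value`, `significant`), `pairs` (per-pair `p`, `q`, `n_features`),
#'   `skipped` (pairs not assessed, with reasons), and optionally
#'   `correlograms`.
#' @export
screenPairs <- function(session, config = NULL, pairs = NULL,
                        keep_correlograms = FALSE) {
  cfg <- asConfig(config)
  trains <- session@trains
  ids <- names(trains)
  usable <- vapply(trains, function(tr) length(tr@times) >= 2L, logical(1))
  skipped <- data.frame(ref = character(0), target = character(0),
                        reason = character(0), stringsAsFactors = FALSE)

  if (is.null(pairs)) {
    if (length(ids) < 2L)
      return(list(edges = emptyEdges(), pairs = emptyPairTable(),
                  skipped = skipped, n_assessed = 0L))
    cmb <- utils::combn(ids, 2L)
    pairs <- data.frame(ref = cmb[1, ], target = cmb[2, ],
                        stringsAsFactors = FALSE)
  } else {
    pairs <- data.frame(ref = as.character(pairs[[1]]),
                        target = as.character(pairs[[2]]),
                        stringsAsFactors = FALSE)
  }

  keep <- rep(TRUE, nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    for (id in c(pairs$ref[i], pairs$target[i]))
      if (!id %in% ids || !usable[[id]]) {
        keep[i] <- FALSE
        skipped <- rbind(skipped, data.frame(
          ref = pairs$ref[i], target = pairs$target[i],
          reason = paste0("unusable train: ", id),
          stringsAsFactors = FALSE))
        break
      }
  }
  pairs <- pairs[keep, , drop = FALSE]

  # per-train surrogate trains are drawn once (seeded by train id) and
  # shared across all pairs the train participates in; they are released
  # once no remaining pair needs them to bound memory
  nhalf <- as.integer(round(cfg$corr_window / cfg$corr_bin_width))
  kbg <- round(cfg$corr_background / cfg$corr_bin_width / 2) * 2 + 1
  usesLeft <- c(table(c(pairs$ref, pairs$target)))
  cache <- new.env(parent = emptyenv())
  getSurr <- function(id) {
    if (!is.null(cache[[id]])) return(cache[[id]])
    tr <- trains[[id]]
    fit <- suppressWarnings(fitGammaSurrogates(tr))
    s <- withSeed(streamSeed(cfg$rng_seed, paste0(id, "/surr")),
                  .gammaTrains(tr@times[1], tr@interval[2], fit$shape,
                               fit$scale, cfg$n_surrogates))
    assign(id, s, envir = cache)
    s
  }
  release <- function(id) {
    usesLeft[[id]] <<- usesLeft[[id]] - 1L
    if (usesLeft[[id]] <= 0L && !is.null(cache[[id]]))
      rm(list = id, envir = cache)
  }

  featList <- vector("list", nrow(pairs))
  corrList <- if (keep_correlograms) vector("list", nrow(pairs)) else NULL
  pvec <- rep(1, nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    r <- trains[[pairs$ref[i]]]
    tg <- trains[[pairs$target[i]]]
    co <- computeCorrelogram(r, tg, cfg$corr_bin_width, cfg$corr_window)
    if (usesLeft[[pairs$ref[i]]] == 1L && usesLeft[[pairs$target[i]]] == 1L) {
      # both trains occur in this pair only: fused generate-and-count
      fr <- suppressWarnings(fitGammaSurrogates(r))
      ft <- suppressWarnings(fitGammaSurrogates(tg))
      sb <- withSeed(
        streamSeed(cfg$rng_seed, paste(pairs$ref[i], pairs$target[i], "surr")),
        .surrogatePairStats(r@times[1], r@interval[2], fr$shape, fr$scale,
                            tg@times[1], tg@interval[2], ft$shape, ft$scale,
                            cfg$n_surrogates, cfg$corr_bin_width, nhalf,
                            as.integer(kbg)))
      sb$k <- kbg
    } else {
      S <- .corrCountsPairList(getSurr(pairs$ref[i]),
                               getSurr(pairs$target[i]),
                               cfg$corr_bin_width, nhalf)
      sb <- bandsFromSurrogates(S, kbg)
    }
    co <- featureCore(co, sb, cfg)
    release(pairs$ref[i]); release(pairs$target[i])
    fe <- co@features
    if (!is.null(attr(fe, "degenerate")))
      skipped <- rbind(skipped, data.frame(
        ref = pairs$ref[i], target = pairs$target[i],
        reason = attr(fe, "degenerate"), stringsAsFactors = FALSE))
    featList[[i]] <- fe
    if (nrow(fe)) pvec[i] <- min(fe$p_mc)
    if (keep_correlograms) corrList[[i]] <- co
  }

  qvec <- stats::p.adjust(pvec, method = "BH")
  pairTab <- data.frame(ref = pairs$ref, target = pairs$target,
                        p = pvec, q = qvec,
                        n_features = vapply(featList, nrow, integer(1)),
                        stringsAsFactors = FALSE)

  # BH threshold: the largest pair p-value that still survives; a
  # feature must itself fall below it (not merely belong to a pair made
  # significant by a stronger sibling feature)
  pStar <- if (any(qvec <= cfg$fdr_q)) max(pvec[qvec <= cfg$fdr_q]) else 0

  edges <- emptyEdges()
  for (i in seq_len(nrow(pairs))) {
    fe <- featList[[i]]
    if (!nrow(fe)) next
    sig <- (qvec[i] <= cfg$fdr_q) & (fe$di >= cfg$di_threshold) &
      (fe$p_mc <= pStar)
    fe$significant <- sig
    if (!any(sig)) next
    fe <- fe[sig, , drop = FALSE]
    edges <- rbind(edges, data.frame(
      source = fe$source, target = fe$target,
      sign = featureSign(fe$kind, fe$position),
      position = fe$position, extremum_lag_s = fe$extremum_lag,
      di = fe$di, p_mc = fe$p_mc, q_value = qvec[i],
      significant = TRUE, stringsAsFactors = FALSE))
  }

  out <- list(edges = edges, pairs = pairTab, skipped = skipped,
              n_assessed = nrow(pairs))
  if (keep_correlograms) out$correlograms <- corrList
  out
}

featureSign <- function(kind, position) {
  ifelse(position == "offset",
         ifelse(kind == "peak", "excitation", "inhibition"),
         ifelse(kind == "peak", "shared_drive", "shared_opposite"))
}

emptyEdges <- function() {
  data.frame(source = character(0), target = character(0),
             sign = character(0), position = character(0),
             extremum_lag_s = numeric(0), di = numeric(0),
             p_mc = numeric(0), q_value = numeric(0),
             significant = logical(0), stringsAsFactors = FALSE)
}

#' Write a correlogram (with bands) or STA to CSV
#'
#' @param x a [Correlogram-class] or [SpikeTriggeredAverage-class].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeCorrelogram <- function(x, path) {
  pad <- function(v, n) if (length(v)) v else rep(NA_real_, n)
  n <- length(x@lags)
  df <- if (is(x, "Correlogram"))
    data.frame(lag_s = x@lags, count = x@counts, rate = x@rate,
               surrogate_mean = pad(x@surrogateMean, n),
               surrogate_lo = pad(x@surrogateLo, n),
               surrogate_hi = pad(x@surrogateHi, n))
  else
    data.frame(lag_s = x@lags, mean = x@meanTrace,
               surrogate_mean = pad(x@surrogateMean, n),
               surrogate_lo = pad(x@surrogateLo, n),
               surrogate_hi = pad(x@surrogateHi, n))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

emptyPairTable <- function() {
  data.frame(ref = character(0), target = character(0), p = numeric(0),
             q = numeric(0), n_features = integer(0),
             stringsAsFactors = FALSE)
}
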