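#' Detect respiratory cycles from the integrated phrenic signal
#'
#' Inspiratory onsets are upward crossings of a threshold on a smoothed
#' copy of the signal (moving average, `smooth_width`), expiratory onsets
#' the subsequent downward crossings of a lower threshold (hysteresis).
#' Thresholds derive from the control window: with baseline `b` (10th
#' percentile) and peak `p` (99.5th percentile),
#' `theta_on = b + k_on (p - b)` and `theta_off = b + k_off (p - b)`.
#'
#' @param phrenic a [ContinuousSignal-class] covering the analysis
#'   window.
#' @param control_window `c(t0, t1)` used to derive thresholds.
#' @param config an [analysisConfig()] list.
#' @return data.frame of complete cycles (`i_onset`, `e_onset`,
#'   `cycle_end`), each satisfying `i_onset < e_onset < cycle_end`; for a
#'   flat signal an empty frame with `attr(, "warning")` set (no error).
#'   `attr(, "bursts")` holds every detected burst (including the final,
#'   cycle-incomplete one) with its smoothed peak and peak time.
#' @export
detectCycles <- function(phrenic, control_window = NULL, config = NULL) {
  cfg <- asConfig(config)
  fs <- phrenic@fs
  tt <- signalTimes(phrenic)
  sm <- movingAverage(phrenic@samples, cfg$smooth_width * fs)
  ctl <- if (is.null(control_window)) sm
         else sm[tt >= control_window[1] & tt < control_window[2]]
  b <- stats::quantile(ctl, 0.10, names = FALSE)
  p <- stats::quantile(ctl, 0.995, names = FALSE)
  empty <- data.frame(i_onset = numeric(0), e_onset = numeric(0),
                      cycle_end = numeric(0))
  if (!is.finite(p - b) || p - b <= max(1e-12, 0.05 * max(abs(ctl), 1e-12))) {
    attr(empty, "warning") <- "flat signal: no cycles detected"
    return(empty)
  }
  thOn <- b + cfg$k_on * (p - b)
  thOff <- b + cfg$k_off * (p - b)

  up <- which(diff(sm >= thOn) == 1L) + 1L
  dn <- which(diff(sm >= thOff) == -1L) + 1L
  ev <- rbind(data.frame(i = up, type = 1L), data.frame(i = dn, type = 0L))
  ev <- ev[order(ev$i), ]
  state <- 0L
  i_on <- integer(0); e_on <- integer(0)
  for (k in seq_len(nrow(ev))) {
    if (ev$type[k] == 1L && state == 0L) {
      i_on <- c(i_on, ev$i[k]); state <- 1L
    } else if (ev$type[k] == 0L && state == 1L) {
      e_on <- c(e_on, ev$i[k]); state <- 0L
    }
  }
  n <- min(length(i_on), length(e_on))
  if (n == 0L) {
    attr(empty, "warning") <- "no complete burst detected"
    return(empty)
  }
  i_on <- i_on[seq_len(n)]; e_on <- e_on[seq_len(n)]
  peak <- t_peak <- numeric(n)
  for (k in seq_len(n)) {
    seg <- i_on[k]:e_on[k]
    peak[k] <- max(sm[seg])
    t_peak[k] <- tt[seg[which.max(sm[seg])]]
  }
  bursts <- data.frame(i_onset = tt[i_on], e_onset = tt[e_on],
                       peak = peak, t_peak = t_peak)
  cycles <- if (n >= 2L)
    data.frame(i_onset = bursts$i_onset[-n], e_onset = bursts$e_onset[-n],
               cycle_end = bursts$i_onset[-1L])
  else empty
  attr(cycles, "bursts") <- bursts
  attr(cycles, "thresholds") <- c(on = thOn, off = thOff, baseline = b,
                                  peak = p)
  cycles
}

# Control-window per-cycle statistics shared by the epoch classifier.
controlCycleStats <- function(bursts, cycles, control_window) {
  inCtl <- cycles$i_onset >= control_window[1] &
    cycles$cycle_end <= control_window[2]
  if (sum(inCtl) < 10L)
    stop("control window contains fewer than 10 cycles (",
         sum(inCtl), ")")
  cyc <- cycles[inCtl, ]
  idur <- cyc$e_onset - cyc$i_onset
  cdur <- cyc$cycle_end - cyc$i_onset
  pk <- bursts$peak[match(cyc$i_onset, bursts$i_onset)]
  list(peak_mean = mean(pk), peak_sd = stats::sd(pk),
       peak_median = stats::median(pk),
       freq_mean = mean(1 / cdur), freq_sd = stats::sd(1 / cdur),
       i_median = stats::median(idur), cycle_median = stats::median(cdur),
       n = sum(inCtl))
}

# Full segmentation engine: burst labels, epochs, sigh and gasp events.
segmentMotorPattern <- function(phrenic, cycles, control_window, cfg) {
  bursts <- attr(cycles, "bursts")
  if (is.null(bursts) || !nrow(bursts))
    return(list(epochs = data.frame(t0 = numeric(0), t1 = numeric(0),
                                    class = character(0)),
                events = data.frame(kind = character(0), time = numeric(0),
                                    magnitude = numeric(0)),
                stats = NULL))
  st <- controlCycleStats(bursts, cycles, control_window)
  nb <- nrow(bursts)
  idur <- bursts$e_onset - bursts$i_onset
  cdur <- c(diff(bursts$i_onset), NA)
  riseFrac <- (bursts$t_peak - bursts$i_onset) / pmax(idur, 1e-9)

  apneustic <- idur > cfg$a_apneusis * st$i_median
  augmented <- bursts$peak > st$peak_mean + cfg$z_augment * st$peak_sd
  augmented <- augmented |
    (!is.na(cdur) & 1 / cdur > st$freq_mean + cfg$z_augment * st$freq_sd)
  gaspShape <- riseFrac < cfg$f_gasp & idur < st$i_median

  # sighs: isolated augmented bursts late in inspiration, judged against
  # neighbouring bursts so epoch-wide amplitude gains do not register
  localMed <- vapply(seq_len(nb), function(k) {
    nb_idx <- setdiff(max(1L, k - 3L):min(nb, k + 3L), k)
    if (length(nb_idx) >= 3L) stats::median(bursts$peak[nb_idx])
    else st$peak_median
  }, numeric(1))
  sigh <- bursts$peak > cfg$s_sigh * localMed & riseFrac > 0.5 & !gaspShape

  t_apnea <- max(2 * st$cycle_median, cfg$t_apnea_floor)
  gapAfter <- c(bursts$i_onset[-1L] - bursts$e_onset[-nb], 0)

  # gasp eligibility: after the first apnea-length silence, until normal
  # (non-gasp-shaped) breathing has resumed for 3 bursts
  label <- rep("normal", nb)
  eligible <- FALSE
  failRun <- 0L
  for (k in seq_len(nb)) {
    if (k > 1L && (bursts$i_onset[k] - bursts$e_onset[k - 1L]) > t_apnea)
      eligible <- TRUE
    if (eligible && gaspShape[k]) {
      label[k] <- "gasp"
      failRun <- 0L
    } else if (eligible) {
      failRun <- failRun + 1L
      if (failRun >= 3L) eligible <- FALSE
    }
  }
  label[label != "gasp" & apneustic] <- "depression_apneusis"
  isAug <- label == "normal" & augmented
  augRuns <- trueRuns(isAug)
  for (r in seq_len(nrow(augRuns)))
    if (augRuns$end[r] - augRuns$start[r] + 1L >= cfg$n_consec)
      label[augRuns$start[r]:augRuns$end[r]] <- "augmentation"
  label[label == "gasp"] <- "gasping"

  # assemble epochs: runs of equal labels anchored at burst onsets, with
  # apnea epochs inserted at over-threshold silences; normal runs become
  # control before the first disturbance and recovery after
  segStart <- which(c(TRUE, label[-1L] != label[-nb] |
                        gapAfter[-nb] > t_apnea))
  epochs <- data.frame(t0 = numeric(0), t1 = numeric(0),
                       class = character(0), stringsAsFactors = FALSE)
  firstDisturb <- which(label != "normal")[1]
  for (si in seq_along(segStart)) {
    k0 <- segStart[si]
    k1 <- if (si < length(segStart)) segStart[si + 1L] - 1L else nb
    cls <- label[k0]
    if (cls == "normal")
      cls <- if (!is.na(firstDisturb) && k0 > firstDisturb) "recovery"
             else "control"
    epochs <- rbind(epochs, data.frame(
      t0 = bursts$i_onset[k0], t1 = bursts$e_onset[k1], class = cls,
      stringsAsFactors = FALSE))
    # an over-threshold silence is an apnea epoch unless it merely
    # separates two gasps of one quasiperiodic gasping episode
    if (gapAfter[k1] > t_apnea && k1 < nb &&
        !(label[k1] == "gasping" && label[k1 + 1L] == "gasping"))
      epochs <- rbind(epochs, data.frame(
        t0 = bursts$e_onset[k1], t1 = bursts$i_onset[k1 + 1L],
        class = "apnea", stringsAsFactors = FALSE))
  }
  # merge consecutive epochs of the same class, then tile: each epoch
  # extends to the start of the next
  keep <- c(TRUE, epochs$class[-1L] != epochs$class[-nrow(epochs)])
  epochs <- epochs[keep, , drop = FALSE]
  tt <- signalTimes(phrenic)
  if (nrow(epochs)) {
    epochs$t1 <- c(epochs$t0[-1L], tt[length(tt)])
    epochs$t0[1] <- tt[1]
  }
  rownames(epochs) <- NULL

  events <- rbind(
    data.frame(kind = rep("sigh", sum(sigh)), time = bursts$t_peak[sigh],
               magnitude = bursts$peak[sigh]),
    data.frame(kind = rep("gasp", sum(label == "gasping")),
               time = bursts$i_onset[label == "gasping"],
               magnitude = bursts$peak[label == "gasping"]))
  events <- events[order(events$time), ]
  rownames(events) <- NULL
  list(epochs = epochs, events = events, labels = label, stats = st)
}

#' Label motor-pattern epochs and detect sigh events
#'
#' Per-cycle features (smoothed peak amplitude, inspiratory duration,
#' cycle duration) are compared with control-window statistics:
#' augmentation is at least `n_consec` consecutive cycles whose amplitude
#' or frequency exceeds the control mean by `z_augment` standard
#' deviations; apneusis is an inspiratory duration beyond `a_apneusis`
#' times the control median; a sigh (augmented burst) is an isolated
#' late-inspiratory peak beyond `s_sigh` times its neighbours' median;
#' apnea is a silence longer than `max(2 * control median cycle,
#' t_apnea_floor)`; gasping is a run of decrementing short bursts
#' during/after apnea; normal cycles before the first disturbance are
#' control, after it recovery. Epoch labels tile the analyzed window.
#'
#' @param phrenic a [ContinuousSignal-class].
#' @param cycles output of [detectCycles()].
#' @param control_window `c(t0, t1)` containing at least 10 cycles.
#' @param config an [analysisConfig()] list.
#' @return list with `epochs` (data.frame `t0`, `t1`, `class`), `events`
#'   (data.frame `kind`, `time`, `magnitude`; sighs and gasps), `labels`
#'   (per-burst) and `stats` (control statistics).
#' @export
classifyEpochs <- function(phrenic, cycles, control_window, config = NULL) {
  segmentMotorPattern(phrenic, cycles, control_window, asConfig(config))
}

#' Detect gasps
#'
#' A burst is a gasp iff it occurs during or after a hypoxic apnea, its
#' time-to-peak is less than `f_gasp` of the burst duration (decrementing
#' shape) and its duration is below the control median inspiratory
#' duration. Returns event onset times.
#'
#' @param phrenic a [ContinuousSignal-class].
#' @param segmentation output of [classifyEpochs()]; alternatively pass
#'   `cycles` and `control_window` to segment internally.
#' @param cycles,control_window,config see [classifyEpochs()].
#' @return data.frame of gasp events (`kind`, `time`, `magnitude`).
#' @export
detectGasps <- function(phrenic, segmentation = NULL, cycles = NULL,
                        control_window = NULL, config = NULL) {
  if (is.null(segmentation)) {
    if (is.null(cycles))
      cycles <- detectCycles(phrenic, control_window, config)
    segmentation <- classifyEpochs(phrenic, cycles, control_window, config)
  }
  ev <- segmentation$events
  ev[ev$kind == "gasp", , drop = FALSE]
}

#' Detect blood-pressure steps and gasp-synchronous neurons
#'
#' A blood-pressure step is a sustained rise of at least `bp_step_height`
#' mmHg achieved within `bp_step_window` seconds on a median-filtered
#' trace. The coincidence count is the number of gasps with a step within
#' 2 s. A neuron is gasp-synchronous iff its firing rate within
#' `sync_halfwidth` of at least half of the gasp onsets exceeds `q_sync`
#' times its session-median rate (median of 1-s binned rates); the table
#' reports each synchronous neuron's control pattern class when CTH
#' classifications are supplied, reproducing the observation that many
#' gasp-recruited cells are not inspiratory during control.
#'
#' @param bp blood-pressure [ContinuousSignal-class].
#' @param gasps gasp events (data.frame with `time`), e.g. from
#'   [detectGasps()].
#' @param trains list of [SpikeTrain-class] objects.
#' @param classes optional data.frame from [classifyAllNeurons()] with
#'   `neuron_id`, `modulation`, `subtype`, `tonicity`.
#' @param config an [analysisConfig()] list.
#' @return list with `bp_steps` (events data.frame), `sync_table`
#'   (synchronous neurons only: `neuron_id`, `frac_gasps`,
#'   `control_class`) and `coincidence_count`.
#' @export
detectBpStepsAndSync <- function(bp, gasps, trains, classes = NULL,
                                 config = NULL) {
  cfg <- asConfig(config)
  fs <- bp@fs
  k <- round(0.5 * fs); if (k %% 2 == 0) k <- k + 1
  med <- stats::runmed(bp@samples, k)
  tt <- signalTimes(bp)
  L <- round(cfg$bp_step_window * fs)
  n <- length(med)
  rise <- med[pmin(seq_len(n) + L, n)] - med
  runs <- trueRuns(rise > cfg$bp_step_height)
  stepT <- numeric(0)
  for (r in seq_len(nrow(runs))) {
    idx <- runs$start[r]:runs$end[r]
    stepT <- c(stepT, tt[idx[which.max(rise[idx])]] + cfg$bp_step_window / 2)
  }
  if (length(stepT) > 1L) {                  # merge near-duplicate events
    keep <- c(TRUE, diff(stepT) > cfg$bp_step_window)
    stepT <- stepT[keep]
  }
  bp_steps <- data.frame(kind = rep("bp_step", length(stepT)),
                         time = stepT,
                         magnitude = rep(cfg$bp_step_height, length(stepT)))

  gaspT <- gasps$time
  coincidence <- if (length(gaspT) && length(stepT))
    sum(vapply(gaspT, function(g) any(abs(stepT - g) <= 2), logical(1)))
  else 0L

  sync <- data.frame(neuron_id = character(0), frac_gasps = numeric(0),
                     control_class = character(0), stringsAsFactors = FALSE)
  if (length(gaspT)) {
    hw <- cfg$sync_halfwidth
    for (tr in trains) {
      iv <- tr@interval
      brk <- seq(iv[1], iv[2], by = 1)
      rates <- graphics::hist(tr@times, breaks = brk, plot = FALSE)$counts
      medRate <- stats::median(rates)
      rg <- vapply(gaspT, function(g)
        sum(tr@times >= g - hw & tr@times <= g + hw) / (2 * hw), numeric(1))
      frac <- mean(rg > cfg$q_sync * medRate)
      if (frac >= 0.5) {
        cls <- "unclassified"
        if (!is.null(classes)) {
          row <- classes[classes$neuron_id == tr@neuronId, ]
          if (nrow(row))
            cls <- if (row$modulation[1] == "NRM") "not respiratory-modulated"
                   else paste0(row$modulation[1],
                               ifelse(row$subtype[1] %in% c("Aug", "Dec"),
                                      paste0("-", row$subtype[1]), ""))
        }
        sync <- rbind(sync, data.frame(neuron_id = tr@neuronId,
                                       frac_gasps = frac,
                                       control_class = cls,
                                       stringsAsFactors = FALSE))
      }
    }
  }
  list(bp_steps = bp_steps, sync_table = sync,
       coincidence_count = as.integer(coincidence))
}
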