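#' Hypoxia motor-pattern schedule
#'
#' Builds the scripted epoch sequence the generator realizes: a normoxic
#' control period, then hypoxia-evoked augmentation (raised amplitude and
#' cycle frequency), depression with apneusis (prolonged inspiration) and
#' intermittent augmented bursts (sighs), apnea, autoresuscitative gasping
#' (short, intense, quasiperiodic decrementing bursts), and recovery.
#' Durations default to a 90-905 s scale hypoxic exposure bracketed by
#' control and recovery.
#'
#' @param control,augmentation,apneusis,apnea,gasping,recovery epoch
#'   durations (s); a duration of 0 drops the epoch.
#' @param amp_gain phrenic amplitude gain during augmentation.
#' @param freq_gain cycle-frequency gain during augmentation.
#' @param i_gain inspiratory-duration gain during apneusis.
#' @param n_sighs augmented bursts placed in the apneusis epoch.
#' @param gasp_interval,gasp_interval_jitter mean and spread (s) of the
#'   quasiperiodic gasp spacing.
#' @param gasp_duration gasp burst envelope duration (s).
#' @return data.frame with one row per epoch: `class`, `duration`,
#'   `amp_gain`, `freq_gain`, `i_gain`, `n_sighs`, and absolute `t0`,
#'   `t1`.
#' @export
hypoxiaSchedule <- function(control = 300, augmentation = 60, apneusis = 60,
                            apnea = 30, gasping = 60, recovery = 120,
                            amp_gain = 1.6, freq_gain = 1.3, i_gain = 2.5,
                            n_sighs = 3L, gasp_interval = 5,
                            gasp_interval_jitter = 1, gasp_duration = 0.4) {
  cls <- c("control", "augmentation", "depression_apneusis", "apnea",
           "gasping", "recovery")
  dur <- c(control, augmentation, apneusis, apnea, gasping, recovery)
  keep <- dur > 0
  sched <- data.frame(
    class = cls[keep], duration = dur[keep],
    amp_gain = ifelse(cls[keep] == "augmentation", amp_gain, 1),
    freq_gain = ifelse(cls[keep] == "augmentation", freq_gain, 1),
    i_gain = ifelse(cls[keep] == "depression_apneusis", i_gain, 1),
    n_sighs = ifelse(cls[keep] == "depression_apneusis",
                     as.integer(n_sighs), 0L),
    stringsAsFactors = FALSE)
  sched$t1 <- cumsum(sched$duration)
  sched$t0 <- sched$t1 - sched$duration
  attr(sched, "gasp_interval") <- gasp_interval
  attr(sched, "gasp_interval_jitter") <- gasp_interval_jitter
  attr(sched, "gasp_duration") <- gasp_duration
  sched
}

#' Realize true respiratory cycles and motor events from a schedule
#'
#' Lays respiratory cycles end-to-end through every cycle-bearing epoch
#' (apnea and gasping epochs carry none), with an integer number of
#' slightly jittered cycles tiling each epoch exactly, and draws the true
#' gasp times (quasiperiodic within gasping epochs) and sigh cycles
#' (evenly spread through the apneusis epoch). These are the ground-truth
#' event times that the segmentation stage is later asked to recover.
#'
#' @param schedule a [hypoxiaSchedule()] data.frame.
#' @param i_dur,e_dur control inspiratory/expiratory durations (s).
#' @param jitter fractional cycle-length jitter (sd).
#' @param seed integer seed.
#' @return list with `cycles` (data.frame `i_onset`, `e_onset`,
#'   `cycle_end`, `epoch`, `sigh`), `gasp_times`, `sigh_times`.
#' @export
scheduleCycles <- function(schedule, i_dur = 1.0, e_dur = 1.5,
                           jitter = 0.02, seed = 1L) {
  withSeed(streamSeed(seed, "cycles"), {
    cyc <- list()
    gasp_times <- numeric(0)
    sigh_times <- numeric(0)
    for (k in seq_len(nrow(schedule))) {
      ep <- schedule[k, ]
      if (ep$class %in% c("apnea")) next
      if (ep$class == "gasping") {
        gi <- attr(schedule, "gasp_interval")
        gj <- attr(schedule, "gasp_interval_jitter")
        gd <- attr(schedule, "gasp_duration")
        t <- ep$t0 + 0.5 * gi
        while (t + gd < ep$t1 - 0.5) {
          gasp_times <- c(gasp_times, t)
          t <- t + gi + stats::runif(1, -gj, gj)
        }
        next
      }
      ii <- i_dur * ep$i_gain / ep$freq_gain
      ee <- e_dur / ep$freq_gain
      len <- ii + ee
      n <- max(1L, round(ep$duration / len))
      w <- 1 + stats::rnorm(n, 0, jitter)
      w <- w / sum(w) * ep$duration          # exact tiling of the epoch
      ends <- ep$t0 + cumsum(w)
      starts <- c(ep$t0, ends[-n])
      e_on <- starts + w * ii / len
      sigh <- rep(FALSE, n)
      if (ep$n_sighs > 0L && n >= ep$n_sighs) {
        at <- unique(round(seq(0.25, 0.85, length.out = ep$n_sighs) * n))
        sigh[at] <- TRUE
        sigh_times <- c(sigh_times, starts[at] + 0.9 * (e_on[at] - starts[at]))
      }
      cyc[[length(cyc) + 1L]] <- data.frame(
        i_onset = starts, e_onset = e_on, cycle_end = ends,
        epoch = ep$class, sigh = sigh, stringsAsFactors = FALSE)
    }
    cycles <- do.call(rbind, cyc)
    cycles <- cycles[order(cycles$i_onset), ]
    rownames(cycles) <- NULL
    list(cycles = cycles, gasp_times = gasp_times, sigh_times = sigh_times)
  })
}
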