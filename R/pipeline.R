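#' Run the full analysis pipeline on a session
#'
#' Stages, in order: respiratory cycle detection from the integrated
#' phrenic signal; motor-pattern epoch segmentation with sigh/gasp
#' detection; blood-pressure step detection and gasp-synchrony; CTH
#' computation, modulation testing and classification on the control
#' window only (as classification is defined on control breathing);
#' all-pairs correlogram screening with surrogate significance and FDR
#' control; optional spike-triggered averages of the phrenic signal; and
#' feature-map assembly with population summaries. All outputs are
#' written as delimited text (plus JSON report and GraphML graph);
#' identical `(config, seed)` give identical outputs.
#'
#' @param session a [Session-class], or a scenario list/path, in which
#'   case a synthetic session is generated first ([genSession()]).
#' @param config an [analysisConfig()] list (its `rng_seed` governs all
#'   stochastic stages).
#' @param out_dir optional output directory; when `NULL` nothing is
#'   written.
#' @param sta_triggers neuron ids for spike-triggered averages (default
#'   none).
#' @param screen_window `NULL` for the whole recording (default) or
#'   `c(t0, t1)`/an epoch class name to restrict correlogram screening
#'   to that part of the record.
#' @return list with `report` ([RunReport-class]), `cycles`,
#'   `segmentation`, `bp`, `classes`, `cths`, `screen`, `map`,
#'   `summary`, `stas`, and `truth` when a scenario was generated.
#' @export
runPipeline <- function(session, config = NULL, out_dir = NULL,
                        sta_triggers = character(0),
                        screen_window = NULL) {
  cfg <- asConfig(config)
  t_start <- proc.time()[["elapsed"]]
  truth <- NULL
  if (!is(session, "Session")) {
    gs <- genSession(session, seed = cfg$rng_seed)
    session <- gs$session
    truth <- gs$truth
  }
  stageMsg <- function(name)
    message(sprintf("[gaspnet] %-10s t=%.1fs", name,
                    proc.time()[["elapsed"]] - t_start))
  partial <- function(stage, e) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      writeLines(paste0("failed at stage: ", stage, "\n", conditionMessage(e)),
                 file.path(out_dir, ".partial"))
    }
    stop("pipeline aborted at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  }
  warnings <- character(0)

  viol <- validateSession(session)
  if (length(viol))
    partial("validate", simpleError(paste(viol, collapse = "; ")))

  phrenic <- session@signals[["phrenic_integrated"]]
  if (is.null(phrenic))
    partial("cycles", simpleError("no phrenic_integrated signal"))

  stageMsg("cycles")
  cycles <- detectCycles(phrenic, session@controlWindow, cfg)
  if (!is.null(attr(cycles, "warning")))
    warnings <- c(warnings, attr(cycles, "warning"))

  stageMsg("epochs")
  seg <- tryCatch(classifyEpochs(phrenic, cycles, session@controlWindow,
                                 cfg),
                  error = function(e) partial("epochs", e))
  gasps <- seg$events[seg$events$kind == "gasp", , drop = FALSE]

  stageMsg("cth")
  ctlCycles <- cycles[cycles$i_onset >= session@controlWindow[1] &
                        cycles$cycle_end <= session@controlWindow[2], ,
                      drop = FALSE]
  if (nrow(ctlCycles) < 10L)
    partial("cth", simpleError(sprintf(
      "control window [%g, %g] contains only %d cycles (need 10)",
      session@controlWindow[1], session@controlWindow[2], nrow(ctlCycles))))
  cls <- classifyAllNeurons(session, ctlCycles, cfg)

  stageMsg("bp")
  bpSig <- session@signals[["blood_pressure"]]
  bp <- if (!is.null(bpSig))
    detectBpStepsAndSync(bpSig, gasps, session@trains, cls$classes, cfg)
  else list(bp_steps = data.frame(), sync_table = data.frame(),
            coincidence_count = 0L)

  stageMsg("screen")
  screenSession <- session
  if (!is.null(screen_window)) {
    if (identical(screen_window, "rhythmic")) {
      # quasi-stationary segments only: apnea and gasping epochs carry
      # nonstationary burst firing outside the surrogate null's reach
      ep <- seg$epochs[!seg$epochs$class %in% c("apnea", "gasping"), ,
                       drop = FALSE]
      if (!nrow(ep))
        partial("screen", simpleError("no rhythmic epochs to screen"))
      screenSession <- spliceSession(session, ep[, c("t0", "t1")])
    } else if (is.character(screen_window)) {
      ep <- seg$epochs[seg$epochs$class == screen_window, , drop = FALSE]
      if (!nrow(ep))
        partial("screen", simpleError(paste0("no epoch of class ",
                                             screen_window)))
      screenSession <- spliceSession(session, ep[, c("t0", "t1")])
    } else {
      screenSession <- restrictSession(session, screen_window)
    }
  }
  screen <- screenPairs(screenSession, cfg)

  stas <- list()
  for (id in intersect(sta_triggers, names(session@trains))) {
    sta <- spikeTriggeredAverage(phrenic, session@trains[[id]],
                                 cfg$sta_window)
    stas[[id]] <- detectStaFeatures(sta, phrenic, session@trains[[id]],
                                    cfg)
  }

  stageMsg("map")
  map <- buildFeatureMap(session, cls$classes, screen$edges)
  summary <- summarizeConnectivity(map)
  heat <- rateHeatmapMatrix(unname(session@trains))

  nUsable <- sum(vapply(session@trains, function(tr)
    length(tr@times) >= 2L, logical(1)))
  report <- new("RunReport",
    config = unclass(cfg),
    counts = list(n_trains = length(session@trains),
                  n_usable_trains = nUsable,
                  n_cycles = nrow(cycles),
                  n_epochs = nrow(seg$epochs),
                  n_events = nrow(seg$events),
                  n_bp_steps = nrow(bp$bp_steps),
                  coincidence_count = bp$coincidence_count,
                  n_classified = nrow(cls$classes),
                  pairs_assessed = screen$n_assessed,
                  significant_pairs =
                    sum(screen$pairs$q <= cfg$fdr_q &
                          screen$pairs$n_features > 0),
                  n_edges = nrow(screen$edges)),
    seeds = list(rng_seed = cfg$rng_seed),
    warnings = warnings)

  out <- list(report = report, cycles = cycles, segmentation = seg,
              bp = bp, classes = cls$classes, cths = cls$cths,
              screen = screen, map = map, summary = summary,
              heatmap = heat, stas = stas, truth = truth)
  if (!is.null(out_dir)) writePipelineOutputs(out, out_dir)
  stageMsg("done")
  out
}

#' Splice selected time windows of a session into one contiguous record
#'
#' Keeps only spikes inside the given windows and concatenates the
#' windows end-to-end (later segments shifted left), yielding a session
#' whose trains span one contiguous interval. Used to screen
#' correlograms over the quasi-stationary rhythmic segments of a
#' recording: apnea and gasping epochs carry intense nonstationary burst
#' firing that violates the renewal assumptions of the gamma-ISI
#' surrogate null, and gasp-synchrony is analyzed by its own module.
#' Correlations across splice boundaries contribute only the few
#' spike pairs within a correlogram window of each seam.
#'
#' @param session a [Session-class].
#' @param windows data.frame or matrix with columns `t0`, `t1` (sorted,
#'   non-overlapping windows).
#' @return a [Session-class] with spliced trains (signals are dropped).
#' @export
spliceSession <- function(session, windows) {
  windows <- as.data.frame(windows)
  o <- order(windows$t0)
  t0 <- windows$t0[o]; t1 <- windows$t1[o]
  dur <- t1 - t0
  offset <- c(0, cumsum(dur))[seq_along(dur)]
  trains <- lapply(session@trains, function(tr) {
    tt <- tr@times
    parts <- lapply(seq_along(t0), function(k)
      tt[tt >= t0[k] & tt < t1[k]] - t0[k] + offset[k])
    spikeTrain(tr@neuronId, unlist(parts), c(0, sum(dur)), tr@region)
  })
  cw <- c(0, min(dur[1], session@controlWindow[2] - t0[1]))
  if (cw[2] <= cw[1]) cw <- c(0, sum(dur))
  newSession(trains, list(), controlWindow = cw,
             metadata = session@metadata)
}

# Restrict every train (and interval) to a time window.
restrictSession <- function(session, window) {
  trains <- lapply(session@trains, function(tr) {
    keep <- tr@times >= window[1] & tr@times < window[2]
    spikeTrain(tr@neuronId, tr@times[keep], window, tr@region)
  })
  newSession(trains, session@signals,
             controlWindow = c(max(window[1], session@controlWindow[1]),
                               min(window[2], session@controlWindow[2])),
             metadata = session@metadata)
}

writePipelineOutputs <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  wcsv(out$cycles, "cycles.csv")
  wcsv(out$segmentation$epochs, "epochs.csv")
  wcsv(out$segmentation$events, "events.csv")
  wcsv(out$bp$sync_table, "sync_table.csv")
  wcsv(out$classes, "classes.csv")
  cthTab <- do.call(rbind, lapply(out$cths, function(h)
    data.frame(neuron_id = h@neuronId, bin_center_phase = h@phase,
               rate = h@rate, scaled_rate = h@scaledRate)))
  wcsv(cthTab, "cth.csv")
  wcsv(out$screen$edges, "edges.csv")
  wcsv(out$screen$pairs, "pairs.csv")
  wcsv(out$summary$groups, "summary.csv")
  utils::write.csv(as.data.frame(out$heatmap), file.path(out_dir,
                                                         "heatmap.csv"))
  for (id in names(out$stas)) {
    writeCorrelogram(out$stas[[id]],
                     file.path(out_dir, paste0("sta_", id, ".csv")))
    fe <- corrFeatures(out$stas[[id]])
    fe$trigger_id <- rep(id, nrow(fe))
    wcsv(fe, paste0("sta_features_", id, ".csv"))
  }
  exportFeatureMap(out$map, file.path(out_dir, "map.graphml"))
  rep <- out$report
  jsonlite::write_json(list(config = rep@config, counts = rep@counts,
                            seeds = rep@seeds, warnings = rep@warnings),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  if (file.exists(file.path(out_dir, ".partial")))
    file.remove(file.path(out_dir, ".partial"))
  invisible(out_dir)
}
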