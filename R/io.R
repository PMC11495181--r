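#' Read a session from delimited-text interchange files
#'
#' The canonical on-disk form is plain delimited text: `spikes.csv` with
#' columns `neuron_id,time_s`; `neurons.csv` with columns
#' `neuron_id,region`; one `<name>.signal.csv` per signal whose first line
#' is `# fs=<Hz> start=<s>` followed by a `value` column; and
#' `session.json` holding the control window, recording interval and
#' free-form metadata. Nothing is rejected silently: any invariant
#' violation raises an error naming the offending entity.
#'
#' @param spike_path path to the spike table.
#' @param signal_paths character vector of signal file paths (may be
#'   empty).
#' @param meta_path path to the session metadata JSON.
#' @param neurons_path optional path to the neuron/region table; regions
#'   default to `"other"` when absent.
#' @return a validated [Session-class].
#' @seealso [writeSession()], [validateSession()]
#' @export
readSession <- function(spike_path, signal_paths = character(0),
                        meta_path = NULL, neurons_path = NULL) {
  sp <- utils::read.csv(spike_path, colClasses = c("character", "numeric"))
  if (!all(c("neuron_id", "time_s") %in% names(sp)))
    stop("spike file must have columns neuron_id,time_s: ", spike_path)

  meta <- list()
  controlWindow <- NULL
  interval <- NULL
  if (!is.null(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    controlWindow <- as.numeric(meta$control_window)
    interval <- as.numeric(meta$interval)
    meta$control_window <- NULL
    meta$interval <- NULL
  }
  if (is.null(interval) || !length(interval)) {
    interval <- if (nrow(sp)) c(min(sp$time_s), max(sp$time_s) + 1e-6)
                else c(0, 1)
  }

  regions <- character(0)
  if (!is.null(neurons_path)) {
    nr <- utils::read.csv(neurons_path, colClasses = "character")
    regions <- stats::setNames(nr$region, nr$neuron_id)
  }

  # ids come from the neuron table when present, so spike-free neurons
  # survive a round trip; otherwise from the spike table
  ids <- if (length(regions)) names(regions) else unique(sp$neuron_id)
  ids <- union(ids, unique(sp$neuron_id))
  trains <- lapply(ids, function(id) {
    tt <- sp$time_s[sp$neuron_id == id]
    if (length(tt) > 1L && any(diff(tt) <= 0))
      stop("times not increasing for ", id)
    spikeTrain(id, tt, interval,
               region = if (id %in% names(regions)) regions[[id]] else "other")
  })

  signals <- lapply(signal_paths, readSignalFile)

  newSession(trains, signals,
             controlWindow = controlWindow %||% interval,
             metadata = as.list(meta))
}

readSignalFile <- function(path) {
  hdr <- readLines(path, n = 1L)
  m <- regmatches(hdr, regexec("^#\\s*fs=([0-9.eE+-]+)\\s+start=([0-9.eE+-]+)",
                               hdr))[[1]]
  if (length(m) != 3L)
    stop("missing fs in signal file header: ", path)
  vals <- utils::read.csv(path, skip = 1L, colClasses = "numeric")
  name <- sub("\\.signal\\.csv$", "", basename(path))
  if (!name %in% SIGNAL_NAMES) name <- "other"
  continuousSignal(name, vals$value, fs = as.numeric(m[2]),
                   start = as.numeric(m[3]))
}

#' Write a session to the delimited-text interchange format
#'
#' Numbers are written with 17 significant digits so that
#' `readSession(writeSession(s))` reproduces every time bit-exactly, and
#' the output is byte-identical for identical content.
#'
#' @param session a [Session-class].
#' @param out_dir output directory (created if missing).
#' @return invisibly, the character vector of files written (the
#'   manifest).
#' @export
writeSession <- function(session, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)

  fmt <- function(x) sprintf("%.17g", x)
  files <- character(0)

  spike_path <- file.path(out_dir, "spikes.csv")
  lines <- c("neuron_id,time_s")
  for (tr in session@trains)
    if (length(tr@times))
      lines <- c(lines, paste0(tr@neuronId, ",", fmt(tr@times)))
  writeLines(lines, spike_path)
  files <- c(files, spike_path)

  neurons_path <- file.path(out_dir, "neurons.csv")
  writeLines(c("neuron_id,region",
               vapply(session@trains, function(tr)
                 paste0(tr@neuronId, ",", tr@region), character(1))),
             neurons_path)
  files <- c(files, neurons_path)

  for (sig in session@signals) {
    p <- file.path(out_dir, paste0(sig@name, ".signal.csv"))
    writeLines(c(sprintf("# fs=%s start=%s", fmt(sig@fs), fmt(sig@start)),
                 "value", fmt(sig@samples)), p)
    files <- c(files, p)
  }

  meta_path <- file.path(out_dir, "session.json")
  interval <- if (length(session@trains))
    session@trains[[1]]@interval else session@controlWindow
  jsonlite::write_json(
    c(list(control_window = session@controlWindow, interval = interval),
      session@metadata),
    meta_path, auto_unbox = TRUE, digits = NA)
  files <- c(files, meta_path)

  invisible(files)
}

# Shared by validateSession() and the Session validity method; returns a
# character vector of violations (empty when valid). Pure: no side
# effects, deterministic.
validateSessionInternal <- function(session) {
  rep <- character(0)
  ids <- vapply(session@trains, function(x) x@neuronId, character(1))
  if (anyDuplicated(ids))
    rep <- c(rep, sprintf("neuron_id not unique: %s",
                          paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  for (tr in session@trains) {
    v <- validObject(tr, test = TRUE)
    if (is.character(v)) rep <- c(rep, v)
  }
  for (sig in session@signals) {
    v <- validObject(sig, test = TRUE)
    if (is.character(v)) rep <- c(rep, v)
  }
  cw <- session@controlWindow
  if (length(cw) != 2L || any(!is.finite(cw)) || cw[1] >= cw[2]) {
    rep <- c(rep, "control window must be [t0, t1] with t0 < t1")
  } else {
    for (tr in session@trains)
      if (cw[1] < tr@interval[1] || cw[2] > tr@interval[2])
        rep <- c(rep, sprintf("control window outside interval of %s",
                              tr@neuronId))
  }
  rep
}

#' Validate a session, reporting (never raising) violations
#'
#' @param session a [Session-class] (possibly constructed unchecked).
#' @return character vector of violations; empty iff all invariants hold.
#' @export
validateSession <- function(session) validateSessionInternal(session)
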