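#' Pairwise coupling specification table
#'
#' Each row injects a millisecond-scale functional connection: after every
#' source spike the target's intensity is multiplied by `strength` over
#' the lag window `[latency, latency + kernel_width]`. Overlapping source
#' spikes compound multiplicatively. `strength > 1` is excitatory;
#' `strength` in `[0, 1)` is inhibitory (multiplicative coupling keeps the
#' intensity nonnegative, so inhibition is bounded at zero).
#'
#' @param source_id,target_id neuron ids (self-connections are rejected at
#'   sampling time).
#' @param sign `"excitatory"` or `"inhibitory"` (consistency-checked
#'   against `strength`).
#' @param latency conduction/synaptic latency (s), `>= 0`.
#' @param kernel_width effect duration (s), `> 0`.
#' @param strength multiplicative rate factor.
#' @return data.frame of connection specs.
#' @export
connectionSpecs <- function(source_id, target_id, sign = NULL,
                            latency = 0.001, kernel_width = 0.002,
                            strength = 3) {
  df <- data.frame(source_id = as.character(source_id),
                   target_id = as.character(target_id),
                   latency = latency, kernel_width = kernel_width,
                   strength = strength, stringsAsFactors = FALSE)
  df$sign <- if (is.null(sign)) ifelse(df$strength > 1, "excitatory",
                                       "inhibitory") else sign
  stopifnot(all(df$latency >= 0), all(df$kernel_width > 0),
            all(df$strength >= 0))
  if (any((df$sign == "excitatory") != (df$strength > 1)))
    stop("sign inconsistent with strength (excitatory iff strength > 1)")
  df
}

#' Common-drive specification
#'
#' A shared, unobserved source of drive: a latent Poisson process whose
#' events multiply every member's intensity by `rate_share` for
#' `kernel_width` seconds. Pairs of members acquire a central correlogram
#' peak (the conventional shared-input signature) without any direct
#' connection.
#'
#' @param member_ids character vector of at least 2 member neuron ids.
#' @param rate_share multiplicative modulation factor (`> 1`).
#' @param kernel_width effect duration (s).
#' @param drive_rate latent event rate (spikes/s).
#' @return a list-of-lists usable as the `common_drives` argument of
#'   [sampleCoupledPopulation()].
#' @export
commonDriveSpec <- function(member_ids, rate_share = 6,
                            kernel_width = 0.003, drive_rate = 25) {
  stopifnot(length(member_ids) >= 2L, rate_share > 1, kernel_width > 0,
            drive_rate > 0)
  list(member_ids = as.character(member_ids), rate_share = rate_share,
       kernel_width = kernel_width, drive_rate = drive_rate)
}

# Kahn topological sort on ids given an edge table; NULL if cyclic.
topoOrder <- function(ids, edges) {
  indeg <- stats::setNames(integer(length(ids)), ids)
  for (t in edges$target_id) indeg[[t]] <- indeg[[t]] + 1L
  queue <- ids[indeg == 0L]
  out <- character(0)
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    out <- c(out, v)
    hit <- edges$source_id == v
    for (t in edges$target_id[hit]) {
      indeg[[t]] <- indeg[[t]] - 1L
      if (indeg[[t]] == 0L) queue <- c(queue, t)
    }
  }
  if (length(out) == length(ids)) out else NULL
}

# Per-connection multiplier exponent at candidate times: number of source
# spikes s with (t - s) in [latency, latency + width].
couplingCount <- function(t, src_times, latency, width) {
  findInterval(t - latency, src_times) -
    findInterval(t - latency - width, src_times)
}

#' Sample a coupled neuronal population by thinning
#'
#' Draws every neuron's spikes from its intensity by exact thinning of a
#' dominating homogeneous Poisson candidate stream. Couplings act
#' multiplicatively on the target intensity after each realized source
#' spike; common drives act through latent Poisson sources wired to all
#' members. Acyclic coupling graphs are sampled vectorized in topological
#' order; cyclic graphs (e.g. reciprocal excitation) fall back to a
#' sequential event walk in global time order. Each neuron draws from its
#' own RNG stream keyed by `neuron_id`, so adding a neuron does not
#' perturb the spikes of the others; identical `(specs, seed)` give
#' identical output.
#'
#' @param specs [neuronSpecs()] data.frame.
#' @param connections [connectionSpecs()] data.frame (may be empty/NULL).
#' @param common_drives list of [commonDriveSpec()]s.
#' @param schedule [hypoxiaSchedule()] data.frame.
#' @param cycles,gasp_times true cycles and gasp times from
#'   [scheduleCycles()].
#' @param seed integer seed.
#' @param interval recording interval; defaults to the schedule span.
#' @param gasp_duration gasp envelope duration (s).
#' @return named list of [SpikeTrain-class] objects (latent drive sources
#'   are not returned).
#' @export
sampleCoupledPopulation <- function(specs, connections = NULL,
                                    common_drives = list(),
                                    schedule, cycles, gasp_times = numeric(0),
                                    seed = 1L, interval = NULL,
                                    gasp_duration = 0.4) {
  if (is.null(connections) || !nrow(as.data.frame(connections)))
    connections <- connectionSpecs(character(0), character(0),
                                   character(0), numeric(0), numeric(0),
                                   numeric(0))
  if (anyDuplicated(specs$neuron_id))
    stop("neuron ids must be unique")
  if (any(connections$source_id == connections$target_id))
    stop("self-connection (source = target) is not allowed")
  if (is.null(interval))
    interval <- c(min(schedule$t0), max(schedule$t1))

  # latent common-drive sources become hidden NRM neurons with
  # excitatory connections onto every member
  hidden <- character(0)
  for (k in seq_along(common_drives)) {
    cd <- common_drives[[k]]
    hid <- paste0(".drive", k)
    hidden <- c(hidden, hid)
    specs <- rbind(specs, neuronSpecs(hid, "other", "NRM",
                                      base_rate = cd$drive_rate))
    connections <- rbind(connections, connectionSpecs(
      rep(hid, length(cd$member_ids)), cd$member_ids,
      latency = 0, kernel_width = cd$kernel_width,
      strength = cd$rate_share))
  }

  ids <- specs$neuron_id
  unknown <- setdiff(c(connections$source_id, connections$target_id), ids)
  if (length(unknown))
    stop("connection references unknown neuron: ",
         paste(unknown, collapse = ", "))

  order <- topoOrder(ids, connections)
  spikes <- vector("list", length(ids))
  names(spikes) <- ids

  sampleNode <- function(id, candidates, u) {
    spec <- as.list(specs[specs$neuron_id == id, ])
    inc <- connections[connections$target_id == id, , drop = FALSE]
    lambdaMax <- specMaxRate(spec, inc$strength)
    if (lambdaMax <= 0 || !length(candidates)) return(numeric(0))
    lam <- evalRateProfile(spec, candidates, cycles, schedule, gasp_times,
                           gasp_duration)
    for (j in seq_len(nrow(inc))) {
      src <- spikes[[inc$source_id[j]]]
      if (!length(src)) next
      m <- couplingCount(candidates, src, inc$latency[j],
                         inc$kernel_width[j])
      lam <- lam * inc$strength[j]^m
    }
    # unique(): RNG granularity can produce tied candidate times among
    # hundreds of thousands of draws, and spike times must be strictly
    # increasing
    unique(candidates[u < lam / lambdaMax])
  }

  drawCandidates <- function(id) {
    spec <- as.list(specs[specs$neuron_id == id, ])
    inc <- connections[connections$target_id == id, , drop = FALSE]
    lambdaMax <- specMaxRate(spec, inc$strength)
    withSeed(streamSeed(seed, id), {
      n <- stats::rpois(1, lambdaMax * diff(interval))
      list(t = sort(stats::runif(n, interval[1], interval[2])),
           u = stats::runif(n), lambdaMax = lambdaMax)
    })
  }

  if (!is.null(order)) {
    for (id in order) {
      cand <- drawCandidates(id)
      spikes[[id]] <- sampleNode(id, cand$t, cand$u)
    }
  } else {
    # cyclic coupling graph: walk all candidates in global time order so
    # each acceptance sees every earlier accepted source spike
    cand <- lapply(ids, drawCandidates)
    names(cand) <- ids
    allT <- unlist(lapply(cand, `[[`, "t"))
    allU <- unlist(lapply(cand, `[[`, "u"))
    allId <- rep(ids, vapply(cand, function(x) length(x$t), integer(1)))
    ord <- base::order(allT)
    allT <- allT[ord]; allU <- allU[ord]; allId <- allId[ord]
    for (id in ids) spikes[[id]] <- numeric(0)
    specL <- split(specs, specs$neuron_id)
    incL <- split(connections, connections$target_id)
    lamMax <- vapply(ids, function(id)
      specMaxRate(as.list(specL[[id]]),
                  incL[[id]]$strength %||% numeric(0)), numeric(1))
    for (i in seq_along(allT)) {
      id <- allId[i]; t <- allT[i]
      spec <- as.list(specL[[id]])
      lam <- evalRateProfile(spec, t, cycles, schedule, gasp_times,
                             gasp_duration)
      inc <- incL[[id]]
      if (!is.null(inc)) for (j in seq_len(nrow(inc))) {
        src <- spikes[[inc$source_id[j]]]
        if (!length(src)) next
        m <- couplingCount(t, src, inc$latency[j], inc$kernel_width[j])
        lam <- lam * inc$strength[j]^m
      }
      if (allU[i] < lam / lamMax[[id]])
        spikes[[id]] <- c(spikes[[id]], t)
    }
  }

  keep <- setdiff(ids, hidden)
  out <- lapply(keep, function(id)
    spikeTrain(id, unique(spikes[[id]]), interval,
               region = specs$region[specs$neuron_id == id]))
  names(out) <- keep
  out
}
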