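#' Assemble significant correlogram features into a feature map
#'
#' Offset peaks become directed excitatory edges (source to target),
#' offset troughs directed inhibitory edges; central peaks undirected
#' shared-drive edges and central troughs undirected shared-opposite
#' edges (shared influences with opposite actions on the two cells).
#' Multiple significant features for one pair produce multiple edges.
#' Nodes carry region and CTH classification annotations.
#'
#' @param session a [Session-class].
#' @param classes data.frame from [classifyAllNeurons()] (optional).
#' @param edges edge data.frame from [screenPairs()].
#' @return a [FeatureMap-class].
#' @export
buildFeatureMap <- function(session, classes = NULL, edges = emptyEdges()) {
  nodes <- data.frame(
    neuron_id = vapply(session@trains, neuronId, character(1)),
    region = vapply(session@trains, region, character(1)),
    stringsAsFactors = FALSE)
  if (!is.null(classes)) {
    m <- match(nodes$neuron_id, classes$neuron_id)
    nodes$modulation <- classes$modulation[m]
    nodes$subtype <- classes$subtype[m]
    nodes$tonicity <- classes$tonicity[m]
  } else {
    nodes$modulation <- nodes$subtype <- nodes$tonicity <- NA_character_
  }
  rownames(nodes) <- NULL
  if (nrow(edges)) {
    unknown <- setdiff(c(edges$source, edges$target), nodes$neuron_id)
    if (length(unknown))
      stop("edge references unknown neuron: ",
           paste(unknown, collapse = ", "))
    edges$directed <- edges$sign %in% c("excitation", "inhibition")
  } else {
    edges <- emptyEdges()
    edges$directed <- logical(0)
  }
  new("FeatureMap", nodes = nodes, edges = as.data.frame(edges))
}

#' Population connectivity summary
#'
#' Per group (region by default, or any node attribute): number of
#' recorded neurons, number functionally connected to at least one other
#' neuron, and their fraction; plus edge counts by sign and the
#' disinhibition-motif count, i.e. chains `A -| B -| C` of two directed
#' inhibitory edges through distinct neurons (silencing of A releases C).
#'
#' @param map a [FeatureMap-class].
#' @param per_group node column to group by (`"region"` default; use
#'   `NULL` for the overall row only).
#' @return list with `groups` (data.frame `group`, `n_recorded`,
#'   `n_connected`, `fraction`), `edge_counts` (by sign) and
#'   `disinhibition_motifs`.
#' @export
summarizeConnectivity <- function(map, per_group = "region") {
  nodes <- map@nodes
  edges <- map@edges
  connected <- unique(c(edges$source, edges$target))
  groupRow <- function(ids, label) {
    data.frame(group = label, n_recorded = length(ids),
               n_connected = sum(ids %in% connected),
               fraction = if (length(ids))
                 sum(ids %in% connected) / length(ids) else 0,
               stringsAsFactors = FALSE)
  }
  groups <- groupRow(nodes$neuron_id, "all")
  if (!is.null(per_group) && per_group %in% names(nodes))
    for (g in sort(unique(nodes[[per_group]])))
      groups <- rbind(groups,
                      groupRow(nodes$neuron_id[nodes[[per_group]] == g], g))
  rownames(groups) <- NULL

  edge_counts <- if (nrow(edges)) table(edges$sign) else table(character(0))

  inh <- edges[edges$sign == "inhibition", , drop = FALSE]
  motifs <- 0L
  if (nrow(inh) >= 2L)
    for (i in seq_len(nrow(inh)))
      for (j in seq_len(nrow(inh)))
        if (i != j && inh$target[i] == inh$source[j] &&
            inh$source[i] != inh$target[j])
          motifs <- motifs + 1L
  list(groups = groups, edge_counts = edge_counts,
       disinhibition_motifs = motifs)
}

#' Normalized firing-rate heat-map matrix
#'
#' Rows are neurons, columns time bins; each entry is the neuron's rate
#' in the bin divided by that neuron's maximum bin rate (luminance
#' proportional to normalized rate). Silent neurons give all-zero rows.
#'
#' @param trains list of [SpikeTrain-class] objects.
#' @param bin_width time bin width (s).
#' @return numeric matrix with neuron ids as row names and bin mid-times
#'   as an attribute `time`.
#' @export
rateHeatmapMatrix <- function(trains, bin_width = 1) {
  stopifnot(bin_width > 0)
  iv <- range(unlist(lapply(trains, function(tr) tr@interval)))
  nb <- max(1L, ceiling((iv[2] - iv[1]) / bin_width - 1e-9))
  breaks <- iv[1] + (0:nb) * bin_width
  M <- t(vapply(trains, function(tr) {
    cnt <- graphics::hist(tr@times, breaks = breaks, plot = FALSE)$counts
    r <- cnt / bin_width
    if (max(r) > 0) r / max(r) else r
  }, numeric(length(breaks) - 1L)))
  rownames(M) <- vapply(trains, neuronId, character(1))
  attr(M, "time") <- (breaks[-1] + breaks[-length(breaks)]) / 2
  M
}

#' Export or import a feature map as GraphML or DOT
#'
#' Uses igraph for the formats; a round trip through GraphML preserves
#' nodes, edges and attributes.
#'
#' @param map a [FeatureMap-class].
#' @param path output path; format from extension (`.graphml` or
#'   `.dot`).
#' @return `exportFeatureMap`: invisibly, `path`. `importFeatureMap`: a
#'   [FeatureMap-class] (from GraphML only).
#' @export
exportFeatureMap <- function(map, path) {
  g <- asIgraph(map)
  fmt <- if (grepl("\\.dot$", path)) "dot" else "graphml"
  suppressWarnings(igraph::write_graph(g, path, format = fmt))
  invisible(path)
}

#' @rdname exportFeatureMap
#' @export
importFeatureMap <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  vdf <- igraph::as_data_frame(g, what = "vertices")
  edf <- igraph::as_data_frame(g, what = "edges")
  nodes <- data.frame(neuron_id = vdf$name, region = vdf$region,
                      modulation = vdf$modulation, subtype = vdf$subtype,
                      tonicity = vdf$tonicity, stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  edges <- if (nrow(edf)) data.frame(
    source = edf$from, target = edf$to, sign = edf$sign,
    position = edf$position, extremum_lag_s = edf$extremum_lag_s,
    di = edf$di, p_mc = edf$p_mc, q_value = edf$q_value,
    significant = as.logical(edf$significant),
    directed = as.logical(edf$directed), stringsAsFactors = FALSE)
  else {
    e <- emptyEdges(); e$directed <- logical(0); e
  }
  rownames(edges) <- NULL
  new("FeatureMap", nodes = nodes, edges = edges)
}

asIgraph <- function(map) {
  nodes <- map@nodes
  edges <- map@edges
  edf <- if (nrow(edges))
    data.frame(from = edges$source, to = edges$target,
               sign = edges$sign, position = edges$position,
               extremum_lag_s = edges$extremum_lag_s, di = edges$di,
               p_mc = edges$p_mc, q_value = edges$q_value,
               significant = edges$significant,
               directed = edges$directed, stringsAsFactors = FALSE)
  else data.frame(from = character(0), to = character(0))
  vdf <- data.frame(name = nodes$neuron_id, region = nodes$region,
                    modulation = nodes$modulation,
                    subtype = nodes$subtype, tonicity = nodes$tonicity,
                    stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edf, directed = TRUE, vertices = vdf)
}
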