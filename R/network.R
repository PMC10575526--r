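#' Build a vascular network from segment and junction tables
#'
#' Assembles the directed graph used throughout the package. Segments not
#' referenced by any junction are retained as isolated vessels (they classify
#' as \code{UNCLASSIFIED}).
#'
#' @param segments data.frame with columns \code{id}, \code{length_um},
#'   \code{diameter_um} and optionally \code{depth_um}, \code{is_feeder};
#'   extra columns are preserved.
#' @param edges data.frame with columns \code{junction_id}, \code{kind}
#'   (\code{BIFURCATION}/\code{CONFLUENCE}), \code{major_id},
#'   \code{minor1_id}, \code{minor2_id}. The CSV written by the synthetic
#'   generator uses the aliases \code{parent_id}/\code{daughter1_id}/
#'   \code{daughter2_id}, which are accepted.
#' @param crossings optional data.frame with columns \code{seg_a},
#'   \code{seg_b}; crossings are stored but never traversed.
#' @return a \linkS4class{VascularNetwork}.
#' @examples
#' seg <- data.frame(id = c("p", "a", "b"), length_um = c(100, 60, 70),
#'                   diameter_um = c(9, 4.5, 4.2))
#' jn <- data.frame(junction_id = "J1", kind = "BIFURCATION",
#'                  major_id = "p", minor1_id = "a", minor2_id = "b")
#' buildNetwork(seg, jn)
#' @export
buildNetwork <- function(segments, edges, crossings = NULL) {
  segments <- as.data.frame(segments, stringsAsFactors = FALSE)
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  alias <- c(parent_id = "major_id", daughter1_id = "minor1_id",
             daughter2_id = "minor2_id")
  for (a in names(alias))
    if (a %in% names(edges) && !alias[[a]] %in% names(edges))
      names(edges)[names(edges) == a] <- alias[[a]]
  if (!nrow(edges))
    edges <- data.frame(junction_id = character(), kind = character(),
                        major_id = character(), minor1_id = character(),
                        minor2_id = character(), stringsAsFactors = FALSE)
  for (col in c("id"))
    segments[[col]] <- as.character(segments[[col]])
  for (col in intersect(c("junction_id", "kind", "major_id", "minor1_id",
                          "minor2_id"), names(edges)))
    edges[[col]] <- as.character(edges[[col]])
  if (nrow(edges)) edges$kind <- toupper(edges$kind)
  if (is.null(crossings))
    crossings <- data.frame(seg_a = character(), seg_b = character(),
                            stringsAsFactors = FALSE)
  new("VascularNetwork", segments = segments, junctions = edges,
      crossings = crossings)
}

## Directed edge list implied by junction kinds: one row per parent->daughter
## flow, tagged with the junction it crosses.
.edgeList <- function(net) {
  jn <- net@junctions
  if (!nrow(jn))
    return(data.frame(from = character(), to = character(),
                      junction_id = character(), kind = character(),
                      stringsAsFactors = FALSE))
  bif <- jn[jn$kind == "BIFURCATION", , drop = FALSE]
  con <- jn[jn$kind == "CONFLUENCE", , drop = FALSE]
  rbind(
    data.frame(from = rep(bif$major_id, 2),
               to = c(bif$minor1_id, bif$minor2_id),
               junction_id = rep(bif$junction_id, 2),
               kind = rep("BIFURCATION", 2 * nrow(bif)),
               stringsAsFactors = FALSE),
    data.frame(from = c(con$minor1_id, con$minor2_id),
               to = rep(con$major_id, 2),
               junction_id = rep(con$junction_id, 2),
               kind = rep("CONFLUENCE", 2 * nrow(con)),
               stringsAsFactors = FALSE))
}

.igraph <- function(net) {
  el <- .edgeList(net)
  g <- igraph::graph_from_data_frame(
    el, directed = TRUE,
    vertices = data.frame(name = net@segments$id, stringsAsFactors = FALSE))
  len <- net@segments$length_um[match(el$from, net@segments$id)]
  igraph::E(g)$weight <- len
  igraph::E(g)$junction_kind <- el$kind
  g
}

#' Identify feeding arterioles
#'
#' A feeding arteriole is a vessel wider than \code{minDiameter} um with no
#' upstream parent inside the field: it supplies the rest of the network.
#'
#' @param net a \linkS4class{VascularNetwork}.
#' @param minDiameter diameter threshold in um (default 8).
#' @return character vector of feeder segment ids.
#' @export
identifyFeeders <- function(net, minDiameter = 8) {
  seg <- net@segments
  el <- .edgeList(net)
  hasInflow <- seg$id %in% el$to
  cand <- !is.na(seg$diameter_um) & seg$diameter_um > minDiameter & !hasInflow
  if (!any(cand))
    stop("no candidate feeding arteriole (diameter > ", minDiameter,
         " um with no inflow); feeder distance is undefined")
  seg$id[cand]
}

#' Validate flow-direction consistency of a network
#'
#' Report-only structural checks: segments that receive (or emit) flow at
#' more than one junction, declared feeders with inflow, and junctions whose
#' labeled kind contradicts the flow implied by the rest of the network
#' (flipping the kind would remove direction conflicts).
#'
#' @param net a \linkS4class{VascularNetwork}.
#' @param feeders optional character vector of segment ids asserted to be
#'   feeding arterioles; defaults to the \code{is_feeder} column when present.
#' @return data.frame with columns \code{type}, \code{id}, \code{message};
#'   zero rows when no violation is found.
#' @export
validateNetwork <- function(net, feeders = NULL) {
  el <- .edgeList(net)
  viol <- list()
  add <- function(type, id, message)
    viol[[length(viol) + 1L]] <<- data.frame(type = type, id = id,
                                             message = message,
                                             stringsAsFactors = FALSE)
  inAt <- function(id) unique(el$junction_id[el$to == id])
  outAt <- function(id) unique(el$junction_id[el$from == id])
  for (id in net@segments$id) {
    if (length(inAt(id)) > 1)
      add("multiple_inflow", id,
          paste("segment receives flow at junctions",
                paste(inAt(id), collapse = ", ")))
    if (length(outAt(id)) > 1)
      add("multiple_outflow", id,
          paste("segment emits flow at junctions",
                paste(outAt(id), collapse = ", ")))
  }
  if (is.null(feeders) && "is_feeder" %in% names(net@segments))
    feeders <- net@segments$id[isTRUE_vec(net@segments$is_feeder)]
  for (f in feeders) {
    if (f %in% el$to)
      add("feeder_inflow", f, "declared feeder receives flow")
    d <- net@segments$diameter_um[net@segments$id == f]
    if (length(d) == 1 && !is.na(d) && d <= 8)
      add("feeder_diameter", f, "declared feeder is not wider than 8 um")
  }
  ## kind mismatch: direction conflicts a junction creates under its stored
  ## kind vs. the flipped kind; the junction(s) whose flip removes the most
  ## conflicts are the suspects
  jn <- net@junctions
  improvement <- vapply(seq_len(nrow(jn)), function(i) {
    j <- jn[i, ]
    conflicts <- function(kind) {
      if (kind == "BIFURCATION") {
        recv <- c(j$minor1_id, j$minor2_id); emit <- j$major_id
      } else {
        recv <- j$major_id; emit <- c(j$minor1_id, j$minor2_id)
      }
      other <- el[el$junction_id != j$junction_id, , drop = FALSE]
      sum(recv %in% other$to) + sum(emit %in% other$from)
    }
    flipped <- if (j$kind == "BIFURCATION") "CONFLUENCE" else "BIFURCATION"
    conflicts(j$kind) - conflicts(flipped)
  }, numeric(1))
  if (length(improvement) && max(improvement) > 0) {
    for (i in which(improvement == max(improvement))) {
      flipped <- if (jn$kind[i] == "BIFURCATION") "CONFLUENCE" else "BIFURCATION"
      add("kind_mismatch", jn$junction_id[i],
          paste("junction labeled", jn$kind[i],
                "but surrounding flow implies", flipped))
    }
  }
  if (!length(viol))
    return(data.frame(type = character(), id = character(),
                      message = character(), stringsAsFactors = FALSE))
  do.call(rbind, viol)
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

## upstream junction: where the segment receives flow; downstream: where it
## emits. Returns kind or NA.
.endKinds <- function(net) {
  el <- .edgeList(net)
  ids <- net@segments$id
  up <- el$kind[match(ids, el$to)]
  down <- el$kind[match(ids, el$from)]
  data.frame(id = ids, upstream = up, downstream = down,
             stringsAsFactors = FALSE)
}

#' Classify capillary segments by their end junctions
#'
#' Capillary taxonomy by the kinds of the supplying and draining junctions:
#' \describe{
#'   \item{AC}{arteriolar capillary: fed by a bifurcation, drained by a
#'     bifurcation (one parent in, two daughters out).}
#'   \item{VC}{venular capillary: fed by a confluence, drained by a
#'     confluence (two parents in, one daughter out).}
#'   \item{TC}{terminal capillary: fed by a bifurcation, drained by a
#'     confluence.}
#'   \item{WC}{"unorthodox" capillary: the collecting junction precedes the
#'     supplying one along the flow direction (confluence then bifurcation).}
#'   \item{UNCLASSIFIED}{either end junction absent or unknown.}
#' }
#'
#' @param net a \linkS4class{VascularNetwork}.
#' @param ids segment ids to classify; default all.
#' @return named character vector of types, one per id.
#' @export
classifySegments <- function(net, ids = net@segments$id) {
  unknown <- setdiff(ids, net@segments$id)
  if (length(unknown))
    stop("unknown segment id(s): ", paste(unknown, collapse = ", "))
  ek <- .endKinds(net)
  ek <- ek[match(ids, ek$id), ]
  type <- rep("UNCLASSIFIED", length(ids))
  has <- !is.na(ek$upstream) & !is.na(ek$downstream)
  u <- ek$upstream; d <- ek$downstream
  type[has & u == "BIFURCATION" & d == "BIFURCATION"] <- "AC"
  type[has & u == "CONFLUENCE" & d == "CONFLUENCE"] <- "VC"
  type[has & u == "BIFURCATION" & d == "CONFLUENCE"] <- "TC"
  type[has & u == "CONFLUENCE" & d == "BIFURCATION"] <- "WC"
  stats::setNames(type, ids)
}

#' @rdname classifySegments
#' @param id a single segment id.
#' @export
classifySegment <- function(net, id) unname(classifySegments(net, id))

## Shortest upstream path (by summed segment length) from the nearest feeder.
## Ties broken by the lexicographically smallest id sequence. Returns
## list(path = ids incl. feeder and target, dist = summed full lengths of all
## path segments except the target, nbif = bifurcations crossed).
.upstreamPath <- function(net, id, feeders) {
  if (!id %in% net@segments$id)
    stop("unknown segment id: ", id)
  g <- .igraph(net)
  dmat <- igraph::distances(g, v = feeders, to = id, mode = "out",
                            weights = igraph::E(g)$weight)
  if (all(!is.finite(dmat)))
    stop("segment '", id, "' is not reachable from any feeding arteriole")
  best <- min(dmat)
  cand <- list()
  for (f in feeders[dmat[, 1] <= best + 1e-9]) {
    sp <- igraph::all_shortest_paths(g, from = f, to = id, mode = "out",
                                     weights = igraph::E(g)$weight)
    for (p in sp$vpaths) cand[[length(cand) + 1L]] <- names(p)
  }
  keys <- vapply(cand, paste, character(1), collapse = "\r")
  path <- cand[[order(keys)[1]]]
  nbif <- 0L
  if (length(path) > 1) {
    eids <- igraph::get_edge_ids(g, rbind(path[-length(path)], path[-1]))
    nbif <- sum(igraph::E(g)$junction_kind[eids] == "BIFURCATION")
  }
  list(path = path, dist = best, nbif = nbif)
}

#' Branch order of a segment
#'
#' The feeding arteriole is of order 1 and the order increases by one for
#' every bifurcation crossed along the upstream path; confluences do not
#' increment the order. With multiple feeders or paths, the path minimizing
#' summed segment length is used (ties by smallest lexicographic id
#' sequence).
#'
#' @param net a \linkS4class{VascularNetwork}.
#' @param id segment id (vectorized).
#' @param feeders feeder ids; computed by [identifyFeeders()] when omitted.
#' @return integer vector of branch orders.
#' @export
branchOrder <- function(net, id, feeders = identifyFeeders(net)) {
  vapply(id, function(i) 1L + .upstreamPath(net, i, feeders)$nbif, integer(1))
}

#' Path distance from the feeding arteriole
#'
#' Summed full lengths of every upstream segment (the feeder included) plus
#' half the length of the queried segment, i.e. the along-flow distance from
#' the upstream end of the feeder to the segment's center. The feeder's own
#' distance is therefore half its length. Shortest-path and tie rules as in
#' [branchOrder()].
#'
#' @inheritParams branchOrder
#' @return numeric vector of distances in um.
#' @export
feederDistance <- function(net, id, feeders = identifyFeeders(net)) {
  seg <- net@segments
  vapply(id, function(i) {
    up <- .upstreamPath(net, i, feeders)
    len <- seg$length_um[match(up$path, seg$id)]
    if (any(is.na(len)))
      stop("missing length on the upstream path of '", i, "'")
    up$dist + len[length(len)] / 2
  }, numeric(1))
}

#' Per-segment topology metrics
#'
#' Convenience wrapper computing capillary type, branch order and feeder
#' distance for every segment reachable from a feeder (order and distance are
#' \code{NA} for unreachable segments).
#'
#' @param net a \linkS4class{VascularNetwork}.
#' @return data.frame with columns \code{id}, \code{capillary_type},
#'   \code{branch_order}, \code{feeder_distance_um}.
#' @export
topologyTable <- function(net) {
  feeders <- identifyFeeders(net)
  ids <- net@segments$id
  type <- classifySegments(net, ids)
  bo <- rep(NA_integer_, length(ids))
  fd <- rep(NA_real_, length(ids))
  for (k in seq_along(ids)) {
    up <- tryCatch(.upstreamPath(net, ids[k], feeders), error = function(e) NULL)
    if (is.null(up)) next
    len <- net@segments$length_um[match(up$path, net@segments$id)]
    bo[k] <- 1L + up$nbif
    fd[k] <- up$dist + len[length(len)] / 2
  }
  data.frame(id = ids, capillary_type = unname(type), branch_order = bo,
             feeder_distance_um = fd, stringsAsFactors = FALSE)
}
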