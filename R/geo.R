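# Euclidean and road-network shortest-path distances between residence and
# injury site.

#' Construct a road network
#'
#' An undirected weighted graph of road segments with planar node
#' coordinates. Invariants enforced at construction: every edge endpoint is
#' a known node, edge lengths are strictly positive (negative weights are
#' rejected so Dijkstra-type shortest paths are exact), and no edge is
#' shorter than the straight-line chord between its endpoints (a road is at
#' least as long as its chord). Connectivity is NOT assumed.
#'
#' @param nodes Data frame with columns `node_id`, `x`, `y` (planar meters).
#' @param edges Data frame with columns `from`, `to`, `length_m`.
#' @return A `road_network` object.
#' @export
road_network <- function(nodes, edges) {
  nodes <- as_tibble(nodes)
  edges <- as_tibble(edges)
  stopifnot(all(c("node_id", "x", "y") %in% names(nodes)),
            all(c("from", "to", "length_m") %in% names(edges)))
  nodes$node_id <- as.character(nodes$node_id)
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (anyDuplicated(nodes$node_id)) stop_domain("duplicated node_id in `nodes`.")
  if (!all(is.finite(nodes$x)) || !all(is.finite(nodes$y))) {
    stop_domain("node coordinates must be finite.")
  }
  unknown <- setdiff(c(edges$from, edges$to), nodes$node_id)
  if (length(unknown) > 0) {
    stop_domain(paste0("edge endpoint(s) not in `nodes`: ",
                       paste(head(unknown, 5), collapse = ", ")))
  }
  if (any(!is.finite(edges$length_m)) || any(edges$length_m <= 0)) {
    stop_domain("edge lengths must be finite and > 0 (nonnegative-weight shortest paths).")
  }
  i <- match(edges$from, nodes$node_id)
  j <- match(edges$to, nodes$node_id)
  chord <- sqrt((nodes$x[i] - nodes$x[j])^2 + (nodes$y[i] - nodes$y[j])^2)
  short <- edges$length_m < chord * (1 - 1e-9)
  if (any(short)) {
    stop_domain(paste0("edge(s) shorter than the straight-line chord between their endpoints: ",
                       paste(head(which(short), 5), collapse = ", ")))
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = nodes$node_id)
  )
  igraph::E(g)$weight <- edges$length_m
  structure(list(nodes = nodes, edges = edges, graph = g),
            class = "road_network")
}

#' @export
print.road_network <- function(x, ...) {
  cat("<road_network> ", nrow(x$nodes), " nodes, ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Straight-line (Euclidean) distance on a projected plane
#'
#' `d^2 = (x1 - x2)^2 + (y1 - y2)^2`, in meters. Vectorised.
#'
#' @param x1,y1,x2,y2 Finite planar coordinates (meters).
#' @return Numeric vector of distances in meters.
#' @export
#' @examples
#' euclidean_distance(0, 0, 3, 4)  # 5
euclidean_distance <- function(x1, y1, x2, y2) {
  v <- cbind(x1, y1, x2, y2)
  if (!all(is.finite(v))) stop_domain("coordinates must be finite.")
  sqrt((x1 - x2)^2 + (y1 - y2)^2)
}

#' Snap points to the nearest network node
#'
#' Each point is mapped to the node minimising Euclidean distance; ties are
#' broken by the lexicographically smallest node id. Snapping to a node (not
#' an interior edge point) approximates the "closest point on the network"
#' of GIS network analysts; synthetic networks can be densified where this
#' matters.
#'
#' @param x,y Planar coordinates of the points (meters), vectorised.
#' @param network A [road_network()].
#' @return Character vector of node ids.
#' @export
snap_to_network <- function(x, y, network) {
  stopifnot(inherits(network, "road_network"))
  if (nrow(network$nodes) == 0) stop_domain("cannot snap to an empty network.")
  if (!all(is.finite(c(x, y)))) stop_domain("coordinates must be finite.")
  nx <- network$nodes$x
  ny <- network$nodes$y
  ids <- network$nodes$node_id
  ord <- order(ids, method = "radix")  # lexicographic tie-break
  vapply(seq_along(x), function(k) {
    d2 <- (nx - x[k])^2 + (ny - y[k])^2
    cand <- ord[d2[ord] <= min(d2) + 0]
    ids[cand[1]]
  }, character(1))
}

#' Shortest-path distance along the road network
#'
#' Minimum total edge length between two nodes (Dijkstra; all weights are
#' positive by construction). Returns 0 when `origin == dest` and `Inf` (the
#' unreachable marker) when the nodes lie in different components — never an
#' exception.
#'
#' @param network A [road_network()].
#' @param origin,dest Node ids (vectorised pairwise).
#' @return Numeric vector of path lengths in meters; `Inf` marks unreachable
#'   pairs.
#' @export
network_distance <- function(network, origin, dest) {
  stopifnot(inherits(network, "road_network"))
  origin <- as.character(origin)
  dest <- as.character(dest)
  unknown <- setdiff(c(origin, dest), network$nodes$node_id)
  if (length(unknown) > 0) {
    stop_domain(paste0("unknown node id(s): ", paste(head(unknown, 5), collapse = ", ")))
  }
  uo <- unique(origin)
  dm <- igraph::distances(network$graph, v = uo, to = unique(dest),
                          weights = igraph::E(network$graph)$weight,
                          algorithm = "dijkstra")
  dm[cbind(match(origin, rownames(dm)), match(dest, colnames(dm)))]
}

#' Annotate a registry with residence-to-injury-site distances
#'
#' Adds `euclidean_m` (straight-line distance between the raw coordinate
#' pairs) and `network_distance_m` (shortest path between the snapped
#' residence and injury nodes), plus a logical `unreachable` flag for pairs
#' whose snapped nodes lie in different network components.
#' `network_distance_m` is `NA` for unreachable pairs, which are counted in
#' attribute `n_unreachable` and reported via a message; they are excluded
#' from distance summaries downstream.
#'
#' @param data Registry tibble with both coordinate pairs.
#' @param network A [road_network()].
#' @return The annotated tibble.
#' @export
annotate_distances <- function(data, network) {
  res_node <- snap_to_network(data$residence_x, data$residence_y, network)
  inj_node <- snap_to_network(data$injury_x, data$injury_y, network)
  nd <- network_distance(network, res_node, inj_node)
  unreachable <- is.infinite(nd)
  out <- data |>
    mutate(
      euclidean_m = euclidean_distance(.data$residence_x, .data$residence_y,
                                       .data$injury_x, .data$injury_y),
      network_distance_m = ifelse(unreachable, NA_real_, nd),
      unreachable = unreachable
    )
  if (any(unreachable)) {
    inform(paste0(sum(unreachable),
                  " record(s) have residence and injury site in disconnected",
                  " network components; network_distance_m set to NA."))
  }
  attr(out, "n_unreachable") <- sum(unreachable)
  out
}
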