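# Road-network file readers: node/edge CSV pair, or GeoJSON LineStrings.

#' Read a road network from node and edge CSV files
#'
#' @param nodes_path CSV with columns `node_id`, `x`, `y`.
#' @param edges_path CSV with columns `from`, `to` (or `node_u`, `node_v`)
#'   and `length_m`.
#' @return A [road_network()].
#' @export
read_road_network <- function(nodes_path, edges_path) {
  nodes <- readr::read_csv(nodes_path, show_col_types = FALSE, progress = FALSE,
                           col_types = readr::cols(node_id = readr::col_character()))
  edges <- readr::read_csv(edges_path, show_col_types = FALSE, progress = FALSE)
  nm <- names(edges)
  nm[nm == "node_u"] <- "from"
  nm[nm == "node_v"] <- "to"
  names(edges) <- nm
  road_network(nodes, edges)
}

#' Read a road network from GeoJSON LineString features
#'
#' Each LineString becomes a chain of edges between consecutive vertices;
#' vertices shared (to 6 decimal places) between features become shared
#' nodes, so crossing roads connect at their common endpoints. Edge lengths
#' are the Euclidean lengths of the segments; coordinates are taken to be
#' planar meters (projection is upstream of this package).
#'
#' @param path GeoJSON file with `LineString` features (a `FeatureCollection`
#'   or a bare geometry list).
#' @return A [road_network()].
#' @export
read_network_geojson <- function(path) {
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features else list(gj)
  coords_list <- lapply(feats, function(f) {
    geom <- if (!is.null(f$geometry)) f$geometry else f
    if (!identical(geom$type, "LineString")) {
      stop_schema(paste0("unsupported GeoJSON geometry: ", geom$type %||% "<missing>"))
    }
    do.call(rbind, lapply(geom$coordinates, function(p) c(p[[1]], p[[2]])))
  })
  key <- function(xy) sprintf("%.6f_%.6f", xy[, 1], xy[, 2])
  all_xy <- do.call(rbind, coords_list)
  keys <- key(all_xy)
  ux <- !duplicated(keys)
  nodes <- tibble(
    node_id = keys[ux],
    x = all_xy[ux, 1],
    y = all_xy[ux, 2]
  )
  edges <- purrr::map_dfr(coords_list, function(xy) {
    k <- key(xy)
    n <- nrow(xy)
    if (n < 2) return(tibble())
    tibble(
      from = k[-n], to = k[-1],
      length_m = sqrt(diff(xy[, 1])^2 + diff(xy[, 2])^2)
    )
  })
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  road_network(nodes, edges)
}
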