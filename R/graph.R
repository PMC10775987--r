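#' Non-metric labeled place graphs
#'
#' A `labeled_graph` is the topological skeleton of a maze - one vertex per
#' corner, one edge per straight segment - labeled with the egomotion
#' measured while walking it: each edge carries the experienced distance
#' `d`, and each ordered triplet of neighboring places (i, j, k) carries the
#' turning angle `alpha` performed at j when traveling i -> j -> k
#' (degrees, CCW-positive, in (-180, 180]). Backtracking triplets (i, j, i)
#' are included with `alpha = 180`. The labels are independent of one
#' another and need not be realizable by any planar configuration; around
#' wormholes they deliberately are not.
#'
#' @param vertices integer vertex ids.
#' @param edges data frame `from`, `to`, `d` (`d` may be `NA` before
#'   [measure_labels()]).
#' @param triplets data frame `i`, `j`, `k`, `alpha`.
#' @param coords optional data frame `id`, `x`, `y` of ground-truth vertex
#'   positions (carried along for reference and for ground-truth
#'   predictions; not used by the embedding).
#' @param wormhole_edges optional data frame `from`, `to` flagging edges
#'   that pass through a wormhole.
#' @return An object of class `labeled_graph`.
#' @export
labeled_graph <- function(vertices, edges, triplets, coords = NULL,
                          wormhole_edges = NULL) {
  edges <- as.data.frame(edges)
  edges$from <- as.integer(edges$from)
  edges$to <- as.integer(edges$to)
  if (is.null(edges$d)) edges$d <- NA_real_
  edges$d <- as.numeric(edges$d)
  triplets <- as.data.frame(triplets)
  if (nrow(triplets)) {
    triplets$i <- as.integer(triplets$i)
    triplets$j <- as.integer(triplets$j)
    triplets$k <- as.integer(triplets$k)
    if (is.null(triplets$alpha)) triplets$alpha <- NA_real_
    triplets$alpha <- as.numeric(triplets$alpha)
  }
  if (!is.null(coords)) {
    coords <- as.data.frame(coords)
    coords$id <- as.integer(coords$id)
    coords$x <- as.numeric(coords$x)
    coords$y <- as.numeric(coords$y)
  }
  if (!is.null(wormhole_edges)) {
    wormhole_edges <- as.data.frame(wormhole_edges)
    wormhole_edges$from <- as.integer(wormhole_edges$from)
    wormhole_edges$to <- as.integer(wormhole_edges$to)
  }
  sw <- edges$from > edges$to
  tmp <- edges$from[sw]; edges$from[sw] <- edges$to[sw]; edges$to[sw] <- tmp
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  structure(
    list(vertices = sort(as.integer(vertices)), edges = edges,
         triplets = as.data.frame(triplets), coords = coords,
         wormhole_edges = wormhole_edges),
    class = "labeled_graph"
  )
}

#' @export
print.labeled_graph <- function(x, ...) {
  cat(sprintf("Labeled graph: %d vertices, %d edges, %d triplets (%d backtracks)\n",
              length(x$vertices), nrow(x$edges), nrow(x$triplets),
              sum(x$triplets$i == x$triplets$k)))
  if (!is.null(x$wormhole_edges) && nrow(x$wormhole_edges))
    cat(sprintf("  %d edge(s) pass through wormholes\n", nrow(x$wormhole_edges)))
  invisible(x)
}

#' Enumerate triplets of neighboring places
#'
#' For every vertex j, every ordered pair of distinct incident edges yields
#' one through-triplet (i, j, k), and every incident edge yields one
#' backtrack triplet (i, j, i). Triplets are returned in lexicographic
#' (i, j, k) order, so enumeration is deterministic.
#'
#' @param graph a [labeled_graph()] with edges.
#' @return The graph with its `triplets` field replaced (labels `NA`).
#' @export
enumerate_triplets <- function(graph) {
  ed <- graph$edges
  nbrs <- lapply(graph$vertices, function(j)
    sort(c(ed$to[ed$from == j], ed$from[ed$to == j])))
  names(nbrs) <- graph$vertices
  out <- list()
  for (jj in seq_along(graph$vertices)) {
    j <- graph$vertices[jj]
    nb <- nbrs[[jj]]
    if (!length(nb)) next
    grid <- expand.grid(i = nb, k = nb)
    thru <- grid[grid$i != grid$k, , drop = FALSE]
    out[[length(out) + 1L]] <-
      data.frame(i = c(thru$i, nb), j = j, k = c(thru$k, nb))
  }
  tr <- do.call(rbind, out)
  tr <- tr[order(tr$i, tr$j, tr$k), , drop = FALSE]
  rownames(tr) <- NULL
  tr$alpha <- NA_real_
  graph$triplets <- tr
  graph
}

#' Measure distance and turn labels in the ground-truth maze
#'
#' Populates edge distances and triplet turn angles from the egomotion
#' returned by [traverse()]. For a Euclidean maze the labels are exactly
#' consistent with the planar coordinates; edges and triplets that span a
#' wormhole carry the locally experienced (teleport-shortened, rotated)
#' values instead. The same labeled graph serves all subjects.
#'
#' @param maze the concrete [maze_spec()] the graph was built from.
#' @param graph a [labeled_graph()] with triplets enumerated.
#' @return The graph with `d` and `alpha` labels filled in.
#' @export
measure_labels <- function(maze, graph) {
  ed <- graph$edges
  for (r in seq_len(nrow(ed)))
    ed$d[r] <- leg_geometry(maze, ed$from[r], ed$to[r])$dist
  graph$edges <- ed
  tr <- graph$triplets
  alpha <- numeric(nrow(tr))
  for (r in seq_len(nrow(tr))) {
    steps <- traverse(maze, c(tr$i[r], tr$j[r], tr$k[r]))
    alpha[r] <- steps$turn[1]
  }
  tr$alpha <- alpha
  graph$triplets <- tr
  graph
}

#' Build the labeled graph of a maze
#'
#' Places one vertex per corner and one edge per straight segment, then
#' enumerates triplets and measures their labels from the egomotion
#' experienced in the requested maze variant. In the wormhole variant,
#' edges through wormholes receive the experienced (shortened but positive)
#' distance and the adjacent turn labels absorb the teleport's rotation;
#' the control variant adds the control-only corners and has no wormholes.
#'
#' @param maze a [maze_spec()] (may describe both variants).
#' @param variant `"wormhole"` or `"control"`; passed to [maze_variant()].
#' @return A fully labeled [labeled_graph()].
#' @export
build_graph <- function(maze, variant = c("wormhole", "control")) {
  variant <- match.arg(variant)
  m <- maze_variant(maze, variant)
  deg <- table(factor(c(m$segments$from, m$segments$to), levels = m$corners$id))
  if (any(deg == 0))
    stop("corner ", names(deg)[deg == 0][1], " has degree 0")
  wh <- NULL
  if (length(m$wormholes))
    wh <- data.frame(
      from = vapply(m$wormholes, function(w) min(w$from, w$to), 0),
      to = vapply(m$wormholes, function(w) max(w$from, w$to), 0))
  g <- labeled_graph(
    vertices = m$corners$id,
    edges = data.frame(from = m$segments$from, to = m$segments$to,
                       d = NA_real_),
    triplets = data.frame(i = integer(), j = integer(), k = integer(),
                          alpha = numeric()),
    coords = data.frame(id = m$corners$id, x = m$corners$x, y = m$corners$y),
    wormhole_edges = wh
  )
  g <- enumerate_triplets(g)
  measure_labels(m, g)
}

#' Read and write labeled graphs as JSON
#'
#' Serializes `vertices`, `edges` (with `d`), `triplets` (with `alpha_deg`)
#' and, when present, ground-truth coordinates; numbers are written at full
#' precision so the graph round-trips exactly.
#'
#' @param graph a [labeled_graph()].
#' @param path file path.
#' @export
write_graph_json <- function(graph, path) {
  tr <- graph$triplets
  names(tr)[names(tr) == "alpha"] <- "alpha_deg"
  doc <- list(vertices = graph$vertices, edges = graph$edges, triplets = tr,
              coords = graph$coords, wormhole_edges = graph$wormhole_edges)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       dataframe = "rows", null = "null")
  invisible(path)
}

#' @rdname write_graph_json
#' @export
read_graph_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = TRUE)
  tr <- doc$triplets
  names(tr)[names(tr) == "alpha_deg"] <- "alpha"
  labeled_graph(doc$vertices, doc$edges, tr, coords = doc$coords,
                wormhole_edges = doc$wormhole_edges)
}
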