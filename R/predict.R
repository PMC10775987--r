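#' Shortest path by distance labels
#'
#' Dijkstra shortest path on the labeled graph using the edge distance
#' labels as weights. Among equal-cost paths the lexicographically smallest
#' vertex sequence is returned, so results are reproducible.
#'
#' @param graph a [labeled_graph()].
#' @param a,b vertex ids.
#' @return Integer vector of vertex ids from `a` to `b` (`c(a)` if
#'   `a == b`), with the total label cost in attribute `"cost"`.
#' @export
shortest_path <- function(graph, a, b) {
  a <- as.integer(a); b <- as.integer(b)
  if (!all(c(a, b) %in% graph$vertices)) stop("vertex not in graph")
  if (a == b) return(structure(a, cost = 0))
  ig <- igraph::graph_from_data_frame(
    graph$edges[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = graph$vertices))
  sp <- suppressWarnings(
    igraph::all_shortest_paths(ig, from = as.character(a),
                               to = as.character(b),
                               weights = graph$edges$d))
  if (!length(sp$vpaths)) stop("vertex ", b, " is unreachable from ", a)
  paths <- lapply(sp$vpaths, function(p) as.integer(names(p)))
  if (length(paths) > 1) {
    key <- vapply(paths, function(p)
      paste(formatC(p, width = 9, flag = "0"), collapse = ","), "")
    paths <- paths[order(key)]
  }
  path <- paths[[1]]
  dkey <- paste(graph$edges$from, graph$edges$to)
  cost <- sum(graph$edges$d[match(
    paste(pmin(path[-length(path)], path[-1]),
          pmax(path[-length(path)], path[-1])), dkey)])
  structure(path, cost = cost)
}

triplet_alpha <- function(graph, i, j, k) {
  tr <- graph$triplets
  m <- which(tr$i == i & tr$j == j & tr$k == k)
  if (!length(m)) stop("missing triplet label (", i, ", ", j, ", ", k, ")")
  tr$alpha[m[1]]
}

#' Vector addition along a graph path
#'
#' Dead-reckons along a path using only the graph's labels: start at the
#' origin facing `start_heading`, advance each edge's distance label, and
#' rotate by the triplet turn label at each interior vertex. The resultant
#' displacement is the labeled graph's belief about where the path ends.
#' On a graph whose labels are consistent with a planar layout the result
#' is path-independent; across wormhole edges it is not.
#'
#' @param graph a [labeled_graph()].
#' @param path integer vertex sequence (consecutive pairs must be edges,
#'   consecutive triples labeled triplets).
#' @param start_heading initial heading in degrees CCW from east.
#' @return Numeric length-2 displacement.
#' @export
path_vector <- function(graph, path, start_heading = 0) {
  path <- as.integer(path)
  if (length(path) < 2) stop("path needs at least two vertices")
  dkey <- paste(graph$edges$from, graph$edges$to)
  h <- start_heading
  v <- c(0, 0)
  for (t in seq_len(length(path) - 1L)) {
    a <- path[t]; b <- path[t + 1L]
    d <- graph$edges$d[match(paste(min(a, b), max(a, b)), dkey)]
    if (is.na(d)) stop("path step ", a, "-", b, " is not an edge")
    v <- v + d * c(cos(deg2rad(h)), sin(deg2rad(h)))
    if (t < length(path) - 1L)
      h <- h + triplet_alpha(graph, a, b, path[t + 2L])
  }
  v
}

## ground-truth orientation of the arm leaving vertex s1 toward s2
arm_orientation <- function(maze, s1, s2) leg_geometry(maze, s1, s2)$h_start

#' Shortcut prediction of the non-metric labeled graph
#'
#' Finds the shortest path from `a` to `b` by distance labels, sums the
#' labels along it into a resultant vector ([path_vector()]), seeded with
#' the ground-truth orientation of the first path arm, and returns the
#' global direction of that resultant as the model's shortcut prediction.
#'
#' @param graph a [labeled_graph()].
#' @param maze the concrete [maze_spec()] the graph was measured in (used
#'   only for the first arm's ground-truth orientation).
#' @param a,b start and goal vertex ids (must differ).
#' @return A one-row data frame: `model`, `start`, `goal`,
#'   `direction_global` (degrees in [0, 360)), `length`, `path`
#'   (dash-separated vertex ids).
#' @export
predict_nonmetric <- function(graph, maze, a, b) {
  if (a == b) stop("start and goal coincide; shortcut direction undefined")
  path <- shortest_path(graph, a, b)
  h0 <- arm_orientation(maze, path[1], path[2])
  v <- path_vector(graph, path, start_heading = h0)
  len <- sqrt(sum(v^2))
  if (len == 0) stop("zero resultant vector; shortcut direction undefined")
  data.frame(model = "nonmetric", start = a, goal = b,
             direction_global = vec_dir(v[1], v[2]), length = len,
             path = paste(path, collapse = "-"))
}

#' Shortcut prediction of the embedded graph
#'
#' In the embedded model a shortcut is simply the straight line between the
#' embedded start and goal positions. The returned global direction lives
#' in the embedding's own (arbitrary) frame; comparisons must therefore go
#' through the local reference frame, see [to_local_reference()].
#'
#' @param X coordinate matrix with vertex-id row names, or a
#'   `cogmap_embedding` (best minimum used).
#' @param a,b start and goal vertex ids.
#' @return A one-row data frame as in [predict_nonmetric()] (`path` is
#'   `NA`).
#' @export
predict_embedded <- function(X, a, b) {
  if (inherits(X, "cogmap_embedding")) X <- coef(X)
  i1 <- match(as.character(a), rownames(X))
  i2 <- match(as.character(b), rownames(X))
  if (is.na(i1) || is.na(i2)) stop("vertex not embedded")
  v <- X[i2, ] - X[i1, ]
  len <- sqrt(sum(v^2))
  if (len == 0) stop("start and goal have coincident embedded positions")
  data.frame(model = "embedded", start = a, goal = b,
             direction_global = vec_dir(v[1], v[2]), length = len,
             path = NA_character_)
}

#' Shortcut prediction of the Euclidean ground truth
#'
#' The straight-line direction between the ground-truth vertex positions.
#'
#' @param maze a concrete [maze_spec()].
#' @param a,b start and goal corner ids.
#' @return A one-row data frame as in [predict_nonmetric()].
#' @export
predict_ground_truth <- function(maze, a, b) {
  pa <- corner_xy(maze, a); pb <- corner_xy(maze, b)
  v <- pb - pa
  len <- sqrt(sum(v^2))
  if (len == 0) stop("start and goal coincide")
  data.frame(model = "ground_truth", start = a, goal = b,
             direction_global = vec_dir(v[1], v[2]), length = len,
             path = NA_character_)
}

#' Express a direction in the local reference frame of the starting arm
#'
#' Because the embedded graph has no defined global reference direction,
#' measurements and predictions are compared as local angles relative to
#' the maze arm the walker starts on. The local angle is the signed
#' difference between the direction and the starting arm's orientation,
#' normalized to (-180, 180]; it is invariant under a common rotation of
#' both arguments.
#'
#' @param direction direction(s) in degrees.
#' @param start_arm_orientation orientation(s) of the starting arm, in the
#'   same frame as `direction`.
#' @return Signed local angle(s) in (-180, 180].
#' @export
to_local_reference <- function(direction, start_arm_orientation) {
  wrap180(direction - start_arm_orientation)
}

#' Shortcut predictions for a set of object pairs under several models
#'
#' Resolves objects to graph vertices (snapping mid-segment objects to the
#' nearest endpoint), derives each model's shortcut prediction, and
#' expresses it in the local reference frame of the starting arm: for the
#' non-metric and ground-truth models the arm's ground-truth orientation,
#' for the embedded model the embedded direction toward the same
#' shortest-path successor - so all models are referred to the same
#' physical arm.
#'
#' @param graph a [labeled_graph()] of the maze.
#' @param maze the concrete [maze_spec()] (with objects, if `pairs` uses
#'   object ids).
#' @param pairs data frame with columns `start`, `goal`: object ids
#'   (character) or vertex ids (numeric).
#' @param X embedding coordinates (or `cogmap_embedding`); required for the
#'   embedded model.
#' @param models subset of `c("nonmetric", "embedded", "ground_truth")`.
#' @return Data frame: `model`, `start`, `goal`, `start_vertex`,
#'   `goal_vertex`, `direction_global`, `direction_local`, `length`,
#'   `path`, `start_arm_global` (the arm orientation used, in the model's
#'   own frame) and `start_arm_gt` (its ground-truth orientation, the
#'   frame measured estimates are referred to).
#' @export
shortcut_predictions <- function(graph, maze, pairs, X = NULL,
                                 models = c("nonmetric", "embedded",
                                            "ground_truth")) {
  models <- match.arg(models, several.ok = TRUE)
  if (!is.null(X) && inherits(X, "cogmap_embedding")) X <- coef(X)
  if ("embedded" %in% models && is.null(X))
    stop("the embedded model needs embedding coordinates `X`")
  as_vertex <- function(z) {
    if (is.character(z) || is.factor(z))
      vapply(as.character(z), function(o) object_vertex(maze, o), 0L)
    else as.integer(z)
  }
  sv <- as_vertex(pairs$start)
  gv <- as_vertex(pairs$goal)
  out <- list()
  for (r in seq_len(nrow(pairs))) {
    a <- sv[r]; b <- gv[r]
    path <- shortest_path(graph, a, b)
    succ <- path[2]
    arm_gt <- arm_orientation(maze, a, succ)
    for (mod in models) {
      pr <- switch(mod,
        nonmetric = predict_nonmetric(graph, maze, a, b),
        embedded = predict_embedded(X, a, b),
        ground_truth = predict_ground_truth(maze, a, b))
      arm <- if (mod == "embedded") {
        i1 <- match(as.character(a), rownames(X))
        i2 <- match(as.character(succ), rownames(X))
        v <- X[i2, ] - X[i1, ]
        if (sum(v^2) == 0) stop("degenerate embedded starting arm")
        vec_dir(v[1], v[2])
      } else arm_gt
      pr$start <- pairs$start[r]; pr$goal <- pairs$goal[r]
      pr$start_vertex <- a; pr$goal_vertex <- b
      pr$direction_local <- to_local_reference(pr$direction_global, arm)
      pr$start_arm_global <- arm
      pr$start_arm_gt <- arm_gt
      out[[length(out) + 1L]] <- pr
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("model", "start", "goal", "start_vertex", "goal_vertex",
          "direction_global", "direction_local", "length", "path",
          "start_arm_global", "start_arm_gt")]
}

#' @param object a `cogmap_embedding`.
#' @param pairs data frame with `start`, `goal` columns (objects or vertex
#'   ids).
#' @param maze the concrete maze the graph was measured in.
#' @param minimum which local minimum to use.
#' @rdname embed_graph
#' @export
predict.cogmap_embedding <- function(object, pairs, maze, minimum = 1, ...) {
  shortcut_predictions(object$graph, maze, pairs,
                       X = coef(object, minimum = minimum),
                       models = "embedded")
}

#' Write or read a shortcut-prediction table as CSV
#'
#' Columns: `model,start,goal,direction_deg_global,direction_deg_local,length,path`.
#' @param predictions data frame from [shortcut_predictions()].
#' @param path file path.
#' @export
write_predictions_csv <- function(predictions, path) {
  out <- data.frame(model = predictions$model,
                    start = predictions$start, goal = predictions$goal,
                    direction_deg_global = predictions$direction_global,
                    direction_deg_local = predictions$direction_local,
                    length = predictions$length, path = predictions$path)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_predictions_csv
#' @export
read_predictions_csv <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  data.frame(model = x$model, start = x$start, goal = x$goal,
             direction_global = x$direction_deg_global,
             direction_local = x$direction_deg_local,
             length = x$length, path = x$path)
}
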