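#' Generate a random Euclidean corridor maze
#'
#' Grows a connected rectilinear corridor maze on a unit grid: starting
#' from the origin, grid cells are attached one at a time at random
#' frontier positions (yielding a corridor tree), then a fraction of the
#' remaining adjacent cell pairs are joined to create loops. The result is
#' a planar, wormhole-free maze whose labeled graph is exactly consistent
#' with its coordinates, so it embeds at (numerically) zero stress.
#'
#' @param seed integer seed; the maze is reproducible given the seed.
#' @param n_corners number of corners (grid cells), >= 2.
#' @param loop_prob probability of adding each feasible loop edge between
#'   adjacent grown cells (default 0.15).
#' @param n_objects number of objects to place on distinct random corners
#'   (default 0). Objects are named `"O1"`, `"O2"`, ...
#' @return A validated [maze_spec()] without wormholes.
#' @export
make_euclidean_maze <- function(seed, n_corners = 30, loop_prob = 0.15,
                                n_objects = 0) {
  if (n_corners < 2) stop("need at least two corners")
  set.seed(seed)
  key <- function(p) paste(p[1], p[2])
  cells <- list(c(0, 0))
  have <- key(c(0, 0))
  segs <- list()
  dirs <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  while (length(cells) < n_corners) {
    i <- sample.int(length(cells), 1)
    d <- dirs[sample.int(4, 1), ]
    cand <- cells[[i]] + d
    if (!(key(cand) %in% have)) {
      cells[[length(cells) + 1L]] <- cand
      have <- c(have, key(cand))
      segs[[length(segs) + 1L]] <- c(i, length(cells))
    }
  }
  # optional loop edges between adjacent cells not already joined
  seg_key <- vapply(segs, function(s) paste(min(s), max(s)), "")
  for (i in seq_along(cells)) {
    for (di in 1:4) {
      j <- match(key(cells[[i]] + dirs[di, ]), have)
      if (!is.na(j) && i < j &&
          !(paste(i, j) %in% seg_key) &&
          stats::runif(1) < loop_prob) {
        segs[[length(segs) + 1L]] <- c(i, j)
        seg_key <- c(seg_key, paste(i, j))
      }
    }
  }
  xy <- do.call(rbind, cells)
  corners <- data.frame(id = seq_along(cells), x = xy[, 1], y = xy[, 2])
  segments <- data.frame(from = vapply(segs, `[`, 0, 1),
                         to = vapply(segs, `[`, 0, 2))
  objects <- NULL
  if (n_objects > 0) {
    if (n_objects > n_corners) stop("more objects than corners")
    objects <- data.frame(object = paste0("O", seq_len(n_objects)),
                          corner = sample(corners$id, n_objects))
  }
  validate_maze(maze_spec(corners, segments, objects = objects))
}

replica_corners <- function() {
  xy <- matrix(c(
    0,0,  2,0,  3,0,  5,0,  6,0,  8,0,
    0,2,  1,1,  3,1,  6,1,  7,1,  6,6,
    8,2,  7,2,  0,3,  1,3,  3,2,  4,2,
    7,3,  8,3,  3,4,  4,4,  5,4,  2,4,
    0,5,  2,5,  4,5,  5,5,  7,5,  8,5,
    2,6,  6,2,  1,7,  3,7,  8,8,
    7,7,  4,7,  0,8,  1,8,  3,8,  5,8,  6,8
  ), ncol = 2, byrow = TRUE)
  data.frame(id = seq_len(nrow(xy)), x = xy[, 1], y = xy[, 2],
             control = seq_len(nrow(xy)) %in% c(12L, 35L))
}

replica_segments <- function() {
  both <- matrix(c(
    1,2, 2,3, 3,4, 4,5, 5,6,            # south wall
    1,7, 7,15, 15,25, 25,38,            # west wall
    6,13, 13,20, 20,30,                 # east wall (lower)
    38,39, 39,40, 40,41, 41,42,         # north wall
    2,24, 24,26, 26,31,                 # x = 2 corridor up to wormhole mouth
    4,23, 23,22, 22,21, 21,17, 17,18,   # central hook
    25,26,                              # west link into x = 2 corridor
    32,10, 10,5,                        # x = 6 corridor below wormhole mouth
    40,34, 34,33,                       # upper-left hook
    20,19, 19,14, 14,11,                # east inner corridor
    18,22, 22,27,                       # central risers
    8,16, 16,15,                        # south-west hook
    30,29, 29,36, 36,37,                # east upper corridor
    24,21,                              # central link
    23,28,                              # stub to statue corner
    39,33,                              # top-left riser
    3,9,                                # stub to plant corner
    11,10,                              # bottom-right link
    13,14                               # east inner link
  ), ncol = 2, byrow = TRUE)
  ctrl <- matrix(c(31,12, 12,32, 30,35, 35,42), ncol = 2, byrow = TRUE)
  worm <- matrix(c(31,32, 30,42), ncol = 2, byrow = TRUE)
  data.frame(from = c(both[, 1], ctrl[, 1], worm[, 1]),
             to = c(both[, 2], ctrl[, 2], worm[, 2]),
             variant = c(rep("both", nrow(both)),
                         rep("control", nrow(ctrl)),
                         rep("wormhole", nrow(worm))))
}

#' The schematic wormhole-maze replica
#'
#' A 42-corner unit-grid corridor maze emulating the structure of the
#' wormhole-maze experiments: 40 navigation corners plus two corners (ids
#' 12 and 35) used only in the wormhole-free control layout, and two
#' wormholes - seamless teleports with a 90-degree rotation - spliced into
#' corridors of the wormhole layout. Each wormhole shortens the
#' experienced distance of its corridor (to 2 length units) without making
#' it zero, and its rotation is absorbed by the adjacent turn labels, so
#' the measured labeled graph is not realizable by any planar
#' configuration. Eleven named objects sit at corners; see
#' [study_design()] for the measurement rosters built on them.
#'
#' The layout is deliberately schematic: corridor lengths are unit-grid
#' and the wormhole placement qualitative, since no exact coordinates of
#' the original maze are published.
#'
#' @param seed ignored; the replica is deterministic. Present so maze
#'   generators share one interface.
#' @return A validated two-variant [maze_spec()]; use [maze_variant()] or
#'   [build_graph()]'s `variant` argument to pick a layout.
#' @export
make_wormhole_replica <- function(seed = NULL) {
  wormholes <- list(
    list(from = 31L, to = 32L,
         entry = list(x = 3, y = 6, heading = 0),
         exit = list(x = 6, y = 3, heading = 270),
         rotation = -90),
    list(from = 30L, to = 42L,
         entry = list(x = 8, y = 6, heading = 90),
         exit = list(x = 7, y = 8, heading = 180),
         rotation = 90)
  )
  objects <- data.frame(
    object = c("chair", "plant", "lamp", "ball", "clock", "vase",
               "book", "shoe", "well", "statue", "gate"),
    corner = c(8L, 9L, 10L, 13L, 26L, 27L, 33L, 37L, 29L, 28L, 15L))
  validate_maze(maze_spec(replica_corners(), replica_segments(),
                          wormholes, objects))
}

#' Measurement designs for shortcut-estimate tables
#'
#' Describes the structure of a directional-estimate dataset: how many
#' subjects and which ordered object pairs each subject estimates.
#' `"route_finding"` is 10 subjects by 4 object pairs, both directions
#' (80 measurements); `"rips_folds"` is 11 subjects by 8 starting objects
#' by 3 targets (264 measurements). Default rosters use the replica maze's
#' objects; `"custom"` takes any roster.
#'
#' @param tag one of `"route_finding"`, `"rips_folds"`, `"custom"`.
#' @param n_subjects number of subjects (defaults per design).
#' @param pairs for `"custom"` (or to override a default roster): data
#'   frame with `start`, `goal` columns of object ids.
#' @return List of class `study_design`: `tag`, `n_subjects`, `pairs`
#'   (ordered roster each subject measures once), `n_measurements`.
#' @export
study_design <- function(tag = c("route_finding", "rips_folds", "custom"),
                         n_subjects = NULL, pairs = NULL) {
  tag <- match.arg(tag)
  if (tag == "route_finding") {
    if (is.null(n_subjects)) n_subjects <- 10L
    if (is.null(pairs)) {
      base <- data.frame(
        start = c("clock", "book", "ball", "chair"),
        goal = c("lamp", "well", "shoe", "vase"))
      pairs <- rbind(base, data.frame(start = base$goal, goal = base$start))
    }
  } else if (tag == "rips_folds") {
    if (is.null(n_subjects)) n_subjects <- 11L
    if (is.null(pairs)) {
      starts <- c("chair", "plant", "lamp", "ball", "clock", "vase",
                  "book", "shoe")
      targets <- c("well", "statue", "gate")
      pairs <- expand.grid(start = starts, goal = targets,
                           KEEP.OUT.ATTRS = FALSE,
                           stringsAsFactors = FALSE)
    }
  } else {
    if (is.null(n_subjects) || is.null(pairs))
      stop("custom designs need n_subjects and pairs")
  }
  pairs <- as.data.frame(pairs)
  structure(list(tag = tag, n_subjects = as.integer(n_subjects),
                 pairs = pairs,
                 n_measurements = as.integer(n_subjects) * nrow(pairs)),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("Study design '%s': %d subjects x %d pairs = %d measurements\n",
              x$tag, x$n_subjects, nrow(x$pairs), x$n_measurements))
  invisible(x)
}

#' Generate a synthetic directional-estimate table
#'
#' Simulates subjects whose shortcut estimates scatter around a generative
#' model's predictions with von Mises angular noise: each measurement is
#' the model's predicted global direction plus a von Mises(0,
#' `kappa_within`) deviate, optionally offset by a per-subject von
#' Mises(0, `kappa_between`) bias (off by default, i.e. infinite
#' concentration). Non-finite concentrations give the noiseless limit.
#'
#' @param predictions data frame with `start`, `goal`,
#'   `direction_global` covering every pair of the design (e.g. one
#'   model's rows from [shortcut_predictions()]).
#' @param design a [study_design()].
#' @param kappa_within within-subject von Mises concentration.
#' @param seed integer seed.
#' @param kappa_between concentration of the per-subject bias (default
#'   `Inf`: no bias).
#' @return Data frame of class `estimate_table` with columns `subject`,
#'   `start`, `goal`, `estimate_deg` (degrees in [0, 360)), and
#'   attributes `design`, `kappa_within`, `kappa_between`, `seed`.
#' @export
generate_estimates <- function(predictions, design, kappa_within = 4,
                               seed = 1, kappa_between = Inf) {
  stopifnot(inherits(design, "study_design"), kappa_within >= 0)
  pk <- paste(predictions$start, predictions$goal)
  dk <- paste(design$pairs$start, design$pairs$goal)
  miss <- setdiff(dk, pk)
  if (length(miss))
    stop("no prediction for design pair ", miss[1])
  i <- match(dk, pk)
  # express the prediction as a world-frame direction: some models (the
  # embedded graph) predict in their own arbitrary frame, so transport
  # through the local angle at the ground-truth starting arm
  mu <- if (all(c("direction_local", "start_arm_gt") %in% names(predictions)))
    wrap360(predictions$start_arm_gt[i] + predictions$direction_local[i])
  else predictions$direction_global[i]
  set.seed(seed)
  rows <- list()
  for (s in seq_len(design$n_subjects)) {
    bias <- if (is.finite(kappa_between))
      wrap180(rvonmises(1, 0, kappa_between)) else 0
    est <- vapply(mu, function(m)
      rvonmises(1, m + bias, kappa_within), 0)
    rows[[s]] <- data.frame(subject = sprintf("S%02d", s),
                            start = design$pairs$start,
                            goal = design$pairs$goal,
                            estimate_deg = est)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, design = design$tag, kappa_within = kappa_within,
            kappa_between = kappa_between, seed = seed,
            class = c("estimate_table", "data.frame"))
}

#' @param object a `cogmap_embedding`.
#' @param nsim number of estimate tables to draw.
#' @param seed integer seed (tables use `seed`, `seed + 1`, ...).
#' @param maze,design,kappa_within,kappa_between passed to
#'   [shortcut_predictions()] and [generate_estimates()]: synthetic
#'   subjects scatter around this embedding's shortcut predictions.
#' @rdname embed_graph
#' @export
simulate.cogmap_embedding <- function(object, nsim = 1, seed = 1, maze,
                                      design, kappa_within = 4,
                                      kappa_between = Inf, minimum = 1, ...) {
  preds <- shortcut_predictions(object$graph, maze, design$pairs,
                                X = coef(object, minimum = minimum),
                                models = "embedded")
  out <- lapply(seq_len(nsim), function(i)
    generate_estimates(preds, design, kappa_within = kappa_within,
                       seed = seed + i - 1L, kappa_between = kappa_between))
  if (nsim == 1) out[[1]] else out
}

#' Write or read an estimate table as CSV
#'
#' The table round-trips losslessly: columns
#' `subject,start,goal,estimate_deg`, full numeric precision, plus an
#' optional JSON metadata sidecar (`<path>.json`) recording the design and
#' generation parameters.
#'
#' @param estimates an `estimate_table` (or any data frame with the four
#'   columns).
#' @param path file path.
#' @param sidecar write the metadata sidecar? (default `TRUE` when the
#'   table carries generation attributes).
#' @export
write_estimates_csv <- function(estimates, path,
                                sidecar = !is.null(attr(estimates, "seed"))) {
  df <- as.data.frame(estimates)[, c("subject", "start", "goal",
                                     "estimate_deg")]
  df$estimate_deg <- formatC(df$estimate_deg, digits = 17, format = "g")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  if (sidecar) {
    meta <- list(design = attr(estimates, "design"),
                 kappa_within = attr(estimates, "kappa_within"),
                 kappa_between = attr(estimates, "kappa_between"),
                 seed = attr(estimates, "seed"))
    jsonlite::write_json(meta, paste0(path, ".json"), digits = NA,
                         auto_unbox = TRUE, null = "null")
  }
  invisible(path)
}

#' @rdname write_estimates_csv
#' @export
read_estimates_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "start", "goal", "estimate_deg")
  if (!all(need %in% names(df)))
    stop("estimate CSV must have columns ", paste(need, collapse = ", "))
  meta_path <- paste0(path, ".json")
  out <- df[, need]
  class(out) <- c("estimate_table", "data.frame")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    attr(out, "design") <- meta$design
    attr(out, "kappa_within") <- meta$kappa_within
    attr(out, "kappa_between") <- meta$kappa_between
    attr(out, "seed") <- meta$seed
  }
  out
}
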