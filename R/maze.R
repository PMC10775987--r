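#' Maze specifications
#'
#' A maze specification (`maze_spec`) describes a planar corridor maze as the
#' walker encounters it: corner points, straight corridor segments between
#' corners, optional wormholes (seamless teleports with a rotation, which make
#' the environment non-Euclidean), and named object locations.
#'
#' Coordinates are planar ground-truth positions in arbitrary length units.
#' Headings and rotations are degrees counterclockwise from east.
#'
#' A specification can describe two variants of the same environment at once:
#' corners flagged `control` exist only in the wormhole-free control layout,
#' and each segment carries a `variant` tag (`"both"`, `"control"` or
#' `"wormhole"`). Use [maze_variant()] to obtain a concrete single-variant
#' maze; plain Euclidean mazes use `variant = "both"` throughout and are their
#' own concrete maze.
#'
#' @param corners data frame with columns `id` (unique integer), `x`, `y`,
#'   and optionally `control` (logical, default `FALSE`).
#' @param segments data frame with columns `from`, `to` (corner ids) and
#'   optionally `variant` (one of `"both"`, `"control"`, `"wormhole"`;
#'   default `"both"`).
#' @param wormholes optional list of wormhole records. Each record is a list
#'   with elements `from`, `to` (the corner pair of the segment the wormhole
#'   lives on), `entry` and `exit` (each `list(x =, y =, heading =)`:
#'   the teleport poses on the corridor stubs leaving `from` and entering
#'   `to`), and `rotation` (degrees; the heading change applied by the
#'   teleport but never experienced by the walker).
#' @param objects optional data frame with columns `object` (character id)
#'   and either `corner` (corner id) or `from`, `to`, `frac` (position at
#'   fraction `frac` along the segment `from`-`to`).
#' @return An object of class `maze_spec`.
#' @seealso [validate_maze()], [traverse()], [build_graph()]
#' @export
maze_spec <- function(corners, segments, wormholes = list(), objects = NULL) {
  corners <- as.data.frame(corners)
  segments <- as.data.frame(segments)
  if (is.null(corners$control)) corners$control <- FALSE
  if (is.null(segments$variant)) segments$variant <- "both"
  corners$id <- as.integer(corners$id)
  corners$x <- as.numeric(corners$x)
  corners$y <- as.numeric(corners$y)
  corners$control <- as.logical(corners$control)
  segments$from <- as.integer(segments$from)
  segments$to <- as.integer(segments$to)
  wormholes <- lapply(wormholes, function(w)
    list(from = as.integer(w$from), to = as.integer(w$to),
         entry = lapply(w$entry[c("x", "y", "heading")], as.numeric),
         exit = lapply(w$exit[c("x", "y", "heading")], as.numeric),
         rotation = as.numeric(w$rotation)))
  if (!is.null(objects)) {
    objects <- as.data.frame(objects)
    if (is.null(objects$corner)) objects$corner <- NA_integer_
  }
  structure(
    list(corners = corners, segments = segments,
         wormholes = wormholes, objects = objects),
    class = "maze_spec"
  )
}

#' @export
print.maze_spec <- function(x, ...) {
  nc <- nrow(x$corners)
  cat(sprintf("Maze: %d corners (%d control-only), %d segments, %d wormholes, %d objects\n",
              nc, sum(x$corners$control), nrow(x$segments),
              length(x$wormholes),
              if (is.null(x$objects)) 0L else nrow(x$objects)))
  invisible(x)
}

corner_xy <- function(maze, id) {
  i <- match(id, maze$corners$id)
  c(maze$corners$x[i], maze$corners$y[i])
}

#' Validate a maze specification
#'
#' Checks referential integrity (unique corner ids, segments and objects
#' referring to existing corners), geometry (distinct segment endpoints with
#' nonzero length, wormhole poses lying on their corridor stubs with a
#' rotation consistent with the entry/exit headings), and connectivity of
#' each concrete variant's segment network.
#'
#' @param spec a [maze_spec()].
#' @return `spec`, invisibly unchanged, if valid; otherwise an error naming
#'   the offending element.
#' @export
validate_maze <- function(spec) {
  stopifnot(inherits(spec, "maze_spec"))
  co <- spec$corners
  if (anyDuplicated(co$id))
    stop("duplicate corner id: ", co$id[duplicated(co$id)][1])
  if (any(!is.finite(co$x)) || any(!is.finite(co$y)))
    stop("non-finite corner coordinate")
  seg <- spec$segments
  bad <- setdiff(c(seg$from, seg$to), co$id)
  if (length(bad))
    stop("segment references unknown corner id: ", bad[1])
  if (any(seg$from == seg$to))
    stop("degenerate segment with identical endpoints at corner ",
         seg$from[seg$from == seg$to][1])
  key <- paste(pmin(seg$from, seg$to), pmax(seg$from, seg$to))
  if (anyDuplicated(key))
    stop("duplicate segment: ", key[duplicated(key)][1])
  lens <- sqrt((co$x[match(seg$from, co$id)] - co$x[match(seg$to, co$id)])^2 +
               (co$y[match(seg$from, co$id)] - co$y[match(seg$to, co$id)])^2)
  wseg <- vapply(spec$wormholes, function(w)
    paste(pmin(w$from, w$to), pmax(w$from, w$to)), "")
  plain <- !(key %in% wseg)
  if (any(plain & lens <= 0))
    stop("zero-length segment: ", key[plain & lens <= 0][1])
  for (w in spec$wormholes) {
    if (!all(c(w$from, w$to) %in% co$id))
      stop("wormhole references unknown corner")
    if (!paste(pmin(w$from, w$to), pmax(w$from, w$to)) %in% key)
      stop("wormhole not attached to an existing segment: ",
           w$from, "-", w$to)
    if (!is.finite(w$rotation)) stop("non-finite wormhole rotation")
    a <- corner_xy(spec, w$from); b <- corner_xy(spec, w$to)
    din <- c(w$entry$x, w$entry$y) - a
    dout <- b - c(w$exit$x, w$exit$y)
    if (sum(din^2) == 0 || sum(dout^2) == 0)
      stop("wormhole entry/exit pose coincides with a corner")
    h_in <- vec_dir(din[1], din[2]); h_out <- vec_dir(dout[1], dout[2])
    if (abs(wrap180(h_in - w$entry$heading)) > 1e-6)
      stop("wormhole entry heading inconsistent with its corridor stub")
    if (abs(wrap180(h_out - w$exit$heading)) > 1e-6)
      stop("wormhole exit heading inconsistent with its corridor stub")
    if (abs(wrap180(w$rotation - (h_out - h_in))) > 1e-6)
      stop("wormhole rotation inconsistent with entry/exit headings")
  }
  if (!is.null(spec$objects)) {
    for (r in seq_len(nrow(spec$objects))) {
      ob <- spec$objects[r, ]
      if (!is.na(ob$corner)) {
        if (!ob$corner %in% co$id)
          stop("object '", ob$object, "' references unknown corner ", ob$corner)
      } else {
        if (is.null(spec$objects$from) ||
            !paste(pmin(ob$from, ob$to), pmax(ob$from, ob$to)) %in% key)
          stop("object '", ob$object, "' does not resolve to a segment")
        if (ob$frac < 0 || ob$frac > 1)
          stop("object '", ob$object, "' has position fraction outside [0, 1]")
      }
    }
  }
  for (v in c("wormhole", "control")) {
    m <- maze_variant(spec, v)
    if (nrow(m$segments) == 0L) next
    deg <- table(factor(c(m$segments$from, m$segments$to),
                        levels = m$corners$id))
    if (any(deg == 0))
      stop("disconnected maze: corner ", names(deg)[deg == 0][1],
           " has no segment (", v, " variant)")
    g <- igraph::graph_from_data_frame(
      m$segments[, c("from", "to")], directed = FALSE,
      vertices = data.frame(name = m$corners$id))
    if (igraph::components(g)$no > 1)
      stop("disconnected maze: the ", v,
           " variant's segment network has multiple components")
  }
  invisible(spec)
}

#' Extract a concrete maze variant
#'
#' @param spec a [maze_spec()].
#' @param variant `"wormhole"` (drops control-only corners and control
#'   segments, keeps wormholes) or `"control"` (keeps all corners, drops
#'   wormhole-only segments and all wormholes).
#' @return A concrete `maze_spec` containing a single layout.
#' @export
maze_variant <- function(spec, variant = c("wormhole", "control")) {
  variant <- match.arg(variant)
  co <- spec$corners; seg <- spec$segments
  if (variant == "wormhole") {
    co <- co[!co$control, , drop = FALSE]
    seg <- seg[seg$variant %in% c("both", "wormhole"), , drop = FALSE]
    wh <- spec$wormholes
  } else {
    seg <- seg[seg$variant %in% c("both", "control"), , drop = FALSE]
    wh <- list()
  }
  maze_spec(co, seg, wh, spec$objects)
}

## wormhole attached to the unordered corner pair {a, b}, or NULL
find_wormhole <- function(maze, a, b) {
  for (w in maze$wormholes)
    if ((w$from == a && w$to == b) || (w$from == b && w$to == a)) return(w)
  NULL
}

## one leg of a route: experienced distance plus true start/end headings
leg_geometry <- function(maze, a, b) {
  pa <- corner_xy(maze, a); pb <- corner_xy(maze, b)
  w <- find_wormhole(maze, a, b)
  if (is.null(w)) {
    d <- sqrt(sum((pb - pa)^2))
    h <- vec_dir(pb[1] - pa[1], pb[2] - pa[2])
    return(list(dist = d, h_start = h, h_end = h))
  }
  en <- c(w$entry$x, w$entry$y); ex <- c(w$exit$x, w$exit$y)
  pf <- corner_xy(maze, w$from); pt <- corner_xy(maze, w$to)
  d <- sqrt(sum((en - pf)^2)) + sqrt(sum((pt - ex)^2))
  if (a == w$from) {
    list(dist = d,
         h_start = vec_dir(en[1] - pf[1], en[2] - pf[2]),
         h_end = vec_dir(pt[1] - ex[1], pt[2] - ex[2]))
  } else {
    list(dist = d,
         h_start = vec_dir(ex[1] - pt[1], ex[2] - pt[2]),
         h_end = vec_dir(pf[1] - en[1], pf[2] - en[2]))
  }
}

segment_exists <- function(maze, a, b) {
  any((maze$segments$from == a & maze$segments$to == b) |
      (maze$segments$from == b & maze$segments$to == a))
}

#' Measure egomotion along a route
#'
#' Walks a route through a concrete maze and records the egomotion the walker
#' experiences: the distance of each leg and the turn performed at each
#' interior corner. A leg through a wormhole contributes the locally
#' experienced (teleport-shortened) distance, and because the teleport's
#' rotation is seamless it is never experienced as a turn - so integrating
#' the returned egomotion disagrees with the planar ground truth beyond a
#' wormhole.
#'
#' @param maze a concrete [maze_spec()] (apply [maze_variant()] first for a
#'   two-variant specification).
#' @param route integer vector of corner ids; consecutive corners must share
#'   a segment.
#' @return data frame with one row per leg: `from`, `to`, `dist`
#'   (nonnegative), `turn` (heading change at the leg's end corner toward the
#'   next leg, degrees CCW-positive in (-180, 180]; `NA` for the final leg),
#'   and `heading` (true heading at the start of the leg, for reference).
#' @export
traverse <- function(maze, route) {
  route <- as.integer(route)
  if (length(route) < 2) stop("route needs at least two corners")
  if (!all(route %in% maze$corners$id))
    stop("route references unknown corner ", setdiff(route, maze$corners$id)[1])
  n <- length(route) - 1L
  legs <- vector("list", n)
  for (i in seq_len(n)) {
    a <- route[i]; b <- route[i + 1L]
    if (!segment_exists(maze, a, b))
      stop("route error: corners ", a, " and ", b, " are not adjacent")
    legs[[i]] <- leg_geometry(maze, a, b)
  }
  dist <- vapply(legs, `[[`, 0, "dist")
  h_start <- vapply(legs, `[[`, 0, "h_start")
  h_end <- vapply(legs, `[[`, 0, "h_end")
  turn <- rep(NA_real_, n)
  if (n > 1)
    turn[seq_len(n - 1)] <-
      wrap180(h_start[-1] - h_end[-n])
  # a backtrack (returning along the same leg) is a 180 degree turn
  back <- which(route[seq_len(n - 1) + 2L] == route[seq_len(n - 1)])
  turn[back] <- 180
  data.frame(from = route[-length(route)], to = route[-1],
             dist = dist, turn = turn, heading = h_start)
}

#' Integrate egomotion steps by dead reckoning
#'
#' Reconstructs positions from the output of [traverse()] exactly as a path
#' integrator would: start at `origin` facing the first leg's heading (or
#' `heading0`), advance each leg's distance, and rotate by each experienced
#' turn. For a wormhole-free maze this reproduces the ground-truth corner
#' coordinates; across a wormhole it does not, which is the mismatch the
#' labeled-graph analysis is built on.
#'
#' @param steps data frame from [traverse()].
#' @param origin numeric length-2 start position.
#' @param heading0 initial heading in degrees; defaults to the first leg's
#'   true heading so that wormhole-free reconstruction is exact rather than
#'   merely rigid-motion-equivalent.
#' @return matrix of positions, one row per visited corner (including start).
#' @export
integrate_egomotion <- function(steps, origin = c(0, 0),
                                heading0 = steps$heading[1]) {
  n <- nrow(steps)
  pos <- matrix(0, n + 1L, 2L)
  pos[1, ] <- origin
  h <- heading0
  for (i in seq_len(n)) {
    pos[i + 1L, ] <- pos[i, ] + steps$dist[i] * c(cos(deg2rad(h)), sin(deg2rad(h)))
    if (i < n) h <- h + steps$turn[i]
  }
  pos
}

object_row <- function(maze, object) {
  if (is.null(maze$objects)) stop("maze has no objects")
  i <- match(object, maze$objects$object)
  if (is.na(i)) stop("unknown object '", object, "'")
  maze$objects[i, ]
}

#' Ground-truth position of an object
#' @param maze a [maze_spec()] with objects.
#' @param object object id.
#' @return numeric length-2 position.
#' @export
object_position <- function(maze, object) {
  ob <- object_row(maze, object)
  if (!is.na(ob$corner)) return(corner_xy(maze, ob$corner))
  a <- corner_xy(maze, ob$from); b <- corner_xy(maze, ob$to)
  a + ob$frac * (b - a)
}

#' Graph vertex an object is snapped to
#'
#' Objects placed mid-segment are snapped to the nearer segment endpoint;
#' objects at corners resolve to that corner.
#' @inheritParams object_position
#' @return a corner id.
#' @export
object_vertex <- function(maze, object) {
  ob <- object_row(maze, object)
  if (!is.na(ob$corner)) return(as.integer(ob$corner))
  as.integer(if (ob$frac <= 0.5) ob$from else ob$to)
}

#' Promote mid-segment objects to corners
#'
#' Splits every segment that carries a mid-segment object, inserting a new
#' corner at the object position, so that predictions can be made for the
#' exact object location instead of the snapped vertex.
#'
#' @param maze a concrete [maze_spec()] without wormholes on the split
#'   segments.
#' @return A new `maze_spec` in which every object references a corner.
#' @export
add_object_vertices <- function(maze) {
  if (is.null(maze$objects)) return(maze)
  co <- maze$corners; seg <- maze$segments; obj <- maze$objects
  nid <- max(co$id)
  for (r in seq_len(nrow(obj))) {
    ob <- obj[r, ]
    if (!is.na(ob$corner)) next
    if (ob$frac %in% c(0, 1)) {
      obj$corner[r] <- if (ob$frac == 0) ob$from else ob$to
      next
    }
    if (!is.null(find_wormhole(maze, ob$from, ob$to)))
      stop("cannot split a wormhole segment at object '", ob$object, "'")
    p <- object_position(maze, ob$object)
    nid <- nid + 1L
    co <- rbind(co, data.frame(id = nid, x = p[1], y = p[2], control = FALSE))
    i <- which((seg$from == ob$from & seg$to == ob$to) |
               (seg$from == ob$to & seg$to == ob$from))[1]
    v <- seg$variant[i]
    seg <- seg[-i, , drop = FALSE]
    seg <- rbind(seg,
                 data.frame(from = ob$from, to = nid, variant = v),
                 data.frame(from = nid, to = ob$to, variant = v))
    obj$corner[r] <- nid
  }
  maze_spec(co, seg, maze$wormholes, obj)
}
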