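# Small mazes built in code, shared across the suite.

# three collinear corners on the x axis
corridor_maze <- function() {
  maze_spec(
    corners = data.frame(id = 1:3, x = c(0, 1, 2), y = 0),
    segments = data.frame(from = c(1, 2), to = c(2, 3))
  )
}

# unit square loop
square_maze <- function() {
  maze_spec(
    corners = data.frame(id = 1:4, x = c(0, 1, 1, 0), y = c(0, 0, 1, 1)),
    segments = data.frame(from = c(1, 2, 3, 4), to = c(2, 3, 4, 1))
  )
}

# T-junction: center corner 2 with three arms
star_maze <- function() {
  maze_spec(
    corners = data.frame(id = 1:4, x = c(-1, 0, 1, 0), y = c(0, 0, 0, 1)),
    segments = data.frame(from = c(1, 2, 2), to = c(2, 3, 4))
  )
}

# four corners, one corridor spliced by a -90 degree wormhole:
# walking 1 -> 2 -> (teleport) -> 3 -> 4; experienced length of 2-3 is 2
mini_wormhole_maze <- function() {
  maze_spec(
    corners = data.frame(id = 1:4, x = c(0, 1, 4, 4), y = c(0, 0, 3, 2)),
    segments = data.frame(from = c(1, 2, 3), to = c(2, 3, 4)),
    wormholes = list(list(
      from = 2L, to = 3L,
      entry = list(x = 2, y = 0, heading = 0),
      exit = list(x = 4, y = 4, heading = 270),
      rotation = -90
    ))
  )
}

# same corridor with a degenerate wormhole: entry == exit, rotation 0
degenerate_wormhole_maze <- function() {
  maze_spec(
    corners = data.frame(id = 1:3, x = c(0, 1, 3), y = 0),
    segments = data.frame(from = c(1, 2), to = c(2, 3)),
    wormholes = list(list(
      from = 2L, to = 3L,
      entry = list(x = 2, y = 0, heading = 0),
      exit = list(x = 2, y = 0, heading = 0),
      rotation = 0
    ))
  )
}

corner_xy_of <- function(maze, id) {
  i <- match(id, maze$corners$id)
  c(maze$corners$x[i], maze$corners$y[i])
}

# ground-truth coordinates of a maze as a matrix keyed by corner id
maze_coords <- function(maze) {
  X <- as.matrix(maze$corners[, c("x", "y")])
  rownames(X) <- maze$corners$id
  X
}

triplet_alpha_of <- function(g, i, j, k) {
  tr <- g$triplets
  tr$alpha[tr$i == i & tr$j == j & tr$k == k][1]
}

expect_angle_equal <- function(a, b, tol = 1e-9) {
  expect_lt(max(abs(mazembed::wrap180(a - b))), tol)
}
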