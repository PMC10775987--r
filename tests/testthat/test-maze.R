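test_that("maze validation enforces referential and geometric integrity", {
  expect_silent(validate_maze(corridor_maze()))

  bad_ref <- maze_spec(
    corners = data.frame(id = 1:2, x = c(0, 1), y = 0),
    segments = data.frame(from = 1, to = 9))
  expect_error(validate_maze(bad_ref), "unknown corner id: 9")

  dup <- maze_spec(
    corners = data.frame(id = c(1, 1, 2), x = c(0, 0, 1), y = 0),
    segments = data.frame(from = 1, to = 2))
  expect_error(validate_maze(dup), "duplicate corner id")

  degen <- maze_spec(
    corners = data.frame(id = 1:2, x = c(0, 1), y = 0),
    segments = data.frame(from = c(1, 2), to = c(2, 2)))
  expect_error(validate_maze(degen), "identical endpoints")

  zero_len <- maze_spec(
    corners = data.frame(id = 1:3, x = c(0, 1, 1), y = c(0, 0, 0)),
    segments = data.frame(from = c(1, 2), to = c(2, 3)))
  expect_error(validate_maze(zero_len), "zero-length segment")

  disjoint <- maze_spec(
    corners = data.frame(id = 1:4, x = c(0, 1, 5, 6), y = 0),
    segments = data.frame(from = c(1, 3), to = c(2, 4)))
  expect_error(validate_maze(disjoint), "disconnected")

  isolated <- maze_spec(
    corners = data.frame(id = 1:3, x = c(0, 1, 5), y = 0),
    segments = data.frame(from = 1, to = 2))
  expect_error(validate_maze(isolated), "corner 3 has no segment")
})

test_that("traverse measures egomotion along plain corridors", {
  steps <- traverse(corridor_maze(), c(1, 2, 3))
  expect_equal(steps$dist, c(1, 1))
  expect_equal(steps$turn, c(0, NA))

  # non-adjacent corners are a route error
  expect_error(traverse(corridor_maze(), c(1, 3)), "not adjacent")

  # backtracking is a 180 degree turn
  steps <- traverse(corridor_maze(), c(1, 2, 1))
  expect_equal(steps$turn[1], 180)
})

test_that("dead reckoning of egomotion reproduces wormhole-free geometry", {
  # closed square loop returns to the origin
  steps <- traverse(square_maze(), c(1, 2, 3, 4, 1))
  pos <- integrate_egomotion(steps)
  expect_lt(sqrt(sum((pos[5, ] - pos[1, ])^2)), 1e-9)

  # along a random walk through a random maze, integration reproduces
  # ground truth
  for (seed in c(2, 5, 9)) {
    maze <- make_euclidean_maze(seed, n_corners = 15)
    set.seed(seed)
    route <- 1L
    for (i in 1:40) {
      nb <- c(maze$segments$to[maze$segments$from == route[length(route)]],
              maze$segments$from[maze$segments$to == route[length(route)]])
      route <- c(route, nb[sample.int(length(nb), 1)])
    }
    steps <- traverse(maze, route)
    pos <- integrate_egomotion(steps, origin = corner_xy_of(maze, route[1]))
    truth <- t(vapply(route, function(id) corner_xy_of(maze, id), c(0, 0)))
    expect_lt(max(abs(pos - truth)), 1e-9)
  }
})

test_that("reversed routes give the same distances in reverse order", {
  for (maze in list(square_maze(), mini_wormhole_maze())) {
    route <- c(1, 2, 3, 4)
    fwd <- traverse(maze, route)
    bwd <- traverse(maze, rev(route))
    expect_equal(bwd$dist, rev(fwd$dist))
  }
})

test_that("crossing a rotation wormhole decouples egomotion from ground truth", {
  maze <- mini_wormhole_maze()
  steps <- traverse(maze, c(1, 2, 3, 4))
  # experienced distance through the wormhole corridor is shortened, not zero
  expect_equal(steps$dist[2], 2)
  expect_gt(steps$dist[2], 0)
  pos <- integrate_egomotion(steps, origin = c(0, 0))
  truth_end <- corner_xy_of(maze, 4) - corner_xy_of(maze, 1)
  expect_gt(sqrt(sum((pos[4, ] - truth_end)^2)), 1)
})

test_that("a zero-rotation wormhole with coincident poses is a plain corridor", {
  with_wh <- traverse(degenerate_wormhole_maze(), c(1, 2, 3))
  plain <- traverse(maze_spec(
    corners = data.frame(id = 1:3, x = c(0, 1, 3), y = 0),
    segments = data.frame(from = c(1, 2), to = c(2, 3))), c(1, 2, 3))
  expect_identical(with_wh$dist, plain$dist)
  expect_identical(with_wh$turn, plain$turn)
})

test_that("maze JSON round-trips exactly", {
  path <- withr::local_tempfile(fileext = ".json")
  maze <- make_wormhole_replica()
  write_maze_json(maze, path)
  back <- read_maze_json(path)
  expect_identical(back$corners, maze$corners)
  expect_identical(back$segments, maze$segments)
  expect_identical(back$objects$corner, maze$objects$corner)
  expect_equal(back$wormholes, maze$wormholes)
  expect_silent(validate_maze(back))
})

test_that("objects resolve to positions and vertices, and can become corners", {
  maze <- maze_spec(
    corners = data.frame(id = 1:3, x = c(0, 2, 4), y = 0),
    segments = data.frame(from = c(1, 2), to = c(2, 3)),
    objects = data.frame(object = c("at_corner", "mid"),
                         corner = c(2L, NA),
                         from = c(NA, 2), to = c(NA, 3), frac = c(NA, 0.25)))
  expect_equal(object_position(maze, "at_corner"), c(2, 0))
  expect_equal(object_position(maze, "mid"), c(2.5, 0))
  expect_equal(object_vertex(maze, "mid"), 2L)
  expect_error(object_position(maze, "nope"), "unknown object")

  split <- add_object_vertices(maze)
  v <- object_vertex(split, "mid")
  expect_equal(object_position(split, "mid"), c(2.5, 0))
  expect_true(v > 3)
  expect_silent(validate_maze(split))
  expect_equal(nrow(split$segments), 3)
})
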