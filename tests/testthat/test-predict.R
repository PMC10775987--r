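test_that("shortest paths follow the distance labels deterministically", {
  g <- build_graph(corridor_maze())
  p <- shortest_path(g, 1, 3)
  expect_equal(as.integer(p), c(1, 2, 3))
  expect_equal(attr(p, "cost"), 2)

  # start == goal
  p0 <- shortest_path(g, 2, 2)
  expect_equal(as.integer(p0), 2)
  expect_equal(attr(p0, "cost"), 0)

  # a shortened label reroutes the path (exhaustive: the square has only
  # two simple routes between opposite corners)
  gs <- build_graph(square_maze())
  gs$edges$d[gs$edges$from == 1 & gs$edges$to == 4] <- 0.2
  gs$edges$d[gs$edges$from == 3 & gs$edges$to == 4] <- 0.3
  p <- shortest_path(gs, 1, 3)
  expect_equal(as.integer(p), c(1, 4, 3))
  expect_equal(attr(p, "cost"), 0.5)

  # equal-cost tie broken toward the lexicographically smaller sequence
  p <- shortest_path(build_graph(square_maze()), 1, 3)
  expect_equal(as.integer(p), c(1, 2, 3))

  # unreachable goals are an error
  gd <- labeled_graph(1:4, data.frame(from = c(1, 3), to = c(2, 4), d = 1),
                      data.frame(i = integer(), j = integer(),
                                 k = integer(), alpha = numeric()))
  expect_error(shortest_path(gd, 1, 4), "unreachable")
})

test_that("path vectors dead-reckon the labels", {
  g <- build_graph(corridor_maze())
  expect_equal(path_vector(g, c(1, 2, 3), start_heading = 0), c(2, 0))

  # unit legs with a +90 turn land at (1, 1)
  gr <- labeled_graph(1:3, data.frame(from = c(1, 2), to = c(2, 3), d = 1),
                      data.frame(i = 1, j = 2, k = 3, alpha = 90))
  expect_equal(path_vector(gr, c(1, 2, 3), 0), c(1, 1), tolerance = 1e-12)

  expect_error(path_vector(g, c(1, 3)), "not an edge")
})

test_that("path vectors are path-independent exactly on consistent graphs", {
  # consistent square: both routes 1->3 agree
  gs <- build_graph(square_maze())
  v_a <- path_vector(gs, c(1, 2, 3), 0)
  v_b <- path_vector(gs, c(1, 4, 3), 90)
  expect_lt(max(abs(v_a - v_b)), 1e-9)

  # any two random walks between the same endpoints of a random maze agree
  maze <- make_euclidean_maze(21, n_corners = 16)
  g <- build_graph(maze)
  arm0 <- traverse(maze, c(5, shortest_path(g, 5, 9)[2]))$heading[1]
  v_short <- path_vector(g, shortest_path(g, 5, 9), arm0)
  gt <- corner_xy_of(maze, 9) - corner_xy_of(maze, 5)
  expect_lt(max(abs(v_short - gt)), 1e-9)

  # on the wormhole graph, two routes between the same vertices disagree
  mazew <- make_wormhole_replica()
  gw <- build_graph(mazew, "wormhole")
  mw <- maze_variant(mazew, "wormhole")
  # via the wormhole: 26 -> 31 -> 32 -> 10; around: 26 -> 24 -> ... -> 10
  via <- c(26, 31, 32, 10)
  around <- c(26, 24, 2, 3, 4, 5, 10)
  h_via <- traverse(mw, via)$heading[1]
  h_around <- traverse(mw, around)$heading[1]
  v_via <- path_vector(gw, via, h_via)
  v_around <- path_vector(gw, around, h_around)
  expect_gt(sqrt(sum((v_via - v_around)^2)), 1)
})

test_that("all models coincide on Euclidean mazes, in the local frame", {
  maze <- make_euclidean_maze(31, n_corners = 18, n_objects = 6)
  g <- build_graph(maze)
  fit <- embed_graph(g, n_restarts = 20, seed = 2)
  pairs <- data.frame(start = c("O1", "O2", "O5"), goal = c("O3", "O4", "O6"))
  pr <- shortcut_predictions(g, maze_variant(maze, "wormhole"), pairs,
                             X = coef(fit))
  for (key in unique(paste(pr$start, pr$goal))) {
    v <- pr$direction_local[paste(pr$start, pr$goal) == key]
    expect_lt(max(abs(wrap180(outer(v, v, "-")))), 1e-3)
  }
  # nonmetric equals ground truth even in the global frame
  nm <- pr[pr$model == "nonmetric", ]
  gt <- pr[pr$model == "ground_truth", ]
  expect_lt(max(abs(wrap180(nm$direction_global - gt$direction_global))), 1e-6)
})

test_that("wormhole-spanning shortcuts deviate from the Euclidean direction", {
  maze <- make_wormhole_replica()
  g <- build_graph(maze, "wormhole")
  m <- maze_variant(maze, "wormhole")
  nm <- predict_nonmetric(g, m, 26, 10)   # crosses wormhole 31-32
  gt <- predict_ground_truth(m, 26, 10)
  expect_match(nm$path, "31-32")
  expect_gt(abs(wrap180(nm$direction_global - gt$direction_global)), 5)

  # identical start and goal has no defined direction
  expect_error(predict_nonmetric(g, m, 26, 26), "undefined")
})

test_that("embedded predictions are straight lines in the embedding frame", {
  X <- rbind(`1` = c(0, 0), `2` = c(1, 1))
  pr <- predict_embedded(X, 1, 2)
  expect_equal(pr$direction_global, 45)
  expect_equal(pr$length, sqrt(2))
  # antisymmetry
  rev <- predict_embedded(X, 2, 1)
  expect_equal(wrap360(pr$direction_global + 180), rev$direction_global)
  expect_error(predict_embedded(rbind(`1` = c(0, 0), `2` = c(0, 0)), 1, 2),
               "coincident")
})

test_that("local reference angles are rotation invariant", {
  expect_equal(to_local_reference(90, 90), 0)
  expect_equal(to_local_reference(10, 350), 20)
  set.seed(8)
  for (i in 1:20) {
    d <- runif(1, 0, 360); a <- runif(1, 0, 360); rot <- runif(1, -720, 720)
    expect_equal(to_local_reference(d + rot, a + rot),
                 to_local_reference(d, a), tolerance = 1e-9)
  }
})

test_that("prediction tables round-trip through CSV", {
  maze <- make_wormhole_replica()
  g <- build_graph(maze, "wormhole")
  fit <- embed_graph(g, n_restarts = 10, seed = 1)
  pr <- shortcut_predictions(g, maze_variant(maze, "wormhole"),
                             data.frame(start = "clock", goal = "lamp"),
                             X = coef(fit))
  path <- withr::local_tempfile(fileext = ".csv")
  write_predictions_csv(pr, path)
  back <- read_predictions_csv(path)
  expect_equal(back$direction_global, pr$direction_global)
  expect_equal(back$direction_local, pr$direction_local)
  expect_equal(back$path, pr$path)
})
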