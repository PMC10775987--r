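# a minimal hand-labeled graph: one corridor with a +90 turn
right_turn_graph <- function() {
  labeled_graph(
    vertices = 1:3,
    edges = data.frame(from = c(1, 2), to = c(2, 3), d = 1),
    triplets = data.frame(i = c(1, 3, 1, 2, 2, 3),
                          j = c(2, 2, 2, 1, 3, 2),
                          k = c(3, 1, 1, 2, 2, 3),
                          alpha = c(90, -90, 180, 180, 180, 180))
  )
}

test_that("stress is zero exactly when coordinates realize the labels", {
  g <- right_turn_graph()
  X <- rbind(c(0, 0), c(1, 0), c(1, 1))
  rownames(X) <- 1:3
  expect_equal(stress(X, g), 0)

  # single right-turn triplet, final vertex perturbed: residuals 0.1 and
  # -0.1 in the dot- and cross-product terms give stress 0.01 + 0.01
  g1 <- labeled_graph(1:3, data.frame(from = c(1, 2), to = c(2, 3), d = 1),
                      data.frame(i = 1, j = 2, k = 3, alpha = 90))
  Xp <- X; Xp[3, ] <- c(1.1, 0.9)
  expect_equal(stress(Xp, g1), 0.02, tolerance = 1e-12)

  # a lone backtrack pair at the right distance has zero stress
  g2 <- labeled_graph(1:2, data.frame(from = 1, to = 2, d = 1),
                      data.frame(i = c(1, 2), j = c(2, 1), k = c(1, 2),
                                 alpha = 180))
  X2 <- rbind(c(0, 0), c(1, 0)); rownames(X2) <- 1:2
  expect_equal(stress(X2, g2), 0)

  # missing coordinates are an error
  expect_error(stress(X[1:2, ], g), "missing coordinates")
})

test_that("the analytic gradient matches central finite differences", {
  maze <- make_euclidean_maze(6, n_corners = 10)
  g <- build_graph(maze)
  set.seed(1)
  X <- matrix(runif(20, 0, 5), 10, 2)
  an <- stress_gradient(X, g)
  fd <- matrix(0, 10, 2)
  h <- 1e-6
  for (i in 1:10) for (j in 1:2) {
    Xp <- X; Xp[i, j] <- Xp[i, j] + h
    Xm <- X; Xm[i, j] <- Xm[i, j] - h
    fd[i, j] <- (stress(Xp, g) - stress(Xm, g)) / (2 * h)
  }
  expect_lt(max(abs(an - fd)) / max(abs(fd)), 1e-5)

  # stationary at a global minimum
  expect_lt(sqrt(sum(stress_gradient(maze_coords(maze), g)^2)), 1e-8)

  # both weights zero: flat objective
  expect_true(all(stress_gradient(X, g, lambda1 = 0, lambda2 = 0) == 0))
})

test_that("stress is rigid-motion invariant but chirality sensitive", {
  maze <- make_euclidean_maze(8, n_corners = 12)
  g <- build_graph(maze)
  set.seed(2)
  for (rep in 1:5) {
    X <- matrix(runif(24, 0, 10), 12, 2)
    th <- runif(1, 0, 2 * pi)
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    Xr <- sweep(X %*% t(R), 2, runif(2, -5, 5), "+")
    expect_lt(abs(stress(Xr, g) - stress(X, g)), 1e-9 * (1 + stress(X, g)))
  }
  # reflection flips the signed-area term: zero-stress ground truth gains
  # stress when mirrored
  gt <- maze_coords(maze)
  mirrored <- gt %*% diag(c(-1, 1))
  rownames(mirrored) <- rownames(gt)
  expect_lt(stress(gt, g), 1e-18)
  expect_gt(stress(mirrored, g), 1)
})

test_that("labels measured from any planar layout embed back to it", {
  maze <- make_euclidean_maze(12, n_corners = 14)
  g <- build_graph(maze)
  fit <- embed_graph(g, n_restarts = 20, seed = 3)
  expect_lt(fit$minima[[1]]$stress, 1e-6)
  expect_lt(procrustes_distance(coef(fit), maze_coords(maze),
                                allow_reflection = FALSE), 1e-3)
  expect_true(fit$minima[[1]]$converged)
})

test_that("every reported minimum improves on its initialization", {
  g <- build_graph(make_wormhole_replica(), "wormhole")
  fit <- embed_graph(g, n_restarts = 15, seed = 4)
  for (m in fit$minima) expect_lte(m$stress, m$init_stress)
})

test_that("embedding is reproducible given the seed", {
  g <- build_graph(square_maze())
  f1 <- embed_graph(g, n_restarts = 5, seed = 11)
  f2 <- embed_graph(g, n_restarts = 5, seed = 11)
  expect_identical(coef(f1), coef(f2))
  expect_identical(vapply(f1$minima, `[[`, 0, "stress"),
                   vapply(f2$minima, `[[`, 0, "stress"))
})

test_that("edge-mode alignment makes the named edge horizontal at the origin", {
  g <- build_graph(square_maze())
  fit <- embed_graph(g, n_restarts = 5, seed = 5)
  A <- align_embedding(fit, edge = c(2, 3))
  expect_equal(unname(A["2", ]), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(A["2", 2]), unname(A["3", 2]), tolerance = 1e-9)
  expect_error(align_embedding(rbind(`1` = c(0, 0), `2` = c(0, 0)),
                               edge = c(1, 2)), "zero-length")
})

test_that("reference-mode alignment undoes an arbitrary rigid motion", {
  set.seed(6)
  X <- matrix(runif(16, 0, 4), 8, 2)
  rownames(X) <- 1:8
  th <- 1.1
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  Y <- sweep(X %*% t(R), 2, c(3, -2), "+")
  rownames(Y) <- 1:8
  back <- align_embedding(Y, reference = X)
  expect_lt(sqrt(mean(rowSums((back - X)^2))), 1e-9)
  # aligning to itself is the identity
  self <- align_embedding(X, reference = X)
  expect_lt(max(abs(self - X)), 1e-12)
})

test_that("procrustes distance detects chirality unless reflection is allowed", {
  X <- rbind(c(0, 0), c(2, 0), c(0, 1))  # scalene: no accidental symmetry
  Y <- X %*% diag(c(1, -1))
  expect_equal(procrustes_distance(X, X), 0)
  expect_gt(procrustes_distance(X, Y, allow_reflection = FALSE), 0.1)
  expect_lt(procrustes_distance(X, Y, allow_reflection = TRUE), 1e-12)
  expect_error(procrustes_distance(X, Y[1:2, ]), "different vertex sets")
})

test_that("rigid superposition agrees with an independent implementation", {
  skip_if_not_installed("vegan")
  set.seed(7)
  X <- matrix(runif(20, 0, 5), 10, 2)
  Y <- X + matrix(rnorm(20, sd = 0.3), 10, 2)
  ours <- procrustes_distance(Y, X, allow_reflection = TRUE)
  vg <- vegan::procrustes(X, Y, scale = FALSE)  # superposes Y onto X
  expect_equal(ours, sqrt(vg$ss / nrow(X)), tolerance = 1e-9)
})
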