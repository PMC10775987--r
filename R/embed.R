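## Triplet stress
##
## For a triplet (i, j, k) with labels (d_ij, d_jk, alpha_ijk), write
## u = x_j - x_i (displacement into j) and w = x_k - x_j (displacement out
## of j). If the coordinates realize the labels, then
##   u . w  = d_ij d_jk cos(alpha)   and   u x w = d_ij d_jk sin(alpha),
## where "x" is the scalar cross product u1 w2 - u2 w1 (twice the signed
## triangle area), and alpha is the heading change at j. The stress is the
## lambda-weighted sum of squared residuals of these two constraints over
## all triplets. Backtracks (i, j, i) give u . w = -|u|^2, u x w = 0,
## matching alpha = 180 exactly.

## precompute triplet index/label arrays for fast stress evaluation
stress_prep <- function(graph, lambda1 = 1, lambda2 = 1) {
  vids <- graph$vertices
  ed <- graph$edges
  dkey <- paste(ed$from, ed$to)
  dval <- ed$d
  if (anyNA(dval)) stop("graph has unmeasured distance labels")
  tr <- graph$triplets
  if (nrow(tr) == 0) stop("graph has no triplets")
  if (anyNA(tr$alpha)) stop("graph has unmeasured angle labels")
  lk <- function(a, b) {
    d <- dval[match(paste(pmin(a, b), pmax(a, b)), dkey)]
    if (anyNA(d)) stop("triplet leg is not an edge of the graph")
    d
  }
  dij <- lk(tr$i, tr$j)
  djk <- lk(tr$j, tr$k)
  a <- deg2rad(tr$alpha)
  list(n = length(vids), vids = vids,
       ii = match(tr$i, vids), jj = match(tr$j, vids), kk = match(tr$k, vids),
       ct = dij * djk * cos(a), st = dij * djk * sin(a),
       l1 = lambda1, l2 = lambda2)
}

coords_matrix <- function(X, vids) {
  if (inherits(X, "cogmap_embedding")) X <- coef(X)
  X <- as.matrix(X)
  if (!is.null(rownames(X))) {
    i <- match(as.character(vids), rownames(X))
    if (anyNA(i)) stop("missing coordinates for vertex ",
                       vids[is.na(i)][1])
    X <- X[i, , drop = FALSE]
  } else if (nrow(X) != length(vids)) {
    stop("coordinate matrix has ", nrow(X), " rows but the graph has ",
         length(vids), " vertices")
  }
  if (any(!is.finite(X))) stop("non-finite coordinate")
  X
}

stress_eval <- function(X, p) {
  u <- X[p$jj, , drop = FALSE] - X[p$ii, , drop = FALSE]
  w <- X[p$kk, , drop = FALSE] - X[p$jj, , drop = FALSE]
  A <- u[, 1] * w[, 1] + u[, 2] * w[, 2] - p$ct
  B <- u[, 1] * w[, 2] - u[, 2] * w[, 1] - p$st
  sum(p$l1 * A^2 + p$l2 * B^2)
}

## Jacobian of the residual vector (sqrt(l1) A_t, sqrt(l2) B_t) w.r.t.
## par = c(x_1..x_n, y_1..y_n); used to assemble the Gauss-Newton part of
## the Hessian
stress_resid_jac <- function(X, p) {
  u <- X[p$jj, , drop = FALSE] - X[p$ii, , drop = FALSE]
  w <- X[p$kk, , drop = FALSE] - X[p$jj, , drop = FALSE]
  Tn <- length(p$ii)
  J <- matrix(0, 2 * Tn, 2 * p$n)
  rA <- seq_len(Tn); rB <- Tn + rA
  s1 <- sqrt(p$l1); s2 <- sqrt(p$l2)
  add <- function(rows, cols, val) {
    idx <- cbind(rows, cols)
    J[idx] <<- J[idx] + val
  }
  # A rows: dA/du = w (at j, -at i), dA/dw = u (at k, -at j)
  add(rA, p$ii, -s1 * w[, 1]);        add(rA, p$n + p$ii, -s1 * w[, 2])
  add(rA, p$jj, s1 * (w[, 1] - u[, 1])); add(rA, p$n + p$jj, s1 * (w[, 2] - u[, 2]))
  add(rA, p$kk, s1 * u[, 1]);         add(rA, p$n + p$kk, s1 * u[, 2])
  # B rows: dB/du = (w2, -w1), dB/dw = (-u2, u1)
  add(rB, p$ii, -s2 * w[, 2]);        add(rB, p$n + p$ii, s2 * w[, 1])
  add(rB, p$jj, s2 * (w[, 2] + u[, 2])); add(rB, p$n + p$jj, -s2 * (w[, 1] + u[, 1]))
  add(rB, p$kk, -s2 * u[, 2]);        add(rB, p$n + p$kk, s2 * u[, 1])
  J
}

## analytic Hessian of the stress. A and B are bilinear in the vertex
## coordinates, so their second derivatives are constant scatter patterns:
## H = 2 J'J + sum_t 2 l1 A_t H_A(t) + 2 l2 B_t H_B(t).
stress_hess_eval <- function(X, p) {
  u <- X[p$jj, , drop = FALSE] - X[p$ii, , drop = FALSE]
  w <- X[p$kk, , drop = FALSE] - X[p$jj, , drop = FALSE]
  A <- u[, 1] * w[, 1] + u[, 2] * w[, 2] - p$ct
  B <- u[, 1] * w[, 2] - u[, 2] * w[, 1] - p$st
  J <- stress_resid_jac(X, p)
  H <- 2 * crossprod(J)
  d <- 2L * p$n
  xi <- p$ii; xj <- p$jj; xk <- p$kk
  yi <- p$n + xi; yj <- p$n + xj; yk <- p$n + xk
  ig <- integer(0); jg <- integer(0); vg <- numeric(0)
  put <- function(a, b, v) {
    # symmetric scatter: both (a, b) and (b, a)
    ig <<- c(ig, a, b); jg <<- c(jg, b, a); vg <<- c(vg, v, v)
  }
  aA <- 2 * p$l1 * A
  # d2A: (xi,xj) +1, (xi,xk) -1, (xj,xj) -2, (xj,xk) +1; same in y
  put(xi, xj, aA); put(xi, xk, -aA); put(xj, xk, aA)
  put(yi, yj, aA); put(yi, yk, -aA); put(yj, yk, aA)
  ig <- c(ig, xj, yj); jg <- c(jg, xj, yj); vg <- c(vg, -2 * aA, -2 * aA)
  bB <- 2 * p$l2 * B
  # d2B: (xi,yj) +1, (xi,yk) -1, (xj,yi) -1, (xj,yk) +1, (xk,yi) +1, (xk,yj) -1
  put(xi, yj, bB); put(xi, yk, -bB); put(xj, yi, -bB)
  put(xj, yk, bB); put(xk, yi, bB); put(xk, yj, -bB)
  key <- (ig - 1) * d + jg
  s <- rowsum(vg, key)
  idx <- as.numeric(rownames(s))
  H[idx] <- H[idx] + s[, 1]
  H
}

## Newton polish with ridge-regularized steps and backtracking; the
## Hessian's 3-dimensional gauge null space (translation, rotation) is
## absorbed by the ridge
newton_polish <- function(par, p, fn, gr, target, maxiter = 40) {
  n <- p$n
  f <- fn(par)
  for (it in seq_len(maxiter)) {
    g <- gr(par)
    if (sqrt(sum(g^2)) <= target) break
    H <- stress_hess_eval(matrix(par, n, 2), p)
    ridge <- max(1e-12, 1e-10 * mean(abs(diag(H))))
    step <- tryCatch(solve(H + ridge * diag(2 * n), g),
                     error = function(e) NULL)
    if (is.null(step)) break
    t <- 1
    repeat {
      f_new <- fn(par - t * step)
      if (f_new <= f + 1e-12 * (1 + abs(f))) break
      t <- t / 2
      if (t < 1e-8) break
    }
    if (t < 1e-8) break
    par <- par - t * step
    f <- f_new
  }
  list(par = par, value = f)
}

stress_grad_eval <- function(X, p) {
  u <- X[p$jj, , drop = FALSE] - X[p$ii, , drop = FALSE]
  w <- X[p$kk, , drop = FALSE] - X[p$jj, , drop = FALSE]
  A <- u[, 1] * w[, 1] + u[, 2] * w[, 2] - p$ct
  B <- u[, 1] * w[, 2] - u[, 2] * w[, 1] - p$st
  Gu <- 2 * p$l1 * A * w + 2 * p$l2 * B * cbind(w[, 2], -w[, 1])
  Gw <- 2 * p$l1 * A * u + 2 * p$l2 * B * cbind(-u[, 2], u[, 1])
  idx <- c(p$ii, p$jj, p$kk)
  M <- rbind(-Gu, Gu - Gw, Gw)
  S <- rowsum(M, idx)
  G <- matrix(0, p$n, 2)
  G[as.integer(rownames(S)), ] <- S
  G
}

#' Triplet stress of a configuration
#'
#' Evaluates the embedding objective: for every labeled triplet (i, j, k),
#' the squared residuals of the dot-product constraint
#' \eqn{u \cdot w = d_{ij} d_{jk} \cos\alpha_{ijk}} and the cross-product
#' (signed-area) constraint \eqn{u \otimes w = d_{ij} d_{jk}
#' \sin\alpha_{ijk}}, with \eqn{u = x_j - x_i} and \eqn{w = x_k - x_j},
#' weighted by `lambda1` and `lambda2` and summed. Zero stress means the
#' coordinates realize every local measurement exactly; for graphs measured
#' in a wormhole maze no such configuration exists.
#'
#' @param X numeric n-by-2 coordinate matrix; row names, if present, are
#'   matched against the graph's vertex ids (otherwise rows are taken in
#'   vertex-id order). A fitted [embed_graph()] object is also accepted
#'   (its best minimum is used).
#' @param graph a fully labeled [labeled_graph()].
#' @param lambda1,lambda2 nonnegative weights of the dot- and cross-product
#'   terms (default 1 and 1).
#' @return `stress()`: a nonnegative scalar. `stress_gradient()`: the n-by-2
#'   matrix of partial derivatives, rows in graph vertex order.
#' @export
stress <- function(X, graph, lambda1 = 1, lambda2 = 1) {
  p <- stress_prep(graph, lambda1, lambda2)
  stress_eval(coords_matrix(X, p$vids), p)
}

#' @rdname stress
#' @export
stress_gradient <- function(X, graph, lambda1 = 1, lambda2 = 1) {
  p <- stress_prep(graph, lambda1, lambda2)
  G <- stress_grad_eval(coords_matrix(X, p$vids), p)
  rownames(G) <- p$vids
  G
}

#' Embed a labeled graph into 2D Euclidean coordinates
#'
#' Fits the metric-embedding model: vertex coordinates minimizing the
#' triplet [stress()] are sought by quasi-Newton (BFGS with the analytic
#' gradient, followed by a PORT polish when needed) from `n_restarts`
#' uniform random initializations. Distinct local minima are deduplicated
#' (equal stress up to a relative tolerance and rigid superposition with
#' reflection allowed) and returned sorted by stress.
#'
#' Local minima are genuine features of the problem: a graph measured in a
#' wormhole maze admits no zero-stress configuration, and different
#' restarts settle into differently folded layouts. Downstream analyses can
#' evaluate every minimum; the global gauge (rotation/translation) of each
#' is arbitrary, see [align_embedding()].
#'
#' @param graph a fully labeled, connected [labeled_graph()].
#' @param n_restarts number of random restarts (default 100).
#' @param seed integer seed for the random initializations.
#' @param lambda1,lambda2 stress term weights.
#' @param init_range length-2 interval for the uniform initial coordinates
#'   (default `c(0, 20)`).
#' @param maxit maximum optimizer iterations per restart (default 5000).
#' @param grad_tol gradient-norm convergence target (default 1e-8, scaled
#'   by `1 + stress`).
#' @param dedup_stress_tol,dedup_rmsd_tol tolerances for identifying two
#'   minima: relative stress difference, and Procrustes RMSD as a fraction
#'   of the mean edge length.
#' @return An object of class `cogmap_embedding`: a list with elements
#'   `minima` (each a list `X`, `stress`, `grad_norm`, `converged`,
#'   `restart`, `count`), `graph`, `seed`, and the configuration. `coef()`
#'   returns the coordinates of the requested minimum, `predict()` derives
#'   shortcut directions, `plot()` draws the embedded graph.
#' @examples
#' maze <- make_euclidean_maze(seed = 1, n_corners = 12)
#' g <- build_graph(maze)
#' fit <- embed_graph(g, n_restarts = 10, seed = 1)
#' fit
#' @export
embed_graph <- function(graph, n_restarts = 100, seed = 1,
                        lambda1 = 1, lambda2 = 1, init_range = c(0, 20),
                        maxit = 5000, grad_tol = 1e-8,
                        dedup_stress_tol = 1e-6, dedup_rmsd_tol = 1e-4) {
  stopifnot(n_restarts >= 1, lambda1 >= 0, lambda2 >= 0)
  p <- stress_prep(graph, lambda1, lambda2)
  n <- p$n
  fn <- function(par) stress_eval(matrix(par, n, 2), p)
  gr <- function(par) as.vector(stress_grad_eval(matrix(par, n, 2), p))
  set.seed(seed)
  inits <- array(stats::runif(n_restarts * n * 2, init_range[1], init_range[2]),
                 dim = c(n_restarts, n * 2))
  runs <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    par0 <- inits[r, ]
    f0 <- fn(par0)
    res <- stats::optim(par0, fn, gr, method = "BFGS",
                        control = list(maxit = maxit, reltol = 1e-14))
    gnorm <- sqrt(sum(gr(res$par)^2))
    if (gnorm > grad_tol * (1 + abs(res$value))) {
      pol <- newton_polish(res$par, p, fn, gr,
                           target = grad_tol * (1 + abs(res$value)))
      if (pol$value <= res$value) res <- list(par = pol$par, value = pol$value)
      gnorm <- sqrt(sum(gr(res$par)^2))
    }
    if (res$value > f0 + 1e-9 * (1 + f0))
      stop("optimizer increased the stress on restart ", r)
    X <- matrix(res$par, n, 2)
    rownames(X) <- p$vids
    runs[[r]] <- list(X = X, stress = res$value, grad_norm = gnorm,
                      converged = gnorm <= grad_tol * (1 + abs(res$value)),
                      restart = r, init_stress = f0)
  }
  if (!any(vapply(runs, `[[`, TRUE, "converged")))
    stop("no restart converged (best gradient norm ",
         format(min(vapply(runs, `[[`, 0, "grad_norm"))), ")")
  runs <- runs[order(vapply(runs, `[[`, 0, "stress"))]
  mean_d <- mean(graph$edges$d)
  minima <- list()
  for (run in runs) {
    dup <- FALSE
    for (m in seq_along(minima)) {
      ref <- minima[[m]]
      if (abs(run$stress - ref$stress) < dedup_stress_tol * (1 + ref$stress) &&
          procrustes_distance(run$X, ref$X, allow_reflection = TRUE) <
            dedup_rmsd_tol * mean_d) {
        minima[[m]]$count <- ref$count + 1L
        dup <- TRUE
        break
      }
    }
    if (!dup) {
      run$count <- 1L
      minima[[length(minima) + 1L]] <- run
    }
  }
  structure(
    list(minima = minima, graph = graph, seed = seed,
         n_restarts = n_restarts,
         config = list(lambda1 = lambda1, lambda2 = lambda2,
                       init_range = init_range, maxit = maxit,
                       grad_tol = grad_tol)),
    class = "cogmap_embedding"
  )
}

#' @export
print.cogmap_embedding <- function(x, ...) {
  cat(sprintf("Graph embedding: %d vertices, %d restarts, %d distinct local minim%s\n",
              length(x$graph$vertices), x$n_restarts, length(x$minima),
              if (length(x$minima) == 1) "um" else "a"))
  for (i in seq_along(x$minima)) {
    m <- x$minima[[i]]
    cat(sprintf("  [%d] stress %.6g  (reached by %d/%d restarts%s)\n",
                i, m$stress, m$count, x$n_restarts,
                if (m$converged) "" else ", not converged"))
  }
  invisible(x)
}

#' @export
summary.cogmap_embedding <- function(object, ...) {
  s <- vapply(object$minima, `[[`, 0, "stress")
  out <- list(n_vertices = length(object$graph$vertices),
              n_restarts = object$n_restarts,
              n_minima = length(object$minima),
              stress = s,
              counts = vapply(object$minima, `[[`, 0L, "count"),
              seed = object$seed)
  class(out) <- "summary.cogmap_embedding"
  out
}

#' @export
print.summary.cogmap_embedding <- function(x, ...) {
  cat("Multi-restart graph embedding\n")
  cat("  vertices:", x$n_vertices, "  restarts:", x$n_restarts,
      "  seed:", x$seed, "\n")
  cat("  distinct local minima:", x$n_minima, "\n")
  print(data.frame(stress = x$stress, restarts = x$counts))
  invisible(x)
}

#' @param object,x a `cogmap_embedding`.
#' @param minimum which local minimum to extract (1 = lowest stress).
#' @rdname embed_graph
#' @export
coef.cogmap_embedding <- function(object, minimum = 1, ...) {
  object$minima[[minimum]]$X
}

#' @param ... further arguments (ignored).
#' @rdname embed_graph
#' @export
plot.cogmap_embedding <- function(x, minimum = 1, ...) {
  X <- x$minima[[minimum]]$X
  ed <- x$graph$edges
  is_wh <- rep(FALSE, nrow(ed))
  if (!is.null(x$graph$wormhole_edges) && nrow(x$graph$wormhole_edges))
    is_wh <- paste(ed$from, ed$to) %in%
      paste(x$graph$wormhole_edges$from, x$graph$wormhole_edges$to)
  plot(X, type = "n", asp = 1, xlab = "x", ylab = "y",
       main = sprintf("Embedding (stress %.4g)", x$minima[[minimum]]$stress),
       ...)
  i1 <- match(as.character(ed$from), rownames(X))
  i2 <- match(as.character(ed$to), rownames(X))
  graphics::segments(X[i1, 1], X[i1, 2], X[i2, 1], X[i2, 2],
                     lty = ifelse(is_wh, 2, 1),
                     col = ifelse(is_wh, "red", "grey30"))
  graphics::points(X, pch = 16, cex = 0.7)
  graphics::text(X, labels = rownames(X), pos = 3, cex = 0.6)
  invisible(x)
}

#' Rigidly align an embedding
#'
#' An embedding's global rotation and translation are arbitrary (gauge
#' freedom). `align_embedding()` fixes the gauge either by making a named
#' edge horizontal with its first vertex at the origin (`edge` mode), or by
#' least-squares rigid superposition onto a reference configuration
#' (`reference` mode; rotation + translation, optionally reflection).
#'
#' @param X coordinate matrix with vertex-id row names, or a
#'   `cogmap_embedding` (best minimum used).
#' @param edge length-2 vector of vertex ids; the edge made horizontal.
#' @param reference coordinate matrix (or embedding) sharing `X`'s vertex
#'   set.
#' @param allow_reflection in reference mode, may the superposition include
#'   a reflection?
#' @return The aligned coordinate matrix.
#' @export
align_embedding <- function(X, edge = NULL, reference = NULL,
                            allow_reflection = FALSE) {
  if (inherits(X, "cogmap_embedding")) X <- coef(X)
  X <- as.matrix(X)
  if (!is.null(edge)) {
    i1 <- match(as.character(edge[1]), rownames(X))
    i2 <- match(as.character(edge[2]), rownames(X))
    if (is.na(i1) || is.na(i2)) stop("reference edge vertex not in embedding")
    v <- X[i2, ] - X[i1, ]
    if (sum(v^2) == 0) stop("zero-length reference edge")
    th <- -atan2(v[2], v[1])
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    out <- sweep(X, 2, X[i1, ]) %*% t(R)
    dimnames(out) <- dimnames(X)
    return(out)
  }
  if (is.null(reference)) stop("supply either `edge` or `reference`")
  if (inherits(reference, "cogmap_embedding")) reference <- coef(reference)
  reference <- as.matrix(reference)
  i <- match(rownames(X), rownames(reference))
  if (anyNA(i)) stop("reference does not share the embedding's vertex set")
  Y <- reference[i, , drop = FALSE]
  fit <- rigid_superpose(X, Y, allow_reflection)
  out <- sweep(X, 2, fit$cx) %*% fit$R
  out <- sweep(out, 2, fit$cy, "+")
  dimnames(out) <- dimnames(X)
  out
}

## optimal rigid (+ optional reflection) superposition of X onto Y
rigid_superpose <- function(X, Y, allow_reflection = FALSE) {
  cx <- colMeans(X); cy <- colMeans(Y)
  A <- crossprod(sweep(X, 2, cx), sweep(Y, 2, cy))
  sv <- svd(A)
  R <- sv$u %*% t(sv$v)
  if (!allow_reflection && det(R) < 0) {
    D <- diag(c(1, -1))
    R <- sv$u %*% D %*% t(sv$v)
  }
  list(R = R, cx = cx, cy = cy)
}

#' Procrustes distance between two configurations
#'
#' Root-mean-square coordinate distance after optimal rigid superposition
#' (rotation and translation; no scaling; reflection optional). Used to
#' compare local minima and to score ground-truth recovery.
#'
#' @param X,Y coordinate matrices over the same vertex set (matched by row
#'   names when present), or `cogmap_embedding` objects.
#' @param allow_reflection may the superposition include a reflection?
#' @return Nonnegative RMSD.
#' @export
procrustes_distance <- function(X, Y, allow_reflection = FALSE) {
  if (inherits(X, "cogmap_embedding")) X <- coef(X)
  if (inherits(Y, "cogmap_embedding")) Y <- coef(Y)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("configurations have different vertex sets")
  if (!is.null(rownames(X)) && !is.null(rownames(Y))) {
    i <- match(rownames(X), rownames(Y))
    if (anyNA(i)) stop("configurations have different vertex sets")
    Y <- Y[i, , drop = FALSE]
  }
  fit <- rigid_superpose(X, Y, allow_reflection)
  Xr <- sweep(sweep(X, 2, fit$cx) %*% fit$R, 2, fit$cy, "+")
  sqrt(mean(rowSums((Xr - Y)^2)))
}
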