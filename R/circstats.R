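#' Circular summary statistics
#'
#' Mean direction, mean resultant length and angular deviation of a sample
#' of angles. The angular deviation is the standard circular spread
#' \eqn{AD = \sqrt{2(1 - R)}} expressed in degrees; it is 0 exactly when
#' all angles coincide (R = 1) and grows toward \eqn{\sqrt 2} rad (about
#' 81 degrees) for a balanced sample.
#'
#' @param angles numeric vector of angles in degrees (any wrap).
#' @return List of class `circ_summary`: `mu` (mean direction in (-180,
#'   180]; `NA` and `mu_defined = FALSE` when R = 0), `R` (mean resultant
#'   length in [0, 1]), `ad` (angular deviation in degrees), `n`.
#' @export
circ_summary <- function(angles) {
  n <- length(angles)
  if (n < 1) stop("need at least one angle")
  th <- deg2rad(angles)
  C <- mean(cos(th)); S <- mean(sin(th))
  R <- sqrt(C^2 + S^2)
  # snap to the boundary within machine precision so AD = 0 iff R = 1
  if (R >= 1 - 4 * .Machine$double.eps) R <- 1
  R <- min(R, 1)
  mu_defined <- R > 1e-12
  mu <- if (mu_defined) wrap180(rad2deg(atan2(S, C))) else NA_real_
  structure(list(mu = mu, R = R, ad = rad2deg(sqrt(2 * (1 - R))),
                 n = n, mu_defined = mu_defined),
            class = "circ_summary")
}

#' @export
print.circ_summary <- function(x, ...) {
  cat(sprintf("Circular summary (n = %d): mu = %s, R = %.4f, AD = %.2f deg\n",
              x$n, if (x$mu_defined) sprintf("%.2f deg", x$mu) else "undefined",
              x$R, x$ad))
  invisible(x)
}

## circular mean of angles in degrees (NA when undefined)
circ_mean <- function(angles) circ_summary(angles)$mu

#' Rayleigh test of circular uniformity
#'
#' Tests the null hypothesis of a uniform circular distribution against a
#' unimodal alternative. The statistic is \eqn{z = n R^2}; the p-value uses
#' the standard series approximation in n and z.
#'
#' @param angles numeric vector of angles in degrees, n >= 2.
#' @return List of class `circ_test`: `statistic` (z), `p_value`, `n`.
#' @export
rayleigh_test <- function(angles) {
  n <- length(angles)
  if (n < 2) stop("need at least two angles")
  R <- circ_summary(angles)$R
  z <- n * R^2
  p <- exp(-z) * (1 + (2 * z - z^2) / (4 * n) -
                  (24 * z - 132 * z^2 + 76 * z^3 - 9 * z^4) / (288 * n^2))
  p <- min(max(p, 0), 1)
  structure(list(test = "Rayleigh", statistic = z, p_value = p, n = n),
            class = "circ_test")
}

#' @export
print.circ_test <- function(x, ...) {
  cat(sprintf("%s test: %s = %.4g", x$test,
              if (x$test == "Rayleigh") "z" else "F", x$statistic))
  if (!is.null(x$df)) cat(sprintf(", df = (%d, %d)", x$df[1], x$df[2]))
  cat(sprintf(", p = %.4g\n", x$p_value))
  if (!is.null(x$d)) cat(sprintf("  effect size d = %.3f\n", x$d))
  invisible(x)
}

## inverse of A(kappa) = I1(kappa)/I0(kappa): standard three-branch
## approximation (Fisher 1993), capped
a1inv <- function(R, cap = 1e4) {
  k <- if (R < 0.53) {
    2 * R + R^3 + 5 * R^5 / 6
  } else if (R < 0.85) {
    -0.4 + 1.39 * R + 0.43 / (1 - R)
  } else {
    1 / (R^3 - 4 * R^2 + 3 * R)
  }
  min(max(k, 0), cap)
}

#' Watson-Williams test for equal mean directions
#'
#' Circular analogue of the one-way ANOVA F-test. Groups are assumed to be
#' von Mises samples with a common concentration; the test statistic uses
#' the standard concentration correction factor \eqn{1 + 3/(8\hat\kappa)}
#' and is referred to an F distribution with (g - 1, N - g) degrees of
#' freedom. A warning is issued when the estimated concentration is below
#' 1, where the approximation becomes unreliable.
#'
#' @param groups list of two or more numeric vectors of angles in degrees,
#'   each of length >= 2.
#' @return List of class `circ_test`: `statistic` (F), `df`, `p_value`,
#'   `kappa` (pooled concentration estimate), `n`.
#' @export
watson_williams <- function(groups) {
  g <- length(groups)
  if (g < 2) stop("need at least two groups")
  if (any(vapply(groups, length, 0L) < 2))
    stop("each group needs at least two angles")
  ns <- vapply(groups, length, 0L)
  N <- sum(ns)
  Rs <- vapply(groups, function(x) {
    s <- circ_summary(x)
    if (s$R < 1e-12) stop("a group has zero resultant length")
    s$R * length(x)
  }, 0)
  Rall <- circ_summary(unlist(groups))$R * N
  rw <- sum(Rs) / N
  kappa <- a1inv(rw)
  if (kappa < 1)
    warning("estimated concentration below 1; the Watson-Williams ",
            "approximation may be unreliable")
  K <- 1 + 3 / (8 * kappa)
  Fstat <- K * ((N - g) * (sum(Rs) - Rall)) / ((g - 1) * (N - sum(Rs)))
  Fstat <- max(Fstat, 0)
  p <- stats::pf(Fstat, g - 1, N - g, lower.tail = FALSE)
  structure(list(test = "Watson-Williams", statistic = Fstat,
                 df = c(g - 1L, N - g), p_value = p, kappa = kappa, n = N),
            class = "circ_test")
}

#' Circular effect size (Cohen's d)
#'
#' Shortest angular difference between the two samples' mean directions,
#' divided by the pooled angular deviation (both in degrees).
#'
#' @param errs1,errs2 numeric vectors of angles in degrees.
#' @return Nonnegative effect size (`Inf`, with a warning, when the pooled
#'   angular deviation is zero but the means differ).
#' @export
cohens_d_circular <- function(errs1, errs2) {
  s1 <- circ_summary(errs1); s2 <- circ_summary(errs2)
  dmu <- abs(wrap180(s1$mu - s2$mu))
  n1 <- s1$n; n2 <- s2$n
  pooled <- sqrt(((n1 - 1) * s1$ad^2 + (n2 - 1) * s2$ad^2) / (n1 + n2 - 2))
  if (pooled == 0) {
    if (dmu == 0) return(0)
    warning("pooled angular deviation is zero with unequal means")
    return(Inf)
  }
  dmu / pooled
}

#' Fit a von Mises noise model
#'
#' Maximum-likelihood von Mises fit: the mean direction is the circular
#' mean, and the concentration is obtained from the mean resultant length
#' by the standard piecewise inverse-A approximation, capped at `cap`.
#'
#' @param errors numeric vector of angles in degrees, n >= 2.
#' @param cap upper bound for kappa (default 1e4).
#' @return List of class `vm_fit`: `mu` (degrees; `NA` when R = 0), `kappa`,
#'   `R`, `n`.
#' @export
fit_von_mises <- function(errors, cap = 1e4) {
  if (length(errors) < 2) stop("need at least two angles")
  s <- circ_summary(errors)
  kappa <- if (s$R < 1e-12) 0 else a1inv(s$R, cap)
  structure(list(mu = s$mu, kappa = kappa, R = s$R, n = s$n,
                 mu_defined = s$mu_defined),
            class = "vm_fit")
}

#' @export
print.vm_fit <- function(x, ...) {
  cat(sprintf("von Mises fit (n = %d): mu = %s, kappa = %.4g\n", x$n,
              if (x$mu_defined) sprintf("%.2f deg", x$mu) else "undefined",
              x$kappa))
  invisible(x)
}

#' von Mises log-likelihood
#'
#' Sum of log densities of `angles` under a von Mises distribution with
#' mean `mu` (degrees) and concentration `kappa`. Uses the exponentially
#' scaled Bessel function so large concentrations do not overflow.
#'
#' @param angles numeric vector of angles in degrees.
#' @param mu mean direction in degrees.
#' @param kappa concentration (>= 0).
#' @return Scalar log-likelihood (of the angles measured in radians).
#' @export
vm_loglik <- function(angles, mu, kappa) {
  th <- deg2rad(angles) - deg2rad(mu)
  # log I0(kappa) = log(besselI(kappa, 0, expon.scaled)) + kappa
  sum(kappa * cos(th) - log(2 * pi) -
        (log(besselI(kappa, 0, expon.scaled = TRUE)) + kappa))
}

#' Draw von Mises random angles
#'
#' Best-Fisher rejection sampler. `kappa = 0` gives the circular uniform
#' distribution; non-finite or very large `kappa` (beyond the cap used in
#' fitting) returns `mu` exactly, the noiseless limit.
#'
#' @param n number of draws.
#' @param mu mean direction in degrees.
#' @param kappa concentration.
#' @return Angles in degrees in [0, 360).
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  if (!is.finite(kappa) || kappa > 1e6) return(wrap360(rep(mu, n)))
  if (kappa < 1e-10) return(wrap360(stats::runif(n, 0, 360)))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 0L
  while (i < n) {
    u1 <- stats::runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    u2 <- stats::runif(1)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      i <- i + 1L
      u3 <- stats::runif(1)
      out[i] <- mu + rad2deg(sign(u3 - 0.5) * acos(f))
    }
  }
  wrap360(out)
}

#' Bayesian information criterion
#'
#' \eqn{BIC = k \ln(n) - 2 \,\mathrm{loglik}}; lower is preferable.
#'
#' @param k number of free parameters (>= 0).
#' @param n number of observations (>= 1).
#' @param loglik maximized log-likelihood.
#' @return List of class `model_score`: `k`, `n`, `loglik`, `bic`.
#' @export
bic_score <- function(k, n, loglik) {
  stopifnot(k >= 0, n >= 1)
  structure(list(k = k, n = n, loglik = loglik,
                 bic = k * log(n) - 2 * loglik),
            class = "model_score")
}

#' @export
print.model_score <- function(x, ...) {
  cat(sprintf("BIC = %.4f  (k = %d, n = %d, loglik = %.4f)\n",
              x$bic, x$k, x$n, x$loglik))
  invisible(x)
}

#' Free-parameter counts of the cognitive-map models
#'
#' The embedded-graph model is specified by the two planar coordinates of
#' every vertex plus the two von Mises noise parameters: \eqn{2|V| + 2}.
#' The non-metric labeled graph is specified by its independent labels plus
#' the noise term; how the angle labels are counted is a convention:
#' `"ordered"` (default) counts one angle per ordered through-triplet,
#' `"unordered"` one per unordered through-triplet (the reversal being
#' determined up to sign), `"per_triplet"` one per triplet including
#' backtracks.
#'
#' @param model `"embedded"` or `"nonmetric"`.
#' @param graph a [labeled_graph()].
#' @param angle_convention counting convention for the non-metric model's
#'   angle labels.
#' @param noise_parameters how many parameters the noise term contributes
#'   (default 2: von Mises mu and kappa).
#' @return Integer parameter count.
#' @export
count_parameters <- function(model = c("embedded", "nonmetric"), graph,
                             angle_convention = c("ordered", "unordered",
                                                  "per_triplet"),
                             noise_parameters = 2L) {
  model <- match.arg(model)
  if (model == "embedded")
    return(2L * length(graph$vertices) + as.integer(noise_parameters))
  angle_convention <- match.arg(angle_convention)
  tr <- graph$triplets
  thru <- tr[tr$i != tr$k, , drop = FALSE]
  n_alpha <- switch(angle_convention,
    ordered = nrow(thru),
    unordered = nrow(thru) / 2L,
    per_triplet = nrow(tr))
  as.integer(nrow(graph$edges) + n_alpha + noise_parameters)
}
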