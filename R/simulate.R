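# run code under a temporary RNG state, restoring the caller's stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specification of a synthetic expression dataset
#'
#' Describes a "large p, small n" dataset with a planted class-separating
#' structure: `m_info` informative genes carry a 1-D curve per class
#' (disjoint parameter intervals, lifted nonlinearly and perturbed with
#' Gaussian noise), the remaining `p - m_info` genes are standard Gaussian
#' noise independent of the labels, and the gene order is randomly permuted.
#'
#' @param n Samples.
#' @param p Genes.
#' @param C Classes.
#' @param proportions Class proportions (default equal), summing to 1.
#' @param m_info Informative genes (`< p`).
#' @param manifold `"swiss_roll_arcs"` (spiral arcs, one parameter interval
#'   per class), `"s_curve_arcs"`, or `"gaussian_linear"` (linearly
#'   separable Gaussian classes, the linear control).
#' @param sigma Noise standard deviation added to the informative
#'   coordinates.
#' @param seed Seed making the dataset fully reproducible.
#' @return A validated list of class `sim_spec`.
#' @export
sim_spec <- function(n = 60, p = 300, C = 2, proportions = NULL,
                     m_info = 10,
                     manifold = c("swiss_roll_arcs", "s_curve_arcs",
                                  "gaussian_linear"),
                     sigma = 0.1, seed = 1) {
  manifold <- match.arg(manifold)
  if (is.null(proportions)) proportions <- rep(1 / C, C)
  if (abs(sum(proportions) - 1) > 1e-8) abort("proportions must sum to 1.")
  if (m_info >= p) abort("m_info must be smaller than p.")
  if (sigma < 0) abort("sigma must be >= 0.")
  if (n < 2 * C) abort("need at least 2 samples per class.")
  structure(list(n = as.integer(n), p = as.integer(p), C = as.integer(C),
                 proportions = proportions, m_info = as.integer(m_info),
                 manifold = manifold, sigma = sigma, seed = as.integer(seed)),
            class = "sim_spec")
}

#' Generate a synthetic expression dataset with planted informative genes
#'
#' Samples of class `c` draw a curve parameter `t` from the disjoint
#' interval `[1.3 (c-1), 1.3 (c-1) + 1]`. Each informative gene is a smooth
#' nonlinear lift of `t` — spiral coordinates and random sinusoidal
#' harmonics for `"swiss_roll_arcs"`, an S-shaped lift for
#' `"s_curve_arcs"` — plus `N(0, sigma)` noise, so classes are separable
#' along the curve but in general not linearly. `"gaussian_linear"` places
#' class means 3 units apart per informative gene instead (the linear
#' control). Noise genes are independent `N(0, 1)`.
#'
#' @param spec A [sim_spec()].
#' @return A list: `dataset` (an [expression_dataset()]) and `informative`
#'   (sorted column indices of the planted genes after permutation).
#' @export
generate_expression <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  with_seed(spec$seed, {
    sizes <- diff(round(cumsum(c(0, spec$proportions)) * spec$n))
    sizes[spec$C] <- spec$n - sum(sizes[-spec$C])
    y <- rep(seq_len(spec$C), sizes)
    t <- runif(spec$n, 1.3 * (y - 1), 1.3 * (y - 1) + 1)
    info <- matrix(0, spec$n, spec$m_info)
    if (spec$manifold == "gaussian_linear") {
      for (j in seq_len(spec$m_info)) info[, j] <- 3 * (y - 1)
    } else {
      # first two informative genes trace the planar curve itself; the rest
      # are random smooth harmonics of the same parameter
      theta <- 1.5 * pi + 2 * t
      if (spec$manifold == "swiss_roll_arcs") {
        base1 <- theta * cos(theta) / pi
        base2 <- theta * sin(theta) / pi
      } else {
        base1 <- sin(pi * t)
        base2 <- sign(t - max(t) / 2) * (cos(pi * t) - 1)
      }
      info[, 1] <- base1
      if (spec$m_info >= 2) info[, 2] <- base2
      if (spec$m_info >= 3) {
        # a harmonic whose class intervals alias to overlapping values would
        # be "informative" in name only; resample until the lift separates
        # the classes (between-class to total spread above a fixed margin)
        for (j in 3:spec$m_info) {
          for (try in 1:50) {
            w <- sample(1:3, 1); phase <- runif(1, 0, 2 * pi)
            amp <- runif(1, 0.8, 1.2)
            g <- amp * sin(w * t + phase)
            mu_c <- tapply(g, y, mean)
            sep <- sqrt(var(mu_c[y])) / sd(g)
            if (is.finite(sep) && sep >= 0.5) break
          }
          info[, j] <- g
        }
      }
    }
    info <- info + matrix(rnorm(spec$n * spec$m_info, sd = spec$sigma),
                          spec$n, spec$m_info)
    noise <- matrix(rnorm(spec$n * (spec$p - spec$m_info)),
                    spec$n, spec$p - spec$m_info)
    X <- cbind(info, noise)
    perm <- sample.int(spec$p)
    X <- X[, perm, drop = FALSE]
    informative <- sort(match(seq_len(spec$m_info), perm))
    dimnames(X) <- list(sprintf("s%03d", seq_len(spec$n)),
                        sprintf("g%04d", seq_len(spec$p)))
    list(dataset = expression_dataset(X, y,
                                      paste0("class", seq_len(spec$C))),
         informative = informative)
  })
}

#' Deterministic fixtures shared across examples and tests
#'
#' @return Named list of small datasets with known properties:
#' \describe{
#'   \item{collinear4}{points 0, 1, 3, 6 on a line (1 column).}
#'   \item{twoclusters}{two 15-point Gaussian clusters (sd 0.5) with centres
#'     50 units apart, with labels — guarantees k-NN disconnection for small
#'     k.}
#'   \item{swissroll200}{200 points on a classic 3-D swiss roll.}
#'   \item{separable}{n = 40, p = 20 linearly separable two-class dataset.}
#'   \item{planted300}{the n = 60, p = 300 planted-manifold dataset with 10
#'     informative genes (seed 1).}
#' }
#' @export
fixture_suite <- function() {
  out <- list()
  out$collinear4 <- matrix(c(0, 1, 3, 6), ncol = 1)
  out$twoclusters <- with_seed(42, {
    pts <- rbind(matrix(rnorm(30, sd = 0.5), 15, 2),
                 matrix(rnorm(30, sd = 0.5), 15, 2) +
                   matrix(c(50, 0), 15, 2, byrow = TRUE))
    list(points = pts, labels = rep(1:2, each = 15))
  })
  out$swissroll200 <- with_seed(7, {
    t <- runif(200, 1.5 * pi, 4.5 * pi)
    h <- runif(200, 0, 10)
    cbind(t * cos(t), h, t * sin(t))
  })
  out$separable <- generate_expression(
    sim_spec(n = 40, p = 20, C = 2, m_info = 4,
             manifold = "gaussian_linear", sigma = 0.3, seed = 5))
  out$planted300 <- generate_expression(
    sim_spec(n = 60, p = 300, C = 2, m_info = 10,
             manifold = "swiss_roll_arcs", sigma = 0.1, seed = 1))
  out
}
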