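#' Pointwise one-sample t-tests against per-participant baselines
#'
#' At each timepoint, tests the across-participant distribution of
#' `curve - own baseline` against zero with a two-tailed one-sample t-test.
#' Timepoints with zero variance are assigned `t = 0`, `p = 1` by
#' convention.
#'
#' @param curves participants-by-timepoints matrix of event-locked values.
#' @param baselines per-participant baseline scalars (recycled to a vector).
#' @return A list with vectors `t` and `p`.
#' @export
pointwise_t <- function(curves, baselines) {
  n <- nrow(curves)
  if (is.null(n) || n < 2) stop("need >= 2 participants for pointwise t-tests")
  D <- sweep(curves, 1, baselines)
  m <- colMeans(D)
  v <- colSums(sweep(D, 2, m)^2) / (n - 1)
  tv <- ifelse(v > 1e-24, m / sqrt(v / n), 0)
  pv <- ifelse(v > 1e-24, 2 * stats::pt(-abs(tv), n - 1), 1)
  list(t = tv, p = pv)
}

#' Form clusters of consecutive significant same-signed timepoints
#'
#' A cluster is a maximal run of consecutive timepoints that all have
#' `p < alpha` and the same sign of effect; its mass is the sum of the
#' t-values over the run.
#'
#' @param t,p pointwise statistics (e.g. from [pointwise_t()]).
#' @param alpha pointwise threshold.
#' @param offsets optional timepoint offsets (s) used to report cluster
#'   extents; defaults to indices.
#' @return Data frame of clusters: `start`, `end`, `sign`, `mass`.
#' @export
form_clusters <- function(t, p, alpha = 0.05, offsets = seq_along(t)) {
  s <- ifelse(p < alpha, sign(t), 0)
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values != 0)
  if (!length(keep))
    return(data.frame(start = numeric(0), end = numeric(0), sign = numeric(0),
                      mass = numeric(0)))
  data.frame(start = offsets[starts[keep]], end = offsets[ends[keep]],
             sign = r$values[keep],
             mass = vapply(keep, function(k) sum(t[starts[k]:ends[k]]), numeric(1)))
}

max_cluster_mass <- function(t, p, alpha) {
  s <- ifelse(p < alpha, sign(t), 0)
  r <- rle(s)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values != 0)
  if (!length(keep)) return(0)
  max(abs(vapply(keep, function(k) sum(t[starts[k]:ends[k]]), numeric(1))))
}

#' Mirror a participant's curve in the baseline
#'
#' `2 * baseline - curve`: subtracts the baseline, flips the sign of the
#' deviation, and adds the baseline back. An involution.
#'
#' @param curve numeric vector.
#' @param baseline scalar baseline.
#' @export
mirror_curve <- function(curve, baseline) 2 * baseline - curve

#' Cluster-mass sign-flip Monte Carlo test
#'
#' Identifies clusters where the across-participant event-locked signal
#' deviates from baseline, and assigns each a Monte Carlo p-value by
#' comparison to a null distribution of extreme cluster masses: on each of
#' `n_iter` iterations every participant's curve is independently mirrored
#' in its baseline with probability 1/2, the cluster computation repeated,
#' and the most extreme absolute cluster mass stored. A cluster's `mc_p` is
#' the proportion of null values strictly exceeding its absolute mass.
#'
#' @inheritParams pointwise_t
#' @param n_iter number of Monte Carlo iterations.
#' @param alpha pointwise cluster-forming threshold.
#' @param seed optional integer seed (results are deterministic given it).
#' @param offsets optional timepoint offsets (s) for reporting.
#' @return An object of class `cluster_result`: list with `clusters` (data
#'   frame incl. `mc_p`), `null_mass`, `n_iterations`, `seed`, and the
#'   pointwise `t` and `p`.
#' @export
monte_carlo_p <- function(curves, baselines, n_iter = 1000, alpha = 0.05,
                          seed = NULL, offsets = NULL) {
  if (n_iter < 1) stop("n_iter must be >= 1")
  n <- nrow(curves)
  pw <- pointwise_t(curves, baselines)
  if (is.null(offsets)) offsets <- seq_along(pw$t)
  obs <- form_clusters(pw$t, pw$p, alpha, offsets)
  if (!is.null(seed)) set.seed(as.integer(seed))
  D <- sweep(curves, 1, baselines)
  ssq <- colSums(D^2)
  S <- matrix(sample(c(-1, 1), n_iter * n, replace = TRUE), n_iter, n)
  M <- (S %*% D) / n
  V <- (matrix(ssq, n_iter, ncol(D), byrow = TRUE) - n * M^2) / (n - 1)
  null_mass <- numeric(n_iter)
  for (i in seq_len(n_iter)) {
    vi <- V[i, ]
    ti <- ifelse(vi > 1e-24, M[i, ] / sqrt(vi / n), 0)
    pi_ <- ifelse(vi > 1e-24, 2 * stats::pt(-abs(ti), n - 1), 1)
    null_mass[i] <- max_cluster_mass(ti, pi_, alpha)
  }
  obs$mc_p <- vapply(obs$mass, function(m) mean(null_mass > abs(m)), numeric(1))
  structure(list(clusters = obs, null_mass = null_mass, n_iterations = n_iter,
                 seed = seed, t = pw$t, p = pw$p, offsets = offsets),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result>", nrow(x$clusters), "cluster(s);",
      x$n_iterations, "Monte Carlo iterations\n")
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}
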