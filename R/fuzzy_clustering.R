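#' Fuzzy c-means clustering in the two-wave bad-performance plane
#'
#' Standard Bezdek alternating optimisation. Each point (a participant's
#' (BP1, BP3) pair) receives a membership in \[0, 1\] for each of the `c`
#' clusters, rows summing to 1. Memberships and centroids are updated in
#' turn:
#' \deqn{u_{ik} = 1 / \sum_j (d_{ik}/d_{jk})^{2/(m-1)}, \qquad
#'       q_i = \sum_k u_{ik}^m x_k / \sum_k u_{ik}^m}
#' until the maximum absolute membership change falls below `tol` or
#' `max_iter` is reached. A point coinciding with a centroid gets a crisp
#' one-hot membership there. The objective
#' \eqn{J = \sum_{ik} u_{ik}^m d_{ik}^2} is non-increasing across
#' iterations.
#'
#' @param points numeric matrix or data frame, one row per participant
#'   (typically two columns: BP at wave 1 and wave 3).
#' @param c number of clusters (>= 1; at most the number of distinct points).
#' @param m fuzzifier, > 1. 2 is the conventional default; as m approaches 1
#'   the solution approaches hard k-means.
#' @param tol convergence tolerance on the maximum membership change.
#' @param max_iter maximum number of iterations.
#' @param seed integer seed for the centroid initialisation (centroids start
#'   at `c` distinct data points).
#' @return an object of class `fcm_fit`: `memberships` (n x c),
#'   `centroids` (c x d), `m`, `objective_value`, `objective_trace`,
#'   `n_iterations`, `converged`.
#' @examples
#' pts <- rbind(matrix(rnorm(60), ncol = 2), matrix(rnorm(60, 8), ncol = 2))
#' fit <- fcm(pts, c = 2, seed = 1)
#' table(assign_hard(fit))
#' @export
fcm <- function(points, c, m = 2, tol = 1e-6, max_iter = 1000, seed = 1) {
  x <- as.matrix(points)
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop("points must be finite")
  if (m <= 1) stop("fuzzifier m must be > 1")
  stopifnot(c >= 1)
  n <- nrow(x)
  distinct <- unique(x)
  if (c > nrow(distinct)) {
    stop("c (", c, ") exceeds the number of distinct points (",
         nrow(distinct), ")")
  }

  set.seed(seed %% 2147483647)
  centroids <- distinct[sample(nrow(distinct), c), , drop = FALSE]

  sqdist <- function(x, q) {
    # n x c matrix of squared Euclidean distances
    outer(rowSums(x^2), rep(1, nrow(q))) +
      outer(rep(1, nrow(x)), rowSums(q^2)) - 2 * x %*% t(q)
  }
  memberships_from <- function(d2) {
    d2 <- pmax(d2, 0)
    u <- d2^(-1 / (m - 1))
    zero <- d2 < 1e-300
    hit <- rowSums(zero) > 0
    if (any(hit)) {
      u[hit, ] <- 0
      u[hit, ] <- zero[hit, , drop = FALSE] / rowSums(zero[hit, , drop = FALSE])
    }
    u / rowSums(u)
  }

  u_old <- matrix(0, n, c)
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    d2 <- sqdist(x, centroids)
    u <- memberships_from(d2)
    w <- u^m
    centroids <- (t(w) %*% x) / colSums(w)
    trace[iter] <- sum(w * sqdist(x, centroids))
    if (max(abs(u - u_old)) < tol) { converged <- TRUE; break }
    if (iter >= max_iter) break
    u_old <- u
  }

  structure(list(
    memberships = u,
    centroids = centroids,
    m = m,
    objective_value = trace[iter],
    objective_trace = trace,
    n_iterations = iter,
    converged = converged
  ), class = "fcm_fit")
}

#' @export
print.fcm_fit <- function(x, ...) {
  cat("Fuzzy c-means fit:", ncol(x$memberships), "clusters,",
      nrow(x$memberships), "points, m =", x$m, "\n")
  cat("  objective:", format(x$objective_value),
      "| iterations:", x$n_iterations,
      "| converged:", x$converged, "\n")
  cat("Centroids:\n"); print(round(x$centroids, 3))
  invisible(x)
}

#' Best-of-restarts fuzzy c-means
#'
#' Runs [fcm()] `restarts` times from seeded random initialisations and
#' keeps the fit with the lowest objective.
#'
#' @inheritParams fcm
#' @param restarts number of random restarts.
#' @return the best `fcm_fit`.
#' @export
fcm_restarts <- function(points, c, m = 2, tol = 1e-6, max_iter = 1000,
                         seed = 1, restarts = 5) {
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- fcm(points, c, m, tol, max_iter, seed = seed + 7 * (r - 1))
    if (is.null(best) || fit$objective_value < best$objective_value) {
      best <- fit
    }
  }
  best
}

#' Hard cluster assignment from a fuzzy partition
#'
#' Assigns each participant to the cluster with the largest membership
#' probability; ties break toward the lowest cluster index.
#'
#' @param partition an `fcm_fit` or a membership matrix.
#' @return integer vector of cluster labels in 1..c.
#' @export
assign_hard <- function(partition) {
  u <- if (inherits(partition, "fcm_fit")) partition$memberships
       else as.matrix(partition)
  max.col(u, ties.method = "first")
}

#' Within-clusters sum of squares
#'
#' The exact sum, over hard-assigned clusters, of squared Euclidean
#' distances between each member and its cluster centroid:
#' \deqn{WSS(c) = \sum_{i=1}^{c} \sum_{x \in C_i} \|x - q_i\|^2}
#'
#' @param points numeric matrix, one row per participant.
#' @param hard_labels integer labels in 1..c.
#' @param centroids c x d centroid matrix.
#' @return the WSS value (non-negative scalar).
#' @export
wss <- function(points, hard_labels, centroids) {
  x <- as.matrix(points)
  q <- as.matrix(centroids)
  if (any(hard_labels < 1 | hard_labels > nrow(q))) {
    stop("hard_labels out of 1..c range")
  }
  sum((x - q[hard_labels, , drop = FALSE])^2)
}

#' Elbow scan over candidate cluster counts
#'
#' Runs best-of-restarts fuzzy c-means for c = 1..`c_max`, hardens each
#' partition, and records WSS(c). The suggested cluster count automates the
#' classical elbow reading: successive WSS drops are normalised by the total
#' dispersion WSS(1), and the suggested c is the smallest whose next drop
#' would explain less than `knee_ratio` of the total, subject to every hard
#' cluster holding at least `min_cluster_size` members (a solution with an
#' excessively small cluster is rejected even if the knee rule would accept
#' it). When the data form a single tight clump (WSS(1)/n below
#' `tight_tol`, in squared bad-performance units) c = 1 is suggested
#' outright. The full scan table is always returned for human review.
#'
#' @inheritParams fcm
#' @param c_max largest cluster count scanned (>= 2; conventionally 10).
#' @param restarts random restarts per c.
#' @param knee_ratio minimum fraction of total dispersion a further cluster
#'   must explain.
#' @param min_cluster_size smallest admissible hard cluster.
#' @param tight_tol mean squared spread below which the data count as one
#'   clump.
#' @return an object of class `elbow_scan`: `table` (c, wss, smallest hard
#'   cluster size), `suggested_c`, and the fitted partitions.
#' @export
elbow_scan <- function(points, c_max = 10, m = 2, restarts = 5, seed = 1,
                       tol = 1e-6, max_iter = 1000,
                       knee_ratio = 0.15, min_cluster_size = 5,
                       tight_tol = 1) {
  x <- as.matrix(points)
  stopifnot(c_max >= 2)
  n_distinct <- nrow(unique(x))
  if (c_max > n_distinct) {
    stop("c_max (", c_max, ") exceeds the number of distinct points (",
         n_distinct, ")")
  }
  n <- nrow(x)
  wss_c <- numeric(c_max)
  min_size <- integer(c_max)
  fits <- vector("list", c_max)
  for (cc in seq_len(c_max)) {
    fit <- fcm_restarts(x, cc, m, tol, max_iter,
                        seed = seed + 1000 * cc, restarts = restarts)
    hard <- assign_hard(fit)
    wss_c[cc] <- wss(x, hard, fit$centroids)
    min_size[cc] <- min(tabulate(hard, nbins = cc))
    fits[[cc]] <- fit
  }

  if (wss_c[1] / n < tight_tol) {
    suggested <- 1L
  } else {
    gain <- c(NA_real_, -diff(wss_c) / wss_c[1])   # gain[c]: drop going to c
    size_ok <- min_size >= min_cluster_size
    suggested <- NA_integer_
    for (cc in seq_len(c_max - 1)) {
      if (gain[cc + 1] < knee_ratio && size_ok[cc]) { suggested <- cc; break }
    }
    if (is.na(suggested)) {
      ok <- which(size_ok)
      suggested <- if (length(ok)) max(ok) else c_max
    }
  }

  structure(list(
    table = data.frame(c = seq_len(c_max), wss = wss_c,
                       min_cluster_size = min_size),
    suggested_c = as.integer(suggested),
    fits = fits
  ), class = "elbow_scan")
}

#' @export
print.elbow_scan <- function(x, ...) {
  cat("WSS elbow scan (suggested c =", x$suggested_c, ")\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Semantic colour labels for a three-cluster solution
#'
#' Maps the three clusters to the conventional colours of the trajectory
#' reading: blue is the healthy cluster (smallest BP1 + BP3 centroid), red
#' the declining cluster (largest wave-3 BP among the rest), green the
#' remaining, typically improving, cluster.
#'
#' @param centroids 3 x 2 centroid matrix, columns (BP1, BP3).
#' @return character vector of length 3 (`"blue"`, `"green"`, `"red"`) named
#'   by cluster index, or NULL with a warning when c != 3.
#' @export
label_semantics <- function(centroids) {
  q <- as.matrix(centroids)
  if (nrow(q) != 3) {
    warning("semantic labelling requires exactly 3 clusters; skipped")
    return(NULL)
  }
  if (anyDuplicated(q) > 0) {
    warning("coincident centroids; semantic labels assigned by index order")
  }
  sums <- q[, 1] + q[, 2]
  blue <- which(sums == min(sums))[1]
  rest <- setdiff(1:3, blue)
  red <- rest[which(q[rest, 2] == max(q[rest, 2]))[1]]
  green <- setdiff(rest, red)
  out <- character(3)
  out[blue] <- "blue"; out[green] <- "green"; out[red] <- "red"
  stats::setNames(out, as.character(1:3))
}
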