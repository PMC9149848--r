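two_blobs <- function(n = 100, sep = 20, spread = 1, seed = 1) {
  set.seed(seed)
  rbind(cbind(rnorm(n, 0, spread), rnorm(n, 0, spread)),
        cbind(rnorm(n, sep, spread), rnorm(n, sep, spread)))
}

test_that("single-cluster fit degenerates to the coordinate-wise mean", {
  pts <- two_blobs(30, seed = 2)
  fit <- fcm(pts, c = 1, seed = 1)
  expect_equal(as.numeric(fit$centroids), colMeans(pts), tolerance = 1e-8)
  expect_true(all(abs(fit$memberships - 1) < 1e-12))
})

test_that("a point midway between symmetric clusters splits its membership", {
  set.seed(3)
  left <- cbind(rnorm(80, -6, 0.3), rnorm(80, 0, 0.3))
  right <- -left   # exact mirror symmetry
  pts <- rbind(left, right, c(0, 0))
  fit <- fcm(pts, c = 2, seed = 4)
  expect_equal(as.numeric(fit$memberships[161, ]), c(0.5, 0.5),
               tolerance = 0.02)
})

test_that("well-separated blobs are recovered exactly", {
  pts <- two_blobs(100, sep = 20, spread = 1, seed = 5)
  fit <- fcm_restarts(pts, c = 2, seed = 6, restarts = 5)
  hard <- assign_hard(fit)
  truth <- rep(1:2, each = 100)
  agree <- max(mean(hard == truth), mean(hard == 3 - truth))
  expect_equal(agree, 1)
  means <- rbind(colMeans(pts[1:100, ]), colMeans(pts[101:200, ]))
  d <- min(sum(abs(fit$centroids - means)), sum(abs(fit$centroids[2:1, ] - means)))
  expect_lt(d / 4, 0.5)
})

test_that("membership rows sum to one and the objective never increases", {
  set.seed(11)
  for (i in 1:20) {
    pts <- matrix(rnorm(2 * sample(20:60, 1), sd = sample(1:5, 1)), ncol = 2)
    cc <- sample(1:4, 1)
    fit <- fcm(pts, c = cc, m = runif(1, 1.3, 3), seed = i)
    expect_true(all(abs(rowSums(fit$memberships) - 1) < 1e-9))
    expect_true(all(diff(fit$objective_trace) <= 1e-8))
    # centroids inside the data's bounding box (convex hull superset check)
    expect_true(all(fit$centroids[, 1] >= min(pts[, 1]) - 1e-9 &
                      fit$centroids[, 1] <= max(pts[, 1]) + 1e-9))
  }
})

test_that("points coinciding with a centroid get crisp membership", {
  pts <- rbind(matrix(0, 10, 2), matrix(5, 10, 2))
  fit <- fcm(pts, c = 2, seed = 1)
  expect_true(all(apply(fit$memberships, 1, max) > 1 - 1e-9))
})

test_that("requesting more clusters than distinct points fails", {
  pts <- rbind(c(0, 0), c(0, 0), c(1, 1))
  expect_error(fcm(pts, c = 3, seed = 1), "distinct")
  expect_error(fcm(rbind(c(0, 0), c(NA, 1)), c = 1), "finite")
  expect_error(fcm(rbind(c(0, 0), c(1, 1)), c = 2, m = 1), "m must be")
})

test_that("near-hard fuzzifier approaches the k-means solution", {
  pts <- two_blobs(50, sep = 12, spread = 1, seed = 8)
  fit <- fcm_restarts(pts, c = 2, m = 1.05, seed = 9, restarts = 5)
  km <- kmeans(pts, centers = rbind(colMeans(pts[1:50, ]),
                                    colMeans(pts[51:100, ])))
  reorder <- if (sum((fit$centroids[1, ] - km$centers[1, ])^2) <
                 sum((fit$centroids[1, ] - km$centers[2, ])^2)) 1:2 else 2:1
  expect_equal(unname(fit$centroids[reorder, ]), unname(km$centers),
               tolerance = 0.05)
  expect_true(all(apply(fit$memberships, 1, max) > 0.95))
})

test_that("hard assignment takes the maximum with low-index tie-break", {
  u <- rbind(c(0.2, 0.5, 0.3), c(0.5, 0.5, 0.0), diag(3))
  expect_equal(assign_hard(u), c(2L, 1L, 1L, 2L, 3L))
})

test_that("WSS matches trivial cases and a brute-force oracle", {
  pts <- rbind(c(0, 0), c(2, 2))
  expect_equal(wss(pts, c(1, 1), rbind(c(1, 1))), 4)
  expect_equal(wss(pts, c(1, 2), pts), 0)
  expect_error(wss(pts, c(1, 3), pts), "out of")
  set.seed(13)
  for (i in 1:100) {
    n <- sample(5:30, 1); cc <- sample(1:4, 1)
    p <- matrix(rnorm(2 * n), ncol = 2)
    lab <- sample(cc, n, replace = TRUE)
    q <- matrix(rnorm(2 * cc), ncol = 2)
    expect_equal(wss(p, lab, q), oracle_wss(p, lab, q), tolerance = 1e-9)
  }
})

test_that("elbow scan returns a full non-negative WSS table", {
  pts <- two_blobs(40, sep = 15, seed = 14)
  scan <- elbow_scan(pts, c_max = 5, seed = 15)
  expect_equal(scan$table$c, 1:5)
  expect_true(all(scan$table$wss >= 0))
  expect_error(elbow_scan(rbind(c(0, 0), c(1, 1), c(0, 0)), c_max = 4),
               "distinct")
})

test_that("a single tight blob suggests one cluster", {
  set.seed(16)
  pts <- matrix(rnorm(120, sd = 0.2), ncol = 2)
  scan <- elbow_scan(pts, c_max = 5, seed = 17)
  expect_equal(scan$suggested_c, 1L)
})

test_that("semantic labels follow the centroid geometry", {
  q <- rbind(c(0.1, 0.1), c(2.5, 1.5), c(1.0, 14))
  expect_equal(unname(label_semantics(q)), c("blue", "green", "red"))
  perm <- q[c(3, 1, 2), ]
  expect_equal(unname(label_semantics(perm)), c("red", "blue", "green"))
  expect_warning(out <- label_semantics(rbind(c(0, 0), c(0, 0), c(1, 9))),
                 "coincident")
  expect_equal(unname(out), c("blue", "green", "red"))
  expect_warning(expect_null(label_semantics(rbind(c(0, 0), c(1, 1)))),
                 "3 clusters")
})
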