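# Independent brute-force oracles, kept free of the package's DTW and
# Hausdorff implementations.

# Exhaustive enumeration of all monotone warping paths from (1,1) to (n,m)
# with steps {(1,0),(0,1),(1,1)}; returns the minimal summed local cost.
dtw_brute_force <- function(v1, v2, lambda) {
  n <- nrow(v1); m <- nrow(v2)
  local_cost <- function(i, j)
    sqrt(sum((v1[i, ] - v2[j, ])^2)) + lambda * abs(i - j)
  best <- Inf
  recurse <- function(i, j, acc) {
    acc <- acc + local_cost(i, j)
    if (i == n && j == m) {
      best <<- min(best, acc)
      return(invisible(NULL))
    }
    if (i < n) recurse(i + 1, j, acc)
    if (j < m) recurse(i, j + 1, acc)
    if (i < n && j < m) recurse(i + 1, j + 1, acc)
    invisible(NULL)
  }
  recurse(1, 1, 0)
  best
}

# Reference trajectory distance built on the brute-force path search.
trajectory_distance_brute <- function(v1, v2, lambda_coeff = 0.045) {
  lambda <- lambda_coeff *
    mean(c(sqrt(rowSums(v1^2)), sqrt(rowSums(v2^2))))
  d <- dtw_brute_force(v1, v2, lambda) / nrow(v1)
  1 - 1 / (d + 1)
}

# Double-loop modified Hausdorff distance.
image_distance_brute <- function(A, B) {
  A <- sweep(as.matrix(A), 2, colMeans(A))
  B <- sweep(as.matrix(B), 2, colMeans(B))
  dAB <- mean(apply(A, 1, function(a)
    min(apply(B, 1, function(b) sqrt(sum((a - b)^2))))))
  dBA <- mean(apply(B, 1, function(b)
    min(apply(A, 1, function(a) sqrt(sum((a - b)^2))))))
  (dAB + dBA) / 2
}

# A smooth random open stroke (positions over time) for property tests.
random_stroke_positions <- function(n = 40) {
  t <- seq(0, 1, length.out = n)
  x <- cumsum(rnorm(n)); y <- cumsum(rnorm(n))
  cbind(stats::fitted(stats::loess(x ~ t, span = 0.5)),
        stats::fitted(stats::loess(y ~ t, span = 0.5)))
}
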