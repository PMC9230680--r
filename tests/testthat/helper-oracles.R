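# Independent oracles used across the suite. These deliberately avoid the
# closed forms under test.

# truncated matrix-exponential series sum_{k=0}^{nterms} M^k / k!
expm_series <- function(M, nterms = 30) {
  out <- diag(nrow(M))
  term <- diag(nrow(M))
  for (k in seq_len(nterms)) {
    term <- term %*% M / k
    out <- out + term
  }
  out
}

# random unit revolute twist (unit omega, arbitrary v)
random_unit_twist <- function() {
  w <- stats::rnorm(3)
  w <- w / sqrt(sum(w^2))
  twist(w, stats::rnorm(3, sd = 20))
}

random_wrench <- function() {
  wrench(stats::rnorm(3, sd = 50), stats::rnorm(3, sd = 500))
}

# maximum elementwise difference between two poses
pose_diff <- function(g1, g2) {
  max(abs(as_matrix4(g1) - as_matrix4(g2)))
}

# bench table values, frozen independently of the packaged CSV
TABLE3 <- data.frame(
  period = 1:10,
  F1 = c(0.56, 12.18, 16.89, 27.28, 35.81, 43.17, 58.65, 70.51, 90.77, 99.62),
  F2 = c(8.56, 20.78, 30.31, 40.03, 53.04, 63.83, 77.15, 91.92, 99.39, 117.54),
  Fz2m = c(5.26, 11.03, 15.58, 48.11, 59.75, 72.83, 93.52, 111.37, 130.25,
           145.39))

TABLE4 <- data.frame(
  period = 1:10,
  Fz2s = c(3.667, 22.32, 32.71, 50.89, 68.53, 81.28, 120.00, 130.60, 151.31,
           155.0))
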