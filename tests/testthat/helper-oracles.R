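# Independent numerical oracles used across the suite. These deliberately
# avoid the package's own projection/fusion/statistics code paths.

## Screen projection of a 3D point from an arbitrary eye, by explicit
## ray-plane intersection with the screen plane z = 0.
oracle_project <- function(p, eye) {
  dir <- p - eye
  t <- -eye[3] / dir[3]
  eye[1:2] + t * dir[1:2]
}

## Triangulate a 3D point from its left/right screen coordinates: find the
## point minimising distance to both eye->screen rays (least squares).
oracle_triangulate <- function(xy_l, xy_r, iod, dist) {
  eye_l <- c(-iod / 2, 0, dist)
  eye_r <- c(iod / 2, 0, dist)
  d1 <- c(xy_l[1], xy_l[2], 0) - eye_l
  d2 <- c(xy_r[1], xy_r[2], 0) - eye_r
  # closest point between the two rays: solve for parameters s, t
  w0 <- eye_l - eye_r
  a <- sum(d1 * d1); b <- sum(d1 * d2); cc <- sum(d2 * d2)
  dd <- sum(d1 * w0); e <- sum(d2 * w0)
  denom <- a * cc - b * b
  s <- (b * e - cc * dd) / denom
  t <- (a * e - b * dd) / denom
  (eye_l + s * d1 + eye_r + t * d2) / 2
}

## Coarse-to-fine 2D grid argmax of the coupling-prior log posterior.
oracle_grid_map <- function(est_T, est_D, sigma_T, sigma_D, sigma_c,
                            half_width = 30, passes = 6, n_grid = 61) {
  logpost <- function(sT, sD) {
    -(est_T - sT)^2 / (2 * sigma_T^2) - (est_D - sD)^2 / (2 * sigma_D^2) -
      (sT - sD)^2 / (2 * sigma_c^2)
  }
  cT <- est_T; cD <- est_D; hw <- half_width
  for (pass in seq_len(passes)) {
    gT <- seq(cT - hw, cT + hw, length.out = n_grid)
    gD <- seq(cD - hw, cD + hw, length.out = n_grid)
    lp <- outer(gT, gD, logpost)
    ij <- arrayInd(which.max(lp), dim(lp))
    cT <- gT[ij[1]]; cD <- gD[ij[2]]
    hw <- hw * 2.5 / (n_grid - 1) * 2   # shrink around current argmax
  }
  c(cT, cD)
}

## Inverse normal CDF by bisection on pnorm (oracle for qnorm-based d').
oracle_z <- function(p) {
  vapply(p, function(pp) {
    stats::uniroot(function(z) stats::pnorm(z) - pp, c(-10, 10),
                   tol = 1e-12)$root
  }, numeric(1))
}

## From-scratch paired t (no stats::t.test).
oracle_paired_t <- function(x, y) {
  d <- x - y
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1))
}

## Default equal-reliability observer used in several simulation tests.
equal_observer <- function(sigma = 5, regime = "mandatory_fusion", ...) {
  observer_params(sigma_T = sigma, sigma_D = sigma, regime = regime, ...)
}

## d-prime from a simulated trial data.frame without correction.
dprime_of <- function(trials, correction = "none") {
  sig <- trials$truth == "different"
  compute_dprime(sum(sig & trials$response == "different"),
                 sum(!sig & trials$response == "different"),
                 sum(sig), sum(!sig), correction = correction)
}
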