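#' Instantaneous voltage topography
#'
#' The value of every scalp electrode at the sample nearest to `t_ms`.
#'
#' @param dw an `erp_difference_wave` (or any object with `data`, `times`
#'   and a montage-labelled row set).
#' @param t_ms time point, ms; must lie within the epoch.
#' @param montage montage supplying the scalp label set; defaults to the
#'   package montage restricted to the rows present in `dw`.
#' @return An `erp_scalp_map`: data.frame (label, value) with attributes
#'   `kind = "voltage"` and `t_ms` (the time of the used sample).
#' @export
voltage_map <- function(dw, t_ms, montage = standard_1010_montage()) {
  if (t_ms < min(dw$times) || t_ms > max(dw$times))
    stop("t_ms outside the epoch time axis")
  i <- which.min(abs(dw$times - t_ms))
  labels <- intersect(montage$labels, rownames(dw$data))
  out <- data.frame(label = labels, value = dw$data[labels, i],
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, kind = "voltage", t_ms = dw$times[i],
            class = c("erp_scalp_map", "data.frame"))
}

# Legendre polynomials P_1..P_n evaluated at x (vector): matrix length(x) x n.
legendre_series <- function(x, n) {
  out <- matrix(0, nrow = length(x), ncol = n)
  out[, 1] <- x
  if (n >= 2) out[, 2] <- (3 * x^2 - 1) / 2
  if (n >= 3) for (k in 3:n)
    out[, k] <- ((2 * k - 1) * x * out[, k - 1] - (k - 1) * out[, k - 2]) / k
  out
}

# Spherical-spline basis functions g (potential) and h (surface Laplacian)
# of the cosine of the inter-electrode angle, truncated Legendre series.
spline_g <- function(cosang, m, n_legendre) {
  n <- seq_len(n_legendre)
  w <- (2 * n + 1) / (n * (n + 1))^m / (4 * pi)
  matrix(legendre_series(as.vector(cosang), n_legendre) %*% w,
         nrow = nrow(cosang))
}

spline_h <- function(cosang, m, n_legendre) {
  n <- seq_len(n_legendre)
  w <- (2 * n + 1) / (n * (n + 1))^(m - 1) / (4 * pi)
  matrix(legendre_series(as.vector(cosang), n_legendre) %*% w,
         nrow = nrow(cosang))
}

# Fit the spherical spline to electrode values v: returns the coefficient
# vector c (sum zero) and offset d such that the interpolated potential is
# G c + d. Adding a constant to v changes only d, so any quantity built
# from c alone is reference-free.
fit_spherical_spline <- function(positions, v, m = 4, lambda = 1e-5,
                                 n_legendre = 50) {
  cosang <- tcrossprod(positions)
  cosang[cosang > 1] <- 1; cosang[cosang < -1] <- -1
  G <- spline_g(cosang, m, n_legendre) + diag(lambda, nrow(positions))
  Gi <- tryCatch(solve(G), error = function(e)
    stop("rank-deficient electrode configuration"))
  ones <- rep(1, nrow(positions))
  d <- sum(Gi %*% v) / sum(Gi %*% ones)
  cvec <- Gi %*% (v - d)
  list(c = as.vector(cvec), d = d, cosang = cosang)
}

#' Current source density topography (spherical-spline surface Laplacian)
#'
#' Fits a spherical spline (flexibility `m`, ridge regularization `lambda`,
#' truncated Legendre series) to the instantaneous voltage map and returns
#' its negative surface Laplacian on the unit sphere at the electrodes —
#' positive values mark current sources, negative values sinks. The
#' transform is linear in the voltages and invariant to the recording
#' reference (adding a constant to all electrodes leaves it unchanged).
#'
#' @inheritParams voltage_map
#' @param m spline flexibility (4 = standard for CSD).
#' @param lambda regularization; 0 makes the interpolation pass through
#'   the data exactly.
#' @param n_legendre number of Legendre terms.
#' @return An `erp_scalp_map` with `kind = "csd"` (uV/m^2-proportional
#'   units on the unit sphere).
#' @export
csd_map <- function(dw, t_ms, m = 4, lambda = 1e-5, n_legendre = 50,
                    montage = standard_1010_montage()) {
  vm <- voltage_map(dw, t_ms, montage)
  pos <- montage$positions[vm$label, , drop = FALSE]
  if (nrow(pos) < 10) stop("CSD needs at least 10 scalp electrodes")
  out <- vm
  out$value <- csd_values(pos, vm$value, m, lambda, n_legendre)
  structure(out, kind = "csd", t_ms = attr(vm, "t_ms"),
            class = c("erp_scalp_map", "data.frame"))
}

#' @rdname csd_map
#' @param positions unit-sphere electrode positions (matrix n x 3).
#' @param v voltages at those electrodes.
#' @export
csd_values <- function(positions, v, m = 4, lambda = 1e-5, n_legendre = 50) {
  fit <- fit_spherical_spline(positions, v, m, lambda, n_legendre)
  H <- spline_h(fit$cosang, m, n_legendre)
  as.vector(H %*% fit$c)
}

#' Spherical-spline interpolation of a scalp map
#'
#' Interpolates electrode values to arbitrary points on the unit sphere
#' (used for dense map rendering and for validating the spline fit).
#'
#' @param positions fitted electrode positions (n x 3).
#' @param v values at `positions`.
#' @param new_positions query points (k x 3, unit norm).
#' @inheritParams csd_map
#' @return Interpolated values at `new_positions`.
#' @export
spline_interpolate <- function(positions, v, new_positions, m = 4,
                               lambda = 1e-5, n_legendre = 50) {
  fit <- fit_spherical_spline(positions, v, m, lambda, n_legendre)
  cosang <- tcrossprod(new_positions, positions)
  cosang[cosang > 1] <- 1; cosang[cosang < -1] <- -1
  as.vector(spline_g(cosang, m, n_legendre) %*% fit$c) + fit$d
}

#' @export
print.erp_scalp_map <- function(x, ...) {
  cat("<erp_scalp_map> ", attr(x, "kind"), " at t = ", attr(x, "t_ms"),
      " ms, ", nrow(x), " electrodes\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 6))
  invisible(x)
}
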