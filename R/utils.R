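# small internal helpers shared across modules

# deterministic sub-seed derivation (Lehmer step, keeps values < 2^31)
derive_seed <- function(seed, k) {
  s <- (as.numeric(seed) %% 2147483647)
  as.integer((s * 48271 + as.numeric(k) * 9973 + 1) %% 2147483647)
}

unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("zero-length direction vector")
  v / n
}

# orthonormal basis perpendicular to direction d
perp_basis <- function(d) {
  d <- unit3(d)
  ref <- if (abs(d[1]) < 0.9) c(1, 0, 0) else c(0, 0, 1)
  u <- unit3(pracma_cross(ref, d))
  v <- pracma_cross(d, u)
  list(u = u, v = v)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# rotate direction d away from itself by polar angle theta (deg) at azimuth az (deg)
tilt_direction <- function(d, theta_deg, az_deg) {
  b <- perp_basis(d)
  th <- theta_deg * pi / 180
  az <- az_deg * pi / 180
  unit3(cos(th) * unit3(d) + sin(th) * (cos(az) * b$u + sin(az) * b$v))
}

angle_between_deg <- function(a, b) {
  ca <- sum(unit3(a) * unit3(b))
  acos(max(-1, min(1, ca))) * 180 / pi
}

# cumulative arclength of an m x 3 polyline
polyline_arclength <- function(pts) {
  if (nrow(pts) < 2) return(0)
  sum(sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2)))
}

cumulative_arclength <- function(pts) {
  if (nrow(pts) < 2) return(0)
  c(0, cumsum(sqrt(rowSums((pts[-1, , drop = FALSE] - pts[-nrow(pts), , drop = FALSE])^2))))
}

# point at arclength fraction f along polyline (linear interpolation)
polyline_point_at <- function(pts, f) {
  s <- cumulative_arclength(pts)
  L <- s[length(s)]
  if (L == 0) return(pts[1, ])
  target <- f * L
  i <- findInterval(target, s, rightmost.closed = TRUE)
  i <- max(1, min(i, nrow(pts) - 1))
  w <- (target - s[i]) / (s[i + 1] - s[i])
  pts[i, ] + w * (pts[i + 1, ] - pts[i, ])
}

# linear interpolation of a per-point value at fraction f
profile_value_at <- function(pts, values, f) {
  s <- cumulative_arclength(pts)
  L <- s[length(s)]
  if (L == 0) return(values[1])
  approx(s / L, values, xout = f, rule = 2)$y
}

# mean of a per-point profile over an arclength-fraction window
profile_window_mean <- function(pts, values, window) {
  s <- cumulative_arclength(pts)
  L <- s[length(s)]
  if (L == 0 || length(values) == 1) return(values[1])
  grid <- seq(window[1], window[2], length.out = 101)
  mean(approx(s / L, values, xout = grid, rule = 2)$y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
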