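# shared fixtures, all generated in code

make_rec <- function(seed = 1, n_ch = 2, rate = 256L, duration_s = 0.5,
                     notes = empty_notes(), ...) {
  spec <- signal_spec(sprintf("Gr%02d", seq_len(n_ch)), rate = rate,
                      duration_s = duration_s, notes = notes, ...)
  synthesize_recording(spec, seed)
}

unit_square_mm <- function() {
  resection_outline(rbind(c(0, 0), c(10, 0), c(10, 10), c(0, 10)))
}

grid_plan_4x5 <- function() {
  idx <- 1:20
  electrode_plan(sprintf("Gr%02d", idx),
                 x = ((idx - 1) %% 5) * 10, y = (ceiling(idx / 5) - 1) * 10)
}

file_bytes <- function(path) readBin(path, "raw", file.info(path)$size)

# independent point-in-polygon oracle: winding by summed signed angles
pip_winding <- function(px, py, v) {
  n <- nrow(v)
  a <- atan2(v[, 2] - py, v[, 1] - px)
  d <- diff(c(a, a[1]))
  d <- ifelse(d > pi, d - 2 * pi, ifelse(d < -pi, d + 2 * pi, d))
  abs(sum(d)) > pi  # ~2*pi inside, ~0 outside
}

# independent distance oracle: dense boundary sampling
poly_boundary_points <- function(v, step = 0.01) {
  n <- nrow(v)
  do.call(rbind, lapply(seq_len(n), function(i) {
    a <- v[i, ]; b <- v[if (i == n) 1 else i + 1, ]
    len <- sqrt(sum((b - a)^2))
    tt <- seq(0, 1, length.out = max(2, ceiling(len / step) + 1))
    cbind(a[1] + tt * (b[1] - a[1]), a[2] + tt * (b[2] - a[2]))
  }))
}

poly_distance_oracle <- function(px, py, v, pts) {
  d <- sqrt(min((pts[, 1] - px)^2 + (pts[, 2] - py)^2))
  if (pip_winding(px, py, v)) -d else d
}
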