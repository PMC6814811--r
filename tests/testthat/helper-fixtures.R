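# Shared fixture builders and an independent plain-R distance reference.

# Regular-polygon approximation of a circle as a membrane trace.
circle_trace <- function(r, n = 360L, centre = c(0, 0), role = "MOM",
                         closed = TRUE, id = "circle") {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  membrane_trace(cbind(centre[1L] + r * cos(th), centre[2L] + r * sin(th)),
                 role = role, closed = closed, object_id = id,
                 check_simple = FALSE)
}

# Concentric arc at radius r + d over the SAME angular grid as a
# circle_trace(r, n): radial scaling of a regular polygon keeps every
# point within distance d of the polygon (equality above vertices).
concentric_arc_trace <- function(r, d, frac, n = 360L, centre = c(0, 0),
                                 phi0 = 0, id = "arc") {
  m <- max(8L, ceiling(frac * n))
  th <- phi0 + seq(0, 2 * pi * frac, length.out = m + 1L)
  membrane_trace(cbind(centre[1L] + (r + d) * cos(th),
                       centre[2L] + (r + d) * sin(th)),
                 role = "ER", closed = FALSE, object_id = id)
}

# Large closed rectangle whose bottom edge lies on y = 0 between x = 0 and
# x = xmax; used to exercise straight-edge band geometry.
rect_trace <- function(xmax = 1000, depth = 5000, id = "rect") {
  membrane_trace(rbind(c(0, 0), c(xmax, 0), c(xmax, -depth), c(0, -depth)),
                 role = "MOM", closed = TRUE, object_id = id)
}

# Plain-R point-to-polyline distance, independent of the compiled kernel.
ref_dist_to_trace <- function(points, trace) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2L, byrow = TRUE)
  v <- trace$vertices
  n <- nrow(v)
  idx <- if (trace$closed) cbind(1:n, c(2:n, 1L)) else cbind(1:(n - 1L), 2:n)
  apply(points, 1L, function(p) {
    d2 <- apply(idx, 1L, function(e) {
      a <- v[e[1L], ]; b <- v[e[2L], ]
      ab <- b - a
      t <- sum((p - a) * ab) / sum(ab^2)
      t <- min(max(t, 0), 1)
      sum((a + t * ab - p)^2)
    })
    sqrt(min(d2))
  })
}

# Single-mitochondrion concentric fixture used across tests: exact circle,
# one ER arc, no noise or jitter.
concentric_spec <- function(seed = 7L, r = 500, d = 12, coverage = 0.25) {
  scene_spec(seed = seed, n_mitochondria = 1L, mito_radius_nm = r,
             shape_noise_amp_nm = 0, er_arcs_per_mito = 1L,
             arc_distance_nm = d, out_of_range_frac = 0,
             arc_coverage_frac = coverage, trace_jitter_nm = 0)
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object / expected - 1), tol)
}
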