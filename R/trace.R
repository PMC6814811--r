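#' Membrane trace
#'
#' An ordered 2D polyline in nanometres representing one segmented membrane:
#' a closed contour for a mitochondrial outer membrane (MOM) or an open or
#' closed curve for an ER membrane profile.
#'
#' Coordinates follow the image convention: x to the right, y downwards,
#' origin at the centre of pixel (0,0), units nanometres.  For closed traces
#' the closing edge from the last vertex back to the first is implicit; a
#' duplicated final vertex equal to the first is dropped on construction.
#'
#' @param vertices numeric matrix with two columns (x_nm, y_nm), one row per
#'   vertex, in order along the membrane.
#' @param role `"MOM"` or `"ER"`.
#' @param closed logical; is the trace a closed contour?  Defaults to `TRUE`
#'   for MOM traces and `FALSE` for ER traces.
#' @param object_id identifier used in error messages and output tables.
#' @param check_simple logical; for closed traces, verify that the polygon is
#'   simple (no self-intersection).  The check is quadratic in the number of
#'   vertices; generators that produce simple polygons by construction may
#'   disable it.
#' @return An object of class `membrane_trace`: a list with fields
#'   `object_id`, `role`, `vertices`, `closed`.
#' @examples
#' sq <- membrane_trace(rbind(c(0, 0), c(100, 0), c(100, 100), c(0, 100)),
#'                      role = "MOM", closed = TRUE)
#' perimeter(sq)  # 400
#' @export
membrane_trace <- function(vertices, role = c("MOM", "ER"),
                           closed = NULL, object_id = "trace",
                           check_simple = TRUE) {
  role <- match.arg(role)
  if (is.null(closed)) closed <- role == "MOM"
  if (is.data.frame(vertices)) vertices <- as.matrix(vertices)
  if (!is.matrix(vertices) || ncol(vertices) != 2L || !is.numeric(vertices))
    stop("'", object_id, "': vertices must be a numeric matrix with 2 columns")
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  if (!all(is.finite(vertices)))
    stop("'", object_id, "': vertices contain non-finite coordinates")
  n <- nrow(vertices)
  if (closed && n >= 2L &&
      all(abs(vertices[n, ] - vertices[1L, ]) < 1e-9)) {
    vertices <- vertices[-n, , drop = FALSE]
    n <- n - 1L
  }
  min_n <- if (closed) 3L else 2L
  if (n < min_n)
    stop("'", object_id, "': needs at least ", min_n, " vertices (has ", n, ")")
  seg <- sqrt(rowSums((vertices[-1L, , drop = FALSE] -
                       vertices[-n, , drop = FALSE])^2))
  if (any(seg <= 1e-9))
    stop("'", object_id, "': consecutive vertices must be distinct (> 1e-9 nm)")
  if (closed) {
    if (sqrt(sum((vertices[1L, ] - vertices[n, ])^2)) <= 1e-9)
      stop("'", object_id, "': consecutive vertices must be distinct (> 1e-9 nm)")
    if (check_simple && !.cpp_polygon_is_simple(vertices))
      stop("'", object_id, "': closed trace is self-intersecting")
  }
  structure(list(object_id = as.character(object_id), role = role,
                 vertices = vertices, closed = closed),
            class = "membrane_trace")
}

#' @export
print.membrane_trace <- function(x, ...) {
  cat(sprintf("<membrane_trace '%s'> role=%s %s, %d vertices, length %.1f nm\n",
              x$object_id, x$role, if (x$closed) "closed" else "open",
              nrow(x$vertices), trace_length(x)))
  invisible(x)
}

is_membrane_trace <- function(x) inherits(x, "membrane_trace")

#' Arc length of a membrane trace
#'
#' Sum of Euclidean edge lengths; for a closed trace the closing edge is
#' included (equal to [perimeter()]).
#'
#' @param trace a [membrane_trace()].
#' @return length in nm.
#' @export
trace_length <- function(trace) {
  stopifnot(is_membrane_trace(trace))
  v <- trace$vertices
  n <- nrow(v)
  len <- sum(sqrt(rowSums((v[-1L, , drop = FALSE] - v[-n, , drop = FALSE])^2)))
  if (trace$closed) len <- len + sqrt(sum((v[1L, ] - v[n, ])^2))
  len
}

#' Perimeter of a closed membrane trace
#'
#' The mitochondrial perimeter P entering the contact coefficient
#' ERMICC = L / (P * D).  Defined for closed traces only.
#'
#' @param trace a closed [membrane_trace()].
#' @return perimeter in nm.
#' @export
perimeter <- function(trace) {
  stopifnot(is_membrane_trace(trace))
  if (!trace$closed)
    stop("perimeter is defined for closed traces only ('",
         trace$object_id, "' is open)")
  trace_length(trace)
}

#' Minimum distance from points to a membrane trace
#'
#' Euclidean distance to the membrane *curve* (not to the enclosed region):
#' a point inside a closed MOM contour has positive distance to the
#' membrane.  This is the metric underlying the dilation bands.
#'
#' @param points numeric vector of length 2 (one point) or matrix with two
#'   columns (x_nm, y_nm).
#' @param trace a [membrane_trace()].
#' @return numeric vector of distances in nm, one per point.
#' @export
distance_to_trace <- function(points, trace) {
  stopifnot(is_membrane_trace(trace))
  if (is.null(dim(points))) points <- matrix(points, ncol = 2L, byrow = TRUE)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 2L || !all(is.finite(points)))
    stop("points must be finite coordinates with 2 columns")
  .cpp_dist_to_polyline(points, trace$vertices, trace$closed)
}

# Nearest point on the trace for each query point; returns an n x 2 matrix.
nearest_on_trace <- function(points, trace) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 2L, byrow = TRUE)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  .cpp_nearest_on_polyline(points, trace$vertices, trace$closed)
}

# Resample a trace into m sub-segments of equal arc length <= step,
# returning midpoints (m x 2) and the sub-segment lengths.
polyline_midpoints <- function(trace, step) {
  v <- trace$vertices
  if (trace$closed) v <- rbind(v, v[1L, ])
  seg <- sqrt(rowSums((v[-1L, , drop = FALSE] -
                       v[-nrow(v), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  m <- max(1L, ceiling(total / step))
  h <- total / m
  s_mid <- (seq_len(m) - 0.5) * h
  x <- stats::approx(cum, v[, 1L], xout = s_mid, ties = "ordered")$y
  y <- stats::approx(cum, v[, 2L], xout = s_mid, ties = "ordered")$y
  list(mid = cbind(x, y), len = rep(h, m), total = total)
}

# Shoelace signed area of a closed vertex matrix (image coordinates).
signed_area <- function(v) {
  n <- nrow(v)
  j <- c(2:n, 1L)
  sum(v[, 1L] * v[j, 2L] - v[j, 1L] * v[, 2L]) / 2
}

# Rigid-transform helper used by tests and examples.
transform_trace <- function(trace, angle = 0, shift = c(0, 0), scale = 1) {
  r <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2L, 2L)
  v <- scale * (trace$vertices %*% t(r))
  v <- sweep(v, 2L, shift, "+")
  membrane_trace(v, role = trace$role, closed = trace$closed,
                 object_id = trace$object_id, check_simple = FALSE)
}
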