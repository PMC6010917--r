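# Planar polygon helpers (UTM metres). Boundaries are n x 2 matrices of
# (easting, northing) vertices; closure is implicit (first vertex need not be
# repeated).

.close_ring <- function(p) {
  p <- as.matrix(p)
  if (nrow(p) >= 2 && all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
  p
}

#' Planar polygon area (shoelace formula)
#' @param boundary n x 2 matrix of vertices in metres.
#' @return Area in square metres.
#' @export
polygon_area_m2 <- function(boundary) {
  p <- .close_ring(boundary)
  n <- nrow(p)
  if (n < 3) return(0)
  i2 <- c(2:n, 1)
  abs(sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2])) / 2
}

# points-in-polygon; x, y vectors, returns logical (boundary counts as inside)
.in_polygon <- function(x, y, boundary) {
  p <- .close_ring(boundary)
  res <- pracma::inpolygon(x, y, p[, 1], p[, 2], boundary = TRUE)
  as.logical(res)
}

# minimum distance from points to a polygon outline (0 inside handled by caller)
.dist_to_outline <- function(x, y, boundary) {
  p <- .close_ring(boundary)
  n <- nrow(p)
  d <- rep(Inf, length(x))
  for (i in seq_len(n)) {
    a <- p[i, ]; b <- p[if (i == n) 1 else i + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    t <- if (len2 == 0) rep(0, length(x)) else
      pmin(1, pmax(0, ((x - a[1]) * ab[1] + (y - a[2]) * ab[2]) / len2))
    d <- pmin(d, sqrt((x - (a[1] + t * ab[1]))^2 + (y - (a[2] + t * ab[2]))^2))
  }
  d
}

# Sutherland-Hodgman clip of a polygon by an axis-aligned rectangle
.clip_rect <- function(boundary, xmin, xmax, ymin, ymax) {
  p <- .close_ring(boundary)
  clip_half <- function(pts, inside, intersect) {
    if (nrow(pts) == 0) return(pts)
    out <- matrix(numeric(0), ncol = 2)
    n <- nrow(pts)
    for (i in seq_len(n)) {
      cur <- pts[i, ]; prv <- pts[if (i == 1) n else i - 1, ]
      cin <- inside(cur); pin <- inside(prv)
      if (cin) {
        if (!pin) out <- rbind(out, intersect(prv, cur))
        out <- rbind(out, cur)
      } else if (pin) {
        out <- rbind(out, intersect(prv, cur))
      }
    }
    out
  }
  ix <- function(a, b, val, dim) {
    t <- (val - a[dim]) / (b[dim] - a[dim])
    a + t * (b - a)
  }
  p <- clip_half(p, function(q) q[1] >= xmin, function(a, b) ix(a, b, xmin, 1))
  p <- clip_half(p, function(q) q[1] <= xmax, function(a, b) ix(a, b, xmax, 1))
  p <- clip_half(p, function(q) q[2] >= ymin, function(a, b) ix(a, b, ymin, 2))
  p <- clip_half(p, function(q) q[2] <= ymax, function(a, b) ix(a, b, ymax, 2))
  p
}
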