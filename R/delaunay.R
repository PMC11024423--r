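# Delaunay triangulation (Bowyer-Watson) and piecewise-linear barycentric
# interpolation. Knot sets are small (tens to a few hundred points), so the
# incremental O(n^2) construction is ample. Coordinates are rescaled to the
# unit box before triangulating to keep the circumcircle predicate stable.

.circumcircle <- function(p, tri) {
  ax <- p[tri[1L], 1L]; ay <- p[tri[1L], 2L]
  bx <- p[tri[2L], 1L]; by <- p[tri[2L], 2L]
  cx <- p[tri[3L], 1L]; cy <- p[tri[3L], 2L]
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-12) return(NULL)  # collinear
  a2 <- ax * ax + ay * ay
  b2 <- bx * bx + by * by
  c2 <- cx * cx + cy * cy
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  c(ux, uy, (ax - ux)^2 + (ay - uy)^2)
}

# pts: n x 2 matrix of distinct points; returns m x 3 matrix of vertex indices
.delaunay <- function(pts) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  if (n < 3L) stop("triangulation needs at least 3 points", call. = FALSE)
  # rescale to the unit box
  lo <- apply(pts, 2L, min)
  span <- max(apply(pts, 2L, max) - lo, .Machine$double.eps)
  q <- sweep(pts, 2L, lo) / span
  # super-triangle comfortably enclosing the unit box
  q <- rbind(q, c(-50, -30), c(50, -30), c(0.5, 60))
  sup <- n + 1:3

  tris <- list(as.integer(sup))
  circ <- list(.circumcircle(q, sup))

  for (i in seq_len(n)) {
    px <- q[i, 1L]; py <- q[i, 2L]
    bad <- logical(length(tris))
    for (t in seq_along(tris)) {
      cc <- circ[[t]]
      if (is.null(cc)) { bad[t] <- TRUE; next }  # degenerate: always recut
      bad[t] <- (px - cc[1L])^2 + (py - cc[2L])^2 <= cc[3L] * (1 + 1e-12)
    }
    if (!any(bad)) stop("triangulation failure: point outside all circumcircles",
                        call. = FALSE)
    # boundary polygon = edges of bad triangles that appear exactly once
    edges <- do.call(rbind, lapply(tris[bad], function(tr) {
      rbind(sort(tr[c(1L, 2L)]), sort(tr[c(2L, 3L)]), sort(tr[c(1L, 3L)]))
    }))
    key <- paste(edges[, 1L], edges[, 2L])
    keep <- !(key %in% key[duplicated(key)])
    edges <- edges[keep, , drop = FALSE]
    tris <- tris[!bad]
    circ <- circ[!bad]
    for (k in seq_len(nrow(edges))) {
      tr <- c(edges[k, 1L], edges[k, 2L], i)
      tris[[length(tris) + 1L]] <- tr
      circ[[length(circ) + 1L]] <- .circumcircle(q, tr)
    }
  }
  out <- do.call(rbind, tris)
  out <- out[rowSums(matrix(out %in% sup, ncol = 3L)) == 0L, , drop = FALSE]
  if (nrow(out) == 0L)
    stop("degenerate point set: no valid triangulation", call. = FALSE)
  out
}

# Barycentric weights of query points within a triangulation.
# Returns list(vertex = nq x 3 vertex indices, w = nq x 3 weights);
# errors if any query lies outside the convex hull.
.bary_weights <- function(pts, tris, qx, qy) {
  nq <- length(qx)
  vert <- matrix(NA_integer_, nq, 3L)
  w <- matrix(NA_real_, nq, 3L)
  open <- seq_len(nq)
  tol <- -1e-9
  for (t in seq_len(nrow(tris))) {
    if (!length(open)) break
    a <- tris[t, 1L]; b <- tris[t, 2L]; cc <- tris[t, 3L]
    x1 <- pts[a, 1L]; y1 <- pts[a, 2L]
    x2 <- pts[b, 1L]; y2 <- pts[b, 2L]
    x3 <- pts[cc, 1L]; y3 <- pts[cc, 2L]
    det <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
    if (abs(det) < 1e-14) next
    dx <- qx[open] - x3
    dy <- qy[open] - y3
    l1 <- ((y2 - y3) * dx + (x3 - x2) * dy) / det
    l2 <- ((y3 - y1) * dx + (x1 - x3) * dy) / det
    l3 <- 1 - l1 - l2
    inside <- l1 >= tol & l2 >= tol & l3 >= tol
    if (any(inside)) {
      hit <- open[inside]
      vert[hit, ] <- matrix(c(a, b, cc), length(hit), 3L, byrow = TRUE)
      w[hit, ] <- cbind(l1[inside], l2[inside], l3[inside])
      open <- open[!inside]
    }
  }
  if (length(open))
    stop(sprintf("%d query point(s) outside the convex hull of the knots",
                 length(open)), call. = FALSE)
  list(vertex = vert, w = w)
}

# Evaluate interpolant(s): z is a vector or nknots x k matrix.
.bary_eval <- function(bw, z) {
  z <- as.matrix(z)
  vapply(seq_len(ncol(z)), function(k) {
    zk <- z[, k]
    bw$w[, 1L] * zk[bw$vertex[, 1L]] +
      bw$w[, 2L] * zk[bw$vertex[, 2L]] +
      bw$w[, 3L] * zk[bw$vertex[, 3L]]
  }, numeric(nrow(bw$w)))
}
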