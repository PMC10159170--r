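## Internal planar/spherical geometry helpers.
## Polygons are matrices with columns lon, lat (rings need not be closed).

# great-circle central angle in degrees (haversine); vectorized, recycling
gcAngle <- function(lon1, lat1, lon2, lat2) {
  r <- pi / 180
  dlat <- (lat2 - lat1) * r / 2
  dlon <- (lon2 - lon1) * r / 2
  a <- sin(dlat)^2 + cos(lat1 * r) * cos(lat2 * r) * sin(dlon)^2
  2 * asin(pmin(1, sqrt(a))) / r
}

# full pairwise central-angle matrix (degrees) between two point sets
gcAngleMatrix <- function(lon1, lat1, lon2, lat2) {
  outer(seq_along(lon1), seq_along(lon2), function(i, j)
    gcAngle(lon1[i], lat1[i], lon2[j], lat2[j]))
}

# ray-casting point-in-polygon for one ring; boundary points count as inside
pointInRing <- function(lon, lat, ring) {
  n <- nrow(ring)
  x <- ring[, 1]; y <- ring[, 2]
  if (x[1] == x[n] && y[1] == y[n]) { x <- x[-n]; y <- y[-n]; n <- n - 1L }
  inside <- rep(FALSE, length(lon))
  j <- n
  for (i in seq_len(n)) {
    xi <- x[i]; yi <- y[i]; xj <- x[j]; yj <- y[j]
    cross <- ((yi > lat) != (yj > lat)) &
      (lon < (xj - xi) * (lat - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# even-odd membership across a list of rings (holes flip membership)
pointInPolygon <- function(lon, lat, rings) {
  if (is.matrix(rings)) rings <- list(rings)
  inside <- rep(FALSE, length(lon))
  for (ring in rings) inside <- xor(inside, pointInRing(lon, lat, ring))
  inside
}

# planar distance from points to a segment (a, b); vectorized over points
pointSegDist <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  L2 <- dx * dx + dy * dy
  if (L2 == 0) return(sqrt((px - ax)^2 + (py - ay)^2))
  t <- pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / L2))
  sqrt((px - ax - t * dx)^2 + (py - ay - t * dy)^2)
}

# planar distance from points to a ring's boundary
pointRingDist <- function(px, py, ring) {
  n <- nrow(ring)
  if (ring[1, 1] != ring[n, 1] || ring[1, 2] != ring[n, 2])
    ring <- rbind(ring, ring[1, ])
  d <- rep(Inf, length(px))
  for (i in seq_len(nrow(ring) - 1))
    d <- pmin(d, pointSegDist(px, py, ring[i, 1], ring[i, 2],
                              ring[i + 1, 1], ring[i + 1, 2]))
  d
}

# planar distance to a polygon (0 inside)
pointPolygonDist <- function(px, py, rings) {
  if (is.matrix(rings)) rings <- list(rings)
  d <- rep(Inf, length(px))
  for (ring in rings) d <- pmin(d, pointRingDist(px, py, ring))
  d[pointInPolygon(px, py, rings)] <- 0
  d
}

## ---- Delaunay triangulation (Bowyer-Watson) --------------------------------

circumcircle <- function(ax, ay, bx, by, cx, cy) {
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  if (abs(d) < 1e-14) return(NULL)  # collinear
  ux <- ((ax^2 + ay^2) * (by - cy) + (bx^2 + by^2) * (cy - ay) +
           (cx^2 + cy^2) * (ay - by)) / d
  uy <- ((ax^2 + ay^2) * (cx - bx) + (bx^2 + by^2) * (ax - cx) +
           (cx^2 + cy^2) * (bx - ax)) / d
  c(ux, uy, sqrt((ax - ux)^2 + (ay - uy)^2))
}

# returns triangles as an n x 3 index matrix plus circumradii
delaunay <- function(x, y) {
  n <- length(x)
  stopifnot(n >= 3)
  # super-triangle enclosing everything
  cx <- mean(range(x)); cy <- mean(range(y))
  span <- max(diff(range(x)), diff(range(y)), 1e-9) * 20
  px <- c(x, cx - span, cx + span, cx)
  py <- c(y, cy - span, cy - span, cy + span)
  tris <- matrix(c(n + 1L, n + 2L, n + 3L), 1)
  cc <- matrix(circumcircle(px[n + 1], py[n + 1], px[n + 2], py[n + 2],
                            px[n + 3], py[n + 3]), 1)
  for (i in seq_len(n)) {
    bad <- which((px[i] - cc[, 1])^2 + (py[i] - cc[, 2])^2 <= cc[, 3]^2 *
                   (1 + 1e-12))
    if (!length(bad)) next
    # boundary = edges of bad triangles not shared by two bad triangles
    edges <- do.call(rbind, lapply(bad, function(t) {
      v <- tris[t, ]
      rbind(sort(c(v[1], v[2])), sort(c(v[2], v[3])), sort(c(v[3], v[1])))
    }))
    key <- paste(edges[, 1], edges[, 2])
    keep <- edges[key %in% names(which(table(key) == 1)), , drop = FALSE]
    tris <- tris[-bad, , drop = FALSE]
    cc <- cc[-bad, , drop = FALSE]
    for (e in seq_len(nrow(keep))) {
      tri <- c(keep[e, 1], keep[e, 2], i)
      circ <- circumcircle(px[tri[1]], py[tri[1]], px[tri[2]], py[tri[2]],
                           px[tri[3]], py[tri[3]])
      if (is.null(circ)) next
      tris <- rbind(tris, tri)
      cc <- rbind(cc, circ)
    }
  }
  real <- apply(tris <= n, 1, all)
  list(triangles = tris[real, , drop = FALSE],
       circumradius = cc[real, 3])
}

pointInTriangle <- function(px, py, ax, ay, bx, by, cx, cy) {
  d1 <- (px - bx) * (ay - by) - (ax - bx) * (py - by)
  d2 <- (px - cx) * (by - cy) - (bx - cx) * (py - cy)
  d3 <- (px - ax) * (cy - ay) - (cx - ax) * (py - ay)
  neg <- (d1 < 0) | (d2 < 0) | (d3 < 0)
  pos <- (d1 > 0) | (d2 > 0) | (d3 > 0)
  !(neg & pos)
}

# planar distance of points to a union of triangles (0 inside any)
pointTrianglesDist <- function(px, py, x, y, triangles) {
  d <- rep(Inf, length(px))
  for (t in seq_len(nrow(triangles))) {
    v <- triangles[t, ]
    inside <- pointInTriangle(px, py, x[v[1]], y[v[1]], x[v[2]], y[v[2]],
                              x[v[3]], y[v[3]])
    d[inside] <- 0
    for (e in list(c(1, 2), c(2, 3), c(3, 1))) {
      a <- v[e[1]]; b <- v[e[2]]
      d <- pmin(d, pointSegDist(px, py, x[a], y[a], x[b], y[b]))
    }
  }
  d
}

## ---- Voronoi by half-plane clipping ----------------------------------------

# Sutherland-Hodgman clip of a convex polygon by half-plane
# {p : (p - m) . nrm <= 0}
clipHalfPlane <- function(poly, m, nrm) {
  n <- nrow(poly)
  out <- matrix(numeric(0), 0, 2)
  val <- (poly[, 1] - m[1]) * nrm[1] + (poly[, 2] - m[2]) * nrm[2]
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    vi <- val[i]; vj <- val[j]
    if (vi <= 0) out <- rbind(out, poly[i, ])
    if ((vi < 0 && vj > 0) || (vi > 0 && vj < 0)) {
      t <- vi / (vi - vj)
      out <- rbind(out, poly[i, ] + t * (poly[j, ] - poly[i, ]))
    }
  }
  out
}

# Voronoi cells of seed points within a bounding rectangle; returns a list
# of convex rings (lon/lat matrices)
voronoiCells <- function(sx, sy, xmin, xmax, ymin, ymax) {
  k <- length(sx)
  rect <- matrix(c(xmin, ymin, xmax, ymin, xmax, ymax, xmin, ymax),
                 ncol = 2, byrow = TRUE)
  lapply(seq_len(k), function(i) {
    poly <- rect
    for (j in seq_len(k)) {
      if (j == i || nrow(poly) == 0) next
      m <- c((sx[i] + sx[j]) / 2, (sy[i] + sy[j]) / 2)
      nrm <- c(sx[j] - sx[i], sy[j] - sy[i])
      poly <- clipHalfPlane(poly, m, nrm)
    }
    poly
  })
}

## ---- mask polygonization and GeoJSON ---------------------------------------

# trace boundary rings of a logical mask on a grid; returns list of rings
polygonizeMask <- function(mask, grid) {
  nr <- nrow(mask); nc <- ncol(mask)
  cs <- grid@cellSize
  xl <- function(c) grid@originLon + (c - 1) * cs
  yt <- function(r) grid@originLat - (r - 1) * cs
  # directed boundary segments, inside kept on the left
  segs <- list()
  inC <- function(r, c) r >= 1 && r <= nr && c >= 1 && c <= nc && mask[r, c]
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c]) next
    x0 <- xl(c); x1 <- x0 + cs; y0 <- yt(r); y1 <- y0 - cs
    if (!inC(r - 1, c)) segs[[length(segs) + 1]] <- c(x0, y0, x1, y0)  # top, E
    if (!inC(r, c + 1)) segs[[length(segs) + 1]] <- c(x1, y0, x1, y1)  # right, S
    if (!inC(r + 1, c)) segs[[length(segs) + 1]] <- c(x1, y1, x0, y1)  # bottom, W
    if (!inC(r, c - 1)) segs[[length(segs) + 1]] <- c(x0, y1, x0, y0)  # left, N
  }
  if (!length(segs)) return(list())
  segm <- do.call(rbind, segs)
  keyOf <- function(x, y) paste(round(x / cs * 2), round(y / cs * 2))
  fromKey <- keyOf(segm[, 1], segm[, 2])
  used <- rep(FALSE, nrow(segm))
  lookup <- split(seq_len(nrow(segm)), fromKey)
  rings <- list()
  for (s in seq_len(nrow(segm))) {
    if (used[s]) next
    ring <- segm[s, 1:2, drop = FALSE]
    cur <- s
    repeat {
      used[cur] <- TRUE
      nx <- segm[cur, 3]; ny <- segm[cur, 4]
      ring <- rbind(ring, c(nx, ny))
      cand <- lookup[[keyOf(nx, ny)]]
      cand <- cand[!used[cand]]
      if (!length(cand)) break
      cur <- cand[1]
    }
    rings[[length(rings) + 1]] <- ring
  }
  rings
}

#' Write polygons to a GeoJSON file
#'
#' @param polys list of rings (lon/lat matrices) or list of such lists
#'   (one element per feature).
#' @param path output path.
#' @param properties optional data.frame of per-feature properties.
#' @return `path`, invisibly
#' @export
writeGeoJSON <- function(polys, path, properties = NULL) {
  if (length(polys) && is.matrix(polys[[1]]))
    polys <- lapply(polys, list)
  closeRing <- function(r) {
    if (!all(r[1, ] == r[nrow(r), ])) r <- rbind(r, r[1, ])
    lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2]))
  }
  feats <- lapply(seq_along(polys), function(i) {
    rings <- lapply(polys[[i]], closeRing)
    props <- if (!is.null(properties)) as.list(properties[i, , drop = FALSE])
    else stats::setNames(list(), character(0))
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon", coordinates = rings))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read polygons from a GeoJSON file
#'
#' Supports `Polygon` and `MultiPolygon` features. Returns one element per
#' feature; each element is a list of rings (lon/lat matrices).
#'
#' @param path input path.
#' @return list of features, with a `properties` attribute
#' @export
readGeoJSON <- function(path) {
  gj <- jsonlite::read_json(path)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features
  else list(gj)
  ringMat <- function(ring)
    do.call(rbind, lapply(ring, function(p) c(p[[1]], p[[2]])))
  out <- lapply(feats, function(f) {
    geom <- if (!is.null(f$geometry)) f$geometry else f
    if (identical(geom$type, "Polygon")) {
      lapply(geom$coordinates, ringMat)
    } else if (identical(geom$type, "MultiPolygon")) {
      unlist(lapply(geom$coordinates, function(poly)
        lapply(poly, ringMat)), recursive = FALSE)
    } else stop("unsupported geometry type: ", geom$type)
  })
  props <- lapply(feats, function(f)
    if (!is.null(f$properties)) f$properties else list())
  attr(out, "properties") <- props
  out
}
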