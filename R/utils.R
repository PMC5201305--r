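# Small shared helpers: seeded RNG scoping, derived seeds, geometry of
# capsule-shaped (coccoid) cell outlines, WKT polygon round-tripping.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `code` and restores the caller's
#' RNG state afterwards, so that seeded generators do not perturb the
#' global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a stage-specific seed from a global seed
#'
#' Deterministically maps (seed, label) to an integer below 2^31 so that
#' every pipeline stage draws from an independent, reproducible stream.
#'
#' @param seed integer global seed.
#' @param label character stage label.
#' @return integer seed in `[1, 2147483628]`.
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483629 # prime below 2^31
  v <- as.numeric(seed) %% m
  for (k in utf8ToInt(paste(label, collapse = ""))) {
    v <- (v * 31 + k) %% m
  }
  as.integer(v %% (m - 2) + 1)
}

fwhm_to_sigma <- function(w) w / (2 * sqrt(2 * log(2)))
sigma_to_fwhm <- function(s) s * 2 * sqrt(2 * log(2))

## ---- polygon geometry -----------------------------------------------------

#' Capsule polygon for a coccoid cell outline
#'
#' Rectangle with semicircular caps, centred at the origin with the long
#' axis along x. Units are whatever the caller uses (nm or px).
#'
#' @param length_ total tip-to-tip length.
#' @param width_ cell width (cap diameter).
#' @param n_arc points per semicircular cap.
#' @return numeric matrix with columns x, y (open ring, counter-clockwise).
#' @export
capsule_polygon <- function(length_, width_, n_arc = 36L) {
  stopifnot(length_ >= width_, width_ > 0)
  r <- width_ / 2
  s <- length_ / 2 - r
  th_r <- seq(-pi / 2, pi / 2, length.out = n_arc)
  th_l <- seq(pi / 2, 3 * pi / 2, length.out = n_arc)
  x <- c(s + r * cos(th_r), -s + r * cos(th_l))
  y <- c(r * sin(th_r), r * sin(th_l))
  cbind(x = x, y = y)
}

#' Rigid transform of a polygon (rotate then translate)
#' @param poly two-column matrix.
#' @param theta rotation angle (radians, counter-clockwise).
#' @param center length-2 translation applied after rotation.
#' @keywords internal
transform_polygon <- function(poly, theta = 0, center = c(0, 0)) {
  ct <- cos(theta); st <- sin(theta)
  cbind(
    x = poly[, 1] * ct - poly[, 2] * st + center[1],
    y = poly[, 1] * st + poly[, 2] * ct + center[2]
  )
}

# Signed-area moments of a simple polygon (area, centroid, central
# covariance of the enclosed region).  Standard Green's-theorem formulas;
# orientation-independent because signs cancel against the signed area.
polygon_moments <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps * max(1, max(abs(poly)))^2) {
    stop("degenerate polygon: zero area")
  }
  cx <- sum((x + xn) * cr) / (6 * a)
  cy <- sum((y + yn) * cr) / (6 * a)
  exx <- sum((x^2 + x * xn + xn^2) * cr) / (12 * a)
  eyy <- sum((y^2 + y * yn + yn^2) * cr) / (12 * a)
  exy <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cr) / (24 * a)
  cov <- matrix(
    c(exx - cx^2, exy - cx * cy, exy - cx * cy, eyy - cy^2), 2, 2
  )
  list(area = abs(a), centroid = c(cx, cy), cov = cov)
}

#' Test points for inclusion in a simple polygon
#'
#' Even-odd ray-casting test, vectorized over points. Points on an edge
#' count as inside for practical purposes (boundary handling follows the
#' crossing rule).
#'
#' @param px,py point coordinates.
#' @param poly two-column polygon matrix (open ring).
#' @return logical vector.
#' @export
point_in_polygon <- function(px, py, poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  jx <- c(x[n], x[-n]); jy <- c(y[n], y[-n])
  inside <- logical(length(px))
  for (i in seq_len(n)) {
    xi <- x[i]; yi <- y[i]; xj <- jx[i]; yj <- jy[i]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
  }
  inside
}

## ---- WKT ------------------------------------------------------------------

#' Serialize a polygon as a WKT POLYGON string
#' @param poly two-column matrix (open ring; closure is added).
#' @return character scalar such as `"POLYGON((x1 y1, x2 y2, ...))"`.
#' @export
polygon_to_wkt <- function(poly) {
  ring <- rbind(poly, poly[1, , drop = FALSE])
  pts <- paste(
    formatC(ring[, 1], format = "g", digits = 10),
    formatC(ring[, 2], format = "g", digits = 10)
  )
  paste0("POLYGON((", paste(pts, collapse = ", "), "))")
}

#' Parse a WKT POLYGON string back to a matrix
#' @param wkt character scalar produced by [polygon_to_wkt()].
#' @return two-column matrix (open ring).
#' @export
wkt_to_polygon <- function(wkt) {
  body <- sub("^\\s*POLYGON\\s*\\(\\(", "", wkt)
  body <- sub("\\)\\)\\s*$", "", body)
  pts <- strsplit(strsplit(body, ",")[[1]], "\\s+")
  m <- do.call(rbind, lapply(pts, function(p) {
    p <- p[nzchar(p)]
    as.numeric(p[1:2])
  }))
  colnames(m) <- c("x", "y")
  # drop the closing vertex duplicated by WKT
  if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
  m
}

# contours column <-> list of polygons, for cells data.frames
cells_polygons <- function(cells) {
  if (!is.null(cells$contour)) {
    lapply(cells$contour, wkt_to_polygon)
  } else if (!is.null(attr(cells, "polygons"))) {
    attr(cells, "polygons")
  } else {
    stop("cells table carries no 'contour' (WKT) column")
  }
}
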