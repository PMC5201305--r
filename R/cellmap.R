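# Projection of spot coordinates into a normalized demi-coccoid model
# cell (800 nm wide, 900 nm half-length), population location maps, axial
# intensity profiles and zone classification.  Scaling is per-cell affine:
# each cell is stretched to the model dimensions, and the axial coordinate
# is folded about midcell so both halves project onto one.

#' The demi-coccoid model cell
#'
#' The projection space is one half of an average coccoid cell: full width
#' 800 nm across the axis (lateral coordinate `u`, sign retained) and
#' 900 nm from midcell to pole apex (axial coordinate `v >= 0`).  The
#' outline is half a capsule; a membrane band hugs the outline and a
#' central ellipse approximates the nucleoid.
#'
#' @param half_length_nm distance midcell to pole apex (default 900).
#' @param width_nm full cell width (default 800).
#' @param membrane_band_nm thickness of the wall + membrane annulus
#'   (must be < width/2).
#' @param nucleoid_scale nucleoid ellipse semi-axes as a fraction of the
#'   model half-dimensions.
#' @param pole_v_fraction v/half_length above which a spot counts as
#'   polar.
#' @return object of class `model_cell`.
#' @export
model_cell <- function(half_length_nm = 900, width_nm = 800,
                       membrane_band_nm = 50, nucleoid_scale = 0.55,
                       pole_v_fraction = 0.6) {
  stopifnot(half_length_nm > 0, width_nm > 0,
            membrane_band_nm > 0, membrane_band_nm < width_nm / 2,
            nucleoid_scale > 0, nucleoid_scale < 1,
            pole_v_fraction > 0, pole_v_fraction < 1)
  structure(
    list(half_length_nm = half_length_nm, width_nm = width_nm,
         membrane_band_nm = membrane_band_nm,
         nucleoid_scale = nucleoid_scale,
         pole_v_fraction = pole_v_fraction),
    class = "model_cell"
  )
}

# signed distance from (u, v) to the model outline (positive inside);
# the straight flank ends at v = half_length - width/2, beyond which the
# outline is the polar cap circle
.model_outline_depth <- function(u, v, model) {
  r <- model$width_nm / 2
  s <- model$half_length_nm - r
  ifelse(v <= s, r - abs(u), r - sqrt(u^2 + (v - s)^2))
}

#' Orientation frame of a cell contour
#'
#' Principal axis of the enclosed region (polygon moments), with length
#' and width measured as vertex extents along/across the axis.
#'
#' @param contour two-column polygon matrix or WKT string.
#' @return list of class `cell_frame`: `centroid`, `axis` (unit vector),
#'   `length`, `width`.
#' @export
cell_frame <- function(contour) {
  poly <- if (is.character(contour)) wkt_to_polygon(contour) else contour
  m <- polygon_moments(poly)
  eig <- eigen(m$cov, symmetric = TRUE)
  axis <- eig$vectors[, 1]
  d <- sweep(poly, 2, m$centroid)
  a <- d %*% axis
  b <- d %*% c(-axis[2], axis[1])
  structure(
    list(centroid = m$centroid, axis = as.numeric(axis),
         length = max(a) - min(a), width = max(b) - min(b)),
    class = "cell_frame"
  )
}

# pull a point that affine scaling pushed marginally outside the model
# outline back onto it (anisotropic scaling of a capsule is not exactly a
# capsule, so sub-nm excursions near the cap are expected)
.clamp_to_model <- function(u, v, model) {
  r <- model$width_nm / 2
  hl <- model$half_length_nm
  v <- pmin(pmax(v, 0), hl)
  u <- pmin(pmax(u, -r), r)
  s <- hl - r
  cap <- v > s
  rad <- sqrt(u^2 + (v - s)^2)
  bad <- cap & rad > r
  if (any(bad)) {
    f <- r / rad[bad]
    u[bad] <- u[bad] * f
    v[bad] <- s + (v[bad] - s) * f
  }
  list(u = u, v = v)
}

#' Project one spot into the model cell
#'
#' The axial offset is folded about midcell and scaled by
#' `half_length / (cell length / 2)`; the lateral offset keeps its sign
#' and is scaled by `width / cell width`.  Intensity is carried over
#' unchanged.
#'
#' @param x,y spot coordinates in the contour's pixel frame.
#' @param frame a [cell_frame()].
#' @param model a [model_cell()].
#' @return list with `u` (nm, signed lateral), `v` (nm, axial >= 0).
#' @export
normalize_spot <- function(x, y, frame, model = model_cell()) {
  d <- c(x - frame$centroid[1], y - frame$centroid[2])
  a <- sum(d * frame$axis)
  b <- d[1] * -frame$axis[2] + d[2] * frame$axis[1]
  v <- abs(a) * model$half_length_nm / (frame$length / 2)
  u <- b * model$width_nm / frame$width
  cl <- .clamp_to_model(u, v, model)
  list(u = cl$u, v = cl$v)
}

#' Project an assigned spot table into the model cell
#'
#' @param spots data.frame with `cell_id`, `x`, `y` and optionally `w`,
#'   `h`, `I` (carried over).
#' @param cells data.frame with `cell_id` and `contour` (WKT).
#' @param model a [model_cell()].
#' @return data.frame with `cell_id`, `u`, `v` plus carried columns.
#' @export
normalize_spots <- function(spots, cells, model = model_cell()) {
  polys <- cells_polygons(cells)
  frames <- lapply(polys, cell_frame)
  names(frames) <- as.character(cells$cell_id)
  u <- numeric(nrow(spots)); v <- numeric(nrow(spots))
  for (i in seq_len(nrow(spots))) {
    fr <- frames[[as.character(spots$cell_id[i])]]
    if (is.null(fr)) stop("spot assigned to unknown cell_id ", spots$cell_id[i])
    nv <- normalize_spot(spots$x[i], spots$y[i], fr, model)
    u[i] <- nv$u; v[i] <- nv$v
  }
  out <- data.frame(cell_id = spots$cell_id, u = u, v = v)
  for (col in intersect(c("w", "h", "I", "is_cluster"), names(spots))) {
    out[[col]] <- spots[[col]]
  }
  if (is.null(out$w) && !is.null(spots$fwhm)) out$w <- spots$fwhm
  out
}

# separable Gaussian blur with zero padding; raw counts are kept alongside
.gaussian_blur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  half <- max(1L, ceiling(3 * sigma))
  k <- dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  pad_conv <- function(v) {
    n <- length(v)
    vp <- c(numeric(half), v, numeric(half))
    out <- numeric(n)
    for (j in seq_along(k)) out <- out + k[j] * vp[j:(j + n - 1)]
    out
  }
  m2 <- apply(mat, 2, pad_conv)
  t(apply(m2, 1, pad_conv))
}

#' Build a population location map
#'
#' 2D histogram of normalized spots on the model half-cell, optionally
#' Gaussian-smoothed.  Raw counts are always retained; their sum equals
#' the number of projected spots.
#'
#' @param nspots output of [normalize_spots()].
#' @param model a [model_cell()].
#' @param bin_nm bin size (nm); must not exceed the model dimensions.
#' @param smooth_nm smoothing kernel sd (nm); 0 disables smoothing.
#' @param weight `"count"` (default) or `"intensity"` (weight by `I`).
#' @return object of class `location_map`: `counts` and `density`
#'   matrices (rows = u bins, cols = v bins), bin break vectors,
#'   `n_spots`, `n_cells`, `model`.
#' @export
build_location_map <- function(nspots, model = model_cell(), bin_nm = 25,
                               smooth_nm = 50, weight = c("count", "intensity")) {
  weight <- match.arg(weight)
  stopifnot(nrow(nspots) >= 1)
  if (bin_nm > model$width_nm || bin_nm > model$half_length_nm) {
    stop("bin_nm larger than the model cell")
  }
  r <- model$width_nm / 2
  u_breaks <- seq(-r, r, by = bin_nm)
  if (u_breaks[length(u_breaks)] < r) u_breaks <- c(u_breaks, r)
  v_breaks <- seq(0, model$half_length_nm, by = bin_nm)
  if (v_breaks[length(v_breaks)] < model$half_length_nm) {
    v_breaks <- c(v_breaks, model$half_length_nm)
  }
  ui <- findInterval(nspots$u, u_breaks, rightmost.closed = TRUE,
                     all.inside = TRUE)
  vi <- findInterval(nspots$v, v_breaks, rightmost.closed = TRUE,
                     all.inside = TRUE)
  nu <- length(u_breaks) - 1L; nv <- length(v_breaks) - 1L
  wts <- if (weight == "intensity") nspots$I else rep(1, nrow(nspots))
  counts <- matrix(0, nu, nv)
  for (i in seq_along(ui)) counts[ui[i], vi[i]] <- counts[ui[i], vi[i]] + wts[i]
  density <- .gaussian_blur(counts, smooth_nm / bin_nm)
  structure(
    list(counts = counts, density = density,
         u_breaks = u_breaks, v_breaks = v_breaks, bin_nm = bin_nm,
         smooth_nm = smooth_nm, weight = weight,
         n_spots = nrow(nspots), n_cells = length(unique(nspots$cell_id)),
         model = model),
    class = "location_map"
  )
}

#' @export
print.location_map <- function(x, ...) {
  cat(sprintf(
    "location map: %d spots from %d cells, %d x %d bins of %g nm (%s-weighted)\n",
    x$n_spots, x$n_cells, nrow(x$counts), ncol(x$counts), x$bin_nm, x$weight
  ))
  invisible(x)
}

#' Heat-map plot of a location map
#' @param x a `location_map`.
#' @param ... passed to [graphics::image()].
#' @export
plot.location_map <- function(x, ...) {
  image(
    x = x$v_breaks, y = x$u_breaks, z = t(x$density),
    col = hcl.colors(64, "viridis"), xlab = "v (nm, midcell to pole)",
    ylab = "u (nm)", useRaster = TRUE, ...
  )
  box()
  invisible(x)
}

#' Axial intensity profile of a location map
#'
#' Sums the map density over a central strip around the long axis and
#' normalizes the profile to a peak of 1.
#'
#' @param map a [build_location_map()] result.
#' @param strip_nm full strip width centred on the axis (default 200 nm).
#' @param use `"density"` (smoothed, default) or `"counts"` (raw).
#' @return data.frame with `v` (bin centres, nm) and `value`.
#' @export
axial_profile <- function(map, strip_nm = 200, use = c("density", "counts")) {
  use <- match.arg(use)
  u_mid <- (map$u_breaks[-1] + map$u_breaks[-length(map$u_breaks)]) / 2
  strip <- abs(u_mid) <= strip_nm / 2
  mat <- map[[use]]
  if (!any(strip)) {
    warning("strip narrower than one bin row: zero profile")
    prof <- numeric(ncol(mat))
  } else {
    prof <- colSums(mat[strip, , drop = FALSE])
  }
  if (max(prof) > 0) prof <- prof / max(prof) else warning("empty axial strip")
  v_mid <- (map$v_breaks[-1] + map$v_breaks[-length(map$v_breaks)]) / 2
  data.frame(v = v_mid, value = prof)
}

#' Classify normalized spots into model-cell zones
#'
#' Precedence: membrane (within the membrane band of the outline) >
#' nucleoid (inside the nucleoid ellipse) > pole (v above
#' `pole_v_fraction * half_length`) > cytoplasm.
#'
#' @param u,v normalized coordinates (nm), vectorized.
#' @param model a [model_cell()].
#' @return factor with levels membrane, nucleoid, pole, cytoplasm.
#' @export
zone_classify <- function(u, v, model = model_cell()) {
  depth <- .model_outline_depth(u, v, model)
  au <- model$nucleoid_scale * model$width_nm / 2
  av <- model$nucleoid_scale * model$half_length_nm
  in_nuc <- (u / au)^2 + (v / av)^2 <= 1
  polar <- v >= model$pole_v_fraction * model$half_length_nm
  zone <- ifelse(depth <= model$membrane_band_nm, "membrane",
          ifelse(in_nuc, "nucleoid",
          ifelse(polar, "pole", "cytoplasm")))
  factor(zone, levels = c("membrane", "nucleoid", "pole", "cytoplasm"))
}

#' Zone occupancy fractions of a normalized spot table
#'
#' @param nspots output of [normalize_spots()].
#' @param model a [model_cell()].
#' @param weight `"count"` (each spot counts once) or `"intensity"`
#'   (spots weighted by `I`, matching signal-weighted density maps).
#' @return named numeric vector of fractions over the four zones.
#' @export
zone_fractions <- function(nspots, model = model_cell(),
                           weight = c("count", "intensity")) {
  weight <- match.arg(weight)
  z <- zone_classify(nspots$u, nspots$v, model)
  w <- if (weight == "intensity") nspots$I else rep(1, nrow(nspots))
  tab <- tapply(w, z, sum, default = 0)
  setNames(as.numeric(tab) / sum(tab), names(tab))
}
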