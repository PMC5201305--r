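# Spot detection and quantification: local-maximum candidate search,
# least-squares fitting of a symmetric 2D Gaussian plus constant
# background, and the intensity statistic I = pi * w^2 * h (w = FWHM,
# h = peak height above background).

#' Detection/fitting configuration
#'
#' @param threshold candidate threshold in multiples of the robust image
#'   noise sd (MAD-based).
#' @param window_halfsize half-size of the square fit window (px, >= 2).
#' @param max_iter maximum fit iterations.
#' @param tol convergence tolerance of the fit.
#' @param min_separation minimum separation between accepted candidates
#'   (px); closer maxima are merged keeping the brighter.
#' @return object of class `detection_config`.
#' @export
detection_config <- function(threshold = 5, window_halfsize = 5L,
                             max_iter = 200L, tol = 1e-8,
                             min_separation = 3) {
  stopifnot(threshold > 0, window_halfsize >= 2, min_separation > 0,
            max_iter >= 1, tol > 0)
  structure(
    list(threshold = threshold, window_halfsize = as.integer(window_halfsize),
         max_iter = as.integer(max_iter), tol = tol,
         min_separation = min_separation),
    class = "detection_config"
  )
}

#' Robust image background and noise estimate
#'
#' Background = median, noise sd = scaled median absolute deviation.
#'
#' @param image numeric matrix.
#' @return list with `background` and `sd`.
#' @export
estimate_image_noise <- function(image) {
  list(background = median(image), sd = mad(image))
}

#' Detect integer-pixel spot candidates
#'
#' Strict 8-neighbour local maxima exceeding `background +
#' threshold * noise_sd`, sorted by decreasing pixel value; maxima closer
#' than `min_separation` (Euclidean) are merged keeping the brighter.
#' Coordinates are 0-based (x = column, y = row).
#'
#' @param image 2D numeric matrix with finite values.
#' @param config a [detection_config()].
#' @return data.frame with columns `x`, `y`, `value` (possibly empty).
#' @export
detect_candidates <- function(image, config = detection_config()) {
  stopifnot(is.matrix(image), all(is.finite(image)))
  empty <- data.frame(x = integer(0), y = integer(0), value = numeric(0))
  if (nrow(image) < 3 || ncol(image) < 3) return(empty)
  ns <- estimate_image_noise(image)
  thr <- ns$background + config$threshold * ns$sd
  nr <- nrow(image); nc <- ncol(image)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- image
  ctr <- pad[2:(nr + 1), 2:(nc + 1)]
  shift <- function(dr, dc) pad[2:(nr + 1) + dr, 2:(nc + 1) + dc]
  # strict on one half-neighbourhood, non-strict on the mirror half so a
  # flat two-pixel plateau yields exactly one candidate
  is_max <- ctr > shift(-1, -1) & ctr > shift(-1, 0) & ctr > shift(-1, 1) &
    ctr > shift(0, -1) &
    ctr >= shift(0, 1) &
    ctr >= shift(1, -1) & ctr >= shift(1, 0) & ctr >= shift(1, 1) &
    ctr > thr
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(empty)
  cand <- data.frame(
    x = idx[, 2] - 1L, y = idx[, 1] - 1L,
    value = image[idx]
  )
  cand <- cand[order(-cand$value), , drop = FALSE]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!any(keep)) {
      keep[i] <- TRUE
      next
    }
    d2 <- (cand$x[keep] - cand$x[i])^2 + (cand$y[keep] - cand$y[i])^2
    keep[i] <- all(d2 >= config$min_separation^2)
  }
  out <- cand[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# model for one window; exported through fit_spot only
.gauss2d <- function(xs, ys, x0, y0, w, h, b) {
  b + h * exp(-4 * log(2) * ((xs - x0)^2 + (ys - y0)^2) / w^2)
}

#' Fit a symmetric 2D Gaussian to one candidate
#'
#' Least-squares fit of `b + h * exp(-4*log(2)*r^2/w^2)` over a square
#' window centred on the candidate.  Windows truncated by the image edge
#' are clipped and flagged.  Non-convergent or degenerate fits (flat
#' window, centre escaping the window, unphysical width) are flagged with
#' `converged = FALSE` and should be discarded downstream.
#'
#' @param image numeric matrix.
#' @param candidate numeric length-2 `c(x, y)` integer-pixel candidate
#'   (0-based), e.g. one row of [detect_candidates()] output.
#' @param config a [detection_config()].
#' @return one-row data.frame with columns `x`, `y`, `w` (FWHM, px), `h`,
#'   `b`, `I` (= pi w^2 h), `residual` (RMS), `converged`, `clipped`.
#' @export
fit_spot <- function(image, candidate, config = detection_config()) {
  hx <- config$window_halfsize
  cx <- round(as.numeric(candidate[[1]])); cy <- round(as.numeric(candidate[[2]]))
  cols <- max(0L, cx - hx):min(ncol(image) - 1L, cx + hx)
  rows <- max(0L, cy - hx):min(nrow(image) - 1L, cy + hx)
  clipped <- length(cols) < 2L * hx + 1L || length(rows) < 2L * hx + 1L
  # expand.grid varies its first factor fastest; image subsets are
  # column-major (row index fastest), so ys must come first
  grid <- expand.grid(ys = rows, xs = cols)
  z <- as.vector(image[rows + 1L, cols + 1L])
  fail <- function() data.frame(
    x = NA_real_, y = NA_real_, w = NA_real_, h = NA_real_, b = NA_real_,
    I = NA_real_, residual = NA_real_, converged = FALSE, clipped = clipped
  )
  b0 <- median(z)
  h0 <- max(z) - b0
  if (!is.finite(h0) || h0 <= .Machine$double.eps * max(1, abs(b0))) {
    return(fail()) # flat window: nothing to fit
  }
  df <- data.frame(z = z, xs = grid$xs, ys = grid$ys)
  k <- 4 * log(2)
  fit <- tryCatch(
    nls(z ~ b + h * exp(-k * ((xs - x0)^2 + (ys - y0)^2) / w^2),
        data = df,
        start = list(x0 = cx, y0 = cy, w = 2.5, h = h0, b = b0),
        algorithm = "port",
        lower = c(x0 = min(cols) - 1, y0 = min(rows) - 1, w = 0.5,
                  h = 0, b = -Inf),
        upper = c(x0 = max(cols) + 1, y0 = max(rows) + 1,
                  w = 4 * (2 * hx + 1), h = Inf, b = Inf),
        control = list(maxiter = config$max_iter, warnOnly = FALSE,
                       tol = config$tol)),
    error = function(e) NULL
  )
  if (is.null(fit)) return(fail())
  p <- coef(fit)
  ok <- p[["h"]] > 0 &&
    p[["w"]] <= (2 * hx + 1) && # width beyond the window is unphysical

    p[["x0"]] >= min(cols) - 0.5 && p[["x0"]] <= max(cols) + 0.5 &&
    p[["y0"]] >= min(rows) - 0.5 && p[["y0"]] <= max(rows) + 0.5
  data.frame(
    x = p[["x0"]], y = p[["y0"]], w = p[["w"]], h = p[["h"]], b = p[["b"]],
    I = pi * p[["w"]]^2 * p[["h"]],
    residual = sqrt(mean(residuals(fit)^2)),
    converged = ok, clipped = clipped
  )
}

#' Detect and fit all spots in an image
#'
#' Convenience wrapper: [detect_candidates()] followed by [fit_spot()] on
#' each candidate; non-converged fits are dropped (their count is kept in
#' the `"rejected"` attribute).
#'
#' @inheritParams detect_candidates
#' @return data.frame of accepted [fit_spot()] rows.
#' @export
fit_spots <- function(image, config = detection_config()) {
  cand <- detect_candidates(image, config)
  if (nrow(cand) == 0L) {
    out <- fit_spot(matrix(0, 3, 3), c(1, 1), detection_config())[0, ]
    attr(out, "rejected") <- 0L
    return(out)
  }
  fits <- do.call(rbind, lapply(seq_len(nrow(cand)), function(i) {
    fit_spot(image, c(cand$x[i], cand$y[i]), config)
  }))
  out <- fits[fits$converged, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- sum(!fits$converged)
  out
}

#' Assign spots to cell contours
#'
#' Each spot is assigned to the unique contour containing it; spots inside
#' no contour are discarded (count in the `"discarded"` attribute).  When
#' contours overlap, the spot goes to the contour with the nearest
#' centroid and a warning is emitted.
#'
#' @param spots data.frame with columns `x`, `y` (same pixel frame as the
#'   contours).
#' @param cells data.frame with columns `cell_id` and `contour` (WKT
#'   polygons), e.g. the `cells` table of a [generate_scene()] truth.
#' @return `spots` with a `cell_id` column, dropping unassigned rows;
#'   attributes `discarded` (count) and `ambiguous` (count).
#' @export
assign_spots_to_cells <- function(spots, cells) {
  polys <- cells_polygons(cells)
  cents <- t(vapply(polys, function(p) polygon_moments(p)$centroid, numeric(2)))
  n <- nrow(spots)
  assigned <- rep(NA_integer_, n)
  ambiguous <- 0L
  inside <- matrix(FALSE, n, length(polys))
  for (j in seq_along(polys)) {
    p <- polys[[j]]
    bb <- apply(p, 2, range)
    near <- spots$x >= bb[1, 1] & spots$x <= bb[2, 1] &
      spots$y >= bb[1, 2] & spots$y <= bb[2, 2]
    if (any(near)) {
      inside[near, j] <- point_in_polygon(spots$x[near], spots$y[near], p)
    }
  }
  hits <- rowSums(inside)
  one <- hits == 1L
  assigned[one] <- max.col(inside[one, , drop = FALSE], ties.method = "first")
  multi <- which(hits > 1L)
  for (i in multi) {
    js <- which(inside[i, ])
    d2 <- (cents[js, 1] - spots$x[i])^2 + (cents[js, 2] - spots$y[i])^2
    assigned[i] <- js[which.min(d2)]
    ambiguous <- ambiguous + 1L
  }
  if (ambiguous > 0L) {
    warning(sprintf("%d spot(s) inside overlapping contours; assigned to nearest centroid", ambiguous))
  }
  keep <- !is.na(assigned)
  out <- spots[keep, , drop = FALSE]
  out$cell_id <- cells$cell_id[assigned[keep]]
  rownames(out) <- NULL
  attr(out, "discarded") <- sum(!keep)
  attr(out, "ambiguous") <- ambiguous
  out
}
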