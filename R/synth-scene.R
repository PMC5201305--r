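# Synthetic microscopy scenes: capsule-shaped coccoid cells containing
# diffraction-limited spots laid out in one of four localization patterns,
# rendered with an isotropic Gaussian PSF plus Poisson/Gaussian noise.
# Ground truth (pre-noise spot parameters, contours, cluster flags) is
# recorded so every downstream stage can be scored.

#' Specification of a synthetic microscopy scene
#'
#' Defaults describe mid-exponential coccoid cells of about 800 x 1800 nm
#' imaged at 65 nm/px with a diffraction-limited PSF (sigma 130 nm, i.e.
#' FWHM ~306 nm ~ 4.7 px).  Spot counts per cell follow a shifted Poisson
#' (at least `min_spots_per_cell`, reflecting that induced cells carry
#' several transcripts); spot heights follow a Gamma distribution.
#'
#' @param n_cells number of cells in the scene.
#' @param cell_width_nm,cell_length_nm mean cell dimensions (nm).
#' @param size_cv coefficient of variation of per-cell dimensions.
#' @param pixel_size_nm camera pixel size (nm).
#' @param psf_sigma_nm PSF standard deviation (nm); rendered spot FWHM is
#'   `2*sqrt(2*log(2))*psf_sigma_nm/pixel_size_nm` pixels.
#' @param pattern localization pattern: `"uniform"`, `"membrane"`,
#'   `"cytoplasmic_nucleoid_excluded"`, or `"polar_cluster"`.
#' @param spots_per_cell_mean mean spots per cell (0 disables spots).
#' @param min_spots_per_cell lower bound of the shifted-Poisson spot count.
#' @param spot_height_mean,spot_height_shape Gamma parameters of spot peak
#'   heights (mean and shape).
#' @param cluster_fraction_of_signal fraction of a polar-cluster cell's
#'   total intensity carried by the single cluster spot.
#' @param nucleoid_scale nucleoid ellipse semi-axes as a fraction of the
#'   cell half-dimensions.
#' @param membrane_inset_nm distance of membrane-pattern spots inside the
#'   contour.
#' @param background constant background level (counts).
#' @param poisson_noise apply Poisson noise to signal + background?
#' @param read_noise_sd Gaussian read-noise standard deviation (counts).
#' @param margin_nm spacing between neighbouring cells.
#' @param canvas_px optional `c(rows, cols)` canvas size; an error is
#'   raised if the requested cells do not fit.
#' @param random_orientation rotate each cell by a uniform random angle?
#' @param seed integer seed; identical spec + seed gives a bit-identical
#'   scene.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(n_cells,
                       cell_width_nm = 800,
                       cell_length_nm = 1800,
                       size_cv = 0.08,
                       pixel_size_nm = 65,
                       psf_sigma_nm = 130,
                       pattern = c("uniform", "membrane",
                                   "cytoplasmic_nucleoid_excluded",
                                   "polar_cluster"),
                       spots_per_cell_mean = 6,
                       min_spots_per_cell = 2L,
                       spot_height_mean = 300,
                       spot_height_shape = 6,
                       cluster_fraction_of_signal = 0.6,
                       nucleoid_scale = 0.55,
                       membrane_inset_nm = 25,
                       background = 100,
                       poisson_noise = TRUE,
                       read_noise_sd = 2,
                       margin_nm = 600,
                       canvas_px = NULL,
                       random_orientation = TRUE,
                       seed = 1L) {
  pattern <- match.arg(pattern)
  stopifnot(
    n_cells >= 1, cell_width_nm > 0, cell_length_nm > 0,
    cell_length_nm >= cell_width_nm,
    pixel_size_nm > 0, psf_sigma_nm > 0,
    spots_per_cell_mean >= 0, spot_height_mean > 0,
    cluster_fraction_of_signal >= 0, cluster_fraction_of_signal <= 1,
    nucleoid_scale > 0, nucleoid_scale < 1,
    background >= 0, read_noise_sd >= 0, size_cv >= 0
  )
  spec <- list(
    n_cells = as.integer(n_cells), cell_width_nm = cell_width_nm,
    cell_length_nm = cell_length_nm, size_cv = size_cv,
    pixel_size_nm = pixel_size_nm, psf_sigma_nm = psf_sigma_nm,
    pattern = pattern, spots_per_cell_mean = spots_per_cell_mean,
    min_spots_per_cell = as.integer(min_spots_per_cell),
    spot_height_mean = spot_height_mean,
    spot_height_shape = spot_height_shape,
    cluster_fraction_of_signal = cluster_fraction_of_signal,
    nucleoid_scale = nucleoid_scale, membrane_inset_nm = membrane_inset_nm,
    background = background, poisson_noise = poisson_noise,
    read_noise_sd = read_noise_sd, margin_nm = margin_nm,
    canvas_px = canvas_px, random_orientation = random_orientation,
    seed = as.integer(seed)
  )
  class(spec) <- "scene_spec"
  spec
}

# capsule membership with an inset margin, local frame (a along axis,
# b across), half-length hl, radius r
.in_capsule <- function(a, b, hl, r, inset = 0) {
  s <- hl - r
  r2 <- r - inset
  abs(b) <= r2 & (abs(a) <= s | (abs(a) - s)^2 + b^2 <= r2^2)
}

# sample n points in the local cell frame according to the pattern
.sample_positions <- function(n, pattern, hl, r, nucleoid_scale,
                              membrane_inset) {
  if (n == 0L) {
    return(cbind(a = numeric(0), b = numeric(0)))
  }
  if (pattern == "membrane") {
    r2 <- r - membrane_inset
    s <- hl - r
    per <- 4 * s + 2 * pi * r2
    t <- runif(n, 0, per)
    a <- numeric(n); b <- numeric(n)
    for (i in seq_len(n)) {
      u <- t[i]
      if (u < 2 * s) {                 # top edge
        a[i] <- -s + u; b[i] <- r2
      } else if (u < 4 * s) {          # bottom edge
        a[i] <- -s + (u - 2 * s); b[i] <- -r2
      } else {
        th <- (u - 4 * s) / r2         # both caps, angle along arcs
        if (th <= pi) {
          a[i] <- s + r2 * sin(th); b[i] <- r2 * cos(th)
        } else {
          a[i] <- -s - r2 * sin(th - pi); b[i] <- r2 * cos(th - pi)
        }
      }
    }
    return(cbind(a = a, b = b))
  }
  inset <- 30
  keep_fun <- switch(pattern,
    uniform = , polar_cluster = function(a, b) .in_capsule(a, b, hl, r, inset),
    cytoplasmic_nucleoid_excluded = function(a, b) {
      .in_capsule(a, b, hl, r, inset) &
        (a / (nucleoid_scale * hl))^2 + (b / (nucleoid_scale * r))^2 > 1
    }
  )
  out <- matrix(NA_real_, 0, 2)
  while (nrow(out) < n) {
    m <- max(2L * (n - nrow(out)), 16L)
    a <- runif(m, -hl, hl); b <- runif(m, -r, r)
    ok <- keep_fun(a, b)
    out <- rbind(out, cbind(a[ok], b[ok]))
  }
  out <- out[seq_len(n), , drop = FALSE]
  colnames(out) <- c("a", "b")
  out
}

#' Render Gaussian spots onto an image
#'
#' Adds symmetric 2D Gaussians `h * exp(-4*log(2) * r^2 / fwhm^2)` on top
#' of a constant background.  Coordinates are 0-based with pixel centres
#' at integer positions (x = column, y = row).
#'
#' @param dim `c(rows, cols)` image size in pixels.
#' @param spots data.frame with columns `x`, `y`, `fwhm`, `h`.
#' @param background constant background added to every pixel.
#' @return numeric matrix.
#' @export
render_spots <- function(dim, spots, background = 0) {
  img <- matrix(background, dim[1], dim[2])
  if (is.null(spots) || nrow(spots) == 0L) return(img)
  k <- 4 * log(2)
  for (i in seq_len(nrow(spots))) {
    w <- spots$fwhm[i]
    half <- ceiling(3 * w)
    cx <- spots$x[i]; cy <- spots$y[i]
    cols <- max(0L, floor(cx) - half):min(dim[2] - 1L, ceiling(cx) + half)
    rows <- max(0L, floor(cy) - half):min(dim[1] - 1L, ceiling(cy) + half)
    if (length(cols) == 0L || length(rows) == 0L) next
    gx <- exp(-k * (cols - cx)^2 / w^2)
    gy <- exp(-k * (rows - cy)^2 / w^2)
    img[rows + 1L, cols + 1L] <-
      img[rows + 1L, cols + 1L] + spots$h[i] * outer(gy, gx)
  }
  img
}

#' Generate a synthetic scene with ground truth
#'
#' Lays cells out on a grid (no overlap), samples spot positions per the
#' requested pattern, renders them with the Gaussian PSF, then applies
#' Poisson noise on signal + background followed by Gaussian read noise.
#' Ground truth records the pre-noise spot parameters, per-cell contours,
#' cluster flags, and per-cell total intensities
#' \eqn{\sum_i \pi w_i^2 h_i}.
#'
#' @param spec a [scene_spec()].
#' @param render render the pixel image? With `FALSE` only ground truth is
#'   produced (fast path for placement-level tests).
#' @return list of class `scene` with elements `image` (matrix or `NULL`),
#'   `truth` (list of data.frames `cells`, `spots`) and `spec`.
#' @export
generate_scene <- function(spec, render = TRUE) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    n <- spec$n_cells
    px <- spec$pixel_size_nm
    clamp <- function(x, mu, cv) {
      if (cv == 0) return(rep(mu, length(x)))
      pmin(pmax(x, mu * (1 - 2.5 * cv)), mu * (1 + 2.5 * cv))
    }
    len <- clamp(rnorm(n, spec$cell_length_nm, spec$size_cv * spec$cell_length_nm),
                 spec$cell_length_nm, spec$size_cv)
    wid <- clamp(rnorm(n, spec$cell_width_nm, spec$size_cv * spec$cell_width_nm),
                 spec$cell_width_nm, spec$size_cv)
    wid <- pmin(wid, len - 1e-6)
    theta <- if (spec$random_orientation) runif(n, 0, pi) else rep(0, n)

    pitch_nm <- spec$cell_length_nm * (1 + 2.5 * spec$size_cv) + spec$margin_nm
    ncols <- ceiling(sqrt(n))
    nrows <- ceiling(n / ncols)
    canvas <- c(
      rows = as.integer(ceiling(nrows * pitch_nm / px)),
      cols = as.integer(ceiling(ncols * pitch_nm / px))
    )
    if (!is.null(spec$canvas_px)) {
      if (spec$canvas_px[1] < canvas[1] || spec$canvas_px[2] < canvas[2]) {
        stop(sprintf(
          "canvas %dx%d px cannot hold %d cells (needs %dx%d px)",
          spec$canvas_px[1], spec$canvas_px[2], n, canvas[1], canvas[2]
        ))
      }
      canvas <- as.integer(spec$canvas_px)
    }

    fwhm_px <- sigma_to_fwhm(spec$psf_sigma_nm) / px
    cell_rows <- vector("list", n)
    spot_rows <- vector("list", n)
    polys <- vector("list", n)
    for (i in seq_len(n)) {
      row <- (i - 1) %/% ncols
      col <- (i - 1) %% ncols
      center_nm <- c((col + 0.5) * pitch_nm, (row + 0.5) * pitch_nm)
      hl <- len[i] / 2; r <- wid[i] / 2
      poly_nm <- transform_polygon(capsule_polygon(len[i], wid[i]),
                                   theta[i], center_nm)
      poly_px <- poly_nm / px
      polys[[i]] <- poly_px

      n_dim <- if (spec$spots_per_cell_mean <= 0) {
        0L
      } else {
        spec$min_spots_per_cell +
          rpois(1, max(0, spec$spots_per_cell_mean - spec$min_spots_per_cell))
      }
      ab <- .sample_positions(
        n_dim, if (spec$pattern == "polar_cluster") "uniform" else spec$pattern,
        hl, r, spec$nucleoid_scale, spec$membrane_inset_nm
      )
      h <- if (n_dim > 0) {
        rgamma(n_dim, shape = spec$spot_height_shape,
               scale = spec$spot_height_mean / spec$spot_height_shape)
      } else {
        numeric(0)
      }
      is_cluster <- logical(n_dim)
      if (spec$pattern == "polar_cluster" && n_dim > 0) {
        f <- spec$cluster_fraction_of_signal
        a_cl <- sample(c(-1, 1), 1) * runif(1, 0.80, 0.95) * hl
        b_cl <- runif(1, -0.1, 0.1) * r
        h_cl <- if (f >= 1) sum(h) * 1e6 else f / (1 - f) * sum(h)
        ab <- rbind(ab, c(a_cl, b_cl))
        h <- c(h, h_cl)
        is_cluster <- c(is_cluster, TRUE)
      }
      m <- nrow(ab)
      if (m > 0) {
        ct <- cos(theta[i]); st <- sin(theta[i])
        x_nm <- ab[, 1] * ct - ab[, 2] * st + center_nm[1]
        y_nm <- ab[, 1] * st + ab[, 2] * ct + center_nm[2]
        spot_rows[[i]] <- data.frame(
          cell_id = i, x = x_nm / px, y = y_nm / px,
          fwhm = fwhm_px, h = h, I = pi * fwhm_px^2 * h,
          is_cluster = is_cluster
        )
      }
      cell_rows[[i]] <- data.frame(
        cell_id = i,
        cx = center_nm[1] / px, cy = center_nm[2] / px,
        theta = theta[i],
        length_px = len[i] / px, width_px = wid[i] / px,
        cluster_flag = spec$pattern == "polar_cluster" && any(is_cluster),
        total_I = if (m > 0) sum(pi * fwhm_px^2 * h) else 0,
        contour = polygon_to_wkt(poly_px),
        stringsAsFactors = FALSE
      )
    }
    cells <- do.call(rbind, cell_rows)
    spots <- if (all(vapply(spot_rows, is.null, logical(1)))) {
      data.frame(cell_id = integer(0), x = numeric(0), y = numeric(0),
                 fwhm = numeric(0), h = numeric(0), I = numeric(0),
                 is_cluster = logical(0))
    } else {
      do.call(rbind, spot_rows[!vapply(spot_rows, is.null, logical(1))])
    }
    rownames(spots) <- NULL
    attr(cells, "polygons") <- polys

    image <- NULL
    if (render) {
      image <- render_spots(canvas, spots, background = spec$background)
      if (spec$poisson_noise) {
        image[] <- rpois(length(image), lambda = pmax(image, 0))
      }
      if (spec$read_noise_sd > 0) {
        image <- image + rnorm(length(image), 0, spec$read_noise_sd)
      }
    }
    structure(
      list(image = image, truth = list(cells = cells, spots = spots),
           spec = spec, canvas_px = canvas),
      class = "scene"
    )
  })
}

#' Write a scene to disk (TIFF + ground-truth CSVs)
#'
#' @param scene a [generate_scene()] result (rendered).
#' @param dir output directory, created if needed.
#' @return named character vector of written paths, invisibly.
#' @export
write_scene <- function(scene, dir) {
  stopifnot(inherits(scene, "scene"), !is.null(scene$image))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    image = file.path(dir, "scene.tif"),
    cells = file.path(dir, "cells.csv"),
    spots = file.path(dir, "truth_spots.csv")
  )
  write_tiff16(scene$image, paths[["image"]])
  write.csv(scene$truth$cells, paths[["cells"]], row.names = FALSE)
  write.csv(scene$truth$spots, paths[["spots"]], row.names = FALSE)
  invisible(paths)
}
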