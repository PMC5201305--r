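# Polar-cluster classification and population statistics: a cell carries
# a polar mRNA cluster when a single compact spot near the pole holds at
# least half the cell's total signal.  Also: cluster fraction vs
# expression level, Gamma fits to expression distributions,
# FWHM/reciprocal-intensity heat maps, focus-to-cluster distances, and
# the axial spread ratio of a fluorescence profile.

#' Cluster-classification configuration
#'
#' A spot qualifies as a polar cluster when it simultaneously (i) carries
#' at least `min_intensity_fraction` of the cell's total intensity,
#' (ii) is compact (`w <= max_fwhm_px`), and (iii) sits near a pole
#' (`v >= polar_v_fraction * half_length`).
#'
#' @param min_intensity_fraction fraction of the cell total carried by one
#'   spot (default 0.5).
#' @param max_fwhm_px compactness cutoff on the fitted FWHM (px).
#' @param polar_v_fraction minimum v / half_length (default 0.6).
#' @param level_threshold_AU expression cutoff used in windows analyses
#'   (default 10 AU).
#' @return object of class `cluster_config`.
#' @export
cluster_config <- function(min_intensity_fraction = 0.5, max_fwhm_px = 5,
                           polar_v_fraction = 0.6,
                           level_threshold_AU = 10) {
  stopifnot(min_intensity_fraction > 0, min_intensity_fraction <= 1,
            polar_v_fraction > 0, polar_v_fraction <= 1,
            max_fwhm_px > 0, level_threshold_AU > 0)
  structure(
    list(min_intensity_fraction = min_intensity_fraction,
         max_fwhm_px = max_fwhm_px, polar_v_fraction = polar_v_fraction,
         level_threshold_AU = level_threshold_AU),
    class = "cluster_config"
  )
}

#' Classify one cell for polar-cluster presence
#'
#' @param spots data.frame of the cell's normalized spots with columns
#'   `u`, `v`, `w`, `I`.
#' @param total_I the cell's total intensity; cells with zero total are
#'   classified negative.
#' @param config a [cluster_config()].
#' @param model a [model_cell()].
#' @return list with `has_cluster` (logical) and `cluster` (the
#'   qualifying spot row of largest I, or `NULL`).
#' @export
classify_cell <- function(spots, total_I, config = cluster_config(),
                          model = model_cell()) {
  if (is.null(spots) || nrow(spots) == 0L || !is.finite(total_I) ||
      total_I <= 0) {
    return(list(has_cluster = FALSE, cluster = NULL))
  }
  qual <- spots$I >= config$min_intensity_fraction * total_I &
    spots$w <= config$max_fwhm_px &
    spots$v >= config$polar_v_fraction * model$half_length_nm
  if (!any(qual)) return(list(has_cluster = FALSE, cluster = NULL))
  best <- which(qual)[which.max(spots$I[qual])]
  list(has_cluster = TRUE, cluster = spots[best, , drop = FALSE])
}

#' Classify every cell in a normalized spot table
#'
#' @param nspots output of [normalize_spots()] (columns `cell_id`, `u`,
#'   `v`, `w`, `I`).
#' @param cell_totals data.frame with `cell_id` and `total_I`; when
#'   missing, totals default to the per-cell sum of spot intensities.
#' @param config a [cluster_config()].
#' @param model a [model_cell()].
#' @return data.frame with one row per cell: `cell_id`, `total_I`,
#'   `has_cluster`, `cluster_I`, `cluster_u`, `cluster_v`.
#' @export
classify_cells <- function(nspots, cell_totals = NULL,
                           config = cluster_config(), model = model_cell()) {
  ids <- if (is.null(cell_totals)) unique(nspots$cell_id) else cell_totals$cell_id
  totals <- if (is.null(cell_totals)) {
    tapply(nspots$I, nspots$cell_id, sum)[as.character(ids)]
  } else {
    setNames(cell_totals$total_I, as.character(cell_totals$cell_id))[as.character(ids)]
  }
  rows <- lapply(seq_along(ids), function(i) {
    sp <- nspots[nspots$cell_id == ids[i], , drop = FALSE]
    cl <- classify_cell(sp, totals[i], config, model)
    data.frame(
      cell_id = ids[i],
      total_I = unname(ifelse(is.na(totals[i]), 0, totals[i])),
      has_cluster = cl$has_cluster,
      cluster_I = if (cl$has_cluster) cl$cluster$I else NA_real_,
      cluster_u = if (cl$has_cluster) cl$cluster$u else NA_real_,
      cluster_v = if (cl$has_cluster) cl$cluster$v else NA_real_
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cluster fraction as a function of expression level
#'
#' Bins cells by total level (equal-count quantile bins by default) and
#' reports the binomial cluster fraction with standard error
#' `sqrt(p (1 - p) / n)` per bin.
#'
#' @param cells data.frame with columns `level` and `has_cluster`.
#' @param n_bins number of quantile bins (ignored when `breaks` given).
#' @param breaks optional explicit level breaks.
#' @return data.frame with `bin_lo`, `bin_hi`, `n`, `fraction`, `se`;
#'   empty input yields an empty table.  Bins with a single cell trigger a
#'   small-n warning (their SE is 0 by the formula).
#' @export
cluster_fraction_by_level <- function(cells, n_bins = 8, breaks = NULL) {
  if (is.null(cells) || nrow(cells) == 0L) {
    return(data.frame(bin_lo = numeric(0), bin_hi = numeric(0),
                      n = integer(0), fraction = numeric(0), se = numeric(0)))
  }
  if (is.null(breaks)) {
    qs <- unique(quantile(cells$level, probs = seq(0, 1, length.out = n_bins + 1)))
    breaks <- qs
  }
  if (length(breaks) < 2) breaks <- range(cells$level) + c(0, 1e-9)
  idx <- findInterval(cells$level, breaks, rightmost.closed = TRUE,
                      all.inside = TRUE)
  out <- do.call(rbind, lapply(seq_len(length(breaks) - 1L), function(b) {
    sel <- idx == b
    n <- sum(sel)
    if (n == 0L) return(NULL) # empty bins reported as missing
    p <- mean(cells$has_cluster[sel])
    data.frame(bin_lo = breaks[b], bin_hi = breaks[b + 1L], n = n,
               fraction = p, se = sqrt(p * (1 - p) / n))
  }))
  if (any(out$n == 1L)) warning("bins with a single cell: SE is not meaningful")
  rownames(out) <- NULL
  out
}

#' Maximum-likelihood Gamma fit to per-cell expression levels
#'
#' Exact zeros (detection floor) are excluded before fitting and their
#' fraction recorded.  Fitting maximizes the Gamma log-likelihood over
#' (log shape, log scale) by quasi-Newton iteration from moment starts.
#'
#' @param levels non-negative per-cell expression levels, n >= 10 after
#'   zero removal.
#' @return list of class `expression_fit`: `shape`, `scale`, `loglik`,
#'   `n_cells`, `zero_fraction`.
#' @export
fit_expression_gamma <- function(levels) {
  stopifnot(is.numeric(levels), all(levels >= 0))
  zero_fraction <- mean(levels == 0)
  x <- levels[levels > 0]
  if (length(x) < 10) stop("need at least 10 positive levels to fit a Gamma")
  if (diff(range(x)) < .Machine$double.eps * mean(x)) {
    stop("degenerate expression data: all levels equal")
  }
  m <- mean(x); v <- var(x)
  start <- c(log(max(m^2 / v, 1e-3)), log(max(v / m, 1e-12)))
  nll <- function(p) -sum(dgamma(x, shape = exp(p[1]), scale = exp(p[2]),
                                 log = TRUE))
  opt <- optim(start, nll, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  structure(
    list(shape = exp(opt$par[1]), scale = exp(opt$par[2]),
         loglik = -opt$value, n_cells = length(x),
         zero_fraction = zero_fraction),
    class = "expression_fit"
  )
}

#' @export
print.expression_fit <- function(x, ...) {
  cat(sprintf(
    "Gamma expression fit: shape %.3f, scale %.3f (n = %d, %.0f%% zeros excluded)\n",
    x$shape, x$scale, x$n_cells, 100 * x$zero_fraction
  ))
  invisible(x)
}

#' 2D density of (FWHM, 1/intensity) spot pairs
#'
#' Dense clusters sit at low reciprocal intensity for a given FWHM; this
#' histogram separates them from dim single transcripts.
#'
#' @param spots data.frame with `w` (> 0) and `I`; spots with `I <= 0`
#'   are excluded with a warning.
#' @param fwhm_range,inv_i_range histogram ranges (defaults from data).
#' @param n_bins bins per axis.
#' @return list of class `fwhm_heatmap`: `counts` matrix (rows = FWHM
#'   bins, cols = 1/I bins) and the two break vectors.
#' @export
fwhm_intensity_heatmap <- function(spots, fwhm_range = NULL,
                                   inv_i_range = NULL, n_bins = 32) {
  bad <- spots$I <= 0
  if (any(bad)) {
    warning(sprintf("%d spot(s) with I <= 0 excluded", sum(bad)))
    spots <- spots[!bad, , drop = FALSE]
  }
  stopifnot(nrow(spots) >= 1, all(spots$w > 0))
  inv <- 1 / spots$I
  fwhm_range <- fwhm_range %||% range(spots$w)
  inv_i_range <- inv_i_range %||% range(inv)
  fb <- seq(fwhm_range[1], fwhm_range[2], length.out = n_bins + 1)
  ib <- seq(inv_i_range[1], inv_i_range[2], length.out = n_bins + 1)
  fi <- findInterval(spots$w, fb, rightmost.closed = TRUE, all.inside = TRUE)
  ii <- findInterval(inv, ib, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- matrix(0L, n_bins, n_bins)
  for (i in seq_along(fi)) counts[fi[i], ii[i]] <- counts[fi[i], ii[i]] + 1L
  structure(list(counts = counts, fwhm_breaks = fb, inv_i_breaks = ib),
            class = "fwhm_heatmap")
}

#' Per-cell distances between protein foci and mRNA clusters
#'
#' For every cell present in both tables, the distance from each protein
#' focus to the nearest cluster spot is computed and the per-cell minimum
#' retained; cells lacking either focus type are skipped and counted.
#'
#' @param foci data.frame with `cell_id`, `x`, `y` (nm).
#' @param clusters data.frame with `cell_id`, `x`, `y` (nm).
#' @return list of class `distance_stats`: `distances` (nm), normal-fit
#'   `mean` and `sd`, `n`, `n_skipped`.
#' @export
foci_distances <- function(foci, clusters) {
  ids <- union(unique(foci$cell_id), unique(clusters$cell_id))
  d <- numeric(0)
  skipped <- 0L
  for (id in ids) {
    f <- foci[foci$cell_id == id, , drop = FALSE]
    cl <- clusters[clusters$cell_id == id, , drop = FALSE]
    if (nrow(f) == 0L || nrow(cl) == 0L) {
      skipped <- skipped + 1L
      next
    }
    dm <- outer(seq_len(nrow(f)), seq_len(nrow(cl)), function(i, j) {
      sqrt((f$x[i] - cl$x[j])^2 + (f$y[i] - cl$y[j])^2)
    })
    d <- c(d, min(dm))
  }
  structure(
    list(distances = d,
         mean = if (length(d)) mean(d) else NA_real_,
         sd = if (length(d) > 1) sd(d) else NA_real_,
         n = length(d), n_skipped = skipped),
    class = "distance_stats"
  )
}

#' Axial spread ratio of a fluorescence profile
#'
#' Length of the contiguous region around the profile maximum where the
#' signal stays at or above `threshold_fraction * max`, divided by the
#' full profile length.  Used to compare e.g. ribosomal-protein spread
#' along the long axis between expression conditions.
#'
#' @param profile numeric vector sampled evenly along the full cell
#'   length.
#' @param threshold_fraction threshold relative to the maximum
#'   (default 0.25).
#' @return ratio in `(0, 1]`.
#' @export
spread_ratio <- function(profile, threshold_fraction = 0.25) {
  stopifnot(is.numeric(profile), length(profile) >= 1)
  mx <- max(profile)
  if (mx <= 0) stop("flat zero profile: spread undefined")
  thr <- threshold_fraction * mx
  i0 <- which.max(profile)
  lo <- i0
  while (lo > 1 && profile[lo - 1] >= thr) lo <- lo - 1
  hi <- i0
  while (hi < length(profile) && profile[hi + 1] >= thr) hi <- hi + 1
  (hi - lo + 1) / length(profile)
}
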