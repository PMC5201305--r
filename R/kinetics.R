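# mRNA decay kinetics: background subtraction, bootstrap of per-time-
# point medians (5 rounds of 500 cells by default), single-exponential
# fitting N(t) = N0 * exp(-lambda * t) with t1/2 = ln(2)/lambda, cluster-
# stratified half-lives, and the quadratic growth-rate model
# log(t1/2) = a*mu^2 + b*mu + c (natural log, mu in 1/h).

#' Subtract an additive background from fluorescence values
#'
#' Values are floored at zero; the number of floored cells is recorded in
#' the `"floored"` attribute.  A warning is emitted when the background
#' exceeds every signal.
#'
#' @param x numeric fluorescence values.
#' @param background scalar background estimate (>= 0).
#' @return corrected values with attribute `floored`.
#' @export
background_subtract <- function(x, background) {
  stopifnot(is.numeric(background), length(background) == 1L, background >= 0)
  out <- x - background
  floored <- sum(out < 0)
  out[out < 0] <- 0
  if (all(out == 0) && length(out) > 0L) {
    warning("background exceeds all signals: corrected values are all zero")
  }
  attr(out, "floored") <- floored
  out
}

#' Bootstrap configuration
#'
#' @param n_rounds bootstrap rounds (default 5).
#' @param n_cells_per_round cells resampled (with replacement) per round
#'   and time point (default 500).
#' @param seed integer seed.
#' @return object of class `bootstrap_config`.
#' @export
bootstrap_config <- function(n_rounds = 5L, n_cells_per_round = 500L,
                             seed = 1L) {
  stopifnot(n_rounds >= 1, n_cells_per_round >= 1)
  structure(
    list(n_rounds = as.integer(n_rounds),
         n_cells_per_round = as.integer(n_cells_per_round),
         seed = as.integer(seed)),
    class = "bootstrap_config"
  )
}

# one bootstrap round: per-time-point medians of a resample
.bootstrap_rounds <- function(dataset, config) {
  times <- sort(unique(dataset$time_min))
  if (length(times) == 0L) stop("empty dataset")
  by_t <- split(dataset$fluorescence, dataset$time_min)
  by_t <- by_t[as.character(times)]
  short <- vapply(by_t, length, integer(1)) < config$n_cells_per_round
  if (any(vapply(by_t, length, integer(1)) == 0L)) {
    stop("time point without cells")
  }
  if (any(short)) {
    warning(sprintf(
      "%d time point(s) have fewer than %d cells; resampling with replacement from what exists",
      sum(short), config$n_cells_per_round
    ))
  }
  with_seed(config$seed, {
    med <- matrix(NA_real_, config$n_rounds, length(times))
    for (r in seq_len(config$n_rounds)) {
      for (ti in seq_along(times)) {
        v <- by_t[[ti]]
        med[r, ti] <- median(v[sample.int(length(v),
                                          config$n_cells_per_round,
                                          replace = TRUE)])
      }
    }
    list(times = times, medians = med)
  })
}

#' Bootstrap medians per time point
#'
#' For each time point, `n_rounds` resamples of `n_cells_per_round` cells
#' (with replacement) are drawn and the median of each resample computed;
#' the mean and sd of the round medians are reported.
#'
#' @param dataset data.frame with columns `time_min` and `fluorescence`.
#' @param config a [bootstrap_config()].
#' @return data.frame with `time_min`, `n_cells`, `median_mean`,
#'   `median_sd`.
#' @export
bootstrap_medians <- function(dataset, config = bootstrap_config()) {
  br <- .bootstrap_rounds(dataset, config)
  n_cells <- as.integer(table(dataset$time_min)[as.character(br$times)])
  data.frame(
    time_min = br$times,
    n_cells = n_cells,
    median_mean = colMeans(br$medians),
    median_sd = apply(br$medians, 2, sd)
  )
}

#' Fit a single-exponential decay
#'
#' Least-squares fit of `N(t) = N0 * exp(-lambda * t)` in linear space
#' (matching how chase curves are normally fitted); values are first
#' normalized to the t = 0 value when `normalize = TRUE`.  Non-decaying
#' data (`lambda <= 0`) are flagged and reported with infinite half-life.
#'
#' @param time_points_min time points (>= 3).
#' @param values fluorescence values (medians), same length.
#' @param normalize divide by the t = 0 value first?
#' @param log_linear use log-linear regression instead of nonlinear least
#'   squares (comparison option; requires positive values).
#' @return object of class `decay_fit`: `N0`, `lambda` (1/min), `t_half`
#'   (min, `= log(2)/lambda` exactly), `decaying`, `residual_rms`,
#'   `n_points`.
#' @export
fit_decay <- function(time_points_min, values, normalize = TRUE,
                      log_linear = FALSE) {
  stopifnot(length(time_points_min) == length(values),
            length(time_points_min) >= 3)
  t <- as.numeric(time_points_min)
  y <- as.numeric(values)
  if (normalize) {
    y0 <- y[which.min(t)]
    if (!is.finite(y0) || y0 <= 0) stop("t = 0 value must be positive to normalize")
    y <- y / y0
  }
  pos <- y > 0
  if (sum(pos) >= 2) {
    lin <- lm(log(y[pos]) ~ t[pos])
    lam0 <- -coef(lin)[[2]]
    n00 <- exp(coef(lin)[[1]])
  } else {
    lam0 <- 0.1; n00 <- max(y, 1)
  }
  if (log_linear) {
    lambda <- lam0; n0 <- n00
    res <- log(pmax(y, .Machine$double.xmin)) - (log(n0) - lambda * t)
  } else {
    df <- data.frame(t = t, y = y)
    # warnOnly fits that stall are still flagged via `decaying` below, so
    # convergence chatter from degenerate inputs is muffled here
    fit <- tryCatch(
      suppressWarnings(
        nls(y ~ N0 * exp(-lambda * t), data = df,
            start = list(N0 = max(n00, 1e-6), lambda = max(lam0, 1e-6)),
            control = list(maxiter = 500, warnOnly = TRUE))
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      lambda <- lam0; n0 <- n00
      res <- y - n0 * exp(-lambda * t)
    } else {
      p <- coef(fit)
      lambda <- p[["lambda"]]; n0 <- p[["N0"]]
      res <- residuals(fit)
    }
  }
  decaying <- is.finite(lambda) && lambda > 0
  structure(
    list(N0 = n0,
         lambda = lambda,
         t_half = if (decaying) log(2) / lambda else Inf,
         decaying = decaying,
         residual_rms = sqrt(mean(res^2)),
         n_points = length(t)),
    class = "decay_fit"
  )
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "exponential decay fit: N0 = %.3g, lambda = %.4g /min, t1/2 = %.3g min%s\n",
    x$N0, x$lambda, x$t_half, if (x$decaying) "" else " [non-decaying]"
  ))
  invisible(x)
}

#' Half-life estimate via bootstrap + exponential fit
#'
#' Runs the full pipeline: per-round bootstrap median time courses, each
#' normalized to its t = 0 median, averaged across rounds, and fitted with
#' [fit_decay()].  The per-round curves are also fitted individually to
#' obtain a bootstrap spread of the half-life.
#'
#' @param dataset data.frame with `time_min`, `fluorescence`.
#' @param config a [bootstrap_config()].
#' @return object of class `half_life_fit`: the main `decay_fit` fields
#'   plus `bootstrap_sd` (sd of per-round half-lives), `round_t_half`,
#'   and `n_cells` per time point.
#' @export
estimate_half_life <- function(dataset, config = bootstrap_config()) {
  br <- .bootstrap_rounds(dataset, config)
  t0_col <- which.min(br$times)
  norm <- br$medians / br$medians[, t0_col]
  avg <- colMeans(norm)
  main <- fit_decay(br$times, avg, normalize = FALSE)
  round_th <- apply(norm, 1, function(r) {
    f <- fit_decay(br$times, r, normalize = FALSE)
    f$t_half
  })
  finite <- round_th[is.finite(round_th)]
  out <- unclass(main)
  out$bootstrap_sd <- if (length(finite) > 1) sd(finite) else NA_real_
  out$round_t_half <- round_th
  out$n_cells <- as.integer(table(dataset$time_min)[as.character(br$times)])
  class(out) <- c("half_life_fit", "decay_fit")
  out
}

#' Cluster-stratified half-lives
#'
#' Applies the bootstrap + exponential-fit pipeline independently to
#' cells with and without polar clusters.  A stratum missing any time
#' point is skipped with a warning.
#'
#' @param dataset data.frame with `time_min`, `fluorescence`,
#'   `cluster_flag` (logical).
#' @param config a [bootstrap_config()]; per-stratum seeds are derived
#'   from `config$seed`.
#' @return list with elements `cluster` and `non_cluster`
#'   ([estimate_half_life()] results or `NULL` if skipped).
#' @export
stratified_half_lives <- function(dataset, config = bootstrap_config()) {
  stopifnot("cluster_flag" %in% names(dataset))
  times <- sort(unique(dataset$time_min))
  run_stratum <- function(sub, label) {
    have <- unique(sub$time_min)
    if (length(sub$time_min) == 0L || !all(times %in% have)) {
      warning(sprintf("stratum '%s' missing time point(s): skipped", label))
      return(NULL)
    }
    cfg <- config
    cfg$seed <- derive_seed(config$seed, label)
    estimate_half_life(sub, cfg)
  }
  list(
    cluster = run_stratum(dataset[dataset$cluster_flag, , drop = FALSE],
                          "cluster"),
    non_cluster = run_stratum(dataset[!dataset$cluster_flag, , drop = FALSE],
                              "non_cluster")
  )
}

#' Quadratic growth-rate model of the half-life
#'
#' `log(t_half) = a * mu^2 + b * mu + c` with natural log, `t_half` in
#' minutes and growth rate `mu` in 1/h.
#'
#' @param a,b,c coefficients.
#' @return object of class `growth_model`.
#' @export
growth_model <- function(a, b, c) {
  structure(list(a = a, b = b, c = c), class = "growth_model")
}

#' Evaluate a growth-rate model
#'
#' @param model a [growth_model()].
#' @param mu growth rate(s) in 1/h (>= 0).
#' @return predicted half-life in minutes, `exp(a*mu^2 + b*mu + c)`.
#' @export
evaluate_growth_model <- function(model, mu) {
  stopifnot(inherits(model, "growth_model"), all(mu >= 0))
  exp(model$a * mu^2 + model$b * mu + model$c)
}

#' Fit the quadratic growth-rate model
#'
#' Least squares of `log(t_half)` on `mu` and `mu^2`; with exactly three
#' distinct growth rates this interpolates the points.
#'
#' @param mu growth rates (1/h), at least 3 distinct values.
#' @param t_half median half-lives (min), same length, > 0.
#' @return a [growth_model()].
#' @export
fit_growth_model <- function(mu, t_half) {
  stopifnot(length(mu) == length(t_half), all(t_half > 0))
  if (length(unique(mu)) < 3) stop("need at least 3 distinct growth rates")
  fit <- lm(log(t_half) ~ mu + I(mu^2))
  cf <- coef(fit)
  growth_model(a = cf[["I(mu^2)"]], b = cf[["mu"]], c = cf[["(Intercept)"]])
}
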