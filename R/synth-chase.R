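# Synthetic rifampicin-chase datasets: per-cell fluorescence drawn from
# N0 * exp(-lambda * t) * (1 + eps) + background, with fresh cells at
# every time point (the chase protocol fixes different cells per time
# point, so no pairing exists across times).

#' One chase subpopulation
#'
#' @param label subpopulation label.
#' @param weight mixing weight (weights across subpopulations must sum
#'   to 1).
#' @param half_life_min mRNA half-life in minutes (> 0).
#' @param n0_meanlog,n0_sdlog log-normal parameters of the initial
#'   per-cell fluorescence N0.
#' @param cluster does this subpopulation carry a polar mRNA cluster?
#' @return a named list.
#' @export
subpopulation <- function(label, weight, half_life_min,
                          n0_meanlog = log(100), n0_sdlog = 0.5,
                          cluster = FALSE) {
  if (!is.numeric(half_life_min) || half_life_min <= 0) {
    stop("half_life_min must be > 0")
  }
  list(label = label, weight = weight, half_life_min = half_life_min,
       n0_meanlog = n0_meanlog, n0_sdlog = n0_sdlog, cluster = cluster)
}

#' Specification of a synthetic rifampicin chase
#'
#' Default time points follow the standard chase design (0, 1, 2, 4, 8,
#' 16, 32, 64 min after transcription arrest).
#'
#' @param time_points_min sampling times, strictly increasing from 0.
#' @param n_cells_per_timepoint cells measured at each time point.
#' @param subpopulations list of [subpopulation()] entries; weights must
#'   sum to 1.
#' @param cell_noise_cv multiplicative cell-to-cell noise (sd of the
#'   relative error).
#' @param background_level additive background (AU).
#' @param seed integer seed.
#' @return object of class `chase_spec`.
#' @export
chase_spec <- function(time_points_min = c(0, 1, 2, 4, 8, 16, 32, 64),
                       n_cells_per_timepoint = 500L,
                       subpopulations = list(
                         subpopulation("all", 1, half_life_min = 10)
                       ),
                       cell_noise_cv = 0.3,
                       background_level = 0,
                       seed = 1L) {
  stopifnot(
    length(time_points_min) >= 2, time_points_min[1] == 0,
    all(diff(time_points_min) > 0),
    n_cells_per_timepoint >= 1, cell_noise_cv >= 0, background_level >= 0
  )
  w <- vapply(subpopulations, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-8) stop("subpopulation weights must sum to 1")
  hl <- vapply(subpopulations, `[[`, numeric(1), "half_life_min")
  if (any(hl <= 0)) stop("half_life_min must be > 0")
  structure(
    list(time_points_min = time_points_min,
         n_cells_per_timepoint = as.integer(n_cells_per_timepoint),
         subpopulations = subpopulations, cell_noise_cv = cell_noise_cv,
         background_level = background_level, seed = as.integer(seed)),
    class = "chase_spec"
  )
}

#' Generate a synthetic chase dataset
#'
#' Each cell carries its subpopulation label and cluster flag.  The
#' fluorescence value is `N0 * exp(-lambda*t) * (1 + eps) + background`
#' with `eps ~ Normal(0, cell_noise_cv)` and `N0` log-normal per
#' subpopulation.  Cells are independent across time points.
#'
#' @param spec a [chase_spec()].
#' @return data.frame with columns `cell_id`, `time_min`, `fluorescence`,
#'   `subpopulation`, `cluster_flag`.
#' @export
generate_chase <- function(spec) {
  stopifnot(inherits(spec, "chase_spec"))
  with_seed(spec$seed, {
    subs <- spec$subpopulations
    w <- vapply(subs, `[[`, numeric(1), "weight")
    lam <- log(2) / vapply(subs, `[[`, numeric(1), "half_life_min")
    labels <- vapply(subs, `[[`, character(1), "label")
    out <- vector("list", length(spec$time_points_min))
    next_id <- 1L
    for (ti in seq_along(spec$time_points_min)) {
      t <- spec$time_points_min[ti]
      nc <- spec$n_cells_per_timepoint
      k <- sample.int(length(subs), nc, replace = TRUE, prob = w)
      n0 <- rlnorm(nc,
                   meanlog = vapply(subs, `[[`, numeric(1), "n0_meanlog")[k],
                   sdlog = vapply(subs, `[[`, numeric(1), "n0_sdlog")[k])
      eps <- if (spec$cell_noise_cv > 0) {
        rnorm(nc, 0, spec$cell_noise_cv)
      } else {
        numeric(nc)
      }
      fl <- n0 * exp(-lam[k] * t) * (1 + eps) + spec$background_level
      out[[ti]] <- data.frame(
        cell_id = seq.int(next_id, length.out = nc),
        time_min = t,
        fluorescence = fl,
        subpopulation = labels[k],
        cluster_flag = vapply(subs, `[[`, logical(1), "cluster")[k],
        stringsAsFactors = FALSE
      )
      next_id <- next_id + nc
    }
    do.call(rbind, out)
  })
}
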