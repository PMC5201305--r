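# End-to-end orchestration: synthesize -> detect -> project -> classify ->
# fit, with a single global seed from which every stage derives its own
# stream, and a manifest (file list + md5 checksums) for reproducibility
# audits.

#' Pipeline run configuration
#'
#' All stage parameters have working defaults so that
#' `run_pipeline(pipeline_config(), tempdir())` performs a complete
#' synthetic run.  Stages can be toggled off; downstream stages that
#' depend on a disabled stage raise a dependency error naming it.
#'
#' @param seed global integer seed; per-stage seeds are derived from it.
#' @param stages named logical vector toggling `scene`, `spots`,
#'   `project`, `classify`, `chase`, `kinetics`, `seqbias`.
#' @param scene arguments for [scene_spec()] (seed is filled in).
#' @param detection arguments for [detection_config()].
#' @param model arguments for [model_cell()].
#' @param cluster arguments for [cluster_config()].
#' @param chase arguments for [chase_spec()] (seed is filled in).
#' @param bootstrap arguments for [bootstrap_config()] (seed filled in).
#' @param seqbias list with `n_per_class`, `n_codons`,
#'   `membrane_density`, `cytoplasmic_density` for the synthetic
#'   sequence stage.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            stages = c(scene = TRUE, spots = TRUE,
                                       project = TRUE, classify = TRUE,
                                       chase = TRUE, kinetics = TRUE,
                                       seqbias = TRUE),
                            scene = list(n_cells = 40,
                                         pattern = "polar_cluster"),
                            detection = list(),
                            model = list(),
                            cluster = list(),
                            chase = list(
                              n_cells_per_timepoint = 200L,
                              subpopulations = list(
                                subpopulation("non_cluster", 0.5, 4.6),
                                subpopulation("cluster", 0.5, 16.1,
                                              cluster = TRUE)
                              )
                            ),
                            bootstrap = list(n_cells_per_round = 200L),
                            seqbias = list(n_per_class = 40L,
                                           n_codons = 200L,
                                           membrane_density = 0.36,
                                           cytoplasmic_density = 0.29)) {
  defaults <- c(scene = TRUE, spots = TRUE, project = TRUE, classify = TRUE,
                chase = TRUE, kinetics = TRUE, seqbias = TRUE)
  defaults[names(stages)] <- stages
  structure(
    list(seed = as.integer(seed), stages = defaults, scene = scene,
         detection = detection, model = model, cluster = cluster,
         chase = chase, bootstrap = bootstrap, seqbias = seqbias),
    class = "pipeline_config"
  )
}

.require_stage <- function(state, what, needed_by) {
  if (is.null(state[[what]])) {
    stop(sprintf("stage '%s' requires output of disabled/failed stage '%s'",
                 needed_by, what))
  }
  state[[what]]
}

#' Run the full pipeline
#'
#' Executes the enabled stages in dependency order, writes every artifact
#' under `out_dir`, and returns (and writes) a manifest listing each file
#' with its md5 checksum together with the global seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly: list with `seed`, `stages`, `files`
#'   (data.frame of path + md5).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  state <- list()
  add <- function(path) paths <<- c(paths, path)

  if (config$stages[["scene"]]) {
    args <- config$scene
    args$seed <- derive_seed(config$seed, "scene")
    scene <- do.call(scene_spec, args)
    state$scene <- generate_scene(scene)
    wp <- write_scene(state$scene, out_dir)
    for (p in wp) add(p)
  }

  if (config$stages[["spots"]]) {
    scene <- .require_stage(state, "scene", "spots")
    dc <- do.call(detection_config, config$detection)
    fits <- fit_spots(scene$image, dc)
    assigned <- assign_spots_to_cells(fits, scene$truth$cells)
    state$spots <- assigned
    p <- file.path(out_dir, "spots.csv")
    write.csv(assigned, p, row.names = FALSE)
    add(p)
  }

  if (config$stages[["project"]]) {
    scene <- .require_stage(state, "scene", "project")
    spots <- .require_stage(state, "spots", "project")
    model <- do.call(model_cell, config$model)
    nspots <- normalize_spots(spots, scene$truth$cells, model)
    state$model <- model
    state$nspots <- nspots
    map <- build_location_map(nspots, model)
    prof <- axial_profile(map)
    zf <- zone_fractions(nspots, model)
    p1 <- file.path(out_dir, "normalized_spots.csv")
    p2 <- file.path(out_dir, "location_map.csv")
    p3 <- file.path(out_dir, "axial_profile.csv")
    p4 <- file.path(out_dir, "zone_fractions.csv")
    write.csv(nspots, p1, row.names = FALSE)
    write.csv(map$counts, p2, row.names = FALSE)
    write.csv(prof, p3, row.names = FALSE)
    write.csv(data.frame(zone = names(zf), fraction = as.numeric(zf)),
              p4, row.names = FALSE)
    for (p in c(p1, p2, p3, p4)) add(p)
  }

  if (config$stages[["classify"]]) {
    scene <- .require_stage(state, "scene", "classify")
    nspots <- .require_stage(state, "nspots", "classify")
    cc <- do.call(cluster_config, config$cluster)
    model <- state$model %||% do.call(model_cell, config$model)
    totals <- data.frame(cell_id = scene$truth$cells$cell_id,
                         total_I = scene$truth$cells$total_I)
    cls <- classify_cells(nspots, totals, cc, model)
    state$classification <- cls
    p <- file.path(out_dir, "classification.csv")
    write.csv(cls, p, row.names = FALSE)
    add(p)
    lev <- data.frame(level = cls$total_I, has_cluster = cls$has_cluster)
    frac <- cluster_fraction_by_level(lev, n_bins = 4)
    p2 <- file.path(out_dir, "cluster_fraction_by_level.csv")
    write.csv(frac, p2, row.names = FALSE)
    add(p2)
  }

  if (config$stages[["chase"]]) {
    args <- config$chase
    args$seed <- derive_seed(config$seed, "chase")
    state$chase <- generate_chase(do.call(chase_spec, args))
    p <- file.path(out_dir, "chase.csv")
    write.csv(state$chase, p, row.names = FALSE)
    add(p)
  }

  if (config$stages[["kinetics"]]) {
    chase <- .require_stage(state, "chase", "kinetics")
    bargs <- config$bootstrap
    bargs$seed <- derive_seed(config$seed, "kinetics")
    bc <- do.call(bootstrap_config, bargs)
    pooled <- estimate_half_life(chase, bc)
    strat <- if (length(unique(chase$cluster_flag)) == 2) {
      stratified_half_lives(chase, bc)
    } else {
      NULL
    }
    fits <- list(
      pooled = list(N0 = pooled$N0, lambda = pooled$lambda,
                    t_half = pooled$t_half,
                    bootstrap_sd = pooled$bootstrap_sd)
    )
    if (!is.null(strat)) {
      for (nm in names(strat)) {
        if (!is.null(strat[[nm]])) {
          fits[[nm]] <- list(N0 = strat[[nm]]$N0,
                             lambda = strat[[nm]]$lambda,
                             t_half = strat[[nm]]$t_half,
                             bootstrap_sd = strat[[nm]]$bootstrap_sd)
        }
      }
    }
    state$kinetics <- fits
    p <- file.path(out_dir, "decay_fits.json")
    jsonlite::write_json(fits, p, auto_unbox = TRUE, digits = NA)
    add(p)
  }

  if (config$stages[["seqbias"]]) {
    sb <- config$seqbias
    seed <- derive_seed(config$seed, "seqbias")
    mem <- synth_coding_sequences(sb$n_per_class, sb$n_codons,
                                  sb$membrane_density, seed)
    cyt <- synth_coding_sequences(sb$n_per_class, sb$n_codons,
                                  sb$cytoplasmic_density, seed + 1L)
    recs <- data.frame(
      gene_id = c(sprintf("mem_%03d", seq_along(mem)),
                  sprintf("cyt_%03d", seq_along(cyt))),
      sequence = c(mem, cyt),
      class = rep(c("membrane", "cytoplasmic"), each = sb$n_per_class),
      stringsAsFactors = FALSE
    )
    dens <- data.frame(gene_id = recs$gene_id,
                       density = unname(uracil_density(recs$sequence)),
                       class = recs$class)
    cmp <- compare_classes(dens)
    bias <- codon_bias(recs$sequence)
    p1 <- file.path(out_dir, "uracil_density.csv")
    p2 <- file.path(out_dir, "codon_bias.csv")
    p3 <- file.path(out_dir, "class_comparison.json")
    write.csv(dens, p1, row.names = FALSE)
    write.csv(as.data.frame(bias), p2, row.names = FALSE)
    jsonlite::write_json(
      list(statistic = cmp$statistic, df = cmp$df, p_value = cmp$p_value,
           method = cmp$method, summary = cmp$summary),
      p3, auto_unbox = TRUE, digits = NA
    )
    for (p in c(p1, p2, p3)) add(p)
  }

  manifest <- list(
    seed = config$seed,
    stages = as.list(config$stages),
    files = data.frame(
      path = basename(paths),
      md5 = unname(tools::md5sum(paths)),
      stringsAsFactors = FALSE
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
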