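#' Pipeline configuration
#'
#' Bundles every stage's parameters for [run_pipeline()]: the synthetic
#' retina (or externally supplied data), the stimulus protocol, the quality
#' and significance thresholds, clustering and map parameters, and the
#' model search grid. Defaults are the standard analysis settings:
#' QI > 0.6, 1000 permutations at the 95% rank threshold, k = 2..10,
#' 10-degree histogram bins, 100-um flow-field grid.
#'
#' @param retina a [retina_config()].
#' @param proto a [stimulus_protocol()]; defaults to the one implied by
#'   `retina`.
#' @param qi_threshold quality-index threshold (strict).
#' @param n_perms permutations per cell and statistic.
#' @param rank_threshold permutation rank threshold.
#' @param k_range,restarts clustering parameters.
#' @param feature_len ON-OFF feature length.
#' @param bin_deg orientation histogram bin width.
#' @param grid_um,min_n flow-field grid spacing and minimum bin count.
#' @param model list of [fit_anchor_and_aspect()] grid arguments
#'   (`anchor_x`, `anchor_y`, `aspects`, `radii`).
#' @param stages character vector of stages to run, in order, from
#'   `c("simulate", "tune", "classify", "cluster", "map", "fit_model")`.
#' @param seed global seed (stage substreams are derived from it).
#' @param output_dir if non-NULL, stage tables are written there as CSV
#'   and a JSON manifest is recorded.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(retina = retina_config(),
                            proto = protocol_from_config(retina),
                            qi_threshold = 0.6,
                            n_perms = 1000L,
                            rank_threshold = 0.95,
                            k_range = 2:10,
                            restarts = 10L,
                            feature_len = 40L,
                            bin_deg = 10,
                            grid_um = 100,
                            min_n = 5L,
                            model = list(),
                            stages = c("simulate", "tune", "classify",
                                       "cluster", "map", "fit_model"),
                            seed = 1L,
                            output_dir = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  out <- as.list(environment())
  class(out) <- "pipeline_config"
  out
}

stage_require <- function(bundle, what, needed_by) {
  if (is.null(bundle[[what]]))
    stop("stage '", needed_by, "' requires output of stage '",
         switch(what,
                retina = "simulate", responses = "simulate",
                summaries = "tune", classified = "classify",
                os_cells = "classify"),
         "' which was not run")
  bundle[[what]]
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> tune -> classify -> cluster -> map -> fit_model in
#' order (any suffix of stages can be disabled via the config). Each stage
#' consumes the previous stage's declared outputs; a disabled upstream
#' stage makes the dependent stage fail fast with the missing stage's name.
#' With `output_dir` set, every stage table is written as CSV and a
#' manifest (package version, seed, parameters, per-stage row counts and
#' files) as JSON; reruns with the same seed are byte-identical.
#'
#' @param config a [pipeline_config()].
#' @return result bundle: a list with (depending on enabled stages)
#'   `retina`, `responses`, `summaries`, `classified`, `os_cells`,
#'   `onoff_clusters`, `histograms`, `deviation`, `flow`,
#'   `region_comparison`, `model_fit` and `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  bundle <- list()
  manifest <- list(package = "osmapr",
                   version = as.character(utils::packageVersion("osmapr")),
                   seed = config$seed,
                   stages = config$stages,
                   counts = list(), files = list())
  outdir <- config$output_dir
  if (!is.null(outdir) && !dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  emit <- function(name, df, writer = write_cell_table) {
    manifest$counts[[name]] <<- nrow(df)
    if (!is.null(outdir)) {
      f <- file.path(outdir, paste0(name, ".csv"))
      writer(df, f)
      manifest$files[[name]] <<- basename(f)
    }
  }

  if ("simulate" %in% config$stages) {
    bundle$retina <- generate_retina(config$retina)
    bundle$responses <- synthesize_responses(bundle$retina$cells,
                                             config$retina, config$proto)
    emit("cells", bundle$retina$cells)
    emit("fovs", bundle$retina$fovs, write_fov_table)
  }

  if ("tune" %in% config$stages) {
    responses <- stage_require(bundle, "responses", "tune")
    bundle$summaries <- summarize_tuning(responses, config$proto)
    emit("tuning", bundle$summaries)
  }

  if ("classify" %in% config$stages) {
    summaries <- stage_require(bundle, "summaries", "classify")
    kept <- quality_filter(summaries, config$qi_threshold)
    classified <- test_selectivity(bundle$responses, kept, config$proto,
                                   n_perms = config$n_perms,
                                   rank_threshold = config$rank_threshold,
                                   seed = config$seed)
    bundle$classified <- classified
    truth <- bundle$retina$cells[match(classified$cell_id,
                                       bundle$retina$cells$cell_id), ]
    bundle$os_cells <- cbind(
      classified[classified$selectivity_class %in% c("OS", "both"), ],
      truth[classified$selectivity_class %in% c("OS", "both"),
            c("fov_id", "x_um", "y_um", "subtype", "orientation_group")])
    emit("classified", classified)
    bundle$class_summary <- as.list(table(classified$selectivity_class))
    manifest$counts$qi_dropped <- attr(kept, "n_dropped")
  }

  if ("cluster" %in% config$stages) {
    os <- stage_require(bundle, "os_cells", "cluster")
    feats <- t(vapply(os$cell_id, function(id)
      extract_onoff_features(bundle$responses[[id]], config$proto,
                             config$feature_len),
      numeric(config$feature_len)))
    sol <- cluster_and_select_k(feats, config$k_range, config$restarts,
                                seed = config$seed + 1L)
    subs <- label_subtypes(sol, config$proto, config$feature_len)
    ## orientation grouping per FOV, where the map is locally constant
    os$subtype_called <- subs$subtype
    os$orientation_group_called <- assign_orientation_groups(
      os$pref_orientation_deg, os$fov_id, k_range = 2:4,
      restarts = config$restarts, seed = config$seed + 2L)
    bundle$os_cells <- os
    bundle$onoff_clusters <- sol
    sil <- data.frame(k = sol$k_range, mean_sv = sol$mean_sv,
                      permuted_mean_sv = sol$permuted_mean_sv)
    emit("silhouette_onoff", sil, function(df, f)
      utils::write.csv(df, f, row.names = FALSE))
    emit("os_cells", os)
  }

  if ("map" %in% config$stages) {
    os <- stage_require(bundle, "os_cells", "map")
    fovs <- bundle$retina$fovs
    grp <- if ("orientation_group_called" %in% names(os))
      os$orientation_group_called else os$orientation_group
    over <- os[grp == "overrepresented", , drop = FALSE]
    bundle$histograms <- lapply(split(os, fovs$quadrant[match(os$fov_id, fovs$fov_id)]),
                                function(d) orientation_histogram(
                                  d$pref_orientation_deg, config$bin_deg))
    bundle$deviation <- deviation_vs_distance(over, fovs)
    bundle$flow <- flow_field(os, config$grid_um, config$min_n)
    ## more- vs less-ventral FOV comparison: split at the median FOV y
    ventral_split <- fovs$center_y_um[match(over$fov_id, fovs$fov_id)] <
      stats::median(fovs$center_y_um)
    if (length(unique(ventral_split)) == 2L)
      bundle$region_comparison <- compare_regions(
        deviation_from_ventral(norm_axis_deg(over$pref_orientation_deg)),
        ventral_split, "more vs less ventral FOVs (median center y)",
        n_perm = 1000L, seed = config$seed + 3L)
    emit("deviation_fov", bundle$deviation$fov_curve, function(df, f)
      utils::write.csv(df, f, row.names = FALSE))
    emit("flow_field", bundle$flow, function(df, f)
      utils::write.csv(df, f, row.names = FALSE))
  }

  if ("fit_model" %in% config$stages) {
    dev <- if (!is.null(bundle$deviation)) bundle$deviation else {
      os <- stage_require(bundle, "os_cells", "fit_model")
      grp <- if ("orientation_group_called" %in% names(os))
        os$orientation_group_called else os$orientation_group
      deviation_vs_distance(os[grp == "overrepresented", ], bundle$retina$fovs)
    }
    fc <- dev$fov_curve
    curves <- lapply(split(fc, fc$quadrant), function(d)
      d[, c("distance_um", "deviation_deg", "center_x_um", "center_y_um")])
    curves <- curves[names(curves) %in% names(sector_center_deg)]
    ## a quadratic fit needs at least 3 FOVs on an axis
    curves <- curves[vapply(curves, function(d)
      length(unique(d$distance_um)) >= 3L, logical(1))]
    if (length(curves) == 0)
      stop("stage 'fit_model' requires >= 3 FOVs with OS cells on some axis")
    args <- c(list(curves = curves), config$model)
    bundle$model_fit <- do.call(fit_anchor_and_aspect, args)
    manifest$model <- list(anchor = bundle$model_fit$anchor,
                           aspect = bundle$model_fit$aspect,
                           score = bundle$model_fit$score)
  }

  bundle$manifest <- manifest
  if (!is.null(outdir))
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  bundle
}
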