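PIPELINE_STAGES <- c("simulate", "segment", "heights", "vi", "dynamics", "gwas")

#' Default pipeline configuration
#'
#' A self-contained configuration for [run_pipeline()]: a scaled trial
#' (20 varieties x 3 nitrogen treatments x 2 replicates) with the
#' default growth, optics and genotype settings and moderate point
#' densities, so a full run finishes on a laptop CPU in a couple of
#' minutes. Any entry can be overridden, or the whole list written to /
#' read from YAML.
#'
#' @param outdir output directory for stage artifacts.
#' @param seed global seed; per-stage seeds are derived from it by a
#'   fixed splitting rule so stages are independently reproducible.
#' @return Nested configuration list.
#' @export
default_field_config <- function(outdir = tempfile("phenofield_run_"), seed = 1L) {
  list(
    outdir = outdir,
    seed = as.integer(seed),
    stages = PIPELINE_STAGES,
    design = list(n_varieties = 20, n_replicates = 2),
    cloud = list(canopy_points_per_plot = 150, ground_density = 40),
    cloud_days = NULL,            # NULL = all design timepoints
    optics = list(res = 0.05, noise_sd = 0.01),
    segment = list(method = "geometric", height_threshold_m = 0.10),
    vi_indices = c("CCCI", "MSAVI", "RVI_1", "RVI_2"),
    dynamics = list(theta = 0.5, grouping = "plot"),
    genotypes = list(n_snps = 300, missing_rate = 0.02,
                     qtl = list(parameter = "a", effect = 4)),
    gwas = list(trait = "v_max", signal = "height", treatment = NULL,
                n_pc = 3, threshold = 3.5)
  )
}

stage_seed <- function(seed, stage) {
  (as.integer(seed) * 97L + match(stage, PIPELINE_STAGES) * 1009L) %%
    .Machine$integer.max
}

read_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  base <- default_field_config()
  modify <- function(b, o) {
    for (nm in names(o)) {
      b[[nm]] <- if (is.list(b[[nm]]) && is.list(o[[nm]]))
        modify(b[[nm]], o[[nm]]) else o[[nm]]
    }
    b
  }
  modify(base, config)
}

#' Run the full phenotyping pipeline
#'
#' Orchestrates simulate -> segment -> heights -> vi -> dynamics -> gwas
#' from one configuration, leaving every intermediate artifact on disk
#' and recording a manifest (config snapshot, per-stage inputs/outputs
#' with MD5 checksums, seeds, timestamps, package version). Any
#' contiguous subset of stages can be run; later stages read the
#' artifacts earlier runs left in `outdir`. Reruns with the same config
#' and seed reproduce identical CSV outputs.
#'
#' @param config a configuration list (see [default_field_config()]) or
#'   the path of a YAML file with overrides.
#' @param stages stages to execute (default: those in the config).
#' @return The manifest, invisibly; also written to
#'   `<outdir>/manifest.json`.
#' @export
run_pipeline <- function(config = default_field_config(), stages = NULL) {
  cfg <- read_config(config)
  if (is.null(stages)) stages <- cfg$stages
  bad <- setdiff(stages, PIPELINE_STAGES)
  if (length(bad))
    stop("unknown stage name(s): ", paste(bad, collapse = ", "), call. = FALSE)
  stages <- PIPELINE_STAGES[PIPELINE_STAGES %in% stages]
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)

  design <- do.call(trial_design, cfg$design)
  layout <- generate_layout(design)
  days <- if (is.null(cfg$cloud_days)) design$timepoints else cfg$cloud_days
  pth <- function(...) file.path(cfg$outdir, sprintf(...))
  manifest <- list(config = cfg, package_version = as.character(
    utils::packageVersion("phenofield")), stages = list())

  run_stage <- function(name, fun) {
    t0 <- Sys.time()
    outputs <- tryCatch(fun(), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    manifest$stages[[name]] <<- list(
      seed = stage_seed(cfg$seed, name),
      started = format(t0, "%Y-%m-%d %H:%M:%S"),
      outputs = outputs,
      checksums = as.list(tools::md5sum(outputs)))
    message(sprintf("[%s] done (%.1fs, %d artifact(s))", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs")),
                    length(outputs)))
  }

  if ("simulate" %in% stages) run_stage("simulate", function() {
    sd <- stage_seed(cfg$seed, "simulate")
    utils::write.csv(layout$plots, pth("layout.csv"), row.names = FALSE)
    gen <- do.call(generate_genotypes, c(
      list(n_varieties = design$n_varieties, seed = sd),
      cfg$genotypes[setdiff(names(cfg$genotypes), "qtl")],
      if (!is.null(cfg$genotypes$qtl))
        list(qtl_spec = as.data.frame(cfg$genotypes$qtl))))
    write_genotypes(gen$genotypes, pth("genotypes.csv"))
    utils::write.csv(gen$qtl_map, pth("qtl_map.csv"), row.names = FALSE)
    ve <- qtl_variety_effects(gen$genotypes, gen$qtl_map)
    truth <- simulate_trajectories(layout, growth_config(), seed = sd,
                                   variety_effects = ve)
    utils::write.csv(truth, pth("truth.csv"), row.names = FALSE)
    ccfg <- do.call(cloud_config, cfg$cloud)
    ocfg <- do.call(optics_config, cfg$optics)
    outs <- c(pth("layout.csv"), pth("genotypes.csv"),
              pth("genotypes.csv.map.csv"), pth("qtl_map.csv"),
              pth("truth.csv"))
    for (d in days) {
      td <- truth[truth$day == d, ]
      cl <- generate_field_cloud(layout, td, ccfg, seed = sd + round(d))
      write_point_cloud(cl, pth("cloud_day%03d.ply", round(d)))
      ra <- generate_multispectral_raster(layout, td, ocfg, seed = sd + round(d))
      write_ms_raster(ra, pth("raster_day%03d.tif", round(d)))
      outs <- c(outs, pth("cloud_day%03d.ply", round(d)),
                pth("raster_day%03d.tif", round(d)))
    }
    outs
  })

  if ("segment" %in% stages) run_stage("segment", function() {
    outs <- character(0)
    model <- NULL
    if (identical(cfg$segment$method, "net")) {
      tr <- read_point_cloud(pth("cloud_day%03d.ply", round(days[1])))
      model <- train_segmenter(tr, seed = stage_seed(cfg$seed, "segment"))
    }
    for (d in days) {
      cl <- read_point_cloud(pth("cloud_day%03d.ply", round(d)))
      labels <- if (is.null(model)) {
        segment_geometric(cl, estimate_ground(cl),
                          cfg$segment$height_threshold_m)
      } else predict_labels(model, cl)
      cl$labels <- labels
      out <- pth("cloud_day%03d_segmented.ply", round(d))
      write_point_cloud(cl, out)
      outs <- c(outs, out)
    }
    outs
  })

  if ("heights" %in% stages) run_stage("heights", function() {
    tabs <- lapply(days, function(d) {
      cl <- read_point_cloud(pth("cloud_day%03d_segmented.ply", round(d)))
      suppressWarnings(plot_heights(cl, layout, day = d))
    })
    out <- pth("heights.csv")
    utils::write.csv(do.call(rbind, tabs), out, row.names = FALSE)
    out
  })

  if ("vi" %in% stages) run_stage("vi", function() {
    tabs <- list()
    for (d in days) {
      ra <- read_ms_raster(pth("raster_day%03d.tif", round(d)))
      masks <- build_plot_masks(layout, ra)
      for (ix in cfg$vi_indices) {
        vir <- compute_vi(ra, ix)
        tabs[[length(tabs) + 1L]] <- plot_mean_vi(vir, masks, day = d)
      }
    }
    out <- pth("vi_means.csv")
    utils::write.csv(do.call(rbind, tabs), out, row.names = FALSE)
    out
  })

  if ("dynamics" %in% stages) run_stage("dynamics", function() {
    hv <- utils::read.csv(pth("heights.csv"), stringsAsFactors = FALSE)
    plots <- layout$plots
    i <- match(hv$plot_id, plots$plot_id)
    hser <- data.frame(plot_id = hv$plot_id, variety_id = plots$variety_id[i],
                       treatment = plots$treatment[i], day = hv$day,
                       value = hv$height_cm, signal = "height")
    vi <- utils::read.csv(pth("vi_means.csv"), stringsAsFactors = FALSE)
    i <- match(vi$plot_id, plots$plot_id)
    vser <- data.frame(plot_id = vi$plot_id, variety_id = plots$variety_id[i],
                       treatment = plots$treatment[i], day = vi$day,
                       value = vi$mean_value, signal = vi$index)
    series <- rbind(hser, vser)
    tt <- trait_table(series, grouping = cfg$dynamics$grouping,
                      theta = cfg$dynamics$theta)
    out <- pth("dynamic_traits.csv")
    utils::write.csv(tt, out, row.names = FALSE)
    # per-variety traits for the association stage
    tv <- trait_table(series, grouping = "variety_treatment",
                      theta = cfg$dynamics$theta)
    outv <- pth("dynamic_traits_by_variety.csv")
    utils::write.csv(tv, outv, row.names = FALSE)
    c(out, outv)
  })

  if ("gwas" %in% stages) run_stage("gwas", function() {
    tv <- utils::read.csv(pth("dynamic_traits_by_variety.csv"),
                          stringsAsFactors = FALSE)
    trt <- cfg$gwas$treatment
    if (is.null(trt)) trt <- utils::tail(names(design$treatments), 1)
    sel <- tv$signal == cfg$gwas$signal & tv$treatment == trt &
      tv$fit_flag == "ok"
    pheno <- stats::setNames(tv[[cfg$gwas$trait]][sel], tv$variety_id[sel])
    G <- read_genotypes(pth("genotypes.csv"))
    G <- qc_filter(G)
    pcs <- pca_covariates(G, n_pc = cfg$gwas$n_pc)
    res <- assoc_scan(G, pheno, pcs)
    out <- pth("gwas_results.csv")
    utils::write.csv(as.data.frame(res), out, row.names = FALSE)
    hits <- flag_significant(res, cfg$gwas$threshold)
    outh <- pth("gwas_hits.csv")
    utils::write.csv(as.data.frame(hits), outh, row.names = FALSE)
    plots <- export_gwas_plots(res, cfg$outdir, cfg$gwas$threshold)
    c(out, outh, plots)
  })

  manifest_path <- file.path(cfg$outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
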