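#' Read and validate a pipeline configuration file
#'
#' Configuration is a plain-text YAML key-value file. Unknown keys are
#' rejected so typos cannot silently fall back to defaults.
#'
#' @param path Path to a YAML file, or a named list of the same keys.
#' @return A validated config list of class `run_config` with defaults
#'   filled in.
#' @export
read_run_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  defaults <- list(
    mode = "simulate",          # "simulate" or "files"
    out_dir = "infoconn-out",
    n_subjects = 10L,
    volume_shape = NULL,        # simulate mode: override generator geometry
    mask_radius_vox = NULL,
    subjects = NULL,            # files mode: list of bold/mask/labels/nuisance
    tr_s = NULL,
    conditions = NULL,
    seed_center = NULL,         # (i, j, k); simulate mode defaults to the
    seed_radius = 3,            # generator's 'seed' region center
    seed_mask = NULL,           # or an explicit NIfTI seed mask
    radius_vox = 3,
    shift_trs = 2L,
    detrend_order = 2L,
    methods = c("ic", "fc"),
    fc_granularity = "voxel",
    fwhm_mm = 8,
    threshold_p = 0.001,
    alpha = 0.05,
    n_subject_perms = 100L,
    n_group_maps = 1000L,
    connectivity = 6L,
    within_run = FALSE,
    rng_seed = 1L
  )
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown)) {
    stop("Unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out <- utils::modifyList(defaults, cfg)
  out$methods <- tolower(out$methods)
  if (!all(out$methods %in% c("ic", "fc"))) {
    stop("`methods` must be a subset of ic, fc.", call. = FALSE)
  }
  if (out$mode == "files" && is.null(out$subjects)) {
    stop("files mode needs a `subjects` list.", call. = FALSE)
  }
  structure(out, class = c("run_config", "list"))
}

#' Run the full informational-connectivity pipeline
#'
#' Preprocess every subject (polynomial detrend, nuisance residualization,
#' per-run z-scoring, label shift), compute the seed's IC and/or FC maps,
#' and run cluster-corrected group inference. All maps, cluster tables, the
#' null distribution and a provenance record of every parameter are written
#' under `config$out_dir`.
#'
#' @param config A [read_run_config()] result (or a path / named list passed
#'   through it).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with per-method `group_result`s, the per-subject
#'   maps, and the written paths.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (!inherits(config, "run_config")) config <- read_run_config(config)
  say <- function(...) if (!quiet) message(...)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  if (config$mode == "simulate") {
    geo <- list(n_subjects = config$n_subjects, rng_seed = config$rng_seed)
    if (!is.null(config$volume_shape)) {
      geo$volume_shape <- as.integer(config$volume_shape)
    }
    if (!is.null(config$mask_radius_vox)) {
      geo$mask_radius_vox <- config$mask_radius_vox
    }
    spec <- do.call(default_paper_design, geo)
    subjects <- lapply(seq_len(config$n_subjects), function(s) {
      say("simulating subject ", s)
      generate_subject(spec, s)
    })
    if (is.null(config$conditions)) config$conditions <- spec$conditions
    if (is.null(config$seed_center)) {
      config$seed_center <- spec$regions[["seed"]]$center
      config$seed_radius <- spec$regions[["seed"]]$radius_vox
    }
  } else {
    subjects <- lapply(config$subjects, function(su) {
      say("loading ", su$bold)
      list(dataset = load_bold(su$bold, su$mask, su$run_table %||% su$labels,
                               tr_s = config$tr_s),
           labels = read_labels(su$labels),
           nuisance = if (!is.null(su$nuisance)) nuisance_set(su$nuisance))
    })
    if (is.null(config$conditions)) {
      config$conditions <- setdiff(unique(subjects[[1]]$labels$condition),
                                   "REST")
    }
  }

  maps <- list(ic = list(), fc = list())
  for (s in seq_along(subjects)) {
    su <- subjects[[s]]
    say("preprocessing subject ", s)
    ds <- preprocess_bold(su$dataset, su$nuisance,
                          order = config$detrend_order)
    lab <- shift_labels(su$labels, config$shift_trs)
    seed <- if (!is.null(config$seed_mask)) {
      voxel_set_from_mask(config$seed_mask)
    } else {
      build_sphere(config$seed_center, config$seed_radius, ds$mask)
    }
    if ("ic" %in% config$methods) {
      say("IC map, subject ", s)
      maps$ic[[s]] <- ic_map(ds, seed, lab, config$conditions,
                             radius_vox = config$radius_vox,
                             keep_series = TRUE, subject = s)
    }
    if ("fc" %in% config$methods) {
      say("FC map, subject ", s)
      maps$fc[[s]] <- fc_map(ds, seed, lab, config$conditions,
                             nuisance = NULL,  # already residualized
                             granularity = config$fc_granularity,
                             radius_vox = config$radius_vox,
                             keep_series = TRUE, subject = s)
    }
  }

  results <- list()
  paths <- character(0)
  for (m in config$methods) {
    say("group inference (", toupper(m), ")")
    res <- group_connectivity(maps[[m]], fwhm_mm = config$fwhm_mm,
                              threshold_p = config$threshold_p,
                              alpha = config$alpha,
                              n_subject_perms = config$n_subject_perms,
                              n_group_maps = config$n_group_maps,
                              connectivity = config$connectivity,
                              within_run = config$within_run,
                              seed = child_seed(config$rng_seed,
                                                match(m, c("ic", "fc"))))
    results[[m]] <- res
    vsz <- maps[[m]][[1]]$voxel_size_mm
    p1 <- file.path(config$out_dir, paste0(m, "_group_t.nii.gz"))
    write_nifti_map(replace(res$t_map, is.na(res$t_map), 0), p1,
                    voxel_size_mm = vsz)
    p2 <- file.path(config$out_dir, paste0(m, "_group_corrected.nii.gz"))
    write_nifti_map(array(as.numeric(res$labels > 0), dim(res$labels)), p2,
                    voxel_size_mm = vsz)
    p3 <- file.path(config$out_dir, paste0(m, "_clusters.tsv"))
    readr::write_tsv(res$clusters, p3)
    for (s in seq_along(maps[[m]])) {
      mp <- maps[[m]][[s]]
      mp$searchlight_series <- NULL; mp$target_series <- NULL
      write_nifti_map(mp, file.path(config$out_dir,
                                    sprintf("%s_sub-%02d.nii.gz", m, s)))
    }
    paths <- c(paths, p1, p2, p3)
  }

  prov <- file.path(config$out_dir, "provenance.json")
  jsonlite::write_json(unclass(config)[!vapply(config, is.null, logical(1))],
                       prov, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, prov)
  say("done; outputs in ", config$out_dir)
  invisible(list(results = results, maps = maps, paths = paths,
                 config = config))
}
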