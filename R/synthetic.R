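#' Specification of a synthetic block-design session
#'
#' Describes a multi-run block-design fMRI session with region-specific
#' condition patterns whose signal-to-noise fluctuates block by block. Two
#' kinds of cross-region coupling are controllable independently: regions
#' sharing an `snr_group` share the block-wise fluctuation of their pattern
#' SNR (the substrate of informational connectivity), and regions sharing a
#' `univ_group` share a block-wise additive fluctuation of their mean signal
#' (the substrate of ordinary functional connectivity).
#'
#' Each run is laid out as `rest_trs` lead-in rest TRs followed by one block
#' of every condition (`block_trs` task TRs then `rest_trs` rest TRs), in a
#' per-run random condition order.
#'
#' @param volume_shape Integer `(i, j, k)` volume shape.
#' @param voxel_size_mm Voxel sizes in mm.
#' @param tr_s Repetition time in seconds.
#' @param n_runs Number of runs.
#' @param conditions Character vector of condition names.
#' @param block_trs Task TRs per block.
#' @param rest_trs Rest TRs separating blocks (also lead-in).
#' @param regions List of [region_spec()]s (disjoint).
#' @param noise_sd iid Gaussian noise sd.
#' @param snr_sdlog,univ_sdlog Log-normal sd (median 1) of the block-wise
#'   SNR and univariate fluctuation series.
#' @param hemodynamic_delay_trs TRs between written label onset and injected
#'   signal — the lag the analysis-side label shift is meant to undo.
#' @param mask_radius_vox Radius of a spherical brain mask centered in the
#'   volume, or `NULL` for a full-volume mask.
#' @param pattern_max_cor Pairwise correlation bound for condition patterns.
#' @param ar1_phi AR(1) coefficient for temporally autocorrelated noise
#'   (0 = iid, the default).
#' @param rng_seed Integer seed; together with the subject index it fully
#'   determines a subject's data.
#' @param n_subjects Number of subjects the spec describes.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(volume_shape, voxel_size_mm = c(3.5, 3.75, 3.75),
                           tr_s = 2.5, n_runs = 12L,
                           conditions = c("bottle", "chair", "scissors", "shoe"),
                           block_trs = 9L, rest_trs = 5L,
                           regions = list(), noise_sd = 1,
                           snr_sdlog = 0.5, univ_sdlog = 0.5,
                           hemodynamic_delay_trs = 2L,
                           mask_radius_vox = NULL,
                           pattern_max_cor = 0.3, ar1_phi = 0,
                           rng_seed = 1L, n_subjects = 1L) {
  stopifnot(block_trs >= 1L, noise_sd > 0, n_runs >= 2L,
            length(conditions) >= 2L)
  names(regions) <- vapply(regions, function(r) r$name, character(1))
  if (anyDuplicated(names(regions))) {
    stop("Region names must be unique.", call. = FALSE)
  }
  structure(list(volume_shape = as.integer(volume_shape),
                 voxel_size_mm = voxel_size_mm, tr_s = tr_s,
                 n_runs = as.integer(n_runs),
                 conditions = as.character(conditions),
                 block_trs = as.integer(block_trs),
                 rest_trs = as.integer(rest_trs),
                 regions = regions, noise_sd = noise_sd,
                 snr_sdlog = snr_sdlog, univ_sdlog = univ_sdlog,
                 hemodynamic_delay_trs = as.integer(hemodynamic_delay_trs),
                 mask_radius_vox = mask_radius_vox,
                 pattern_max_cor = pattern_max_cor, ar1_phi = ar1_phi,
                 rng_seed = as.integer(rng_seed),
                 n_subjects = as.integer(n_subjects)),
            class = "synthetic_spec")
}

#' Region specification for the synthetic generator
#'
#' @param name Region id.
#' @param center Integer `(i, j, k)` sphere center.
#' @param radius_vox Sphere radius in voxels.
#' @param base_snr Pattern amplitude scale; 0 means the region carries no
#'   condition information.
#' @param base_mean_amplitude Univariate (mean) signal amplitude scale.
#' @param snr_group Id shared by regions whose pattern-SNR fluctuations are
#'   coupled, or `NA` for a private (independent) series.
#' @param univ_group Id shared by regions whose univariate mean fluctuations
#'   are coupled, or `NA`.
#' @return A `region_spec` list.
#' @export
region_spec <- function(name, center, radius_vox = 3, base_snr = 3,
                        base_mean_amplitude = 0, snr_group = NA,
                        univ_group = NA) {
  structure(list(name = name, center = as.integer(center),
                 radius_vox = radius_vox, base_snr = base_snr,
                 base_mean_amplitude = base_mean_amplitude,
                 snr_group = snr_group, univ_group = univ_group),
            class = "region_spec")
}

#' Zero-mean, unit-norm condition pattern vectors
#'
#' Draws one spatial pattern per condition: zero mean across voxels, unit
#' Euclidean norm, pairwise correlations below `max_abs_cor` (redrawn until
#' satisfied). With `orthogonalize = TRUE` the patterns are made exactly
#' mutually orthogonal (zero pairwise correlation).
#'
#' @param n_voxels Pattern length (must exceed the condition count by at
#'   least 2).
#' @param conditions Condition names.
#' @param max_abs_cor Pairwise |correlation| bound.
#' @param orthogonalize Force exact orthogonality.
#' @param max_tries Redraw budget before declaring the bound infeasible.
#' @return Named list of numeric pattern vectors.
#' @export
make_patterns <- function(n_voxels, conditions, max_abs_cor = 0.3,
                          orthogonalize = FALSE, max_tries = 100L) {
  K <- length(conditions)
  if (n_voxels < K + 2L) {
    stop("Need n_voxels >= number of conditions + 2.", call. = FALSE)
  }
  for (try in seq_len(max_tries)) {
    M <- matrix(stats::rnorm(n_voxels * K), n_voxels, K)
    M <- sweep(M, 2, colMeans(M))
    if (orthogonalize) {
      # Gram-Schmidt inside the zero-mean subspace (closed under linear
      # combinations, so centering is preserved)
      for (a in seq_len(K)) {
        if (a > 1L) {
          prev <- M[, seq_len(a - 1L), drop = FALSE]
          M[, a] <- M[, a] - prev %*% crossprod(prev, M[, a])
        }
        M[, a] <- M[, a] / sqrt(sum(M[, a]^2))
      }
    } else {
      M <- sweep(M, 2, sqrt(colSums(M^2)), "/")
    }
    cors <- crossprod(M)  # zero-mean unit-norm => dot product = correlation
    diag(cors) <- 0
    if (max(abs(cors)) <= max_abs_cor + 1e-12) {
      out <- lapply(seq_len(K), function(a) M[, a])
      names(out) <- conditions
      return(out)
    }
  }
  stop("Could not satisfy the pairwise correlation bound ", max_abs_cor,
       " in ", max_tries, " draws.", call. = FALSE)
}

spherical_mask <- function(shape, radius_vox) {
  center <- ceiling(shape / 2)
  g <- expand.grid(i = seq_len(shape[1]), j = seq_len(shape[2]),
                   k = seq_len(shape[3]))
  d2 <- (g$i - center[1])^2 + (g$j - center[2])^2 + (g$k - center[3])^2
  array(d2 <= radius_vox^2, dim = shape)
}

# Deterministic per-subject child seed, kept below 2^31.
child_seed <- function(rng_seed, subject_index) {
  as.integer((as.numeric(rng_seed) * 7919 + subject_index * 104729) %%
               .Machine$integer.max)
}

#' Generate one synthetic subject
#'
#' Builds the label timeline, nuisance table and 4D volume for one subject
#' of a [synthetic_spec()]. During each (hemodynamically delayed) task block
#' of condition `c`, every voxel of a region receives
#' `base_mean_amplitude * u_g(block) + base_snr * s_g(block) * pattern_c[v]`
#' on top of Gaussian noise, where `s_g` and `u_g` are block-wise log-normal
#' (median 1) fluctuation series shared within a coupling group and
#' independent across groups and subjects. Voxels outside all regions carry
#' pure noise. Nuisance regressors are smooth random-walk series with no true
#' contribution to the data.
#'
#' @param spec A [synthetic_spec()].
#' @param subject_index Positive integer; with `spec$rng_seed` it determines
#'   the subject's RNG stream.
#' @return List with `dataset` ([bold_dataset()]), `labels` (unshifted
#'   [label_timeline()] — stimulus onsets, to be shifted by the analysis),
#'   `nuisance` ([nuisance_set()]), and `manifest` (every latent series:
#'   fluctuations, patterns, region members, block table, seeds).
#' @export
generate_subject <- function(spec, subject_index = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  seed_used <- child_seed(spec$rng_seed, subject_index)
  set.seed(seed_used)
  shape <- spec$volume_shape
  K <- length(spec$conditions)
  run_len <- spec$rest_trs + K * (spec$block_trs + spec$rest_trs)
  n_tr <- run_len * spec$n_runs
  mask <- if (is.null(spec$mask_radius_vox)) array(TRUE, dim = shape)
          else spherical_mask(shape, spec$mask_radius_vox)

  # labels: per-run random condition order
  cond_vec <- character(n_tr)
  cond_vec[] <- "REST"
  run_vec <- rep(seq_len(spec$n_runs), each = run_len)
  block_table <- list()
  b <- 0L
  for (r in seq_len(spec$n_runs)) {
    order_r <- sample(spec$conditions)
    pos <- (r - 1L) * run_len + spec$rest_trs
    for (cc in order_r) {
      b <- b + 1L
      onset <- pos + 1L
      trs <- seq(onset, onset + spec$block_trs - 1L)
      cond_vec[trs] <- cc
      block_table[[b]] <- tibble::tibble(block = b, run = r, condition = cc,
                                         onset_tr = onset)
      pos <- pos + spec$block_trs + spec$rest_trs
    }
  }
  block_table <- dplyr::bind_rows(block_table)
  labels <- label_timeline(tibble::tibble(run = run_vec, condition = cond_vec))
  n_blocks <- nrow(block_table)

  # resolve regions and check disjointness
  flat_of <- function(m) m[, 1] + (m[, 2] - 1L) * shape[1] +
    (m[, 3] - 1L) * shape[1] * shape[2]
  region_vox <- lapply(spec$regions, function(rg) {
    build_sphere(rg$center, rg$radius_vox, mask)
  })
  all_flat <- unlist(lapply(region_vox, function(v) flat_of(v$members)))
  if (anyDuplicated(all_flat)) {
    stop("Regions overlap; they must be disjoint.", call. = FALSE)
  }

  # block-wise fluctuation series per coupling group (private groups for
  # regions with NA group ids)
  group_id <- function(rg, field, prefix) {
    g <- rg[[field]]
    if (is.na(g)) paste0(".private_", prefix, "_", rg$name) else as.character(g)
  }
  snr_groups <- unique(vapply(spec$regions, group_id, character(1),
                              field = "snr_group", prefix = "s"))
  univ_groups <- unique(vapply(spec$regions, group_id, character(1),
                               field = "univ_group", prefix = "u"))
  s_series <- lapply(snr_groups, function(g)
    stats::rlnorm(n_blocks, 0, spec$snr_sdlog))
  names(s_series) <- snr_groups
  u_series <- lapply(univ_groups, function(g)
    stats::rlnorm(n_blocks, 0, spec$univ_sdlog))
  names(u_series) <- univ_groups

  # patterns per informative region
  patterns <- lapply(spec$regions, function(rg) {
    if (rg$base_snr > 0) {
      make_patterns(region_vox[[rg$name]]$n_members, spec$conditions,
                    max_abs_cor = spec$pattern_max_cor)
    }
  })

  # noise volume
  if (spec$ar1_phi != 0) {
    eps <- matrix(stats::rnorm(prod(shape) * n_tr, 0,
                               spec$noise_sd * sqrt(1 - spec$ar1_phi^2)),
                  prod(shape), n_tr)
    V <- eps
    for (t in 2:n_tr) V[, t] <- spec$ar1_phi * V[, t - 1] + eps[, t]
  } else {
    V <- matrix(stats::rnorm(prod(shape) * n_tr, 0, spec$noise_sd),
                prod(shape), n_tr)
  }

  # inject delayed block signal
  delay <- spec$hemodynamic_delay_trs
  for (bb in seq_len(n_blocks)) {
    trs <- block_table$onset_tr[bb] + delay + seq_len(spec$block_trs) - 1L
    run_end <- block_table$run[bb] * run_len
    trs <- trs[trs <= run_end]
    if (!length(trs)) next
    cc <- block_table$condition[bb]
    for (rg in spec$regions) {
      vox <- flat_of(region_vox[[rg$name]]$members)
      sg <- s_series[[group_id(rg, "snr_group", "s")]][bb]
      ug <- u_series[[group_id(rg, "univ_group", "u")]][bb]
      add <- rg$base_mean_amplitude * ug
      if (rg$base_snr > 0) {
        V[vox, trs] <- V[vox, trs] + add +
          rg$base_snr * sg * patterns[[rg$name]][[cc]]
      } else if (add != 0) {
        V[vox, trs] <- V[vox, trs] + add
      }
    }
  }

  # smooth random-walk nuisance series (true contribution is zero)
  nuis_names <- c("pitch", "roll", "yaw", "x", "y", "z", "white_matter")
  nuis <- vapply(nuis_names, function(nm) {
    as.numeric(stats::filter(stats::rnorm(n_tr, 0, 0.05), 0.95,
                             method = "recursive"))
  }, numeric(n_tr))
  nuisance <- nuisance_set(tibble::as_tibble(as.data.frame(nuis)))

  dataset <- bold_dataset(array(V, dim = c(shape, n_tr)), run_vec,
                          mask = mask, voxel_size_mm = spec$voxel_size_mm,
                          tr_s = spec$tr_s)
  manifest <- list(subject_index = subject_index, seed_used = seed_used,
                   block_table = block_table,
                   snr_series = s_series, univ_series = u_series,
                   patterns = patterns,
                   region_members = lapply(region_vox, function(v) v$members),
                   hemodynamic_delay_trs = delay,
                   spec = spec[setdiff(names(spec), "regions")],
                   regions = spec$regions)
  list(dataset = dataset, labels = labels, nuisance = nuisance,
       manifest = manifest)
}

#' The standard emulated session design
#'
#' A 12-run, 4-condition block design at TR 2.5 s with 9-TR (~24 s) task
#' blocks separated by 5-TR (~12 s) rest — the layout under which a 2-TR
#' label shift leaves 108 labeled TRs per condition and 432 analyzed
#' time-points per session — in a 20^3 volume with a spherical brain mask
#' and four 123-voxel regions instantiating the IC/FC dissociation
#' quadrants:
#' \describe{
#'   \item{seed}{condition patterns, SNR coupled to `partner`, univariate
#'     mean coupled to `univar`.}
#'   \item{partner}{condition patterns whose SNR fluctuations follow the
#'     seed's, but independent univariate fluctuations — detectable by IC,
#'     not FC.}
#'   \item{univar}{no condition patterns, but univariate fluctuations shared
#'     with the seed — detectable by FC, not IC.}
#'   \item{control}{condition patterns with fully independent fluctuations —
#'     detectable by neither.}
#' }
#'
#' The four regions sit at tetrahedron vertices, pairwise ~14 voxels apart,
#' so that no searchlight (radius 3) centered in one region can reach
#' another and map smoothing cannot bridge them. The `partner` and
#' `control` regions carry a constant univariate mean (no task-evoked mean
#' response): a region whose mean responds to the task shares the block
#' timing with every other responsive region, which ordinary functional
#' connectivity picks up regardless of coupling — the dissociation requires
#' the information-coupled region to be decodable while univariately silent.
#'
#' @param n_subjects Number of subjects described.
#' @param rng_seed Master seed.
#' @param coupled If `FALSE`, all coupling groups are made distinct (a
#'   global-null design for type-I error checks).
#' @param volume_shape,mask_radius_vox Override the volume geometry (keep
#'   the defaults for the standard design; smaller volumes bring the
#'   regions within searchlight reach of each other).
#' @return A [synthetic_spec()].
#' @export
default_paper_design <- function(n_subjects = 10L, rng_seed = 1L,
                                 coupled = TRUE,
                                 volume_shape = c(24L, 24L, 24L),
                                 mask_radius_vox = 11.7) {
  ctr <- ceiling(volume_shape / 2)
  d <- max(1L, round(min(volume_shape) / 4.8))  # 5 at the default 24^3
  regions <- list(
    region_spec("seed", ctr + c(d, d, d), 3, base_snr = 3,
                base_mean_amplitude = 2,
                snr_group = "info", univ_group = "univ"),
    region_spec("partner", ctr + c(d, -d, -d), 3, base_snr = 3,
                base_mean_amplitude = 0,
                snr_group = if (coupled) "info" else NA, univ_group = NA),
    region_spec("univar", ctr + c(-d, d, -d), 3, base_snr = 0,
                base_mean_amplitude = 2,
                snr_group = NA,
                univ_group = if (coupled) "univ" else NA),
    region_spec("control", ctr + c(-d, -d, d), 3, base_snr = 3,
                base_mean_amplitude = 0, snr_group = NA, univ_group = NA)
  )
  synthetic_spec(volume_shape = volume_shape,
                 mask_radius_vox = mask_radius_vox,
                 regions = regions, rng_seed = rng_seed,
                 n_subjects = n_subjects)
}

#' Write a synthetic subject to standard files
#'
#' Emits the 4D volume and mask as NIfTI-1, labels and nuisance as TSV, and
#' the ground-truth manifest as JSON, ready for the main pipeline.
#'
#' @param subject Output of [generate_subject()].
#' @param dir Output directory (created if missing).
#' @param prefix File name prefix.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_synthetic_subject <- function(subject, dir, prefix = "sub-01") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    bold = file.path(dir, paste0(prefix, "_bold.nii.gz")),
    mask = file.path(dir, paste0(prefix, "_mask.nii.gz")),
    labels = file.path(dir, paste0(prefix, "_labels.tsv")),
    nuisance = file.path(dir, paste0(prefix, "_nuisance.tsv")),
    manifest = file.path(dir, paste0(prefix, "_truth.json"))
  )
  write_nifti_map(subject$dataset, paths["bold"])
  write_nifti_map(array(as.numeric(subject$dataset$mask),
                        dim = dim(subject$dataset$mask)),
                  paths["mask"], voxel_size_mm = subject$dataset$voxel_size_mm)
  readr::write_tsv(as.data.frame(subject$labels), paths["labels"])
  readr::write_tsv(as.data.frame(subject$nuisance), paths["nuisance"])
  manifest <- subject$manifest
  manifest$region_members <- lapply(manifest$region_members,
                                    function(m) as.data.frame(m))
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE,
                       force = TRUE)
  invisible(paths)
}
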