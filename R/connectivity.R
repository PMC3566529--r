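#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values (ties receive average ranks).
#' Series whose ranks have zero variance get a correlation of 0 with
#' attribute `degenerate = TRUE`.
#'
#' @param a,b Numeric vectors of equal length `>= 3`.
#' @return Rank correlation in `[-1, 1]`.
#' @export
spearman_cor <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3L) {
    stop("Vectors must share length >= 3.", call. = FALSE)
  }
  ra <- rank(a)
  rb <- rank(b)
  if (stats::sd(ra) == 0 || stats::sd(rb) == 0) {
    return(structure(0, degenerate = TRUE))
  }
  sum(scale(ra) * scale(rb)) / (length(a) - 1)
}

# Spearman of one reference vector against every column of a matrix.
# Returns list(r, degenerate). Columns with zero rank variance -> 0.
spearman_vs_matrix <- function(ref, M) {
  rr <- rank(ref)
  RM <- apply(M, 2, rank)
  spearman_ranked(rr, RM)
}

# Same, with the matrix already column-ranked (reused across permutations).
spearman_ranked <- function(ref_ranks, ranked_M) {
  n <- length(ref_ranks)
  r0 <- ref_ranks - mean(ref_ranks)
  s0 <- sqrt(sum(r0^2))
  mu <- colMeans(ranked_M)
  Mc <- sweep(ranked_M, 2, mu)
  sM <- unname(sqrt(colSums(Mc^2)))
  degenerate <- sM == 0 | s0 == 0
  denom <- s0 * sM
  denom[degenerate] <- Inf
  r <- as.vector(crossprod(r0, Mc)) / denom
  r[degenerate] <- 0
  list(r = r, degenerate = degenerate)
}

# Sweep every searchlight: discriminability series (and per-searchlight
# summaries) for each masked center. Heavy path; vectorized per fold inside
# discrim_core.
searchlight_sweep <- function(dataset, labels, conditions, radius_vox) {
  conditions <- sort(as.character(conditions))
  check_runs_have_conditions(labels, conditions)
  sel <- select_condition_trs(labels, conditions)
  d <- dim(dataset$data)
  V <- matrix(dataset$data, prod(d[1:3]), d[4])[, sel, drop = FALSE]
  sl <- iter_searchlights(dataset$mask, radius_vox, as = "indices")
  C <- nrow(sl$centers)
  N <- length(sel)
  run_sel <- labels$run[sel]
  cond_sel <- labels$condition[sel]
  series <- matrix(NA_real_, N, C)
  accuracy <- numeric(C)
  mean_activation <- numeric(C)
  n_members <- lengths(sl$members)
  prep <- discrim_prep(run_sel, cond_sel, conditions)
  for (n in seq_len(C)) {
    X <- V[sl$members[[n]], , drop = FALSE]
    core <- discrim_core(X, run_sel, cond_sel, conditions, prep = prep)
    series[, n] <- core$values
    accuracy[n] <- mean(!is.na(core$predicted) & core$predicted == cond_sel)
    mean_activation[n] <- mean(X)
  }
  list(centers = sl$centers, members = sl$members, series = series,
       accuracy = accuracy, mean_activation = mean_activation,
       n_members = n_members, sel = sel,
       run_sel = run_sel, cond_sel = cond_sel,
       block_sel = labels$block[sel])
}

new_connectivity_map <- function(values, mask, voxel_size_mm, method, seed,
                                 conditions = NULL, subject = NA,
                                 fisher_transformed = FALSE,
                                 smoothed_fwhm_mm = NULL,
                                 n_degenerate = 0L, extras = list()) {
  seed_desc <- if (inherits(seed, "voxel_set")) {
    list(center = seed$center, radius_vox = seed$radius_vox,
         n_members = seed$n_members)
  } else seed
  structure(
    c(list(values = values, mask = mask, voxel_size_mm = voxel_size_mm,
           method = method, seed = seed_desc, conditions = conditions,
           subject = subject, fisher_transformed = fisher_transformed,
           smoothed_fwhm_mm = smoothed_fwhm_mm,
           n_degenerate = n_degenerate),
      extras),
    class = "connectivity_map"
  )
}

connectivity_map_metadata <- function(map) {
  list(method = map$method, seed = map$seed, conditions = map$conditions,
       subject = map$subject, fisher_transformed = map$fisher_transformed,
       smoothed_fwhm_mm = map$smoothed_fwhm_mm,
       voxel_size_mm = map$voxel_size_mm,
       n_degenerate = map$n_degenerate)
}

#' @export
print.connectivity_map <- function(x, ...) {
  cat("<connectivity_map> ", x$method, " map, ",
      paste(dim(x$values), collapse = " x "), " voxels (",
      sum(x$mask), " in mask)\n", sep = "")
  cat("  seed center (", paste(x$seed$center, collapse = ","), "), ",
      x$seed$n_members, " voxels; Fisher: ", x$fisher_transformed,
      "; smoothed: ",
      if (is.null(x$smoothed_fwhm_mm)) "no" else
        paste0(x$smoothed_fwhm_mm, " mm FWHM"), "\n", sep = "")
  invisible(x)
}

#' Informational connectivity map from a seed
#'
#' Computes the seed's multi-voxel pattern discriminability timeseries, the
#' equivalent series for a spherical searchlight centered on every masked
#' voxel, and places the Spearman rank correlation between the two at each
#' searchlight's center voxel. High values mark regions whose pattern
#' discriminability waxes and wanes in synchrony with the seed — regions
#' "informationally connected" to it.
#'
#' @param dataset A preprocessed [bold_dataset()].
#' @param seed A `voxel_set` seed region.
#' @param labels A (shifted) [label_timeline()].
#' @param conditions Conditions to analyze.
#' @param radius_vox Searchlight radius in voxels (123 voxels at radius 3).
#' @param keep_series Keep the per-searchlight discriminability series and
#'   the seed series inside the returned object (needed to build permutation
#'   nulls without re-sweeping; costs memory).
#' @param subject Optional subject id recorded in the map metadata.
#' @return A `connectivity_map` (method `"IC"`), values on the Spearman r
#'   scale (not yet Fisher-transformed).
#' @export
ic_map <- function(dataset, seed, labels, conditions, radius_vox = 3,
                   keep_series = FALSE, subject = NA) {
  seed_ts <- discriminability_timeseries(dataset, seed, labels, conditions)
  sweep_res <- searchlight_sweep(dataset, labels, conditions, radius_vox)
  sp <- spearman_vs_matrix(seed_ts$value, sweep_res$series)
  values <- array(NA_real_, dim(dataset$mask))
  values[sweep_res$centers] <- sp$r
  extras <- list(centers = sweep_res$centers,
                 seed_values = seed_ts$value,
                 block_sel = seed_ts$block,
                 run_sel = seed_ts$run,
                 radius_vox = radius_vox)
  if (keep_series) extras$searchlight_series <- sweep_res$series
  new_connectivity_map(values, dataset$mask, dataset$voxel_size_mm,
                       method = "IC", seed = seed,
                       conditions = sort(as.character(conditions)),
                       subject = subject,
                       n_degenerate = sum(sp$degenerate),
                       extras = extras)
}

# Partial correlation between a predictor and each column of Y, given
# covariates Z (residual-on-residual Pearson). Targets (or predictor) lying
# in the covariate span — residual norm below a relative tolerance — are
# degenerate and map to 0.
partial_cor_vs_matrix <- function(x, Y, Z = NULL) {
  n <- length(x)
  X <- cbind(rep(1, n), Z)
  dec <- qr(X)
  xr <- qr.resid(dec, x)
  Yr <- qr.resid(dec, Y)
  sx <- sqrt(sum(xr^2))
  sY <- unname(sqrt(colSums(Yr^2)))
  nx <- sqrt(sum(x^2))
  nY <- unname(sqrt(colSums(Y^2)))
  degenerate <- sY <= 1e-10 * pmax(nY, .Machine$double.xmin) |
    sx <= 1e-10 * pmax(nx, .Machine$double.xmin)
  denom <- sx * sY
  denom[degenerate] <- Inf
  r <- as.vector(crossprod(xr, Yr)) / denom
  r[degenerate] <- 0
  list(r = r, degenerate = degenerate)
}

#' Seed-based functional connectivity map
#'
#' Extracts the seed region's mean activation timeseries over the analyzed
#' TRs (the same TRs used for informational connectivity) and associates it
#' with every target timeseries in a GLM with the nuisance regressors as
#' covariates. The stored value is the partial correlation between seed
#' predictor and target given the covariates — the "map of correlation
#' values" convention. Targets are voxel timeseries (default) or
#' searchlight-mean timeseries.
#'
#' @param dataset A preprocessed [bold_dataset()].
#' @param seed A `voxel_set` seed region.
#' @param labels A (shifted) [label_timeline()].
#' @param conditions Conditions whose TRs are analyzed.
#' @param nuisance Optional [nuisance_set()] used as GLM covariates (pass
#'   `NULL` when the data were already residualized).
#' @param granularity `"voxel"` or `"searchlight"`.
#' @param radius_vox Searchlight radius (searchlight granularity only).
#' @param keep_series Keep the seed/target series inside the object (needed
#'   for permutation nulls).
#' @param subject Optional subject id.
#' @return A `connectivity_map` (method `"FC"`) on the correlation scale.
#' @export
fc_map <- function(dataset, seed, labels, conditions, nuisance = NULL,
                   granularity = c("voxel", "searchlight"), radius_vox = 3,
                   keep_series = FALSE, subject = NA) {
  granularity <- match.arg(granularity)
  conditions <- sort(as.character(conditions))
  sel <- select_condition_trs(labels, conditions)
  seed_mean <- colMeans(extract_patterns(dataset, seed))[sel]
  d <- dim(dataset$data)
  V <- matrix(dataset$data, prod(d[1:3]), d[4])[, sel, drop = FALSE]
  Z <- if (!is.null(nuisance)) {
    as.matrix(as.data.frame(nuisance))[sel, , drop = FALSE]
  }
  if (granularity == "voxel") {
    centers <- which(dataset$mask, arr.ind = TRUE)
    colnames(centers) <- c("i", "j", "k")
    targets <- t(V[which(dataset$mask), , drop = FALSE])
  } else {
    sl <- iter_searchlights(dataset$mask, radius_vox, as = "indices")
    centers <- sl$centers
    targets <- vapply(sl$members,
                      function(mem) colMeans(V[mem, , drop = FALSE]),
                      numeric(length(sel)))
  }
  pc <- partial_cor_vs_matrix(seed_mean, targets, Z)
  values <- array(NA_real_, dim(dataset$mask))
  values[centers] <- pc$r
  extras <- list(centers = centers,
                 seed_values = seed_mean,
                 block_sel = labels$block[sel],
                 run_sel = labels$run[sel],
                 granularity = granularity,
                 radius_vox = radius_vox)
  if (keep_series) {
    extras$target_series <- targets
    extras$covariates <- Z
  }
  new_connectivity_map(values, dataset$mask, dataset$voxel_size_mm,
                       method = "FC", seed = seed, conditions = conditions,
                       subject = subject,
                       n_degenerate = sum(pc$degenerate),
                       extras = extras)
}

#' Fisher-transform a connectivity map
#'
#' Applies `artanh` elementwise (values clipped to +/-(1 - 1e-7) first).
#' Applying it twice is an error.
#'
#' @param map A `connectivity_map`.
#' @return The transformed map with `fisher_transformed = TRUE`.
#' @export
fisher_map <- function(map) {
  stopifnot(inherits(map, "connectivity_map"))
  if (isTRUE(map$fisher_transformed)) {
    stop("Map is already Fisher-transformed.", call. = FALSE)
  }
  map$values <- atanh(clip_r(map$values))
  map$fisher_transformed <- TRUE
  map
}

#' Spatially smooth a connectivity map within the brain mask
#'
#' Gaussian smoothing with per-axis sigma `(fwhm_mm / voxel_size_axis) /
#' (2 sqrt(2 ln 2))` voxels. Smoothing is mask-aware: values outside the mask
#' are neither read nor written, and the kernel is renormalized over its
#' in-mask support, so edges are not attenuated toward zero.
#'
#' @param map A `connectivity_map`.
#' @param fwhm_mm Full width at half maximum of the kernel, in mm (8 mm is
#'   the conventional choice for group connectivity maps).
#' @return The smoothed map.
#' @export
smooth_map <- function(map, fwhm_mm) {
  stopifnot(inherits(map, "connectivity_map"))
  if (fwhm_mm < 0) stop("`fwhm_mm` must be >= 0.", call. = FALSE)
  if (fwhm_mm == 0) {
    map$smoothed_fwhm_mm <- 0
    return(map)
  }
  sm <- make_smoother(map$mask, fwhm_mm, map$voxel_size_mm)
  map$values <- sm(map$values)
  map$smoothed_fwhm_mm <- fwhm_mm
  map
}

# Precompute an FFT-based mask-aware Gaussian smoother; returns a closure
# applied to any values array defined on the same mask. Off-mask input is
# ignored; off-mask output is NA.
make_smoother <- function(mask, fwhm_mm, voxel_size_mm) {
  d <- dim(mask)
  sigma <- (fwhm_mm / voxel_size_mm) / (2 * sqrt(2 * log(2)))
  half <- pmax(ceiling(3 * sigma), 1L)
  kern1 <- lapply(1:3, function(a) {
    if (sigma[a] == 0) return(1)
    g <- stats::dnorm(seq(-half[a], half[a]), sd = sigma[a])
    g / sum(g)
  })
  P <- d + 2L * half
  # kernel embedded with its center at the origin (circular layout)
  kpad <- array(0, P)
  ax_idx <- lapply(1:3, function(a) ((seq(-half[a], half[a])) %% P[a]) + 1L)
  k3 <- outer(outer(kern1[[1]], kern1[[2]]), kern1[[3]])
  dim(k3) <- 2L * half + 1L
  kpad[ax_idx[[1]], ax_idx[[2]], ax_idx[[3]]] <- k3
  Kf <- stats::fft(kpad)
  maskA <- array(0, P)
  core <- lapply(1:3, function(a) seq_len(d[a]))
  maskA[core[[1]], core[[2]], core[[3]]] <- as.numeric(mask)
  den <- Re(stats::fft(stats::fft(maskA) * Kf, inverse = TRUE)) / prod(P)
  den <- den[core[[1]], core[[2]], core[[3]]]
  function(values) {
    v <- values
    v[!mask | is.na(v)] <- 0
    vA <- array(0, P)
    vA[core[[1]], core[[2]], core[[3]]] <- v
    num <- Re(stats::fft(stats::fft(vA) * Kf, inverse = TRUE)) / prod(P)
    num <- num[core[[1]], core[[2]], core[[3]]]
    out <- array(NA_real_, d)
    out[mask] <- num[mask] / den[mask]
    out
  }
}

#' Voxels whose searchlight overlaps a seed region
#'
#' Marks every masked voxel whose centered searchlight (radius
#' `radius_vox`) shares at least one voxel with the seed region —
#' searchlights whose connectivity with the seed is partly self-correlation
#' and are conventionally removed at the reporting stage. `extra_vox`
#' widens the zone (e.g. by twice the smoothing sigma, to cover values bled
#' outward by map smoothing).
#'
#' @param mask 3D logical brain mask.
#' @param seed A `voxel_set`.
#' @param radius_vox Searchlight radius in voxels.
#' @param extra_vox Additional Euclidean dilation in voxels.
#' @return 3D logical array, `TRUE` inside the exclusion zone.
#' @export
seed_overlap_zone <- function(mask, seed, radius_vox = 3, extra_vox = 0) {
  centers <- which(mask, arr.ind = TRUE)
  mem <- seed$members
  reach <- (radius_vox + extra_vox)^2
  hit <- vapply(seq_len(nrow(centers)), function(n) {
    d2 <- (mem[, 1] - centers[n, 1])^2 + (mem[, 2] - centers[n, 2])^2 +
      (mem[, 3] - centers[n, 3])^2
    any(d2 <= reach)
  }, logical(1))
  out <- array(FALSE, dim(mask))
  out[centers[hit, , drop = FALSE]] <- TRUE
  out
}

#' Characterize every searchlight for map interpretation
#'
#' For each masked searchlight center: the mean univariate activation over
#' the analyzed condition TRs, the leave-one-run-out multi-class decoding
#' accuracy, the value of each supplied connectivity map at that center, and
#' whether the searchlight overlaps the seed region (overlapping searchlights
#' are flagged here and typically removed at the reporting stage).
#'
#' @param dataset A preprocessed [bold_dataset()].
#' @param labels A (shifted) [label_timeline()].
#' @param conditions Conditions to analyze.
#' @param radius_vox Searchlight radius in voxels.
#' @param maps Named list of `connectivity_map`s sharing the dataset's
#'   geometry.
#' @param seed Optional `voxel_set` used for the overlap flag.
#' @return A tibble with one row per searchlight center.
#' @export
characterize_searchlights <- function(dataset, labels, conditions,
                                      radius_vox = 3, maps = list(),
                                      seed = NULL) {
  sw <- searchlight_sweep(dataset, labels, conditions, radius_vox)
  out <- tibble::tibble(
    i = sw$centers[, 1], j = sw$centers[, 2], k = sw$centers[, 3],
    n_members = sw$n_members,
    mean_activation = sw$mean_activation,
    accuracy = sw$accuracy
  )
  for (nm in names(maps)) {
    stopifnot(identical(dim(maps[[nm]]$values), dim(dataset$mask)))
    out[[nm]] <- maps[[nm]]$values[sw$centers]
  }
  if (!is.null(seed)) {
    d <- dim(dataset$mask)
    seed_flat <- seed$members[, 1] + (seed$members[, 2] - 1L) * d[1] +
      (seed$members[, 3] - 1L) * d[1] * d[2]
    out$seed_overlap <- vapply(sw$members,
                               function(mem) any(mem %in% seed_flat),
                               logical(1))
  }
  out
}
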