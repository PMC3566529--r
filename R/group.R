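#' Voxelwise one-sample group t-test
#'
#' Tests, at every masked voxel, whether the across-subject mean of the
#' (Fisher-transformed, smoothed) connectivity values exceeds zero:
#' `t = mean / (sd / sqrt(n))` with a one-sided p-value for `t > 0`. Voxels
#' with zero across-subject variance have no defined t; they receive
#' `t = NA`, `p = 1` and are counted in `n_degenerate`.
#'
#' @param maps List of per-subject `connectivity_map`s sharing geometry
#'   (at least 2 subjects), or a subjects-by-voxels matrix plus `mask`.
#' @param mask Optional 3D logical mask (taken from the first map if omitted).
#' @return List with `t_map`, `p_map` (3D arrays, NA / 1 outside mask),
#'   `n_subjects`, `n_degenerate`.
#' @export
group_ttest <- function(maps, mask = NULL) {
  if (is.list(maps) && inherits(maps[[1]], "connectivity_map")) {
    mask <- maps[[1]]$mask
    S <- do.call(rbind, lapply(maps, function(m) m$values[mask]))
  } else {
    S <- maps
    if (is.null(mask)) stop("Supply `mask` with a bare matrix.", call. = FALSE)
  }
  if (nrow(S) < 2L) stop("Need at least 2 subjects.", call. = FALSE)
  tt <- ttest_columns(S)
  t_map <- array(NA_real_, dim(mask)); t_map[mask] <- tt$t
  p_map <- array(1, dim(mask)); p_map[mask] <- tt$p
  list(t_map = t_map, p_map = p_map, n_subjects = nrow(S),
       n_degenerate = sum(tt$degenerate))
}

# Closed-form one-sample t over matrix columns; one-sided p for t > 0.
ttest_columns <- function(S) {
  n <- nrow(S)
  mu <- colMeans(S)
  sdv <- sqrt(colSums(sweep(S, 2, mu)^2) / (n - 1))
  degenerate <- sdv == 0
  t <- mu / (sdv / sqrt(n))
  t[degenerate] <- NA_real_
  p <- stats::pt(t, df = n - 1, lower.tail = FALSE)
  p[degenerate] <- 1
  list(t = t, p = p, degenerate = degenerate)
}

neighbor_offsets <- function(connectivity = c(6L, 18L, 26L)) {
  connectivity <- match.arg(as.character(connectivity[1]), c("6", "18", "26"))
  g <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  d2 <- g$di^2 + g$dj^2 + g$dk^2
  keep <- switch(connectivity,
                 "6" = d2 == 1,
                 "18" = d2 >= 1 & d2 <= 2,
                 "26" = d2 >= 1)
  as.matrix(g[keep, , drop = FALSE])
}

#' Label connected clusters in a binary 3D map
#'
#' Connected-component labeling under face (6), edge (18) or corner (26)
#' adjacency, by iterative frontier expansion.
#'
#' @param binary 3D logical (or 0/1) array of suprathreshold voxels.
#' @param connectivity 6 (default), 18 or 26.
#' @return List with `labels` (integer 3D array, 0 = background) and
#'   `clusters`, a tibble with `id` and `size_voxels` sorted by decreasing
#'   size.
#' @export
label_clusters <- function(binary, connectivity = 6L) {
  stopifnot(length(dim(binary)) == 3L)
  d <- dim(binary)
  off <- neighbor_offsets(connectivity)
  coords <- which(binary != 0, arr.ind = TRUE)
  labels <- array(0L, d)
  n_vox <- nrow(coords)
  if (n_vox == 0L) {
    return(list(labels = labels,
                clusters = tibble::tibble(id = integer(0),
                                          size_voxels = integer(0))))
  }
  pos <- array(0L, d)  # row index of each suprathreshold voxel
  pos[coords] <- seq_len(n_vox)
  lab_of_row <- integer(n_vox)
  next_label <- 0L
  for (v in seq_len(n_vox)) {
    if (lab_of_row[v] != 0L) next
    next_label <- next_label + 1L
    lab_of_row[v] <- next_label
    frontier <- v
    while (length(frontier)) {
      ci <- coords[frontier, 1]; cj <- coords[frontier, 2]
      ck <- coords[frontier, 3]
      ni <- rep(ci, nrow(off)) + rep(off[, 1], each = length(frontier))
      nj <- rep(cj, nrow(off)) + rep(off[, 2], each = length(frontier))
      nk <- rep(ck, nrow(off)) + rep(off[, 3], each = length(frontier))
      ok <- ni >= 1 & ni <= d[1] & nj >= 1 & nj <= d[2] & nk >= 1 & nk <= d[3]
      rows <- pos[cbind(ni[ok], nj[ok], nk[ok])]
      rows <- unique(rows[rows > 0L])
      rows <- rows[lab_of_row[rows] == 0L]
      lab_of_row[rows] <- next_label
      frontier <- rows
    }
  }
  labels[coords] <- lab_of_row
  sizes <- tabulate(lab_of_row, nbins = next_label)
  ord <- order(sizes, decreasing = TRUE)
  list(labels = labels,
       clusters = tibble::tibble(id = ord, size_voxels = sizes[ord]))
}

#' Block-permute a seed timeseries
#'
#' Shuffles the seed's per-TR values by randomly swapping whole blocks of
#' presentations (the contiguous same-condition TR stretches separated by
#' rest), preserving the within-block value order and the multiset of
#' values. Blocks are swapped only with blocks of the same length (and, with
#' `within_run = TRUE`, of the same run).
#'
#' @param values Numeric per-TR series (the analyzed TRs, in trial order) or
#'   a `discrim_ts` (its `value` column is used).
#' @param block Integer block id per entry (taken from a `discrim_ts`
#'   automatically). Every entry must belong to a block.
#' @param run Optional run id per entry, required for `within_run = TRUE`.
#' @param within_run Restrict swaps to blocks of the same run.
#' @return Numeric vector: the permuted series.
#' @export
permute_seed_series <- function(values, block = NULL, run = NULL,
                                within_run = FALSE) {
  if (inherits(values, "discrim_ts")) {
    block <- values$block
    run <- values$run
    values <- values$value
  }
  if (is.null(block) || anyNA(block)) {
    stop("Every entry of the series must belong to a block.", call. = FALSE)
  }
  perm <- permute_block_order(block, run, within_run)
  idx_by_block <- split(seq_along(values), factor(block, levels = unique(block)))
  out <- values
  for (b in seq_along(idx_by_block)) {
    out[idx_by_block[[b]]] <- values[idx_by_block[[perm[b]]]]
  }
  out
}

# Permuted slot assignment over blocks: perm[b] = which original block's
# values occupy slot b. Swaps only within matching-length (and optionally
# matching-run) groups.
permute_block_order <- function(block, run = NULL, within_run = FALSE) {
  blk <- factor(block, levels = unique(block))
  lens <- as.integer(table(blk))
  n_blocks <- length(lens)
  grp <- as.character(lens)
  if (within_run) {
    if (is.null(run)) stop("`within_run` needs per-entry run ids.", call. = FALSE)
    run_of_block <- vapply(split(run, blk), function(r) r[1], run[1])
    grp <- paste(grp, run_of_block)
  }
  perm <- seq_len(n_blocks)
  for (g in unique(grp)) {
    slots <- which(grp == g)
    if (length(slots) > 1L) perm[slots] <- slots[sample.int(length(slots))]
  }
  perm
}

#' Null distribution of maximum cluster sizes
#'
#' Builds the permutation null for cluster-corrected group inference. Each
#' subject's seed series is block-permuted `n_subject_perms` times; each
#' permuted series is pushed through the same map pipeline as the real data
#' (re-correlation against the unchanged searchlight/target series, Fisher
#' transform, smoothing). Then `n_group_maps` null group maps are formed by
#' independently sampling one permuted map per subject, each is submitted to
#' the one-sided group t-test and voxel threshold, and its largest
#' suprathreshold cluster size is recorded (0 if none survive).
#'
#' @param maps List of per-subject raw (un-Fisher-transformed, unsmoothed)
#'   `connectivity_map`s built with `keep_series = TRUE`.
#' @param fwhm_mm Smoothing applied to each permuted map (same as the real
#'   pipeline).
#' @param n_subject_perms Permuted series per subject (100 in the standard
#'   recipe).
#' @param n_group_maps Null group maps (1000 in the standard recipe).
#' @param threshold_p One-sided voxel threshold applied to each null group
#'   map (0.001 standard).
#' @param connectivity Cluster adjacency rule: 6, 18 or 26.
#' @param within_run Restrict block swaps to within-run.
#' @param seed Integer RNG seed for reproducibility.
#' @return Object of class `null_distribution` with fields
#'   `max_cluster_sizes`, `n_group_maps`, `n_subject_perms`, `threshold_p`,
#'   `rng_seed`.
#' @export
build_null <- function(maps, fwhm_mm, n_subject_perms = 100L,
                       n_group_maps = 1000L, threshold_p = 0.001,
                       connectivity = 6L, within_run = FALSE, seed = NULL) {
  if (n_subject_perms < 1L) stop("`n_subject_perms` must be >= 1.", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  mask <- maps[[1]]$mask
  n_mask <- sum(mask)
  smoother <- if (fwhm_mm > 0) {
    make_smoother(mask, fwhm_mm, maps[[1]]$voxel_size_mm)
  }
  subj_perms <- lapply(maps, function(map) {
    engine <- permutation_engine(map)
    out <- matrix(NA_real_, n_subject_perms, n_mask)
    for (p in seq_len(n_subject_perms)) {
      perm_seed <- permute_seed_series(engine$seed_values, engine$block,
                                       engine$run, within_run = within_run)
      values <- array(NA_real_, dim(mask))
      values[engine$centers] <- engine$remap(perm_seed)
      values <- atanh(clip_r(values))
      if (!is.null(smoother)) values <- smoother(values)
      out[p, ] <- values[mask]
    }
    out
  })
  n_subj <- length(maps)
  max_sizes <- integer(n_group_maps)
  S <- matrix(0, n_subj, n_mask)
  for (g in seq_len(n_group_maps)) {
    for (s in seq_len(n_subj)) {
      S[s, ] <- subj_perms[[s]][sample.int(n_subject_perms, 1L), ]
    }
    tt <- ttest_columns(S)
    binary <- array(FALSE, dim(mask))
    binary[mask] <- !tt$degenerate & tt$p < threshold_p
    cl <- label_clusters(binary, connectivity)
    max_sizes[g] <- if (nrow(cl$clusters)) cl$clusters$size_voxels[1] else 0L
  }
  structure(list(max_cluster_sizes = max_sizes,
                 n_group_maps = as.integer(n_group_maps),
                 n_subject_perms = as.integer(n_subject_perms),
                 threshold_p = threshold_p,
                 rng_seed = seed),
            class = "null_distribution")
}

# Cheap per-subject map recomputation under a permuted seed series. IC maps
# rank-correlate against the cached searchlight series; FC maps
# partial-correlate against the cached target series.
permutation_engine <- function(map) {
  stopifnot(inherits(map, "connectivity_map"))
  if (map$method == "IC") {
    D <- map$searchlight_series
    if (is.null(D)) {
      stop("IC map was not built with keep_series = TRUE.", call. = FALSE)
    }
    RM <- apply(D, 2, rank)
    list(seed_values = map$seed_values, block = map$block_sel,
         run = map$run_sel, centers = map$centers,
         remap = function(perm_seed) {
           spearman_ranked(rank(perm_seed), RM)$r
         })
  } else {
    Y <- map$target_series
    if (is.null(Y)) {
      stop("FC map was not built with keep_series = TRUE.", call. = FALSE)
    }
    Z <- map$covariates
    list(seed_values = map$seed_values, block = map$block_sel,
         run = map$run_sel, centers = map$centers,
         remap = function(perm_seed) {
           partial_cor_vs_matrix(perm_seed, Y, Z)$r
         })
  }
}

#' Corrected minimum cluster size from a null distribution
#'
#' The k-th largest null max-cluster size, with `k = round(alpha *
#' n_group_maps)` — e.g. the 50th largest of 1000 at `alpha = 0.05`. Real
#' clusters strictly larger than this value are significant at the corrected
#' level.
#'
#' @param null A `null_distribution` from [build_null()] (or a bare integer
#'   vector of null max-cluster sizes).
#' @param alpha Corrected significance level in (0, 1).
#' @return Integer cluster-size threshold.
#' @export
corrected_min_cluster <- function(null, alpha = 0.05) {
  sizes <- if (inherits(null, "null_distribution")) null$max_cluster_sizes
           else as.numeric(null)
  if (length(sizes) == 0L) stop("Empty null distribution.", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1).", call. = FALSE)
  k <- max(1L, as.integer(round(alpha * length(sizes))))
  sort(sizes, decreasing = TRUE)[k]
}

#' Apply voxel and cluster-size thresholds to a group map
#'
#' Keeps clusters that survive both the voxelwise one-sided threshold
#' (`p < threshold_p`, positive t) and the corrected size threshold (strictly
#' larger than `min_cluster_size`).
#'
#' @param ttest Output of [group_ttest()] (list with `t_map`, `p_map`,
#'   `n_subjects`).
#' @param threshold_p Voxelwise one-sided p threshold (0.001 standard; 0.005
#'   as a robustness check).
#' @param min_cluster_size Cluster-size threshold from
#'   [corrected_min_cluster()].
#' @param connectivity Cluster adjacency rule (6, 18, 26).
#' @param exclude Optional 3D logical array of voxels removed before
#'   clustering (e.g. a [seed_overlap_zone()], the reporting-stage removal
#'   of searchlights that overlap the seed).
#' @param null Optional `null_distribution`, carried into the result.
#' @return Object of class `group_result`: `t_map`, `p_map`, `threshold_p`,
#'   `min_cluster_size`, `clusters` (tibble: id, size, peak t, peak
#'   coordinates), `labels` (3D array labeling significant clusters),
#'   `n_subjects`, `null`.
#' @export
apply_correction <- function(ttest, threshold_p = 0.001,
                             min_cluster_size = 0L, connectivity = 6L,
                             exclude = NULL, null = NULL) {
  t_map <- ttest$t_map
  p_map <- ttest$p_map
  binary <- !is.na(t_map) & t_map > 0 & p_map < threshold_p
  if (!is.null(exclude)) binary <- binary & !exclude
  cl <- label_clusters(binary, connectivity)
  keep <- cl$clusters$id[cl$clusters$size_voxels > min_cluster_size]
  rows <- lapply(keep, function(id) {
    vox <- which(cl$labels == id, arr.ind = TRUE)
    tv <- t_map[vox]
    peak <- vox[which.max(tv), ]
    tibble::tibble(id = id, size_voxels = nrow(vox),
                   peak_t = max(tv),
                   peak_i = peak[1], peak_j = peak[2], peak_k = peak[3])
  })
  clusters <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(id = integer(0), size_voxels = integer(0),
                   peak_t = numeric(0), peak_i = integer(0),
                   peak_j = integer(0), peak_k = integer(0))
  if (nrow(clusters)) {
    clusters <- clusters[order(clusters$size_voxels, decreasing = TRUE), ]
    clusters$id <- seq_len(nrow(clusters))
  }
  labels <- array(0L, dim(t_map))
  for (r in seq_len(nrow(clusters))) {
    labels[cl$labels == keep[r]] <- clusters$id[r]
  }
  structure(list(t_map = t_map, p_map = p_map,
                 threshold_p = threshold_p,
                 min_cluster_size = as.integer(min_cluster_size),
                 clusters = clusters, labels = labels,
                 n_subjects = ttest$n_subjects, null = null),
            class = "group_result")
}

#' @export
print.group_result <- function(x, ...) {
  cat("<group_result> ", x$n_subjects, " subjects, voxel p < ",
      x$threshold_p, ", corrected min cluster > ", x$min_cluster_size,
      " voxels\n", sep = "")
  if (nrow(x$clusters)) print(x$clusters) else cat("  no significant clusters\n")
  invisible(x)
}

#' Full cluster-corrected group analysis of per-subject connectivity maps
#'
#' Fisher-transforms and smooths each subject's raw map, runs the one-sided
#' group t-test, builds the block-permutation null of maximum cluster sizes,
#' derives the corrected minimum cluster size at `alpha`, and returns the
#' thresholded result.
#'
#' @param maps Per-subject raw `connectivity_map`s built with
#'   `keep_series = TRUE`.
#' @param fwhm_mm Map smoothing FWHM in mm (8 mm standard).
#' @param threshold_p Voxelwise one-sided threshold (0.001 standard).
#' @param alpha Corrected significance level.
#' @param exclude Optional 3D logical exclusion array applied at the
#'   reporting stage (see [apply_correction()]).
#' @inheritParams build_null
#' @return A `group_result` (with the `null_distribution` attached).
#' @export
group_connectivity <- function(maps, fwhm_mm = 8, threshold_p = 0.001,
                               alpha = 0.05, n_subject_perms = 100L,
                               n_group_maps = 1000L, connectivity = 6L,
                               within_run = FALSE, exclude = NULL,
                               seed = NULL) {
  processed <- lapply(maps, function(m) smooth_map(fisher_map(m), fwhm_mm))
  tt <- group_ttest(processed)
  null <- build_null(maps, fwhm_mm = fwhm_mm,
                     n_subject_perms = n_subject_perms,
                     n_group_maps = n_group_maps, threshold_p = threshold_p,
                     connectivity = connectivity, within_run = within_run,
                     seed = seed)
  k <- corrected_min_cluster(null, alpha)
  apply_correction(tt, threshold_p = threshold_p, min_cluster_size = k,
                   connectivity = connectivity, exclude = exclude,
                   null = null)
}
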