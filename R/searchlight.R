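#' Integer lattice offsets of a sphere
#'
#' All integer offsets `(di, dj, dk)` with squared Euclidean norm at most
#' `radius_vox^2`, in deterministic lexicographic order (di, then dj, then
#' dk). The radius is measured in voxel index units on an isotropic index
#' grid, ignoring voxel anisotropy — the convention under which a radius-3
#' sphere contains exactly 123 voxels. Offsets whose norm equals the radius
#' exactly are included.
#'
#' @param radius_vox Non-negative sphere radius, in voxels.
#' @return Integer matrix with columns `di`, `dj`, `dk`, one row per offset.
#' @export
sphere_offsets <- function(radius_vox) {
  stopifnot(is.numeric(radius_vox), length(radius_vox) == 1L)
  if (radius_vox < 0) stop("`radius_vox` must be >= 0.", call. = FALSE)
  r <- floor(radius_vox)
  g <- seq.int(-r, r)
  grid <- expand.grid(dk = g, dj = g, di = g)  # di varies slowest
  keep <- grid$di^2 + grid$dj^2 + grid$dk^2 <= radius_vox^2
  out <- cbind(di = grid$di, dj = grid$dj, dk = grid$dk)[keep, , drop = FALSE]
  out[order(out[, 1], out[, 2], out[, 3]), , drop = FALSE]
}

#' Construct a spherical voxel set (seed or searchlight)
#'
#' Translates [sphere_offsets()] to `center`, then keeps only voxels inside
#' the volume bounds and the mask. Searchlights at mask or volume edges are
#' truncated, not discarded; `n_members` records the resulting size.
#'
#' @param center Integer `(i, j, k)` triple, 1-based, inside the volume.
#' @param radius_vox Sphere radius in voxels.
#' @param mask 3D logical array (volume bounds are taken from its shape).
#' @return An object of class `voxel_set` with fields `center`, `radius_vox`,
#'   `members` (integer matrix of voxel triples) and `n_members`.
#' @export
build_sphere <- function(center, radius_vox, mask) {
  center <- as.integer(center)
  stopifnot(length(center) == 3L, length(dim(mask)) == 3L)
  dims <- dim(mask)
  if (any(center < 1L) || any(center > dims)) {
    stop("Sphere center (", paste(center, collapse = ","),
         ") lies outside the volume.", call. = FALSE)
  }
  off <- sphere_offsets(radius_vox)
  pts <- sweep(off, 2, center, "+")
  inb <- pts[, 1] >= 1 & pts[, 1] <= dims[1] &
         pts[, 2] >= 1 & pts[, 2] <= dims[2] &
         pts[, 3] >= 1 & pts[, 3] <= dims[3]
  pts <- pts[inb, , drop = FALSE]
  inm <- mask[pts]
  members <- pts[inm, , drop = FALSE]
  colnames(members) <- c("i", "j", "k")
  voxel_set(center, radius_vox, members)
}

voxel_set <- function(center, radius_vox, members) {
  structure(
    list(center = as.integer(center),
         radius_vox = radius_vox,
         members = members,
         n_members = nrow(members)),
    class = "voxel_set"
  )
}

#' Build a voxel set from an explicit binary mask volume
#'
#' @param seed_mask 3D logical/0-1 array (or path to a NIfTI mask) marking
#'   the member voxels.
#' @return A `voxel_set`; its `center` is the member closest to the member
#'   centroid and `radius_vox` is `NA`.
#' @export
voxel_set_from_mask <- function(seed_mask) {
  if (is.character(seed_mask)) {
    seed_mask <- as.array(RNifti::readNifti(seed_mask)) != 0
  }
  members <- which(seed_mask != 0, arr.ind = TRUE)
  if (nrow(members) == 0L) stop("Seed mask is empty.", call. = FALSE)
  colnames(members) <- c("i", "j", "k")
  centroid <- colMeans(members)
  d2 <- rowSums(sweep(members, 2, centroid)^2)
  vs <- voxel_set(members[which.min(d2), ], NA_real_, members)
  vs
}

#' @export
print.voxel_set <- function(x, ...) {
  cat("<voxel_set> center (", paste(x$center, collapse = ","),
      "), radius ", x$radius_vox, " vox, ", x$n_members, " member voxel(s)\n",
      sep = "")
  invisible(x)
}

#' Enumerate searchlights over every masked voxel
#'
#' One spherical searchlight per masked voxel, centered on it, in
#' deterministic raster order (first array index fastest — R array order).
#' For large masks prefer `as = "indices"`, which returns flat voxel indices
#' ready for matrix extraction, over materializing full `voxel_set` objects.
#'
#' @param mask 3D logical array.
#' @param radius_vox Searchlight radius in voxels.
#' @param as `"voxel_sets"` for a list of [build_sphere()] results,
#'   `"indices"` for a list with `centers` (matrix) and `members` (list of
#'   integer vectors of flat voxel indices).
#' @return See `as`.
#' @export
iter_searchlights <- function(mask, radius_vox, as = c("voxel_sets", "indices")) {
  as <- match.arg(as)
  if (!any(mask)) stop("Mask is empty.", call. = FALSE)
  centers <- which(mask, arr.ind = TRUE)
  colnames(centers) <- c("i", "j", "k")
  if (as == "voxel_sets") {
    return(lapply(seq_len(nrow(centers)),
                  function(n) build_sphere(centers[n, ], radius_vox, mask)))
  }
  dims <- dim(mask)
  off <- sphere_offsets(radius_vox)
  # flat-index arithmetic: idx = i + (j-1)*di + (k-1)*di*dj
  off_flat <- off[, 1] + off[, 2] * dims[1] + off[, 3] * dims[1] * dims[2]
  center_flat <- which(mask)
  in_mask_flat <- rep(FALSE, prod(dims))
  in_mask_flat[center_flat] <- TRUE
  members <- vector("list", length(center_flat))
  ci <- centers[, 1]; cj <- centers[, 2]; ck <- centers[, 3]
  for (n in seq_along(center_flat)) {
    pi <- ci[n] + off[, 1]; pj <- cj[n] + off[, 2]; pk <- ck[n] + off[, 3]
    ok <- pi >= 1 & pi <= dims[1] & pj >= 1 & pj <= dims[2] &
          pk >= 1 & pk <= dims[3]
    cand <- center_flat[n] + off_flat[ok]
    members[[n]] <- cand[in_mask_flat[cand]]
  }
  list(centers = centers, members = members)
}
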