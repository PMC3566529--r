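#' BOLD dataset container
#'
#' Bundles a 4D voxel timeseries with its run structure and voxel geometry.
#' This is the object every preprocessing and analysis stage consumes.
#'
#' @param data 4D numeric array indexed `(i, j, k, t)`.
#' @param run_of_tr Integer vector, one run id per volume (TR). Run ids must
#'   be contiguous and non-decreasing along time (all of run 1, then all of
#'   run 2, ...).
#' @param mask 3D logical array with the same spatial shape as `data`;
#'   `TRUE` marks brain voxels. Defaults to all-`TRUE`.
#' @param voxel_size_mm Positive length-3 numeric, voxel edge lengths in mm.
#' @param tr_s Positive scalar, repetition time in seconds.
#' @param affine Optional 4x4 spatial transform. Carried through unchanged;
#'   never interpreted by this package.
#'
#' @return An object of class `bold_dataset`.
#' @export
bold_dataset <- function(data, run_of_tr,
                         mask = NULL,
                         voxel_size_mm = c(1, 1, 1),
                         tr_s = 1,
                         affine = NULL) {
  if (length(dim(data)) != 4L) {
    stop("`data` must be a 4D array (i, j, k, t); got ",
         length(dim(data)), " dimensions.", call. = FALSE)
  }
  spatial <- dim(data)[1:3]
  n_tr <- dim(data)[4]
  run_of_tr <- as.integer(run_of_tr)
  if (length(run_of_tr) != n_tr) {
    stop("`run_of_tr` has ", length(run_of_tr), " entries but data has ",
         n_tr, " TRs.", call. = FALSE)
  }
  if (is.unsorted(run_of_tr)) {
    stop("Run ids must be contiguous and non-decreasing along time.",
         call. = FALSE)
  }
  if (is.null(mask)) {
    mask <- array(TRUE, dim = spatial)
  }
  if (!is.logical(mask)) mask <- array(as.logical(mask), dim = dim(mask))
  if (!identical(as.integer(dim(mask)), as.integer(spatial))) {
    stop("Mask shape (", paste(dim(mask), collapse = "x"),
         ") does not match data spatial shape (",
         paste(spatial, collapse = "x"), ").", call. = FALSE)
  }
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0)) {
    stop("`voxel_size_mm` must be 3 positive numbers.", call. = FALSE)
  }
  if (!is.numeric(tr_s) || length(tr_s) != 1L || !is.finite(tr_s) || tr_s <= 0) {
    stop("`tr_s` must be a positive scalar (seconds).", call. = FALSE)
  }
  masked <- which(mask)
  if (length(masked)) {
    flat <- matrix(data, prod(spatial), n_tr)
    if (!all(is.finite(flat[masked, , drop = FALSE]))) {
      stop("Every masked voxel must have a finite timeseries.", call. = FALSE)
    }
  }
  structure(
    list(
      data = data,
      run_of_tr = run_of_tr,
      mask = mask,
      voxel_size_mm = voxel_size_mm,
      tr_s = as.numeric(tr_s),
      affine = affine
    ),
    class = "bold_dataset"
  )
}

#' @export
print.bold_dataset <- function(x, ...) {
  sp <- dim(x$data)[1:3]
  cat("<bold_dataset> ", paste(sp, collapse = " x "),
      " voxels, ", dim(x$data)[4], " TRs, ",
      length(unique(x$run_of_tr)), " run(s)\n", sep = "")
  cat("  voxel size: ", paste(format(x$voxel_size_mm), collapse = " x "),
      " mm; TR: ", x$tr_s, " s; ", sum(x$mask), " masked voxels\n", sep = "")
  invisible(x)
}

#' @export
dim.bold_dataset <- function(x) dim(x$data)

n_trs <- function(dataset) dim(dataset$data)[4]

#' Load a 4D BOLD volume and brain mask from NIfTI files
#'
#' Reads the functional volume and mask with RNifti, pulls voxel sizes and the
#' repetition time from the NIfTI header, and attaches the run structure.
#'
#' @param volume_path Path to a 4D NIfTI-1 file (`.nii` / `.nii.gz`).
#' @param mask_path Path to a 3D NIfTI mask with matching spatial shape, or
#'   `NULL` for an all-brain mask.
#' @param run_table Either an integer vector (one run id per TR), or a data
#'   frame with columns `tr` and `run` (one row per TR; `tr` may start at 0 or
#'   1 and is only used for ordering), or a path to a TSV with those columns.
#' @param tr_s Repetition time in seconds; required if the header does not
#'   record one.
#'
#' @return A [bold_dataset()].
#' @export
load_bold <- function(volume_path, mask_path = NULL, run_table, tr_s = NULL) {
  img <- RNifti::readNifti(volume_path)
  data <- unclass(as.array(img))
  if (length(dim(data)) != 4L) {
    stop("Expected a 4D volume at ", volume_path, "; got ",
         length(dim(data)), " dimensions.", call. = FALSE)
  }
  pix <- RNifti::pixdim(img)
  voxel_size_mm <- pix[1:3]
  header_tr <- if (length(pix) >= 4) pix[4] else NA_real_
  if (is.null(tr_s)) {
    if (!is.finite(header_tr) || header_tr <= 0) {
      stop("Header carries no usable TR; pass `tr_s` explicitly.",
           call. = FALSE)
    }
    tr_s <- header_tr
  }
  mask <- NULL
  if (!is.null(mask_path)) {
    mask <- as.array(RNifti::readNifti(mask_path)) != 0
    dim(mask) <- dim(mask)[1:3]
  }
  run_of_tr <- resolve_run_table(run_table, dim(data)[4])
  bold_dataset(data, run_of_tr, mask = mask,
               voxel_size_mm = voxel_size_mm, tr_s = tr_s,
               affine = structure(RNifti::xform(img), code = NULL))
}

resolve_run_table <- function(run_table, n_tr) {
  if (is.character(run_table) && length(run_table) == 1L) {
    run_table <- readr::read_tsv(run_table, show_col_types = FALSE)
  }
  if (is.data.frame(run_table)) {
    if (!all(c("tr", "run") %in% names(run_table))) {
      stop("Run table needs columns `tr` and `run`.", call. = FALSE)
    }
    run_table <- run_table[order(run_table$tr), ]
    run_of_tr <- as.integer(run_table$run)
  } else {
    run_of_tr <- as.integer(run_table)
  }
  if (length(run_of_tr) != n_tr) {
    stop("Run table has ", length(run_of_tr), " rows but the volume has ",
         n_tr, " TRs.", call. = FALSE)
  }
  run_of_tr
}

#' Write a 3D map (or a bold_dataset) to a NIfTI-1 file
#'
#' @param x A 3D/4D numeric array, a [bold_dataset()], or a
#'   [connectivity_map] (its `values` array is written and a JSON provenance
#'   sidecar is placed next to the volume).
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @param voxel_size_mm Voxel sizes for bare arrays (objects carry their own).
#' @return `path`, invisibly.
#' @export
write_nifti_map <- function(x, path, voxel_size_mm = c(1, 1, 1)) {
  sidecar <- NULL
  tr_s <- 1
  if (inherits(x, "connectivity_map")) {
    sidecar <- connectivity_map_metadata(x)
    voxel_size_mm <- x$voxel_size_mm
    arr <- x$values
    arr[is.na(arr)] <- 0
  } else if (inherits(x, "bold_dataset")) {
    voxel_size_mm <- x$voxel_size_mm
    tr_s <- x$tr_s
    arr <- x$data
  } else {
    arr <- x
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(voxel_size_mm,
                           if (length(dim(arr)) == 4) tr_s else NULL)
  RNifti::writeNifti(img, path)
  if (!is.null(sidecar)) {
    side_path <- sub("\\.nii(\\.gz)?$", ".json", path)
    jsonlite::write_json(sidecar, side_path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  }
  invisible(path)
}
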