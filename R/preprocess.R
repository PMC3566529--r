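#' Polynomial detrending, per voxel and per run
#'
#' Removes, for each voxel and each run independently, the least-squares
#' polynomial fit of the timeseries on time (including the mean; order 0 is
#' plain demeaning). The conventional choice for block-design data is
#' `order = 2`.
#'
#' @param dataset A [bold_dataset()].
#' @param order Non-negative integer polynomial order.
#' @return A [bold_dataset()] of residuals.
#' @export
detrend_polynomial <- function(dataset, order = 2L) {
  stopifnot(inherits(dataset, "bold_dataset"))
  order <- as.integer(order)
  if (order < 0L) stop("`order` must be >= 0.", call. = FALSE)
  apply_per_run(dataset, function(Y, run) {
    if (nrow(Y) <= order + 1L) {
      stop("Run ", run, " has ", nrow(Y),
           " TRs; need more than order + 1 = ", order + 1L, ".",
           call. = FALSE)
    }
    tt <- seq_len(nrow(Y))
    X <- matrix(1, nrow(Y), 1L)
    if (order >= 1L) {
      X <- cbind(X, stats::poly(tt, degree = order, raw = FALSE))
    }
    qr.resid(qr(X), Y)
  })
}

#' Regress nuisance covariates out of every voxel timeseries
#'
#' For each voxel and each run, replaces the timeseries with the residual of
#' an ordinary least-squares fit on an intercept plus the nuisance regressors
#' (e.g. six motion parameters and the mean white-matter signal). This is
#' equivalent to entering the same covariates in a connectivity GLM.
#' Constant-zero or linearly dependent regressor columns are dropped with a
#' warning.
#'
#' @param dataset A [bold_dataset()].
#' @param nuisance A [nuisance_set()] (or data frame) with one row per TR of
#'   `dataset`.
#' @return A [bold_dataset()] of residuals.
#' @export
residualize_nuisance <- function(dataset, nuisance) {
  stopifnot(inherits(dataset, "bold_dataset"))
  R <- as.matrix(as.data.frame(nuisance))
  if (nrow(R) != n_trs(dataset)) {
    stop("Nuisance table has ", nrow(R), " rows but the dataset has ",
         n_trs(dataset), " TRs.", call. = FALSE)
  }
  zero_col <- apply(R, 2, function(v) all(v == 0))
  if (any(zero_col)) {
    warning("Dropping all-zero nuisance column(s): ",
            paste(colnames(R)[zero_col], collapse = ", "), call. = FALSE)
    R <- R[, !zero_col, drop = FALSE]
  }
  apply_per_run(dataset, function(Y, run) {
    idx <- attr(Y, "tr_index")
    X <- cbind(`(intercept)` = 1, R[idx, , drop = FALSE])
    dec <- qr(X)
    if (dec$rank < ncol(X)) {
      dropped <- colnames(X)[dec$pivot[(dec$rank + 1L):ncol(X)]]
      warning("Run ", run, ": rank-deficient nuisance design; dropping ",
              paste(dropped, collapse = ", "), call. = FALSE)
      X <- X[, dec$pivot[seq_len(dec$rank)], drop = FALSE]
      dec <- qr(X)
    }
    qr.resid(dec, Y)
  })
}

#' Z-score each voxel's timeseries within each run
#'
#' Normalizes every voxel's run segment (task and rest TRs alike) to mean 0
#' and unit variance, using the sample (n - 1) standard deviation. Voxels
#' whose segment is constant are set to all zeros for that run, with a
#' warning, so spatial shapes stay aligned.
#'
#' @param dataset A [bold_dataset()].
#' @return A z-scored [bold_dataset()].
#' @export
zscore_within_run <- function(dataset) {
  stopifnot(inherits(dataset, "bold_dataset"))
  n_degenerate <- 0L
  masked <- which(dataset$mask)
  out <- apply_per_run(dataset, function(Y, run) {
    mu <- colMeans(Y)
    sd <- sqrt(colSums(sweep(Y, 2, mu)^2) / (nrow(Y) - 1))
    bad <- sd == 0 | !is.finite(sd)
    n_degenerate <<- n_degenerate + sum(bad[masked])
    sd[bad] <- Inf  # constant segment -> zeros
    sweep(sweep(Y, 2, mu), 2, sd, "/")
  })
  if (n_degenerate > 0L) {
    warning(n_degenerate,
            " constant voxel-run segment(s) set to zero during z-scoring.",
            call. = FALSE)
  }
  out
}

#' Apply the full preprocessing contract
#'
#' Fixed order: polynomial detrend, then nuisance residualization, then
#' per-run z-scoring (so that z-scoring is the final normalization before
#' pattern analysis). Label shifting is a separate step ([shift_labels()])
#' because it acts on the timeline, not the data.
#'
#' @inheritParams residualize_nuisance
#' @inheritParams detrend_polynomial
#' @return A preprocessed [bold_dataset()].
#' @export
preprocess_bold <- function(dataset, nuisance = NULL, order = 2L) {
  dataset <- detrend_polynomial(dataset, order = order)
  if (!is.null(nuisance)) dataset <- residualize_nuisance(dataset, nuisance)
  zscore_within_run(dataset)
}

# Run fn(Y, run) on every run segment, where Y is a (TRs-in-run x voxels)
# matrix with attr "tr_index" giving the segment's TR indices. Reassembles a
# bold_dataset with the same geometry.
apply_per_run <- function(dataset, fn) {
  d <- dim(dataset$data)
  V <- matrix(dataset$data, prod(d[1:3]), d[4])  # voxels x T
  out <- V
  for (r in unique(dataset$run_of_tr)) {
    idx <- which(dataset$run_of_tr == r)
    Y <- t(V[, idx, drop = FALSE])
    attr(Y, "tr_index") <- idx
    res <- fn(Y, r)
    out[, idx] <- t(res)
  }
  new_data <- array(out, dim = d)
  ds <- dataset
  ds$data <- new_data
  ds
}
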