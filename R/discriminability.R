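#' Extract the multi-voxel pattern matrix for a voxel set
#'
#' @param dataset A [bold_dataset()].
#' @param voxels A `voxel_set` ([build_sphere()] / [voxel_set_from_mask()]).
#' @return Numeric matrix, voxels x TRs.
#' @export
extract_patterns <- function(dataset, voxels) {
  stopifnot(inherits(dataset, "bold_dataset"), inherits(voxels, "voxel_set"))
  d <- dim(dataset$data)
  flat <- voxels$members[, 1] +
    (voxels$members[, 2] - 1L) * d[1] +
    (voxels$members[, 3] - 1L) * d[1] * d[2]
  V <- matrix(dataset$data, prod(d[1:3]), d[4])
  V[flat, , drop = FALSE]
}

#' Leave-one-run-out condition prototypes
#'
#' A prototype is the arithmetic mean multi-voxel pattern of a condition,
#' computed over all labeled TRs of the training runs (every run except
#' `held_out_run`).
#'
#' @param patterns Voxels x TRs matrix for one voxel set (whole session),
#'   e.g. from [extract_patterns()].
#' @param labels A [label_timeline()] aligned with `patterns` columns.
#' @param held_out_run Run id excluded from training.
#' @param conditions Conditions to build prototypes for.
#' @return Object of class `prototype_set`: `held_out_run`,
#'   `prototypes` (voxels x conditions matrix, columns in sorted condition
#'   order), `m` (voxel count).
#' @export
fit_prototypes <- function(patterns, labels, held_out_run, conditions) {
  conditions <- sort(as.character(conditions))
  if (length(unique(labels$run)) < 2L) {
    stop("Leave-one-run-out training needs at least 2 runs.", call. = FALSE)
  }
  train <- labels$run != held_out_run
  P <- matrix(NA_real_, nrow(patterns), length(conditions),
              dimnames = list(NULL, conditions))
  for (cc in conditions) {
    cols <- which(train & labels$condition == cc)
    if (length(cols) == 0L) {
      stop("Condition '", cc, "' absent from training runs (held-out run ",
           held_out_run, ").", call. = FALSE)
    }
    P[, cc] <- rowMeans(patterns[, cols, drop = FALSE])
  }
  structure(list(held_out_run = held_out_run, prototypes = P,
                 m = nrow(patterns)),
            class = "prototype_set")
}

#' Pearson correlation via the normalized-vector dot product
#'
#' Computes the correlation between a time-point's activity pattern and a
#' prototype as the dot product of the mean-centered, sd-normalized vectors
#' divided by `m - 1` — algebraically identical to Pearson's r. A constant
#' vector has no defined correlation; the value is 0 with attribute
#' `degenerate = TRUE`.
#'
#' @param x,prototype Numeric vectors of equal length `m >= 3`.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pattern_correlation <- function(x, prototype) {
  m <- length(x)
  if (m < 3L || length(prototype) != m) {
    stop("Vectors must share length m >= 3.", call. = FALSE)
  }
  xs <- stats::sd(x)
  ps <- stats::sd(prototype)
  if (xs == 0 || ps == 0 || !is.finite(xs) || !is.finite(ps)) {
    return(structure(0, degenerate = TRUE))
  }
  sum(((x - mean(x)) / xs) * ((prototype - mean(prototype)) / ps)) / (m - 1)
}

clip_r <- function(r, eps = 1e-7) pmin(pmax(r, -1 + eps), 1 - eps)

#' Multi-voxel pattern discriminability of a single time-point
#'
#' Fisher-z correlation with the correct condition's prototype minus the
#' Fisher-z correlation with the most similar incorrect prototype. Positive
#' exactly when the correlation classifier's argmax prediction is correct.
#' Correlations are clipped to +/-(1 - 1e-7) before `artanh` so the value
#' stays finite when a test pattern equals a prototype.
#'
#' @param x Activity pattern (length-m vector).
#' @param prototypes A `prototype_set` from [fit_prototypes()].
#' @param correct_condition The condition actually presented at this
#'   time-point.
#' @return Scalar discriminability value.
#' @export
discriminability_at_tr <- function(x, prototypes, correct_condition) {
  stopifnot(inherits(prototypes, "prototype_set"))
  P <- prototypes$prototypes
  if (ncol(P) < 2L) stop("Need at least 2 conditions.", call. = FALSE)
  if (!correct_condition %in% colnames(P)) {
    stop("Unknown condition '", correct_condition, "'.", call. = FALSE)
  }
  r <- vapply(colnames(P), function(cc) as.numeric(
    pattern_correlation(x, P[, cc])), numeric(1))
  r_c <- r[[correct_condition]]
  r_i <- max(r[setdiff(names(r), correct_condition)])
  atanh(clip_r(r_c)) - atanh(clip_r(r_i))
}

# Precompute the leave-one-run-out fold structure shared by every voxel set:
# G is an N x (n_runs * K) averaging matrix such that X %*% G yields every
# fold's condition prototypes in one multiply.
discrim_prep <- function(run_sel, cond_sel, conditions) {
  conditions <- sort(as.character(conditions))
  K <- length(conditions)
  runs <- unique(run_sel)
  N <- length(run_sel)
  G <- matrix(0, N, length(runs) * K)
  folds <- vector("list", length(runs))
  for (fi in seq_along(runs)) {
    r <- runs[fi]
    for (ki in seq_len(K)) {
      cols <- which(run_sel != r & cond_sel == conditions[ki])
      if (length(cols) == 0L) {
        stop("Condition '", conditions[ki],
             "' has no training TRs when run ", r, " is held out.",
             call. = FALSE)
      }
      G[cols, (fi - 1L) * K + ki] <- 1 / length(cols)
    }
    folds[[fi]] <- list(test = which(run_sel == r),
                        gcols = (fi - 1L) * K + seq_len(K))
  }
  list(G = G, folds = folds, conditions = conditions, K = K,
       cond_col = match(cond_sel, conditions))
}

# Vectorized discriminability engine for one voxel set.
# X: voxels x N matrix of selected-TR patterns; run_sel/cond_sel: per-column
# run and condition. Correlations are computed as dot products of centered,
# unit-norm columns (exactly Pearson's r). Returns values, predicted (NA on
# degenerate tie), r_correct, r_incorrect.
discrim_core <- function(X, run_sel, cond_sel, conditions, prep = NULL) {
  if (is.null(prep)) prep <- discrim_prep(run_sel, cond_sel, conditions)
  K <- prep$K
  if (K < 2L) stop("Need at least 2 conditions.", call. = FALSE)
  m <- nrow(X)
  N <- ncol(X)
  mu <- colMeans(X)
  Xc <- X - rep(mu, each = m)
  cn <- sqrt(colSums(Xc^2))
  degen <- cn == 0
  cn[degen] <- Inf
  Xn <- Xc / rep(cn, each = m)
  P <- X %*% prep$G
  Pc <- P - rep(colMeans(P), each = m)
  pn <- sqrt(colSums(Pc^2))
  pn[pn == 0] <- Inf  # constant prototype -> correlation 0
  Pn <- Pc / rep(pn, each = m)
  rmat <- matrix(0, K, N)  # conditions x time-points
  for (fold in prep$folds) {
    rmat[, fold$test] <- crossprod(Pn[, fold$gcols, drop = FALSE],
                                   Xn[, fold$test, drop = FALSE])
  }
  pred_idx <- max.col(t(rmat), ties.method = "first")
  rc <- rmat[cbind(prep$cond_col, seq_len(N))]
  rtmp <- rmat
  rtmp[cbind(prep$cond_col, seq_len(N))] <- -Inf
  ri <- rtmp[1, ]
  for (k in seq_len(K)[-1]) ri <- pmax(ri, rtmp[k, ])
  values <- atanh(clip_r(rc)) - atanh(clip_r(ri))
  values[degen] <- 0
  predicted <- prep$conditions[pred_idx]
  predicted[degen] <- NA_character_
  list(values = values, predicted = predicted,
       r_correct = rc, r_incorrect = ri)
}

check_runs_have_conditions <- function(labels, conditions) {
  for (r in unique(labels$run)) {
    present <- unique(labels$condition[labels$run == r])
    missing <- setdiff(conditions, present)
    if (length(missing)) {
      stop("Run ", r, " lacks condition(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Discriminability timeseries of a voxel set
#'
#' Runs the full leave-one-run-out sweep: each labeled TR is scored with the
#' prototype set whose held-out run is that TR's run. Rest TRs never enter
#' prototypes or the series. The trial index `n` follows temporal order.
#'
#' @param dataset A preprocessed [bold_dataset()].
#' @param voxels A `voxel_set`.
#' @param labels A [label_timeline()] (already shifted for hemodynamic
#'   delay).
#' @param conditions Conditions to analyze (every run must contain each).
#' @return A tibble of class `discrim_ts` with columns `n`, `tr`, `run`,
#'   `block`, `condition`, `value`, `predicted`.
#' @export
discriminability_timeseries <- function(dataset, voxels, labels, conditions) {
  conditions <- sort(as.character(conditions))
  check_runs_have_conditions(labels, conditions)
  sel <- select_condition_trs(labels, conditions)
  X <- extract_patterns(dataset, voxels)[, sel, drop = FALSE]
  core <- discrim_core(X, labels$run[sel], labels$condition[sel], conditions)
  out <- tibble::tibble(
    n = seq_along(sel),
    tr = sel,
    run = labels$run[sel],
    block = labels$block[sel],
    condition = labels$condition[sel],
    value = core$values,
    predicted = core$predicted
  )
  attr(out, "conditions") <- conditions
  attr(out, "n_voxels") <- voxels$n_members
  class(out) <- c("discrim_ts", class(out))
  out
}

#' Classification accuracy of a discriminability timeseries
#'
#' Fraction of analyzed time-points whose argmax-correlation prediction
#' matches the presented condition (chance is 1/K for K conditions;
#' degenerate time-points with no prediction count as incorrect).
#'
#' @param ts A `discrim_ts` from [discriminability_timeseries()].
#' @return Proportion in `[0, 1]`.
#' @export
classification_accuracy <- function(ts) {
  if (nrow(ts) == 0L) stop("Empty discriminability series.", call. = FALSE)
  mean(!is.na(ts$predicted) & ts$predicted == ts$condition)
}

#' Write a discriminability series to TSV
#'
#' @param ts A `discrim_ts`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_discrim_tsv <- function(ts, path) {
  readr::write_tsv(as.data.frame(ts), path)
  invisible(path)
}
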