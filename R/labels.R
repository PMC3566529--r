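#' Per-TR condition/run label timeline
#'
#' A label timeline assigns each TR of a session to a run and to a condition
#' (or `"REST"`). Blocks — maximal stretches of contiguous TRs sharing run and
#' condition — are derived automatically and never span runs; rest TRs carry
#' `NA` block ids.
#'
#' @param x A data frame with columns `run` and `condition`, one row per TR in
#'   temporal order; an optional `tr` column (starting at 0 or 1) is used only
#'   to order rows. `condition` may be character or factor; `"REST"` marks
#'   unlabeled TRs.
#'
#' @return A tibble of class `label_timeline` with columns
#'   `tr` (1-based TR index), `run`, `condition`, `block`.
#' @export
label_timeline <- function(x) {
  if (!is.data.frame(x)) stop("`x` must be a data frame.", call. = FALSE)
  if (!all(c("run", "condition") %in% names(x))) {
    stop("Label table needs columns `run` and `condition`.", call. = FALSE)
  }
  if ("tr" %in% names(x)) x <- x[order(x$tr), ]
  out <- tibble::tibble(
    tr = seq_len(nrow(x)),
    run = as.integer(x$run),
    condition = as.character(x$condition)
  )
  if (is.unsorted(out$run)) {
    stop("Run ids must be contiguous and non-decreasing along time.",
         call. = FALSE)
  }
  out$block <- compute_blocks(out$run, out$condition)
  class(out) <- c("label_timeline", class(out))
  out
}

# Block id: new block at every (run, condition) change; REST -> NA.
compute_blocks <- function(run, condition) {
  n <- length(run)
  if (n == 0L) return(integer(0))
  change <- c(TRUE, run[-1] != run[-n] | condition[-1] != condition[-n])
  seg <- cumsum(change)
  task <- condition != "REST"
  block <- rep(NA_integer_, n)
  if (any(task)) {
    block[task] <- as.integer(factor(seg[task], levels = unique(seg[task])))
  }
  block
}

#' Read a label timeline from a TSV file
#'
#' Expects columns `tr`, `run`, `condition` (REST allowed).
#'
#' @param path Path to a tab-separated file.
#' @return A [label_timeline()].
#' @export
read_labels <- function(path) {
  label_timeline(readr::read_tsv(path, show_col_types = FALSE))
}

#' Shift condition labels in time to account for hemodynamic delay
#'
#' The condition label originally at TR `t` is reassigned to TR
#' `t + shift_trs`, independently within each run. Labels shifted past a run's
#' end are dropped (never wrapped, which would mix blocks across runs); the
#' vacated TRs at the start of each run become `"REST"`. Block ids are
#' recomputed.
#'
#' @param labels A [label_timeline()].
#' @param shift_trs Non-negative integer number of TRs to shift (the
#'   conventional choice for a 2.5-s TR is 2).
#' @return A new [label_timeline()].
#' @export
shift_labels <- function(labels, shift_trs) {
  stopifnot(is.numeric(shift_trs), length(shift_trs) == 1L)
  shift_trs <- as.integer(shift_trs)
  if (shift_trs < 0L) stop("`shift_trs` must be >= 0.", call. = FALSE)
  if (shift_trs == 0L) return(label_timeline(labels))
  cond <- labels$condition
  run <- labels$run
  new_cond <- cond
  for (r in unique(run)) {
    idx <- which(run == r)
    len <- length(idx)
    if (shift_trs >= len) {
      stop("Shift of ", shift_trs, " TRs is not smaller than run ", r,
           " (", len, " TRs).", call. = FALSE)
    }
    shifted <- c(rep("REST", shift_trs), cond[idx][seq_len(len - shift_trs)])
    new_cond[idx] <- shifted
  }
  label_timeline(tibble::tibble(run = run, condition = new_cond))
}

#' Select the analyzed TRs for a set of conditions
#'
#' Returns the temporally ordered 1-based TR indices whose label is one of
#' `conditions`. This ordering defines the trial index `n = 1...N` used by the
#' discriminability timeseries.
#'
#' @param labels A [label_timeline()].
#' @param conditions Character vector of condition ids (must not include
#'   `"REST"`).
#' @return Integer vector of TR indices, ascending.
#' @export
select_condition_trs <- function(labels, conditions) {
  if (length(conditions) == 0L) {
    stop("`conditions` must be nonempty.", call. = FALSE)
  }
  known <- setdiff(unique(labels$condition), "REST")
  unknown <- setdiff(conditions, known)
  if (length(unknown)) {
    stop("Unknown condition id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  idx <- which(labels$condition %in% conditions)
  if (length(idx) == 0L) {
    stop("No TRs carry the requested condition labels.", call. = FALSE)
  }
  sort(idx)
}

#' Per-TR nuisance regressor set
#'
#' @param x A data frame (or path to a TSV) with one row per TR and one named
#'   column per covariate — typically six motion parameters (pitch, roll, yaw,
#'   x, y, z) and the mean white-matter signal. Constant-zero columns are
#'   rejected.
#' @return A tibble of class `nuisance_set`.
#' @export
nuisance_set <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    x <- readr::read_tsv(x, show_col_types = FALSE)
  }
  if (!is.data.frame(x) || ncol(x) == 0L) {
    stop("Nuisance table must be a data frame with named columns.",
         call. = FALSE)
  }
  x <- tibble::as_tibble(x)
  all_zero <- vapply(x, function(col) all(col == 0), logical(1))
  if (any(all_zero)) {
    stop("Constant-zero nuisance column(s): ",
         paste(names(x)[all_zero], collapse = ", "), call. = FALSE)
  }
  class(x) <- c("nuisance_set", class(x))
  x
}
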