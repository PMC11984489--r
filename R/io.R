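# CSV/JSON interchange. Matrices and vectors travel as headered CSV
# (decimal point, comma separator); scalar summaries as JSON.

.sg_read_csv <- function(path) {
  if (!file.exists(path)) {
    .sg_stop("sg_io_error", "input file not found: %s", path)
  }
  out <- tryCatch(utils::read.csv(path, check.names = FALSE),
                  error = function(e) {
                    .sg_stop("sg_io_error", "failed to parse %s: %s",
                             path, conditionMessage(e))
                  })
  out
}

#' Read a numeric matrix from headered CSV
#'
#' An optional first column named `state` (row labels) is dropped.
#'
#' @param path CSV file path.
#' @return A plain numeric matrix.
#' @export
read_matrix_csv <- function(path) {
  df <- .sg_read_csv(path)
  if (ncol(df) > 1 && names(df)[1] == "state") df <- df[, -1, drop = FALSE]
  M <- as.matrix(df)
  if (!is.numeric(M)) {
    .sg_stop("sg_io_error", "%s contains non-numeric entries", path)
  }
  dimnames(M) <- NULL
  M
}

#' Write a numeric matrix as headered CSV
#'
#' @param M Numeric matrix.
#' @param path Output CSV path.
#' @export
write_matrix_csv <- function(M, path) {
  M <- as.matrix(M)
  colnames(M) <- paste0("s", seq_len(ncol(M)))
  utils::write.csv(as.data.frame(M), path, row.names = FALSE)
  invisible(path)
}

#' Read a numeric vector from single-column CSV
#'
#' @param path CSV file with one column named `value`.
#' @return Numeric vector.
#' @export
read_vector_csv <- function(path) {
  df <- .sg_read_csv(path)
  if (!"value" %in% names(df)) {
    .sg_stop("sg_io_error", "%s must have a column named 'value'", path)
  }
  as.numeric(df$value)
}

#' Write a numeric vector as single-column CSV
#'
#' @param x Numeric vector.
#' @param path Output CSV path.
#' @export
write_vector_csv <- function(x, path) {
  utils::write.csv(data.frame(value = as.numeric(x)), path, row.names = FALSE)
  invisible(path)
}

#' Write a simplex-flow trajectory as CSV
#'
#' Columns: `t`, `p_1 ... p_n`, `entropy`, `constraint_residual`,
#' `grad_norm`.
#'
#' @param traj An `"sg_trajectory"` from [evolve()].
#' @param path Output CSV path.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "sg_trajectory"))
  states <- traj$states
  colnames(states) <- paste0("p_", seq_len(ncol(states)))
  df <- data.frame(t = traj$times, states,
                   entropy = traj$entropy,
                   constraint_residual = traj$constraint_residual,
                   grad_norm = traj$grad_norm)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a balance-model trajectory to a directory
#'
#' Writes `diagnostics.csv` (step, time, goal_value, row_sum_residual,
#' min_entry, effective_gamma) plus per-sample matrices
#' `P_000000.csv, ...` when `matrices = TRUE` (always including the first
#' and last sample).
#'
#' @param traj A `"balance_trajectory"` from [evolve_balance()].
#' @param dir Output directory (created if missing).
#' @param matrices Write every stored matrix (default `TRUE`).
#' @export
write_balance_trajectory <- function(traj, dir, matrices = TRUE) {
  stopifnot(inherits(traj, "balance_trajectory"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  diag_df <- data.frame(step = seq_along(traj$times) - 1L,
                        time = traj$times,
                        goal_value = traj$goal,
                        row_sum_residual = traj$row_sum_residual,
                        min_entry = traj$min_entry,
                        effective_gamma = traj$effective_gamma)
  utils::write.csv(diag_df, file.path(dir, "diagnostics.csv"), row.names = FALSE)
  idx <- if (matrices) seq_along(traj$matrices) else c(1L, length(traj$matrices))
  for (i in unique(idx)) {
    write_matrix_csv(traj$matrices[[i]],
                     file.path(dir, sprintf("P_%06d.csv", i - 1L)))
  }
  invisible(dir)
}

#' Write an entropy report as JSON
#'
#' @param report An `"entropy_report"` from [entropy_report()].
#' @param path Output JSON path.
#' @export
write_entropy_report <- function(report, path) {
  stopifnot(inherits(report, "entropy_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  invisible(path)
}
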