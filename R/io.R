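## Table schemas: documented CSV headers enforced on read.
cell_table_columns <- c("cell_id", "fov_id", "x_um", "y_um",
                        "selectivity_class", "subtype", "orientation_group",
                        "true_pref_orientation_deg",
                        "true_pref_direction_deg", "true_tuning_kappa")
fov_table_columns <- c("fov_id", "center_x_um", "center_y_um",
                       "quadrant", "distance_um")

norm_angle_columns <- function(df) {
  acols <- grep("orientation_deg$", names(df), value = TRUE)
  for (cn in acols) {
    v <- df[[cn]]
    bad <- !is.na(v) & (v >= 180 | v < 0)
    if (any(bad)) {
      warning("column ", cn, ": ", sum(bad),
              " angle(s) outside [0, 180) normalized on read")
      df[[cn]][bad] <- norm_axis_deg(v[bad])
    }
  }
  df
}

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(what, ": missing column(s): ", paste(missing, collapse = ", "))
  df
}

#' Write / read the per-cell table
#'
#' Cell tables are UTF-8 CSV with '.' decimal separator and documented
#' headers; orientation columns are normalized to `[0, 180)` (with a
#' warning) on read, and the schema is validated strictly.
#'
#' @param cells data.frame of cells (at minimum the ground-truth columns;
#'   tuning/significance columns are preserved if present).
#' @param path file path.
#' @return `read_cell_table` returns the validated data.frame.
#' @export
write_cell_table <- function(cells, path) {
  utils::write.csv(cells, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, cell_table_columns[1:2], "cell table")
  norm_angle_columns(df)
}

#' Write / read the FOV table
#' @param fovs data.frame of fields of view.
#' @param path file path.
#' @export
write_fov_table <- function(fovs, path) {
  utils::write.csv(fovs, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fov_table
#' @export
read_fov_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, fov_table_columns, "FOV table")
  df
}

#' Write / read response sets
#'
#' Response containers are serialized as long-format CSV with columns
#' `cell_id`, `direction_deg`, `rep`, `frame`, `dfof`; one row per sample.
#' Frame and rep indices are 1-based. `read_responses` rebuilds the named
#' list-of-matrices container and validates shape consistency against the
#' protocol.
#'
#' @param responses named list (by cell id) of response sets (named lists
#'   of T x R matrices keyed by direction).
#' @param path file path.
#' @param proto a [stimulus_protocol()].
#' @export
write_responses <- function(responses, path) {
  chunks <- lapply(names(responses), function(id) {
    rm <- responses[[id]]
    per_dir <- lapply(names(rm), function(dd) {
      M <- rm[[dd]]
      data.frame(cell_id = id, direction_deg = as.numeric(dd),
                 rep = rep(seq_len(ncol(M)), each = nrow(M)),
                 frame = rep(seq_len(nrow(M)), times = ncol(M)),
                 dfof = as.vector(M))
    })
    do.call(rbind, per_dir)
  })
  utils::write.csv(do.call(rbind, chunks), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_responses
#' @export
read_responses <- function(path, proto) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, c("cell_id", "direction_deg", "rep", "frame", "dfof"),
                "response table")
  T <- proto$frames_per_trial; R <- proto$n_reps
  out <- lapply(split(df, df$cell_id), function(dc) {
    rm <- lapply(split(dc, dc$direction_deg), function(dd) {
      if (nrow(dd) != T * R)
        stop("response table: cell ", dd$cell_id[1], " direction ",
             dd$direction_deg[1], " has ", nrow(dd), " samples, expected ",
             T * R)
      M <- matrix(0, T, R)
      M[cbind(dd$frame, dd$rep)] <- dd$dfof
      M
    })
    names(rm) <- names(split(dc, dc$direction_deg))
    rm
  })
  out[unique(df$cell_id)]
}
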