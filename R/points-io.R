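POINT_COLUMNS <- c(
  "id", "x_um", "y_um", "z_um", "intensity", "circularity",
  "theta_deg", "phi_deg", "zone"
)
ZONE_LEVELS <- c("CZ", "GZ", "MR", "unassigned")

#' Construct a point table of detected or simulated nuclei
#'
#' The canonical tabular exchange format of the package: one row per nucleus,
#' coordinates in micrometres, optional spherical angles (theta from the
#' anterior pole, phi azimuth) and an epithelial zone label. Extra columns
#' (e.g. ground-truth annotations) are preserved.
#'
#' @param x_um,y_um,z_um numeric coordinates in um.
#' @param id integer ids (unique); default `seq_along(x_um)`.
#' @param intensity,circularity,theta_deg,phi_deg optional per-nucleus values.
#' @param zone zone labels among `CZ`, `GZ`, `MR`, `unassigned`.
#' @param ... further columns, recycled to the table length.
#' @return data frame of class `point_table`.
#' @export
point_table <- function(x_um = numeric(), y_um = numeric(), z_um = numeric(),
                        id = seq_along(x_um), intensity = NA_real_,
                        circularity = NA_real_, theta_deg = NA_real_,
                        phi_deg = NA_real_, zone = "unassigned", ...) {
  n <- length(x_um)
  rl <- function(v) rep_len(v, n)
  df <- data.frame(
    id = rl(as.integer(id)), x_um = as.numeric(x_um),
    y_um = rl(as.numeric(y_um)), z_um = rl(as.numeric(z_um)),
    intensity = rl(as.numeric(intensity)),
    circularity = rl(as.numeric(circularity)),
    theta_deg = rl(as.numeric(theta_deg)), phi_deg = rl(as.numeric(phi_deg)),
    zone = rl(as.character(zone)),
    stringsAsFactors = FALSE
  )
  extra <- list(...)
  for (nm in names(extra)) df[[nm]] <- rep_len(extra[[nm]], n)
  validate_point_table(df)
}

validate_point_table <- function(df) {
  if (anyDuplicated(df$id)) stop("point table ids must be unique")
  th <- df$theta_deg[!is.na(df$theta_deg)]
  if (length(th) && (min(th) < 0 || max(th) > 180)) {
    stop("theta_deg must lie in [0, 180]")
  }
  ph <- df$phi_deg[!is.na(df$phi_deg)]
  if (length(ph) && (min(ph) < 0 || max(ph) >= 360)) {
    stop("phi_deg must lie in [0, 360)")
  }
  bad <- setdiff(unique(df$zone[!is.na(df$zone)]), ZONE_LEVELS)
  if (length(bad)) stop("unknown zone label(s): ", paste(bad, collapse = ", "))
  class(df) <- c("point_table", "data.frame")
  df
}

#' Read / write point tables as CSV
#'
#' The CSV header is fixed: `id,x_um,y_um,z_um,intensity,circularity,
#' theta_deg,phi_deg,zone` (additional columns may follow). Missing optional
#' columns are filled with `NA` / `"unassigned"`; a missing coordinate or id
#' column is a format error naming the column.
#'
#' @param path CSV file path.
#' @return [read_points()]: a `point_table`; [write_points()]: `path`,
#'   invisibly.
#' @export
read_points <- function(path) {
  if (!file.exists(path)) stop("cannot read point table: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("id", "x_um", "y_um", "z_um")
  missing_req <- setdiff(required, names(df))
  if (length(missing_req)) {
    stop(
      "malformed point CSV '", basename(path), "': missing column(s) ",
      paste(missing_req, collapse = ", ")
    )
  }
  for (col in setdiff(POINT_COLUMNS, names(df))) {
    df[[col]] <- if (col == "zone") "unassigned" else NA_real_
  }
  df$zone[is.na(df$zone) | df$zone == ""] <- "unassigned"
  extra <- setdiff(names(df), POINT_COLUMNS)
  df <- df[, c(POINT_COLUMNS, extra), drop = FALSE]
  validate_point_table(df)
}

#' @rdname read_points
#' @param table a `point_table` (or compatible data frame).
#' @export
write_points <- function(table, path) {
  if (!is.data.frame(table)) stop("table must be a data frame")
  for (col in setdiff(POINT_COLUMNS, names(table))) {
    table[[col]] <- if (col == "zone") "unassigned" else NA_real_
  }
  extra <- setdiff(names(table), POINT_COLUMNS)
  table <- table[, c(POINT_COLUMNS, extra), drop = FALSE]
  write.csv(table, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
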