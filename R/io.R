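track_schema <- c("experiment", "cell_id", "parent_id", "frame", "t_min",
                  "au_yfp", "au_cfp", "x_um", "y_um", "area_px", "class",
                  "alive")

#' Read a single-cell track table
#'
#' Delimited text with the documented header: `experiment, cell_id,
#' parent_id, frame, t_min, au_yfp, au_cfp, x_um, y_um, area_px, class,
#' alive`. The header must match exactly; an extra or missing column is
#' an error naming the offending column.
#'
#' @param path File path (CSV).
#' @return Track tibble.
#' @export
read_tracks <- function(path) {
  hdr <- names(utils::read.csv(path, nrows = 1, check.names = FALSE))
  if (length(hdr) == 0 || !identical(hdr, track_schema)) {
    extra <- setdiff(hdr, track_schema)
    miss <- setdiff(track_schema, hdr)
    stop("read_tracks(): schema mismatch",
         if (length(extra)) paste0("; unexpected column(s): ",
                                   paste(extra, collapse = ", ")),
         if (length(miss)) paste0("; missing column(s): ",
                                  paste(miss, collapse = ", ")))
  }
  # base strtod parsing is exact to the last ulp (vroom's fast path is not)
  tibble::as_tibble(utils::read.csv(path, colClasses = c(
    experiment = "character", cell_id = "integer",
    parent_id = "integer", frame = "integer", t_min = "numeric",
    au_yfp = "numeric", au_cfp = "numeric", x_um = "numeric",
    y_um = "numeric", area_px = "numeric", class = "character",
    alive = "integer")))
}

#' Write a table as delimited text at full precision
#'
#' Doubles are written with shortest round-trip representation, so a
#' write/read cycle reproduces the values exactly.
#'
#' @param table Data frame / tibble.
#' @param path Output path (CSV).
#' @return `path`, invisibly.
#' @export
write_table <- function(table, path) {
  # 17 significant digits guarantee exact double round-trips
  out <- as.data.frame(lapply(table, function(col) {
    if (is.double(col)) {
      s <- sprintf("%.17g", col)
      s[is.na(col)] <- NA_character_
      s
    } else col
  }), optional = TRUE, check.names = FALSE)
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a pipeline configuration file
#'
#' YAML key-value file; unknown keys are rejected and `seed` is
#' mandatory. See [pipeline_config()] for the keys.
#'
#' @param path YAML file path.
#' @return A validated `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}
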