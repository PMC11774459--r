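#' Read and write landmark tables (CSV / JSON)
#'
#' Serialises landmark tables losslessly. Coordinates are written with
#' 17 significant digits so that write -> read -> write round-trips are
#' byte-identical. The `type` column is serialised as `1`, `2` or
#' `unrefined` and mapped back to `type1` / `type2` on read. Unknown
#' extra columns are preserved verbatim as character. The format
#' (`"csv"` or `"json"`) is inferred from the file extension.
#'
#' @param path File path ending in `.csv` or `.json`.
#' @param landmarks A landmark data frame ([landmark_frame()]).
#' @return `read_landmarks` returns a landmark data frame;
#'   `write_landmarks` returns `path` invisibly.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- jsonlite::fromJSON(path)
    if (length(df) == 0L || (is.data.frame(df) && nrow(df) == 0L))
      return(landmark_frame())
    df <- as.data.frame(df, stringsAsFactors = FALSE)
  } else {
    lines <- readLines(path)
    if (length(lines) == 0L) stop(sprintf("empty landmark file: %s", path))
    header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
    nfield <- length(header)
    body <- lines[-1]
    body <- body[nzchar(body)]
    if (length(body) > 0L) {
      counts <- vapply(strsplit(body, ",", fixed = TRUE), length, integer(1))
      bad <- which(counts != nfield)
      if (length(bad) > 0L)
        stop(sprintf("malformed landmark row at line %d of %s (%d fields, expected %d)",
                     bad[1] + 1L, path, counts[bad[1]], nfield))
    }
    df <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  }
  required <- c("id", "case", "image", "x_mm", "y_mm", "z_mm", "type",
                "flagged", "substrate")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop(sprintf("landmark file %s lacks columns: %s", path,
                 paste(missing, collapse = ", ")))
  df$image <- as.integer(df$image)
  df$flagged <- as.integer(df$flagged)
  for (cc in c("x_mm", "y_mm", "z_mm")) df[[cc]] <- as.numeric(df[[cc]])
  df$type <- ifelse(df$type %in% c("1", "type1"), "type1",
                    ifelse(df$type %in% c("2", "type2"), "type2", df$type))
  out <- landmark_frame(id = df$id, case = df$case, image = df$image,
                        x_mm = df$x_mm, y_mm = df$y_mm, z_mm = df$z_mm,
                        type = df$type, flagged = df$flagged,
                        substrate = df$substrate)
  extra <- setdiff(names(df), required)
  for (cc in extra) out[[cc]] <- as.character(df[[cc]])
  out
}

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[!is.finite(x)] <- as.character(x[!is.finite(x)])
  out
}

#' @rdname read_landmarks
#' @export
write_landmarks <- function(landmarks, path) {
  stopifnot(is.data.frame(landmarks))
  type_out <- ifelse(landmarks$type == "type1", "1",
                     ifelse(landmarks$type == "type2", "2", landmarks$type))
  required <- c("id", "case", "image", "x_mm", "y_mm", "z_mm", "type",
                "flagged", "substrate")
  extra <- setdiff(names(landmarks), c(required, "out_of_grid"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- landmarks
    df$type <- type_out
    jsonlite::write_json(df[, c(required, extra), drop = FALSE], path,
                         dataframe = "rows", digits = NA, auto_unbox = TRUE)
  } else {
    cols <- c("id", "case", "image", "x_mm", "y_mm", "z_mm", "type",
              "flagged", "substrate", extra)
    mat <- cbind(landmarks$id, landmarks$case, as.character(landmarks$image),
                 fmt_num(landmarks$x_mm), fmt_num(landmarks$y_mm),
                 fmt_num(landmarks$z_mm), type_out,
                 as.character(landmarks$flagged), landmarks$substrate)
    for (cc in extra) mat <- cbind(mat, as.character(landmarks[[cc]]))
    lines <- c(paste(cols, collapse = ","),
               if (nrow(landmarks) > 0L) apply(mat, 1, paste, collapse = ","))
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read a run configuration (YAML or JSON)
#'
#' Loads a configuration file into a named list and fills missing
#' fields from the package defaults: a `growth` block ([growth_config()]),
#' a `vesselness` block ([vesselness_config()]), a `phantom` block
#' (amplitude/period ranges for [sample_phantom_transform()]) and
#' top-level `seed`, `log_level`, `out_dir`. A round trip through
#' [write_run_config()] preserves every field.
#'
#' @param path `.yaml`/`.yml` or `.json` file, or `NULL` for defaults.
#' @return A named list of configuration blocks.
#' @export
read_run_config <- function(path = NULL) {
  user <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
    user <- if (grepl("\\.json$", path, ignore.case = TRUE))
      jsonlite::fromJSON(path, simplifyVector = TRUE)
    else yaml::read_yaml(path)
  }
  base <- list(
    seed = 1L, log_level = "info", out_dir = ".",
    growth = unclass(growth_config()),
    vesselness = unclass(vesselness_config()),
    phantom = list(amplitude_range = c(0, 5), period_range = c(60, 120)),
    evaluate = list(cutoff = NULL))
  modifyList(base, user, keep.null = TRUE)
}

#' @rdname read_run_config
#' @param config A configuration list.
#' @export
write_run_config <- function(config, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  } else {
    yaml::write_yaml(config, path)
  }
  invisible(path)
}
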