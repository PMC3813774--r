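# on-disk schemas: comma-separated UTF-8 with a header row. Column `rename`
# maps file headers to in-memory names; `check` is a row-level predicate
# (TRUE = valid) applied after type coercion.
table_schemas <- function() {
  list(
    fetuses = list(
      required = c("fetus_id", "litter_id", "treatment", "genotype",
                   "fetal_weight", "placental_weight"),
      optional = c("crown_rump", "abdominal_circ", "head_circ",
                   "tail_tip_fraction", "dpm_accumulated", "sample_time_x"),
      character = c("fetus_id", "litter_id", "treatment", "genotype"),
      checks = list(
        fetal_weight = function(x) !is.na(x) & x > 0,
        placental_weight = function(x) !is.na(x) & x > 0,
        tail_tip_fraction = function(x) is.na(x) | (x >= 0 & x < 0.2),
        dpm_accumulated = function(x) is.na(x) | x >= 0,
        genotype = function(x) x %in% c("WT", "P0"),
        treatment = function(x) x %in% c("water", "SC")
      )
    ),
    litters = list(
      required = c("litter_id", "treatment", "litter_size"),
      optional = "gestational_day",
      character = c("litter_id", "treatment"),
      checks = list(
        litter_size = function(x) !is.na(x) & x >= 1,
        treatment = function(x) x %in% c("water", "SC")
      )
    ),
    plasma = list(
      required = c("dam_id", "time_min", "dpm_per_ul"),
      optional = character(0),
      character = "dam_id",
      rename = c(time = "time_min", concentration = "dpm_per_ul"),
      checks = list(
        time_min = function(x) !is.na(x) & x >= 0,
        dpm_per_ul = function(x) !is.na(x) & x >= 0
      )
    ),
    traces = list(
      required = c("trace_id", "time_s", "velocity_mm_s"),
      optional = character(0),
      character = "trace_id",
      rename = c(time = "time_s", velocity = "velocity_mm_s"),
      checks = list(
        time_s = function(x) !is.na(x) & x >= 0,
        velocity_mm_s = function(x) !is.na(x)
      )
    )
  )
}

#' Read and validate a delimited data table
#'
#' Reads a comma-separated table (UTF-8, header row) against one of the
#' package schemas (`"fetuses"`, `"litters"`, `"plasma"`, `"traces"`). A
#' missing required column is a schema error; rows violating row-level rules
#' (non-positive weights, out-of-range fractions, unknown factor levels, ...)
#' are dropped with a warning that names their file line numbers, and the
#' remainder is loaded. File headers are mapped to in-memory column names
#' (`time_min` -> `time`, `dpm_per_ul` -> `concentration`,
#' `time_s`/`velocity_mm_s` -> `time`/`velocity`).
#'
#' @param path Path to the CSV file.
#' @param schema_name One of `"fetuses"`, `"litters"`, `"plasma"`,
#'   `"traces"`.
#' @return A validated tibble; attribute `"n_rejected"` carries the count of
#'   dropped rows.
#' @export
validate_table <- function(path, schema_name) {
  schemas <- table_schemas()
  if (!schema_name %in% names(schemas)) {
    abort(paste0("unknown schema `", schema_name, "`; available: ",
                 paste(names(schemas), collapse = ", ")))
  }
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  schema <- schemas[[schema_name]]

  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(schema$required, names(tab))
  if (length(missing) > 0) {
    abort(sprintf("schema error in %s: missing required column(s) %s",
                  path, paste(missing, collapse = ", ")))
  }
  for (col in intersect(schema$character, names(tab))) {
    tab[[col]] <- as.character(tab[[col]])
  }
  numeric_cols <- setdiff(c(schema$required, schema$optional),
                          schema$character)
  for (col in intersect(numeric_cols, names(tab))) {
    tab[[col]] <- suppressWarnings(as.numeric(tab[[col]]))
  }

  ok <- rep(TRUE, nrow(tab))
  for (col in names(schema$checks)) {
    if (col %in% names(tab)) ok <- ok & schema$checks[[col]](tab[[col]])
  }
  if (any(!ok)) {
    # +1 for the header row, so numbers match the file
    lines <- which(!ok) + 1L
    warn(sprintf(
      "%s: rejected %d row(s) violating the %s schema (file line%s %s)",
      path, sum(!ok), schema_name, if (sum(!ok) > 1) "s" else "",
      paste(head(lines, 10), collapse = ", ")))
    tab <- tab[ok, , drop = FALSE]
  }
  if (!is.null(schema$rename)) {
    for (new in names(schema$rename)) {
      names(tab)[names(tab) == schema$rename[[new]]] <- new
    }
  }
  attr(tab, "n_rejected") <- sum(!ok)
  tab
}

#' @rdname validate_table
#' @export
read_fetus_table <- function(path) validate_table(path, "fetuses")

#' @rdname validate_table
#' @export
read_plasma_table <- function(path) validate_table(path, "plasma")

#' @rdname validate_table
#' @export
read_trace_table <- function(path) validate_table(path, "traces")

#' Write cohort tables to a directory
#'
#' Writes `litters.csv` and `fetuses.csv` (plus `plasma.csv` and
#' `traces.csv` when supplied) in the package schemas, CSV with header row.
#'
#' @param cohort List with `litters` and `fetuses` tibbles, e.g. from
#'   [generate_cohort()].
#' @param dir Output directory (created if absent).
#' @param plasma Optional plasma tibble (`dam_id`, `time`, `concentration`).
#' @param traces Optional trace tibble (`trace_id`, `time`, `velocity`).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir, plasma = NULL, traces = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    litters = file.path(dir, "litters.csv"),
    fetuses = file.path(dir, "fetuses.csv"))
  readr::write_csv(cohort$litters, paths[["litters"]])
  readr::write_csv(cohort$fetuses, paths[["fetuses"]])
  if (!is.null(plasma)) {
    p <- file.path(dir, "plasma.csv")
    readr::write_csv(
      dplyr::rename(plasma, time_min = "time", dpm_per_ul = "concentration"),
      p)
    paths <- c(paths, plasma = p)
  }
  if (!is.null(traces)) {
    p <- file.path(dir, "traces.csv")
    readr::write_csv(
      dplyr::rename(tibble::as_tibble(traces),
                    time_s = "time", velocity_mm_s = "velocity"), p)
    paths <- c(paths, traces = p)
  }
  invisible(paths)
}
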