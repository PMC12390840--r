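#' Table schemas used across the pipeline
#'
#' Named list of schemas for the delimited (CSV, UTF-8, header row)
#' interchange tables: the co-precipitation table, the geologic record,
#' long-format Raman scans, binary presence maps, reconstruction output,
#' binned output and compiled delta13C series. Each schema lists column
#' names, types (`"numeric"`/`"character"`) and whether they are required;
#' unknown columns in a file are preserved, never dropped.
#'
#' @return Named list of `feoc_schema` objects.
#' @export
feoc_schemas <- function() {
  sch <- function(name, cols, types, required = rep(TRUE, length(cols))) {
    structure(list(name = name,
                   columns = data.frame(name = cols, type = types,
                                        required = required,
                                        stringsAsFactors = FALSE),
                   version = "1"),
              class = "feoc_schema")
  }
  list(
    coprecip = sch("coprecip",
      c("mineral", "endmember", "x", "loading", "d13c_doc", "d13c_feoc",
        "delta13c", "temperature", "pH", "duration", "fe_source",
        "doc_timing", "fraction", "replicate"),
      c("character", "character", "numeric", "numeric", "numeric",
        "numeric", "numeric", "numeric", "numeric", "numeric", "character",
        "character", "character", "numeric")),
    record = sch("record",
      c("sample_id", "formation", "age", "mineral", "loading",
        "loading_sd", "d13c_feoc", "d13c_sd", "palaeolatitude"),
      c("character", "character", "numeric", "character", "numeric",
        "numeric", "numeric", "numeric", "numeric"),
      c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)),
    raman_scan = sch("raman_scan",
      c("pixel_id", "row", "col", "wavenumber", "intensity"),
      c("numeric", "numeric", "numeric", "numeric", "numeric")),
    binary_map = sch("binary_map",
      c("row", "col", "ratio", "presence", "degenerate"),
      c("numeric", "numeric", "numeric", "numeric", "numeric")),
    reconstruction = sch("reconstruction",
      c("sample_id", "formation", "age", "mineral", "x_med", "doc_star",
        "doc_star_lo", "doc_star_hi", "d13c_doc", "d13c_doc_lo",
        "d13c_doc_hi", "f_M", "f_C", "f_FA", "clamped_frac"),
      c("character", "character", "numeric", "character", "numeric",
        "numeric", "numeric", "numeric", "numeric", "numeric", "numeric",
        "numeric", "numeric", "numeric", "numeric")),
    binned = sch("binned",
      c("bin_lo", "bin_hi", "mineral", "n", "mean", "sd"),
      c("numeric", "numeric", "character", "numeric", "numeric",
        "numeric")),
    compiled_d13c = sch("compiled_d13c",
      c("age", "value", "source_class"),
      c("numeric", "numeric", "character")))
}

.validate_table <- function(df, schema, path = "<data>") {
  cols <- schema$columns
  missing <- setdiff(cols$name[cols$required], names(df))
  .assert(length(missing) == 0,
          sprintf("%s: missing required column(s): %s", path,
                  paste(missing, collapse = ", ")),
          "feoc_schema_error")
  for (i in seq_len(nrow(cols))) {
    nm <- cols$name[i]
    if (!nm %in% names(df) || cols$type[i] != "numeric") next
    raw <- df[[nm]]
    if (is.numeric(raw)) next
    parsed <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(parsed) & !is.na(raw) & trimws(raw) != "")
    .assert(length(bad) == 0,
            sprintf("%s: non-numeric value in column '%s' at row %s",
                    path, nm, paste(utils::head(bad, 5), collapse = ", ")),
            "feoc_parse_error")
    df[[nm]] <- parsed
  }
  df
}

#' Read a schema-validated table
#'
#' Reads a comma-separated UTF-8 table, checks required columns, parses
#' numeric columns with a locale-independent decimal point (empty cells
#' become `NA`) and preserves any extra columns verbatim.
#'
#' @param path File path.
#' @param schema A schema from [feoc_schemas()].
#' @return Data frame.
#' @export
read_feoc_table <- function(path, schema) {
  .assert(file.exists(path), sprintf("file not found: %s", path),
          "feoc_data_error")
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                 colClasses = "character", na.strings = character())
  df <- .validate_table(df, schema, path)
  for (nm in names(df)) if (is.character(df[[nm]])) {
    df[[nm]][df[[nm]] == ""] <- NA_character_
  }
  df
}

#' Write a schema-validated table
#'
#' @param df Data frame satisfying the schema.
#' @param schema A schema from [feoc_schemas()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feoc_table <- function(df, schema, path) {
  df <- .validate_table(df, schema, "<data>")
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Serialize a calibration set to structured text
#'
#' Writes fitted parameters, covariances, diagnostics and the selection
#' policy as JSON at full double precision, so a written-then-read set
#' evaluates bit-identically.
#'
#' @param set A `feoc_calibration_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calibration <- function(set, path) {
  .assert(inherits(set, "feoc_calibration_set"),
          "set must be a calibration set", "feoc_data_error")
  ser <- list(schema_version = "1",
              selection_policy = set$selection_policy,
              exclusions = as.list(set$exclusions),
              fits = lapply(set$fits, function(f) {
                list(loading = unclass(f$loading),
                     delta = unclass(f$delta))
              }))
  # 17 significant digits round-trips IEEE doubles exactly
  json <- jsonlite::toJSON(ser, digits = I(17), auto_unbox = TRUE,
                           pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Read a serialized calibration set
#'
#' @param path Path written by [write_calibration()].
#' @return A `feoc_calibration_set`.
#' @export
read_calibration <- function(path) {
  .assert(file.exists(path), sprintf("file not found: %s", path),
          "feoc_data_error")
  ser <- jsonlite::fromJSON(readLines(path), simplifyVector = TRUE)
  fits <- lapply(ser$fits, function(f) {
    lf <- f$loading; df <- f$delta
    lf$covariance <- matrix(unlist(lf$covariance), 2, 2,
                            dimnames = list(c("log_k", "n"),
                                            c("log_k", "n")))
    nm <- c("a1", "a2", "log_x1", "log_x2")
    df$covariance <- matrix(unlist(df$covariance), 4, 4,
                            dimnames = list(nm, nm))
    list(loading = structure(lf, class = "feoc_loading_fit"),
         delta = structure(df, class = "feoc_delta_fit"))
  })
  structure(list(fits = fits, selection_policy = ser$selection_policy,
                 exclusions = unlist(ser$exclusions)),
            class = "feoc_calibration_set")
}

#' Convert fraction modern to an uncalibrated radiocarbon age
#'
#' `age = -8033 * ln(Fm)`, in 14C yr BP; strictly decreasing in Fm, zero
#' at Fm = 1.
#'
#' @param Fm Fraction modern, positive.
#' @return Age in 14C yr BP.
#' @export
fm_to_age <- function(Fm) {
  .assert(all(Fm > 0), "Fm must be positive", "feoc_domain_error")
  -8033 * log(Fm) + 0  # + 0 normalizes the signed zero at Fm = 1
}
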