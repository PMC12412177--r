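#' Read arrival-time-distribution data
#'
#' Reads a collection of ATD traces from disk. Two dialects are supported:
#'
#' * `"csv_long"` (canonical): a CSV with columns `analyte`, `t_s`, `time`,
#'   `intensity` and optional `mz`, `charge`. One row per sampled point;
#'   one trace per (analyte, t_s) block.
#' * `"xlsx_sheets"`: an XLSX workbook with one sheet per trace, named
#'   `<analyte>__ts<t_s>` (a single underscore before `ts` is also
#'   accepted), each sheet holding two columns `drift_time_ms` and
#'   `intensity`. Requires the readxl package.
#'
#' With `dialect = "auto"` the file extension decides (.csv vs .xlsx).
#'
#' @param path Path to the file.
#' @param dialect One of `"auto"`, `"csv_long"`, `"xlsx_sheets"`.
#' @return A named list of [atd_trace] objects, in file order.
#' @export
read_atd_workbook <- function(path,
                              dialect = c("auto", "csv_long", "xlsx_sheets")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.xlsx$", path, ignore.case = TRUE))
      "xlsx_sheets" else "csv_long"
  }
  switch(dialect,
         csv_long = read_atd_csv_long(path),
         xlsx_sheets = read_atd_xlsx(path))
}

read_atd_csv_long <- function(path) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, strip.white = TRUE)
  need <- c("analyte", "t_s", "time", "intensity")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("format error in '", basename(path), "': missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(names(raw))) {
    stop("format error in '", basename(path), "': duplicated column header(s) ",
         paste(unique(names(raw)[duplicated(names(raw))]), collapse = ", "),
         call. = FALSE)
  }
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) &
                   !(raw[[col]] %in% c("", "NA")))
    if (length(bad)) {
      stop("parse error in '", basename(path), "': non-numeric value '",
           raw[[col]][bad[1]], "' in column '", col, "', row ",
           bad[1] + 1L, call. = FALSE)  # +1 for the header line
    }
    v
  }
  t_s <- num("t_s"); tm <- num("time"); y <- num("intensity")
  mz <- if ("mz" %in% names(raw)) num("mz") else rep(NA_real_, nrow(raw))
  z <- if ("charge" %in% names(raw)) num("charge") else rep(NA_real_, nrow(raw))
  key <- paste(raw$analyte, t_s, sep = "\r")
  idx <- split(seq_len(nrow(raw)), factor(key, levels = unique(key)))
  traces <- lapply(idx, function(i) {
    o <- i[order(tm[i])]
    atd_trace(raw$analyte[o[1]], t_s[o[1]], tm[o], y[o],
              mz = mz[o[1]],
              charge = if (is.na(z[o[1]])) NA_integer_ else as.integer(z[o[1]]))
  })
  names(traces) <- vapply(traces, function(tr)
    sprintf("%s__ts%g", tr$analyte_id, tr$separation_time), character(1))
  traces
}

read_atd_xlsx <- function(path) {
  if (!requireNamespace("readxl", quietly = TRUE)) {
    stop("reading .xlsx requires the readxl package; ",
         "use the CSV long format instead", call. = FALSE)
  }
  sheets <- readxl::excel_sheets(path)
  traces <- lapply(sheets, function(sh) {
    m <- regmatches(sh, regexec("^(.*?)_{1,2}ts([0-9.]+)$", sh))[[1]]
    if (length(m) != 3L) {
      stop("format error: sheet '", sh,
           "' does not match '<analyte>__ts<t_s>'", call. = FALSE)
    }
    df <- as.data.frame(readxl::read_xlsx(path, sheet = sh,
                                          col_types = "text"))
    need <- c("drift_time_ms", "intensity")
    if (!all(need %in% names(df))) {
      stop("format error: sheet '", sh, "' must have columns ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    num <- function(col, colletter) {
      v <- suppressWarnings(as.numeric(df[[col]]))
      bad <- which(is.na(v) & !is.na(df[[col]]))
      if (length(bad)) {
        stop("parse error in sheet '", sh, "': non-numeric value '",
             df[[col]][bad[1]], "' at cell ", colletter, bad[1] + 1L,
             call. = FALSE)
      }
      v
    }
    tm <- num("drift_time_ms", "A"); y <- num("intensity", "B")
    o <- order(tm)
    atd_trace(m[2], as.numeric(m[3]), tm[o], y[o])
  })
  names(traces) <- sheets
  traces
}

#' Write ATD traces to the canonical CSV long format
#'
#' Writes one row per sampled point with columns `analyte`, `t_s`, `time`,
#' `intensity` and, when present on any trace, `mz` and `charge`. Output is
#' deterministic for identical input (trace order preserved, full-precision
#' decimal formatting), so repeated writes are byte-identical.
#'
#' @param traces List of [atd_trace] objects.
#' @param path Output file path (.csv).
#' @return `path`, invisibly.
#' @export
write_atd_workbook <- function(traces, path) {
  if (inherits(traces, "atd_trace")) traces <- list(traces)
  rows <- lapply(traces, function(tr) {
    data.frame(analyte = tr$analyte_id, t_s = tr$separation_time,
               time = tr$times, intensity = tr$intensities,
               mz = tr$mz, charge = tr$charge,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (all(is.na(df$mz))) df$mz <- NULL
  if (all(is.na(df$charge))) df$charge <- NULL
  num_cols <- vapply(df, is.numeric, logical(1))
  df[num_cols] <- lapply(df[num_cols], function(v)
    ifelse(is.na(v), "NA", formatC(v, digits = 15, format = "g")))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a calibrant list
#'
#' Reads a CSV with one calibrant standard per row. Required columns:
#' `name`, `mz`, `charge` and a reference CCS column (`ccs`, `ccs_ref`, or
#' `ccs_a2`), in squared Angstroms. An optional `adduct` column is carried
#' through.
#'
#' @param path Path to the CSV file.
#' @return A data.frame with columns `name`, `mz`, `charge`, `ccs_ref` and
#'   optionally `adduct`, in file order.
#' @export
read_calibrant_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, strip.white = TRUE, stringsAsFactors = FALSE)
  ccs_col <- intersect(c("ccs", "ccs_ref", "ccs_a2"), names(df))[1]
  missing_cols <- setdiff(c("name", "mz", "charge"), names(df))
  if (is.na(ccs_col)) missing_cols <- c(missing_cols, "ccs")
  if (length(missing_cols)) {
    stop("format error in '", basename(path), "': missing column(s) ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- data.frame(name = as.character(df$name),
                    mz = as.numeric(df$mz),
                    charge = as.integer(df$charge),
                    ccs_ref = as.numeric(df[[ccs_col]]),
                    stringsAsFactors = FALSE)
  if ("adduct" %in% names(df)) out$adduct <- as.character(df$adduct)
  if (anyDuplicated(out$name)) {
    stop("duplicate calibrant name(s): ",
         paste(unique(out$name[duplicated(out$name)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- which(!is.finite(out$ccs_ref) | out$ccs_ref <= 0)
  if (length(bad)) {
    stop("invalid reference CCS (must be > 0) for calibrant(s): ",
         paste(out$name[bad], collapse = ", "), call. = FALSE)
  }
  if (any(out$charge < 1L, na.rm = TRUE)) {
    stop("calibrant charge must be >= 1", call. = FALSE)
  }
  out
}

curve_format_tag <- "cimscal-curve/1"

#' Persist and reload a calibration curve
#'
#' Saves a [ccs_calibration] object as a versioned JSON document and loads
#' it back. The JSON carries the power-law coefficients, mode, gas mass,
#' fit diagnostics and the full calibrant audit table; numeric fields
#' round-trip to better than 1e-12 relative (17 significant digits).
#'
#' @param curve A `ccs_calibration` object (see [build_curve]).
#' @param path Output/input JSON path.
#' @return `persist_curve` returns `path` invisibly; `load_curve` returns
#'   the restored `ccs_calibration`.
#' @export
persist_curve <- function(curve, path) {
  stopifnot(inherits(curve, "ccs_calibration"))
  doc <- list(
    format = curve_format_tag,
    A = curve$A, B = curve$B, mode = curve$mode,
    gas_mass = curve$gas_mass, fit_r_squared = curve$fit_r_squared,
    drift_range = curve$drift_range,
    calibrant_table = curve$calibrant_table,
    created_with = curve$created_with
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = 17,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname persist_curve
#' @export
load_curve <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop("format error: '", basename(path),
                         "' is not a valid calibration-curve JSON document (",
                         conditionMessage(e), ")", call. = FALSE)
                  })
  if (is.null(doc$format) || !identical(doc$format, curve_format_tag)) {
    stop("unsupported calibration-curve format",
         if (!is.null(doc$format)) paste0(" '", doc$format, "'"),
         "; expected '", curve_format_tag, "'", call. = FALSE)
  }
  new_ccs_calibration(
    A = doc$A, B = doc$B, mode = doc$mode, gas_mass = doc$gas_mass,
    fit_r_squared = doc$fit_r_squared,
    drift_range = as.numeric(doc$drift_range),
    calibrant_table = as.data.frame(doc$calibrant_table),
    created_with = doc$created_with,
    fit = NULL
  )
}

#' Write a results table
#'
#' Writes CCS results as CSV in input row order. An optional comment line
#' with a timestamp is prepended; suppress it for bit-stable output.
#'
#' @param results Data.frame of results (see [process_traces]).
#' @param path Output CSV path.
#' @param timestamp Prepend a `# generated ...` comment line?
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, timestamp = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  if (timestamp) {
    writeLines(sprintf("# generated %s by cimscal", format(Sys.time())), con)
  }
  utils::write.csv(results, con, row.names = FALSE)
  invisible(path)
}
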