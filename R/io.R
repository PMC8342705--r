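# Reading, validation and replicate aggregation of the measurement tables.
#
# Canonical CSV schemas (comma-separated, UTF-8, "." decimal, header
# required; Unicode minus signs are normalised on read):
#   measurements.csv: sample_id,temperature_C,epsilon_r,run
#   aux.csv:          sample_id,quantity,value,run
# with quantity one of "zeta_mV", "enthalpy_J_per_g_degC".

.AUX_QUANTITIES <- c("zeta_mV", "enthalpy_J_per_g_degC")

.read_normalised_csv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  # map Unicode minus (U+2212) and non-breaking space to ASCII
  lines <- gsub("−", "-", lines, fixed = TRUE)
  lines <- gsub(" ", " ", lines, fixed = TRUE)
  utils::read.csv(text = paste(lines, collapse = "\n"),
                  stringsAsFactors = FALSE, colClasses = "character",
                  strip.white = TRUE)
}

.require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  }
}

#' Read a dielectric measurement table
#'
#' Reads and validates the canonical measurement CSV
#' (`sample_id,temperature_C,epsilon_r,run`). Rows with non-numeric
#' cells, non-positive permittivity, temperatures outside the declared
#' instrument range, or non-positive run indices are rejected with a
#' warning naming their file line numbers; duplicate
#' (sample, temperature, run) keys and missing columns are errors.
#'
#' @param path Path to a CSV file.
#' @param temperature_range Allowed instrument range, degrees Celsius.
#' @return A data.frame of validated records (columns `sample_id`,
#'   `temperature_C`, `epsilon_r`, `run`), with attribute
#'   `rejected_lines` (integer vector of 1-based file line numbers).
#' @export
read_measurements <- function(path, temperature_range = c(0, 100)) {
  df <- .read_normalised_csv(path)
  .require_columns(df, c("sample_id", "temperature_C", "epsilon_r", "run"), path)
  n <- nrow(df)
  out <- data.frame(sample_id = df$sample_id,
                    temperature_C = suppressWarnings(as.numeric(df$temperature_C)),
                    epsilon_r = suppressWarnings(as.numeric(df$epsilon_r)),
                    run = suppressWarnings(as.integer(df$run)),
                    stringsAsFactors = FALSE)
  bad <- !nzchar(out$sample_id) |
    is.na(out$temperature_C) | is.na(out$epsilon_r) | is.na(out$run) |
    out$epsilon_r <= 0 | out$run < 1 |
    out$temperature_C < temperature_range[1] |
    out$temperature_C > temperature_range[2]
  if (any(bad)) {
    lines <- which(bad) + 1L  # +1 for the header line
    warning("rejected ", sum(bad), " malformed row(s) at line(s): ",
            paste(lines, collapse = ", "))
    out <- out[!bad, , drop = FALSE]
  }
  key <- paste(out$sample_id, out$temperature_C, out$run, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- which(duplicated(key) | duplicated(key, fromLast = TRUE))
    stop("duplicate (sample_id, temperature_C, run) key(s) in ", path,
         " at data row(s): ", paste(sort(dup), collapse = ", "))
  }
  rownames(out) <- NULL
  attr(out, "rejected_lines") <- if (any(bad)) which(bad) + 1L else integer(0)
  out
}

#' Read an auxiliary (zeta potential / DSC enthalpy) table
#'
#' Reads and validates the canonical auxiliary CSV
#' (`sample_id,quantity,value,run`). `quantity` must be one of
#' `"zeta_mV"` or `"enthalpy_J_per_g_degC"`.
#'
#' @param path Path to a CSV file.
#' @return A data.frame of validated records with attribute
#'   `rejected_lines` as in [read_measurements()].
#' @export
read_aux <- function(path) {
  df <- .read_normalised_csv(path)
  .require_columns(df, c("sample_id", "quantity", "value", "run"), path)
  out <- data.frame(sample_id = df$sample_id,
                    quantity = df$quantity,
                    value = suppressWarnings(as.numeric(df$value)),
                    run = suppressWarnings(as.integer(df$run)),
                    stringsAsFactors = FALSE)
  bad <- !nzchar(out$sample_id) | !(out$quantity %in% .AUX_QUANTITIES) |
    is.na(out$value) | is.na(out$run) | out$run < 1
  if (any(bad)) {
    warning("rejected ", sum(bad), " malformed row(s) at line(s): ",
            paste(which(bad) + 1L, collapse = ", "))
    out <- out[!bad, , drop = FALSE]
  }
  key <- paste(out$sample_id, out$quantity, out$run, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate (sample_id, quantity, run) key(s) in ", path)
  }
  rownames(out) <- NULL
  attr(out, "rejected_lines") <- if (any(bad)) which(bad) + 1L else integer(0)
  out
}

#' Write a measurement or auxiliary table
#'
#' Writes the canonical CSV so that reading it back with
#' [read_measurements()] / [read_aux()] is value-identical.
#'
#' @param df A data.frame in one of the canonical schemas.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Aggregate replicate runs
#'
#' Averages replicate runs per (sample, temperature) for dielectric
#' records or per (sample, quantity) for auxiliary records. The spread is
#' 0 for a single run, half the range for two runs (matching the
#' two-run repeatability bars of the dielectric sweeps), and the sample
#' standard deviation for three or more replicates (matching the
#' triplicate zeta-potential tables).
#'
#' @param records A data.frame from [read_measurements()] or
#'   [read_aux()] (detected by its columns).
#' @return A data.frame with the grouping columns, `n_runs`, `mean`, and
#'   `spread`. Order of input rows does not affect the result.
#' @export
average_runs <- function(records) {
  stopifnot(is.data.frame(records))
  if (all(c("temperature_C", "epsilon_r") %in% names(records))) {
    keys <- c("sample_id", "temperature_C"); valcol <- "epsilon_r"
  } else if (all(c("quantity", "value") %in% names(records))) {
    keys <- c("sample_id", "quantity"); valcol <- "value"
  } else {
    stop("unrecognised record schema: need dielectric or auxiliary columns")
  }
  if (nrow(records) == 0L) {
    out <- records[keys]
    out$n_runs <- integer(0); out$mean <- numeric(0); out$spread <- numeric(0)
    return(out)
  }
  split_key <- interaction(records[keys], drop = TRUE, lex.order = TRUE)
  idx <- split(seq_len(nrow(records)), split_key)
  groups <- lapply(idx, function(i) records[[valcol]][i])
  keydf <- records[vapply(idx, `[`, integer(1), 1L), keys, drop = FALSE]
  agg <- data.frame(keydf,
                    n_runs = vapply(groups, length, integer(1)),
                    mean = vapply(groups, mean, numeric(1)),
                    spread = vapply(groups, function(v) {
                      if (length(v) == 1L) 0
                      else if (length(v) == 2L) diff(range(v)) / 2
                      else stats::sd(v)
                    }, numeric(1)),
                    stringsAsFactors = FALSE)
  rownames(agg) <- NULL
  agg
}

#' Format a value at a table's printed precision
#'
#' The source report's tables truncate toward zero rather than round
#' (e.g. a mean of -19.1667 mV printed as -19.1, 6.6867 mV as 6.68), so
#' truncation is the default; rounding is available.
#'
#' @param x Numeric vector.
#' @param digits Decimal places of the printed table.
#' @param style `"trunc"` (truncate toward zero, default) or `"round"`.
#' @return Numeric vector at the printed precision.
#' @export
printed_value <- function(x, digits = 2, style = c("trunc", "round")) {
  style <- match.arg(style)
  if (style == "round") return(round(x, digits))
  v <- x * 10^digits
  # snap values within representation error of an integer before truncating
  snap <- abs(v - round(v)) <= 1e-8 * pmax(1, abs(v))
  v[snap] <- round(v[snap])
  trunc(v) / 10^digits
}
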