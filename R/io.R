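## Trace and report IO. Traces travel as two-column CSV (time_ms, current)
## with an optional '#' header block recording conditions, or as Axon Text
## Files (ATF): a "ATF\t1.0" signature line, a "nHeaderLines\tnColumns"
## line, quoted header records, a column-title line, then tab-separated
## data. Time at IO boundaries is in milliseconds, 0-referenced to the
## first sample.

#' Write a current trace
#'
#' @param trace a [CurrentTrace-class]
#' @param path output file
#' @param conditions optional named list/vector recorded in the header
#' @param format "csv" or "atf"
#' @return the path, invisibly
#' @export
writeTrace <- function(trace, path, conditions = NULL,
                       format = c("csv", "atf")) {
  format <- match.arg(format)
  t <- trace@times - trace@times[1]
  df <- data.frame(time_ms = t, current = trace@current)
  if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(conditions))
      writeLines(sprintf("# %s: %s", names(conditions),
                         vapply(conditions, base::format, "")), con)
    if (nrow(trace@annotations))
      writeLines(sprintf("# event %s: %s ms", trace@annotations$label,
                         format(trace@annotations$time_ms)), con)
    writeLines("time_ms,current", con)
    utils::write.table(format(df, digits = 15, trim = TRUE,
                              scientific = FALSE),
                       con, sep = ",", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  } else {
    hdr <- c(sprintf("\"Comment=%s\"",
                     if (is.null(conditions)) "slc1kin trace" else
                       paste(names(conditions), unlist(conditions),
                             sep = "=", collapse = "; ")),
             "\"SweepStartTimesMS=0\"")
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("ATF\t1.0", sprintf("%d\t%d", length(hdr), 2L), hdr,
                 "\"Time (ms)\"\t\"Current ()\""), con)
    utils::write.table(format(df, digits = 15, trim = TRUE,
                              scientific = FALSE),
                       con, sep = "\t", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

.parseNumericRows <- function(lines, firstLine, sep, path) {
  parts <- strsplit(lines, sep, fixed = (sep != ""))
  nf <- lengths(parts)
  if (any(nf != nf[1])) {
    bad <- which(nf != nf[1])[1]
    stop("jagged row in ", path, " at line ", firstLine + bad - 1,
         ": expected ", nf[1], " fields, found ", nf[bad], call. = FALSE)
  }
  vals <- suppressWarnings(
    matrix(as.numeric(unlist(parts)), ncol = nf[1], byrow = TRUE))
  if (anyNA(vals)) {
    bad <- which(apply(vals, 1, anyNA))[1]
    stop("non-numeric data in ", path, " at line ", firstLine + bad - 1,
         call. = FALSE)
  }
  vals
}

#' Read a current trace from CSV or ATF
#'
#' Accepts two-column CSV (optional '#' comment block and header row) and
#' Axon Text Files (tab-separated, header block per the ATF convention;
#' format auto-detected from the signature line). Times are converted to
#' ms, 0-referenced, and validated as strictly increasing with uniform
#' sampling.
#'
#' @param path input file
#' @return a [CurrentTrace-class]
#' @export
readTrace <- function(path) {
  if (!file.exists(path)) stop("trace file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty trace file: ", path)
  if (startsWith(lines[1], "ATF")) {
    if (length(lines) < 2) stop("truncated ATF file: ", path)
    counts <- suppressWarnings(as.integer(strsplit(lines[2], "\t")[[1]]))
    nHdr <- counts[1]
    dataStart <- 3L + nHdr + 1L          # signature, counts, headers, titles
    body <- lines[dataStart:length(lines)]
    vals <- .parseNumericRows(body, dataStart, "\t", path)
  } else {
    keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
    body <- lines[keep]
    lineNo <- which(keep)
    firstFields <- strsplit(body[1], ",", fixed = TRUE)[[1]]
    hasHeader <- anyNA(suppressWarnings(as.numeric(firstFields)))
    if (hasHeader) { body <- body[-1]; lineNo <- lineNo[-1] }
    if (!length(body)) stop("no data rows in ", path)
    vals <- .parseNumericRows(body, lineNo[1], ",", path)
    ## report jagged/non-numeric errors with true file line numbers
  }
  if (ncol(vals) < 2) stop("expected two columns (time, current) in ", path)
  t <- vals[, 1]; i <- vals[, 2]
  if (any(diff(t) <= 0)) {
    bad <- which(diff(t) <= 0)[1] + 1
    stop("non-monotone time column in ", path, " at data row ", bad,
         call. = FALSE)
  }
  new("CurrentTrace", times = t - t[1], current = i)
}

## ---------------------------------------------------------------------------
## Fit reports

.fitToList <- function(fit) {
  if (is(fit, "DoseResponseFit"))
    list(type = "dose_response",
         parameters = list(I1 = fit@I1, I2 = fit@I2, Ki = fit@Ki,
                           residual_fraction = fit@residualFraction),
         se = as.list(fit@se), partial = fit@partial, status = fit@status)
  else if (is(fit, "MMFit"))
    list(type = "michaelis_menten",
         parameters = list(Km = fit@Km, Imax = fit@Imax),
         se = as.list(fit@se), non_saturating = fit@nonSaturating)
  else if (is(fit, "BiexpFit"))
    list(type = "biexponential",
         parameters = list(I1 = fit@I1, I2 = fit@I2, tau_rise = fit@tauRise,
                           tau_decay = fit@tauDecay,
                           baseline = fit@baseline),
         rss = fit@rss, se = as.list(fit@se), status = fit@status)
  else if (is(fit, "MechanismCall"))
    list(type = "mechanism", verdict = fit@verdict,
         parameters = list(Ki0 = fit@Ki0, slope_stat = fit@slopeStat),
         residuals = as.list(fit@residuals))
  else if (is(fit, "QVFit"))
    list(type = "boltzmann_qv",
         parameters = list(Qmax = fit@Qmax, Vhalf = fit@Vhalf,
                           z_app = fit@zApp, offset = fit@offset),
         se = as.list(fit@se), converged = fit@converged,
         saturated_warning = fit@saturatedWarning)
  else if (is(fit, "RecoveryFit"))
    list(type = "recovery",
         parameters = list(tau_ms = fit@tau, amplitude = fit@amplitude),
         se = as.list(fit@se), data = fit@data)
  else stop("unsupported fit object of class ", class(fit))
}

#' Write a JSON fit report
#'
#' @param fit a fit object (dose-response, MM, biexponential, mechanism,
#'   Q-V or recovery fit)
#' @param path output JSON path
#' @param input optional input dataset path; its MD5 checksum is recorded
#' @return the path, invisibly
#' @export
writeFitReport <- function(fit, path, input = NULL) {
  rep <- .fitToList(fit)
  if (!is.null(input) && file.exists(input))
    rep$input_checksum <- unname(tools::md5sum(input))
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}
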