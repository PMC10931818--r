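#' Fluorescence trace matrix for one session
#'
#' @param values neurons x samples numeric matrix (dF or z-units), no NAs.
#' @param neuron_ids character vector, one per row (defaults to rownames).
#' @param session_id session identifier.
#' @param sampling_rate sampling rate in Hz (default 10).
#' @param zscored whether rows are already standardized.
#' @return Object of class `trace_matrix`.
#' @export
trace_matrix <- function(values, neuron_ids = rownames(values),
                         session_id = "s1", sampling_rate = 10,
                         zscored = FALSE) {
  values <- as.matrix(values)
  if (anyNA(values)) stop("trace matrix contains missing samples")
  if (is.null(neuron_ids)) neuron_ids <- paste0("n", seq_len(nrow(values)))
  if (length(neuron_ids) != nrow(values)) stop("one neuron_id per row required")
  rownames(values) <- neuron_ids
  structure(list(session_id = session_id, neuron_ids = as.character(neuron_ids),
                 values = values, sampling_rate = sampling_rate,
                 zscored = isTRUE(zscored)),
            class = "trace_matrix")
}

#' @export
print.trace_matrix <- function(x, ...) {
  cat(sprintf("trace_matrix %s: %d neurons x %d samples @ %g Hz%s\n",
              x$session_id, nrow(x$values), ncol(x$values), x$sampling_rate,
              if (x$zscored) " (z-scored)" else ""))
  invisible(x)
}

#' Standardize traces per neuron within a session
#'
#' Z-scores each row of the trace matrix independently (sample-sd
#' convention), matching the per-session normalization applied before any
#' peri-event analysis. Constant rows are left at zero and flagged in the
#' `constant_rows` attribute of the result.
#'
#' @param tm a [trace_matrix] not yet z-scored.
#' @return A z-scored [trace_matrix].
#' @export
zscore_traces <- function(tm) {
  stopifnot(inherits(tm, "trace_matrix"))
  if (tm$zscored) stop("traces are already z-scored")
  mu <- rowMeans(tm$values)
  sdv <- apply(tm$values, 1, stats::sd)
  flat <- sdv < .Machine$double.eps
  sdv[flat] <- 1
  vals <- (tm$values - mu) / sdv
  vals[flat, ] <- 0
  out <- trace_matrix(vals, tm$neuron_ids, tm$session_id, tm$sampling_rate,
                      zscored = TRUE)
  attr(out, "constant_rows") <- tm$neuron_ids[flat]
  out
}

#' Write / read a trace matrix as wide delimited text
#'
#' First column `neuron_id`, remaining columns one per sample. A header
#' comment line stores the sampling rate.
#'
#' @param tm a [trace_matrix].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_traces <- function(tm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# session_id=%s sampling_rate=%g zscored=%d",
                     tm$session_id, tm$sampling_rate, as.integer(tm$zscored)), con)
  df <- data.frame(neuron_id = tm$neuron_ids, tm$values, check.names = FALSE)
  utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  hdr <- readLines(path, n = 1L)
  meta <- regmatches(hdr, gregexpr("[a-z_]+=[^ ]+", hdr))[[1]]
  kv <- strsplit(meta, "=")
  vals <- stats::setNames(vapply(kv, `[`, "", 2), vapply(kv, `[`, "", 1))
  df <- utils::read.table(path, header = TRUE, sep = "\t", skip = 1L,
                          check.names = FALSE)
  trace_matrix(as.matrix(df[, -1, drop = FALSE]), df$neuron_id,
               session_id = vals[["session_id"]],
               sampling_rate = as.numeric(vals[["sampling_rate"]]),
               zscored = vals[["zscored"]] == "1")
}
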