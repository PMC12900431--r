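#' Timestamped beat annotations
#'
#' Container for a sequence of annotated beats: sinus (`N`) or ectopic (`V`),
#' each expressed or blocked, with an optional morphology id per beat
#' (clinical annotation pipelines label the QRS shape of each PVC).
#'
#' @param times beat times in seconds, non-decreasing; strictly increasing
#'   among expressed beats.
#' @param labels character vector, `"N"` or `"V"`.
#' @param expressed logical vector (default all TRUE).
#' @param morph optional morphology ids (character), `NA` allowed.
#' @param id optional record identifier.
#' @return a `beat_record`: data.frame with columns `time`, `label`,
#'   `expressed`, and `morph` when supplied.
#' @export
beat_record <- function(times, labels, expressed = TRUE, morph = NULL,
                        id = NULL) {
  n <- length(times)
  expressed <- rep_len(expressed, n)
  if (length(labels) != n) stop("`labels` length mismatch", call. = FALSE)
  if (!all(labels %in% c("N", "V")))
    stop("labels must be 'N' or 'V'", call. = FALSE)
  o <- order(times)
  times <- times[o]; labels <- labels[o]; expressed <- expressed[o]
  if (!is.null(morph)) morph <- rep_len(morph, n)[o]
  tx <- times[expressed]
  if (length(tx) > 1 && any(diff(tx) <= 0))
    stop("expressed beat times must be strictly increasing", call. = FALSE)
  df <- data.frame(time = times, label = labels, expressed = expressed)
  if (!is.null(morph)) df$morph <- morph
  structure(df, class = c("beat_record", "data.frame"), id = id)
}

#' @export
print.beat_record <- function(x, ...) {
  cat(sprintf("<beat_record: %d beats (%d N, %d V; %d expressed), %.1f s>\n",
              nrow(x), sum(x$label == "N"), sum(x$label == "V"),
              sum(x$expressed),
              if (nrow(x)) diff(range(x$time)) else 0))
  invisible(x)
}

# expressed beats only, as a plain data.frame
expressed_beats <- function(record) {
  as.data.frame(record)[record$expressed, , drop = FALSE]
}

#' Read a beat-annotation CSV
#'
#' Accepts `time_s,label,expressed` (and optionally `morph`); a two-column
#' `time_s,label` file is read with all beats taken as expressed.
#'
#' @param path file path.
#' @return a [beat_record].
#' @export
read_beat_record <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("time_s", "label") %in% names(df)))
    stop("beat file must have columns `time_s` and `label`", call. = FALSE)
  expressed <- if ("expressed" %in% names(df)) as.logical(df$expressed) else TRUE
  morph <- if ("morph" %in% names(df)) as.character(df$morph) else NULL
  beat_record(df$time_s, df$label, expressed, morph)
}

#' Write a beat record to CSV
#'
#' @param record a [beat_record].
#' @param path output path.
#' @export
write_beat_record <- function(record, path) {
  df <- as.data.frame(record)
  names(df)[names(df) == "time"] <- "time_s"
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read beats from a textual WFDB-style annotation listing
#'
#' Parses the plain-text listing produced by WFDB's `rdann -v` (columns:
#' elapsed time, sample number, annotation symbol, ...). Beat codes `N` and
#' `V` are kept; all other symbols are dropped with a message stating the
#' count. Elapsed times may be `ss.mmm`, `mm:ss.mmm`, or `hh:mm:ss.mmm`.
#'
#' @param path file path.
#' @return a [beat_record] (all beats expressed).
#' @export
read_wfdb_annotations <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^(Time|#)", lines)]
  parts <- strsplit(lines, "[[:space:]]+")
  parts <- parts[vapply(parts, length, integer(1)) >= 3]
  tm <- vapply(parts, function(p) {
    f <- as.numeric(strsplit(p[1], ":", fixed = TRUE)[[1]])
    sum(f * rev(60^(seq_along(f) - 1)))
  }, numeric(1))
  sym <- vapply(parts, `[[`, character(1), 3L)
  keep <- sym %in% c("N", "V")
  if (any(!keep))
    message(sum(!keep), " non-beat annotations dropped")
  beat_record(tm[keep], sym[keep])
}

#' Tagged interval series, NIB sequence and coupling intervals
#'
#' Computes, over expressed beats only: the consecutive-beat intervals tagged
#' by their flanking labels (NN, NV, VN, VV), the NIB sequence (number of
#' intervening sinus beats between consecutive V beats), and the coupling
#' interval of each V beat (the NV interval from the immediately preceding
#' expressed sinus beat).
#'
#' @param record a [beat_record].
#' @return list with `intervals` (`data.frame time, interval, type` where
#'   `time` is the interval start), `nib` (integer vector), `coupling`
#'   (`data.frame time, ci`: time of each V preceded by an N and its coupling
#'   interval). All elements empty when fewer than 2 expressed beats.
#' @export
interval_series <- function(record) {
  eb <- expressed_beats(record)
  empty <- list(intervals = data.frame(time = numeric(0),
                                       interval = numeric(0),
                                       type = character(0)),
                nib = integer(0),
                coupling = data.frame(time = numeric(0), ci = numeric(0)))
  if (nrow(eb) < 2) return(empty)
  n <- nrow(eb)
  iv <- data.frame(time = eb$time[-n],
                   interval = diff(eb$time),
                   type = paste0(eb$label[-n], eb$label[-1]))
  vi <- which(eb$label == "V")
  nib <- if (length(vi) >= 2) {
    vapply(seq_len(length(vi) - 1), function(k)
      sum(eb$label[(vi[k] + 1):(vi[k + 1] - 1)] == "N"), integer(1))
  } else integer(0)
  cp <- vi[vi > 1]
  cp <- cp[eb$label[cp - 1] == "N"]
  coupling <- data.frame(time = eb$time[cp],
                         ci = eb$time[cp] - eb$time[cp - 1])
  list(intervals = iv, nib = nib, coupling = coupling)
}

#' PVC burden of a beat record
#'
#' Percentage of expressed beats that are ectopic:
#' `100 * V / (N + V)` over expressed beats.
#'
#' @param record a [beat_record].
#' @return burden in percent, in \[0, 100\].
#' @export
pvc_burden <- function(record) {
  eb <- expressed_beats(record)
  if (!nrow(eb)) stop("no expressed beats: burden undefined", call. = FALSE)
  100 * sum(eb$label == "V") / nrow(eb)
}
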