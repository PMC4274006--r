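## Trace quality control: windowed end-trimming, trace score (TS), contiguous
## read length (CRL), quality levels and per-region success-rate reporting.

empty_trim <- function(read) {
  structure(list(read_id = read$read_id, sample_id = read$sample_id,
                 locus_id = read$locus_id, individual = read$individual,
                 direction = read$direction, start = NA_integer_,
                 end = NA_integer_, bases = "", qv = integer(0),
                 secondary_fraction = numeric(0), second_base = character(0),
                 empty = TRUE),
            class = "trimmed_read")
}

#' Trim low-quality read ends
#'
#' From each end, the trim point advances inward one base at a time until the
#' terminal window of `window` bases contains fewer than `max_bad` bases that
#' are low quality (`qv < qv_floor`) or ambiguous (not `A`, `C`, `G` or `T`).
#' The 5' end is scanned first; the 3' scan then runs on the remaining
#' interval. If no interval satisfies the rule an explicit empty-trim marker
#' is returned (never an error).
#'
#' @param read a `quality_read`.
#' @param window window width in bases (shrinks to the read/interval length
#'   when longer).
#' @param qv_floor bases with quality below this count as bad.
#' @param max_bad a terminal window is acceptable when it holds fewer than
#'   this many bad bases.
#' @return A `trimmed_read` with `start`/`end` (1-based, inclusive, on the
#'   original read) and the retained slices, or an empty-trim marker
#'   (`$empty == TRUE`).
#' @export
trim_read <- function(read, window = 25L, qv_floor = 25L, max_bad = 3L) {
  n <- nchar(read$bases)
  if (n == 0) return(empty_trim(read))
  ch <- split_string(read$bases)
  bad <- read$qv < qv_floor | !(ch %in% c("A", "C", "G", "T"))
  w <- min(window, n)
  cs <- cumsum(c(0L, bad))
  win_bad <- function(s, width) cs[s + width] - cs[s]  # bad count in [s, s+width-1]

  start <- NA_integer_
  for (s in seq_len(n - w + 1L)) {
    if (win_bad(s, w) < max_bad) { start <- s; break }
  }
  if (is.na(start)) return(empty_trim(read))

  w2 <- min(window, n - start + 1L)
  end <- NA_integer_
  for (e in seq(n, start + w2 - 1L)) {
    if (win_bad(e - w2 + 1L, w2) < max_bad) { end <- e; break }
  }
  if (is.na(end) || start > end) return(empty_trim(read))

  idx <- start:end
  structure(list(read_id = read$read_id, sample_id = read$sample_id,
                 locus_id = read$locus_id, individual = read$individual,
                 direction = read$direction, start = start, end = end,
                 bases = paste(ch[idx], collapse = ""),
                 qv = read$qv[idx],
                 secondary_fraction = read$secondary_fraction[idx],
                 second_base = read$second_base[idx],
                 empty = FALSE),
            class = "trimmed_read")
}

#' Trace score (TS)
#'
#' Arithmetic mean basecall quality of the retained (post-trim) bases; an
#' empty trim has TS 0 by definition.
#'
#' @param trimmed a `trimmed_read` (a `quality_read` is accepted and used
#'   untrimmed).
#' @return A single numeric value.
#' @export
trace_score <- function(trimmed) {
  if (isTRUE(trimmed$empty) || length(trimmed$qv) == 0) return(0)
  mean(trimmed$qv)
}

#' Contiguous read length (CRL)
#'
#' Length of the longest contiguous run of positions whose windowed (centered
#' moving average, shrinking at the read ends) quality exceeds `qv_threshold`.
#' With `smooth = FALSE` the raw per-base quality is used instead of the
#' moving average.
#'
#' @param read a `quality_read` or `trimmed_read`.
#' @param qv_threshold run positions must have smoothed quality strictly above
#'   this value.
#' @param window moving-average window size in bases.
#' @param smooth use the windowed average (default) or raw per-base quality.
#' @return Integer run length (0 for an empty read).
#' @export
crl <- function(read, qv_threshold = 20L, window = 20L, smooth = TRUE) {
  qv <- read$qv
  n <- length(qv)
  if (n == 0) return(0L)
  if (smooth) {
    half_lo <- floor((window - 1) / 2)
    half_hi <- ceiling((window - 1) / 2)
    cs <- cumsum(c(0, qv))
    lo <- pmax(1L, seq_len(n) - half_lo)
    hi <- pmin(n, seq_len(n) + half_hi)
    qv <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  }
  ok <- qv > qv_threshold
  if (!any(ok)) return(0L)
  r <- rle(ok)
  as.integer(max(r$lengths[r$values]))
}

#' Quality level of a trace score
#'
#' `low` for TS in `[0, 20]`, `medium` for `(20, 34]`, `high` for `(34, 100]`
#' (the conventional printed intervals 0-20 / 21-34 / 35-100 on integer
#' scores).
#'
#' @param ts trace score(s).
#' @return Character vector in `c("low", "medium", "high")`.
#' @export
quality_level <- function(ts) {
  ifelse(ts <= 20, "low", ifelse(ts < 35, "medium", "high"))
}

#' Per-trace QC metrics
#'
#' Applies the QC chain to one read: end-trimming, TS on the trimmed read,
#' CRL on the full read, quality level, and the pass flag
#' (`TS >= ts_min` and `CRL >= crl_min`).
#'
#' @param read a `quality_read`.
#' @param ts_min,crl_min pass thresholds.
#' @param trim_window,trim_qv,trim_max_bad trimming parameters, see
#'   [trim_read()].
#' @return A one-row data frame of metrics plus the `trimmed_read` as an
#'   attribute `"trimmed"`.
#' @export
trace_metrics <- function(read, ts_min = 35, crl_min = 200,
                          trim_window = 25L, trim_qv = 25L, trim_max_bad = 3L) {
  tr <- trim_read(read, trim_window, trim_qv, trim_max_bad)
  ts <- trace_score(tr)
  cr <- crl(read)
  out <- data.frame(read_id = read$read_id, sample_id = read$sample_id,
                    locus_id = read$locus_id, individual = read$individual,
                    direction = read$direction,
                    trace_score = ts, crl = cr,
                    quality_level = quality_level(ts),
                    trimmed_length = if (tr$empty) 0L else tr$end - tr$start + 1L,
                    passes = ts >= ts_min && cr >= crl_min)
  attr(out, "trimmed") <- tr
  out
}

#' Sequencing success rate
#'
#' Percentage of passing traces among all traces, reported to one decimal
#' place with half-up rounding (112 of 116 gives 96.6).
#'
#' @param passes logical vector of per-trace pass flags, or a data frame with
#'   a `passes` column.
#' @return A single numeric percentage.
#' @export
success_rate <- function(passes) {
  if (is.data.frame(passes)) passes <- passes$passes
  if (length(passes) == 0) stop("success rate undefined for an empty collection")
  round_half_up(100 * sum(passes) / length(passes), 1)
}

#' Per-region QC report
#'
#' The machine twin of a sequencing-success table: one row per locus with
#' trace counts, percent passing, and the TS summary over passing traces.
#'
#' @param metrics data frame of per-trace metrics (rbind of [trace_metrics()]
#'   rows).
#' @return Data frame with columns `region`, `n_traces`, `pct_pass`,
#'   `mean_ts`, `min_ts`, `max_ts`, `mean_trimmed_length`.
#' @export
qc_report <- function(metrics) {
  do.call(rbind, lapply(split(metrics, metrics$locus_id), function(d) {
    pass <- d[d$passes, , drop = FALSE]
    data.frame(region = d$locus_id[1],
               n_traces = nrow(d),
               n_pass = nrow(pass),
               pct_pass = success_rate(d),
               mean_ts = if (nrow(pass)) round(mean(pass$trace_score)) else NA,
               min_ts = if (nrow(pass)) round(min(pass$trace_score)) else NA,
               max_ts = if (nrow(pass)) round(max(pass$trace_score)) else NA,
               mean_trimmed_length = round(mean(d$trimmed_length)))
  }))
}
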