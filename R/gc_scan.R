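# Windowed GC segmentation. Endogenous PLVs sit in long stretches whose
# GC composition deviates from the host baseline; the scan computes a
# fixed-window GC track, calls maximal deviant runs as segments, and
# quantifies the element-vs-flank GC delta used as corroborating
# evidence in element calling.

#' Tiling-window GC track for a contig
#'
#' Non-overlapping windows cover the contig; the final window may be
#' short. GC is computed over non-N bases only and is `NA` (undefined)
#' for all-N windows.
#'
#' @param seq Contig sequence.
#' @param window_bp Window size in bp (default 500, the usual
#'   genome-browser triage resolution).
#' @param contig_id Contig name for the output.
#' @return Tibble with `contig_id`, `start`, `end` (0-based half-open),
#'   `gc`, `n_count`.
#' @export
windowed_gc <- function(seq, window_bp = 500L, contig_id = "contig") {
  stopifnot(window_bp >= 1)
  n <- nchar(seq)
  if (n == 0) {
    return(tibble::tibble(contig_id = character(), start = integer(),
                          end = integer(), gc = numeric(), n_count = integer()))
  }
  starts <- seq.int(1L, n, by = window_bp)
  ends <- pmin(starts + window_bp - 1L, n)
  v <- Biostrings::Views(Biostrings::DNAString(seq), start = starts, end = ends)
  f <- Biostrings::letterFrequency(v, letters = c("G", "C", "A", "T", "N"))
  acgt <- rowSums(f[, c("G", "C", "A", "T"), drop = FALSE])
  gc <- ifelse(acgt > 0, (f[, "G"] + f[, "C"]) / acgt, NA_real_)
  tibble::tibble(contig_id = contig_id, start = starts - 1L, end = ends,
                 gc = as.numeric(gc), n_count = as.integer(f[, "N"]))
}

#' Call GC-deviant segments from a window track
#'
#' A window is deviant when `|gc - host_baseline| >= min_delta_points/100`.
#' Maximal runs of deviant windows are reported as segments; a run may
#' bridge a single non-deviant window (nested insertions and short
#' host-like stretches inside elements would otherwise split it), and
#' undefined (all-N) windows neither break nor extend a run. Segments
#' are kept when their length is within `[min_len_bp, max_len_bp]`.
#'
#' @param windows Window tibble from [windowed_gc()] (one contig, sorted).
#' @param host_baseline Host-genome GC fraction in `[0, 1]`.
#' @param min_delta_points Minimum absolute deviation in percentage points.
#' @param min_len_bp,max_len_bp Reported segment length bounds.
#' @return Tibble of segments with `mean_gc`, `host_baseline_gc`,
#'   `delta_points`.
#' @export
call_gc_segments <- function(windows, host_baseline, min_delta_points = 10,
                             min_len_bp = 5000, max_len_bp = 80000) {
  stopifnot(host_baseline >= 0, host_baseline <= 1)
  if (min_len_bp > max_len_bp) stop("min_len_bp exceeds max_len_bp")
  empty <- tibble::tibble(contig_id = character(), start = integer(),
                          end = integer(), mean_gc = numeric(),
                          host_baseline_gc = numeric(), delta_points = numeric())
  if (nrow(windows) == 0) return(empty)
  state <- ifelse(is.na(windows$gc), "U",
                  ifelse(abs(windows$gc - host_baseline) >= min_delta_points / 100,
                         "D", "I"))
  runs <- list()
  run_start <- NA_integer_   # index of first deviant window of open run
  run_last <- NA_integer_    # index of last deviant window seen
  pending_break <- FALSE     # one non-deviant window already bridged
  close_run <- function() {
    if (!is.na(run_start)) runs[[length(runs) + 1L]] <<- c(run_start, run_last)
    run_start <<- NA_integer_; run_last <<- NA_integer_
    pending_break <<- FALSE
  }
  for (i in seq_along(state)) {
    s <- state[i]
    if (s == "D") {
      if (is.na(run_start)) run_start <- i
      run_last <- i
      pending_break <- FALSE
    } else if (s == "I") {
      if (!is.na(run_start)) {
        if (pending_break) close_run() else pending_break <- TRUE
      }
    }
    # "U": transparent - neither breaks nor extends
  }
  close_run()
  if (length(runs) == 0) return(empty)
  segs <- lapply(runs, function(r) {
    idx <- r[1]:r[2]
    w <- windows[idx, ]
    defined <- !is.na(w$gc)
    bases <- (w$end - w$start) - w$n_count
    mean_gc <- sum(w$gc[defined] * bases[defined]) / sum(bases[defined])
    tibble::tibble(contig_id = w$contig_id[1],
                   start = w$start[1], end = w$end[nrow(w)],
                   mean_gc = mean_gc, host_baseline_gc = host_baseline,
                   delta_points = 100 * (mean_gc - host_baseline))
  })
  out <- dplyr::bind_rows(segs)
  out <- dplyr::filter(out, (.data$end - .data$start) >= min_len_bp,
                       (.data$end - .data$start) <= max_len_bp)
  dplyr::arrange(out, .data$start)
}

#' GC delta between an element and its host flanks
#'
#' Returns `100 * (GC(element) - GC(flanks))`, with flanks of
#' `flank_bp` on each side truncated at the contig ends and at adjacent
#' annotated elements when provided. If the element covers the whole
#' contig (no flank sequence), the delta is computed against
#' `assembly_baseline` with a warning.
#'
#' @param seq Contig sequence.
#' @param start,end Element interval, 0-based half-open.
#' @param flank_bp Flank length per side (default 10 kb).
#' @param other_elements Optional tibble with `start`/`end` of other
#'   elements on the contig, which flanks must not run into.
#' @param assembly_baseline Assembly-wide GC fraction, used only when no
#'   flank sequence is available.
#' @return Signed delta in percentage points.
#' @export
element_gc_delta <- function(seq, start, end, flank_bp = 10000,
                             other_elements = NULL, assembly_baseline = NULL) {
  n <- nchar(seq)
  stopifnot(start >= 0, end > start, end <= n)
  elem_gc <- gc_fraction(substr(seq, start + 1, end))
  lo <- max(0, start - flank_bp)
  hi <- min(n, end + flank_bp)
  if (!is.null(other_elements) && nrow(other_elements) > 0) {
    left_ends <- other_elements$end[other_elements$end <= start]
    if (length(left_ends)) lo <- max(lo, max(left_ends))
    right_starts <- other_elements$start[other_elements$start >= end]
    if (length(right_starts)) hi <- min(hi, min(right_starts))
  }
  flank_seq <- paste0(substr(seq, lo + 1, start), substr(seq, end + 1, hi))
  if (nchar(flank_seq) == 0) {
    warning("element covers the entire contig; using assembly-wide baseline")
    base <- if (!is.null(assembly_baseline)) assembly_baseline else gc_fraction(seq)
    return(100 * (elem_gc - base))
  }
  100 * (elem_gc - gc_fraction(flank_seq))
}

#' Export a GC track as bedGraph-style TSV
#'
#' Four columns (contig, start, end, gc), 0-based half-open, loadable as
#' a genome-browser track.
#'
#' @param windows Window tibble from [windowed_gc()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gc_track <- function(windows, path) {
  readr::write_tsv(windows[, c("contig_id", "start", "end", "gc")], path,
                   col_names = FALSE)
  invisible(path)
}
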