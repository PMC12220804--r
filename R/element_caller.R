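# Element calling: integrates filtered TIR pairs, GC evidence and
# hallmark-gene hits into classified element calls, then per-genome
# expansion statistics.

MARKER_CLASSES <- c("MCP_PLV", "MCP_virophage", "mCP", "pATPase", "protease",
                    "rve_INT", "YREC", "pPolB", "other")

#' Load and filter a hallmark-gene hit table
#'
#' Accepts either the pipeline's own TSV layout (header row with columns
#' `protein_id`, `contig_id`, `start`, `end`, `strand`, `marker_class`,
#' `model_id`, `e_value`, `model_coverage`, `query_coverage`) or a
#' HMMER domain-table-style file (comment lines starting with `#`,
#' whitespace-separated). Hits failing the e-value or coverage
#' thresholds are dropped with per-threshold counts reported; MCP
#' classes additionally require `mcp_min_cov` coverage of both the
#' model and the query. Per protein, the best (lowest e-value) hit per
#' marker class is retained.
#'
#' @param path Input path.
#' @param e_value_max E-value cutoff (default 1e-3).
#' @param min_model_cov,min_query_cov Coverage cutoffs applied to all
#'   classes (default 0).
#' @param mcp_min_cov Coverage cutoff applied to both model and query
#'   for MCP classes (default 0.70).
#' @return Marker-hit tibble.
#' @export
load_marker_hits <- function(path, e_value_max = 1e-3,
                             min_model_cov = 0, min_query_cov = 0,
                             mcp_min_cov = 0.70) {
  first <- readLines(path, n = 1)
  if (length(first) && startsWith(first, "#")) {
    hits <- parse_domtbl(path)
  } else {
    hits <- readr::read_tsv(path, show_col_types = FALSE)
    required <- c("protein_id", "contig_id", "start", "end",
                  "marker_class", "model_id", "e_value",
                  "model_coverage", "query_coverage")
    missing <- setdiff(required, names(hits))
    if (length(missing)) {
      stop("malformed marker table ", path, ": missing column(s) ",
           paste(missing, collapse = ", "))
    }
  }
  filter_marker_hits(hits, e_value_max, min_model_cov, min_query_cov,
                     mcp_min_cov)
}

#' @rdname load_marker_hits
#' @param hits A marker-hit tibble already in memory.
#' @export
filter_marker_hits <- function(hits, e_value_max = 1e-3,
                               min_model_cov = 0, min_query_cov = 0,
                               mcp_min_cov = 0.70) {
  bad_class <- !hits$marker_class %in% MARKER_CLASSES
  if (any(bad_class)) {
    stop("unknown marker class(es): ",
         paste(unique(hits$marker_class[bad_class]), collapse = ", "))
  }
  n0 <- nrow(hits)
  drop_e <- hits$e_value >= e_value_max
  hits <- hits[!drop_e, , drop = FALSE]
  is_mcp <- grepl("^MCP_", hits$marker_class)
  need_model <- ifelse(is_mcp, pmax(min_model_cov, mcp_min_cov), min_model_cov)
  need_query <- ifelse(is_mcp, pmax(min_query_cov, mcp_min_cov), min_query_cov)
  drop_cov <- hits$model_coverage < need_model | hits$query_coverage < need_query
  hits <- hits[!drop_cov, , drop = FALSE]
  message("marker filter: ", n0, " hits; dropped ", sum(drop_e),
          " by e-value, ", sum(drop_cov), " by coverage")
  hits %>%
    dplyr::group_by(.data$protein_id, .data$marker_class) %>%
    dplyr::slice_min(.data$e_value, n = 1, with_ties = FALSE) %>%
    dplyr::ungroup()
}

parse_domtbl <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 22) {
      stop("malformed domain-table row at line ", i, ": ",
           length(f), " fields")
    }
    # standard domtblout: target, tlen(3), query/model name(4), qlen(6),
    # full-seq e-value(7), ali coords(18,19), hmm coords(16,17)
    tlen <- as.numeric(f[3]); qlen <- as.numeric(f[6])
    ali_from <- as.numeric(f[18]); ali_to <- as.numeric(f[19])
    hmm_from <- as.numeric(f[16]); hmm_to <- as.numeric(f[17])
    tibble::tibble(
      protein_id = f[1], contig_id = sub("_[0-9]+$", "", f[1]),
      start = NA_integer_, end = NA_integer_, strand = ".",
      marker_class = f[4], model_id = f[4],
      e_value = as.numeric(f[7]),
      model_coverage = (hmm_to - hmm_from + 1) / qlen,
      query_coverage = (ali_to - ali_from + 1) / tlen)
  })
  dplyr::bind_rows(rows)
}

# TSD-guided boundary polish. A TSD is a direct repeat of host sequence
# lying immediately OUTSIDE the element; when its copies contain
# reverse-complement-palindromic positions the maximum-scoring inverted-
# repeat alignment legitimately extends a few columns into them, pulling
# both element edges outward symmetrically. Scan symmetric inward shifts
# t = 0..max_shift and maximise
#     J(t) = tsd_score(t) - ir_cost(t)
# where tsd_score = matches - mismatches of the TSD callable at that
# boundary (required >= 5, so exact 4-mers cannot relocate a boundary)
# and ir_cost is the +1/-2 match/error score of the t outer alignment
# columns sacrificed by the shift (never below 0). Genuine arm columns
# are expensive to sacrifice while palindromic TSD overshoot is cheap.
# Every sacrificed column costs at least +1 even when observed as a
# mismatch: a boundary shift always discards one column of inverted-
# repeat support, and pricing observed mismatches at zero would let
# chance one-base TSD extensions relocate boundaries for free. Ties in
# J are broken toward the smaller total TSD offset (canonical integrase
# TSDs sit flush against the element; equal-J interpretations that need
# a pad are chance extensions), then toward the smaller shift. A
# boundary reinterpretation that extends the duplication by one base
# pair on each side while discarding one genuine match column is then a
# tie, resolved in place; genuine palindromic-TSD overshoot clears the
# cost because most of the duplication lies outside the alignment.
# Returns the chosen shift.
refine_boundary_shift <- function(seq, start, end, head_w = numeric(0),
                                  max_shift = 15L, flank_bp = 50L,
                                  tsd_args = list()) {
  w <- c(head_w, rep(1, max(0, max_shift - length(head_w))))
  # cost of a shift = number of matching alignment columns discarded
  # (discarding a mismatch column is free), floored at 1 so a chance
  # one-base TSD extension can never relocate a boundary for free
  cost <- pmax(cumsum(w > 0), 1)
  cost <- c(0, cost)                     # cost[t + 1] = cost of shift t
  best <- list(t = 0L, j = 0, off = Inf)
  for (t in 0:max_shift) {
    if (end - t <= start + t) break
    fl <- suppressWarnings(extract_flanks(seq, start + t, end - t, flank_bp))
    tsd <- do.call(call_tsd, c(list(left = fl$left, right = fl$right),
                               tsd_args))
    if (is.null(tsd)) next
    sc <- tsd$length_bp - 2L * tsd$n_mismatches
    if (sc < 5) next
    j <- sc - cost[t + 1]
    off <- tsd$left_offset_bp + tsd$right_offset_bp
    if (j > best$j + 1e-9 ||
        (abs(j - best$j) <= 1e-9 && off < best$off)) {
      best <- list(t = t, j = j, off = off)  # ascending t: ties keep first
    }
  }
  best$t
}

classify_element <- function(classes) {
  has_plv <- "MCP_PLV" %in% classes
  has_vir <- "MCP_virophage" %in% classes
  if (has_plv && has_vir) return("hybrid")
  if (has_plv) return("PLV")
  if (has_vir) return("virophage")
  "unassigned"
}

#' Call classified elements on one contig
#'
#' Every size-filtered TIR pair is a candidate. A candidate is accepted
#' when it contains at least one marker hit (if `require_marker`) and
#' its element-vs-flank GC delta magnitude is at least `min_gc_delta`
#' (default 0: GC corroborates but does not gate). A TSD is attached
#' from the flanks; the element is classified PLV / virophage / hybrid
#' by the MCP classes present, or unassigned when only non-MCP markers
#' are inside. Elements are complete by construction (TIR-flanked);
#' TIR-only candidates rejected by the marker rule are returned
#' separately rather than silently dropped. Nested retroelement inserts
#' are annotated from GC-divergent sub-segments (relative to the
#' element's own mean GC) that carry a retroelement-type (`other`)
#' marker.
#'
#' @param seq Contig sequence.
#' @param contig_id Contig name.
#' @param tir_pairs Size-filtered TIR-pair tibble for this contig.
#' @param markers Marker-hit tibble (filtered) for this contig; needs
#'   `start`/`end` coordinates.
#' @param require_marker Require at least one interior marker hit.
#' @param min_gc_delta Minimum |GC delta| in points (default 0).
#' @param flank_bp Flank used for the GC delta (default 10 kb).
#' @param tsd_args List of arguments forwarded to [call_tsd()].
#' @param max_shift Maximum symmetric inward boundary shift explored by
#'   the TSD-guided polish (see Details in the package vignette); 0
#'   disables polishing.
#' @param window_bp GC window for nested-insert annotation.
#' @return List with `elements` (accepted calls), `tsds` (their TSD
#'   calls, keyed by `element_id`), and `candidates_unconfirmed`
#'   (TIR-only candidates that failed the marker/GC rules).
#' @export
call_elements <- function(seq, contig_id, tir_pairs, markers = NULL,
                          require_marker = TRUE, min_gc_delta = 0,
                          flank_bp = 10000, tsd_args = list(),
                          max_shift = 15L, window_bp = 500L) {
  empty <- list(elements = tibble::tibble(), tsds = tibble::tibble(),
                candidates_unconfirmed = tibble::tibble())
  if (is.null(tir_pairs) || nrow(tir_pairs) == 0) return(empty)
  elements <- list(); tsds <- list(); rejected <- list()
  other_iv <- tir_pairs[, c("insert_start", "insert_end")]
  names(other_iv) <- c("start", "end")
  scoring <- ir_scoring()
  for (i in seq_len(nrow(tir_pairs))) {
    p <- tir_pairs[i, ]
    es <- p$insert_start; ee <- p$insert_end
    head_w <- numeric(0)
    if (max_shift > 0) {
      arm5 <- substr(seq, p$arm5_start + 1, p$arm5_end)
      arm3 <- substr(seq, p$arm3_start + 1, p$arm3_end)
      aln <- nw_align_cpp(arm5, revcomp(arm3), scoring$match,
                          scoring$mismatch, scoring$gap_penalty,
                          band = alignment_band(arm5, arm3))
      ops <- strsplit(aln$ops, "")[[1]]
      head_w <- ifelse(utils::head(ops, max_shift) == "M", 1, -2)
    }
    shift <- refine_boundary_shift(seq, es, ee, head_w = head_w,
                                   max_shift = max_shift,
                                   tsd_args = tsd_args)
    es <- es + shift; ee <- ee - shift
    eid <- sprintf("%s_elem_%d", contig_id, i)
    inside <- if (!is.null(markers) && nrow(markers) > 0) {
      markers[markers$contig_id == contig_id &
                markers$start >= es & markers$end <= ee, , drop = FALSE]
    } else {
      tibble::tibble(marker_class = character(0))
    }
    gc_delta <- element_gc_delta(seq, es, ee, flank_bp = flank_bp,
                                 other_elements = other_iv[-i, , drop = FALSE])
    accept <- (!require_marker || nrow(inside) > 0) &&
      abs(gc_delta) >= min_gc_delta
    row <- tibble::tibble(
      element_id = eid, contig_id = contig_id,
      start = es, end = ee, length = ee - es,
      arm5_len = p$arm5_len, arm3_len = p$arm3_len,
      tir_score = p$score, tir_identity_pct = p$arm_identity_pct,
      gc_delta_points = gc_delta,
      n_markers = nrow(inside),
      marker_classes = paste(sort(unique(inside$marker_class)),
                             collapse = ","),
      classification = classify_element(inside$marker_class),
      complete = TRUE)
    if (!accept) { rejected[[eid]] <- row; next }
    fl <- extract_flanks(seq, es, ee)
    tsd <- do.call(call_tsd, c(list(left = fl$left, right = fl$right),
                               tsd_args))
    if (!is.null(tsd)) {
      tsd$element_id <- eid
      tsds[[eid]] <- tsd
    }
    row$has_tsd <- !is.null(tsd)
    ni <- annotate_nested(seq, es, ee, inside, window_bp = window_bp)
    row$n_nested <- nrow(ni)
    elements[[eid]] <- row
  }
  list(elements = dplyr::bind_rows(elements),
       tsds = dplyr::bind_rows(tsds),
       candidates_unconfirmed = dplyr::bind_rows(rejected))
}

# GC-divergent sub-segments (vs the element's own mean GC) of nested-
# retroelement size that contain an "other"-class marker hit.
annotate_nested <- function(seq, es, ee, markers_inside, window_bp = 500L,
                            min_delta_points = 10, min_len_bp = 3000,
                            max_len_bp = 10500) {
  elem_seq <- substr(seq, es + 1, ee)
  rt <- markers_inside[markers_inside$marker_class == "other", , drop = FALSE]
  if (nrow(rt) == 0) return(tibble::tibble())
  w <- windowed_gc(elem_seq, window_bp = window_bp)
  segs <- call_gc_segments(w, host_baseline = gc_fraction(elem_seq),
                           min_delta_points = min_delta_points,
                           min_len_bp = min_len_bp, max_len_bp = max_len_bp)
  if (nrow(segs) == 0) return(tibble::tibble())
  segs$start <- segs$start + es
  segs$end <- segs$end + es
  keep <- vapply(seq_len(nrow(segs)), function(i) {
    any(rt$start < segs$end[i] & rt$end > segs$start[i])
  }, logical(1))
  segs[keep, c("start", "end", "mean_gc", "delta_points"), drop = FALSE]
}

#' Per-genome expansion statistics
#'
#' @param elements Element-call tibble (may be empty).
#' @param assembly_len_bp Total assembly length in bp (> 0).
#' @param genome_id Genome label.
#' @param tsd_summary Optional output of [tsd_conservation_summary()].
#' @return One-row tibble with element counts, density per Mb, percent
#'   of the genome in elements, mean element length, mean TIR identity
#'   and the conserved-TSD fraction. Densities are full precision;
#'   round to one decimal for reporting.
#' @export
genome_stats <- function(elements, assembly_len_bp, genome_id = "genome",
                         tsd_summary = NULL) {
  stopifnot(assembly_len_bp > 0)
  n <- if (is.null(elements)) 0L else nrow(elements)
  total_bp <- if (n > 0) sum(elements$length) else 0
  tibble::tibble(
    genome_id = genome_id,
    assembly_len_bp = assembly_len_bp,
    n_elements = n,
    n_complete = if (n > 0 && "complete" %in% names(elements))
                   sum(elements$complete) else n,
    density_per_mb = n / (assembly_len_bp / 1e6),
    pct_genome_in_elements = 100 * total_bp / assembly_len_bp,
    mean_element_len_bp = if (n > 0) mean(elements$length) else NA_real_,
    mean_tir_identity_pct = if (n > 0 &&
                                "tir_identity_pct" %in% names(elements))
                              mean(elements$tir_identity_pct) else NA_real_,
    frac_tsd_conserved = if (!is.null(tsd_summary))
                           tsd_summary$frac_conserved else NA_real_)
}
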