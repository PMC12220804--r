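# Terminal-inverted-repeat detection. Scoring follows the EMBOSS
# einverted defaults (match +3, mismatch -4, linear gap 12, threshold 50)
# with a configurable maximum separation between the outer edges of the
# two arms. Small contigs are scanned with an exhaustive local-alignment
# DP; large contigs with reverse-complement k-mer seeding plus banded
# X-drop extension. Both report arm pairs whose score, recomputed by
# end-to-end alignment of arm5 against revcomp(arm3), meets the
# threshold.

#' Inverted-repeat scoring parameters
#'
#' Defaults are the EMBOSS einverted conventions: match +3, mismatch -4,
#' linear gap penalty 12 per base, minimum score 50, and a maximum
#' separation (outer edge to outer edge) of 80 kb.
#'
#' @param match,mismatch,gap_penalty Alignment scores; `match > 0 > mismatch`,
#'   `gap_penalty > 0`.
#' @param min_score Minimum alignment score for a reported pair.
#' @param max_separation_bp Maximum insert length (arm5 start to arm3 end).
#' @return A list of class `ir_scoring`.
#' @export
ir_scoring <- function(match = 3L, mismatch = -4L, gap_penalty = 12L,
                       min_score = 50L, max_separation_bp = 80000) {
  stopifnot(match > 0, mismatch < 0, gap_penalty > 0, min_score > 0,
            max_separation_bp > 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_penalty = as.integer(gap_penalty),
                 min_score = as.integer(min_score),
                 max_separation_bp = max_separation_bp),
            class = "ir_scoring")
}

empty_tir_table <- function() {
  tibble::tibble(contig_id = character(),
                 arm5_start = integer(), arm5_end = integer(),
                 arm3_start = integer(), arm3_end = integer(),
                 insert_start = integer(), insert_end = integer(),
                 insert_len = integer(),
                 arm5_len = integer(), arm3_len = integer(),
                 score = integer(), arm_identity_pct = numeric(),
                 n_mismatches = integer(), n_gaps = integer())
}

#' Find terminal-inverted-repeat pairs in a contig
#'
#' Reports pairs of inverted arms (arm5 strictly upstream of arm3) whose
#' local alignment of arm5 against revcomp(arm3) scores at least
#' `scoring$min_score`, with the outer-edge separation capped at
#' `scoring$max_separation_bp`. Overlapping same-locus hits are reduced
#' to the best-scoring one. Coordinates are 0-based half-open.
#'
#' Contigs up to `exact_max_len` bp are scanned exhaustively (every
#' arm-pair alignment is considered via a full local-alignment DP);
#' longer contigs use reverse-complement k-mer seeding (`seed_k`) with
#' banded X-drop extension, which recovers arm pairs that share at least
#' one exact `seed_k`-mer.
#'
#' @param seq Contig sequence (uppercase A/C/G/T/N string).
#' @param scoring An [ir_scoring()] object.
#' @param contig_id Contig name used in the output table.
#' @param exact_max_len Contig length up to which the exhaustive DP is used.
#' @param seed_k Seed k-mer length for the large-contig path.
#' @param band Half-width of the extension band (gaps are rare at gap
#'   penalty 12, so a narrow band suffices).
#' @param xdrop Score drop-off that terminates extension.
#' @param trim_ends Refine arm boundaries by trimming terminal alignment
#'   columns back to the maximal-scoring core under a +1 match / -2
#'   mismatch-or-gap weighting. Max-score local alignments frequently
#'   overrun the true repeat boundary by a few bases of chance matching
#'   flank (any net-positive extension is kept by the DP); the trim
#'   removes terminal segments below two-thirds identity, which sparse
#'   chance extensions essentially never reach while genuine arm ends do.
#' @return A TIR-pair tibble (one row per pair, sorted by position) with
#'   arm and insert coordinates, alignment score, percent identity,
#'   mismatch and gap counts.
#' @export
find_inverted_repeats <- function(seq, scoring = ir_scoring(),
                                  contig_id = "contig",
                                  exact_max_len = 1500L, seed_k = 12L,
                                  band = 16L, xdrop = 100L,
                                  trim_ends = TRUE) {
  stopifnot(is.character(seq), length(seq) == 1)
  n <- nchar(seq)
  if (n < 2) return(empty_tir_table())
  if (n <= exact_max_len) {
    raw <- ir_scan_exact_cpp(seq, scoring$match, scoring$mismatch,
                             scoring$gap_penalty, scoring$min_score,
                             scoring$max_separation_bp)
  } else {
    raw <- ir_scan_seeded_cpp(seq, as.integer(seed_k),
                              scoring$match, scoring$mismatch,
                              scoring$gap_penalty, scoring$min_score,
                              scoring$max_separation_bp,
                              as.integer(band), as.integer(xdrop))
    raw <- dedupe_tir_hits(raw)
  }
  if (nrow(raw) == 0) return(empty_tir_table())
  if (trim_ends) {
    raw <- trim_tir_boundaries(raw, seq, scoring)
    if (nrow(raw) == 0) return(empty_tir_table())
  }
  stats <- lapply(seq_len(nrow(raw)), function(i) {
    arm5 <- substr(seq, raw$arm5_start[i] + 1, raw$arm5_end[i])
    arm3 <- substr(seq, raw$arm3_start[i] + 1, raw$arm3_end[i])
    nw_align_cpp(arm5, revcomp(arm3), scoring$match, scoring$mismatch,
                 scoring$gap_penalty, band = alignment_band(arm5, arm3))
  })
  out <- tibble::tibble(
    contig_id = contig_id,
    arm5_start = as.integer(raw$arm5_start), arm5_end = as.integer(raw$arm5_end),
    arm3_start = as.integer(raw$arm3_start), arm3_end = as.integer(raw$arm3_end),
    insert_start = as.integer(raw$arm5_start), insert_end = as.integer(raw$arm3_end),
    insert_len = as.integer(raw$arm3_end - raw$arm5_start),
    arm5_len = as.integer(raw$arm5_end - raw$arm5_start),
    arm3_len = as.integer(raw$arm3_end - raw$arm3_start),
    score = vapply(stats, function(s) as.integer(s$score), integer(1)),
    arm_identity_pct = vapply(stats, function(s) s$identity, numeric(1)),
    n_mismatches = vapply(stats, function(s) as.integer(s$mismatches), integer(1)),
    n_gaps = vapply(stats, function(s) as.integer(s$gaps), integer(1)))
  out <- dplyr::filter(out, .data$score >= scoring$min_score)
  dplyr::arrange(out, .data$arm5_start, .data$arm3_start)
}

# Boundary refinement: align each arm pair end-to-end, then trim
# terminal alignment columns back to the maximal-scoring core under a
# +1 match / -2 mismatch-or-gap weighting (argmin of the prefix sums
# from each end; the first index attaining the minimum, so ties trim
# least). The head of the alignment touches the outer edges of both
# arms, the tail the inner edges.
trim_tir_boundaries <- function(raw, seq, scoring) {
  out <- raw
  keep <- logical(nrow(raw))
  for (i in seq_len(nrow(raw))) {
    arm5 <- substr(seq, raw$arm5_start[i] + 1, raw$arm5_end[i])
    arm3 <- substr(seq, raw$arm3_start[i] + 1, raw$arm3_end[i])
    aln <- nw_align_cpp(arm5, revcomp(arm3), scoring$match, scoring$mismatch,
                        scoring$gap_penalty, band = alignment_band(arm5, arm3))
    ops <- strsplit(aln$ops, "")[[1]]
    if (length(ops) == 0) next
    w <- ifelse(ops == "M", 1, -2)
    cs_head <- cumsum(w)
    t_head <- if (min(cs_head) < 0) which.min(cs_head) else 0L
    cs_tail <- cumsum(rev(w))
    t_tail <- if (min(cs_tail) < 0) which.min(cs_tail) else 0L
    if (t_head + t_tail >= length(ops)) next
    head_ops <- if (t_head > 0) ops[seq_len(t_head)] else character(0)
    tail_ops <- if (t_tail > 0) rev(ops)[seq_len(t_tail)] else character(0)
    # a-consumption (arm5): M/X/U columns; b-consumption (revcomp(arm3)):
    # M/X/L. b's start is arm3's outer (3') edge.
    out$arm5_start[i] <- raw$arm5_start[i] + sum(head_ops %in% c("M", "X", "U"))
    out$arm3_end[i] <- raw$arm3_end[i] - sum(head_ops %in% c("M", "X", "L"))
    out$arm5_end[i] <- raw$arm5_end[i] - sum(tail_ops %in% c("M", "X", "U"))
    out$arm3_start[i] <- raw$arm3_start[i] + sum(tail_ops %in% c("M", "X", "L"))
    keep[i] <- out$arm5_end[i] > out$arm5_start[i] &&
      out$arm3_end[i] > out$arm3_start[i] &&
      out$arm5_end[i] <= out$arm3_start[i]
  }
  out[keep, , drop = FALSE]
}

# Band for the verification alignment: must cover the length difference;
# generous slack for substitution-dominated arms.
alignment_band <- function(a, b) {
  as.integer(abs(nchar(a) - nchar(b)) + 64L)
}

# Reduce overlapping same-locus hits (both arms overlapping) to the
# best-scoring one; ties broken toward the longer, then leftmost pair.
dedupe_tir_hits <- function(raw) {
  if (nrow(raw) <= 1) return(raw)
  ord <- order(-raw$ext_score,
               -(raw$arm5_end - raw$arm5_start + raw$arm3_end - raw$arm3_start),
               raw$arm5_start)
  raw <- raw[ord, , drop = FALSE]
  keep <- logical(nrow(raw))
  for (i in seq_len(nrow(raw))) {
    ok <- TRUE
    for (j in which(keep)) {
      o5 <- raw$arm5_start[i] < raw$arm5_end[j] && raw$arm5_start[j] < raw$arm5_end[i]
      o3 <- raw$arm3_start[i] < raw$arm3_end[j] && raw$arm3_start[j] < raw$arm3_end[i]
      if (o5 && o3) { ok <- FALSE; break }
    }
    keep[i] <- ok
  }
  raw[keep, , drop = FALSE]
}

#' Apply the element-candidate size filters
#'
#' Retains TIR pairs whose insert length lies within
#' `[min_insert, max_insert]` and both arm lengths within
#' `[min_tir, max_tir]`; all bounds inclusive. Idempotent and
#' order-preserving.
#'
#' @param pairs TIR-pair tibble from [find_inverted_repeats()].
#' @param min_insert,max_insert Insert-length bounds in bp (default 6-80 kb).
#' @param min_tir,max_tir Arm-length bounds in bp (default 100 bp-8 kb).
#' @return Filtered TIR-pair tibble.
#' @export
filter_candidates <- function(pairs, min_insert = 6000, max_insert = 80000,
                              min_tir = 100, max_tir = 8000) {
  dplyr::filter(pairs,
                .data$insert_len >= min_insert, .data$insert_len <= max_insert,
                .data$arm5_len >= min_tir, .data$arm5_len <= max_tir,
                .data$arm3_len >= min_tir, .data$arm3_len <= max_tir)
}

#' Percent identity between the two arms of a TIR pair
#'
#' End-to-end alignment of arm5 against revcomp(arm3) under the pair's
#' scoring scheme; identity is matches over alignment columns, in percent.
#'
#' @param pair One row of a TIR-pair tibble.
#' @param seq The contig sequence the pair was called on.
#' @param scoring An [ir_scoring()] object.
#' @return Percent identity in `[0, 100]`.
#' @export
tir_identity <- function(pair, seq, scoring = ir_scoring()) {
  arm5 <- substr(seq, pair$arm5_start + 1, pair$arm5_end)
  arm3 <- substr(seq, pair$arm3_start + 1, pair$arm3_end)
  res <- nw_align_cpp(arm5, revcomp(arm3), scoring$match, scoring$mismatch,
                      scoring$gap_penalty, band = alignment_band(arm5, arm3))
  res$identity
}
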