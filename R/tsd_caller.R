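# Target-site-duplication calling. Integrase-mediated insertion copies
# a short host motif to both sides of the element; the caller aligns the
# two 50-bp flanks by exhaustive sliding/padding over all candidate
# lengths and per-side offsets and reports the best-supported consensus
# duplication. Degenerate (low-complexity) calls are flagged as likely
# spurious.

#' Extract element flanks from a contig
#'
#' @param seq Contig sequence.
#' @param start,end Element interval, 0-based half-open.
#' @param flank_bp Flank length per side (default 50).
#' @return `list(left =, right =)`; flanks are truncated (with a
#'   warning) when the element sits at a contig edge.
#' @export
extract_flanks <- function(seq, start, end, flank_bp = 50L) {
  n <- nchar(seq)
  stopifnot(start >= 0, end > start, end <= n)
  lo <- max(0L, start - flank_bp)
  hi <- min(n, end + flank_bp)
  left <- substr(seq, lo + 1, start)
  right <- substr(seq, end + 1, hi)
  if (nchar(left) < flank_bp || nchar(right) < flank_bp) {
    warning("element at contig edge: flank truncated to ",
            nchar(left), "/", nchar(right), " bp")
  }
  list(left = left, right = right)
}

# strict lexicographic comparison of numeric keys
lex_gt <- function(a, b) {
  i <- which(a != b)[1]
  !is.na(i) && a[i] > b[i]
}

hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  if (nchar(a) == 0) return(0L)
  va <- strsplit(a, "")[[1]]
  vb <- strsplit(b, "")[[1]]
  sum(va != vb | va == "N" | vb == "N")
}

#' Call a target site duplication from element flanks
#'
#' Scores every candidate triple (length `L` in `[min_tsd, max_tsd]`,
#' left pad `o_l` and right pad `o_r` in `[0, max_offset]`): the left
#' copy is the last `L` bases of the left flank before an `o_l`-bp pad,
#' the right copy the first `L` bases of the right flank after an
#' `o_r`-bp pad. A candidate is valid when its Hamming mismatch count is
#' at most `min(max_mismatch, floor(L/5))`. The best candidate maximises
#' matches minus mismatches; ties go to the longer length, then the
#' smaller total offset, then fewer mismatches, then the smaller left
#' offset. The consensus takes the left-copy base at mismatch positions.
#'
#' @param left,right Flank sequences (non-empty).
#' @param min_tsd,max_tsd Candidate length bounds (default 4-25 bp,
#'   covering canonical ~4-6 bp duplications and the longer 7-23 bp
#'   recombinase-associated class).
#' @param max_offset Maximum pad between the element boundary and a
#'   copy, per side (default 3).
#' @param max_mismatch Absolute mismatch cap (default 2).
#' @return One-row tibble (`left_copy`, `right_copy`, `consensus`,
#'   `length_bp`, `n_mismatches`, `left_offset_bp`, `right_offset_bp`,
#'   `low_complexity`) or `NULL` when no valid candidate exists.
#' @export
call_tsd <- function(left, right, min_tsd = 4L, max_tsd = 25L,
                     max_offset = 3L, max_mismatch = 2L) {
  if (nchar(left) == 0 || nchar(right) == 0) return(NULL)
  nl <- nchar(left); nr <- nchar(right)
  best <- NULL
  for (L in min_tsd:max_tsd) {
    cap <- min(max_mismatch, L %/% 5L)
    for (ol in 0:max_offset) {
      a_end <- nl - ol
      if (a_end < L) next
      lc <- substr(left, a_end - L + 1, a_end)
      for (orr in 0:max_offset) {
        if (orr + L > nr) next
        rc <- substr(right, orr + 1, orr + L)
        mm <- hamming(lc, rc)
        if (mm > cap) next
        cand <- list(lc = lc, rc = rc, L = L, mm = mm, ol = ol, orr = orr,
                     score = (L - mm) - mm)
        cand$key <- c(cand$score, cand$L, -(cand$ol + cand$orr), -cand$mm,
                      -cand$ol)
        if (is.null(best) || lex_gt(cand$key, best$key)) best <- cand
      }
    }
  }
  if (is.null(best)) return(NULL)
  tibble::tibble(left_copy = best$lc, right_copy = best$rc,
                 consensus = best$lc, length_bp = best$L,
                 n_mismatches = as.integer(best$mm),
                 left_offset_bp = as.integer(best$ol),
                 right_offset_bp = as.integer(best$orr),
                 low_complexity = flag_low_complexity(best$lc))
}

#' Flag a low-complexity TSD call
#'
#' TRUE when the sequence uses at most two distinct bases or one base
#' makes up at least 80% of it - the weakest rule that flags degenerate
#' short matches (e.g. GAGGG) while passing ordinary calls.
#'
#' @param tsd Non-empty nucleotide string.
#' @return Logical.
#' @export
flag_low_complexity <- function(tsd) {
  stopifnot(nchar(tsd) > 0)
  tab <- table(strsplit(tsd, "")[[1]])
  length(tab) <= 2 || max(tab) / nchar(tsd) >= 0.8
}

#' Fraction of elements with a conserved TSD
#'
#' An element counts as TSD-conserved when it has a call with at most
#' `max_mismatch` mismatches that is not low-complexity. Because the
#' precise notion of "conserved" (exact copies vs one tolerated
#' mismatch) is a convention, both numerators are reported.
#'
#' @param calls Tibble of TSD calls with an `element_id` column (rows
#'   may be absent for elements without a call).
#' @param element_ids Character vector of all element ids considered.
#' @param max_mismatch Mismatch tolerance for the lenient numerator.
#' @return One-row tibble: `n_elements`, `n_tsd`, `frac_conserved`
#'   (mismatches <= max_mismatch, not low-complexity), `frac_exact`
#'   (zero mismatches, not low-complexity). All-`NA` fractions when
#'   `element_ids` is empty.
#' @export
tsd_conservation_summary <- function(calls, element_ids, max_mismatch = 2L) {
  n <- length(element_ids)
  if (n == 0) {
    return(tibble::tibble(n_elements = 0L, n_tsd = 0L,
                          frac_conserved = NA_real_, frac_exact = NA_real_))
  }
  if (is.null(calls) || nrow(calls) == 0) {
    return(tibble::tibble(n_elements = n, n_tsd = 0L,
                          frac_conserved = 0, frac_exact = 0))
  }
  calls <- calls[calls$element_id %in% element_ids, , drop = FALSE]
  ok <- !calls$low_complexity & calls$n_mismatches <= max_mismatch
  exact <- !calls$low_complexity & calls$n_mismatches == 0L
  tibble::tibble(
    n_elements = n, n_tsd = nrow(calls),
    frac_conserved = length(unique(calls$element_id[ok])) / n,
    frac_exact = length(unique(calls$element_id[exact])) / n)
}
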