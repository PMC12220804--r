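#!/usr/bin/env Rscript
# Target-site-duplication analysis: the canonical worked examples, the
# conservation summary on detected elements, and exact recovery of the
# planted duplications measured two ways - from the true element
# boundaries (the caller in isolation) and through the detected
# boundaries (end to end, where a small fraction of elements admit a
# strictly longer duplication consistent with a shifted boundary).

library(plvscan)
library(readr)

# fixed worked-example constructs
toy <- toy_worked_examples()
e <- toy$truth$elements
for (i in 1:2) {
  fl <- extract_flanks(toy$assembly$seq[i], e$start[i], e$end[i])
  call <- call_tsd(fl$left, fl$right)
  cat(sprintf("construct %s: %s / %s -> length %d, %d mismatch(es)\n",
              e$element_id[i], call$left_copy, call$right_copy,
              call$length_bp, call$n_mismatches))
}

sim <- simulate_assembly(sim_config(seed = 1L))
det <- detect_elements(sim$assembly, filter_marker_hits(sim$marker_hits))

recover <- function(starts, ends, contigs) {
  ok <- 0; tot <- 0
  for (j in seq_along(starts)) {
    tt <- sim$truth$tsds[sim$truth$tsds$element_id ==
                           sim$truth$elements$element_id[j], ]
    if (tt$length_bp < 5 || tt$n_mismatches > 1) next
    tot <- tot + 1
    seqc <- sim$assembly$seq[sim$assembly$id == contigs[j]]
    fl <- extract_flanks(seqc, starts[j], ends[j])
    call <- call_tsd(fl$left, fl$right)
    if (!is.null(call) && call$length_bp == tt$length_bp &&
        call$left_copy == tt$left_copy) ok <- ok + 1
  }
  c(ok = ok, tot = tot)
}

tr <- sim$truth$elements
at_truth <- recover(tr$start, tr$end, tr$contig_id)

# match detected elements to truth for the end-to-end figure
ok2 <- 0; tot2 <- 0
for (j in seq_len(nrow(tr))) {
  tt <- sim$truth$tsds[sim$truth$tsds$element_id == tr$element_id[j], ]
  if (tt$length_bp < 5 || tt$n_mismatches > 1) next
  tot2 <- tot2 + 1
  hit <- which(det$elements$contig_id == tr$contig_id[j] &
                 abs(det$elements$start - tr$start[j]) <= 5 &
                 abs(det$elements$end - tr$end[j]) <= 5)
  if (!length(hit)) next
  call <- det$tsds[det$tsds$element_id == det$elements$element_id[hit[1]], ]
  if (nrow(call) && call$length_bp == tt$length_bp &&
      call$left_copy == tt$left_copy) ok2 <- ok2 + 1
}

summary <- tibble::tibble(
  measure = c("exact_at_true_boundaries", "exact_through_detection",
              "frac_conserved_detected", "frac_exact_detected"),
  value = c(at_truth["ok"] / at_truth["tot"], ok2 / tot2,
            det$tsd_summary$frac_conserved, det$tsd_summary$frac_exact))
write_tsv(summary, "results/tsd_summary.tsv")
cat("\n")
print(as.data.frame(summary))
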