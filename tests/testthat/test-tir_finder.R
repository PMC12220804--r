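test_that("a perfect planted arm pair is recovered with exact arithmetic", {
  set.seed(2)
  # flanks and spacer are poly-A so the alignment cannot extend past the
  # planted arms by chance (A pairs only with T under reverse complement)
  arm <- random_dna_str(200, gc = 0.5)
  s <- paste0(strrep("A", 300), arm, strrep("A", 5000), revcomp(arm),
              strrep("A", 300))
  hits <- find_inverted_repeats(s)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$arm_identity_pct, 100)
  expect_equal(hits$score, 600L)                # 200 x (+3)
  expect_equal(hits$arm5_start, 300L)
  expect_equal(hits$arm5_end, 500L)
  expect_equal(hits$insert_len, hits$arm3_end - hits$arm5_start)
})

test_that("homopolymer contigs contain no inverted repeats", {
  expect_equal(nrow(find_inverted_repeats(strrep("A", 5000))), 0L)
  expect_equal(nrow(find_inverted_repeats(strrep("A", 500))), 0L)
})

test_that("exact scan equals the DP oracle on small random/planted inputs", {
  set.seed(77)
  n_hit <- 0
  for (rep in 1:60) {
    plant <- rep %% 2 == 0
    s <- random_ir_case(len = sample(80:300, 1), plant = plant,
                        arm = sample(20:50, 1),
                        identity = runif(1, 0.8, 1),
                        spacer = sample(20:80, 1))
    oracle <- oracle_ir_best_score(s)
    hits <- find_inverted_repeats(s, trim_ends = FALSE)
    if (oracle >= 50) {
      n_hit <- n_hit + 1
      expect_equal(max(hits$score), oracle)
    } else {
      expect_equal(nrow(hits), 0L)
    }
  }
  expect_gt(n_hit, 10)   # the case generator must exercise the hit path
})

test_that("reported scores are reproducible from the reported arms", {
  set.seed(41)
  s <- random_ir_case(len = 4000, plant = TRUE, arm = 300, identity = 0.9,
                      spacer = 2000)
  scoring <- ir_scoring()
  hits <- find_inverted_repeats(s, scoring)
  expect_gte(nrow(hits), 1L)
  for (i in seq_len(nrow(hits))) {
    arm5 <- substr(s, hits$arm5_start[i] + 1, hits$arm5_end[i])
    arm3 <- substr(s, hits$arm3_start[i] + 1, hits$arm3_end[i])
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(arm5),
      Biostrings::reverseComplement(Biostrings::DNAString(arm3)),
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 3, mismatch = -4, baseOnly = TRUE),
      gapOpening = 0, gapExtension = 12, type = "global")
    expect_equal(hits$score[i], Biostrings::score(aln))
  }
})

test_that("seeded and exact modes agree on a mid-size planted case", {
  set.seed(19)
  s <- random_ir_case(len = 1400, plant = TRUE, arm = 120, identity = 0.95,
                      spacer = 400)
  exact <- find_inverted_repeats(s, exact_max_len = 2000L)
  seeded <- find_inverted_repeats(s, exact_max_len = 10L)
  expect_equal(nrow(exact), nrow(seeded))
  expect_equal(exact$arm5_start, seeded$arm5_start)
  expect_equal(exact$arm3_end, seeded$arm3_end)
  expect_equal(exact$score, seeded$score)
})

test_that("strand symmetry: the reverse complement carries the mirrored pair", {
  set.seed(23)
  s <- random_ir_case(len = 900, plant = TRUE, arm = 80, identity = 1,
                      spacer = 300)
  h1 <- find_inverted_repeats(s)
  h2 <- find_inverted_repeats(revcomp(s))
  expect_equal(nrow(h1), 1L)
  expect_equal(nrow(h2), 1L)
  n <- nchar(s)
  expect_equal(h2$arm5_start, n - h1$arm3_end)
  expect_equal(h2$arm3_end, n - h1$arm5_start)
  expect_equal(h2$score, h1$score)
})

test_that("size filters are inclusive, idempotent and order-preserving", {
  mk <- function(ins, a5, a3) tibble::tibble(
    contig_id = "c", arm5_start = 0L, arm5_end = a5,
    arm3_start = ins - a3, arm3_end = ins,
    insert_start = 0L, insert_end = ins, insert_len = ins,
    arm5_len = a5, arm3_len = a3, score = 100L,
    arm_identity_pct = 95, n_mismatches = 0L, n_gaps = 0L)
  pairs <- dplyr::bind_rows(
    mk(5999, 100, 100),    # below insert bound -> rejected
    mk(6000, 100, 100),    # inclusive lower bound -> kept
    mk(80000, 8000, 8000), # inclusive upper bounds -> kept
    mk(80001, 100, 100),   # above insert bound
    mk(20000, 99, 100),    # arm too short
    mk(20000, 100, 8001),  # arm too long
    mk(20000, 100, 100),   # kept
    mk(7000, 3500, 3500),  # kept (arms together equal insert)
    mk(10000, 50, 50),     # both arms too short
    mk(40000, 8000, 100))  # kept
  kept <- filter_candidates(pairs)
  expect_equal(nrow(kept), 5L)
  expect_identical(filter_candidates(kept), kept)
  expect_equal(kept$insert_len,
               pairs$insert_len[c(2, 3, 7, 8, 10)])
})

test_that("tir_identity matches construction", {
  set.seed(6)
  arm <- random_dna_str(100, 0.5)
  v <- strsplit(revcomp(arm), "")[[1]]
  pos <- sample(100, 3)
  for (p in pos) v[p] <- setdiff(c("A", "C", "G", "T"), v[p])[1]
  s <- paste0(strrep("A", 50), arm, random_dna_str(500, 0.5),
              paste(v, collapse = ""), strrep("A", 50))
  pair <- tibble::tibble(arm5_start = 50L, arm5_end = 150L,
                         arm3_start = 650L, arm3_end = 750L)
  expect_equal(tir_identity(pair, s), 97.0)
  pair_perfect <- tibble::tibble(arm5_start = 50L, arm5_end = 150L,
                                 arm3_start = 650L, arm3_end = 750L)
  s2 <- paste0(strrep("A", 50), arm, random_dna_str(500, 0.5),
               revcomp(arm), strrep("A", 50))
  expect_equal(tir_identity(pair_perfect, s2), 100.0)
  # unrelated random arms stay far from the planted range
  ids <- replicate(20, {
    s3 <- paste0(random_dna_str(100, 0.5), random_dna_str(100, 0.5))
    tir_identity(tibble::tibble(arm5_start = 0L, arm5_end = 100L,
                                arm3_start = 100L, arm3_end = 200L), s3)
  })
  expect_lt(max(ids), 60)
})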