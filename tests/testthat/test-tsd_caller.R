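test_that("flank extraction is plain coordinate arithmetic with edge warnings", {
  s <- random_dna_str(300)
  fl <- extract_flanks(s, 100, 200, flank_bp = 50)
  expect_equal(fl$left, substr(s, 51, 100))
  expect_equal(fl$right, substr(s, 201, 250))
  expect_warning(fl0 <- extract_flanks(s, 0, 100), "contig edge")
  expect_equal(fl0$left, "")
  # synthetic truth round-trip: planted flanks re-extracted exactly
  sim <- simulate_assembly(small_sim_config(seed = 3L))
  el <- sim$truth$elements[1, ]
  tsd <- sim$truth$tsds[sim$truth$tsds$element_id == el$element_id, ]
  seqc <- sim$assembly$seq[sim$assembly$id == el$contig_id]
  fl <- extract_flanks(seqc, el$start, el$end)
  expect_true(endsWith(fl$left, tsd$left_copy))
  expect_true(startsWith(fl$right, tsd$right_copy))
})

test_that("the caller reproduces the canonical worked duplications", {
  set.seed(100)
  ctx <- function(n) random_dna_str(n)
  left <- paste0(ctx(43), "TGAATAA")
  right <- paste0("TCAATAA", ctx(43))
  call <- call_tsd(left, right)
  expect_equal(call$length_bp, 7L)
  expect_equal(call$n_mismatches, 1L)
  expect_equal(call$left_copy, "TGAATAA")
  expect_equal(call$right_copy, "TCAATAA")
  expect_equal(call$consensus, "TGAATAA")   # left-copy base at the mismatch

  left2 <- paste0(ctx(45), "GTTAT")
  right2 <- paste0("GTTAT", ctx(45))
  call2 <- call_tsd(left2, right2)
  expect_equal(call2$consensus, "GTTAT")
  expect_equal(call2$length_bp, 5L)
  expect_equal(call2$n_mismatches, 0L)
  expect_false(call2$low_complexity)
})

test_that("call_tsd equals the naive triple enumeration oracle", {
  set.seed(55)
  n_called <- 0
  for (rep in 1:150) {
    if (rep %% 3 == 0) {
      # plant a duplication so the hit path is exercised
      tsd <- random_dna_str(sample(4:12, 1))
      left <- paste0(random_dna_str(50 - nchar(tsd)), tsd)
      right <- paste0(tsd, random_dna_str(50 - nchar(tsd)))
    } else {
      left <- random_dna_str(50); right <- random_dna_str(50)
    }
    got <- call_tsd(left, right)
    want <- oracle_call_tsd(left, right)
    if (is.null(want)) {
      expect_null(got)
    } else {
      n_called <- n_called + 1
      expect_equal(got$left_copy, want$lc)
      expect_equal(got$right_copy, want$rc)
      expect_equal(got$length_bp, want$L)
      expect_equal(got$n_mismatches, want$mm)
      expect_equal(got$left_offset_bp, want$ol)
      expect_equal(got$right_offset_bp, want$orr)
    }
  }
  expect_gt(n_called, 40)
})

test_that("reported copies are verbatim flank substrings at their offsets", {
  set.seed(60)
  for (rep in 1:30) {
    tsd <- random_dna_str(sample(5:10, 1))
    left <- paste0(random_dna_str(40), tsd, random_dna_str(sample(0:3, 1)))
    right <- paste0(random_dna_str(sample(0:3, 1)), tsd, random_dna_str(40))
    call <- call_tsd(left, right)
    if (is.null(call)) next
    nl <- nchar(left)
    expect_equal(call$left_copy,
                 substr(left, nl - call$left_offset_bp - call$length_bp + 1,
                        nl - call$left_offset_bp))
    expect_equal(call$right_copy,
                 substr(right, call$right_offset_bp + 1,
                        call$right_offset_bp + call$length_bp))
  }
})

test_that("the null rate on unrelated flanks matches first principles", {
  # under the defaults a chance call needs an exact short duplication at
  # one of the (offset, length) placements; the union over placements
  # puts the expected null rate in the tens of percent, dominated by
  # exact 4-mers, and it must agree with the brute-force enumeration
  set.seed(70)
  calls <- vapply(1:300, function(i) {
    left <- random_dna_str(50); right <- random_dna_str(50)
    got <- call_tsd(left, right)
    want <- oracle_call_tsd(left, right)
    expect_equal(is.null(got), is.null(want))
    !is.null(got)
  }, logical(1))
  expect_lte(mean(calls), 0.30)
  # restricting to flush placements and length >= 5 makes chance calls rare
  strict <- vapply(1:300, function(i) {
    !is.null(call_tsd(random_dna_str(50), random_dna_str(50),
                      min_tsd = 5, max_offset = 0))
  }, logical(1))
  expect_lte(mean(strict), 0.05)
})

test_that("low-complexity rule flags degenerate calls only", {
  expect_true(flag_low_complexity("GAGGG"))     # 4/5 G
  expect_false(flag_low_complexity("GTTAT"))    # 3 bases, max 2/5
  expect_true(flag_low_complexity("AAAAAA"))
  expect_true(flag_low_complexity("ATATAT"))    # two distinct bases
  expect_false(flag_low_complexity("TGAATAA"))  # 4/7 A is below 0.8
  expect_error(flag_low_complexity(""))
})

test_that("conservation summary counts non-flagged calls per element", {
  ids <- paste0("e", 1:10)
  expect_equal(tsd_conservation_summary(NULL, ids)$frac_conserved, 0)
  empty <- tsd_conservation_summary(NULL, character(0))
  expect_true(is.na(empty$frac_conserved))

  calls <- tibble::tibble(
    element_id = c("e1", "e2", "e3", "e4"),
    length_bp = c(6L, 7L, 5L, 5L),
    n_mismatches = c(0L, 1L, 0L, 3L),
    low_complexity = c(FALSE, FALSE, TRUE, FALSE))
  s <- tsd_conservation_summary(calls, ids, max_mismatch = 2L)
  expect_equal(s$frac_conserved, 0.2)   # e1 and e2
  expect_equal(s$frac_exact, 0.1)       # e1 only
  # adding a low-complexity-only call never raises the fraction
  more <- dplyr::bind_rows(calls, tibble::tibble(
    element_id = "e5", length_bp = 5L, n_mismatches = 0L,
    low_complexity = TRUE))
  s2 <- tsd_conservation_summary(more, ids, max_mismatch = 2L)
  expect_equal(s2$frac_conserved, s$frac_conserved)
})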