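mk_hits <- function(...) {
  base <- tibble::tibble(
    protein_id = "p1", contig_id = "c1", start = 100L, end = 1000L,
    strand = "+", marker_class = "pATPase", model_id = "HMM",
    e_value = 1e-20, model_coverage = 0.9, query_coverage = 0.9)
  dplyr::bind_rows(lapply(list(...), function(x) {
    utils::modifyList(base, x) |> tibble::as_tibble()
  }))
}

test_that("marker filtering applies e-value and class-specific coverage", {
  hits <- mk_hits(
    list(protein_id = "a", e_value = 1e-2),                 # fails e-value
    list(protein_id = "b", e_value = 1e-4),                 # passes
    list(protein_id = "c", marker_class = "MCP_PLV",
         model_coverage = 0.65),                            # fails MCP cov
    list(protein_id = "d", marker_class = "MCP_PLV",
         model_coverage = 0.75, query_coverage = 0.80),     # passes
    list(protein_id = "e", model_coverage = 0.10))          # non-MCP: kept
  suppressMessages(out <- filter_marker_hits(hits))
  expect_setequal(out$protein_id, c("b", "d", "e"))
  # per-protein best hit per class
  dup <- mk_hits(list(protein_id = "x", e_value = 1e-10),
                 list(protein_id = "x", e_value = 1e-30))
  suppressMessages(best <- filter_marker_hits(dup))
  expect_equal(nrow(best), 1L)
  expect_equal(best$e_value, 1e-30)
  expect_error(suppressMessages(
    filter_marker_hits(mk_hits(list(marker_class = "nonsense")))),
    "unknown marker class")
})

test_that("marker tables load from TSV and empty tables give empty lists", {
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(mk_hits(list(protein_id = "a")), f)
  suppressMessages(out <- load_marker_hits(f))
  expect_equal(nrow(out), 1L)
  readr::write_tsv(mk_hits(list())[0, ], f)
  suppressMessages(out0 <- load_marker_hits(f))
  expect_equal(nrow(out0), 0L)
  # malformed: missing columns
  readr::write_tsv(tibble::tibble(foo = 1), f)
  expect_error(load_marker_hits(f), "missing column")
})

test_that("domain-table-style input is parsed with coverages computed", {
  f <- withr::local_tempfile(fileext = ".domtblout")
  lines <- c(
    "# comment",
    paste("ctg1_10 - 200 MCP_PLV - 120 1e-20 50 1.0 1 1 1e-21 1e-20 45 0.1",
          "10 110 20 180 20 185 0.90 desc"),
    paste("ctg1_11 - 100 pATPase - 90 1e-2 10 1.0 1 1 1e-3 1e-2 9 0.1",
          "5 85 10 95 10 95 0.90 desc"))
  writeLines(lines, f)
  suppressMessages(out <- load_marker_hits(f))
  expect_equal(out$protein_id, "ctg1_10")       # second row fails e-value
  expect_equal(out$model_coverage, (110 - 10 + 1) / 120)
  expect_equal(out$query_coverage, (180 - 20 + 1) / 200)
  writeLines(c("#", "too few fields"), f)
  expect_error(load_marker_hits(f), "line")
})

test_that("classification is total and deterministic over marker subsets", {
  cls <- plvscan:::classify_element
  expect_equal(cls(c("MCP_PLV", "pATPase")), "PLV")
  expect_equal(cls("MCP_virophage"), "virophage")
  expect_equal(cls(c("MCP_PLV", "MCP_virophage")), "hybrid")
  expect_equal(cls(c("pATPase", "rve_INT")), "unassigned")
  expect_equal(cls(character(0)), "unassigned")
  classes <- c("MCP_PLV", "MCP_virophage", "mCP", "pATPase", "protease",
               "rve_INT", "YREC", "pPolB", "other")
  for (k in 0:3) {
    for (i in 1:10) {
      sub <- sample(classes, k)
      expect_true(cls(sub) %in% c("PLV", "virophage", "hybrid", "unassigned"))
      expect_identical(cls(sub), cls(sub))
    }
  }
})

test_that("candidates without interior markers are diverted, not called", {
  set.seed(33)
  arm <- random_dna_str(300, 0.4)
  s <- paste0(strrep("A", 2000), arm, random_dna_str(8000, 0.4),
              revcomp(arm), strrep("A", 2000))
  pairs <- filter_candidates(find_inverted_repeats(s))
  expect_equal(nrow(pairs), 1L)
  res <- call_elements(s, "c1", pairs, markers = NULL)
  expect_equal(nrow(res$elements), 0L)
  expect_equal(nrow(res$candidates_unconfirmed), 1L)
  # same candidate with an interior marker is called and classified
  mk <- tibble::tibble(protein_id = "p", contig_id = "c1",
                       start = pairs$insert_start + 1000,
                       end = pairs$insert_start + 2000,
                       strand = "+", marker_class = "MCP_PLV",
                       model_id = "m", e_value = 1e-9,
                       model_coverage = 0.9, query_coverage = 0.9)
  res2 <- call_elements(s, "c1", pairs, markers = mk)
  expect_equal(nrow(res2$elements), 1L)
  expect_equal(res2$elements$classification, "PLV")
  expect_true(res2$elements$complete)
  # both MCP classes inside -> hybrid
  mk2 <- dplyr::bind_rows(mk, utils::modifyList(
    mk, list(protein_id = "q", marker_class = "MCP_virophage")))
  res3 <- call_elements(s, "c1", pairs, markers = mk2)
  expect_equal(res3$elements$classification, "hybrid")
})

test_that("genome statistics reproduce the reference density arithmetic", {
  elements <- tibble::tibble(element_id = paste0("e", 1:706),
                             length = 22200, complete = TRUE,
                             tir_identity_pct = 90)
  gs <- genome_stats(elements, 331e6, "R_lacustris")
  expect_equal(round(gs$density_per_mb, 1), 2.1)
  expect_equal(gs$n_elements, 706L)
  expect_equal(gs$pct_genome_in_elements,
               100 * 706 * 22200 / 331e6)
  # zero elements
  gs0 <- genome_stats(NULL, 1e6)
  expect_equal(gs0$density_per_mb, 0)
  expect_equal(gs0$pct_genome_in_elements, 0)
  expect_error(genome_stats(NULL, 0))
})

test_that("pipeline statistics agree with truth-table recomputation", {
  sim <- simulate_assembly(small_sim_config(seed = 17L))
  res <- suppressMessages(
    detect_elements(sim$assembly, filter_marker_hits(sim$marker_hits)))
  truth_stats <- genome_stats(sim$truth$elements, sum(sim$assembly$length),
                              "truth")
  expect_equal(res$stats$n_elements, truth_stats$n_elements)
  expect_equal(res$stats$density_per_mb, truth_stats$density_per_mb)
  expect_lt(abs(res$stats$pct_genome_in_elements -
                  truth_stats$pct_genome_in_elements), 0.05)
  # every element interval lies inside its contig
  for (i in seq_len(nrow(res$elements))) {
    len <- sim$assembly$length[sim$assembly$id == res$elements$contig_id[i]]
    expect_gte(res$elements$start[i], 0)
    expect_lte(res$elements$end[i], len)
  }
})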