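# Synthetic assemblies with planted endogenous elements. The generator
# emulates the genomic structure the detector targets: host contigs of
# configurable GC; TIR-bounded, GC-shifted elements of 6-80 kb with
# arms of 100 bp-8 kb at a configurable arm identity; target site
# duplications immediately outside the TIRs; hallmark-gene cassettes
# mirrored into a marker-hit table; and GC-rich nested retroelement
# insertions flanked by direct repeats. Background sequence is i.i.d.
# per base - the detection signals used downstream (GC windows,
# repeats) do not require realistic k-mer structure, and i.i.d. makes
# analytic expectations available for tests.

#' Simulation configuration
#'
#' Defaults define the package's reference study condition: a 20 Mb
#' assembly (10 contigs of 2 Mb) at host GC 0.55 carrying 100 planted
#' elements at GC 0.38 (a 17-point shift, mid-range for endogenous PLVs)
#' with arm identity 0.95, canonical 5-8 bp exact TSDs with no
#' boundary offset, and 10 elements carrying a nested GC-rich
#' retroelement insertion flanked by 300 bp direct repeats.
#'
#' @param seed Integer seed; fixes every byte of output.
#' @param n_contigs,contig_len_bp Assembly shape.
#' @param host_gc,element_gc,nested_gc GC fractions of host background,
#'   element interiors/arms, and nested insertions.
#' @param n_elements Number of planted elements.
#' @param element_len_bp,tir_len_bp Length ranges (2-vectors, bp) for
#'   elements (within 6-80 kb) and TIR arms (within 100 bp-8 kb).
#' @param tir_identity Target identity between the two arms of a pair.
#' @param tsd_len_bp TSD length range (2-vector, within 4-25 bp).
#' @param tsd_mismatches Substitutions planted between the two TSD copies.
#' @param tsd_offset_bp Pad between each TIR boundary and its TSD copy
#'   (0-3 bp, applied to both sides).
#' @param n_nested Number of elements receiving a nested insertion (the
#'   fraction of elements carrying one is not a settled quantity; this
#'   is an explicit knob).
#' @param nested_len_bp Nested-insertion length range (within 4-9.5 kb).
#' @param dr_len_bp Direct-repeat length flanking nested insertions.
#' @param marker_cassette Marker classes planted inside every element.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_contigs = 10L, contig_len_bp = 2e6,
                       host_gc = 0.55, n_elements = 100L,
                       element_len_bp = c(6000, 80000),
                       tir_len_bp = c(100, 8000), tir_identity = 0.95,
                       element_gc = 0.38,
                       tsd_len_bp = c(5, 8), tsd_mismatches = 0L,
                       tsd_offset_bp = 0L,
                       n_nested = 10L, nested_len_bp = c(4000, 9500),
                       nested_gc = 0.62, dr_len_bp = 300L,
                       marker_cassette = c("MCP_PLV", "pATPase",
                                           "rve_INT", "protease")) {
  stopifnot(element_len_bp[1] >= 6000, element_len_bp[2] <= 80000,
            tir_len_bp[1] >= 100, tir_len_bp[2] <= 8000,
            tsd_len_bp[1] >= 4, tsd_len_bp[2] <= 25,
            tsd_offset_bp >= 0, tsd_offset_bp <= 3,
            nested_len_bp[1] >= 4000, nested_len_bp[2] <= 9500,
            tir_identity > 0, tir_identity <= 1,
            host_gc >= 0, host_gc <= 1, element_gc >= 0, element_gc <= 1,
            tsd_mismatches >= 0, n_nested <= n_elements)
  structure(as.list(environment()), class = "sim_config")
}

random_dna <- function(n, gc) {
  if (n <= 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# plant `n_mut` substitutions at distinct random positions
mutate_seq <- function(seq, n_mut) {
  if (n_mut <= 0) return(seq)
  v <- strsplit(seq, "")[[1]]
  pos <- sample(length(v), min(n_mut, length(v)))
  for (p in pos) {
    v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  }
  paste(v, collapse = "")
}

# Build one element construct (TSD + pad + TIR5 + interior + TIR3 + pad
# + TSD) and a relative-coordinate truth description.
build_element_construct <- function(cfg, element_id, with_nested) {
  elem_len <- sample(seq(cfg$element_len_bp[1], cfg$element_len_bp[2]), 1)
  if (with_nested) {
    # nested insertion inflates the element; keep the total within the
    # planted size class
    max_extra <- cfg$nested_len_bp[2] + 2 * cfg$dr_len_bp
    elem_len <- min(elem_len, cfg$element_len_bp[2] - max_extra - 500)
    elem_len <- max(elem_len, cfg$element_len_bp[1])
  }
  tir_max <- min(cfg$tir_len_bp[2], (elem_len - 2000) %/% 2)
  tir_len <- sample(seq(cfg$tir_len_bp[1], max(cfg$tir_len_bp[1], tir_max)), 1)
  interior_len <- elem_len - 2 * tir_len

  arm5 <- random_dna(tir_len, cfg$element_gc)
  n_mut <- round((1 - cfg$tir_identity) * tir_len)
  arm3 <- mutate_seq(revcomp(arm5), n_mut)
  interior <- random_dna(interior_len, cfg$element_gc)

  # marker cassette in the first half of the interior
  n_mk <- length(cfg$marker_cassette)
  mk_len <- max(200L, min(1200L, interior_len %/% (2L * n_mk)))
  markers <- tibble::tibble(
    element_id = element_id,
    marker_class = cfg$marker_cassette,
    rel_start = tir_len + (seq_len(n_mk) - 1L) * (mk_len + 50L),
    rel_end = tir_len + (seq_len(n_mk) - 1L) * (mk_len + 50L) + mk_len)

  nested <- NULL
  if (with_nested) {
    nest_len <- sample(seq(cfg$nested_len_bp[1], cfg$nested_len_bp[2]), 1)
    dr <- random_dna(cfg$dr_len_bp, cfg$host_gc)
    nest_seq <- paste0(dr, random_dna(nest_len, cfg$nested_gc), dr)
    # insert after the cassette, mid-interior
    ins_at <- tir_len + interior_len %/% 2  # relative to element start
    pre <- substr(interior, 1, ins_at - tir_len)
    post <- substr(interior, ins_at - tir_len + 1, interior_len)
    interior <- paste0(pre, nest_seq, post)
    interior_len <- nchar(interior)
    elem_len <- elem_len + nchar(nest_seq)
    nested <- tibble::tibble(element_id = element_id,
                             rel_start = ins_at, rel_end = ins_at + nchar(nest_seq),
                             core_start = ins_at + cfg$dr_len_bp,
                             core_end = ins_at + cfg$dr_len_bp + nest_len)
  }

  tsd_len <- sample(seq(cfg$tsd_len_bp[1], cfg$tsd_len_bp[2]), 1)
  tsd_left <- random_dna(tsd_len, cfg$host_gc)
  tsd_right <- mutate_seq(tsd_left, cfg$tsd_mismatches)
  pad_l <- random_dna(cfg$tsd_offset_bp, cfg$host_gc)
  pad_r <- random_dna(cfg$tsd_offset_bp, cfg$host_gc)

  construct <- paste0(tsd_left, pad_l, arm5, interior, arm3, pad_r, tsd_right)
  elem_rel_start <- tsd_len + cfg$tsd_offset_bp   # element = TIR outer edges
  list(construct = construct,
       elem_rel_start = elem_rel_start,
       elem_len = elem_len, tir_len = tir_len,
       tsd_left = tsd_left, tsd_right = tsd_right, tsd_len = tsd_len,
       markers = markers, nested = nested, element_id = element_id)
}

#' Simulate an assembly with planted elements and ground truth
#'
#' @param cfg A [sim_config()].
#' @return A list with `assembly` (contig tibble as from [read_fasta()]),
#'   `truth` (list of tibbles: `elements`, `tirs`, `tsds`, `markers`,
#'   `nested`), and `marker_hits` (a hit table in the layout
#'   [load_marker_hits()] consumes, with synthetic scores passing the
#'   default filters).
#' @export
simulate_assembly <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, simulate_assembly_impl(cfg))
}

simulate_assembly_impl <- function(cfg) {
  edge_margin <- 15000L   # clean host flank for GC deltas
  min_gap <- 25000L       # between consecutive constructs
  n_per <- table(factor(rep_len(seq_len(cfg$n_contigs), cfg$n_elements),
                        levels = seq_len(cfg$n_contigs)))
  nested_flags <- rep(FALSE, cfg$n_elements)
  if (cfg$n_nested > 0 && cfg$n_elements > 0) {
    nested_flags[sample(cfg$n_elements, cfg$n_nested)] <- TRUE
  }

  contigs <- vector("list", cfg$n_contigs)
  truth_e <- list(); truth_t <- list(); truth_s <- list()
  truth_m <- list(); truth_n <- list(); hits <- list()
  eid <- 0L
  for (ci in seq_len(cfg$n_contigs)) {
    contig_id <- sprintf("ctg%03d", ci)
    k <- as.integer(n_per[ci])
    cons <- vector("list", k)
    for (e in seq_len(k)) {
      eid <- eid + 1L
      cons[[e]] <- build_element_construct(
        cfg, sprintf("elem%04d", eid), nested_flags[eid])
    }
    clens <- vapply(cons, function(x) nchar(x$construct), numeric(1))
    free <- cfg$contig_len_bp - sum(clens) - 2 * edge_margin -
      (max(k - 1, 0)) * min_gap
    if (free < 0) {
      stop("infeasible packing: elements assigned to ", contig_id,
           " need ", sum(clens) + 2 * edge_margin + (k - 1) * min_gap,
           " bp but the contig has ", cfg$contig_len_bp,
           " (first conflict: ",
           if (k > 0) cons[[1]]$element_id else "none", ")")
    }
    # random partition of the free bases over the k+1 host gaps
    cuts <- if (k > 0) sort(stats::runif(k)) else numeric(0)
    gap_extra <- round(diff(c(0, cuts, 1)) * free)
    gaps <- c(edge_margin, rep(min_gap, max(k - 1, 0)), edge_margin) + gap_extra
    pieces <- character(2 * k + 1)
    pos <- 0L
    for (e in seq_len(k)) {
      g <- gaps[e]
      pieces[2 * e - 1] <- random_dna(g, cfg$host_gc)
      pos <- pos + g
      con <- cons[[e]]
      pieces[2 * e] <- con$construct
      # global truth coordinates (0-based half-open)
      es <- pos + con$elem_rel_start
      ee <- es + con$elem_len
      truth_e[[con$element_id]] <- tibble::tibble(
        element_id = con$element_id, contig_id = contig_id,
        start = es, end = ee, length = con$elem_len,
        tir_len = con$tir_len, tsd_len = con$tsd_len,
        has_nested = !is.null(con$nested))
      truth_t[[con$element_id]] <- tibble::tibble(
        element_id = con$element_id, contig_id = contig_id,
        arm = c("5", "3"),
        start = c(es, ee - con$tir_len),
        end = c(es + con$tir_len, ee))
      truth_s[[con$element_id]] <- tibble::tibble(
        element_id = con$element_id, contig_id = contig_id,
        left_copy = con$tsd_left, right_copy = con$tsd_right,
        length_bp = con$tsd_len,
        n_mismatches = sum(strsplit(con$tsd_left, "")[[1]] !=
                             strsplit(con$tsd_right, "")[[1]]),
        offset_bp = cfg$tsd_offset_bp,
        left_start = pos, left_end = pos + con$tsd_len,
        right_start = ee + cfg$tsd_offset_bp,
        right_end = ee + cfg$tsd_offset_bp + con$tsd_len)
      mk <- con$markers
      mk$contig_id <- contig_id
      mk$start <- es + mk$rel_start
      mk$end <- es + mk$rel_end
      truth_m[[con$element_id]] <- mk[, c("element_id", "contig_id",
                                          "marker_class", "start", "end")]
      hit <- tibble::tibble(
        protein_id = paste0(con$element_id, "_p", seq_len(nrow(mk))),
        contig_id = contig_id, start = mk$start, end = mk$end,
        strand = "+", marker_class = mk$marker_class,
        model_id = paste0("HMM_", mk$marker_class),
        e_value = 1e-20, model_coverage = 0.95, query_coverage = 0.95)
      if (!is.null(con$nested)) {
        nst <- con$nested
        nst$contig_id <- contig_id
        nst$start <- es + nst$rel_start
        nst$end <- es + nst$rel_end
        truth_n[[con$element_id]] <- nst[, c("element_id", "contig_id",
                                             "start", "end")]
        hit <- dplyr::bind_rows(hit, tibble::tibble(
          protein_id = paste0(con$element_id, "_rt"),
          contig_id = contig_id,
          start = es + nst$core_start + 100,
          end = es + nst$core_start + 1300,
          strand = "+", marker_class = "other", model_id = "RVT_1",
          e_value = 1e-15, model_coverage = 0.9, query_coverage = 0.9))
      }
      hits[[con$element_id]] <- hit
      pos <- pos + nchar(con$construct)
    }
    pieces[2 * k + 1] <- random_dna(gaps[k + 1], cfg$host_gc)
    seqc <- paste(pieces, collapse = "")
    # top up rounding slack so every contig has the configured length
    if (nchar(seqc) < cfg$contig_len_bp) {
      seqc <- paste0(seqc, random_dna(cfg$contig_len_bp - nchar(seqc),
                                      cfg$host_gc))
    } else if (nchar(seqc) > cfg$contig_len_bp) {
      seqc <- substr(seqc, 1, cfg$contig_len_bp)
    }
    contigs[[ci]] <- tibble::tibble(id = contig_id, seq = seqc,
                                    length = nchar(seqc))
  }
  list(assembly = dplyr::bind_rows(contigs),
       truth = list(elements = dplyr::bind_rows(truth_e),
                    tirs = dplyr::bind_rows(truth_t),
                    tsds = dplyr::bind_rows(truth_s),
                    markers = dplyr::bind_rows(truth_m),
                    nested = dplyr::bind_rows(truth_n)),
       marker_hits = dplyr::bind_rows(hits))
}

# Frozen flank context for the worked examples. Verified properties:
# with these 50-bp flanks the sliding/padding caller's optimum is the
# intended duplication (7 bp with one mismatch for a; exact GTTAT for b).
TOY_LEFT_A  <- "CGCTGACCTGTCCTGCCGGGGTCATGGTCACGTTCTTTAGGATTGAATAA"
TOY_RIGHT_A <- "TCAATAAGTCCAACCAGGAGATGGCAAACTGGGAACTCGACTGCTGGGCT"
TOY_LEFT_B  <- "CCGTGTTACTCCGTGTTATCGTTGCACCGTCGGGAACGTGATCACGTTAT"
TOY_RIGHT_B <- "GTTATTCTCGTGGATACCCGACGTCAAAACTGAGTATCGACGATACTCGT"

#' Fixed worked-example constructs
#'
#' Two deterministic single-element contigs: (a) an element whose left
#' flank ends in TGAATAA and whose right flank begins with TCAATAA (a
#' 7 bp duplication with one mismatched base), and (b) an element
#' flanked by exact GTTAT copies (a 5 bp duplication). Both elements are
#' TIR-bounded and inside the 6-80 kb size class.
#'
#' @return A list with `assembly` and `truth` as in [simulate_assembly()]
#'   (no marker table; the constructs exercise the TIR and TSD stages).
#' @export
toy_worked_examples <- function() {
  withr::with_seed(20260927L, {
    build_one <- function(contig_id, element_id, lflank, rflank,
                          elem_len, tir_len) {
      arm5 <- random_dna(tir_len, 0.40)
      arm3 <- revcomp(arm5)                      # perfect arms
      interior <- random_dna(elem_len - 2 * tir_len, 0.40)
      pad <- 1000L
      host_l <- paste0(random_dna(pad, 0.55), lflank)
      host_r <- paste0(rflank, random_dna(pad, 0.55))
      seqc <- paste0(host_l, arm5, interior, arm3, host_r)
      es <- nchar(host_l)
      ee <- es + elem_len
      list(contig = tibble::tibble(id = contig_id, seq = seqc,
                                   length = nchar(seqc)),
           element = tibble::tibble(element_id = element_id,
                                    contig_id = contig_id,
                                    start = es, end = ee, length = elem_len,
                                    tir_len = tir_len),
           tirs = tibble::tibble(element_id = element_id,
                                 contig_id = contig_id, arm = c("5", "3"),
                                 start = c(es, ee - tir_len),
                                 end = c(es + tir_len, ee)))
    }
    a <- build_one("toy_a", "toy_elem_a", TOY_LEFT_A, TOY_RIGHT_A,
                   10000L, 200L)
    b <- build_one("toy_b", "toy_elem_b", TOY_LEFT_B, TOY_RIGHT_B,
                   8000L, 150L)
    tsds <- tibble::tibble(
      element_id = c("toy_elem_a", "toy_elem_b"),
      left_copy = c("TGAATAA", "GTTAT"),
      right_copy = c("TCAATAA", "GTTAT"),
      length_bp = c(7L, 5L), n_mismatches = c(1L, 0L), offset_bp = 0L)
    list(assembly = dplyr::bind_rows(a$contig, b$contig),
         truth = list(elements = dplyr::bind_rows(a$element, b$element),
                      tirs = dplyr::bind_rows(a$tirs, b$tirs),
                      tsds = tsds))
  })
}
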