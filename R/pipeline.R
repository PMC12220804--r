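# Pipeline orchestration: one configuration object, in-memory stage
# runners, and file-writing wrappers with a run manifest so every run
# is reproducible and every filter's drop count is auditable.

#' Default pipeline configuration
#'
#' All stage thresholds in one nested list; every default matches the
#' stage function it parameterises.
#'
#' @return Nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    gc = list(window_bp = 500L, min_delta_points = 10, min_len_bp = 5000,
              max_len_bp = 80000, flank_bp = 10000),
    tir = list(match = 3L, mismatch = -4L, gap_penalty = 12L,
               min_score = 50L, max_separation_bp = 80000,
               min_insert = 6000, max_insert = 80000,
               min_tir = 100, max_tir = 8000,
               exact_max_len = 1500L, seed_k = 12L, band = 16L,
               xdrop = 100L),
    tsd = list(flank_bp = 50L, min_tsd = 4L, max_tsd = 25L,
               max_offset = 3L, max_mismatch = 2L),
    markers = list(e_value_max = 1e-3, min_model_cov = 0,
                   min_query_cov = 0, mcp_min_cov = 0.70,
                   require_marker = TRUE, min_gc_delta = 0),
    network = list(min_cluster_size = 10L, resolution = 1.0,
                   n_restarts = 8L, derep_identity = 0.90,
                   derep_coverage = 0.90))
}

#' Read / write a pipeline configuration
#'
#' YAML on disk; round-trips losslessly.
#'
#' @param path File path.
#' @param config Configuration list.
#' @return `read_config`: the configuration list; `write_config`:
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  utils::modifyList(default_config(), cfg)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Run the detection stages on an in-memory assembly
#'
#' Per contig: GC windows and segments, inverted-repeat search, size
#' filtering, element calling with marker evidence, TSD calling; then
#' genome-level statistics.
#'
#' @param assembly Contig tibble (as from [read_fasta()]).
#' @param marker_hits Filtered marker-hit tibble (or `NULL` with
#'   `require_marker = FALSE`).
#' @param config Configuration list (see [default_config()]).
#' @param genome_id Genome label for the statistics row.
#' @return List: `elements`, `tsds`, `candidates_unconfirmed`,
#'   `gc_segments`, `tir_pairs` (size-filtered), `stats`, `funnel`
#'   (per-filter candidate counts).
#' @export
detect_elements <- function(assembly, marker_hits = NULL,
                            config = default_config(),
                            genome_id = "assembly") {
  tir_cfg <- config$tir
  scoring <- ir_scoring(tir_cfg$match, tir_cfg$mismatch, tir_cfg$gap_penalty,
                        tir_cfg$min_score, tir_cfg$max_separation_bp)
  if (config$markers$require_marker && is.null(marker_hits)) {
    stop("require_marker is TRUE but no marker table was given; ",
         "supply marker hits or set markers$require_marker to FALSE")
  }
  all_el <- list(); all_tsd <- list(); all_rej <- list()
  all_seg <- list(); all_tir <- list()
  n_raw <- 0L; n_sized <- 0L
  assembly_gc <- if (nrow(assembly) > 0) {
    gcs <- vapply(assembly$seq, gc_fraction, numeric(1))
    stats::weighted.mean(gcs, assembly$length, na.rm = TRUE)
  } else NA_real_
  for (i in seq_len(nrow(assembly))) {
    cid <- assembly$id[i]; seqc <- assembly$seq[i]
    w <- windowed_gc(seqc, config$gc$window_bp, contig_id = cid)
    segs <- call_gc_segments(w, host_baseline = assembly_gc,
                             min_delta_points = config$gc$min_delta_points,
                             min_len_bp = config$gc$min_len_bp,
                             max_len_bp = config$gc$max_len_bp)
    pairs <- find_inverted_repeats(seqc, scoring, contig_id = cid,
                                   exact_max_len = tir_cfg$exact_max_len,
                                   seed_k = tir_cfg$seed_k,
                                   band = tir_cfg$band, xdrop = tir_cfg$xdrop)
    n_raw <- n_raw + nrow(pairs)
    sized <- filter_candidates(pairs, tir_cfg$min_insert, tir_cfg$max_insert,
                               tir_cfg$min_tir, tir_cfg$max_tir)
    n_sized <- n_sized + nrow(sized)
    called <- call_elements(
      seqc, cid, sized,
      markers = marker_hits,
      require_marker = config$markers$require_marker,
      min_gc_delta = config$markers$min_gc_delta,
      flank_bp = config$gc$flank_bp,
      tsd_args = config$tsd[c("min_tsd", "max_tsd", "max_offset",
                              "max_mismatch")],
      window_bp = config$gc$window_bp)
    all_el[[cid]] <- called$elements
    all_tsd[[cid]] <- called$tsds
    all_rej[[cid]] <- called$candidates_unconfirmed
    all_seg[[cid]] <- segs
    all_tir[[cid]] <- sized
  }
  elements <- dplyr::bind_rows(all_el)
  tsds <- dplyr::bind_rows(all_tsd)
  tsd_sum <- tsd_conservation_summary(
    tsds, if (nrow(elements)) elements$element_id else character(0),
    max_mismatch = config$tsd$max_mismatch)
  total_len <- sum(assembly$length)
  stats <- if (total_len > 0) {
    genome_stats(elements, total_len, genome_id, tsd_summary = tsd_sum)
  } else {
    tibble::tibble(genome_id = genome_id, assembly_len_bp = 0,
                   n_elements = 0L, n_complete = 0L, density_per_mb = 0,
                   pct_genome_in_elements = 0,
                   mean_element_len_bp = NA_real_,
                   mean_tir_identity_pct = NA_real_,
                   frac_tsd_conserved = NA_real_)
  }
  funnel <- tibble::tibble(
    stage = c("tir_pairs_raw", "tir_pairs_size_filtered",
              "elements_marker_confirmed"),
    n = c(n_raw, n_sized, nrow(elements)))
  list(elements = elements, tsds = tsds,
       candidates_unconfirmed = dplyr::bind_rows(all_rej),
       gc_segments = dplyr::bind_rows(all_seg),
       tir_pairs = dplyr::bind_rows(all_tir),
       tsd_summary = tsd_sum, stats = stats, funnel = funnel)
}

#' Run detection end-to-end on files and write outputs
#'
#' Reads the assembly FASTA and marker table, runs [detect_elements()],
#' and writes element GFF3 + TSVs, GC segments, genome statistics, the
#' filter funnel, and a run manifest (archived config + input
#' checksums) into `out_dir`.
#'
#' @param assembly_path FASTA path.
#' @param marker_path Marker-table path (optional when
#'   `require_marker = FALSE`).
#' @param out_dir Output directory (created if needed).
#' @param config Configuration list.
#' @param genome_id Genome label.
#' @return The [detect_elements()] result, invisibly.
#' @export
run_detect <- function(assembly_path, marker_path = NULL, out_dir,
                       config = default_config(), genome_id = "assembly") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  assembly <- read_fasta(assembly_path)
  markers <- NULL
  if (!is.null(marker_path)) {
    markers <- load_marker_hits(
      marker_path, e_value_max = config$markers$e_value_max,
      min_model_cov = config$markers$min_model_cov,
      min_query_cov = config$markers$min_query_cov,
      mcp_min_cov = config$markers$mcp_min_cov)
  }
  res <- detect_elements(assembly, markers, config, genome_id)
  if (nrow(res$elements) > 0) {
    feats <- feature_record(res$elements$contig_id, res$elements$start,
                            res$elements$end, kind = "element",
                            element_id = res$elements$element_id,
                            classification = res$elements$classification)
    write_features(feats, file.path(out_dir, "elements.gff3"), "gff3")
  }
  readr::write_tsv(res$elements, file.path(out_dir, "elements.tsv"))
  readr::write_tsv(res$tsds, file.path(out_dir, "tsds.tsv"))
  readr::write_tsv(res$gc_segments, file.path(out_dir, "gc_segments.tsv"))
  readr::write_tsv(res$stats, file.path(out_dir, "genome_stats.tsv"))
  readr::write_tsv(res$funnel, file.path(out_dir, "filter_funnel.tsv"))
  write_manifest(out_dir, config,
                 c(assembly = assembly_path,
                   if (!is.null(marker_path)) c(markers = marker_path)))
  invisible(res)
}

#' Run the network stage on membership tables
#'
#' @param membership_path Two-column TSV `protein_id`, `ortholog_id`.
#' @param genome_path TSV `protein_id`, `genome_id`.
#' @param out_dir Output directory.
#' @param config Configuration list.
#' @param annotations Optional `genome_id`/`marker_class` tibble for the
#'   cluster gene-content summary.
#' @return List with `graph`, `assignment`, `summary`, invisibly.
#' @export
run_network <- function(membership_path, genome_path, out_dir,
                        config = default_config(), annotations = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  membership <- readr::read_tsv(membership_path, show_col_types = FALSE)
  genomes <- readr::read_tsv(genome_path, show_col_types = FALSE)
  graph <- build_graph(membership, genomes,
                       min_cluster_size = config$network$min_cluster_size)
  assignment <- detect_communities(graph, seed = config$seed,
                                   resolution = config$network$resolution,
                                   n_restarts = config$network$n_restarts)
  readr::write_tsv(graph$edges, file.path(out_dir, "edges.tsv"))
  comm <- tibble::tibble(
    node = names(assignment$communities),
    class = ifelse(names(assignment$communities) %in% graph$genome_nodes,
                   "genome", "ortholog"),
    community = unname(assignment$communities))
  readr::write_tsv(comm, file.path(out_dir, "communities.tsv"))
  summary <- NULL
  if (!is.null(annotations)) {
    summary <- summarize_clusters(assignment, graph, annotations)
    readr::write_tsv(summary, file.path(out_dir, "cluster_summary.tsv"))
  }
  write_manifest(out_dir, config,
                 c(membership = membership_path, genomes = genome_path))
  invisible(list(graph = graph, assignment = assignment, summary = summary))
}

#' Write a simulation fixture bundle
#'
#' FASTA + truth (GFF3 and TSVs) + synthetic marker table +
#' expected-statistics TSV + the archived simulation config.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory.
#' @return The [simulate_assembly()] result, invisibly.
#' @export
run_simulate <- function(cfg = sim_config(), out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_assembly(cfg)
  write_fasta(sim$assembly, file.path(out_dir, "assembly.fasta"))
  readr::write_tsv(sim$marker_hits, file.path(out_dir, "marker_hits.tsv"))
  for (nm in names(sim$truth)) {
    readr::write_tsv(sim$truth[[nm]],
                     file.path(out_dir, paste0("truth_", nm, ".tsv")))
  }
  te <- sim$truth$elements
  if (nrow(te) > 0) {
    feats <- feature_record(te$contig_id, te$start, te$end, kind = "element",
                            element_id = te$element_id)
    write_features(feats, file.path(out_dir, "truth_elements.gff3"), "gff3")
  }
  expected <- genome_stats(te, sum(sim$assembly$length), "synthetic_truth")
  readr::write_tsv(expected, file.path(out_dir, "expected_stats.tsv"))
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "sim_config.yaml"))
  invisible(sim)
}

write_manifest <- function(out_dir, config, input_paths) {
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config, cfg_path)
  manifest <- list(
    package_version = as.character(utils::packageVersion("plvscan")),
    config_md5 = unname(tools::md5sum(cfg_path)),
    inputs = as.list(vapply(input_paths, function(p) {
      unname(tools::md5sum(p))
    }, character(1))))
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(NULL)
}

#' Compare detected elements against a simulation truth table
#'
#' An element matches a truth element when both boundaries agree within
#' `tol_bp`. Precision is matched calls over all calls; recall is
#' matched truth elements over all truth elements.
#'
#' @param elements Element-call tibble.
#' @param truth_elements Truth tibble from [simulate_assembly()].
#' @param tol_bp Boundary tolerance (default 5).
#' @return One-row tibble: `n_called`, `n_truth`, `n_matched`,
#'   `precision`, `recall`.
#' @export
score_detection <- function(elements, truth_elements, tol_bp = 5L) {
  n_called <- nrow(elements); n_truth <- nrow(truth_elements)
  if (n_called == 0 || n_truth == 0) {
    return(tibble::tibble(n_called = n_called, n_truth = n_truth,
                          n_matched = 0L,
                          precision = ifelse(n_called == 0, NA, 0),
                          recall = ifelse(n_truth == 0, NA, 0)))
  }
  matched_truth <- logical(n_truth)
  matched_call <- logical(n_called)
  for (i in seq_len(n_called)) {
    j <- which(!matched_truth &
                 truth_elements$contig_id == elements$contig_id[i] &
                 abs(truth_elements$start - elements$start[i]) <= tol_bp &
                 abs(truth_elements$end - elements$end[i]) <= tol_bp)
    if (length(j)) {
      matched_truth[j[1]] <- TRUE
      matched_call[i] <- TRUE
    }
  }
  tibble::tibble(n_called = n_called, n_truth = n_truth,
                 n_matched = sum(matched_call),
                 precision = mean(matched_call), recall = mean(matched_truth))
}
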