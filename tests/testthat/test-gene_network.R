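mk_membership <- function(cluster_sizes, genomes_per_cluster = NULL) {
  mem <- list(); gen <- list(); p <- 0
  for (i in seq_along(cluster_sizes)) {
    n <- cluster_sizes[i]
    ids <- paste0("p", p + seq_len(n)); p <- p + n
    mem[[i]] <- tibble::tibble(protein_id = ids,
                               ortholog_id = paste0("og", i))
    gs <- if (is.null(genomes_per_cluster)) {
      paste0("g", rep_len(seq_len(n), n))
    } else genomes_per_cluster[[i]]
    gen[[i]] <- tibble::tibble(protein_id = ids, genome_id = gs)
  }
  list(membership = dplyr::bind_rows(mem), genomes = dplyr::bind_rows(gen))
}

test_that("clusters below the size threshold are excluded from the graph", {
  x <- mk_membership(c(9, 10))
  g <- build_graph(x$membership, x$genomes)
  expect_equal(g$ortholog_nodes, "og2")            # 9-member cluster dropped
  expect_equal(sum(g$edges$ortholog_id == "og2"), 10L)  # degree 10
  # boundary inclusive at exactly 10
  expect_equal(nrow(build_graph(x$membership, x$genomes,
                                min_cluster_size = 9)$edges), 19L)
})

test_that("edge weights equal a direct recount on random tables", {
  set.seed(14)
  membership <- tibble::tibble(protein_id = paste0("p", 1:300),
                               ortholog_id = sample(paste0("og", 1:6), 300,
                                                    TRUE))
  genomes <- tibble::tibble(protein_id = paste0("p", 1:300),
                            genome_id = sample(paste0("g", 1:8), 300, TRUE))
  g <- build_graph(membership, genomes, min_cluster_size = 1)
  joint <- merge(membership, genomes, by = "protein_id")
  for (r in sample(nrow(g$edges), 20)) {
    e <- g$edges[r, ]
    expect_equal(e$weight,
                 sum(joint$genome_id == e$genome_id &
                       joint$ortholog_id == e$ortholog_id))
  }
  expect_equal(sum(g$edges$weight), 300L)
})

test_that("a protein assigned to two genomes is a hard error", {
  x <- mk_membership(c(12))
  bad <- dplyr::bind_rows(x$genomes,
                          tibble::tibble(protein_id = "p1",
                                         genome_id = "gOTHER"))
  expect_error(build_graph(x$membership, bad), "more than one genome")
})

test_that("disjoint bicliques are split into their exact optimum", {
  e <- rbind(expand.grid(genome_id = paste0("g", 1:3),
                         ortholog_id = paste0("o", 1:3)),
             expand.grid(genome_id = paste0("g", 4:6),
                         ortholog_id = paste0("o", 4:6)))
  e$weight <- 1
  g <- structure(list(genome_nodes = paste0("g", 1:6),
                      ortholog_nodes = paste0("o", 1:6),
                      edges = tibble::as_tibble(e)),
                 class = "bipartite_graph")
  a <- detect_communities(g, seed = 1)
  expect_equal(a$n_genome_communities, 2L)
  expect_equal(a$n_ortholog_communities, 2L)
  expect_equal(a$barber_modularity, 0.5)
  expect_equal(a$barber_modularity,
               oracle_barber_optimum(plvscan:::graph_matrix(g)))
})

test_that("a single-edge graph merges its two endpoints", {
  g <- structure(list(genome_nodes = "g1", ortholog_nodes = "o1",
                      edges = tibble::tibble(genome_id = "g1",
                                             ortholog_id = "o1", weight = 1)),
                 class = "bipartite_graph")
  a <- detect_communities(g, seed = 1)
  expect_equal(length(unique(a$communities)), 1L)
  empty <- structure(list(genome_nodes = character(0),
                          ortholog_nodes = character(0),
                          edges = tibble::tibble()),
                     class = "bipartite_graph")
  expect_error(detect_communities(empty), "empty graph")
})

test_that("assignment invariants hold on random graphs", {
  set.seed(99)
  for (rep in 1:10) {
    rg <- random_bipartite_graph(sample(4:10, 1), sample(4:10, 1), 0.4)
    a <- detect_communities(rg$graph, seed = rep)
    # reported modularity is recomputable to 1e-9
    expect_lt(abs(barber_modularity(rg$graph, a$communities) -
                    a$barber_modularity), 1e-9)
    # beats the all-singletons and single-community baselines
    nodes <- c(rg$graph$genome_nodes, rg$graph$ortholog_nodes)
    singletons <- stats::setNames(seq_along(nodes), nodes)
    lumped <- stats::setNames(rep(1, length(nodes)), nodes)
    expect_gte(a$barber_modularity,
               barber_modularity(rg$graph, singletons) - 1e-12)
    expect_gte(a$barber_modularity,
               barber_modularity(rg$graph, lumped) - 1e-12)
    # determinism
    b <- detect_communities(rg$graph, seed = rep)
    expect_identical(a$communities, b$communities)
    # connectivity: every mixed community carries at least one edge
    # between its genome and ortholog members
    for (cc in unique(a$communities)) {
      gs <- intersect(names(a$communities)[a$communities == cc],
                      rg$graph$genome_nodes)
      os <- intersect(names(a$communities)[a$communities == cc],
                      rg$graph$ortholog_nodes)
      if (length(gs) > 0 && length(os) > 0) {
        expect_true(any(rg$graph$edges$genome_id %in% gs &
                          rg$graph$edges$ortholog_id %in% os))
      }
    }
  }
})

test_that("planted six-block structure is recovered across seeds", {
  ari <- vapply(1:5, function(s) {
    pb <- make_planted_bipartite(seed = s)
    a <- detect_communities(pb$graph, seed = s)
    mclust::adjustedRandIndex(a$communities[names(pb$truth)], pb$truth)
  }, numeric(1))
  expect_gte(mean(ari), 0.95)
})

test_that("dereplication clusters by identity and coverage", {
  set.seed(42)
  base <- random_dna_str(2000)
  mutate_at <- function(s, rate) {
    v <- strsplit(s, "")[[1]]
    pos <- sample(length(v), round(rate * length(v)))
    for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
    paste(v, collapse = "")
  }
  seqs <- c(a = base, b = mutate_at(base, 0.02), c = mutate_at(base, 0.3),
            d = base)
  out <- dereplicate_genomes(seqs)
  expect_equal(out$representative[out$id == "d"],
               out$representative[out$id == "a"])
  expect_equal(out$representative[out$id == "b"],
               out$representative[out$id == "a"])
  expect_false(out$representative[out$id == "c"] ==
                 out$representative[out$id == "a"])
  # identical elements collapse to one representative
  two <- dereplicate_genomes(c(x = base, y = base))
  expect_equal(length(unique(two$representative)), 1L)
})

test_that("cluster gene-content fractions match direct counting", {
  x <- mk_membership(rep(12, 4))
  g <- build_graph(x$membership, x$genomes)
  a <- detect_communities(g, seed = 2)
  set.seed(7)
  ann <- tibble::tibble(
    genome_id = sample(g$genome_nodes, 30, TRUE),
    marker_class = sample(c("rve_INT", "YREC", "pPolB"), 30, TRUE))
  s <- summarize_clusters(a, g, ann)
  ann_u <- dplyr::distinct(ann)
  for (r in sample(nrow(s), min(10, nrow(s)))) {
    row <- s[r, ]
    members <- g$genome_nodes[a$communities[g$genome_nodes] == row$community]
    want <- sum(members %in%
                  ann_u$genome_id[ann_u$marker_class == row$marker_class])
    expect_equal(row$n_with, want)
    expect_equal(row$fraction, want / length(members))
  }
  # the reference worked fraction: 260 of 305 members
  frac <- 260 / 305
  expect_equal(round(frac, 3), 0.852)
})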