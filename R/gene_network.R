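# Genome-ortholog gene-sharing network. Genomes and ortholog clusters
# are the two node classes of a bipartite graph; communities are found
# by greedy optimisation of Barber's bipartite modularity
#   Q_B = (1/m) * sum_ij (A_ij - k_i d_j / m) * delta(c_i, c_j)
# with A the genome x ortholog weight matrix, k and d the class
# degrees, and m the total edge weight. Louvain-style sweeps alternate
# over the two node classes ("sequential mode") so genome and ortholog
# clusters emerge independently.

#' Build the genome-ortholog bipartite graph
#'
#' Ortholog clusters with fewer than `min_cluster_size` member proteins
#' are removed before edge construction. An edge (genome, ortholog)
#' exists when the genome contributes at least one protein to the
#' cluster, weighted by the contribution count.
#'
#' @param membership Tibble with `protein_id`, `ortholog_id` (a protein
#'   maps to at most one cluster; proteins absent from the table carry
#'   no edge).
#' @param genomes Tibble with `protein_id`, `genome_id` (each protein in
#'   exactly one genome).
#' @param min_cluster_size Minimum cluster size retained (default 10).
#' @return A list of class `bipartite_graph`: `genome_nodes`,
#'   `ortholog_nodes`, `edges` (tibble `genome_id`, `ortholog_id`,
#'   `weight`).
#' @export
build_graph <- function(membership, genomes, min_cluster_size = 10L) {
  dup <- genomes %>%
    dplyr::distinct(.data$protein_id, .data$genome_id) %>%
    dplyr::count(.data$protein_id) %>%
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("protein(s) assigned to more than one genome: ",
         paste(utils::head(dup$protein_id, 5), collapse = ", "))
  }
  sizes <- dplyr::count(membership, .data$ortholog_id, name = "size")
  keep <- sizes$ortholog_id[sizes$size >= min_cluster_size]
  mem <- membership %>%
    dplyr::filter(.data$ortholog_id %in% keep) %>%
    dplyr::left_join(dplyr::distinct(genomes, .data$protein_id,
                                     .data$genome_id),
                     by = "protein_id")
  if (any(is.na(mem$genome_id))) {
    stop("protein(s) in the membership table without a genome assignment")
  }
  edges <- mem %>%
    dplyr::count(.data$genome_id, .data$ortholog_id, name = "weight")
  structure(list(genome_nodes = sort(unique(edges$genome_id)),
                 ortholog_nodes = sort(unique(edges$ortholog_id)),
                 edges = edges),
            class = "bipartite_graph")
}

graph_matrix <- function(graph) {
  g <- graph$genome_nodes; o <- graph$ortholog_nodes
  A <- matrix(0, length(g), length(o), dimnames = list(g, o))
  A[cbind(match(graph$edges$genome_id, g),
          match(graph$edges$ortholog_id, o))] <- graph$edges$weight
  A
}

#' Barber bipartite modularity of a community assignment
#'
#' @param graph A `bipartite_graph`.
#' @param communities Named integer vector over all genome and ortholog
#'   nodes (names are node ids; genomes and orthologs share one
#'   community-id space).
#' @param resolution Resolution parameter gamma (1 = standard).
#' @return Modularity in `[-1, 1]`.
#' @export
barber_modularity <- function(graph, communities, resolution = 1.0) {
  A <- graph_matrix(graph)
  m <- sum(A)
  if (m == 0) stop("graph has no edges")
  k <- rowSums(A); d <- colSums(A)
  cg <- communities[rownames(A)]
  co <- communities[colnames(A)]
  if (anyNA(cg) || anyNA(co)) stop("assignment missing node(s)")
  q <- 0
  for (c in unique(c(cg, co))) {
    gi <- which(cg == c); oj <- which(co == c)
    if (length(gi) == 0 || length(oj) == 0) next
    q <- q + sum(A[gi, oj, drop = FALSE]) -
      resolution * sum(k[gi]) * sum(d[oj]) / m
  }
  q / m
}

#' Detect communities by bipartite-modularity optimisation
#'
#' Small graphs (smaller node class of size at most `exact_max_class`)
#' are solved exactly: all partitions of the smaller class are
#' enumerated and the larger class is assigned optimally per node,
#' which is globally optimal for Q_B. Larger graphs use a multi-level
#' (Louvain-style) heuristic: greedy local moves alternating full
#' sweeps over genome nodes then ortholog nodes until no move improves
#' Q_B, followed by aggregation, restarted `n_restarts` times from
#' seed-shuffled node orders; the best assignment is returned. Ties in
#' modularity gain are broken toward the lower community id (which also
#' resolves the single-edge tie by merging the two endpoints).
#' Deterministic given `seed`.
#'
#' @param graph A non-empty `bipartite_graph`.
#' @param seed Integer seed controlling node-order shuffles.
#' @param resolution Resolution gamma (default 1).
#' @param n_restarts Number of restarts (default 8).
#' @param exact_max_class Largest smaller-class size solved exactly
#'   (default 8; Bell(8) = 4140 partitions).
#' @return A list of class `community_assignment`: `communities` (named
#'   vector, compacted ids), `barber_modularity`,
#'   `n_genome_communities`, `n_ortholog_communities`, `seed`.
#' @export
detect_communities <- function(graph, seed = 1L, resolution = 1.0,
                               n_restarts = 8L, exact_max_class = 8L) {
  if (is.null(graph$edges) || nrow(graph$edges) == 0) {
    stop("empty graph: no edges to cluster")
  }
  A <- graph_matrix(graph)
  withr::with_seed(as.integer(seed), {
    if (min(dim(A)) <= exact_max_class) {
      best <- exact_bipartite_communities(A, resolution)
    } else {
      best <- NULL
      for (r in seq_len(n_restarts)) {
        res <- louvain_once(A, resolution)
        if (is.null(best) || res$q > best$q + 1e-12) best <- res
      }
    }
    comm <- best$comm
    # compact community ids in order of first appearance
    ids <- stats::setNames(seq_along(unique(comm)), unique(comm))
    comm <- ids[as.character(comm)]
    names(comm) <- c(rownames(A), colnames(A))
    structure(list(
      communities = comm,
      barber_modularity = best$q,
      n_genome_communities = length(unique(comm[rownames(A)])),
      n_ortholog_communities = length(unique(comm[colnames(A)])),
      seed = as.integer(seed)),
      class = "community_assignment")
  })
}

# Exact Q_B optimisation: enumerate all partitions of the smaller node
# class (restricted growth strings); given a partition, each node of
# the larger class contributes independently and joins the community
# maximising (w_ic - gamma * deg_i * Deg_c / m), or stays a singleton
# when every contribution is negative (zero-contribution ties merge, so
# a single-edge graph yields one community). Globally optimal.
exact_bipartite_communities <- function(A, gamma) {
  transposed <- nrow(A) > ncol(A)
  B <- if (transposed) t(A) else A     # rows = smaller class
  nr <- nrow(B); nc <- ncol(B)
  m <- sum(B)
  k <- rowSums(B); d <- colSums(B)
  best_q <- -Inf; best_rpart <- NULL; best_cpart <- NULL
  assign_cols <- function(part) {
    ids <- unique(part)
    W <- vapply(ids, function(c) colSums(B[part == c, , drop = FALSE]),
                numeric(nc))
    if (!is.matrix(W)) W <- matrix(W, nrow = nc)
    K <- vapply(ids, function(c) sum(k[part == c]), numeric(1))
    contrib <- W - outer(d, K) * gamma / m       # nc x ncomm
    cpart <- integer(nc); q <- 0
    for (j in seq_len(nc)) {
      bestc <- which(contrib[j, ] >= max(contrib[j, ]) - 1e-12)[1]
      if (contrib[j, bestc] >= -1e-12 && W[j, bestc] > 0) {
        cpart[j] <- ids[bestc]
        q <- q + unname(contrib[j, bestc])
      } else {
        cpart[j] <- 0L                           # singleton, filled later
      }
    }
    list(q = q / m, cpart = cpart)
  }
  rec <- function(i, maxc, part) {
    if (i > nr) {
      res <- assign_cols(part)
      if (res$q > best_q + 1e-12) {
        best_q <<- res$q; best_rpart <<- part; best_cpart <<- res$cpart
      }
      return()
    }
    for (c in seq_len(maxc + 1)) rec(i + 1L, max(maxc, c), c(part, c))
  }
  if (nr == 1) {
    res <- assign_cols(1L)
    best_q <- res$q; best_rpart <- 1L; best_cpart <- res$cpart
  } else {
    rec(2L, 1L, 1L)
  }
  # fill singleton ids for unassigned larger-class nodes
  nxt <- max(best_rpart) + 1L
  for (j in seq_len(nc)) {
    if (best_cpart[j] == 0L) { best_cpart[j] <- nxt; nxt <- nxt + 1L }
  }
  if (transposed) {
    list(comm = c(best_cpart, best_rpart), q = best_q)
  } else {
    list(comm = c(best_rpart, best_cpart), q = best_q)
  }
}

# Greedy local moves on a (possibly aggregated) weighted incidence
# matrix, starting from the given row/col community assignment.
louvain_local_moves <- function(A, rcomm, ccomm, gamma) {
  ng <- nrow(A); no <- ncol(A)
  m <- sum(A)
  k <- rowSums(A); d <- colSums(A)
  comm <- c(rcomm, ccomm)
  Kc <- numeric(max(comm)); Dc <- numeric(max(comm))
  for (i in seq_len(ng)) Kc[comm[i]] <- Kc[comm[i]] + k[i]
  for (j in seq_len(no)) Dc[comm[ng + j]] <- Dc[comm[ng + j]] + d[j]

  sweep_class <- function(is_genome) {
    idx <- if (is_genome) sample.int(ng) else sample.int(no)
    moved <- FALSE
    for (i in idx) {
      node <- if (is_genome) i else ng + i
      deg <- if (is_genome) k[i] else d[i]
      cur <- comm[node]
      w <- if (is_genome) A[i, ] else A[, i]
      nb_comm <- comm[if (is_genome) ng + which(w > 0) else which(w > 0)]
      wsum <- tapply(w[w > 0], nb_comm, sum)
      cand <- unique(c(cur, as.integer(names(wsum))))
      # remove node from its community before computing gains
      if (is_genome) Kc[cur] <<- Kc[cur] - deg else Dc[cur] <<- Dc[cur] - deg
      gain <- vapply(cand, function(cc) {
        wi <- if (as.character(cc) %in% names(wsum))
                wsum[[as.character(cc)]] else 0
        opp <- if (is_genome) Dc[cc] else Kc[cc]
        (wi - gamma * deg * opp / m) / m
      }, numeric(1))
      tol <- 1e-12
      tied <- cand[gain > max(gain) - tol]
      target <- min(tied)                       # tie toward lower id
      gcur <- gain[match(cur, cand)]
      gtar <- gain[match(target, cand)]
      if (!(gtar > gcur + tol || (abs(gtar - gcur) <= tol && target < cur))) {
        target <- cur
      }
      if (is_genome) Kc[target] <<- Kc[target] + deg
      else Dc[target] <<- Dc[target] + deg
      if (target != cur) { comm[node] <<- target; moved <- TRUE }
    }
    moved
  }

  any_moved <- FALSE
  repeat {
    m1 <- sweep_class(TRUE)
    m2 <- sweep_class(FALSE)
    if (m1 || m2) any_moved <- TRUE
    if (!m1 && !m2) break
  }
  list(rcomm = comm[seq_len(ng)], ccomm = comm[ng + seq_len(no)],
       moved = any_moved)
}

# Multi-level bipartite Louvain: local moves to convergence, then
# aggregation (each community becomes one super-genome and one
# super-ortholog node, which may separate again at the next level),
# repeated until aggregation yields no further improvement.
louvain_once <- function(A, resolution) {
  ng0 <- nrow(A); no0 <- ncol(A)
  gmap <- seq_len(ng0)                 # genome -> current community
  omap <- ng0 + seq_len(no0)           # ortholog -> current community
  Ac <- A
  rids <- gmap; cids <- omap           # community ids of Ac rows/cols
  rcomm <- seq_along(rids); ccomm <- length(rids) + seq_along(cids)
  for (level in 1:50) {
    res <- louvain_local_moves(Ac, rcomm, ccomm, resolution)
    # map nodes through this level's assignment
    new_r <- res$rcomm; new_c <- res$ccomm
    gmap <- new_r[match(gmap, rids)]
    omap <- new_c[match(omap, cids)]
    if (!res$moved) break
    # aggregate: one super-row and one super-col per community
    comms <- sort(unique(c(new_r, new_c)))
    Ac2 <- matrix(0, length(comms), length(comms))
    ri <- match(new_r, comms); ci <- match(new_c, comms)
    for (a in seq_along(new_r)) {
      for (b in seq_along(new_c)) {
        Ac2[ri[a], ci[b]] <- Ac2[ri[a], ci[b]] + Ac[a, b]
      }
    }
    keep_r <- which(rowSums(Ac2) > 0); keep_c <- which(colSums(Ac2) > 0)
    Ac <- Ac2[keep_r, keep_c, drop = FALSE]
    rids <- comms[keep_r]; cids <- comms[keep_c]
    # renumber: start each super-row and super-col of one community
    # together
    rcomm <- match(rids, comms); ccomm <- match(cids, comms)
    # remap node-level communities into the new id space
    gmap <- match(gmap, comms); omap <- match(omap, comms)
    rids <- match(rids, comms); cids <- match(cids, comms)
  }
  q <- barber_modularity_matrix(A, gmap, omap, resolution)
  list(comm = c(gmap, omap), q = q)
}

barber_modularity_matrix <- function(A, cg, co, gamma = 1.0) {
  m <- sum(A)
  k <- rowSums(A); d <- colSums(A)
  q <- 0
  for (c in unique(c(cg, co))) {
    gi <- which(cg == c); oj <- which(co == c)
    if (length(gi) == 0 || length(oj) == 0) next
    q <- q + sum(A[gi, oj, drop = FALSE]) -
      gamma * sum(k[gi]) * sum(d[oj]) / m
  }
  q / m
}

#' Dereplicate element sequences
#'
#' Greedy longest-first clustering: a sequence joins the first existing
#' representative it aligns to with at least `identity` over at least
#' `coverage` of the shorter sequence (local alignment); otherwise it
#' becomes a new representative.
#'
#' @param seqs Named character vector of element nucleotide sequences.
#' @param identity Identity threshold (default 0.90).
#' @param coverage Coverage-of-shorter threshold (default 0.90).
#' @return Tibble with `id`, `representative`.
#' @export
dereplicate_genomes <- function(seqs, identity = 0.90, coverage = 0.90) {
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  ord <- order(-nchar(seqs))
  reps <- character(0)
  assign_to <- character(length(seqs))
  names(assign_to) <- names(seqs)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                  baseOnly = TRUE)
  for (i in ord) {
    id <- names(seqs)[i]
    placed <- NA_character_
    for (r in reps) {
      shorter <- min(nchar(seqs[[id]]), nchar(seqs[[r]]))
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(seqs[[id]]), Biostrings::DNAString(seqs[[r]]),
        type = "local", substitutionMatrix = mat,
        gapOpening = 5, gapExtension = 2)
      ncols <- Biostrings::nchar(aln)
      nmatch <- Biostrings::nmatch(aln)
      alen <- min(nchar(as.character(Biostrings::pattern(aln))),
                  nchar(as.character(Biostrings::subject(aln))))
      if (ncols > 0 && nmatch / ncols >= identity &&
          alen / shorter >= coverage) {
        placed <- r
        break
      }
    }
    if (is.na(placed)) {
      reps <- c(reps, id)
      assign_to[id] <- id
    } else {
      assign_to[id] <- placed
    }
  }
  tibble::tibble(id = names(seqs), representative = unname(assign_to))
}

#' Per-community gene-content summary
#'
#' For each genome community: member count and, per marker class, the
#' fraction of member genomes carrying at least one gene of that class.
#'
#' @param assignment A `community_assignment`.
#' @param graph The `bipartite_graph` it was computed on.
#' @param annotations Tibble with `genome_id`, `marker_class` (one row
#'   per carried class per genome; genomes may be absent).
#' @return Tibble with `community`, `n_members`, `marker_class`,
#'   `n_with`, `fraction` (0 for classes no member carries).
#' @export
summarize_clusters <- function(assignment, graph, annotations) {
  comm <- assignment$communities[graph$genome_nodes]
  members <- tibble::tibble(genome_id = graph$genome_nodes,
                            community = unname(comm))
  classes <- unique(annotations$marker_class)
  if (length(classes) == 0) classes <- MARKER_CLASSES
  grid <- tidyr_expand_grid(unique(members$community), classes)
  ann <- dplyr::distinct(annotations, .data$genome_id, .data$marker_class)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    cc <- grid$community[i]; mc <- grid$marker_class[i]
    ids <- members$genome_id[members$community == cc]
    n_with <- sum(ids %in% ann$genome_id[ann$marker_class == mc])
    tibble::tibble(community = cc, n_members = length(ids),
                   marker_class = mc, n_with = n_with,
                   fraction = n_with / length(ids))
  })
  dplyr::bind_rows(out)
}

tidyr_expand_grid <- function(community, marker_class) {
  comm_col <- rep(community, each = length(marker_class))
  class_col <- rep(marker_class, times = length(community))
  tibble::tibble(community = comm_col, marker_class = class_col)
}

#' Planted 6-block bipartite benchmark graph
#'
#' Genome and ortholog nodes are split into `n_blocks` matched groups;
#' within-block edges appear with probability `p_in`, between-block
#' edges with `p_out`.
#'
#' @param n_blocks Number of planted blocks (default 6).
#' @param genomes_per_block,orthologs_per_block Block sizes.
#' @param p_in,p_out Edge probabilities (defaults 0.8 / 0.02).
#' @param seed Integer seed.
#' @return List with `graph` (a `bipartite_graph`) and `truth` (named
#'   block id per genome node).
#' @export
make_planted_bipartite <- function(n_blocks = 6L, genomes_per_block = 10L,
                                   orthologs_per_block = 20L,
                                   p_in = 0.8, p_out = 0.02, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    g_ids <- sprintf("g%03d", seq_len(n_blocks * genomes_per_block))
    o_ids <- sprintf("og%03d", seq_len(n_blocks * orthologs_per_block))
    g_block <- rep(seq_len(n_blocks), each = genomes_per_block)
    o_block <- rep(seq_len(n_blocks), each = orthologs_per_block)
    p <- ifelse(outer(g_block, o_block, "=="), p_in, p_out)
    adj <- matrix(stats::rbinom(length(p), 1, p), nrow = length(g_ids))
    idx <- which(adj == 1, arr.ind = TRUE)
    edges <- tibble::tibble(genome_id = g_ids[idx[, 1]],
                            ortholog_id = o_ids[idx[, 2]], weight = 1)
    graph <- structure(list(genome_nodes = sort(unique(edges$genome_id)),
                            ortholog_nodes = sort(unique(edges$ortholog_id)),
                            edges = edges),
                       class = "bipartite_graph")
    list(graph = graph,
         truth = stats::setNames(g_block, g_ids))
  })
}
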