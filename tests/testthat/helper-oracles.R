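# Independent oracles used across the suite. These deliberately use
# different algorithmic formulations from the package code paths they
# check (row-vectorised DP, naive enumeration, exhaustive partition
# search).

# Best local-alignment score between S and revcomp(S) over arm pairs
# with arm5 strictly upstream of arm3 (endpoint cells with i + j <= n),
# linear gaps. Row-vectorised Smith-Waterman.
oracle_ir_best_score <- function(seq, match = 3, mismatch = -4, gap = 12) {
  n <- nchar(seq)
  if (n < 2) return(0)
  X <- strsplit(seq, "")[[1]]
  Y <- strsplit(plvscan::revcomp(seq), "")[[1]]
  prev <- numeric(n + 1)
  best <- 0
  jj <- seq_len(n)
  for (i in seq_len(n)) {
    s <- ifelse(Y == X[i] & X[i] != "N", match, mismatch)
    T <- pmax(0, prev[jj] + s, prev[jj + 1] - gap)
    cur <- cummax(T + gap * jj) - gap * jj
    if (i < n) best <- max(best, cur[seq_len(n - i)])
    prev <- c(0, cur)
  }
  best
}

# random sequence with optional planted inverted-repeat pair
random_ir_case <- function(len = 200, plant = TRUE, arm = 30,
                           identity = 0.9, spacer = 60) {
  s <- paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = "")
  if (!plant) return(s)
  a <- paste(sample(c("A", "C", "G", "T"), arm, TRUE), collapse = "")
  b <- strsplit(plvscan::revcomp(a), "")[[1]]
  nmut <- round((1 - identity) * arm)
  if (nmut > 0) {
    pos <- sample(arm, nmut)
    for (p in pos) b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1)
  }
  ins <- paste(sample(c("A", "C", "G", "T"), spacer, TRUE), collapse = "")
  at <- sample(max(1, len - (2 * arm + spacer)), 1)
  paste0(substr(s, 1, at), a, ins, paste(b, collapse = ""),
         substr(s, at + 1, len))
}

# Naive exhaustive TSD caller: enumerate every (L, o_l, o_r) triple into
# a data frame, filter, and sort by the declared tie-break order.
oracle_call_tsd <- function(left, right, min_tsd = 4, max_tsd = 25,
                            max_offset = 3, max_mismatch = 2) {
  nl <- nchar(left); nr <- nchar(right)
  grid <- expand.grid(L = min_tsd:max_tsd, ol = 0:max_offset,
                      orr = 0:max_offset)
  rows <- list()
  for (r in seq_len(nrow(grid))) {
    L <- grid$L[r]; ol <- grid$ol[r]; orr <- grid$orr[r]
    if (nl - ol < L || orr + L > nr) next
    lc <- substr(left, nl - ol - L + 1, nl - ol)
    rc <- substr(right, orr + 1, orr + L)
    mm <- sum(strsplit(lc, "")[[1]] != strsplit(rc, "")[[1]] |
                strsplit(lc, "")[[1]] == "N" | strsplit(rc, "")[[1]] == "N")
    if (mm > min(max_mismatch, L %/% 5)) next
    rows[[length(rows) + 1]] <- data.frame(
      lc = lc, rc = rc, L = L, mm = mm, ol = ol, orr = orr,
      score = L - 2 * mm)
  }
  if (!length(rows)) return(NULL)
  df <- do.call(rbind, rows)
  df <- df[order(-df$score, -df$L, df$ol + df$orr, df$mm, df$ol), ]
  df[1, ]
}

# Exhaustive Barber-modularity optimum: enumerate all partitions of the
# genome class; orthologs are assigned independently given a partition.
oracle_barber_optimum <- function(A, gamma = 1) {
  ng <- nrow(A); no <- ncol(A)
  m <- sum(A); k <- rowSums(A); d <- colSums(A)
  best <- -Inf
  score_part <- function(part) {
    q <- 0
    for (j in seq_len(no)) {
      contrib <- vapply(unique(part), function(c) {
        sum(A[part == c, j]) - gamma * sum(k[part == c]) * d[j] / m
      }, numeric(1))
      q <- q + max(c(contrib, 0))
    }
    q / m
  }
  rec <- function(i, maxc, part) {
    if (i > ng) {
      best <<- max(best, score_part(part))
      return()
    }
    for (c in seq_len(maxc + 1)) rec(i + 1, max(maxc, c), c(part, c))
  }
  if (ng == 1) best <- score_part(1L) else rec(2L, 1L, 1L)
  best
}

random_bipartite_graph <- function(ng, no, p = 0.5) {
  repeat {
    A <- matrix(stats::rbinom(ng * no, 1, p), ng, no)
    if (sum(A) > 0 && all(rowSums(A) > 0) && all(colSums(A) > 0)) break
  }
  rownames(A) <- paste0("g", seq_len(ng))
  colnames(A) <- paste0("o", seq_len(no))
  idx <- which(A == 1, arr.ind = TRUE)
  graph <- structure(list(
    genome_nodes = rownames(A), ortholog_nodes = colnames(A),
    edges = tibble::tibble(genome_id = rownames(A)[idx[, 1]],
                           ortholog_id = colnames(A)[idx[, 2]],
                           weight = 1)),
    class = "bipartite_graph")
  list(A = A, graph = graph)
}

random_dna_str <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, TRUE, prob = p), collapse = "")
}

# small, fast simulation configuration used by pipeline-level tests
small_sim_config <- function(seed = 7L) {
  plvscan::sim_config(seed = seed, n_contigs = 2L, contig_len_bp = 4e5,
                      n_elements = 6L, element_len_bp = c(6000, 30000),
                      tir_len_bp = c(150, 2000), n_nested = 1L)
}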