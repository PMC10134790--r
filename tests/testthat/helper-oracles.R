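# Independent oracles and small random-input builders shared across the
# suite. Each oracle re-implements the published contract of the
# operation it checks from scratch (different code path, same rules).

AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

rand_protein <- function(len) paste(sample(AA, len, TRUE), collapse = "")

# Pure-R Needleman-Wunsch with the same published contract as the
# package's aligner: linear gaps, deterministic tie-break (diagonal,
# then gap-in-b, then gap-in-a) applied to the canonically ordered pair.
nw_oracle <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  first <- sort(c(a, b), method = "radix")[[1]]
  if (!identical(a, first)) {
    al <- nw_oracle(b, a, match, mismatch, gap)
    return(list(score = al$score, identity = al$identity,
                cov_a = al$cov_b, cov_b = al$cov_a))
  }
  nw_oracle_raw(a, b, match, mismatch, gap)
}

nw_oracle_raw <- function(a, b, match = 1, mismatch = 0, gap = -1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  S <- matrix(0, n + 1, m + 1)
  S[, 1] <- (0:n) * gap
  S[1, ] <- (0:m) * gap
  for (i in seq_len(n))
    for (j in seq_len(m))
      S[i + 1, j + 1] <- max(
        S[i, j] + if (A[[i]] == B[[j]]) match else mismatch,
        S[i, j + 1] + gap,
        S[i + 1, j] + gap)
  i <- n; j <- m
  ai <- integer(0); bi <- integer(0)
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        S[i + 1, j + 1] ==
          S[i, j] + (if (A[[i]] == B[[j]]) match else mismatch)) {
      ai <- c(i, ai); bi <- c(j, bi); i <- i - 1; j <- j - 1
    } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] + gap) {
      ai <- c(i, ai); bi <- c(0L, bi); i <- i - 1
    } else {
      ai <- c(0L, ai); bi <- c(j, bi); j <- j - 1
    }
  }
  both <- ai > 0 & bi > 0
  ident <- sum(A[ai[both]] == B[bi[both]])
  start <- max(min(which(ai > 0)), min(which(bi > 0)))
  end <- min(max(which(ai > 0)), max(which(bi > 0)))
  list(score = S[n + 1, m + 1],
       identity = ident / min(n, m),
       cov_a = sum(ai[start:end] > 0) / n,
       cov_b = sum(bi[start:end] > 0) / m)
}

# Random small annotated genome with LuxR/LuxI domains sprinkled at high
# rates, for exercising the neighborhood rule near its boundaries.
rand_genome <- function(n_genes = 30, n_replicons = 2,
                        p_luxr = 0.15, p_luxi = 0.15,
                        genome_id = "rg") {
  per <- sort(table(sample(seq_len(n_replicons), n_genes, TRUE)))
  genes <- list(); prot <- character(0); dom <- list()
  k <- 0L
  for (r in seq_along(per)) {
    n <- per[[r]]
    starts <- cumsum(sample(200:500, n, TRUE))
    for (i in seq_len(n)) {
      k <- k + 1L
      pid <- sprintf("%s_p%02d", genome_id, k)
      prot[[pid]] <- rand_protein(sample(40:60, 1))
      u <- runif(1)
      pf <- if (u < p_luxr) "PF03472" else if (u < p_luxr + p_luxi)
        "PF00765" else sample(c("PF11111", "PF22222", NA), 1)
      if (!is.na(pf))
        dom[[length(dom) + 1L]] <- data.frame(
          protein_id = pid, pfam_acc = pf, ali_start = 1L,
          ali_end = 30L, score = 50, stringsAsFactors = FALSE)
      genes[[k]] <- data.frame(
        gene_id = sprintf("%s_g%02d", genome_id, k),
        replicon_id = sprintf("rep%d", r),
        start = starts[[i]], end = starts[[i]] + 150L,
        strand = sample(c("+", "-"), 1),
        protein_id = pid, stringsAsFactors = FALSE)
    }
  }
  annotated_genome(genome_id, do.call(rbind, genes), prot,
                   if (length(dom)) do.call(rbind, dom) else
                     soloscan:::empty_domains())
}

# Brute-force solo scan: for every PF03472 protein (PF00765-fused ones
# excluded), search ALL genes and test |rank difference| <= window on the
# same replicon for the synthase domain.
solo_oracle <- function(genome, window = 4) {
  g <- genome$genes
  d <- genome$domains
  luxr <- unique(d$protein_id[d$pfam_acc == "PF03472"])
  luxi <- unique(d$protein_id[d$pfam_acc == "PF00765"])
  luxr <- setdiff(luxr, luxi)
  res <- logical(0)
  for (i in seq_len(nrow(g))) {
    p <- g$protein_id[[i]]
    if (is.na(p) || !(p %in% luxr)) next
    blocked <- FALSE
    for (j in seq_len(nrow(g))) {
      if (j == i || g$replicon_id[[j]] != g$replicon_id[[i]]) next
      if (abs(g$rank[[j]] - g$rank[[i]]) > window) next
      q <- g$protein_id[[j]]
      if (!is.na(q) && q %in% luxi) { blocked <- TRUE; break }
    }
    res[[p]] <- !blocked
  }
  res
}

# Independent DBSCAN: eps-graph over core points -> igraph connected
# components; labels ordered by each component's smallest id; border
# points to the nearest core point within eps.
dbscan_oracle <- function(points, eps, min_samples) {
  points <- points[order(rownames(points)), , drop = FALSE]
  ids <- rownames(points)
  D <- as.matrix(dist(points))
  within <- D <= eps
  core <- rowSums(within) >= min_samples
  labels <- stats::setNames(rep(-1L, nrow(points)), ids)
  if (any(core)) {
    adj <- within[core, core, drop = FALSE]
    diag(adj) <- FALSE
    gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(gr)$membership
    names(comp) <- ids[core]
    first <- tapply(names(comp), comp, min)
    relabel <- stats::setNames(order(order(first)) - 1L, names(first))
    labels[names(comp)] <- relabel[as.character(comp)]
    for (i in which(!core)) {
      cand <- which(within[i, ] & core)
      if (length(cand)) {
        best <- cand[order(D[i, cand], cand)][[1]]
        labels[[i]] <- labels[[best]]
      }
    }
  }
  labels
}

# Random additive distance matrix from a random tree with known branch
# lengths; the matrix is exactly additive by construction.
rand_additive <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, rooted = FALSE,
                   br = function(k) runif(k, 0.05, 1))
  dm <- ape::cophenetic.phylo(tr)
  ids <- sort(rownames(dm))
  list(tree = tr, dm = dm[ids, ids])
}

expect_same_clustering <- function(a, b) {
  stopifnot(length(a) == length(b))
  expect_equal(unname(a == -1L), unname(b == -1L))
  tab <- table(a, b)
  expect_true(all(rowSums(tab > 0) <= 1), label = "labels map 1-to-1")
  expect_true(all(colSums(tab > 0) <= 1), label = "labels map 1-to-1")
}
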