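# Genomic-context subgrouping: clusters of solos are fingerprinted by the
# Pfam content of their members' gene neighborhoods, the fingerprints are
# embedded in 3 dimensions, and density clustering assigns subgroups (or
# the noise label -1).

#' Neighborhood-Pfam frequency profiles for large clusters
#'
#' For every cluster with at least `min_members` members (default 51, i.e.
#' strictly more than 50), counts the fraction of members whose gene
#' neighborhood contains at least one gene carrying each Pfam domain
#' (presence per member, not multiplicity). Pfams whose frequency falls
#' below `freq_floor` are dropped; the frequency-5% boundary itself is
#' retained. The focal gene is not part of the neighborhood, and the
#' LuxR-defining domain itself is excluded as an uninformative constant.
#' Smaller clusters are skipped with a message.
#'
#' @param clusters Membership table from [greedy_cluster()].
#' @param solos Solo-call table from [detect_solos()] (rows for every
#'   cluster member, with the `neighborhood` list-column).
#' @param min_members Minimum cluster size to profile (default 51).
#' @param freq_floor Minimum retained frequency (default 0.05).
#' @param exclude_pfams Pfams never counted (default the LuxR domain).
#' @return Long-format data.frame `cluster_id`, `pfam_acc`, `frequency`,
#'   with per-cluster member counts in `attr(, "n_members")`.
#' @export
build_context_profiles <- function(clusters, solos, min_members = 51L,
                                   freq_floor = 0.05,
                                   exclude_pfams = LUXR_PFAM) {
  empty <- data.frame(cluster_id = integer(), pfam_acc = character(),
                      frequency = numeric(), stringsAsFactors = FALSE)
  if (!nrow(clusters)) return(empty)

  member_pfams <- member_neighborhood_pfams(solos, exclude_pfams)

  sizes <- cluster_sizes(clusters)
  keep <- sizes$n_members >= min_members
  if (any(!keep))
    message("skipping ", sum(!keep), " cluster(s) with fewer than ",
            min_members, " members")

  out <- vector("list", sum(keep))
  n_members <- integer(0)
  j <- 0L
  for (cid in sizes$cluster_id[keep]) {
    members <- clusters$member_id[clusters$cluster_id == cid]
    miss <- setdiff(members, names(member_pfams))
    if (length(miss))
      stop("contract violation: cluster ", cid,
           " member(s) without a solo call: ",
           paste(utils::head(miss, 5), collapse = ", "), call. = FALSE)
    n <- length(members)
    tab <- table(unlist(lapply(member_pfams[members], unique),
                        use.names = FALSE))
    freq <- as.numeric(tab) / n
    keep_p <- freq >= freq_floor
    j <- j + 1L
    out[[j]] <- data.frame(cluster_id = cid,
                           pfam_acc = names(tab)[keep_p],
                           frequency = freq[keep_p],
                           stringsAsFactors = FALSE)
    n_members <- c(n_members, stats::setNames(n, as.character(cid)))
  }
  res <- if (j) do.call(rbind, out[seq_len(j)]) else empty
  res <- res[order(res$cluster_id, res$pfam_acc), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_members") <- n_members
  res
}

member_neighborhood_pfams <- function(solos, exclude_pfams = character(0)) {
  if (!nrow(solos)) return(stats::setNames(list(), character(0)))
  out <- lapply(solos$neighborhood, function(nb) {
    p <- unlist(strsplit(nb$pfams[nzchar(nb$pfams)], ",", fixed = TRUE),
                use.names = FALSE)
    setdiff(unique(p), exclude_pfams)
  })
  stats::setNames(out, solos$protein_id)
}

#' Vectorize context profiles over the union of retained Pfams
#'
#' @param profiles Long-format output of [build_context_profiles()], or an
#'   already-wide numeric matrix (returned unchanged).
#' @return Numeric matrix, one row per cluster (rownames = cluster ids),
#'   one column per Pfam; absent Pfams are 0.
#' @export
profiles_matrix <- function(profiles) {
  if (is.matrix(profiles)) return(profiles)
  ids <- sort(unique(profiles$cluster_id))
  pfams <- sort(unique(profiles$pfam_acc))
  m <- matrix(0, length(ids), length(pfams),
              dimnames = list(as.character(ids), pfams))
  m[cbind(match(profiles$cluster_id, ids),
          match(profiles$pfam_acc, pfams))] <- profiles$frequency
  m
}

#' Embed context profiles in a low-dimensional space
#'
#' Default method is a deterministic principal-component projection
#' (centered, unscaled; each component's sign is fixed so its
#' largest-magnitude loading is positive). `method = "umap"` runs the
#' nonlinear neighborhood-preserving embedding of umap-learn through the
#' host Python interpreter and requires an explicit `seed`; it is the
#' method used for the original corpus-scale survey, while PCA gives the
#' reproducible default for desk-scale reanalysis.
#'
#' @param profiles Long-format profile table or wide matrix
#'   (see [profiles_matrix()]); at least 2 profiles.
#' @param method `"pca"` (default) or `"umap"`.
#' @param n_components Embedding dimension (default 3).
#' @param seed Integer seed, required for `"umap"`.
#' @return Numeric matrix (rows = cluster ids, columns `x`, `y`, `z`, ...).
#' @export
embed_profiles <- function(profiles, method = c("pca", "umap"),
                           n_components = 3L, seed = NULL) {
  method <- match.arg(method)
  x <- profiles_matrix(profiles)
  if (nrow(x) < 2L)
    stop("degenerate input: need at least 2 profiles to embed",
         call. = FALSE)

  emb <- if (method == "pca") {
    pr <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    k <- min(n_components, ncol(pr$x))
    scores <- pr$x[, seq_len(k), drop = FALSE]
    for (j in seq_len(k)) {
      load <- pr$rotation[, j]
      if (load[[which.max(abs(load))]] < 0) scores[, j] <- -scores[, j]
    }
    if (k < n_components)
      scores <- cbind(scores, matrix(0, nrow(x), n_components - k))
    scores
  } else {
    umap_embed(x, n_components, seed)
  }
  dimnames(emb) <- list(rownames(x),
                        c("x", "y", "z", paste0("d", seq_len(max(
                          0, n_components - 3))))[seq_len(n_components)])
  emb
}

umap_embed <- function(x, n_components, seed) {
  if (is.null(seed))
    stop("method = \"umap\" requires an explicit integer seed",
         call. = FALSE)
  py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py))
    stop("method = \"umap\" needs a python interpreter with umap-learn ",
         "on the PATH", call. = FALSE)
  fin <- tempfile(fileext = ".csv"); fout <- tempfile(fileext = ".csv")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  utils::write.table(x, fin, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  script <- paste(
    "import sys, numpy as np, umap",
    "X = np.loadtxt(sys.argv[1], delimiter=',', ndmin=2)",
    sprintf("nn = min(15, X.shape[0] - 1)"),
    sprintf(paste0("e = umap.UMAP(n_components=%d, random_state=%d,",
                   " n_neighbors=nn).fit_transform(X)"),
            as.integer(n_components), as.integer(seed)),
    "np.savetxt(sys.argv[2], e, delimiter=',')",
    sep = "\n")
  status <- system2(py, c("-c", shQuote(script), shQuote(fin), shQuote(fout)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(fout) || !file.size(fout))
    stop("umap embedding failed (is umap-learn importable from ", py, "?)",
         call. = FALSE)
  as.matrix(utils::read.table(fout, sep = ","))
}

#' Density-based clustering with a noise label
#'
#' Standard DBSCAN under the Euclidean metric: a point is a core point iff
#' at least `min_samples` points (itself included) lie within `eps`;
#' clusters are the eps-connected components of core points; a non-core
#' point joins the cluster of its nearest core point within `eps` (ties
#' broken by id order) or is labeled -1 (noise). Labels are numbered from
#' 0 in order of each cluster's smallest point id, so the labeling is
#' deterministic and invariant to input permutation.
#'
#' @param points Numeric matrix with unique rownames (ids), or a
#'   data.frame of coordinates.
#' @param eps Neighborhood radius (> 0; default 0.5).
#' @param min_samples Core-point threshold (>= 1; default 10).
#' @return Named integer vector of labels (-1 = noise), in id-sorted order.
#' @export
dbscan_cluster <- function(points, eps = 0.5, min_samples = 10L) {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (!nrow(points)) return(stats::setNames(integer(0), character(0)))
  stopifnot(eps > 0, min_samples >= 1)
  if (is.null(rownames(points)))
    rownames(points) <- as.character(seq_len(nrow(points)))
  points <- points[order(rownames(points)), , drop = FALSE]
  ids <- rownames(points)
  n <- nrow(points)

  D <- as.matrix(stats::dist(points))
  within <- D <= eps
  core <- rowSums(within) >= min_samples

  labels <- rep.int(-1L, n)
  next_label <- 0L
  for (i in seq_len(n)) {
    if (!core[[i]] || labels[[i]] != -1L) next
    comp <- i
    queue <- i
    labels[[i]] <- next_label
    while (length(queue)) {
      j <- queue[[1]]; queue <- queue[-1]
      nb <- which(within[j, ] & core & labels == -1L)
      labels[nb] <- next_label
      queue <- c(queue, nb)
    }
    next_label <- next_label + 1L
  }
  for (i in which(!core)) {
    cand <- which(within[i, ] & core)
    if (length(cand)) {
      best <- cand[order(D[i, cand], cand)][[1]]
      labels[[i]] <- labels[[best]]
    }
  }
  stats::setNames(labels, ids)
}
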