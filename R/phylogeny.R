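# Distance-based summary tree over cluster representatives: pairwise
# alignment identities -> 1 - identity distances -> classical
# neighbor-joining -> annotated Newick.

#' Pairwise 1 - identity distance matrix
#'
#' @param representatives Named character vector of protein sequences
#'   (>= 2).
#' @param match,mismatch,gap Alignment scoring, see [pairwise_identity()].
#' @return Symmetric numeric matrix with zero diagonal, dimnames = ids.
#' @export
distance_matrix <- function(representatives, match = 1, mismatch = 0,
                            gap = -1) {
  n <- length(representatives)
  if (n < 2L)
    stop("degenerate input: need at least 2 sequences", call. = FALSE)
  ids <- names(representatives)
  if (is.null(ids) || anyDuplicated(ids))
    stop("representatives must be uniquely named", call. = FALSE)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      al <- pairwise_identity(representatives[[i]], representatives[[j]],
                              match, mismatch, gap)
      d[i, j] <- d[j, i] <- 1 - al$identity
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classical neighbor-joining: iteratively joins the pair minimizing the
#' Q-criterion, with the usual branch-length and distance-update formulas;
#' exact on additive distance matrices. Ties in Q (within 1e-12) are
#' broken by the lexically smallest id pair, where an internal node
#' carries the smaller id of the two nodes it joined, so the output is
#' fully deterministic. A negative branch length is clamped to zero and
#' the difference moved to its sister branch, preserving the path length
#' through the joined pair.
#'
#' @param dm Symmetric distance matrix with >= 3 taxa (ids in dimnames).
#' @return An unrooted `ape::phylo` tree with branch lengths.
#' @export
neighbor_joining <- function(dm) {
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  if (nrow(dm) < 3L)
    stop("degenerate input: neighbor joining needs >= 3 taxa",
         call. = FALSE)
  if (max(abs(dm - t(dm))) > 1e-12 || any(dm < 0) ||
      any(abs(diag(dm)) > 1e-12))
    stop("distance matrix must be symmetric, non-negative, ",
         "zero-diagonal", call. = FALSE)
  ids <- rownames(dm)
  if (is.null(ids) || anyDuplicated(ids))
    stop("distance matrix needs unique dimnames", call. = FALSE)

  frag <- stats::setNames(as.list(ids), ids)  # Newick fragments
  D <- dm
  fmt <- function(x) sprintf("%.12g", x)

  while (nrow(D) > 3L) {
    n <- nrow(D)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- apply(cand, 1L, function(ij) {
      p <- sort(rownames(D)[ij])
      paste(p, collapse = "\r")
    })
    pick <- cand[order(key)[[1]], ]
    i <- pick[[1]]; j <- pick[[2]]

    bi <- D[i, j] / 2 + (r[[i]] - r[[j]]) / (2 * (n - 2))
    bj <- D[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }

    id_i <- rownames(D)[[i]]; id_j <- rownames(D)[[j]]
    new_id <- min(id_i, id_j)
    new_frag <- paste0("(", frag[[id_i]], ":", fmt(bi), ",",
                       frag[[id_j]], ":", fmt(bj), ")")

    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    rn <- c(rownames(D)[keep], new_id)
    dimnames(D2) <- list(rn, rn)
    D <- D2
    frag[[id_i]] <- NULL; frag[[id_j]] <- NULL
    frag[[new_id]] <- new_frag
  }

  nm <- rownames(D)
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  ls <- pmax(c(la, lb, lc), 0)
  nwk <- paste0("(", frag[[nm[[1]]]], ":", fmt(ls[[1]]), ",",
                frag[[nm[[2]]]], ":", fmt(ls[[2]]), ",",
                frag[[nm[[3]]]], ":", fmt(ls[[3]]), ");")
  ape::read.tree(text = nwk)
}

#' Write a tree as annotated Newick with a sidecar annotation table
#'
#' Leaf labels are suffixed `|sg<subgroup>|<class>|<environment>` for every
#' annotated leaf, and the same annotations are mirrored in a sidecar TSV
#' (so standard Newick readers that dislike decorated labels can use the
#' plain table). Annotations for unknown leaves are dropped with a
#' warning.
#'
#' @param tree An `ape::phylo`.
#' @param annotations Optional data.frame with columns `id`,
#'   `subgroup_id`, `class_hint`, `environment_label`.
#' @param path Optional output file; the sidecar is written next to it as
#'   `<path minus extension>_annotations.tsv`.
#' @return Invisibly, a list: `newick` (string), `annotations`
#'   (the applied table), and the file paths when `path` was given.
#' @export
write_annotated_newick <- function(tree, annotations = NULL, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  labels <- tree$tip.label
  applied <- data.frame(id = character(), subgroup_id = integer(),
                        class_hint = character(),
                        environment_label = character(),
                        stringsAsFactors = FALSE)
  if (!is.null(annotations) && nrow(annotations)) {
    unknown <- setdiff(annotations$id, labels)
    if (length(unknown))
      warning("dropping annotation(s) for unknown leaves: ",
              paste(unknown, collapse = ", "), call. = FALSE)
    applied <- annotations[annotations$id %in% labels, , drop = FALSE]
    idx <- match(applied$id, labels)
    labels[idx] <- paste0(labels[idx],
                          "|sg", applied$subgroup_id,
                          "|", applied$class_hint,
                          "|", applied$environment_label)
    tree$tip.label <- labels
  }
  nwk <- ape::write.tree(tree)
  out <- list(newick = nwk, annotations = applied)
  if (!is.null(path)) {
    writeLines(nwk, path)
    sidecar <- paste0(tools::file_path_sans_ext(path), "_annotations.tsv")
    utils::write.table(applied, sidecar, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$path <- path
    out$sidecar <- sidecar
  }
  invisible(out)
}
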