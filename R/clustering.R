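# Greedy incremental clustering of solo proteins, in the style of
# CD-HIT's default single pass: sequences are visited longest-first and
# either join the first representative they match at >= 80% identity with
# >= 80% coverage of both sequences, or found a new cluster.

#' Greedy incremental sequence clustering
#'
#' Sequences are processed in order of decreasing length (ties broken by
#' lexical id); each sequence joins the first existing cluster whose
#' representative it matches at `identity >= id_threshold` with coverage
#' `>= cov_threshold` of *both* sequences (see [pairwise_identity()]),
#' otherwise it founds a new cluster and becomes its representative.
#' Representatives are therefore always the longest member. Identity is
#' computed over the shorter sequence; a pair whose length ratio is below
#' `cov_threshold` cannot satisfy bidirectional coverage and is skipped
#' without alignment. Cluster ids number clusters in creation order.
#' Output is invariant to the input order of `sequences`.
#'
#' @param sequences Named character vector (protein_id -> sequence).
#' @param id_threshold,cov_threshold Membership thresholds (defaults 0.80
#'   and 0.80).
#' @param match,mismatch,gap Alignment scoring, see [pairwise_identity()].
#' @return data.frame with one row per member: `cluster_id`,
#'   `representative_id`, `member_id`, `identity_to_rep`, `cov_member`,
#'   `cov_rep`.
#' @export
greedy_cluster <- function(sequences, id_threshold = 0.80,
                           cov_threshold = 0.80,
                           match = 1, mismatch = 0, gap = -1) {
  empty <- data.frame(cluster_id = integer(), representative_id = character(),
                      member_id = character(), identity_to_rep = numeric(),
                      cov_member = numeric(), cov_rep = numeric(),
                      stringsAsFactors = FALSE)
  if (!length(sequences)) return(empty)
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("sequences must be uniquely named by protein id", call. = FALSE)
  for (i in seq_along(sequences))
    check_protein(sequences[[i]], names(sequences)[[i]])

  ord <- order(-nchar(sequences), names(sequences), method = "radix")
  ids <- names(sequences)[ord]
  seqs <- unname(sequences[ord])
  lens <- nchar(seqs)

  rep_id <- character(0)
  rep_seq <- character(0)
  rep_len <- integer(0)
  rows <- vector("list", length(ids))

  for (i in seq_along(ids)) {
    assigned <- FALSE
    for (k in seq_along(rep_id)) {
      if (lens[[i]] / rep_len[[k]] < cov_threshold) next  # member <= rep
      al <- nw_canonical(seqs[[i]], rep_seq[[k]], match, mismatch, gap)
      if (al$identity >= id_threshold && al$cov_a >= cov_threshold &&
          al$cov_b >= cov_threshold) {
        rows[[i]] <- list(cluster_id = k, representative_id = rep_id[[k]],
                          member_id = ids[[i]],
                          identity_to_rep = al$identity,
                          cov_member = al$cov_a, cov_rep = al$cov_b)
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      rep_id <- c(rep_id, ids[[i]])
      rep_seq <- c(rep_seq, seqs[[i]])
      rep_len <- c(rep_len, lens[[i]])
      k <- length(rep_id)
      rows[[i]] <- list(cluster_id = k, representative_id = ids[[i]],
                        member_id = ids[[i]], identity_to_rep = 1.0,
                        cov_member = 1.0, cov_rep = 1.0)
    }
  }

  out <- do.call(rbind, lapply(rows, function(r)
    data.frame(r, stringsAsFactors = FALSE)))
  out <- out[order(out$cluster_id, out$member_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sizes of clusters in a membership table
#'
#' @param clusters Output of [greedy_cluster()].
#' @return data.frame `cluster_id`, `representative_id`, `n_members`.
#' @export
cluster_sizes <- function(clusters) {
  if (!nrow(clusters))
    return(data.frame(cluster_id = integer(), representative_id = character(),
                      n_members = integer(), stringsAsFactors = FALSE))
  agg <- stats::aggregate(member_id ~ cluster_id + representative_id,
                          data = clusters, FUN = length)
  names(agg)[names(agg) == "member_id"] <- "n_members"
  agg[order(agg$cluster_id), , drop = FALSE]
}
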