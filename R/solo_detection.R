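# LuxR-solo calling: a LuxR-family protein (autoinducer-binding domain
# PF03472) is a "solo" when none of the 4 genes upstream or 4 genes
# downstream on its replicon encodes a LuxI-family AHL synthase (PF00765).
# The window is ordinal (gene ranks), replicons never wrap, and neighbor
# strand is ignored.

#' Detect LuxR solos in one genome
#'
#' Emits one call per protein carrying the LuxR-defining Pfam domain.
#' `is_solo` is `TRUE` iff no gene within `window` ranks on the same
#' replicon (the gene itself excluded) encodes a protein carrying the
#' LuxI-defining domain. Proteins carrying *both* domains are flagged as
#' fused synthase-regulators (`is_fused`), excluded from solo calling
#' (`is_solo` is `NA` for them), and never counted as solos downstream.
#' `luxr_length_ok` records whether the protein falls in the canonical
#' 230-270 aa LuxR length range; it is advisory metadata, never a filter.
#'
#' @param genome An [annotated_genome].
#' @param window Neighborhood half-width in gene ranks (default 4, i.e.
#'   the surrounding 8 genes).
#' @param luxr_pfam,luxi_pfam Pfam accessions defining the LuxR
#'   autoinducer-binding and LuxI synthase domains.
#' @return data.frame ordered by (replicon, rank) with one row per LuxR
#'   protein: `genome_id`, `replicon_id`, `gene_id`, `protein_id`, `rank`,
#'   `is_fused`, `is_solo`, `blocking_luxI` (nearest in-window synthase
#'   protein, NA if none), `luxr_length_ok`, `window_genes` (per-neighbor
#'   comma-joined Pfam lists, semicolon-separated), and a list-column
#'   `neighborhood` of per-neighbor data.frames (`gene_id`, `protein_id`,
#'   `rel_rank`, `pfams`).
#' @export
detect_solos <- function(genome, window = 4L,
                         luxr_pfam = LUXR_PFAM, luxi_pfam = LUXI_PFAM) {
  stopifnot(inherits(genome, "annotated_genome"), window >= 1L)
  g <- genome$genes
  dom <- genome$domains

  pfams_of <- split(dom$pfam_acc, dom$protein_id)
  luxr_prots <- unique(dom$protein_id[dom$pfam_acc == luxr_pfam])
  luxi_prots <- unique(dom$protein_id[dom$pfam_acc == luxi_pfam])
  fused_prots <- intersect(luxr_prots, luxi_prots)

  focal <- g[!is.na(g$protein_id) & g$protein_id %in% luxr_prots, ,
             drop = FALSE]
  focal <- focal[order(focal$replicon_id, focal$rank), , drop = FALSE]

  empty <- data.frame(
    genome_id = character(), replicon_id = character(),
    gene_id = character(), protein_id = character(), rank = integer(),
    is_fused = logical(), is_solo = logical(),
    blocking_luxI = character(), luxr_length_ok = logical(),
    window_genes = character(), stringsAsFactors = FALSE)
  if (!nrow(focal)) {
    empty$neighborhood <- list()
    return(empty)
  }

  luxi_gene <- !is.na(g$protein_id) & g$protein_id %in% luxi_prots

  rows <- vector("list", nrow(focal))
  for (i in seq_len(nrow(focal))) {
    f <- focal[i, ]
    on_rep <- g[g$replicon_id == f$replicon_id, , drop = FALSE]
    rel <- on_rep$rank - f$rank
    nb <- on_rep[rel != 0L & abs(rel) <= window, , drop = FALSE]
    nb_rel <- nb$rank - f$rank

    nb_pfams <- vapply(nb$protein_id, function(p) {
      if (is.na(p) || is.null(pfams_of[[p]])) "" else
        paste(sort(unique(pfams_of[[p]])), collapse = ",")
    }, character(1))
    neighborhood <- data.frame(
      gene_id = nb$gene_id, protein_id = nb$protein_id,
      rel_rank = nb_rel, pfams = unname(nb_pfams),
      stringsAsFactors = FALSE)

    blockers <- nb[!is.na(nb$protein_id) &
                     nb$protein_id %in% luxi_prots, , drop = FALSE]
    blocking <- NA_character_
    if (nrow(blockers)) {
      brel <- blockers$rank - f$rank
      ord <- order(abs(brel), brel)  # nearest; upstream wins ties
      blocking <- blockers$protein_id[ord[[1]]]
    }

    fused <- f$protein_id %in% fused_prots
    plen <- nchar(genome$proteome[[f$protein_id]])
    rows[[i]] <- list(
      genome_id = genome$genome_id, replicon_id = f$replicon_id,
      gene_id = f$gene_id, protein_id = f$protein_id, rank = f$rank,
      is_fused = fused,
      is_solo = if (fused) NA else is.na(blocking),
      blocking_luxI = if (fused) NA_character_ else blocking,
      luxr_length_ok = plen >= 230L && plen <= 270L,
      window_genes = paste(neighborhood$pfams, collapse = ";"),
      neighborhood = neighborhood)
  }

  out <- do.call(rbind, lapply(rows, function(r)
    data.frame(r[setdiff(names(r), "neighborhood")],
               stringsAsFactors = FALSE)))
  out$neighborhood <- lapply(rows, `[[`, "neighborhood")
  rownames(out) <- NULL
  out
}

#' Classify the genomic arrangement of a luxI/luxR pair
#'
#' Arrangement is determined by strand and relative order alone:
#' `tandem` when both genes lie on the same strand, `convergent` when they
#' point toward each other (left gene on `+`, right on `-`), `divergent`
#' when they point apart, and `complex` when at least one gene intervenes
#' (rank difference > 1), whatever the strands. Pairs closer than 3,000 bp
#' of intergenic sequence are flagged `linked`, the canonical genetic
#' linkage distance of luxI/luxR cassettes.
#'
#' @param luxr,luxi Single gene records (one-row data.frames or named
#'   lists with `replicon_id`, `start`, `end`, `strand`, `rank`, and ids).
#' @param linkage_bp Linkage threshold in bp (default 3000, exclusive).
#' @return A list: `luxr_id`, `luxi_id`, `arrangement`, `intergenic_bp`,
#'   `linked`.
#' @export
classify_pair_topology <- function(luxr, luxi, linkage_bp = 3000L) {
  luxr <- as.list(luxr); luxi <- as.list(luxi)
  if (!identical(as.character(luxr$replicon_id),
                 as.character(luxi$replicon_id)))
    stop("contract violation: luxR and luxI lie on different replicons",
         call. = FALSE)

  if (luxr$start <= luxi$start) { left <- luxr; right <- luxi }
  else { left <- luxi; right <- luxr }
  intergenic <- max(0L, as.integer(right$start) - as.integer(left$end) - 1L)

  arrangement <-
    if (abs(luxr$rank - luxi$rank) > 1L) "complex"
    else if (identical(left$strand, right$strand)) "tandem"
    else if (left$strand == "+") "convergent"
    else "divergent"

  list(luxr_id = luxr$gene_id %||% luxr$protein_id,
       luxi_id = luxi$gene_id %||% luxi$protein_id,
       arrangement = arrangement,
       intergenic_bp = intergenic,
       linked = intergenic < linkage_bp)
}
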