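# Residue/motif-based ligand-class hints. Nine residues are highly
# conserved across QS LuxR-family receptors -- six lining the AHL-binding
# cavity (W57, Y61, D70, P71, W85, G113 in TraR numbering) and three in
# the helix-turn-helix domain (E178, L182, G188). Plant-associated (PAB)
# solos carry the hallmark W57M / Y61W substitutions and a proline
# iminopeptidase (pip) gene next door; pyrone/dialkylresorcinol sensors
# carry TYDQCS (PluR-like) or TYDQYI (PauR-like) in place of the canonical
# WYDPWG residue set.

#' Load the TraR-anchored reference map
#'
#' Reads the packaged reference (a synthetic TraR-like anchor carrying the
#' nine consensus residues at their literal TraR positions, plus the
#' diagnostic motif catalog and neighborhood-rule Pfam accessions). The
#' anchor's inter-key residues are a documented stand-in for TraR; pass
#' `sequence` to substitute a real TraR sequence with the same numbering.
#'
#' @param path YAML file (default: the packaged map).
#' @param sequence Optional replacement anchor sequence.
#' @return List of class `reference_map`: `sequence`, `key_positions`
#'   (data.frame `pos`, `consensus`, `domain`), `motifs`, `pip_pfam`,
#'   `sdia_context_pfams`.
#' @export
reference_map <- function(path = system.file("extdata",
                                             "reference_map.yaml",
                                             package = "soloscan"),
                          sequence = NULL) {
  y <- yaml::read_yaml(path)
  seq <- gsub("[ \n]", "", sequence %||% y$reference$sequence)
  check_protein(seq, "reference sequence")
  kp <- do.call(rbind, lapply(y$key_positions, function(k)
    data.frame(pos = as.integer(k$pos), consensus = k$consensus,
               domain = k$domain, stringsAsFactors = FALSE)))
  if (nrow(kp) != 9L || any(diff(kp$pos) <= 0))
    stop("reference map must list 9 strictly increasing key positions",
         call. = FALSE)
  if (sum(kp$domain == "ligand_binding") != 6L ||
      sum(kp$domain == "hth") != 3L)
    stop("reference map must have 6 ligand-binding + 3 HTH positions",
         call. = FALSE)
  if (max(kp$pos) > nchar(seq))
    stop("anchor sequence shorter than the last key position",
         call. = FALSE)
  structure(list(sequence = seq, key_positions = kp,
                 motifs = unlist(y$motifs),
                 pip_pfam = y$pip_pfam,
                 sdia_context_pfams = unlist(y$sdia_context_pfams)),
            class = "reference_map")
}

#' Map reference positions onto a query protein
#'
#' Globally aligns the query to the reference anchor (same scoring
#' contract as [pairwise_identity()]) and reports, for every reference key
#' position, the query residue aligned to it ("-" for a gap).
#'
#' @param query Protein sequence (length >= 50).
#' @param ref A [reference_map()].
#' @return Named character vector, names = reference positions.
#' @export
anchor_align <- function(query, ref = reference_map()) {
  check_protein(query, "query")
  if (nchar(query) < 50L)
    stop("query too short to anchor (< 50 aa)", call. = FALSE)
  al <- nw_align_cpp(ref$sequence, query, 1, 0, -1)
  pos <- ref$key_positions$pos
  col <- match(pos, al$a_pos)
  qpos <- al$b_pos[col]
  res <- ifelse(!is.na(qpos) & qpos > 0L,
                substring(query, qpos, qpos), "-")
  stats::setNames(res, as.character(pos))
}

#' Score conserved residues and diagnostic motifs of one protein
#'
#' Anchors the query to TraR numbering, counts how many of the nine
#' consensus residues are conserved, tests the PAB hallmark (M at 57 and W
#' at 61), and scans the whole sequence for the diagnostic 6-mers
#' (canonical first, then the PluR and PauR variants).
#'
#' @param query Protein sequence.
#' @param ref A [reference_map()].
#' @return List: `aligned_key_residues`, `n_conserved` (0-9),
#'   `key_residues` (9-char string), `pab_signature`, `motif_match`
#'   (`canonical`, `pluR`, `pauR` or `none`).
#' @export
score_conserved_residues <- function(query, ref = reference_map()) {
  obs <- anchor_align(query, ref)
  cons <- ref$key_positions$consensus
  n_conserved <- sum(obs == cons)

  motif_match <- "none"
  for (nm in c("canonical", "pluR", "pauR")) {
    if (grepl(ref$motifs[[nm]], query, fixed = TRUE)) {
      motif_match <- nm
      break
    }
  }

  list(aligned_key_residues = obs,
       n_conserved = as.integer(n_conserved),
       key_residues = paste(obs, collapse = ""),
       pab_signature = unname(obs[["57"]] == "M" && obs[["61"]] == "W"),
       motif_match = motif_match)
}

#' Complete a ligand-class report with neighborhood rules
#'
#' Applies the genomic-context rules to a residue report of a *solo* call:
#' `pip_adjacent_PAB` when a neighborhood gene carries the configured
#' proline-iminopeptidase Pfam, `sdiA_like` when the full SdiA-like
#' enteric context (all configured accessions) is present, else `other`.
#' The class hint follows the precedence pyrone/DAR > PAB > AHL:
#' a PluR/PauR motif wins; otherwise the PAB residue hallmark or a pip
#' neighbor; otherwise >= 8 conserved residues (with no competing motif)
#' reads as a canonical AHL sensor; anything else is `unclassified`. The
#' hint is sequence/context evidence only, never a functional claim.
#'
#' @param report Output of [score_conserved_residues()].
#' @param solo_call One row of [detect_solos()] output with
#'   `is_solo = TRUE`.
#' @param ref A [reference_map()] (source of the rule accessions).
#' @return `report` extended with `protein_id`, `neighborhood_class` and
#'   `predicted_class_hint`.
#' @export
classify_solo <- function(report, solo_call, ref = reference_map()) {
  call <- as.list(solo_call)
  if (!isTRUE(call$is_solo))
    stop("contract violation: classify_solo requires a solo call",
         call. = FALSE)
  nb <- call$neighborhood
  if (is.list(nb) && !is.data.frame(nb)) nb <- nb[[1]]
  pfams <- unique(unlist(strsplit(nb$pfams[nzchar(nb$pfams)], ",",
                                  fixed = TRUE), use.names = FALSE))

  pip_adjacent <- ref$pip_pfam %in% pfams
  neighborhood_class <-
    if (pip_adjacent) "pip_adjacent_PAB"
    else if (all(ref$sdia_context_pfams %in% pfams)) "sdiA_like"
    else "other"

  hint <-
    if (report$motif_match %in% c("pluR", "pauR")) "pyrone_DAR_type"
    else if (report$pab_signature || pip_adjacent) "PAB_type"
    else if (report$n_conserved >= 8L) "AHL_type"
    else "unclassified"

  c(list(protein_id = call$protein_id), report,
    list(neighborhood_class = neighborhood_class,
         predicted_class_hint = hint))
}
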