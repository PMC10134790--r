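# Reading and writing the pipeline's data: annotated genomes in
# (GFF3, protein FASTA, domain table) triplets, and the fixed output set.

#' Construct and validate an annotated genome
#'
#' The in-memory unit of the survey: ordered gene models per replicon, the
#' proteome, and precomputed Pfam domain hits. Genes are ranked 1..n per
#' replicon in coordinate order; neighborhood logic elsewhere operates on
#' these ranks. Genes without a protein product are kept: they occupy
#' neighborhood slots.
#'
#' @param genome_id Genome identifier.
#' @param genes data.frame with columns `gene_id`, `replicon_id`, `start`,
#'   `end`, `strand` ("+"/"-"), `protein_id` (NA for non-coding). `rank` is
#'   (re)computed here.
#' @param proteome Named character vector of protein sequences.
#' @param domains data.frame with columns `protein_id`, `pfam_acc`,
#'   `ali_start`, `ali_end`, `score`; may have zero rows.
#' @param taxon_label,environment_label Optional genus / isolation-source
#'   labels carried through to tree annotation.
#' @return An object of class `annotated_genome`.
#' @export
annotated_genome <- function(genome_id, genes, proteome,
                             domains = empty_domains(),
                             taxon_label = NA_character_,
                             environment_label = NA_character_) {
  stopifnot(is.character(genome_id), length(genome_id) == 1L)
  need <- c("gene_id", "replicon_id", "start", "end", "strand", "protein_id")
  if (!all(need %in% names(genes)))
    stop("genes is missing columns: ",
         paste(setdiff(need, names(genes)), collapse = ", "), call. = FALSE)
  genes <- genes[, need, drop = FALSE]
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)

  if (any(genes$start > genes$end))
    stop("gene(s) with start > end: ",
         paste(genes$gene_id[genes$start > genes$end], collapse = ", "),
         call. = FALSE)
  if (!all(genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'", call. = FALSE)
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id values", call. = FALSE)

  genes <- genes[order(genes$replicon_id, genes$start, genes$end,
                       genes$gene_id), , drop = FALSE]
  dup_start <- unlist(lapply(split(genes$start, genes$replicon_id),
                             duplicated))
  if (any(dup_start))
    stop("gene starts must be strictly increasing within a replicon",
         call. = FALSE)
  genes$rank <- as.integer(stats::ave(genes$start, genes$replicon_id,
                                      FUN = seq_along))
  rownames(genes) <- NULL

  coding <- genes$protein_id[!is.na(genes$protein_id)]
  missing <- setdiff(coding, names(proteome))
  if (length(missing))
    stop("integrity error: protein(s) absent from proteome: ",
         paste(missing, collapse = ", "), call. = FALSE)

  domains <- validate_domains(domains, proteome)

  structure(
    list(genome_id = genome_id,
         taxon_label = taxon_label,
         environment_label = environment_label,
         genes = genes,
         proteome = proteome,
         domains = domains),
    class = "annotated_genome")
}

empty_domains <- function() {
  data.frame(protein_id = character(), pfam_acc = character(),
             ali_start = integer(), ali_end = integer(),
             score = numeric(), stringsAsFactors = FALSE)
}

validate_domains <- function(domains, proteome) {
  need <- c("protein_id", "pfam_acc", "ali_start", "ali_end", "score")
  if (!all(need %in% names(domains)))
    stop("domain table is missing columns: ",
         paste(setdiff(need, names(domains)), collapse = ", "),
         call. = FALSE)
  domains <- domains[, need, drop = FALSE]
  if (nrow(domains) == 0L) return(domains)
  if (!all(grepl(PFAM_RE, domains$pfam_acc)))
    stop("malformed Pfam accession(s): ",
         paste(unique(domains$pfam_acc[!grepl(PFAM_RE, domains$pfam_acc)]),
               collapse = ", "), call. = FALSE)
  unlinked <- !(domains$protein_id %in% names(proteome))
  if (any(unlinked)) {
    warning("dropping ", sum(unlinked),
            " domain hit(s) on proteins absent from the proteome: ",
            paste(unique(domains$protein_id[unlinked]), collapse = ", "),
            call. = FALSE)
    domains <- domains[!unlinked, , drop = FALSE]
  }
  if (nrow(domains)) {
    plen <- nchar(proteome[domains$protein_id])
    bad <- domains$ali_start > domains$ali_end | domains$ali_start < 1L |
      domains$ali_end > plen
    if (any(bad))
      stop("domain hit(s) with invalid alignment coordinates on: ",
           paste(unique(domains$protein_id[bad]), collapse = ", "),
           call. = FALSE)
  }
  rownames(domains) <- NULL
  domains
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat("<annotated_genome> ", x$genome_id,
      if (!is.na(x$taxon_label)) paste0(" (", x$taxon_label, ")"), "\n",
      sep = "")
  cat("  replicons: ", length(unique(x$genes$replicon_id)),
      ", genes: ", nrow(x$genes),
      ", proteins: ", length(x$proteome),
      ", domain hits: ", nrow(x$domains), "\n", sep = "")
  invisible(x)
}

#' Read one annotated genome from a GFF3 / FASTA / domain-table triplet
#'
#' Gene models come from GFF3 `gene` features (or `CDS` features when no
#' `gene` rows are present), the proteome from a protein FASTA whose
#' headers' first word is the protein id, and domain hits from either a
#' HMMER3 per-domain tabular file ("domtblout", hmmsearch or hmmscan
#' orientation) or a 5-column TSV (`protein_id`, `pfam_acc`, `ali_start`,
#' `ali_end`, `score`). Optional `##genome-id`, `##taxon` and
#' `##environment` GFF3 pragmas supply metadata.
#'
#' Domain hits on proteins absent from the FASTA are dropped with a
#' warning; a CDS whose protein is absent is an integrity error.
#'
#' @param gff_path,fasta_path,domains_path Input files; `domains_path` may
#'   be `NULL` for a genome with no domain annotation.
#' @return An [annotated_genome].
#' @export
read_genome <- function(gff_path, fasta_path, domains_path = NULL) {
  for (p in c(gff_path, fasta_path, domains_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)

  gff <- tryCatch(
    suppressWarnings(rtracklayer::import(gff_path, format = "gff3")),
    error = function(e)
      stop("malformed GFF3 in ", gff_path, ": ", conditionMessage(e),
           call. = FALSE))
  meta <- read_gff_pragmas(gff_path)

  df <- as.data.frame(gff)
  if (!nrow(df)) stop("no features in ", gff_path, call. = FALSE)
  is_gene <- df$type == "gene"
  is_cds <- df$type == "CDS"
  if (any(is_gene)) {
    g <- df[is_gene, , drop = FALSE]
    cds <- df[is_cds, , drop = FALSE]
    pid_of <- character(0)
    if (nrow(cds)) {
      parent <- vapply(cds$Parent, function(p)
        if (length(p)) p[[1]] else NA_character_, character(1))
      pid <- if ("protein_id" %in% names(cds)) cds$protein_id else cds$ID
      pid_of <- pid[!is.na(parent)]
      names(pid_of) <- parent[!is.na(parent)]
    }
    genes <- data.frame(
      gene_id = g$ID,
      replicon_id = as.character(g$seqnames),
      start = g$start, end = g$end, strand = as.character(g$strand),
      protein_id = unname(pid_of[g$ID]),
      stringsAsFactors = FALSE)
  } else if (any(is_cds)) {
    g <- df[is_cds, , drop = FALSE]
    genes <- data.frame(
      gene_id = g$ID,
      replicon_id = as.character(g$seqnames),
      start = g$start, end = g$end, strand = as.character(g$strand),
      protein_id = if ("protein_id" %in% names(g)) g$protein_id else g$ID,
      stringsAsFactors = FALSE)
  } else {
    stop("no gene or CDS features in ", gff_path, call. = FALSE)
  }

  proteome <- read_proteome(fasta_path)
  domains <- if (is.null(domains_path)) empty_domains() else
    read_domain_table(domains_path)

  annotated_genome(
    genome_id = meta$genome_id %||%
      tools::file_path_sans_ext(basename(gff_path)),
    genes = genes, proteome = proteome, domains = domains,
    taxon_label = meta$taxon %||% NA_character_,
    environment_label = meta$environment %||% NA_character_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_gff_pragmas <- function(path) {
  lines <- readLines(path, n = 100L, warn = FALSE)
  lines <- lines[startsWith(lines, "##")]
  pick <- function(key) {
    hit <- grep(paste0("^##", key, " "), lines, value = TRUE)
    if (length(hit)) sub(paste0("^##", key, " +"), "", hit[[1]]) else NULL
  }
  list(genome_id = pick("genome-id"), taxon = pick("taxon"),
       environment = pick("environment"))
}

read_proteome <- function(fasta_path) {
  aa <- tryCatch(Biostrings::readAAStringSet(fasta_path),
                 error = function(e)
                   stop("malformed FASTA in ", fasta_path, ": ",
                        conditionMessage(e), call. = FALSE))
  seqs <- as.character(aa)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs))) {
    for (id in unique(names(seqs)[duplicated(names(seqs))])) {
      if (length(unique(seqs[names(seqs) == id])) > 1L)
        stop("integrity error: protein_id ", id,
             " occurs with differing sequences", call. = FALSE)
    }
    seqs <- seqs[!duplicated(names(seqs))]
  }
  seqs
}

#' Read a domain-hit table (HMMER3 domtblout dialect or simple TSV)
#'
#' Auto-detects the format: '#'-commented whitespace-delimited rows with
#' 20 or more fields are treated as HMMER3 per-domain tabular output (both the
#' hmmsearch orientation, protein in column 1 / Pfam accession in column 5,
#' and the hmmscan orientation, Pfam accession in column 2 / protein in
#' column 4, are recognized; `ali_from`/`ali_to` are columns 18/19 and the
#' domain bit score column 14). Anything else must be a TSV with header
#' `protein_id  pfam_acc  ali_start  ali_end  score`. Pfam accession
#' versions (e.g. `PF03472.12`) are stripped.
#'
#' @param path Input file.
#' @return data.frame of domain hits.
#' @export
read_domain_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  if (!length(lines)) return(empty_domains())

  fields1 <- strsplit(trimws(lines[[1]]), "[ \t]+")[[1]]
  if (length(fields1) >= 20L) {
    rows <- strsplit(trimws(lines), "[ \t]+")
    strip <- function(x) sub("\\.[0-9]+$", "", x)
    parse_row <- function(f) {
      if (length(f) < 19L)
        stop("short domtblout row: ", paste(f, collapse = " "),
             call. = FALSE)
      if (grepl(PFAM_RE, strip(f[[5]]))) {         # hmmsearch orientation
        c(protein_id = f[[1]], pfam_acc = strip(f[[5]]))
      } else if (grepl(PFAM_RE, strip(f[[2]]))) {  # hmmscan orientation
        c(protein_id = f[[4]], pfam_acc = strip(f[[2]]))
      } else {
        stop("no Pfam accession in domtblout row for target ", f[[1]],
             call. = FALSE)
      }
    }
    ids <- t(vapply(rows, parse_row, character(2)))
    data.frame(protein_id = unname(ids[, "protein_id"]),
               pfam_acc = unname(ids[, "pfam_acc"]),
               ali_start = as.integer(vapply(rows, `[[`, "", 18L)),
               ali_end = as.integer(vapply(rows, `[[`, "", 19L)),
               score = as.numeric(vapply(rows, `[[`, "", 14L)),
               stringsAsFactors = FALSE)
  } else {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, comment.char = "#")
    need <- c("protein_id", "pfam_acc", "ali_start", "ali_end", "score")
    if (!all(need %in% names(tab)))
      stop("domain TSV ", path, " must have columns: ",
           paste(need, collapse = ", "), call. = FALSE)
    tab$pfam_acc <- sub("\\.[0-9]+$", "", tab$pfam_acc)
    tab[, need]
  }
}

#' Write one genome back to its GFF3 / FASTA / domain-TSV triplet
#'
#' Inverse of [read_genome()]; file names are `<genome_id>.gff3`,
#' `<genome_id>.faa`, `<genome_id>.domains.tsv`. Metadata travels as GFF3
#' pragmas.
#'
#' @param genome An [annotated_genome].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_genome_files <- function(genome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- genome$genome_id
  gff <- file.path(dir, paste0(id, ".gff3"))
  faa <- file.path(dir, paste0(id, ".faa"))
  dom <- file.path(dir, paste0(id, ".domains.tsv"))

  g <- genome$genes
  header <- c("##gff-version 3",
              paste("##genome-id", id),
              if (!is.na(genome$taxon_label))
                paste("##taxon", genome$taxon_label),
              if (!is.na(genome$environment_label))
                paste("##environment", genome$environment_label))
  gene_rows <- sprintf("%s\tsoloscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$replicon_id, g$start, g$end, g$strand, g$gene_id)
  coding <- !is.na(g$protein_id)
  cds_rows <- sprintf(
    "%s\tsoloscan\tCDS\t%d\t%d\t.\t%s\t0\tID=cds-%s;Parent=%s;protein_id=%s",
    g$replicon_id[coding], g$start[coding], g$end[coding], g$strand[coding],
    g$gene_id[coding], g$gene_id[coding], g$protein_id[coding])
  body <- character(0)
  ci <- 1L
  for (i in seq_len(nrow(g))) {
    body <- c(body, gene_rows[[i]])
    if (coding[[i]]) { body <- c(body, cds_rows[[ci]]); ci <- ci + 1L }
  }
  writeLines(c(header, body), gff)

  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(genome$proteome), faa)

  utils::write.table(genome$domains, dom, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(gff = gff, faa = faa, domains = dom))
}

# Canonical column sets of the fixed output files.
OUTPUT_SCHEMAS <- list(
  solos = c("genome_id", "replicon_id", "protein_id", "is_solo",
            "blocking_luxI", "window_genes", "luxr_length_ok"),
  clusters = c("cluster_id", "representative_id", "member_id",
               "identity_to_rep", "cov_member", "cov_rep"),
  context_profiles = c("cluster_id", "pfam_acc", "frequency"),
  subgroups = c("cluster_id", "x", "y", "z", "subgroup_id"),
  ligand_classes = c("protein_id", "n_conserved", "key_residues",
                     "pab_signature", "motif_match", "neighborhood_class",
                     "predicted_class_hint"),
  tree_annotations = c("id", "subgroup_id", "class_hint",
                       "environment_label"))

#' Write the pipeline's fixed output file set
#'
#' Emits `solos.tsv`, `clusters.tsv`, `context_profiles.tsv`,
#' `subgroups.tsv`, `ligand_classes.tsv`, `tree_annotations.tsv`,
#' `tree.nwk` and `summary.json` into `out_dir`. Missing/empty result
#' elements yield headers-only tables (and an empty `tree.nwk`), so the
#' file set is always complete; identical results produce byte-identical
#' files.
#'
#' @param results Named list with any of `solos`, `clusters`,
#'   `context_profiles`, `subgroups`, `ligand_classes`, `tree_annotations`
#'   (data.frames), `tree` (an `ape::phylo` or Newick string or `NULL`)
#'   and `summary` (a list).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a manifest data.frame (`file`, `bytes`, `md5`).
#' @export
write_outputs <- function(results, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0)
    stop("output directory not writable: ", out_dir, call. = FALSE)

  paths <- character(0)
  for (nm in names(OUTPUT_SCHEMAS)) {
    cols <- OUTPUT_SCHEMAS[[nm]]
    tab <- results[[nm]]
    if (is.null(tab) || !nrow(tab)) {
      tab <- as.data.frame(stats::setNames(
        replicate(length(cols), character(0), simplify = FALSE), cols))
    } else {
      miss <- setdiff(cols, names(tab))
      if (length(miss))
        stop("results$", nm, " is missing columns: ",
             paste(miss, collapse = ", "), call. = FALSE)
      tab <- tab[, cols, drop = FALSE]
    }
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    utils::write.table(tab, p, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n")
    paths <- c(paths, p)
  }

  nwk <- file.path(out_dir, "tree.nwk")
  tree <- results$tree
  if (is.null(tree)) {
    writeLines(character(0), nwk)
  } else if (inherits(tree, "phylo")) {
    ape::write.tree(tree, file = nwk)
  } else {
    writeLines(as.character(tree), nwk)
  }
  paths <- c(paths, nwk)

  js <- file.path(out_dir, "summary.json")
  jsonlite::write_json(results$summary %||% list(), js,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, js)

  manifest <- data.frame(
    file = basename(paths),
    bytes = unname(file.size(paths)),
    md5 = unname(tools::md5sum(paths)),
    stringsAsFactors = FALSE)
  invisible(manifest)
}
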