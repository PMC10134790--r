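# End-to-end orchestration: detect -> pair topologies -> cluster ->
# context profiles -> subgroups -> ligand classes -> tree -> report.

#' Default pipeline configuration
#'
#' @return Nested list of stage settings; override any subset and pass as
#'   `config` to [run_pipeline()]. Keys: `window`, `luxr_pfam`,
#'   `luxi_pfam`, `linkage_bp`, `cluster$id_threshold`,
#'   `cluster$cov_threshold`, `profile$min_members`, `profile$freq_floor`,
#'   `embed$method`, `embed$n_components`, `embed$seed`, `dbscan$eps`,
#'   `dbscan$min_samples`, `stop_after` (run only a stage prefix: one of
#'   "detect", "cluster", "profile", "subgroup", "classify", "tree").
#' @export
pipeline_config <- function() {
  list(window = 4L, luxr_pfam = LUXR_PFAM, luxi_pfam = LUXI_PFAM,
       linkage_bp = 3000L,
       cluster = list(id_threshold = 0.80, cov_threshold = 0.80),
       profile = list(min_members = 51L, freq_floor = 0.05),
       embed = list(method = "pca", n_components = 3L, seed = NULL),
       dbscan = list(eps = 0.5, min_samples = 10L),
       stop_after = NULL)
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Summarize the per-genome solo-count distribution
#'
#' Counts genomes with zero, one, or more than one LuxR solo and reports
#' percentages (100 * count / n_genomes) rounded half-up to one decimal,
#' the convention of the corpus survey. Genomes absent from `solo_calls`
#' count as zero.
#'
#' @param solo_calls A [detect_solos()]-style data.frame (`genome_id`,
#'   `is_solo`) covering any number of genomes, or a named integer vector
#'   of per-genome solo counts.
#' @param n_genomes Total number of genomes surveyed.
#' @return List of class `distribution_summary`: `n_genomes`,
#'   `n_solo_hits`, `n_zero`, `n_one`, `n_multi`, `pct_zero`, `pct_one`,
#'   `pct_multi`.
#' @export
summarize_distribution <- function(solo_calls, n_genomes) {
  counts <- if (is.data.frame(solo_calls)) {
    hit <- solo_calls[!is.na(solo_calls$is_solo) & solo_calls$is_solo, ,
                      drop = FALSE]
    vapply(split(hit$protein_id, hit$genome_id), length, integer(1))
  } else {
    stats::setNames(as.integer(solo_calls), names(solo_calls))
  }
  counts <- counts[counts > 0L]
  if (length(counts) > n_genomes)
    stop("contract violation: more genomes with solos (", length(counts),
         ") than genomes surveyed (", n_genomes, ")", call. = FALSE)

  n_one <- sum(counts == 1L)
  n_multi <- sum(counts > 1L)
  n_zero <- n_genomes - n_one - n_multi
  pct <- function(k) round_half_up(100 * k / n_genomes, 1L)
  structure(
    list(n_genomes = as.integer(n_genomes),
         n_solo_hits = as.integer(sum(counts)),
         n_zero = as.integer(n_zero), n_one = n_one, n_multi = n_multi,
         pct_zero = pct(n_zero), pct_one = pct(n_one),
         pct_multi = pct(n_multi)),
    class = "distribution_summary")
}

#' @export
print.distribution_summary <- function(x, ...) {
  cat(sprintf(
    "%d genomes, %d solo hits: %.1f%% none, %.1f%% one, %.1f%% multiple\n",
    x$n_genomes, x$n_solo_hits, x$pct_zero, x$pct_one, x$pct_multi))
  invisible(x)
}

read_corpus_dir <- function(input_dir) {
  gffs <- sort(list.files(input_dir, pattern = "\\.gff3$",
                          full.names = TRUE))
  if (!length(gffs)) stop("no .gff3 files in ", input_dir, call. = FALSE)
  lapply(gffs, function(gff) {
    base <- tools::file_path_sans_ext(gff)
    dom <- paste0(base, ".domains.tsv")
    read_genome(gff, paste0(base, ".faa"),
                if (file.exists(dom)) dom else NULL)
  })
}

#' Run the full LuxR-solo survey pipeline
#'
#' Stages, in order: solo detection per genome; luxI/luxR pair-topology
#' classification for non-solo LuxRs; greedy sequence clustering of solo
#' proteins; neighborhood-Pfam context profiles for large clusters;
#' embedding + density subgrouping; residue/motif ligand-class reports for
#' every solo; a neighbor-joining tree of cluster representatives; and the
#' distribution summary. Degenerate inputs take documented shortcuts:
#' fewer than 2 profiled clusters skips subgrouping (empty table), fewer
#' than 3 clusters skips the tree; both are logged, not errors. All
#' outputs are written via [write_outputs()]; identical inputs and seed
#' give byte-identical files.
#'
#' @param input_dir Directory of genome triplets (as written by
#'   [generate_corpus()]); ignored when `synthetic` is given.
#' @param out_dir Output directory.
#' @param config Overrides merged into [pipeline_config()].
#' @param seed Integer seed (generator and any seeded embedding).
#' @param synthetic Optional [corpus_config()] list: generate the corpus
#'   (written under `out_dir`/corpus) instead of reading `input_dir`.
#' @return Invisibly, a list with all stage tables (`solos`, `pairs`,
#'   `clusters`, `context_profiles`, `subgroups`, `ligand_classes`),
#'   `tree`, `summary`, `manifest`, and `genomes`.
#' @export
run_pipeline <- function(input_dir = NULL, out_dir, config = list(),
                         seed = 1L, synthetic = NULL) {
  cfg <- merge_config(pipeline_config(), config)
  ref <- reference_map()
  stages <- c("detect", "cluster", "profile", "subgroup", "classify",
              "tree")
  last <- if (is.null(cfg$stop_after)) "tree" else
    match.arg(cfg$stop_after, stages)
  run_upto <- function(stage)
    match(stage, stages) <= match(last, stages)

  genomes <- if (!is.null(synthetic)) {
    message("[simulate] generating synthetic corpus (seed ", seed, ")")
    corpus <- generate_corpus(synthetic, seed = seed,
                              dir = file.path(out_dir, "corpus"),
                              ref = ref)
    corpus$genomes
  } else {
    read_corpus_dir(input_dir)
  }
  names(genomes) <- vapply(genomes, `[[`, "", "genome_id")

  solos <- do.call(rbind, lapply(genomes, detect_solos,
                                 window = cfg$window,
                                 luxr_pfam = cfg$luxr_pfam,
                                 luxi_pfam = cfg$luxi_pfam))
  rownames(solos) <- NULL
  n_solo <- sum(!is.na(solos$is_solo) & solos$is_solo)
  message("[detect] ", length(genomes), " genomes, ", nrow(solos),
          " LuxR proteins, ", n_solo, " solos")

  pairs <- classify_detected_pairs(solos, genomes, cfg$linkage_bp)
  message("[detect] ", nrow(pairs), " luxI/luxR pairs classified")

  solo_rows <- solos[!is.na(solos$is_solo) & solos$is_solo, ,
                     drop = FALSE]
  solo_seqs <- stats::setNames(
    vapply(seq_len(nrow(solo_rows)), function(i)
      genomes[[solo_rows$genome_id[[i]]]]$proteome[[
        solo_rows$protein_id[[i]]]], character(1)),
    solo_rows$protein_id)

  clusters <- empty_clusters <- greedy_cluster(character(0))
  profiles <- build_context_profiles(empty_clusters, solos)
  subgroups <- data.frame(cluster_id = integer(), x = numeric(),
                          y = numeric(), z = numeric(),
                          subgroup_id = integer(), stringsAsFactors = FALSE)
  ligand <- data.frame()
  tree <- NULL
  tree_annotations <- NULL

  if (run_upto("cluster")) {
    clusters <- greedy_cluster(solo_seqs,
                               id_threshold = cfg$cluster$id_threshold,
                               cov_threshold = cfg$cluster$cov_threshold)
    message("[cluster] ", length(solo_seqs), " solo proteins -> ",
            length(unique(clusters$cluster_id)), " clusters")
  }

  if (run_upto("profile")) {
    profiles <- build_context_profiles(
      clusters, solos, min_members = cfg$profile$min_members,
      freq_floor = cfg$profile$freq_floor,
      exclude_pfams = cfg$luxr_pfam)
    message("[profile] ", length(unique(profiles$cluster_id)),
            " clusters profiled")
  }

  if (run_upto("subgroup")) {
    n_prof <- length(unique(profiles$cluster_id))
    if (n_prof >= 2L) {
      emb <- embed_profiles(profiles, method = cfg$embed$method,
                            n_components = cfg$embed$n_components,
                            seed = cfg$embed$seed %||% seed)
      labels <- dbscan_cluster(emb, eps = cfg$dbscan$eps,
                               min_samples = cfg$dbscan$min_samples)
      emb <- emb[names(labels), , drop = FALSE]
      subgroups <- data.frame(cluster_id = as.integer(names(labels)),
                              x = emb[, 1], y = emb[, 2], z = emb[, 3],
                              subgroup_id = unname(labels),
                              stringsAsFactors = FALSE)
      subgroups <- subgroups[order(subgroups$cluster_id), , drop = FALSE]
      rownames(subgroups) <- NULL
      message("[subgroup] ",
              length(unique(labels[labels >= 0])), " subgroups, ",
              sum(labels == -1L), " noise clusters")
    } else {
      message("[subgroup] skipped: fewer than 2 profiled clusters")
    }
  }

  if (run_upto("classify") && nrow(solo_rows)) {
    lig <- vector("list", nrow(solo_rows))
    for (i in seq_len(nrow(solo_rows))) {
      rep_i <- score_conserved_residues(solo_seqs[[i]], ref)
      full <- classify_solo(rep_i, solo_rows[i, ], ref)
      lig[[i]] <- data.frame(
        protein_id = full$protein_id, n_conserved = full$n_conserved,
        key_residues = full$key_residues,
        pab_signature = full$pab_signature,
        motif_match = full$motif_match,
        neighborhood_class = full$neighborhood_class,
        predicted_class_hint = full$predicted_class_hint,
        stringsAsFactors = FALSE)
    }
    ligand <- do.call(rbind, lig)
    message("[classify] ", nrow(ligand), " solos scored: ",
            paste(names(table(ligand$predicted_class_hint)),
                  table(ligand$predicted_class_hint),
                  sep = "=", collapse = ", "))
  }

  if (run_upto("tree")) {
    reps <- unique(clusters$representative_id)
    if (length(reps) >= 3L) {
      rep_seqs <- solo_seqs[reps]
      tree <- neighbor_joining(distance_matrix(rep_seqs))
      sg_of <- stats::setNames(subgroups$subgroup_id,
                               as.character(subgroups$cluster_id))
      cid_of_rep <- stats::setNames(
        clusters$cluster_id[match(reps, clusters$member_id)], reps)
      hint_of <- stats::setNames(ligand$predicted_class_hint,
                                 ligand$protein_id)
      env_of <- vapply(reps, function(p)
        genomes[[solo_rows$genome_id[[match(p, solo_rows$protein_id)]]
                 ]]$environment_label %||% NA_character_, character(1))
      sg <- sg_of[as.character(cid_of_rep[reps])]
      tree_annotations <- data.frame(
        id = reps,
        subgroup_id = ifelse(is.na(sg), NA_integer_, as.integer(sg)),
        class_hint = unname(hint_of[reps]),
        environment_label = unname(env_of),
        stringsAsFactors = FALSE)
      message("[tree] neighbor-joining tree over ", length(reps),
              " representatives")
    } else {
      message("[tree] skipped: fewer than 3 cluster representatives")
    }
  }

  summary <- summarize_distribution(solos, length(genomes))
  results <- list(
    solos = solos, pairs = pairs, clusters = clusters,
    context_profiles = profiles, subgroups = subgroups,
    ligand_classes = ligand, tree = tree,
    tree_annotations = tree_annotations,
    summary = list(
      schema_version = "1.0",
      seed = as.integer(seed),
      distribution = unclass(summary),
      n_luxr_proteins = nrow(solos),
      n_fused = sum(solos$is_fused),
      n_pairs = nrow(pairs),
      pair_arrangements = as.list(table(pairs$arrangement)),
      n_clusters = length(unique(clusters$cluster_id)),
      n_profiled_clusters = length(unique(profiles$cluster_id)),
      n_subgroups = length(unique(
        subgroups$subgroup_id[subgroups$subgroup_id >= 0])),
      n_noise_clusters = sum(subgroups$subgroup_id == -1L),
      class_hints = if (nrow(ligand))
        as.list(table(ligand$predicted_class_hint)) else list()))

  manifest <- write_outputs(results, out_dir)
  message("[report] wrote ", nrow(manifest), " files to ", out_dir)
  results$manifest <- manifest
  results$summary_distribution <- summary
  results$genomes <- genomes
  invisible(results)
}

# For every non-fused, non-solo LuxR call, classify the topology of the
# (focal LuxR, nearest blocking LuxI) pair.
classify_detected_pairs <- function(solos, genomes, linkage_bp = 3000L) {
  out <- data.frame(genome_id = character(), luxr_protein = character(),
                    luxi_protein = character(), arrangement = character(),
                    intergenic_bp = integer(), linked = logical(),
                    stringsAsFactors = FALSE)
  idx <- which(!is.na(solos$is_solo) & !solos$is_solo)
  if (!length(idx)) return(out)
  rows <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    call <- solos[idx[[k]], ]
    g <- genomes[[call$genome_id]]$genes
    luxr <- g[g$gene_id == call$gene_id, ]
    luxi <- g[!is.na(g$protein_id) &
                g$protein_id == call$blocking_luxI &
                g$replicon_id == call$replicon_id, ]
    luxi <- luxi[which.min(abs(luxi$rank - luxr$rank)), ]
    topo <- classify_pair_topology(luxr, luxi, linkage_bp)
    rows[[k]] <- data.frame(
      genome_id = call$genome_id, luxr_protein = call$protein_id,
      luxi_protein = call$blocking_luxI,
      arrangement = topo$arrangement,
      intergenic_bp = topo$intergenic_bp, linked = topo$linked,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
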