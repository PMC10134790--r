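# Seeded generator of synthetic annotated genomes with planted ground
# truth: complete luxI/luxR pairs in the canonical topologies, LuxR solos
# with designed neighborhood signatures, and decoy genes. Every pipeline
# stage is testable against the emitted truth table without downloads.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(len) paste(sample(AA20, len, TRUE), collapse = "")

mutate_protein <- function(seq, rate, mutable) {
  if (rate <= 0 || !length(mutable)) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- mutable[stats::runif(length(mutable)) < rate]
  for (i in hit) {
    chars[[i]] <- sample(setdiff(AA20, chars[[i]]), 1L)
  }
  paste(chars, collapse = "")
}

#' Default settings of the synthetic-corpus generator
#'
#' The defaults emulate the statistical structure of the proteobacterial
#' survey: the per-genome solo-count mixture uses the surveyed proportions
#' of genomes with zero, one, or multiple solos (14351 : 12235 : 4448 out
#' of 31,034); five solo archetypes plant the neighborhood signatures the
#' survey recognizes (generic AHL sensor; PAB with the W57M/Y61W hallmark
#' and an adjacent proline-iminopeptidase gene; an mfs1-like
#' transporter-adjacent subgroup; the SdiA-like enteric context; and a
#' PluR-like pyrone sensor carrying TYDQCS). Sequence families derive from
#' per-archetype ancestors by i.i.d. substitutions at 4% per mutable site
#' (key residues and the planted motif window are immutable), far inside
#' the 80% clustering identity threshold, while ancestors are ~50%
#' diverged from each other, far outside it.
#'
#' @param n_genomes Number of genomes (default 100).
#' @return Named list of generator settings; override fields and pass to
#'   [generate_corpus()].
#' @export
corpus_config <- function(n_genomes = 100L) {
  list(
    n_genomes = as.integer(n_genomes),
    # P(zero, one, >1 solos per genome), from the surveyed genome counts
    solo_mixture = c(zero = 14351, one = 12235, multi = 4448) / 31034,
    multi_solo_counts = c(2L, 3L),
    genes_per_replicon = c(25L, 45L),
    plasmid_prob = 0.25,
    plasmid_genes = c(14L, 20L),
    pair_prob = 0.5,
    pair_topologies = c(tandem = 0.40, convergent = 0.30,
                        divergent = 0.15, complex = 0.15),
    pair_unlinked_prob = 0.15,
    linked_gap = c(50L, 2500L),
    unlinked_gap = c(3200L, 4500L),
    intergenic_range = c(50L, 400L),
    decoy_len_range = c(80L, 300L),
    decoy_domain_prob = 0.7,
    noncoding_prob = 0.05,
    mutation_rate = 0.04,
    archetype_divergence = 0.5,
    luxi_len_range = c(185L, 215L),
    hth_pfam = "PF00196",
    motif_window = 118L:123L,
    decoy_pfams = sprintf("PF%05d", c(10000:10014, 11000:11014)),
    taxa = c("Rhizobium", "Pseudomonas", "Burkholderia", "Agrobacterium",
             "Escherichia", "Xanthomonas", "Kosakonia", "Photorhabdus"),
    environments = c("plant", "terrestrial", "aquatic", "human"),
    archetypes = list(
      ahl = list(planted_class = "AHL_type", signature_pfams = numeric(0),
                 environment = "terrestrial", pab = FALSE, motif = NA),
      pab = list(planted_class = "PAB_type",
                 signature_pfams = c(PF00561 = 1.0),
                 environment = "plant", pab = TRUE, motif = NA),
      mfs1 = list(planted_class = "AHL_type",
                  signature_pfams = c(PF07690 = 1.0),
                  environment = "aquatic", pab = FALSE, motif = NA),
      sdia = list(planted_class = "AHL_type",
                  signature_pfams = c(PF00005 = 1.0, PF00072 = 1.0),
                  environment = "human", pab = FALSE, motif = NA),
      plur = list(planted_class = "pyrone_DAR_type",
                  signature_pfams = c(PF00109 = 0.9),
                  environment = "terrestrial", pab = FALSE,
                  motif = "TYDQCS")))
}

# Archetype ancestor sequences, derived from the packaged anchor inside
# the corpus RNG stream: a fixed fraction of mutable (non-key, non-motif)
# positions is substituted per archetype, key residues stay at consensus
# (except the PAB W57M/Y61W hallmark) and the PluR-like ancestor carries
# its motif at the fixed window.
build_ancestors <- function(config, ref) {
  anchor <- strsplit(ref$sequence, "")[[1]]
  keys <- ref$key_positions$pos
  mutable <- setdiff(seq_along(anchor), c(keys, config$motif_window))
  lapply(config$archetypes, function(a) {
    chars <- anchor
    n_mut <- round(config$archetype_divergence * length(mutable))
    at <- sample(mutable, n_mut)
    for (i in at) chars[[i]] <- sample(setdiff(AA20, chars[[i]]), 1L)
    if (isTRUE(a$pab)) { chars[[57]] <- "M"; chars[[61]] <- "W" }
    if (!is.na(a$motif))
      chars[config$motif_window] <- strsplit(a$motif, "")[[1]]
    paste(chars, collapse = "")
  })
}

#' Generate a synthetic corpus of annotated genomes with planted truth
#'
#' Deterministic given `seed`. Each genome gets 1-2 replicons of decoy
#' genes; a luxI/luxR pair is planted with probability `pair_prob` in a
#' drawn topology (tandem / convergent / divergent / complex, the last
#' with one intervening gene) and linkage distance; solos are planted
#' according to the solo-count mixture, each drawn from an archetype whose
#' signature Pfams are placed on neighboring genes at their configured
#' prevalence. Planted elements are separated by at least 12 gene ranks so
#' neighborhoods never overlap. Decoy genes carry random Pfams disjoint
#' from all signature accessions; a few are non-coding and simply occupy
#' neighborhood slots.
#'
#' @param config Settings from [corpus_config()].
#' @param seed Integer seed.
#' @param dir Optional directory: when given, every genome is written as a
#'   GFF3/FASTA/domain-TSV triplet plus `truth.tsv`.
#' @param ref A [reference_map()] (source of anchor and key positions).
#' @return List: `genomes` (list of [annotated_genome]), `truth`
#'   (data.frame `genome_id`, `protein_id`, `role`, `planted_subgroup`,
#'   `planted_class`, `topology`, `linked`, `environment`), `dir`.
#' @export
generate_corpus <- function(config = corpus_config(), seed = 1L,
                            dir = NULL, ref = reference_map()) {
  if (abs(sum(config$solo_mixture) - 1) > 1e-9)
    stop("config error: solo_mixture must sum to 1", call. = FALSE)
  if (abs(sum(config$pair_topologies) - 1) > 1e-9)
    stop("config error: pair_topologies must sum to 1", call. = FALSE)

  withr::with_seed(as.integer(seed), {
    ancestors <- build_ancestors(config, ref)
    mutable <- setdiff(seq_len(nchar(ref$sequence)),
                       c(ref$key_positions$pos, config$motif_window))
    genomes <- vector("list", config$n_genomes)
    truth <- vector("list", config$n_genomes)
    for (g in seq_len(config$n_genomes)) {
      gid <- sprintf("g%04d", g)
      built <- build_genome(gid, config, ancestors, mutable)
      genomes[[g]] <- built$genome
      truth[[g]] <- built$truth
    }
    truth <- do.call(rbind, truth)
    rownames(truth) <- NULL

    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      for (gm in genomes) write_genome_files(gm, dir)
      utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    list(genomes = genomes, truth = truth, dir = dir)
  })
}

# One genome: lay out decoy gene skeletons per replicon, reserve anchor
# ranks for planted events, then materialize sequences, domains and
# coordinates.
build_genome <- function(gid, config, ancestors, mutable) {
  n_solos <- sample(c(0L, 1L, 99L), 1L, prob = config$solo_mixture)
  if (n_solos == 99L) n_solos <- sample(config$multi_solo_counts, 1L)
  has_pair <- stats::runif(1) < config$pair_prob
  has_plasmid <- stats::runif(1) < config$plasmid_prob

  solo_archetypes <- sample(names(config$archetypes), n_solos,
                            replace = TRUE)

  # events per replicon: pair and most solos on the chromosome, the last
  # solo on the plasmid when one exists
  chr_events <- list()
  pls_events <- list()
  if (has_pair) {
    topo <- sample(names(config$pair_topologies), 1L,
                   prob = config$pair_topologies)
    linked <- stats::runif(1) >= config$pair_unlinked_prob
    chr_events <- c(chr_events,
                    list(list(kind = "pair", topology = topo,
                              linked = linked)))
  }
  for (i in seq_len(n_solos)) {
    ev <- list(list(kind = "solo", archetype = solo_archetypes[[i]]))
    if (has_plasmid && i == n_solos) pls_events <- c(pls_events, ev)
    else chr_events <- c(chr_events, ev)
  }

  n_chr <- sample(seq(config$genes_per_replicon[[1]],
                      config$genes_per_replicon[[2]]), 1L)
  n_chr <- max(n_chr, 14L * length(chr_events) + 8L)
  reps <- list(chromosome = list(n = n_chr, events = chr_events))
  if (has_plasmid) {
    n_pls <- sample(seq(config$plasmid_genes[[1]],
                        config$plasmid_genes[[2]]), 1L)
    n_pls <- max(n_pls, 14L * length(pls_events) + 8L)
    reps$plasmid <- list(n = n_pls, events = pls_events)
  }

  genes <- list(); proteome <- character(0); domains <- list()
  truth <- list()
  env_vote <- character(0)

  for (rep_name in names(reps)) {
    rp <- reps[[rep_name]]
    rep_id <- paste0(gid, "_", substr(rep_name, 1, 3))
    n <- rp$n
    n_ev <- length(rp$events)
    anchors <- if (n_ev)
      3L + (seq_len(n_ev) - 1L) * 14L + sample(0L:3L, n_ev, TRUE)
    else integer(0)

    # skeleton: everything starts as a decoy
    plen <- sample(seq(config$decoy_len_range[[1]],
                       config$decoy_len_range[[2]]), n, TRUE)
    strand <- sample(c("+", "-"), n, TRUE)
    coding <- stats::runif(n) >= config$noncoding_prob
    role <- rep("decoy", n)
    pfam <- rep(NA_character_, n)
    has_dom <- stats::runif(n) < config$decoy_domain_prob
    pfam[has_dom] <- sample(config$decoy_pfams, sum(has_dom), TRUE)
    seqs <- rep(NA_character_, n)
    gap_override <- rep(NA_integer_, n)  # gap AFTER gene i
    ev_meta <- vector("list", n)

    for (e in seq_len(n_ev)) {
      ev <- rp$events[[e]]
      r <- anchors[[e]]
      if (ev$kind == "solo") {
        arch <- config$archetypes[[ev$archetype]]
        role[[r]] <- "solo"; coding[[r]] <- TRUE
        seqs[[r]] <- mutate_protein(ancestors[[ev$archetype]],
                                    config$mutation_rate, mutable)
        pfam[[r]] <- NA_character_
        ev_meta[[r]] <- list(archetype = ev$archetype)
        env_vote <- c(env_vote, arch$environment)
        offsets <- sample(c(-2L, -1L, 1L, 2L))
        sig <- arch$signature_pfams
        for (k in seq_along(sig)) {
          if (stats::runif(1) < sig[[k]]) {
            nb <- r + offsets[[k]]
            coding[[nb]] <- TRUE
            role[[nb]] <- "signature"
            pfam[[nb]] <- names(sig)[[k]]
          }
        }
      } else {
        luxr_first <- stats::runif(1) < 0.5
        width <- if (ev$topology == "complex") 2L else 1L
        ra <- r; rb <- r + width
        r_luxr <- if (luxr_first) ra else rb
        r_luxi <- if (luxr_first) rb else ra
        role[[r_luxr]] <- "pair_luxR"; role[[r_luxi]] <- "pair_luxI"
        coding[c(ra, rb)] <- TRUE
        seqs[[r_luxr]] <- mutate_protein(ancestors$ahl,
                                         config$mutation_rate, mutable)
        seqs[[r_luxi]] <- random_protein(
          sample(seq(config$luxi_len_range[[1]],
                     config$luxi_len_range[[2]]), 1L))
        pfam[c(ra, rb)] <- NA_character_
        st <- switch(ev$topology,
                     tandem = rep(sample(c("+", "-"), 1L), 2L),
                     complex = rep(sample(c("+", "-"), 1L), 2L),
                     convergent = c("+", "-"),
                     divergent = c("-", "+"))
        strand[[ra]] <- st[[1]]; strand[[rb]] <- st[[2]]
        # complex pairs put an intervening gene (<= ~900 bp) inside the
        # luxR-luxI span, so cap the drawn gap to keep the linkage truth
        gp_max <- if (ev$topology == "complex")
          min(config$linked_gap[[2]], 1700L) else config$linked_gap[[2]]
        gp <- if (ev$linked)
          sample(seq(config$linked_gap[[1]], gp_max), 1L)
        else
          sample(seq(config$unlinked_gap[[1]],
                     config$unlinked_gap[[2]]), 1L)
        if (ev$topology == "complex") {
          gap_override[[ra]] <- gp %/% 2L
          gap_override[[ra + 1L]] <- gp %/% 2L
        } else {
          gap_override[[ra]] <- gp
        }
        ev_meta[[r_luxr]] <- list(topology = ev$topology,
                                  linked = ev$linked)
      }
    }

    # materialize proteins, coordinates, domains
    plen[role == "solo" | role == "pair_luxR"] <-
      nchar(seqs[role == "solo" | role == "pair_luxR"])
    plen[role == "pair_luxI"] <- nchar(seqs[role == "pair_luxI"])
    glen <- ifelse(coding, 3L * plen, sample(200:600, n, TRUE))
    gaps <- sample(seq(config$intergenic_range[[1]],
                       config$intergenic_range[[2]]), n, TRUE)
    gaps[!is.na(gap_override)] <- gap_override[!is.na(gap_override)]
    starts <- cumsum(c(101L, utils::head(glen + gaps, -1L)))
    ends <- starts + glen - 1L

    pid <- ifelse(coding, sprintf("%s_p%03d", rep_id, seq_len(n)),
                  NA_character_)
    for (i in seq_len(n)) {
      if (!coding[[i]]) next
      if (is.na(seqs[[i]])) seqs[[i]] <- random_protein(plen[[i]])
      proteome[[pid[[i]]]] <- seqs[[i]]
      if (role[[i]] %in% c("solo", "pair_luxR")) {
        domains[[length(domains) + 1L]] <- data.frame(
          protein_id = pid[[i]],
          pfam_acc = c(LUXR_PFAM, config$hth_pfam),
          ali_start = c(8L, 180L), ali_end = c(170L, 230L),
          score = round(stats::runif(2, c(150, 40), c(250, 90)), 1),
          stringsAsFactors = FALSE)
      } else if (role[[i]] == "pair_luxI") {
        domains[[length(domains) + 1L]] <- data.frame(
          protein_id = pid[[i]], pfam_acc = LUXI_PFAM,
          ali_start = 5L, ali_end = min(180L, plen[[i]]),
          score = round(stats::runif(1, 120, 220), 1),
          stringsAsFactors = FALSE)
      } else if (!is.na(pfam[[i]])) {
        ae <- max(2L, min(plen[[i]] - 1L, plen[[i]] - 10L))
        domains[[length(domains) + 1L]] <- data.frame(
          protein_id = pid[[i]], pfam_acc = pfam[[i]],
          ali_start = 2L, ali_end = ae,
          score = round(stats::runif(1, 25, 120), 1),
          stringsAsFactors = FALSE)
      }
      meta <- ev_meta[[i]]
      if (role[[i]] == "solo") {
        arch <- config$archetypes[[meta$archetype]]
        truth[[length(truth) + 1L]] <- data.frame(
          genome_id = gid, protein_id = pid[[i]], role = "solo",
          planted_subgroup = meta$archetype,
          planted_class = arch$planted_class,
          topology = NA_character_, linked = NA,
          stringsAsFactors = FALSE)
      } else if (role[[i]] == "pair_luxR") {
        truth[[length(truth) + 1L]] <- data.frame(
          genome_id = gid, protein_id = pid[[i]], role = "pair_luxR",
          planted_subgroup = NA_character_, planted_class = "none",
          topology = meta$topology, linked = meta$linked,
          stringsAsFactors = FALSE)
      } else if (role[[i]] == "pair_luxI") {
        truth[[length(truth) + 1L]] <- data.frame(
          genome_id = gid, protein_id = pid[[i]], role = "pair_luxI",
          planted_subgroup = NA_character_, planted_class = "none",
          topology = NA_character_, linked = NA,
          stringsAsFactors = FALSE)
      }
    }

    genes[[length(genes) + 1L]] <- data.frame(
      gene_id = sprintf("%s_g%03d", rep_id, seq_len(n)),
      replicon_id = rep_id, start = starts, end = ends, strand = strand,
      protein_id = pid, stringsAsFactors = FALSE)
  }

  environment_label <-
    if (length(env_vote) && stats::runif(1) < 0.8) env_vote[[1]]
    else sample(config$environments, 1L)

  genome <- annotated_genome(
    genome_id = gid,
    genes = do.call(rbind, genes),
    proteome = proteome,
    domains = if (length(domains)) do.call(rbind, domains)
              else empty_domains(),
    taxon_label = sample(config$taxa, 1L),
    environment_label = environment_label)

  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(genome_id = character(), protein_id = character(),
               role = character(), planted_subgroup = character(),
               planted_class = character(), topology = character(),
               linked = logical(), stringsAsFactors = FALSE)
  truth_df$environment <- if (nrow(truth_df)) environment_label else
    character(0)
  list(genome = genome, truth = truth_df)
}

#' Generate labeled context-profile vectors from signature archetypes
#'
#' Produces synthetic per-cluster Pfam-frequency profiles for exercising
#' the embedding + density-clustering stage: `k_archetypes` archetypes
#' each contribute `clusters_per_archetype` profiles sharing a disjoint
#' 5-Pfam signature (frequency `0.02 + 0.9 * separation`) perturbed by
#' bounded uniform noise (+-0.04), plus `n_noise` profiles uniform over
#' the feature space. At `separation = 0` the archetypes coincide and
#' merge; at the default full separation they are recoverable by
#' [embed_profiles()] + [dbscan_cluster()].
#'
#' @param k_archetypes,clusters_per_archetype,n_noise Design counts.
#' @param separation Signature strength in \[0, 1\] (default 1).
#' @param n_features Number of Pfam features (grown to fit 5 per
#'   archetype if needed; default 24).
#' @param seed Integer seed.
#' @return List: `profiles` (matrix, rownames = synthetic cluster ids),
#'   `labels` (named integer vector; archetypes 1..k, noise -1).
#' @export
generate_profile_blobs <- function(k_archetypes, clusters_per_archetype,
                                   n_noise, separation = 1,
                                   n_features = 24L, seed = 1L) {
  stopifnot(k_archetypes >= 1L, clusters_per_archetype >= 1L,
            n_noise >= 0L, separation >= 0, separation <= 1)
  p <- max(n_features, 5L * k_archetypes + 4L)
  withr::with_seed(as.integer(seed), {
    n <- k_archetypes * clusters_per_archetype + n_noise
    m <- matrix(0, n, p)
    labels <- integer(n)
    row <- 0L
    for (a in seq_len(k_archetypes)) {
      sig <- rep(0.02, p)
      sig[((a - 1L) * 5L + 1L):(a * 5L)] <- 0.02 + 0.9 * separation
      for (i in seq_len(clusters_per_archetype)) {
        row <- row + 1L
        m[row, ] <- pmin(1, pmax(0, sig + stats::runif(p, -0.04, 0.04)))
        labels[[row]] <- a
      }
    }
    for (i in seq_len(n_noise)) {
      row <- row + 1L
      m[row, ] <- stats::runif(p)
      labels[[row]] <- -1L
    }
    ids <- sprintf("c%03d", seq_len(n))
    dimnames(m) <- list(ids, sprintf("PF%05d", 90000L + seq_len(p)))
    list(profiles = m, labels = stats::setNames(labels, ids))
  })
}
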