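test_that("genome construction ranks genes per replicon and validates links", {
  genes <- data.frame(
    gene_id = c("g3", "g1", "g2"),
    replicon_id = "chr",
    start = c(900L, 100L, 500L), end = c(1100L, 400L, 800L),
    strand = c("+", "+", "-"),
    protein_id = c("p3", "p1", "p2"), stringsAsFactors = FALSE)
  prot <- c(p1 = "MKLV", p2 = "MKIV", p3 = "MWWL")
  gm <- annotated_genome("gA", genes, prot)
  expect_s3_class(gm, "annotated_genome")
  expect_equal(gm$genes$gene_id, c("g1", "g2", "g3"))
  expect_equal(gm$genes$rank, 1:3)
  expect_true(all(diff(gm$genes$start) > 0))

  # missing protein is an integrity error naming the id
  expect_error(annotated_genome("gA", genes, prot[-2]), "p2")
  # start > end rejected
  bad <- genes; bad$end[1] <- 10L
  expect_error(annotated_genome("gA", bad, prot), "start > end")
})

test_that("empty domain table is valid; unlinked hits warn and drop", {
  genes <- data.frame(gene_id = "g1", replicon_id = "chr", start = 1L,
                      end = 90L, strand = "+", protein_id = "p1",
                      stringsAsFactors = FALSE)
  gm <- annotated_genome("gB", genes, c(p1 = "MKLVMKLV"))
  expect_equal(nrow(gm$domains), 0L)

  dom <- data.frame(protein_id = c("p1", "ghost"),
                    pfam_acc = c("PF03472", "PF00765"),
                    ali_start = c(1L, 1L), ali_end = c(5L, 5L),
                    score = c(10, 10), stringsAsFactors = FALSE)
  expect_warning(
    gm2 <- annotated_genome("gB", genes, c(p1 = "MKLVMKLV"), dom),
    "ghost")
  expect_equal(gm2$domains$protein_id, "p1")

  # coordinates beyond the protein are invariant violations
  dom_bad <- dom[1, ]; dom_bad$ali_end <- 50L
  expect_error(annotated_genome("gB", genes, c(p1 = "MKLVMKLV"), dom_bad),
               "coordinates")
})

test_that("domain tables parse in the TSV and both domtblout orientations", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tpfam_acc\tali_start\tali_end\tscore",
               "p1\tPF03472.12\t8\t170\t201.5"), tsv)
  got <- read_domain_table(tsv)
  expect_equal(got$pfam_acc, "PF03472")  # version stripped
  expect_equal(got$ali_start, 8L)

  # hmmsearch orientation: protein is the target (col 1), Pfam the query
  # accession (col 5); ali_from/ali_to are columns 18/19, score column 14
  hs <- tempfile()
  writeLines(c(
    "# comment line",
    paste("p1 - 240 autoind_bind PF03472.12 155 1e-40 130.2 0.1 1 1",
          "1e-42 1e-41 201.5 0.1 3 150 8 170 5 175 0.95 desc")), hs)
  got2 <- read_domain_table(hs)
  expect_equal(got2, data.frame(protein_id = "p1", pfam_acc = "PF03472",
                                ali_start = 8L, ali_end = 170L,
                                score = 201.5, stringsAsFactors = FALSE))

  # hmmscan orientation: Pfam model is the target (accession col 2)
  hc <- tempfile()
  writeLines(paste("autoind_bind PF03472.12 155 p1 - 240 1e-40 130.2 0.1 1",
                   "1 1e-42 1e-41 201.5 0.1 3 150 8 170 5 175 0.95 desc"),
             hc)
  expect_equal(read_domain_table(hc), got2)

  # empty table
  empty <- tempfile(); writeLines("# nothing", empty)
  expect_equal(nrow(read_domain_table(empty)), 0L)
})

test_that("a written genome reads back identically", {
  set.seed(42)
  corpus <- generate_corpus(corpus_config(n_genomes = 2), seed = 5,
                            dir = tempfile("corpus"))
  for (gm in corpus$genomes) {
    base <- file.path(corpus$dir, gm$genome_id)
    back <- read_genome(paste0(base, ".gff3"), paste0(base, ".faa"),
                        paste0(base, ".domains.tsv"))
    expect_equal(back$genome_id, gm$genome_id)
    expect_equal(back$taxon_label, gm$taxon_label)
    expect_equal(back$environment_label, gm$environment_label)
    expect_equal(back$genes, gm$genes)
    expect_equal(back$proteome[sort(names(back$proteome))],
                 gm$proteome[sort(names(gm$proteome))])
    dsort <- function(d) {
      d <- d[order(d$protein_id, d$pfam_acc, d$ali_start), ]
      rownames(d) <- NULL
      d
    }
    expect_equal(dsort(back$domains), dsort(gm$domains))
  }
})

test_that("write_outputs emits the complete, deterministic file set", {
  out1 <- tempfile("o1"); out2 <- tempfile("o2")
  empty <- list(summary = list(n_genomes = 0L))
  m1 <- write_outputs(empty, out1)
  expect_setequal(m1$file,
                  c("solos.tsv", "clusters.tsv", "context_profiles.tsv",
                    "subgroups.tsv", "ligand_classes.tsv",
                    "tree_annotations.tsv", "tree.nwk", "summary.json"))
  solos <- read.table(file.path(out1, "solos.tsv"), header = TRUE,
                      sep = "\t")
  expect_equal(nrow(solos), 0L)
  expect_named(solos, c("genome_id", "replicon_id", "protein_id",
                        "is_solo", "blocking_luxI", "window_genes",
                        "luxr_length_ok"))

  one <- list(solos = data.frame(
    genome_id = "g1", replicon_id = "chr", protein_id = "p1",
    is_solo = TRUE, blocking_luxI = NA, window_genes = "PF00005",
    luxr_length_ok = TRUE), summary = list(n_genomes = 1L))
  m2 <- write_outputs(one, out1)
  expect_equal(nrow(read.table(file.path(out1, "solos.tsv"),
                               header = TRUE, sep = "\t")), 1L)
  m3 <- write_outputs(one, out2)
  expect_equal(m2$md5, m3$md5)  # identical inputs -> identical bytes
})
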