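make_genome <- function(pfams, replicon = "chr", genome_id = "gx",
                        lens = NULL) {
  # pfams: character vector per gene (NA = no domain), one gene per entry
  n <- length(pfams)
  if (is.null(lens)) lens <- rep(240L, n)
  starts <- cumsum(rep(1000L, n)) - 999L
  pid <- sprintf("p%02d", seq_len(n))
  genes <- data.frame(gene_id = sprintf("g%02d", seq_len(n)),
                      replicon_id = replicon, start = starts,
                      end = starts + 900L, strand = "+",
                      protein_id = pid, stringsAsFactors = FALSE)
  prot <- stats::setNames(
    vapply(lens, function(l) paste(rep("A", l), collapse = ""),
           character(1)), pid)
  hits <- which(!is.na(pfams))
  dom <- data.frame(protein_id = pid[hits], pfam_acc = pfams[hits],
                    ali_start = 1L, ali_end = 30L, score = 100,
                    stringsAsFactors = FALSE)
  annotated_genome(genome_id, genes, prot, dom)
}

test_that("the neighborhood rule flips on adjacency and window boundary", {
  # LuxI right next door: not a solo
  gm <- make_genome(c(NA, "PF03472", "PF00765"))
  calls <- detect_solos(gm)
  expect_equal(nrow(calls), 1L)
  expect_false(calls$is_solo)
  expect_equal(calls$blocking_luxI, "p03")

  # nearest synthase 5 ranks away: solo (window is 4)
  gm2 <- make_genome(c("PF03472", NA, NA, NA, NA, "PF00765"))
  expect_true(detect_solos(gm2)$is_solo)
  # ... and at exactly 4 ranks: blocked
  gm3 <- make_genome(c("PF03472", NA, NA, NA, "PF00765"))
  expect_false(detect_solos(gm3)$is_solo)

  # replicon edge: window truncates, never wraps
  gm4 <- make_genome(c("PF03472", NA, NA))
  call4 <- detect_solos(gm4)
  expect_true(call4$is_solo)
  expect_equal(nrow(call4$neighborhood[[1]]), 2L)  # downstream only
  expect_equal(call4$neighborhood[[1]]$rel_rank, c(1L, 2L))

  # 230-270 aa length annotation is advisory metadata
  gm5 <- make_genome(c("PF03472", NA), lens = c(150L, 240L))
  call5 <- detect_solos(gm5)
  expect_false(call5$luxr_length_ok)
  expect_true(call5$is_solo)
})

test_that("synthase-regulator fusions are flagged and excluded", {
  gm <- make_genome(c(NA, "PF03472", NA))
  gm$domains <- rbind(gm$domains, data.frame(
    protein_id = "p02", pfam_acc = "PF00765", ali_start = 40L,
    ali_end = 80L, score = 90, stringsAsFactors = FALSE))
  gm <- annotated_genome("gx", gm$genes, gm$proteome, gm$domains)
  calls <- detect_solos(gm)
  expect_true(calls$is_fused)
  expect_true(is.na(calls$is_solo))
})

test_that("detect_solos agrees exactly with the brute-force oracle", {
  set.seed(101)
  for (rep in 1:15) {
    gm <- rand_genome(n_genes = sample(10:50, 1),
                      n_replicons = sample(1:3, 1),
                      genome_id = sprintf("rg%02d", rep))
    for (w in c(2L, 4L, 6L)) {
      calls <- detect_solos(gm, window = w)
      calls <- calls[!calls$is_fused, ]
      got <- stats::setNames(calls$is_solo, calls$protein_id)
      want <- solo_oracle(gm, window = w)
      expect_equal(got[sort(names(got))], want[sort(names(want))])
    }
  }
})

test_that("enlarging the window only flips calls solo -> non-solo", {
  set.seed(202)
  for (rep in 1:8) {
    gm <- rand_genome(n_genes = 40, genome_id = sprintf("rm%02d", rep))
    prev <- NULL
    for (w in 1:8) {
      calls <- detect_solos(gm, window = w)
      calls <- calls[!calls$is_fused, ]
      cur <- stats::setNames(calls$is_solo, calls$protein_id)
      if (!is.null(prev))
        expect_true(all(cur[names(prev)] <= prev))  # no FALSE -> TRUE
      prev <- cur
    }
  }
})

pair_genes <- function(s1, e1, st1, s2, e2, st2, ranks = c(1L, 2L)) {
  list(luxi = list(gene_id = "luxi", replicon_id = "chr", start = s1,
                   end = e1, strand = st1, rank = ranks[[1]]),
       luxr = list(gene_id = "luxr", replicon_id = "chr", start = s2,
                   end = e2, strand = st2, rank = ranks[[2]]))
}

test_that("pair topologies classify by strand, order and rank gap", {
  p <- pair_genes(100L, 700L, "+", 800L, 1500L, "+")
  t1 <- classify_pair_topology(p$luxr, p$luxi)
  expect_equal(t1$arrangement, "tandem")
  expect_equal(t1$intergenic_bp, 99L)
  expect_true(t1$linked)

  p2 <- pair_genes(100L, 700L, "+", 800L, 1500L, "-")
  expect_equal(classify_pair_topology(p2$luxr, p2$luxi)$arrangement,
               "convergent")
  p3 <- pair_genes(100L, 700L, "-", 800L, 1500L, "+")
  expect_equal(classify_pair_topology(p3$luxr, p3$luxi)$arrangement,
               "divergent")

  # one intervening gene: complex, whatever the strands
  p4 <- pair_genes(100L, 700L, "+", 2000L, 2700L, "+", ranks = c(1L, 3L))
  expect_equal(classify_pair_topology(p4$luxr, p4$luxi)$arrangement,
               "complex")

  # 3,500 bp apart: outside the canonical linkage distance
  p5 <- pair_genes(100L, 700L, "+", 4201L, 4900L, "+")
  t5 <- classify_pair_topology(p5$luxr, p5$luxi)
  expect_equal(t5$intergenic_bp, 3500L)
  expect_false(t5$linked)
  # boundary: 2,999 bp is still linked ("less than 3,000")
  p6 <- pair_genes(100L, 700L, "+", 3700L, 4400L, "+")
  expect_true(classify_pair_topology(p6$luxr, p6$luxi)$linked)
  p7 <- pair_genes(100L, 700L, "+", 3701L, 4400L, "+")
  expect_false(classify_pair_topology(p7$luxr, p7$luxi)$linked)

  # overlapping genes have zero intergenic distance
  p8 <- pair_genes(100L, 700L, "+", 650L, 1300L, "+")
  expect_equal(classify_pair_topology(p8$luxr, p8$luxi)$intergenic_bp, 0L)

  # different replicons violate the contract
  bad <- p$luxi; bad$replicon_id <- "plasmid"
  expect_error(classify_pair_topology(p$luxr, bad), "replicon")
})
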