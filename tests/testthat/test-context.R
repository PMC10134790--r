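# Build a minimal solo-call table whose members carry prescribed
# neighborhood Pfams.
fake_solos <- function(member_pfams) {
  ids <- names(member_pfams)
  data.frame(
    genome_id = "g", replicon_id = "chr", gene_id = ids,
    protein_id = ids, rank = seq_along(ids), is_fused = FALSE,
    is_solo = TRUE, blocking_luxI = NA_character_,
    luxr_length_ok = TRUE,
    window_genes = vapply(member_pfams, paste, "", collapse = ";"),
    neighborhood = I(lapply(member_pfams, function(p)
      data.frame(gene_id = paste0("n", seq_along(p)),
                 protein_id = paste0("np", seq_along(p)),
                 rel_rank = seq_along(p), pfams = p,
                 stringsAsFactors = FALSE))),
    stringsAsFactors = FALSE)
}

fake_cluster <- function(ids, cid = 1L) {
  data.frame(cluster_id = cid, representative_id = ids[[1]],
             member_id = ids, identity_to_rep = 1, cov_member = 1,
             cov_rep = 1, stringsAsFactors = FALSE)
}

test_that("profile frequencies respect the 5% floor and >50-member rule", {
  ids <- sprintf("m%02d", 1:60)
  nb <- stats::setNames(rep(list("PF99001"), 60), ids)
  nb[1:3] <- lapply(nb[1:3], c, "PF00005")   # 3/60 = 0.05, kept
  nb[4:5] <- lapply(nb[4:5], c, "PF01234")   # 2/60 = 0.033, dropped
  solos <- fake_solos(nb)
  prof <- build_context_profiles(fake_cluster(ids), solos)
  expect_setequal(prof$pfam_acc, c("PF99001", "PF00005"))
  expect_equal(prof$frequency[prof$pfam_acc == "PF00005"], 0.05)
  expect_equal(prof$frequency[prof$pfam_acc == "PF99001"], 1.0)
  expect_true(all(prof$frequency >= 0.05))

  # exactly 50 members: skipped ("more than 50" is strict)
  ids50 <- ids[1:50]
  expect_message(
    p50 <- build_context_profiles(fake_cluster(ids50), solos),
    "skipping")
  expect_equal(nrow(p50), 0L)
  # 51 members: profiled
  p51 <- build_context_profiles(fake_cluster(ids[1:51]), solos)
  expect_gt(nrow(p51), 0L)

  # the LuxR domain itself is excluded from profiles
  nb2 <- stats::setNames(rep(list(c("PF03472", "PF99001")), 60), ids)
  p_ex <- build_context_profiles(fake_cluster(ids), fake_solos(nb2))
  expect_false("PF03472" %in% p_ex$pfam_acc)

  # members lacking a solo call violate the contract
  expect_error(
    build_context_profiles(fake_cluster(c(ids, "absent")), solos),
    "without a solo call")
})

test_that("pca embedding is deterministic and separates one-hot profiles", {
  prof <- data.frame(
    cluster_id = rep(1:3, each = 1),
    pfam_acc = c("PF00001", "PF00002", "PF00001"),
    frequency = c(1, 1, 1), stringsAsFactors = FALSE)
  # clusters 1 and 3 identical, cluster 2 orthogonal
  emb <- embed_profiles(prof)
  expect_equal(dim(emb), c(3L, 3L))
  expect_equal(emb["1", ], emb["3", ])
  # maximal separation on component 1, zero on the rest
  expect_gt(abs(emb["1", 1] - emb["2", 1]), 1)
  expect_equal(unname(emb[, 2]), rep(0, 3))
  expect_equal(embed_profiles(prof), emb)

  expect_error(embed_profiles(prof[1, ]), "at least 2")
})

test_that("dbscan labels trivial point sets per the density rule", {
  pts <- matrix(0, 12, 3,
                dimnames = list(sprintf("p%02d", 1:12), NULL))
  lab <- dbscan_cluster(pts, eps = 0.5, min_samples = 10)
  expect_equal(unname(lab), rep(0L, 12))

  pts5 <- pts[1:5, ]
  expect_equal(unname(dbscan_cluster(pts5, 0.5, 10)), rep(-1L, 5))

  expect_equal(length(dbscan_cluster(pts[0, , drop = FALSE])), 0L)
})

test_that("dbscan matches the eps-graph connected-components oracle", {
  set.seed(51)
  for (rep in 1:10) {
    n <- sample(c(40, 120, 200), 1)
    # mix of tight blobs and scattered background
    k <- sample(2:4, 1)
    centers <- matrix(runif(3 * k, -5, 5), k, 3)
    pts <- do.call(rbind, c(
      lapply(seq_len(k), function(i)
        sweep(matrix(rnorm(3 * (n %/% (k + 1)), sd = 0.15),
                     ncol = 3), 2, centers[i, ], `+`)),
      list(matrix(runif(3 * (n %/% (k + 1)) * 1, -6, 6), ncol = 3))))
    rownames(pts) <- sprintf("q%03d", seq_len(nrow(pts)))
    for (eps in c(0.3, 0.5, 1.0)) {
      got <- dbscan_cluster(pts, eps = eps, min_samples = 8)
      want <- dbscan_oracle(pts, eps = eps, min_samples = 8)
      expect_same_clustering(got[sort(names(got))],
                             want[sort(names(want))])
    }
  }
})

test_that("dbscan labeling is invariant under input permutation", {
  set.seed(52)
  pts <- rbind(matrix(rnorm(60, sd = 0.1), ncol = 3),
               matrix(rnorm(60, mean = 4, sd = 0.1), ncol = 3))
  rownames(pts) <- sprintf("r%02d", 1:40)
  l1 <- dbscan_cluster(pts, 0.5, 10)
  l2 <- dbscan_cluster(pts[sample(rownames(pts)), ], 0.5, 10)
  expect_equal(l1, l2)
})

test_that("the seeded nonlinear embedding is reproducible", {
  set.seed(53)
  b <- generate_profile_blobs(2, 12, 3, seed = 3)
  e1 <- embed_profiles(b$profiles, method = "umap", seed = 99)
  e2 <- embed_profiles(b$profiles, method = "umap", seed = 99)
  expect_equal(dim(e1), c(27L, 3L))
  expect_equal(e1, e2)
  expect_error(embed_profiles(b$profiles, method = "umap"), "seed")
})
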