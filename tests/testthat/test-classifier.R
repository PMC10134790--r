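ref <- reference_map()

with_subs <- function(seq, ...) {
  subs <- list(...)
  ch <- strsplit(seq, "")[[1]]
  for (pos in names(subs)) ch[[as.integer(pos)]] <- subs[[pos]]
  paste(ch, collapse = "")
}

test_that("the reference map carries 6 ligand-binding + 3 HTH positions", {
  expect_equal(nrow(ref$key_positions), 9L)
  expect_equal(sum(ref$key_positions$domain == "ligand_binding"), 6L)
  expect_equal(sum(ref$key_positions$domain == "hth"), 3L)
  expect_true(all(diff(ref$key_positions$pos) > 0))
  # the six cavity residues read WYDPWG in anchored order
  lb <- ref$key_positions[ref$key_positions$domain == "ligand_binding", ]
  expect_equal(paste(lb$consensus, collapse = ""), "WYDPWG")
  expect_equal(paste(ref$key_positions$consensus, collapse = ""),
               "WYDPWGELG")
})

test_that("the reference scores all nine conserved residues", {
  r <- score_conserved_residues(ref$sequence, ref)
  expect_equal(r$n_conserved, 9L)
  expect_equal(r$key_residues, "WYDPWGELG")
  expect_false(r$pab_signature)
})

test_that("the PAB W57M/Y61W substitution drops exactly two residues", {
  pab <- with_subs(ref$sequence, `57` = "M", `61` = "W")
  r <- score_conserved_residues(pab, ref)
  expect_equal(r$n_conserved, 7L)
  expect_true(r$pab_signature)

  # same property on a diverged family member that keeps the keys
  set.seed(61)
  member <- strsplit(ref$sequence, "")[[1]]
  mut <- setdiff(sample(240, 40), ref$key_positions$pos)
  for (i in mut) member[[i]] <- sample(setdiff(AA, member[[i]]), 1)
  member <- paste(member, collapse = "")
  r0 <- score_conserved_residues(member, ref)
  r1 <- score_conserved_residues(
    with_subs(member, `57` = "M", `61` = "W"), ref)
  expect_equal(r0$n_conserved, 9L)
  expect_equal(r1$n_conserved, 7L)
  expect_true(r1$pab_signature)
})

test_that("anchored numbering survives an upstream deletion", {
  ch <- strsplit(ref$sequence, "")[[1]]
  query <- paste(ch[-10], collapse = "")  # delete residue 10
  m <- anchor_align(query, ref)
  # every key position still maps to its (shifted) consensus residue
  expect_equal(unname(m), ref$key_positions$consensus)
  # and the shift is exactly one: reference 57 aligns to query 56
  al <- pairwise_identity(ref$sequence, query)
  expect_equal(al$identity, 1.0)
})

test_that("degenerate queries are scored without error", {
  polyA <- paste(rep("A", 240), collapse = "")
  r <- score_conserved_residues(polyA, ref)
  expect_lte(r$n_conserved, 1L)
  expect_equal(r$motif_match, "none")
  expect_error(anchor_align("MKLV", ref), "too short")
})

test_that("diagnostic 6-mers are found with canonical priority", {
  base <- ref$sequence
  plu <- paste0(substr(base, 1, 120), "TYDQCS", substr(base, 127, 240))
  expect_equal(score_conserved_residues(plu, ref)$motif_match, "pluR")
  pau <- paste0(substr(base, 1, 120), "TYDQYI", substr(base, 127, 240))
  expect_equal(score_conserved_residues(pau, ref)$motif_match, "pauR")
  both <- paste0(substr(plu, 1, 200), "WYDPWG", substr(plu, 207, 240))
  expect_equal(score_conserved_residues(both, ref)$motif_match,
               "canonical")
})

solo_call_with <- function(pfams) {
  list(protein_id = "p1", is_solo = TRUE,
       neighborhood = data.frame(
         gene_id = paste0("n", seq_along(pfams)),
         protein_id = paste0("np", seq_along(pfams)),
         rel_rank = seq_along(pfams), pfams = pfams,
         stringsAsFactors = FALSE))
}

test_that("class hints compose residue, motif and neighborhood evidence", {
  r_ref <- score_conserved_residues(ref$sequence, ref)
  r_pab <- score_conserved_residues(
    with_subs(ref$sequence, `57` = "M", `61` = "W"), ref)
  r_plu <- score_conserved_residues(
    paste0(substr(ref$sequence, 1, 120), "TYDQCS",
           substr(ref$sequence, 127, 240)), ref)

  # pip neighbor + PAB hallmark -> PAB_type
  out <- classify_solo(r_pab, solo_call_with(c("PF00561", "PF10000")), ref)
  expect_equal(out$neighborhood_class, "pip_adjacent_PAB")
  expect_equal(out$predicted_class_hint, "PAB_type")
  # PAB hallmark alone is enough
  expect_equal(classify_solo(r_pab, solo_call_with("PF10000"),
                             ref)$predicted_class_hint, "PAB_type")

  # all nine residues, no competing evidence -> AHL_type
  out2 <- classify_solo(r_ref, solo_call_with("PF10000"), ref)
  expect_equal(out2$predicted_class_hint, "AHL_type")
  expect_equal(out2$neighborhood_class, "other")

  # pyrone motif outranks a pip neighbor
  out3 <- classify_solo(r_plu, solo_call_with("PF00561"), ref)
  expect_equal(out3$predicted_class_hint, "pyrone_DAR_type")

  # the full SdiA-like enteric context
  out4 <- classify_solo(r_ref, solo_call_with(c("PF00005", "PF00072")),
                        ref)
  expect_equal(out4$neighborhood_class, "sdiA_like")

  # classification is a pure function of its inputs
  expect_identical(out, classify_solo(r_pab,
                                      solo_call_with(c("PF00561",
                                                       "PF10000")), ref))

  # non-solo input violates the contract
  bad <- solo_call_with("PF10000"); bad$is_solo <- FALSE
  expect_error(classify_solo(r_ref, bad, ref), "solo")
})
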