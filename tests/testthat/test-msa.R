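test_that("column frequencies count the 21-symbol alphabet", {
  aln <- ref_alignment(c("r", "a", "b", "c"),
                       c("AAKV", "AAKV", "AGKV", "A-KV"), "r")
  f <- column_frequencies(aln, "1")
  expect_equal(f$freq[f$symbol == "A"], 1)
  expect_equal(sum(f$freq), 1, tolerance = 1e-12)
  f2 <- column_frequencies(aln, "2")
  expect_equal(f2$freq[f2$symbol == "A"], 0.5)
  expect_equal(f2$freq[f2$symbol == "G"], 0.25)
  expect_equal(f2$freq[f2$symbol == "-"], 0.25)
  # ambiguity codes count as gap, with a warning
  aln2 <- ref_alignment(c("r", "a"), c("AX", "AB"), "r")
  expect_warning(f3 <- column_frequencies(aln2, "2"), "non-canonical")
  expect_equal(f3$freq[f3$symbol == "-"], 1)
  # unmapped positions error
  expect_error(column_frequencies(aln, "99"), "not in column map")
})

test_that("sequence entropy has its closed-form values", {
  expect_equal(sequence_entropy(c(1, rep(0, 20))), 0)
  expect_equal(sequence_entropy(rep(1 / 21, 21)), log(21))
  expect_equal(round(sequence_entropy(rep(1 / 21, 21)), 2), 3.04)
  expect_equal(sequence_entropy(c(0.5, 0.5)), log(2))
  # permutation invariance and zero-padding invariance
  f <- c(0.5, 0.3, 0.2)
  expect_equal(sequence_entropy(f), sequence_entropy(rev(f)))
  expect_equal(sequence_entropy(f), sequence_entropy(c(f, 0, 0, 0)))
  # bounded by log(21) for any 21-symbol distribution
  set.seed(11)
  for (i in 1:20) {
    p <- rgamma(21, 0.5)
    p <- p / sum(p)
    h <- sequence_entropy(p)
    expect_gte(h, 0)
    expect_lte(h, log(21) + 1e-12)
  }
})

test_that("motif subsetting keeps exactly the matching sequences", {
  aln <- ref_alignment(
    c("r", "a", "b", "c"),
    c("LYP", "LYP", "LFP", "LY-"), "r", reference_offset = 45L
  )
  sub <- subset_by_motif(aln, c("46" = "Y"))
  expect_setequal(sub$sequences$id, c("r", "a", "c"))
  # gap at a motif position is a mismatch
  sub2 <- subset_by_motif(aln, c("46" = "Y", "47" = "P"))
  expect_setequal(sub2$sequences$id, c("r", "a"))
  # matching is case-insensitive
  sub3 <- subset_by_motif(aln, c("46" = "y"))
  expect_equal(nrow(sub3$sequences), 3)
  # all sequences match: identical membership
  expect_equal(nrow(subset_by_motif(aln, c("45" = "L"))$sequences), 4)
  # no sequences match: empty with a warning, column map preserved
  expect_warning(sub4 <- subset_by_motif(aln, c("45" = "W")), "No sequences")
  expect_equal(nrow(sub4$sequences), 0)
  expect_equal(sub4$column_map, aln$column_map)
})

test_that("motif-constrained columns have zero entropy in the subset", {
  sim <- simulate_msa(sim_msa_config(seed = 21, n_sequences = 150))
  sub <- subset_by_motif(sim$alignment, ypal_motif())
  ent <- entropy_table(sub, names(ypal_motif()))
  expect_equal(ent$entropy, rep(0, 4))
})

test_that("restricting an alignment never adds symbols to a column", {
  sim <- simulate_msa(sim_msa_config(seed = 33, n_sequences = 120))
  sub <- subset_by_motif(sim$alignment, ypal_motif())
  for (pos in sim$alignment$column_map$position) {
    full_syms <- unique(column_frequencies(sim$alignment, pos)$symbol[
      column_frequencies(sim$alignment, pos)$freq > 0])
    sub_syms <- unique(column_frequencies(sub, pos)$symbol[
      column_frequencies(sub, pos)$freq > 0])
    expect_true(all(sub_syms %in% full_syms))
  }
})

test_that("nested sequence sets have non-increasing median entropy", {
  sim <- simulate_msa(sim_msa_config(seed = 13))
  aln <- sim$alignment
  motif_sub <- subset_by_motif(aln, ypal_motif())
  fam_sub <- aln
  fam_sub$sequences <- aln$sequences[
    aln$sequences$id %in% sim$truth$id[sim$truth$in_subfamily], ,
    drop = FALSE]
  h_all <- entropy_table(aln)$entropy
  h_motif <- entropy_table(motif_sub)$entropy
  h_sub <- entropy_table(fam_sub)$entropy
  expect_lte(median(h_motif), median(h_all))
  expect_lte(median(h_sub), median(h_motif))
})

test_that("tier separation applies the published entropy cuts", {
  tiers <- linker_entropies() |>
    dplyr::transmute(position = position, mutated = mutated,
                     entropy = ypal_seqs) |>
    tier_separation()
  toggles <- tiers$position[tiers$tier == "toggle_candidate"]
  expect_setequal(toggles, c("47", "49", "53", "56"))
  expect_true(all(
    tiers$tier[tiers$mutated] == "rheostat_candidate"
  ))
  # a value exactly at the rheostat cut qualifies (>= semantics)
  expect_equal(
    tier_separation(tibble::tibble(position = "50", entropy = 0.6))$tier,
    "rheostat_candidate"
  )
  # a value exactly at the toggle cut is intermediate (< semantics)
  expect_equal(
    tier_separation(tibble::tibble(position = "p", entropy = 0.1))$tier,
    "intermediate"
  )
  # all-zero entropies are all toggle candidates
  z <- tier_separation(tibble::tibble(position = c("1", "2"),
                                      entropy = c(0, 0)))
  expect_true(all(z$tier == "toggle_candidate"))
})
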