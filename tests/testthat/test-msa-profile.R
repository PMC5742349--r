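test_that("identical sequences align gap-free and ungapping is exact", {
  rec <- protein_records(paste0("S", 1:4), rep("MKVLWAALKQ", 4))
  m <- align_msa(rec)
  expect_false(any(grepl("-", m$rows, fixed = TRUE)))
  expect_true(all(m$rows == "MKVLWAALKQ"))

  # mutated + truncated set: ungapping each row reproduces its input
  fam <- generate_families(
    evolution_scenario(1, 8, 7, substitution_rate = 0.2,
                       fragment_rate = 0.25, seed = 61))
  m2 <- align_msa(fam$records)
  for (i in seq_len(nrow(fam$records))) {
    expect_equal(gsub("-", "", m2$rows[m2$accessions ==
                                         fam$records$accession[i]]),
                 fam$records$sequence[i])
  }
  expect_warning(align_msa(fam$records[1, ]), "single")
})

test_that("pairwise alignment score equals the exhaustive global DP oracle", {
  set.seed(19)
  for (rep in 1:20) {
    a <- random_aa_seq(sample(4:12, 1))
    b <- random_aa_seq(sample(4:12, 1))
    expect_equal(global_alignment_score(a, b), oracle_global_score(a, b),
                 info = paste(a, b))
  }
})

test_that("a zero-noise family aligns into identical gap-free rows", {
  fam <- generate_families(
    evolution_scenario(1, 6, 7, substitution_rate = 0, seed = 71))
  m <- align_msa(fam$records)
  expect_length(unique(m$rows), 1L)
  expect_false(any(grepl("-", m$rows, fixed = TRUE)))
})

test_that("conservation anchors the best column at exactly 100", {
  # column 3 invariant W, other columns scrambled
  set.seed(5)
  rows <- vapply(1:12, function(i) {
    chars <- sample(AA_ALPHABET, 7, replace = TRUE)
    chars[3] <- "W"
    paste(chars, collapse = "")
  }, character(1))
  m <- msa_object(paste0("S", 1:12), rows)
  cons <- conservation_profile(m)
  expect_equal(max(cons$relative_score), 100)
  expect_equal(cons$relative_score[3], 100)
})

test_that("gap handling: all-gap columns score 0 and gap-majority columns cannot claim the anchor", {
  m <- msa_object(paste0("S", 1:4),
                  c("AW-A", "AW-A", "-W-C", "-W-D"))
  cons <- conservation_profile(m)
  expect_equal(cons$raw_score[3], 0)   # all-gap column
  expect_equal(cons$gap_fraction[3], 1)
  # a high-scoring column with > 50% gaps is still scored but must not set
  # the normalising maximum: here column 2 (3 x W, 5 gaps) outscores the
  # eligible column 1 in raw terms, yet column 1 anchors the 100
  m2 <- msa_object(paste0("S", 1:8),
                   c("KW", "DW", "SW", "G-", "--", "--", "--", "--"))
  cons2 <- conservation_profile(m2)
  expect_gt(cons2$raw_score[2], cons2$raw_score[1])
  expect_equal(cons2$relative_score[1], 100)
  expect_gt(cons2$relative_score[2], 100)
  expect_equal(max(cons2$relative_score[cons2$gap_fraction <= 0.5]), 100)
})

test_that("conservation is invariant under row permutation", {
  fam <- generate_families(
    evolution_scenario(1, 10, 3, substitution_rate = 0.3, seed = 81))
  m <- align_msa(fam$records)
  cons <- conservation_profile(m)
  perm <- sample(seq_along(m$rows))
  m2 <- msa_object(m$accessions[perm], m$rows[perm])
  cons2 <- conservation_profile(m2)
  expect_equal(cons$raw_score, cons2$raw_score)
  expect_equal(cons$relative_score, cons2$relative_score)
})

test_that("logo information content follows the entropy definition", {
  # uniform over all 20 residues: 0 bits
  m_unif <- msa_object(paste0("S", 1:20),
                       vapply(AA_ALPHABET, function(a) a, character(1)))
  lm <- logo_matrix(m_unif)
  expect_equal(lm$information_bits[1], 0)
  # single residue: log2(20) bits
  m_one <- msa_object(paste0("S", 1:5), rep("W", 5))
  expect_equal(logo_matrix(m_one)$information_bits[1], log2(20))
  # 50/50 two residues: log2(20) - 1
  m_half <- msa_object(paste0("S", 1:4), c("W", "W", "Y", "Y"))
  expect_equal(logo_matrix(m_half)$information_bits[1], log2(20) - 1)
  # heights are frequency * information
  expect_equal(unname(logo_matrix(m_half)$heights["W", 1]),
               0.5 * (log2(20) - 1))
  # bounds on generated data
  fam <- generate_families(
    evolution_scenario(1, 10, 3, substitution_rate = 0.3, seed = 91))
  bits <- logo_matrix(align_msa(fam$records))$information_bits
  expect_true(all(bits >= -1e-12 & bits <= log2(20) + 1e-12))
})

test_that("reference coordinate maps are strictly increasing and invertible", {
  m <- msa_object(c("REF", "OTH"), c("A-C", "AGC"))
  rmap <- map_reference(m, "REF")
  expect_equal(rmap$column_to_residue, c(`1` = 1L, `3` = 2L))
  expect_equal(rmap$residue_to_column, c(`1` = 1L, `2` = 3L))
  # gap-free reference: identity map
  m2 <- msa_object(c("REF", "OTH"), c("AGC", "AGC"))
  rmap2 <- map_reference(m2, "REF")
  expect_equal(unname(rmap2$column_to_residue), 1:3)
  # round trip over the mapped set
  for (col in names(rmap$column_to_residue)) {
    expect_equal(unname(rmap$residue_to_column[
      as.character(rmap$column_to_residue[col])]), as.integer(col))
  }
  expect_error(map_reference(m, "MISSING"), "absent")
})

test_that("aligned FASTA round-trips through disk", {
  fam <- generate_families(
    evolution_scenario(1, 4, 3, substitution_rate = 0.2, seed = 101))
  m <- align_msa(fam$records)
  f <- tempfile(fileext = ".fasta")
  write_msa_fasta(m, f)
  m2 <- read_msa_fasta(f)
  expect_equal(m2$rows, m$rows)
  expect_equal(m2$accessions, m$accessions)
})
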