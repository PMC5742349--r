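test_that("TMH-count bins classify into the four family classes", {
  expect_equal(classify_architecture(3), "semiSWEET")
  expect_equal(classify_architecture(4), "semiSWEET")
  expect_equal(classify_architecture(6), "SWEET")
  expect_equal(classify_architecture(7), "SWEET")
  expect_equal(classify_architecture(14), "extraSWEET")
  expect_equal(classify_architecture(15), "extraSWEET")
  expect_equal(classify_architecture(18), "superSWEET")
  expect_equal(classify_architecture(25), "superSWEET")
  expect_equal(classify_architecture(5), "atypical")
  expect_equal(classify_architecture(0), "atypical")
  bad <- default_arch_bins(); bad$SWEET <- c(4L, 6L, 7L)
  expect_error(classify_architecture(7, bad), "overlapping")
})

# helper: a fabricated topology with n equally spaced helices
fake_topology <- function(n, helix_len = 15L, loop_len = 12L) {
  starts <- loop_len + 1L + (seq_len(n) - 1L) * (helix_len + loop_len)
  structure(list(helices = cbind(start = starts, end = starts + helix_len - 1L),
                 count = n), class = "tmh_topology")
}

test_that("canonical unit plans decompose 3/4/7/15-TMH topologies", {
  seq7 <- strrep("A", 12 + 7 * 27)
  u7 <- decompose_units(fake_topology(7), seq7)
  expect_equal(u7$unit_type, c("triplet", "linker", "triplet"))
  expect_equal(u7$tmh_first, c(1L, 4L, 5L))
  expect_equal(u7$tmh_last, c(3L, 4L, 7L))

  u3 <- decompose_units(fake_topology(3), strrep("A", 12 + 3 * 27))
  expect_equal(u3$unit_type, "triplet")
  u15 <- decompose_units(fake_topology(15), strrep("A", 12 + 15 * 27))
  expect_equal(sum(u15$unit_type == "triplet"), 4L)
  expect_equal(sum(u15$unit_type == "linker"), 3L)
})

test_that("greedy decomposition covers non-canonical helix counts", {
  u25 <- decompose_units(fake_topology(25), strrep("A", 12 + 25 * 27))
  expect_equal(sum(u25$unit_type == "triplet"), 7L)
  expect_equal(sum(u25$unit_type == "linker"), 4L)
  # helix ordinals partition 1..25
  covered <- unlist(mapply(seq, u25$tmh_first, u25$tmh_last))
  expect_equal(sort(covered), 1:25)
  # spans partition the sequence without overlap
  expect_equal(u25$start[1], 1L)
  expect_equal(u25$end[nrow(u25)], 12L + 25L * 27L)
  expect_true(all(u25$start[-1] == head(u25$end, -1) + 1L))

  u23 <- decompose_units(fake_topology(23), strrep("A", 12 + 23 * 27))
  expect_equal(sum(u23$unit_type == "unresolved"), 1L)
  covered23 <- unlist(mapply(seq, u23$tmh_first, u23$tmh_last))
  expect_equal(sort(covered23), 1:23)
  expect_error(decompose_units(fake_topology(0), "A"), "0 helices")
})

test_that("zero-noise architecture calls match truth exactly for all plans", {
  fam <- generate_families(
    evolution_scenario(4, 2, c(3, 7, 15, 25), substitution_rate = 0,
                       seed = 13))
  for (f in 1:4) {
    ft <- fam$truth$families[[f]]
    rec <- fam$records[fam$truth$sequences$family == f, ][1, ]
    call <- architecture_call(rec$sequence)
    expect_equal(call$tmh_count, ft$tmh_count)
    expect_equal(call$arch_class, ft$arch_class)
    expect_equal(call$units$start, ft$units$start)
    expect_equal(call$units$end, ft$units$end)
    expect_equal(call$units$unit_type, ft$units$unit_type)
  }
})

test_that("repeat units of a duplicated template align to it at high identity", {
  set.seed(77)
  tpl <- random_unit_templates(1, seed = 55)
  # a 7-TMH protein built from two copies of the same unit
  fam <- generate_families(
    evolution_scenario(1, 1, 7, substitution_rate = 0.05, n_invariant = 0,
                       n_covarying = 0, seed = 55), tpl)
  s <- fam$records$sequence[1]
  call <- architecture_call(s)
  refs <- protein_records("U1", tpl[[1]]$sequence)
  fe <- detect_fusion(call$units, s, refs)
  expect_equal(nrow(fe), 2L)  # both triplet units scored
  expect_true(all(fe$best_reference_accession == "U1"))
  expect_true(all(fe$percent_identity >= 90))
  expect_true(all(fe$fusion_evidence))
})

test_that("degenerate and unrelated units are not flagged as fusions", {
  units <- data.frame(unit_type = "triplet", tmh_first = 1, tmh_last = 3,
                      start = 1, end = 60)
  refs <- protein_records("R1", strrep("IVLIVVIL", 10))
  # poly-K unit: all substitution scores negative, identity reported as 0
  fe <- detect_fusion(units, strrep("K", 60), refs)
  expect_equal(fe$percent_identity, 0)
  expect_false(fe$fusion_evidence)
  # two unrelated random units stay far below the 70% threshold
  set.seed(9)
  fe2 <- detect_fusion(units, random_aa_seq(60), refs)
  expect_lt(fe2$percent_identity, 70)
  expect_error(detect_fusion(units, "AAAA", refs[0, ]), "reference")
})
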