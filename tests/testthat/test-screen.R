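test_that("dedupe keeps the lexicographically smallest accession and is idempotent", {
  rec <- protein_records(c("B", "A"), c("MKV", "MKV"))
  dd <- dedupe_records(rec)
  expect_equal(dd$kept$accession, "A")
  expect_equal(dd$removed$removed, "B")
  expect_equal(dd$removed$representative, "A")

  rec3 <- protein_records(c("X", "Y", "Z"), c("MKV", "MKW", "MKY"))
  dd3 <- dedupe_records(rec3)
  expect_equal(nrow(dd3$removed), 0L)
  expect_equal(dd3$kept$accession, c("X", "Y", "Z"))

  # idempotence
  dd2 <- dedupe_records(dd$kept)
  expect_equal(nrow(dd2$removed), 0L)

  expect_error(dedupe_records(protein_records("A", "MK")[c(1, 1), ]),
               "duplicate accession")
})

test_that("hydropathy helix calls match the brute-force window-mean oracle", {
  # all-hydrophilic: no helix
  polyk <- strrep("K", 60)
  expect_equal(predict_tmh(polyk)$count, 0L)

  # single hydrophobic block flanked by lysines
  s <- paste0(strrep("K", 20), strrep("L", 23), strrep("K", 20))
  topo <- predict_tmh(s, window = 19, threshold = 1.6,
                      min_helix_len = 15, merge_gap = 3)
  expect_equal(topo$count, 1L)
  # the helix overlaps the L block (positions 21..43)
  expect_lte(topo$helices[1, "start"], 43)
  expect_gte(topo$helices[1, "end"], 21)
  cand <- oracle_tmh_candidates(s, 19, 1.6)
  expect_equal(unname(topo$helices[1, "start"]), min(which(cand)))
  expect_equal(unname(topo$helices[1, "end"]), max(which(cand)))

  # random sequences: candidate positions equal the oracle's
  set.seed(11)
  for (rep in 1:10) {
    r <- random_aa_seq(sample(60:200, 1))
    cand <- oracle_tmh_candidates(r, 19, 1.6)
    runs <- rle(cand)
    ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
    seg <- cbind(starts[runs$values], ends[runs$values])
    # merge < 3 apart, keep >= 15 long (the documented rules)
    if (nrow(seg) > 1) {
      keep <- seg[1, , drop = FALSE]
      for (i in 2:nrow(seg)) {
        if (seg[i, 1] - keep[nrow(keep), 2] - 1 < 3) {
          keep[nrow(keep), 2] <- seg[i, 2]
        } else keep <- rbind(keep, seg[i, , drop = FALSE])
      }
      seg <- keep
    }
    seg <- seg[seg[, 2] - seg[, 1] + 1 >= 15, , drop = FALSE]
    topo <- predict_tmh(r)
    expect_equal(unname(topo$helices[, "start"]), unname(seg[, 1]))
    expect_equal(unname(topo$helices[, "end"]), unname(seg[, 2]))
  }
})

test_that("a zero-noise 7-TMH synthetic protein yields exactly 7 helices", {
  fam <- generate_families(
    evolution_scenario(1, 1, 7, substitution_rate = 0, seed = 2),
    random_unit_templates(2, seed = 2))
  expect_equal(predict_tmh(fam$records$sequence[1])$count, 7L)
})

test_that("PQ motif modes behave as defined near the first helix", {
  fam <- generate_families(
    evolution_scenario(1, 1, 7, substitution_rate = 0, seed = 4),
    random_unit_templates(2, seed = 4))
  s <- fam$records$sequence[1]
  topo <- predict_tmh(s)
  pq_true <- fam$truth$families[[1]]$pq_positions[1]
  expect_equal(find_pq_motif(s, topo, "strict_PQ"), pq_true)
  # direct scan confirms P,Q at the reported position
  expect_equal(substr(s, pq_true, pq_true + 1), "PQ")

  # mutate the Q: strict misses, relaxed still finds the P
  s2 <- s
  substr(s2, pq_true + 1, pq_true + 1) <- "A"
  topo2 <- predict_tmh(s2)
  expect_true(is.na(find_pq_motif(s2, topo2, "strict_PQ")))
  expect_equal(find_pq_motif(s2, topo2, "relaxed_P"), pq_true)

  # no proline anywhere: absent
  s3 <- gsub("P", "N", s)
  expect_true(is.na(find_pq_motif(s3, predict_tmh(s3), "strict_PQ")))
})

test_that("screening filters apply in fixed order with one reason per record", {
  fam <- generate_families(
    evolution_scenario(2, 10, 7, substitution_rate = 0.1,
                       fragment_rate = 0.15, duplicate_rate = 0.1, seed = 8))
  scr <- screen_records(fam$records)
  truth <- fam$truth$sequences
  # duplicates and fragments removed for the right reasons
  expect_setequal(scr$report$accession[scr$report$removal_reason == "fragment"],
                  truth$accession[truth$is_fragment &
                                    !nzchar(truth$duplicate_of)])
  dup_acc <- truth$accession[nzchar(truth$duplicate_of)]
  dup_removed <- scr$report$accession[scr$report$removal_reason == "duplicate"]
  # every removed-duplicate is one member of an identical pair
  expect_equal(length(dup_removed), length(dup_acc))
  # survivors are exactly the non-fragment, non-duplicate records
  expect_setequal(scr$passed$accession,
                  setdiff(truth$accession[!truth$is_fragment], dup_removed))
  # passed <=> reason none
  expect_equal(scr$report$passed, scr$report$removal_reason == "none")
  # deterministic
  scr2 <- screen_records(fam$records)
  expect_identical(scr$report, scr2$report)
})

test_that("records with too few helices are removed as too_few_tmh", {
  fam <- generate_families(
    evolution_scenario(1, 3, 3, substitution_rate = 0.05, seed = 6))
  rec <- fam$records
  scr <- screen_records(rec, min_tmh = 4L)
  expect_true(all(scr$report$removal_reason == "too_few_tmh"))
  expect_true(all(scr$report$tmh_count == 3L))
  scr_ok <- screen_records(rec, min_tmh = 3L)
  expect_true(all(scr_ok$report$passed))
  expect_error(screen_records(rec[0, ]), "empty")
})
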