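test_that("column MI matches closed forms and the counting oracle", {
  # constant column vs anything: MI = 0
  m <- msa_object(paste0("S", 1:6), c("AW", "AY", "AW", "AY", "AW", "AY"))
  mi <- column_mi(m, min_effective_rows = 2)
  expect_equal(mi$mi_nats[mi$col_a == 1 & mi$col_b == 2], 0)

  # perfectly covarying binary columns at 50/50: MI = ln 2
  m2 <- msa_object(paste0("S", 1:8),
                   rep(c("WD", "YE"), 4))
  mi2 <- column_mi(m2, min_effective_rows = 2)
  expect_equal(mi2$mi_nats, log(2))

  # small random MSAs vs the brute-force contingency oracle
  set.seed(23)
  for (rep in 1:20) {
    rows <- vapply(1:6, function(i) random_aa_seq(4), character(1))
    mm <- msa_object(paste0("S", 1:6), rows)
    mi_all <- column_mi(mm, min_effective_rows = 2)
    mat <- do.call(rbind, strsplit(rows, ""))
    for (k in seq_len(nrow(mi_all))) {
      expect_equal(mi_all$mi_nats[k],
                   oracle_mi(mat[, mi_all$col_a[k]], mat[, mi_all$col_b[k]]),
                   tolerance = 1e-9)
    }
  }
})

test_that("MI is symmetric, non-negative and row-duplication invariant", {
  set.seed(29)
  rows <- vapply(1:10, function(i) random_aa_seq(6), character(1))
  m <- msa_object(paste0("S", 1:10), rows)
  mi <- column_mi(m)
  expect_true(all(mi$mi_nats >= -1e-12))
  expect_true(all(mi$col_a < mi$col_b))
  # duplicating every row leaves unweighted MI unchanged
  m2 <- msa_object(paste0("S", 1:20), c(rows, rows))
  mi2 <- column_mi(m2)
  expect_equal(mi$mi_nats, mi2$mi_nats, tolerance = 1e-12)
})

test_that("gapped rows are excluded pairwise and sparse columns are skipped", {
  rows <- c("AW", "AY", "A-", "-W", "AW", "AY")
  m <- msa_object(paste0("S", 1:6), rows)
  mi <- column_mi(m, min_effective_rows = 4)
  # pairwise-complete rows are 1,2,5,6: constant col1 -> MI 0
  expect_equal(mi$mi_nats, 0)
  # a column with too few ungapped rows is skipped with a message
  m2 <- msa_object(paste0("S", 1:6), c("AW", "AY", "--", "--", "--", "--"))
  expect_message(out <- column_mi(m2, min_effective_rows = 5), "skipping")
  expect_equal(nrow(out), 0L)
})

test_that("shuffle z-scores are seeded and separate signal from noise", {
  set.seed(31)
  tails <- replicate(12, random_aa_seq(2))
  m <- msa_object(paste0("S", 1:12), paste0(rep(c("WD", "YE"), 6), tails))
  pairs <- column_mi(m, min_effective_rows = 2)
  z1 <- mi_zscores(pairs, m, n_shuffles = 50, seed = 42)
  z2 <- mi_zscores(pairs, m, n_shuffles = 50, seed = 42)
  expect_identical(z1$mi_z, z2$mi_z)
  z3 <- mi_zscores(pairs, m, n_shuffles = 50, seed = 43)
  expect_false(identical(z1$mi_z, z3$mi_z))
  # the perfectly covarying pair dominates
  expect_gt(z1$mi_z[z1$col_a == 1 & z1$col_b == 2], 6.5)
  expect_error(mi_zscores(pairs, m, n_shuffles = 5), "at least 20")
})

test_that("independent columns rarely exceed the significance threshold", {
  # 200 random column pairs x 3 seeds: >= 99% below z = 6.5
  total <- 0; below <- 0
  for (seed in 1:3) {
    set.seed(seed * 1000)
    rows <- vapply(1:40, function(i) random_aa_seq(21), character(1))
    m <- msa_object(paste0("S", 1:40), rows)
    pairs <- column_mi(m)
    pairs <- pairs[seq_len(200), ]
    z <- mi_zscores(pairs, m, n_shuffles = 50, seed = seed)
    total <- total + nrow(z)
    below <- below + sum(z$mi_z <= 6.5)
  }
  expect_gte(below / total, 0.99)
})

test_that("edge classes split by the 5/25/70 percentile rule", {
  mk <- function(n) data.frame(col_a = seq_len(n), col_b = seq_len(n) + n,
                               mi_nats = seq(n, 1))
  c100 <- classify_mi_edges(mk(100))
  expect_equal(as.integer(table(c100$edge_class)[c("red", "black", "gray")]),
               c(5L, 25L, 70L))
  # the top 5 MI values are the red ones
  expect_true(all(c100$edge_class[order(-c100$mi_nats)][1:5] == "red"))
  c1 <- classify_mi_edges(mk(1))
  expect_equal(c1$edge_class, "red")
  c20 <- classify_mi_edges(mk(20))
  expect_equal(as.integer(table(c20$edge_class)[c("red", "black", "gray")]),
               c(1L, 5L, 14L))
  expect_error(classify_mi_edges(data.frame(col_a = integer(0),
                                            col_b = integer(0),
                                            mi_nats = numeric(0))),
               "at least one")
})

test_that("cumulative MI sums significant pair weights per column", {
  expect_equal(cumulative_mi(data.frame(col_a = integer(0),
                                        col_b = integer(0),
                                        mi_nats = numeric(0)), 5),
               rep(0, 5))
  one <- data.frame(col_a = 2, col_b = 4, mi_nats = 1.5)
  expect_equal(cumulative_mi(one, 5), c(0, 1.5, 0, 1.5, 0))
  star <- data.frame(col_a = c(1, 1, 1), col_b = c(2, 3, 4),
                     mi_nats = c(1, 2, 3))
  expect_equal(cumulative_mi(star, 4)[1], 6)
})

test_that("proximity MI averages cMI over spatial neighbours", {
  rmap <- structure(list(reference = "R",
                         column_to_residue = setNames(1:5, 1:5),
                         residue_to_column = setNames(1:5, 1:5)),
                    class = "reference_map")
  # two residues 3 Angstrom apart with cMI 4 and 0
  coords2 <- data.frame(residue = 1:2, x = c(0, 3), y = 0, z = 0)
  rmap2 <- structure(list(reference = "R",
                          column_to_residue = setNames(1:2, 1:2),
                          residue_to_column = setNames(1:2, 1:2)),
                     class = "reference_map")
  p2 <- proximity_mi(c(4, 0), coords2, rmap2, radius_angstrom = 5)
  expect_equal(p2$pmi, c(0, 4))
  # isolated residue: no neighbour, pMI 0
  p_iso <- proximity_mi(c(4, 0), data.frame(residue = 1:2, x = c(0, 50),
                                            y = 0, z = 0), rmap2, 5)
  expect_equal(p_iso$pmi, c(0, 0))
  # 5-residue line at 3 Angstrom spacing, radius 5: neighbours are +-1
  coords5 <- data.frame(residue = 1:5, x = 3 * (0:4), y = 0, z = 0)
  cmi <- c(1, 2, 3, 4, 5)
  p5 <- proximity_mi(cmi, coords5, rmap, radius_angstrom = 5)
  expect_equal(p5$pmi, c(2, (1 + 3) / 2, (2 + 4) / 2, (3 + 5) / 2, 4))
  # residues missing from the coordinate table are skipped with a message
  expect_message(pm <- proximity_mi(cmi, coords5[1:4, ], rmap, 5), "skipping")
  expect_equal(nrow(pm), 4L)
})

test_that("alpha-carbon coordinates parse from a PDB-format file", {
  pdb <- tempfile(fileext = ".pdb")
  writeLines(c(
    sprintf("ATOM  %5d  N   ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           N", 1, 1, 0, 0, 0),
    sprintf("ATOM  %5d  CA  ALA A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C", 2, 1, 1.5, 0, 0),
    sprintf("ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C", 3, 2, 4.5, 0, 0),
    "END"), pdb)
  co <- read_ca_coords(pdb)
  expect_equal(co$residue, 1:2)
  expect_equal(co$x, c(1.5, 4.5))
})

test_that("planted covarying pairs are recovered above the threshold", {
  fam <- generate_families(
    evolution_scenario(1, 50, 7, substitution_rate = 0.3, n_covarying = 2,
                       seed = 45))
  m <- align_msa(fam$records)
  planted <- fam$truth$families[[1]]$covarying_pairs
  net <- mi_network(m, columns = unlist(planted), n_shuffles = 100, seed = 7)
  for (p in planted) {
    row <- net$significant[net$significant$col_a == p[1] &
                             net$significant$col_b == p[2], ]
    expect_equal(nrow(row), 1L)
    expect_gt(row$mi_z, 6.5)
  }
})
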