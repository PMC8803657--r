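# Build a repertoire with exact CDR3 amino-acid sequences by reverse
# coding each residue through a fixed stop-free codon table.
.codon_for <- c(A="GCA", C="TGT", D="GAC", E="GAA", F="TTT", G="GGA",
                H="CAC", I="ATC", K="AAA", L="CTG", M="ATG", N="AAC",
                P="CCA", Q="CAA", R="AGA", S="AGC", T="ACA", V="GTG",
                W="TGG", Y="TAC")

rep_from_aa <- function(aa_seqs, counts = 1L, sample_id = "aa") {
  nt <- vapply(aa_seqs, function(s) {
    paste(.codon_for[strsplit(s, "")[[1]]], collapse = "")
  }, character(1))
  repertoire(data.frame(cdr3_nt = nt, v_gene = "TRBV4", d_gene = "",
                        j_gene = "TRBJ1-1",
                        count = rep_len(counts, length(aa_seqs)),
                        stringsAsFactors = FALSE), sample_id = sample_id)
}

test_that("aa composition matches direct residue counting", {
  rep <- rep_from_aa("CASSF")
  comp <- aa_composition(rep)
  expect_equal(comp[["C"]], 0.2)
  expect_equal(comp[["A"]], 0.2)
  expect_equal(comp[["S"]], 0.4)
  expect_equal(comp[["F"]], 0.2)
  expect_equal(sum(comp), 1, tolerance = 1e-12)
})

test_that("count weighting shifts total but not unique composition", {
  r1 <- rep_from_aa(c("CAAAF", "CYYYF"), counts = c(1L, 1L))
  r2 <- rep_from_aa(c("CAAAF", "CYYYF"), counts = c(2L, 1L))
  expect_equal(aa_composition(r1, "unique"), aa_composition(r2, "unique"))
  expect_gt(aa_composition(r2, "total")[["A"]],
            aa_composition(r1, "total")[["A"]])
})

test_that("Bhattacharyya distance: identity, closed form, disjoint, errors", {
  p <- c(0.5, 0.5, rep(0, 18))
  q <- c(1, rep(0, 19))
  expect_equal(bhattacharyya_distance(p, p), 0)
  expect_equal(bhattacharyya_distance(p, q), -log(sqrt(0.5)),
               tolerance = 1e-12)
  r <- c(0, 1, rep(0, 18))
  expect_equal(bhattacharyya_distance(q, r), Inf)
  expect_equal(bhattacharyya_distance(q, r), bhattacharyya_distance(r, q))
  expect_error(bhattacharyya_distance(c(0.5, 0.6), c(0.5, 0.5)), "sum to 1")
  # symmetry and nonnegativity on random compositions
  set.seed(6)
  for (k in 1:50) {
    a <- as.vector(rmultinom(1, 100, rep(1 / 20, 20))) / 100
    b <- as.vector(rmultinom(1, 100, rep(1 / 20, 20))) / 100
    expect_equal(bhattacharyya_distance(a, b), bhattacharyya_distance(b, a),
                 tolerance = 1e-12)
    expect_gte(bhattacharyya_distance(a, b), 0)
  }
})

test_that("hydrophobic index counts doublets at positions 6-7 of 13-mers", {
  all_lv <- rep_from_aa(c("CASSALVEQYFTF", "CASSQLVEQYFTF"))
  expect_equal(hydrophobic_index(all_lv), 1.0)
  none <- rep_from_aa("CASSQQEEQYFTF")
  expect_equal(hydrophobic_index(none), 0.0)
  mix <- rep_from_aa(c("CASSALVEQYFTF", "CASSQQEEQYFTF", "CASSRQEEQYFTF"),
                     counts = c(2L, 1L, 1L))
  expect_equal(hydrophobic_index(mix), 0.5)
  expect_equal(hydrophobic_index(mix, weighting = "unique"), 1 / 3,
               tolerance = 1e-12)
  # growing the doublet set can only increase the index
  small <- hydrophobic_index(mix, doublet_set = c("LV"))
  big <- hydrophobic_index(mix, doublet_set = c("LV", "QQ", "RQ"))
  expect_gte(big, small)
  expect_error(hydrophobic_index(rep_from_aa("CASSF"), length_class = 13),
               "length 13")
})

test_that("cysteine index anchors at the midpoint and skips position 1", {
  # C at position 5 of a 13-mer: midpoint 7, window 2 covers 5..9
  pos5 <- rep_from_aa("CASSCGGAYEQYF")
  expect_equal(cysteine_index(pos5), 1.0)
  no_c <- rep_from_aa("CASSGGGAYEQYF")
  expect_equal(cysteine_index(no_c), 0.0)
  # the invariant position-1 cysteine never counts
  only_first <- rep_from_aa("CAS")
  expect_equal(cysteine_index(only_first), 0.0)
  mid <- rep_from_aa("CASGCGA")  # 7-mer, C at exact midpoint 4 (not pos 1)
  expect_equal(cysteine_index(mid), 1.0)
  # C outside the window does not count
  pos4 <- rep_from_aa("CASCAGGAYEQYF")  # midpoint 7, window 5..9; C at 4
  expect_equal(cysteine_index(pos4), 0.0)
  expect_equal(cysteine_index(pos4, window = 3L), 1.0)
})

test_that("positional composition sums to 1 and matches construction", {
  rep <- rep_from_aa(c("CASSQSLVEQYTF", "CASSQGLVEQYTF"), counts = c(1L, 1L))
  v6 <- positional_composition(rep, 13L, 6L)
  expect_equal(v6[["S"]], 0.5)
  expect_equal(v6[["G"]], 0.5)
  expect_equal(sum(v6), 1, tolerance = 1e-12)
  uniform <- positional_composition(rep_from_aa("CASSALVEQYFTF"), 13L, 6L)
  expect_equal(uniform[["L"]], 1)
  expect_error(positional_composition(rep, 13L, 14L), "position")
})
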