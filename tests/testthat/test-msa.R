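degap <- function(s) gsub("-", "", s)

test_that("identical sequences align gap-free; de-gapping recovers inputs", {
  rs <- seq_set(c("a", "b"), c("ITCGQVSSAL", "ITCGQVSSAL"))
  msa <- progressive_msa(rs)
  expect_equal(msa$ncol, 10)
  expect_false(any(grepl("-", msa$aln)))
  rs2 <- generate_family(family_spec(n = 5, identity = 0.6, seed = 3))$records
  msa2 <- progressive_msa(rs2)
  expect_equal(unname(vapply(msa2$aln, degap, character(1))), rs2$residues)
})

test_that("a single insertion produces a single gap column at the insertion", {
  a <- "ITCGQVSSAL"
  b <- "ITCGQWVSSAL"   # W inserted after position 5
  msa <- progressive_msa(seq_set(c("a", "b"), c(a, b)))
  expect_equal(msa$ncol, 11)
  expect_equal(sum(strsplit(msa$aln[["a"]], "")[[1]] == "-"), 1)
  expect_equal(msa$aln[["b"]], b)
  # placement agrees with optimal pairwise alignment of the same pair
  pw <- pairwise_align(a, b, "global")
  expect_equal(msa$aln[["a"]], pw$a)
})

test_that("conservation symbols follow the Clustal group tables", {
  msa <- make_msa(c("AIAC-AW", "ALACSAW", "AVGCAAW"))
  sym <- conservation_symbols(msa)
  expect_equal(sym[1], "*")   # identical column
  expect_equal(sym[2], ":")   # I/L/V = strong MILV group
  expect_equal(sym[3], ".")   # A/G = weak SAG group
  expect_equal(sym[4], "*")
  expect_equal(sym[5], " ")   # gap disqualifies
  expect_equal(sym[7], "*")
  expect_equal(conservation_symbols(make_msa(c("A", "W"))), " ")
})

test_that("conservation symbols are invariant under row reordering", {
  fam <- generate_family(family_spec(n = 6, identity = 0.7, seed = 4))$records
  msa <- progressive_msa(fam)
  perm <- c(4, 1, 6, 2, 5, 3)
  msa_perm <- make_msa(unname(msa$aln[perm]), msa$ids[perm])
  expect_equal(conservation_symbols(msa), conservation_symbols(msa_perm))
})

test_that("percent conservation score floors to the printed integer values", {
  # 15 rows; reference row 1.  Column 1: all 15 match; column 2: 14 of 15;
  # column 3: 2 of 15 carry the reference residue.
  rows <- c("ADC", "ADC", rep("ADA", 12), "AAA")
  msa <- make_msa(rows)
  sc <- conservation_score(msa, "s1")
  expect_equal(sc$score, c(15, 14, 2) * 100 / 15, tolerance = 1e-12)
  expect_equal(sc$score_floor, c(100, 93, 13))
  expect_true(all(sc$score %in% (0:15 * 100 / 15)))
  expect_error(conservation_score(msa, "nope"), "reference id")
})

test_that("score 100 coincides with '*' on gap-free columns; gaps never match", {
  msa <- make_msa(c("AC-", "ACD", "ACD"))
  prof <- conservation_profile(msa, "s2")
  expect_equal(prof$symbol[prof$score == 100], c("*", "*"))
  # reference residue D in column 3: the gapped row does not count
  expect_equal(prof$score[3], 2 * 100 / 3)
})

test_that("p-distance matrix ignores gapped columns and is symmetric", {
  msa <- make_msa(c("ACDEFGHIKL", "ACDEFGHIKV", "AC-EFGHIKL"))
  d <- distance_matrix(msa)
  expect_equal(d["s1", "s2"], 0.1)
  expect_equal(d["s1", "s3"], 0)          # 9 comparable columns, all equal
  expect_equal(d, t(d))
  expect_equal(diag(d), setNames(rep(0, 3), rownames(d)))
  expect_error(distance_matrix(make_msa(c("A-", "-A"))), "no comparable")
})

test_that("3-taxon NJ solves the closed-form branch lengths", {
  d <- matrix(c(0, 3, 4,
                3, 0, 5,
                4, 5, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  bl <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(bl[["a"]], (3 + 4 - 5) / 2)
  expect_equal(bl[["b"]], (3 + 5 - 4) / 2)
  expect_equal(bl[["c"]], (4 + 5 - 3) / 2)
  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
})

test_that("NJ reproduces an additive 4-taxon matrix exactly", {
  tr0 <- ape::read.tree(text = "((a:1,b:2):1.5,(c:1,d:2.5):1);")
  d <- ape::cophenetic.phylo(tr0)
  tr <- nj_tree(d)
  expect_equal(ape::cophenetic.phylo(tr)[rownames(d), colnames(d)], d,
               tolerance = 1e-10)
  expect_equal(ape::dist.topo(ape::unroot(tr0), tr), structure(0, Nnode = 2),
               ignore_attr = TRUE)
})

test_that("newick output round-trips through ape", {
  fam <- generate_family(family_spec(n = 5, identity = 0.7, seed = 8))$records
  msa <- progressive_msa(fam)
  tr <- nj_tree(distance_matrix(msa))
  expect_true(all(tr$edge.length >= 0))
  p <- tempfile(fileext = ".nwk")
  write_newick(tr, p)
  back <- ape::read.tree(p)
  expect_setequal(back$tip.label, fam$id)
})
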