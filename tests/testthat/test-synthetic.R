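test_that("identity 1 gives clones and an all-star conservation profile", {
  fam <- generate_family(family_spec(n = 4, identity = 1, seed = 2))
  expect_equal(length(unique(fam$records$residues)), 1)
  expect_equal(nrow(fam$truth$mutations), 0)
  msa <- progressive_msa(fam$records)
  expect_true(all(conservation_symbols(msa) == "*"))
})

test_that("realized pairwise identity tracks the target", {
  fam <- generate_family(family_spec(n = 6, identity = 0.7, length = 93,
                                     seed = 1))
  expect_lt(abs(mean_pairwise_identity(fam$records) - 0.7), 0.05)
})

test_that("realized identity is monotone decreasing in the mutation rate", {
  rates <- c(0.05, 0.15, 0.3, 0.5, 0.7)
  ids <- vapply(rates, function(r) {
    fam <- generate_family(family_spec(n = 8, identity = 0.5, seed = 33,
                                       rate = r))
    mean_pairwise_identity(fam$records)
  }, numeric(1))
  expect_true(all(diff(ids) < 0))
})

test_that("cysteine scaffold sites never mutate and score 100", {
  fam <- generate_family(family_spec(n = 10, identity = 0.5, seed = 6))
  cys <- ltp_cysteine_positions()
  for (s in fam$records$residues)
    expect_equal(unique(substring(s, cys, cys)), "C")
  msa <- progressive_msa(fam$records)
  sc <- conservation_score(msa, "d1")
  expect_equal(sc$score[cys], rep(100, 8))
  expect_true(all(conservation_symbols(msa)[sc$column[cys]] == "*"))
})

test_that("mutation log replays the ancestor into each descendant", {
  fam <- generate_family(family_spec(n = 4, identity = 0.6, seed = 9))
  for (d in 1:4) {
    s <- strsplit(fam$ancestor, "")[[1]]
    log <- fam$truth$mutations[fam$truth$mutations$descendant == d, ]
    expect_equal(s[log$site], log$from)
    s[log$site] <- log$to
    expect_equal(paste(s, collapse = ""), fam$records$residues[d])
  }
})

test_that("planted motifs are recoverable as shared regions of their carriers", {
  spec <- family_spec(n = 6, identity = 0.7, seed = 10,
                      motifs = list(list(motif = "IPYKIS", members = 1:5,
                                         position = 60)))
  fam <- generate_family(spec)
  carriers <- fam$records$residues[1:5]
  expect_true(all(grepl("IPYKIS", carriers)))
  expect_false(grepl("IPYKIS", fam$records$residues[6]))
  sh <- shared_substrings(carriers[1], carriers[2])
  expect_true(any(vapply(sh$motif, function(m) grepl("IPYKIS", m, fixed = TRUE),
                         logical(1))))
})

test_that("motif placement respects the cysteine scaffold", {
  expect_error(
    family_spec(motifs = list(list(motif = "AAAAA", members = 1,
                                   position = 1))),
    "cysteine scaffold")
  # overwrite flag or a motif carrying the scaffold cysteine is accepted
  expect_silent(family_spec(motifs = list(list(motif = "AACAA", members = 1,
                                               position = 1))))
  expect_silent(family_spec(motifs = list(list(motif = "AAAAA", members = 1,
                                               position = 1, overwrite = TRUE))))
  expect_error(family_spec(motifs = list(list(motif = "AAAA", members = 1,
                                              position = 91))),
               "fit within")
})

test_that("star tree with zero branch lengths yields identical leaves", {
  tr <- ape::read.tree(text = "(a:0,b:0,c:0,d:0);")
  rs <- generate_tree_family(tr, rate = 1, seed = 3)
  expect_equal(length(unique(rs$residues)), 1)
})

test_that("NJ recovers the generating topology on tree-simulated families", {
  bal <- ape::read.tree(text = "((a:0.1,b:0.1):0.6,(c:0.1,d:0.1):0.6);")
  hits <- 0
  for (seed in 1:20) {
    rs <- generate_tree_family(bal, rate = 1, seed = seed)
    msa <- make_msa(rs$residues, rs$id)
    tr <- nj_tree(distance_matrix(msa))
    if (ape::dist.topo(ape::unroot(bal), tr) == 0) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("NJ recovers a 6-taxon caterpillar at low mutation rate", {
  cat6 <- ape::read.tree(
    text = "(((((a:0.05,b:0.05):0.2,c:0.05):0.2,d:0.05):0.2,e:0.05):0.2,f:0.05);")
  hits <- 0
  for (seed in 1:20) {
    rs <- generate_tree_family(cat6, rate = 1, seed = seed, length = 200)
    msa <- make_msa(rs$residues, rs$id)
    tr <- nj_tree(distance_matrix(msa))
    if (ape::dist.topo(ape::unroot(cat6), tr) == 0) hits <- hits + 1
  }
  expect_gte(hits, 18)
})
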