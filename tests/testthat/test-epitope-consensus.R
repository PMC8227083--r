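test_that("window statistics: window 1 returns raw scale values; termini truncate", {
  sc <- propensity_scales()$parker_hydrophilicity
  seq <- "ACDEFGHIKL"
  p1 <- scale_profile(seq, "parker_hydrophilicity", window = 1)
  expect_equal(p1$raw, unname(sc[strsplit(seq, "")[[1]]]))
  p3 <- scale_profile(seq, "parker_hydrophilicity", window = 3)
  expect_equal(p3$raw[1], mean(sc[c("A", "C")]), ignore_attr = TRUE)
  expect_equal(p3$raw[5], mean(sc[c("E", "F", "G")]), ignore_attr = TRUE)
  expect_error(scale_profile(seq, "parker_hydrophilicity", window = 4), "odd")
  expect_error(scale_profile("ACD", "parker_hydrophilicity", window = 7),
               "window larger")
  expect_error(scale_profile(seq, "no_such_scale"), "unknown scale")
})

test_that("zero-variance profiles make no calls on any scale", {
  homo <- paste(rep("A", 20), collapse = "")
  for (s in default_scales()) {
    p <- scale_profile(homo, s)
    expect_true(all(p$z == 0), info = s)
    expect_false(any(p$call), info = s)
  }
})

test_that("an adversarial scale concentrates calls on runs of its residue", {
  # one dominating residue: brute-force the expected mask independently
  adv <- setNames(rep(0, 20), strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
  adv["D"] <- 10
  seq <- "AAADDDDDAAAAAADDDDDAAA"
  w <- 5
  p <- scale_profile(seq, adv, window = w)
  res <- strsplit(seq, "")[[1]]
  n <- length(res)
  raw <- vapply(seq_len(n), function(i) {
    win <- res[max(1, i - 2):min(n, i + 2)]
    mean(adv[win])
  }, numeric(1))
  z <- (raw - mean(raw)) / sd(raw)
  expect_equal(p$raw, unname(raw))
  expect_equal(p$call, unname(z > 0))
  # every called residue lies within half a window of a D run
  d_pos <- grep("D", res)
  expect_true(all(vapply(which(p$call),
                         function(i) min(abs(i - d_pos)) <= 2, logical(1))))
})

test_that("emini uses the product form", {
  sc <- propensity_scales()$emini_accessibility
  p <- scale_profile("KKKKKK", "emini_accessibility", window = 3)
  expect_equal(p$raw[2], prod(sc[c("K", "K", "K")]) * 0.37^-3,
               ignore_attr = TRUE)
})

test_that("consensus voting keeps >= min_votes residues and filters short runs", {
  mkprof <- function(call) structure(
    list(scale = "x", window = 1, seq = paste(rep("A", length(call)), collapse = ""),
         raw = as.numeric(call), z = as.numeric(call), call = call),
    class = "propensity_profile")
  n <- 20
  base <- rep(FALSE, n)
  on5 <- base; on5[3:12] <- TRUE        # called by 5 profiles
  on4 <- base; on4[14:19] <- TRUE       # called by 4 profiles
  profiles <- c(replicate(5, mkprof(on5 | on4), simplify = FALSE),
                replicate(3, mkprof(base), simplify = FALSE))
  # residues 3:12 and 14:19 get 5 votes of 8 -> kept (>= ceiling(5/8*8) = 5)
  r <- consensus_regions(profiles, min_region_length = 6, id = "q")
  expect_equal(nrow(r), 2)
  expect_equal(r$start, c(3, 14))
  expect_equal(r$end, c(12, 19))
  # 4 of 8 votes -> dropped
  profiles4 <- c(replicate(4, mkprof(on4), simplify = FALSE),
                 replicate(4, mkprof(base), simplify = FALSE))
  expect_equal(nrow(consensus_regions(profiles4, min_votes = 5)), 0)
  # run of 5 with min_region_length 6 -> dropped
  on5short <- base; on5short[1:5] <- TRUE
  profiles5 <- replicate(5, mkprof(on5short), simplify = FALSE)
  expect_equal(nrow(consensus_regions(profiles5, min_votes = 5,
                                      min_region_length = 6)), 0)
  expect_equal(nrow(consensus_regions(profiles5, min_votes = 5,
                                      min_region_length = 5)), 1)
})

test_that("votes are monotone: adding a predictor never removes a consensus residue", {
  set.seed(21)
  fam <- generate_family(family_spec(n = 1, identity = 1, seed = 21))$records
  scales <- default_scales()
  profs <- lapply(scales, function(s) scale_profile(fam$residues[1], s))
  for (k in 3:(length(profs) - 1)) {
    r1 <- consensus_regions(profs[1:k], min_votes = 3, min_region_length = 1)
    r2 <- consensus_regions(profs[1:(k + 1)], min_votes = 3, min_region_length = 1)
    kept1 <- unlist(mapply(seq, r1$start, r1$end, SIMPLIFY = FALSE))
    kept2 <- unlist(mapply(seq, r2$start, r2$end, SIMPLIFY = FALSE))
    expect_true(all(kept1 %in% kept2))
  }
})

test_that("min_votes 1 equals the union of per-scale calls merged into runs", {
  fam <- generate_family(family_spec(n = 1, identity = 1, seed = 22))$records
  profs <- lapply(default_scales(), function(s) scale_profile(fam$residues[1], s))
  r <- consensus_regions(profs, min_votes = 1, min_region_length = 1)
  kept <- unlist(mapply(seq, r$start, r$end, SIMPLIFY = FALSE))
  union_mask <- Reduce(`|`, lapply(profs, function(p) p$call))
  expect_equal(sort(kept), which(union_mask))
})

test_that("predicted regions are disjoint, sorted and within bounds", {
  for (seed in 1:5) {
    fam <- generate_family(family_spec(n = 1, identity = 1, seed = seed))$records
    r <- predict_epitopes(fam[1, , drop = FALSE])
    if (nrow(r) == 0) next
    expect_true(all(r$start <= r$end))
    expect_true(all(r$start >= 1 & r$end <= nchar(fam$residues[1])))
    if (nrow(r) > 1) expect_true(all(r$start[-1] > r$end[-nrow(r)]))
    expect_equal(r$residues,
                 substring(fam$residues[1], r$start, r$end))
  }
})

test_that("the reported-epitope fixture loads with verified coordinates", {
  df <- suppressWarnings(load_reported_epitopes())
  chick2 <- df[df$source == "chickpea" & df$epitope == 2, ]
  expect_equal(c(chick2$start, chick2$end), c(56, 70))
  expect_equal(chick2$residues, "RNLNSAAVTTPDRQA")
  expect_equal(nchar(chick2$residues), 15)
  expect_equal(sum(df$source == "soybean"), 5)
  peach3 <- df[df$source == "peach" & df$epitope == 3, ]
  expect_equal(peach3$residues, "GKCGVSIPYK")
  expect_equal(peach3$end - peach3$start + 1, nchar(peach3$residues))
  expect_false(peach3$length_mismatch)
})

test_that("the known range/string discrepancy is flagged, not guessed away", {
  expect_warning(df <- load_reported_epitopes(), "peach epitope 2")
  bad <- df[df$length_mismatch, ]
  expect_equal(nrow(bad), 1)
  expect_equal(bad$residues, "IRNVNNLARTTTPDRQ")  # string kept authoritative
  expect_error(load_reported_epitopes(strict = TRUE), "peach epitope 2")
})
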