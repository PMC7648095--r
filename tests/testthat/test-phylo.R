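test_that("distance closed forms and pairwise deletion are exact", {
  # identical sequences
  d0 <- pairwise_distance(c(a = "ACGTACGT", b = "ACGTACGT"), "p")
  expect_identical(d0$d[1, 2], 0)
  expect_identical(pairwise_distance(c(a = "ACGTACGT", b = "ACGTACGT"),
                                     "K2P")$d[1, 2], 0)

  # one transition among four sites: p = 1/4, K2P = 1/2 ln 2
  dp <- pairwise_distance(c(a = "ACGT", b = "GCGT"), "p")
  expect_equal(dp$d[1, 2], 0.25)
  dk <- pairwise_distance(c(a = "ACGT", b = "GCGT"), "K2P")
  expect_equal(dk$d[1, 2], 0.5 * log(2))

  # pairwise deletion: distance equals that of the unmasked subsequence
  full <- c(a = "ACGTACGTAC", b = "ACGAACGTCC")
  half <- c(a = paste0("NNNNN", substr(full[1], 6, 10)),
            b = paste0("NNNNN", substr(full[2], 6, 10)))
  dh <- pairwise_distance(half, "p")
  dref <- pairwise_distance(c(a = substr(full[1], 6, 10),
                              b = substr(full[2], 6, 10)), "p")
  expect_equal(dh$d[1, 2], dref$d[1, 2])
  expect_identical(dh$usable[1, 2], 5L)

  # gaps count as missing too
  dg <- pairwise_distance(c(a = "AC-T", b = "ACGT"), "p")
  expect_identical(dg$usable[1, 2], 3L)

  # errors name the offending pair
  expect_error(pairwise_distance(c(x = "NNNN", y = "ACGT"), "p"),
               "\\(x, y\\)")
  expect_error(pairwise_distance(c(p1 = "ACAC", p2 = "GTGT"), "K2P"),
               "p1, p2")
})

test_that("cross-check against ape's distance implementation", {
  cp <- make_clade_panel(3, 3, 0.08, 0.01, 1200, seed = 91)
  aln <- cp$alignment
  # punch missing data into two haplotypes
  a1 <- strsplit(aln[[1]], "")[[1]]; a1[101:300] <- "N"
  aln[1] <- paste(a1, collapse = "")
  bin <- ape::as.DNAbin(t(sapply(strsplit(tolower(aln), ""), identity)))
  for (model in c("p", "K2P")) {
    mine <- pairwise_distance(aln, model)$d
    apes <- as.matrix(ape::dist.dna(bin,
                                    model = if (model == "p") "raw"
                                            else "K80",
                                    pairwise.deletion = TRUE))
    expect_equal(mine, apes[rownames(mine), colnames(mine)],
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("NJ recovers additive trees exactly", {
  # n = 3: three-point formulas
  D3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- neighbor_joining(D3)
  expect_equal(sort(ape::cophenetic.phylo(t3)[c("a", "b", "c"),
                                              c("a", "b", "c")]),
               sort(D3), ignore_attr = TRUE)
  # branch lengths: ((3+4-5)/2, (3+5-4)/2, (4+5-3)/2) = (1, 2, 3)
  expect_setequal(round(t3$edge.length, 9), c(1, 2, 3))

  # 4 taxa, tree ((A,B),(C,D)) with all branches 1
  D4 <- matrix(c(0, 2, 3, 3,
                 2, 0, 3, 3,
                 3, 3, 0, 2,
                 3, 3, 2, 0), 4, 4,
               dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  t4 <- neighbor_joining(D4)
  expect_equal(ape::cophenetic.phylo(t4)[LETTERS[1:4], LETTERS[1:4]],
               D4, tolerance = 1e-9, ignore_attr = TRUE)
  ref4 <- ape::read.tree(text = "((A:1,B:1):1,C:1,D:1);")
  expect_identical(ape::dist.topo(t4, ref4)[1], 0)

  # random 5-taxon additive matrices across seeds
  for (s in 1:20) {
    fx <- random_additive_matrix(5, seed = 900 + s)
    tr <- neighbor_joining(fx$D)
    expect_equal(ape::cophenetic.phylo(tr)[rownames(fx$D), colnames(fx$D)],
                 fx$D, tolerance = 1e-9, ignore_attr = TRUE)
    expect_identical(ape::dist.topo(tr, fx$tree)[1], 0)
    # independent oracle: ape's own NJ agrees on the topology
    expect_identical(ape::dist.topo(tr, ape::nj(fx$D))[1], 0)
  }

  expect_error(neighbor_joining(matrix(c(0, 1, 2, 0), 2, 2,
                                       dimnames = list(c("a", "b"),
                                                       c("a", "b")))),
               "symmetric|3 taxa")
})

test_that("negative NJ branch lengths are clamped with a recorded deficit", {
  D <- matrix(c(0, 8, 3, 8, 0, 3, 3, 3, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  # d(a,b) > d(a,c) + d(c,b): the three-point formula goes negative
  tr <- neighbor_joining(D)
  expect_true(all(tr$edge.length >= 0))
  expect_gt(attr(tr, "clamp_deficit"), 0)
})

test_that("bootstrap supports behave at the extremes", {
  cp <- make_clade_panel(3, 3, 0.2, 0.001, 1500, seed = 92)
  # single replicate: supports are 0 or 100
  b1 <- bootstrap_support(cp, replicates = 1, seed = 93)
  expect_true(all(b1$supports %in% c(0, 100)))
  # clearly separated clades: every true clade edge at 100
  b <- bootstrap_support(cp, replicates = 60, seed = 94)
  for (cl in unique(cp$clades)) {
    members <- names(cp$clades)[cp$clades == cl]
    key <- paste(sort(members), collapse = "|")
    ref <- sort(names(cp$alignment))[1]
    if (ref %in% members)
      key <- paste(sort(setdiff(names(cp$alignment), members)),
                   collapse = "|")
    expect_true(key %in% names(b$supports))
    expect_equal(unname(b$supports[key]), 100)
  }
})

test_that("two conflicting informative sites give intermediate support", {
  # 20 columns support AB|CD, 20 support AC|BD, plus constant padding
  pat1 <- c(A = "A", B = "A", C = "G", D = "G")
  pat2 <- c(A = "A", B = "G", C = "A", D = "G")
  const <- c(A = "C", B = "C", C = "C", D = "C")
  cols <- cbind(matrix(rep(pat1, 20), 4), matrix(rep(pat2, 20), 4),
                matrix(rep(const, 60), 4))
  aln <- setNames(apply(cols, 1, paste, collapse = ""), names(pat1))
  b <- bootstrap_support(aln, model = "p", replicates = 200, seed = 95)
  expect_true(all(b$supports >= 20 & b$supports <= 80))
})

test_that("clade assignment finds the minimal monochromatic grouping", {
  cp <- make_clade_panel(4, 3, 0.1, 0.005, 2000, seed = 96)
  # query identical to a panel haplotype
  q <- unname(cp$alignment[["clade3_h2"]])
  pl <- place_query(cp, q, replicates = 40, seed = 97)
  expect_identical(pl$clade, "clade3")
  expect_equal(pl$support, 100)
  # the newick in the result carries every input label once
  tr <- ape::read.tree(text = pl$newick)
  expect_setequal(tr$tip.label, c(names(cp$alignment), "query"))

  # query missing from the tree
  expect_error(assign_clade(neighbor_joining(
    pairwise_distance(cp$alignment)), cp$clades, "ghost"), "ghost")
})

test_that("a query midway between two clades is flagged, not forced", {
  cp <- make_clade_panel(4, 3, 0.1, 0.004, 3000, seed = 98)
  # mosaic of the two clade founders: equidistant by construction
  h1 <- strsplit(cp$alignment[["clade1_h1"]], "")[[1]]
  h2 <- strsplit(cp$alignment[["clade2_h1"]], "")[[1]]
  mid <- h1
  alt <- withr::with_seed(99, sample(length(h1), length(h1) / 2))
  mid[alt] <- h2[alt]
  pl <- place_query(cp, paste(mid, collapse = ""), replicates = 60,
                    seed = 100)
  expect_true(pl$clade == "unresolved" || is.na(pl$support) ||
                pl$support < 70)
})

test_that("serialization round-trips preserve the bipartitions", {
  fx <- random_additive_matrix(6, seed = 101)
  tr <- neighbor_joining(fx$D)
  back <- ape::read.tree(text = ape::write.tree(tr))
  expect_identical(ape::dist.topo(tr, back)[1], 0)
  expect_setequal(tree_splits_keys(tr), tree_splits_keys(back))
})
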