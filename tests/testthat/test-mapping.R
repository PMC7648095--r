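test_that("index enumerates k-mers of both strands", {
  p <- reference_panel(list(G = c(s = "ACGTACGT")))
  idx <- build_index(p, k = 8)
  fwd <- index_lookup(idx, "ACGTACGT")
  expect_identical(fwd$pos, c(0L, 0L))
  # the k-mer is its own reverse complement here, so both strand entries
  # land on the same key
  expect_setequal(fwd$strand, c("+", "-"))

  # sequence shorter than k -> warning, nothing indexed
  expect_warning(idx2 <- build_index(
    reference_panel(list(G = c(tiny = "ACGT"))), k = 16), "unindexed")

  # two identical chromosomes: every k-mer at >= 2 locations
  s <- rand_seq(50, seed = 31)
  p3 <- reference_panel(list(G = c(c1 = s, c2 = s)))
  idx3 <- build_index(p3, k = 16)
  hit <- index_lookup(idx3, substr(s, 1, 16))
  expect_gte(sum(hit$strand == "+"), 2)

  expect_error(build_index(p, k = 4), "k must")
})

test_that("map_read resolves unique and shared placements", {
  s1 <- rand_seq(400, seed = 32)
  shared <- rand_seq(60, seed = 33)
  s2 <- rand_seq(400, seed = 34)
  p <- reference_panel(list(G1 = c(chr = paste0(s1, shared)),
                            G2 = c(chr = paste0(shared, s2))))
  idx <- build_index(p)

  # unique substring of one genome: single perfect unique hit
  m <- map_read(substr(s1, 101, 160), idx)
  expect_identical(nrow(m$hits), 1L)
  expect_identical(m$hits$genome, "G1")
  expect_identical(m$hits$start, 100L)
  expect_identical(m$hits$mismatches, 0L)
  expect_true(m$summary$unique_in_genome)

  # region identical in both genomes: unique within each, hits in both
  m2 <- map_read(substr(shared, 11, 50), idx)
  expect_setequal(m2$hits$genome, c("G1", "G2"))
  expect_true(all(m2$summary$unique_in_genome))

  # minus-strand placement is recovered at the forward coordinate
  m3 <- map_read(revcomp(substr(s1, 51, 110)), idx)
  expect_identical(m3$hits$strand, "-")
  expect_identical(m3$hits$start, 50L)
})

test_that("simulated reads map back to their truth coordinates", {
  p <- two_genome_panel(30000, 0.05, seed = 35)
  rs <- simulate_reads(p, "G1",
                       simulation_config(seed = 36, n_reads = 1000,
                                         endogenous_frac = 1,
                                         damage_p0 = 0))
  idx <- build_index(p)
  m <- map_reads(rs, idx, max_mismatch_frac = 0.1)
  uh <- unique_hits(m, "G1")
  expect_identical(nrow(uh), 1000L)
  tr <- rs$truth[match(uh$read_id, rs$truth$id), ]
  expect_identical(uh$start, tr$start)
  expect_identical(uh$strand, tr$strand)
  expect_true(all(uh$mismatches == 0L))
})

test_that("mapping is order-independent", {
  p <- two_genome_panel(10000, 0.05, seed = 37)
  rs <- simulate_reads(p, "G1",
                       simulation_config(seed = 38, n_reads = 200))
  idx <- build_index(p)
  m1 <- map_reads(rs, idx)
  perm <- withr::with_seed(39, sample.int(n_reads(rs)))
  rs2 <- read_set(rs$reads$id[perm], rs$reads$seq[perm],
                  rs$reads$qual[perm])
  m2 <- map_reads(rs2, idx)
  key <- function(m) {
    s <- as.data.frame(m$summary)
    s[order(s$read_id, s$genome), c("read_id", "genome", "n_hits",
                                    "best", "unique_in_genome")]
  }
  expect_equal(key(m1), key(m2), ignore_attr = TRUE)
  expect_setequal(hit_key(m1$hits), hit_key(m2$hits))
})

test_that("duplicate removal keeps one representative per placement", {
  h <- data.frame(
    read_id = paste0("r", 1:10),
    genome = "G", seq_name = "s",
    start = c(rep(5L, 4), rep(40L, 3), 80L, 90L, 100L),
    strand = "+",
    mismatches = c(2L, 0L, 1L, 3L, 1L, 1L, 1L, 0L, 0L, 0L),
    len = 30L)
  dd <- remove_duplicates(h)
  expect_identical(nrow(dd$hits), 5L)
  expect_identical(dd$n_removed, 5L)
  # fewest mismatches wins, ties by smallest read id
  expect_true("r2" %in% dd$hits$read_id)   # 0 mismatches at start 5
  expect_true("r5" %in% dd$hits$read_id)   # tie on 1 mismatch: r5 < r6 < r7

  # identity on distinct placements, and idempotence
  distinct <- h[8:10, ]
  expect_identical(remove_duplicates(distinct)$n_removed, 0L)
  once <- remove_duplicates(h)
  twice <- remove_duplicates(once$hits)
  expect_identical(twice$hits, once$hits)
  expect_identical(twice$n_removed, 0L)
})

test_that("endogenous content matches the simulated fraction", {
  p <- two_genome_panel(30000, 0.4, seed = 40)
  f <- 0.4; n <- 8000
  rs <- simulate_reads(p, "G1",
                       simulation_config(seed = 41, n_reads = n,
                                         endogenous_frac = f,
                                         contaminant = "G2"))
  idx <- build_index(p)
  m <- map_reads(rs, idx)
  ec <- endogenous_content(m, rs, "G1")
  expect_lt(abs(ec$percent / 100 - f), 3 * sqrt(f * (1 - f) / n))
  expect_error(endogenous_content(m, read_set(character(0), character(0)),
                                  "G1"), "empty")
})

test_that("pileup depth equals a hand-computed tiling profile", {
  ref <- rand_seq(100, seed = 42)
  reads <- read_set(c("a", "b", "c"),
                    c(substr(ref, 1, 40), substr(ref, 21, 70),
                      substr(ref, 61, 100)))
  hits <- data.frame(read_id = c("a", "b", "c"), genome = "G",
                     seq_name = "s", start = c(0L, 20L, 60L),
                     strand = "+", mismatches = 0L,
                     len = c(40L, 50L, 40L))
  pu <- build_pileup(hits, reads, ref, "s")
  expected <- integer(100)
  expected[1:40] <- expected[1:40] + 1L
  expected[21:70] <- expected[21:70] + 1L
  expected[61:100] <- expected[61:100] + 1L
  expect_identical(pu$depth, expected)
  # bases match the reference at every covered site
  covered <- which(pu$depth > 0)
  refbase <- strsplit(ref, "")[[1]]
  expect_true(all(pu$counts[cbind(covered,
                                  match(refbase[covered],
                                        c("A", "C", "G", "T")))] ==
                  pu$depth[covered]))

  cs <- coverage_stats(pu, depths = c(1, 2, 3))
  expect_equal(cs$mean_depth, sum(expected) / 100)
  expect_equal(cs$pct_zero, 0)
  expect_equal(unname(cs$pct_below["d2"]), 100 * mean(expected < 2))
})

test_that("coverage fractions are closed-form for simple cases", {
  # no hits
  empty <- build_pileup(data.frame(read_id = character(0),
                                   genome = character(0),
                                   seq_name = character(0),
                                   start = integer(0),
                                   strand = character(0),
                                   len = integer(0)),
                        read_set(character(0), character(0)),
                        rand_seq(50, seed = 43), "s")
  cs0 <- coverage_stats(empty)
  expect_equal(cs0$mean_depth, 0)
  expect_equal(cs0$pct_zero, 100)

  # single L-length hit on an N-length reference
  ref <- rand_seq(200, seed = 44)
  rs <- read_set("a", substr(ref, 51, 110))
  hits <- data.frame(read_id = "a", genome = "G", seq_name = "s",
                     start = 50L, strand = "+", len = 60L)
  cs1 <- coverage_stats(build_pileup(hits, rs, ref, "s"))
  expect_equal(cs1$mean_depth, 60 / 200)
  expect_equal(cs1$pct_zero, 100 * 140 / 200)

  # fraction(depth < d) is non-decreasing in d; depth=0 equals depth<1
  p <- two_genome_panel(5000, 0.05, seed = 45)
  rsim <- simulate_reads(p, "G1",
                         simulation_config(seed = 46, n_reads = 200))
  m <- map_reads(rsim, build_index(p))
  pu <- build_pileup(remove_duplicates(unique_hits(m, "G1"))$hits, rsim,
                     p$genomes$G1[[1]], names(p$genomes$G1)[1])
  cs <- coverage_stats(pu, depths = 1:6)
  expect_true(all(diff(cs$pct_below) >= 0))
  expect_equal(unname(cs$pct_below["d1"]), cs$pct_zero)
})
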