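test_that("reference panel divergence is exact by construction", {
  # zero divergence -> identical sequences
  dv0 <- matrix(0, 2, 2)
  p0 <- make_reference_panel(5000, 2, dv0, seed = 1)
  expect_identical(p0$genomes$G1, p0$genomes$G2)

  # 5% of 10 kb -> exactly 500 differing sites vs genome 1
  dv <- matrix(0.05, 3, 3); diag(dv) <- 0
  p <- make_reference_panel(10000, 3, dv, seed = 2)
  d12 <- mapply(function(a, b) sum(utf8ToInt(a) != utf8ToInt(b)),
                p$genomes$G1, p$genomes$G2)
  d13 <- mapply(function(a, b) sum(utf8ToInt(a) != utf8ToInt(b)),
                p$genomes$G1, p$genomes$G3)
  expect_identical(unname(d12), 500L)
  expect_identical(unname(d13), 500L)

  # mutual divergence of two independently derived genomes: each site
  # differs with p = 2d(1-d) + (2/3)d^2 (both mutated and coincide with
  # probability 1/3); assert the realized count within 3 binomial SD
  d23 <- sum(utf8ToInt(p$genomes$G2[[1]]) != utf8ToInt(p$genomes$G3[[1]]))
  d <- 0.05; L <- 10000
  pexp <- 2 * d * (1 - d) + (2 / 3) * d^2
  expect_lt(abs(d23 - L * pexp), 3 * sqrt(L * pexp * (1 - pexp)))
})

test_that("panel construction validates its divergence matrix", {
  expect_error(make_reference_panel(100, 2, matrix(c(0, .1, .2, 0), 2, 2)),
               "symmetric")
  expect_error(make_reference_panel(100, 2, matrix(c(0, .8, .8, 0), 2, 2)),
               "0.75")
  expect_error(make_reference_panel(100, 2, matrix(c(.1, .1, .1, 0), 2, 2)),
               "diagonal")
})

test_that("clade panel respects its hierarchical structure", {
  # within = 0 -> all haplotypes of a clade identical
  cp0 <- make_clade_panel(3, 3, 0.05, 0, 2000, seed = 4)
  for (cl in unique(cp0$clades)) {
    h <- cp0$alignment[names(cp0$clades)[cp0$clades == cl]]
    expect_length(unique(unname(h)), 1)
  }

  # within-clade distances below every between-clade pair
  cp <- make_clade_panel(4, 3, 0.05, 0.005, 4000, seed = 5)
  enc <- encode_alignment(cp)
  ham <- function(i, j) mean(enc[i, ] != enc[j, ])
  labs <- rownames(enc)
  cl <- cp$clades[labs]
  within <- c(); between <- list()
  for (i in 1:(length(labs) - 1)) for (j in (i + 1):length(labs)) {
    d <- ham(i, j)
    if (cl[i] == cl[j]) within <- c(within, d)
    else {
      key <- paste(sort(c(cl[i], cl[j])), collapse = "-")
      between[[key]] <- c(between[[key]], d)
    }
  }
  for (key in names(between))
    expect_lt(mean(within), mean(between[[key]]))

  # single haplotype per clade -> star of n_clades sequences
  star <- make_clade_panel(5, 1, 0.05, 0.004, 1000, seed = 6)
  expect_length(star$alignment, 5)
  tr <- ape::read.tree(text = star$tree)
  expect_equal(sort(tr$tip.label), sort(names(star$alignment)))

  expect_error(make_clade_panel(1, 2, 0.05, 0.005, 100), "at least 2")
})

test_that("simulated reads honour their ground truth", {
  p <- two_genome_panel(20000, 0.3, seed = 10)
  # no damage -> every read is an exact (oriented) substring of its source
  cfg <- simulation_config(seed = 3, n_reads = 200, endogenous_frac = 1,
                           damage_p0 = 0)
  rs <- simulate_reads(p, "G1", cfg)
  expect_true(all(rs$truth$donor == "G1"))
  for (i in seq_len(nrow(rs$reads))) {
    tr <- rs$truth[i, ]
    frag <- substr(p$genomes$G1[[tr$seq_name]], tr$start + 1,
                   tr$start + nchar(rs$reads$seq[i]))
    if (tr$strand == "-") frag <- revcomp(frag)
    expect_identical(rs$reads$seq[i], frag)
  }
  expect_true(all(rs$truth$n_damaged == 0))
})

test_that("endogenous fraction is recovered within binomial noise", {
  p <- two_genome_panel(20000, 0.3, seed = 11)
  f <- 0.4; n <- 10000
  rs <- simulate_reads(p, "G1",
                       simulation_config(seed = 9, n_reads = n,
                                         endogenous_frac = f))
  emp <- mean(rs$truth$donor == "G1")
  expect_lt(abs(emp - f), 3 * sqrt(f * (1 - f) / n))
})

test_that("terminal damage decays monotonically along the read", {
  p <- reference_panel(list(G1 = c(s = rand_seq(30000, seed = 12))))
  rs <- simulate_reads(p, "G1",
                       simulation_config(seed = 13, n_reads = 8000,
                                         endogenous_frac = 1,
                                         damage_p0 = 0.2,
                                         damage_lambda = 0.3))
  # pooled 5' C->T frequency per position, measured against the truth
  idx <- build_index(p)
  m <- map_reads(rs, idx)
  prof <- estimate_damage(remove_duplicates(unique_hits(m, "G1"))$hits,
                          rs, p, "G1")
  fit <- lm(freq ~ pos, data = prof$five_prime[1:15, ])
  expect_lt(coef(fit)[["pos"]], 0)
})

test_that("identical simulation config gives byte-identical FASTQ", {
  p <- two_genome_panel(5000, 0.1, seed = 14)
  cfg <- simulation_config(seed = 21, n_reads = 300)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_fastq(simulate_reads(p, "G1", cfg), f1)
  write_fastq(simulate_reads(p, "G1", cfg), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("FASTQ round-trip preserves ids, sequences and qualities", {
  rs <- read_set(c("a", "b", "c"), c("ACGT", "GGGTT", "TTT"),
                 c("IIII", "JJJJJ", "KKK"))
  f <- tempfile(fileext = ".fastq")
  write_fastq(rs, f)
  back <- read_fastq(f)
  expect_identical(back$reads, rs$reads)

  # empty file -> empty set with a warning
  fe <- tempfile(); file.create(fe)
  expect_warning(empty <- read_fastq(fe), "empty")
  expect_identical(n_reads(empty), 0L)

  # malformed records are reported with line numbers / read ids
  fb <- tempfile()
  writeLines(c("@r1", "ACGT", "+", "III"), fb)   # qual too short
  expect_error(read_fastq(fb), "read id 'r1' at line 2")
  writeLines(c("r1", "ACGT", "+", "IIII"), fb)   # missing @
  expect_error(read_fastq(fb), "line 1")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "AC"), fb)
  expect_error(read_fastq(fb), "line 7")
})

test_that("truth sidecar and FASTA round-trips are faithful", {
  p <- two_genome_panel(4000, 0.1, seed = 15)
  rs <- simulate_reads(p, "G1", simulation_config(seed = 5, n_reads = 50))
  ft <- tempfile(fileext = ".tsv")
  write_truth(rs, ft)
  expect_equal(read_truth(ft), rs$truth)

  fa <- tempfile(fileext = ".fa")
  write_fasta(p, fa)
  p2 <- panel_from_fasta(fa)
  expect_identical(p2$genomes, p$genomes)

  cp <- make_clade_panel(2, 2, 0.05, 0.01, 500, seed = 16)
  fc <- tempfile(fileext = ".fa")
  write_fasta(cp, fc)
  expect_identical(read_fasta(fc), cp$alignment)
})

test_that("simulation config enforces its invariants", {
  expect_error(simulation_config(endogenous_frac = 1.5), "endogenous_frac")
  expect_error(simulation_config(damage_p0 = -0.1), "damage_p0")
  expect_error(simulation_config(mean_len = 10, min_len = 30), "mean_len")
  p <- two_genome_panel(2000, 0.1, seed = 17)
  expect_error(simulate_reads(p, "nope", simulation_config()), "donor")
})
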