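# shared fixtures, all generated in code under fixed seeds

rand_seq <- function(n, seed = NULL) {
  draw <- function() paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

two_genome_panel <- function(len = 30000, div = 0.05, seed = 101) {
  dv <- matrix(c(0, div, div, 0), 2, 2)
  make_reference_panel(len, 2, dv, seed = seed)
}

# toy six-read screen fixture with hand-enumerable categories:
#   r1, r2  unique to G1 only            -> G1 category A
#   r3      two loci in G1, absent in G2 -> G1 category B
#   r4, r5  unique in G1 and in G2       -> category C in both
#   r6      matches nothing              -> unmapped
toy_screen_fixture <- function(seed = 77) {
  withr::with_seed(seed, {
    u1a <- rand_seq(40); u1b <- rand_seq(40)
    rpt <- rand_seq(40)             # repeated twice in G1
    shared <- rand_seq(40)          # present once in G1 and once in G2
    f1 <- rand_seq(60); f2 <- rand_seq(60); f3 <- rand_seq(60)
    g1 <- paste0(f1, u1a, rpt, shared, u1b, rpt, f2)
    g2 <- paste0(f3, shared, f1)
    panel <- reference_panel(list(G1 = c(chr = g1), G2 = c(chr = g2)))
    reads <- read_set(
      id = paste0("r", 1:6),
      seq = c(u1a, u1b, rpt, shared, substr(shared, 3, 38), rand_seq(40)))
    list(panel = panel, reads = reads)
  })
}

tree_splits_keys <- function(tr) skimprov:::tree_splits(tr)$keys

# additive distance matrix from a random tree; NJ must reproduce it exactly
random_additive_matrix <- function(n, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.1, 1))
    tr <- ape::unroot(tr)
    list(D = ape::cophenetic.phylo(tr), tree = tr)
  })
}
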