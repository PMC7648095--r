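# Independent oracles, kept free of the implementation paths they check.

# Brute-force read mapper: every offset of every sequence on both strands,
# via Biostrings::matchPattern. Returns hits in the same column layout as
# map_reads() plus per-(read, genome) uniqueness flags computed from the
# same scoring rule.
brute_force_map <- function(readset, panel, max_mismatch_frac = 0.1,
                            score_gap = 4, mismatch_penalty = 2) {
  rows <- list()
  subjects <- list()
  for (g in names(panel$genomes))
    for (s in names(panel$genomes[[g]]))
      subjects[[paste(g, s, sep = "\r")]] <-
        Biostrings::DNAString(panel$genomes[[g]][[s]])
  for (ri in seq_len(nrow(readset$reads))) {
    rd <- readset$reads$seq[ri]
    id <- readset$reads$id[ri]
    len <- nchar(rd)
    mm_max <- as.integer(ceiling(max_mismatch_frac * len - 1e-9))
    for (key in names(subjects)) {
      gs <- strsplit(key, "\r", fixed = TRUE)[[1]]
      subj <- subjects[[key]]
      for (st in c("+", "-")) {
        q <- Biostrings::DNAString(if (st == "+") rd else revcomp(rd))
        m <- Biostrings::matchPattern(q, subj, max.mismatch = mm_max,
                                      with.indels = FALSE, fixed = TRUE)
        if (!length(m)) next
        starts <- BiocGenerics::start(m)
        mm <- Biostrings::neditStartingAt(q, subj, starting.at = starts,
                                          fixed = TRUE)
        rows[[length(rows) + 1]] <- data.frame(
          read_id = id, genome = gs[1], seq_name = gs[2],
          start = starts - 1L, strand = st, mismatches = as.integer(mm),
          score = (len - mm) - mismatch_penalty * mm, len = len,
          stringsAsFactors = FALSE)
      }
    }
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(read_id = character(0), genome = character(0),
               seq_name = character(0), start = integer(0),
               strand = character(0), mismatches = integer(0),
               score = numeric(0), len = integer(0))
  flags <- do.call(rbind, lapply(
    split(hits, paste(hits$read_id, hits$genome, sep = "\r")),
    function(h) {
      sc <- sort(h$score, decreasing = TRUE)
      data.frame(read_id = h$read_id[1], genome = h$genome[1],
                 n_hits = nrow(h), best = sc[1],
                 unique_in_genome = nrow(h) == 1 ||
                   (sum(h$score == sc[1]) == 1 && sc[1] - sc[2] >= score_gap),
                 stringsAsFactors = FALSE)
    }))
  rownames(flags) <- NULL
  list(hits = hits, flags = flags)
}

# canonical string form of a hit table for set comparison
hit_key <- function(h) {
  sort(sprintf("%s:%s:%s:%d:%s:%d", h$read_id, h$genome, h$seq_name,
               h$start, h$strand, h$mismatches))
}

# plain (unweighted) delete-one jackknife standard error
plain_jackknife_se <- function(block_means) {
  g <- length(block_means)
  theta <- mean(block_means)
  loo <- vapply(seq_len(g), function(j) mean(block_means[-j]), numeric(1))
  sqrt((g - 1) / g * sum((loo - mean(loo))^2))
}

# per-site f3 values recomputed directly from the matrix columns
oracle_f3_values <- function(m, A, B, C, transversions_only = TRUE) {
  keep <- !is.na(m[[A]]) & !is.na(m[[B]]) & !is.na(m[[C]])
  if (transversions_only) keep <- keep & m$class == "tv"
  a <- m[[A]][keep]; b <- m[[B]][keep]; cc <- m[[C]][keep]
  v <- (cc - a) * (cc - b)
  nc <- attr(m, "sample_sizes")[[C]]
  if (nc >= 2) v <- v - cc * (1 - cc) / (nc - 1)
  list(values = v, pos = m$pos[keep], seq = m$seq[keep])
}
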