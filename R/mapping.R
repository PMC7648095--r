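#' Build an exact k-mer index over a reference panel
#'
#' Every k-mer of every panel sequence is indexed on both strands (the
#' reverse-complement entry points at the forward-strand coordinate). K-mers
#' containing non-ACGT characters are skipped.
#'
#' @param panel a `reference_panel`.
#' @param k k-mer size, between 8 and 32.
#' @return an object of class `kmer_index` (opaque; valid for the current R
#'   session).
#' @export
build_index <- function(panel, k = 16L) {
  stopifnot(inherits(panel, "reference_panel"))
  if (k < 8 || k > 32) stop("k must lie in [8, 32]")
  seq_tab <- data.frame(
    genome = rep(names(panel$genomes), lengths(panel$genomes)),
    seq_name = unlist(lapply(panel$genomes, names), use.names = FALSE),
    length = unlist(lapply(panel$genomes, nchar), use.names = FALSE),
    stringsAsFactors = FALSE)
  short <- seq_tab$length < k
  if (any(short))
    warning("sequence(s) shorter than k left unindexed: ",
            paste(seq_tab$seq_name[short], collapse = ", "))
  seqs <- unlist(panel$genomes, use.names = FALSE)
  ptr <- cpp_build_index(seqs, as.integer(k))
  structure(list(ptr = ptr, k = as.integer(k), seqs = seq_tab,
                 genomes = names(panel$genomes)),
            class = "kmer_index")
}

#' @export
print.kmer_index <- function(x, ...) {
  cat("<kmer_index> k=", x$k, ", ", nrow(x$seqs), " sequence(s) over ",
      length(x$genomes), " genome(s), ", cpp_index_size(x$ptr),
      " distinct k-mers\n", sep = "")
  invisible(x)
}

#' Look up one k-mer in an index
#'
#' @param index a `kmer_index`.
#' @param kmer literal k-mer string of length `k`.
#' @return data.frame with columns `genome`, `seq_name`, `pos` (0-based
#'   forward coordinate), `strand` (`"+"` for a forward entry, `"-"` for a
#'   reverse-complement entry).
#' @export
index_lookup <- function(index, kmer) {
  hits <- cpp_index_lookup(index$ptr, toupper(kmer))
  data.frame(genome = index$seqs$genome[hits$seq],
             seq_name = index$seqs$seq_name[hits$seq],
             pos = hits$pos,
             strand = c("+", "-")[hits$strand + 1L],
             stringsAsFactors = FALSE)
}

#' Map reads against an indexed panel
#'
#' Candidate loci are collected from exact seed hits of the read's k-mers
#' (taken on a stride, always including the final window) and scored by
#' full-length ungapped comparison. Hits with more than
#' `ceil(max_mismatch_frac * read_length)` mismatches are dropped; any
#' non-ACGT base in read or reference counts as a mismatch. Within each
#' genome a read is flagged unique when its best-scoring locus beats the
#' second best by at least `score_gap` (or it is the only hit); best-score
#' ties at distinct loci are never assigned and leave the read
#' multi-mapping.
#'
#' @param readset a `read_set` (or character vector of sequences).
#' @param index a `kmer_index` from [build_index()].
#' @param max_mismatch_frac maximum mismatch fraction per read.
#' @param score_gap minimum score lead of the best locus for uniqueness.
#' @param mismatch_penalty per-mismatch score penalty
#'   (`score = matches - mismatch_penalty * mismatches`).
#' @param stride seed spacing along the read.
#' @return an object of class `mapping_result` with elements `hits`
#'   (data.table: `read_id`, `genome`, `seq_name`, `start` 0-based,
#'   `strand`, `mismatches`, `score`, `len`), `summary` (per read x genome:
#'   hit count, best/second score, uniqueness flag), `read_ids`, `n_reads`,
#'   and the mapping parameters.
#' @export
map_reads <- function(readset, index, max_mismatch_frac = 0.1,
                      score_gap = 4, mismatch_penalty = 2, stride = 4L) {
  if (is.character(readset))
    readset <- read_set(paste0("read_", seq_along(readset)), readset)
  stopifnot(inherits(readset, "read_set"), inherits(index, "kmer_index"))
  raw <- cpp_map_reads(index$ptr, readset$reads$seq, as.integer(stride),
                       max_mismatch_frac, mismatch_penalty)
  hits <- data.table(
    read_id = readset$reads$id[raw$read],
    genome = index$seqs$genome[raw$seq],
    seq_name = index$seqs$seq_name[raw$seq],
    start = raw$start,
    strand = c("+", "-")[raw$strand + 1L],
    mismatches = raw$mismatches,
    score = raw$score,
    len = nchar(readset$reads$seq)[raw$read])
  summary <- hits[, {
    sc <- sort(score, decreasing = TRUE)
    list(n_hits = .N, best = sc[1],
         second = if (.N > 1) sc[2] else NA_real_,
         n_best = sum(score == sc[1]))
  }, by = .(read_id, genome)]
  summary[, unique_in_genome := n_hits == 1L |
            (n_best == 1L & (best - second) >= score_gap)]
  structure(list(hits = hits, summary = summary, genomes = index$genomes,
                 read_ids = readset$reads$id, n_reads = nrow(readset$reads),
                 params = list(k = index$k, stride = stride,
                               max_mismatch_frac = max_mismatch_frac,
                               score_gap = score_gap,
                               mismatch_penalty = mismatch_penalty)),
            class = "mapping_result")
}

#' @export
print.mapping_result <- function(x, ...) {
  cat("<mapping_result> ", x$n_reads, " reads vs ",
      length(unique(x$hits$genome)), " genome(s); ",
      length(unique(x$hits$read_id)), " reads with >=1 hit\n", sep = "")
  invisible(x)
}

#' Map a single read
#'
#' Convenience wrapper over [map_reads()] for one sequence.
#'
#' @param read a single read sequence.
#' @inheritParams map_reads
#' @param ... passed to [map_reads()].
#' @return a `mapping_result` for the one read.
#' @export
map_read <- function(read, index, ...) {
  stopifnot(length(read) == 1)
  map_reads(read_set("read_1", read), index, ...)
}

#' Best unique placements of reads within one genome
#'
#' Returns one row per read flagged unique-in-genome: its best-scoring hit
#' in that genome.
#'
#' @param mapping a `mapping_result`.
#' @param genome genome name.
#' @return data.table of hits (same columns as `mapping$hits`).
#' @export
unique_hits <- function(mapping, genome) {
  g <- genome
  uniq <- mapping$summary[genome == g & unique_in_genome == TRUE, read_id]
  h <- mapping$hits[genome == g & read_id %in% uniq]
  h[h[, .I[which.max(score)], by = read_id]$V1]
}

#' Remove duplicate placements (PCR/optical clone removal)
#'
#' Hits sharing `(genome, seq_name, start, strand, len)` are collapsed to a
#' single representative: the hit with the fewest mismatches, ties broken by
#' the lexicographically smallest read id. Idempotent.
#'
#' @param hits data.table/data.frame of hits carrying the grouping columns.
#' @return list with `hits` (deduplicated, original column set) and
#'   `n_removed`.
#' @export
remove_duplicates <- function(hits) {
  h <- as.data.table(hits)
  if (!nrow(h)) return(list(hits = h, n_removed = 0L))
  setorder(h, genome, seq_name, start, strand, len, mismatches, read_id)
  keep <- h[, .I[1], by = .(genome, seq_name, start, strand, len)]$V1
  out <- h[sort(keep)]
  list(hits = out, n_removed = nrow(h) - length(keep))
}

#' Endogenous content of a read set with respect to one genome
#'
#' Percentage of retained input reads that map uniquely to the genome after
#' duplicate removal.
#'
#' @param mapping a `mapping_result`.
#' @param readset the mapped `read_set`.
#' @param genome genome name.
#' @return list with `percent` (two decimals), `n_unique` (post-dedup),
#'   `n_reads`, `n_duplicates_removed`.
#' @export
endogenous_content <- function(mapping, readset, genome) {
  if (!n_reads(readset)) stop("empty read set")
  uh <- unique_hits(mapping, genome)
  dd <- remove_duplicates(uh)
  list(percent = round(100 * nrow(dd$hits) / n_reads(readset), 2),
       n_unique = nrow(dd$hits), n_reads = n_reads(readset),
       n_duplicates_removed = dd$n_removed)
}

#' Per-site base counts over one reference sequence
#'
#' Stacks the given (deduplicated) hits on the reference and tallies
#' A/C/G/T counts per site; read Ns contribute nothing. Depth at a site is
#' the sum of its base counts.
#'
#' @param hits hits on a single reference sequence (data.frame with
#'   `read_id`, `seq_name`, `start`, `strand`, `len`).
#' @param readset the `read_set` the hits refer to.
#' @param ref_seq reference sequence string.
#' @param seq_name name of the reference sequence (hits are filtered to it).
#' @return an object of class `pileup`: `seq_name`, `ref`, `counts`
#'   (length x 4 matrix, columns A/C/G/T), `depth`.
#' @export
build_pileup <- function(hits, readset, ref_seq, seq_name) {
  target <- seq_name
  h <- as.data.table(hits)
  h <- h[h$seq_name == target]
  L <- nchar(ref_seq)
  counts <- matrix(0L, nrow = L, ncol = 4,
                   dimnames = list(NULL, DNA_BASES))
  if (nrow(h)) {
    reads <- readset$reads$seq[match(h$read_id, readset$reads$id)]
    oriented <- ifelse(h$strand == "-", revcomp(reads), reads)
    pos <- sequence(h$len) + rep(h$start, h$len)   # 1-based site index
    base <- unlist(strsplit(oriented, "", fixed = TRUE), use.names = FALSE)
    ok <- base %in% DNA_BASES & pos >= 1 & pos <= L
    tab <- data.table(pos = pos[ok], base = base[ok])[, .N, by = .(pos, base)]
    counts[cbind(tab$pos, match(tab$base, DNA_BASES))] <- tab$N
  }
  structure(list(seq_name = seq_name, ref = ref_seq, counts = counts,
                 depth = as.integer(rowSums(counts))),
            class = "pileup")
}

#' Construct a pileup from explicit base counts
#'
#' Useful for building small worked examples by hand; [build_pileup()] is
#' the production path.
#'
#' @param counts integer matrix, one row per reference site, columns
#'   A/C/G/T.
#' @param ref optional reference string (defaults to all-N of matching
#'   length).
#' @param seq_name sequence name.
#' @return a `pileup`.
#' @export
pileup <- function(counts, ref = strrep("N", nrow(counts)),
                   seq_name = "seq") {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == 4, all(counts >= 0),
            nchar(ref) == nrow(counts))
  colnames(counts) <- DNA_BASES
  structure(list(seq_name = seq_name, ref = ref, counts = counts,
                 depth = as.integer(rowSums(counts))),
            class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat("<pileup> ", x$seq_name, ": ", length(x$depth), " sites, mean depth ",
      round(mean(x$depth), 2), "\n", sep = "")
  invisible(x)
}

#' Coverage summary of a pileup
#'
#' @param pileup a `pileup`.
#' @param depths depth thresholds to report `fraction(depth < d)` for.
#' @return list with `mean_depth` (total aligned bases / reference length),
#'   `pct_zero` (percent of sites with zero depth) and `pct_below` (named
#'   percent vector, one entry per threshold). `fraction(depth = 0)` equals
#'   `fraction(depth < 1)` by construction.
#' @export
coverage_stats <- function(pileup, depths = c(1, 3)) {
  d <- pileup$depth
  list(mean_depth = sum(d) / length(d),
       pct_zero = 100 * mean(d == 0),
       pct_below = stats::setNames(
         vapply(depths, function(k) 100 * mean(d < k), numeric(1)),
         paste0("d", depths)))
}
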