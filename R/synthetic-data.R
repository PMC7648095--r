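#' Simulation settings for ancient-DNA-like reads
#'
#' Bundles the parameters of the read simulator. Defaults emulate a degraded
#' genome-skim library: short fragments (mean 59 bp), elevated terminal C->T
#' deamination (10% at the first 5' position, decaying exponentially along
#' the read), and a configurable endogenous fraction.
#'
#' @param seed integer RNG seed; the simulator is byte-deterministic given it.
#' @param n_reads number of reads to draw.
#' @param mean_len,len_sd mean and standard deviation (bp) of the fragment
#'   length distribution (normal, truncated below at `min_len` and above at
#'   the source sequence length).
#' @param min_len minimum fragment length (bp).
#' @param endogenous_frac fraction of reads drawn from the donor genome (the
#'   rest come from `contaminant`); each read is an independent Bernoulli
#'   draw, so the realized count is binomial.
#' @param damage_p0 probability that a C at the first 5' position reads as T
#'   (and, symmetrically, a G at the last 3' position as A).
#' @param damage_lambda per-position exponential decay rate of the damage
#'   probability: position `i` (0-based) is damaged with probability
#'   `damage_p0 * exp(-damage_lambda * i)`.
#' @param contaminant name of the panel genome supplying non-endogenous
#'   reads; default (`NULL`) picks the panel genome most divergent from the
#'   donor.
#' @param copy_number optional named numeric vector of per-sequence copy
#'   numbers; a sequence's sampling weight is its length times its copy
#'   number (e.g. `c(chrX = 0.5)` halves X-chromosome dosage for a male).
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_reads = 10000L, mean_len = 59,
                              len_sd = 12, min_len = 30,
                              endogenous_frac = 0.5, damage_p0 = 0.10,
                              damage_lambda = 0.3, contaminant = NULL,
                              copy_number = NULL) {
  stopifnot(n_reads >= 1, min_len >= 1, mean_len >= min_len, len_sd >= 0,
            damage_lambda >= 0)
  if (endogenous_frac < 0 || endogenous_frac > 1)
    stop("endogenous_frac must lie in [0, 1]")
  if (damage_p0 < 0 || damage_p0 > 1)
    stop("damage_p0 must lie in [0, 1]")
  structure(list(seed = as.integer(seed), n_reads = as.integer(n_reads),
                 mean_len = mean_len, len_sd = len_sd, min_len = min_len,
                 endogenous_frac = endogenous_frac, damage_p0 = damage_p0,
                 damage_lambda = damage_lambda, contaminant = contaminant,
                 copy_number = copy_number),
            class = "simulation_config")
}

validate_divergence_matrix <- function(m, n_genomes) {
  if (!is.matrix(m) || nrow(m) != n_genomes || ncol(m) != n_genomes)
    stop("divergence_matrix must be a ", n_genomes, " x ", n_genomes, " matrix")
  if (!isTRUE(all.equal(m, t(m))))
    stop("divergence_matrix must be symmetric")
  if (any(diag(m) != 0))
    stop("divergence_matrix must have a zero diagonal")
  if (any(m < 0) || any(m >= 0.75))
    stop("divergence fractions must lie in [0, 0.75)")
  invisible(m)
}

# substitute exactly round(frac * length) sites, drawn without replacement,
# each replaced by a base drawn uniformly from the three alternatives
mutate_sequence <- function(chars, frac) {
  L <- length(chars)
  m <- round(frac * L)
  if (m == 0) return(chars)
  idx <- sample.int(L, m)
  alt <- rbind(c("C", "G", "T"), c("A", "G", "T"), c("A", "C", "T"),
               c("A", "C", "G"))
  chars[idx] <- alt[cbind(match(chars[idx], DNA_BASES),
                          sample.int(3L, m, replace = TRUE))]
  chars
}

#' Build a panel of related reference genomes
#'
#' Genome 1 is drawn uniformly over A/C/G/T; every further genome is derived
#' from genome 1 by substituting exactly `round(d * length)` sites (positions
#' without replacement, substitute base uniform over the three alternatives),
#' where `d` is that genome's entry in the first row of `divergence_matrix`.
#' Realized divergence to genome 1 is therefore exact by construction;
#' divergence between two derived genomes is emergent (approximately
#' `d_i + d_j` minus coincident hits).
#'
#' @param base_length sequence length in bp (used for every sequence unless
#'   `seq_lengths` is given).
#' @param n_genomes number of genomes in the panel.
#' @param divergence_matrix symmetric matrix with zero diagonal; entries in
#'   `[0, 0.75)`. Only the first row drives the construction; the full matrix
#'   is validated so callers state their intent explicitly.
#' @param seed integer RNG seed.
#' @param genome_names,taxa optional genome names and taxon labels.
#' @param seq_lengths optional named integer vector giving one entry per
#'   sequence (chromosome/organelle) of each genome, e.g.
#'   `c(chrX = 50000, chr8 = 54000)`.
#' @return an object of class `reference_panel`: a named list of genomes,
#'   each a named character vector of sequences, plus taxon labels.
#' @export
make_reference_panel <- function(base_length, n_genomes, divergence_matrix,
                                 seed = 1L, genome_names = NULL, taxa = NULL,
                                 seq_lengths = NULL) {
  if (is.null(seq_lengths)) seq_lengths <- c(seq1 = as.integer(base_length))
  if (is.null(names(seq_lengths)))
    names(seq_lengths) <- paste0("seq", seq_along(seq_lengths))
  validate_divergence_matrix(divergence_matrix, n_genomes)
  if (is.null(genome_names)) genome_names <- paste0("G", seq_len(n_genomes))
  stopifnot(!anyDuplicated(genome_names), !anyDuplicated(names(seq_lengths)),
            all(seq_lengths > 0))
  if (is.null(taxa)) taxa <- genome_names
  with_seed(seed, {
    base <- lapply(seq_lengths, function(L)
      sample(DNA_BASES, L, replace = TRUE))
    genomes <- vector("list", n_genomes)
    names(genomes) <- genome_names
    genomes[[1]] <- vapply(base, paste, character(1), collapse = "")
    for (g in seq_len(n_genomes)[-1]) {
      d <- divergence_matrix[1, g]
      genomes[[g]] <- vapply(base, function(chars)
        paste(mutate_sequence(chars, d), collapse = ""), character(1))
    }
    structure(list(genomes = genomes,
                   taxa = stats::setNames(taxa, genome_names)),
              class = "reference_panel")
  })
}

#' Construct a reference panel from explicit sequences
#'
#' @param genomes named list; each element a named character vector of
#'   sequences over A/C/G/T/N.
#' @param taxa optional taxon labels (defaults to genome names).
#' @return a `reference_panel`.
#' @export
reference_panel <- function(genomes, taxa = NULL) {
  stopifnot(is.list(genomes), length(genomes) >= 1,
            !is.null(names(genomes)), !anyDuplicated(names(genomes)))
  for (g in names(genomes)) {
    s <- genomes[[g]]
    if (is.null(names(s)) || anyDuplicated(names(s)))
      stop("sequences of genome '", g, "' must carry unique names")
    if (any(nchar(s) == 0)) stop("zero-length sequence in genome '", g, "'")
  }
  if (is.null(taxa)) taxa <- names(genomes)
  structure(list(genomes = genomes,
                 taxa = stats::setNames(taxa, names(genomes))),
            class = "reference_panel")
}

#' @export
print.reference_panel <- function(x, ...) {
  cat("<reference_panel> ", length(x$genomes), " genome(s)\n", sep = "")
  for (g in names(x$genomes)) {
    s <- x$genomes[[g]]
    cat(sprintf("  %s (%s): %d sequence(s), %s bp total\n", g, x$taxa[[g]],
                length(s), format(sum(nchar(s)), big.mark = ",")))
  }
  invisible(x)
}

#' Generate a clade-structured panel of aligned mitogenome haplotypes
#'
#' An ancestor sequence is drawn uniformly; each clade receives a founder
#' mutated from the ancestor at `between_clade_div`, and each haplotype is
#' mutated from its clade founder at `within_clade_div`. Haplotypes within a
#' clade are therefore closer to each other than to any other clade when
#' `between_clade_div` sufficiently exceeds `within_clade_div`. A newick tree
#' of the generating topology is recorded.
#'
#' @param n_clades number of clades (at least 2).
#' @param haplotypes_per_clade haplotypes per clade.
#' @param between_clade_div,within_clade_div substitution fractions ancestor
#'   -> clade founder and founder -> haplotype; `between > within >= 0`.
#' @param length alignment length (bp).
#' @param seed integer RNG seed.
#' @return an object of class `clade_panel`: aligned haplotypes (named
#'   character vector), clade label per haplotype, and the generating tree
#'   in newick.
#' @export
make_clade_panel <- function(n_clades, haplotypes_per_clade,
                             between_clade_div, within_clade_div, length,
                             seed = 1L) {
  if (n_clades < 2) stop("n_clades must be at least 2")
  stopifnot(haplotypes_per_clade >= 1, length >= 1,
            within_clade_div >= 0, between_clade_div > within_clade_div,
            between_clade_div < 0.75)
  L <- as.integer(length)
  with_seed(seed, {
    anc <- sample(DNA_BASES, L, replace = TRUE)
    haps <- character(0)
    clades <- character(0)
    clade_newick <- character(n_clades)
    for (ci in seq_len(n_clades)) {
      founder <- mutate_sequence(anc, between_clade_div)
      labs <- sprintf("clade%d_h%d", ci, seq_len(haplotypes_per_clade))
      hs <- vapply(seq_len(haplotypes_per_clade), function(hi)
        paste(mutate_sequence(founder, within_clade_div), collapse = ""),
        character(1))
      haps <- c(haps, stats::setNames(hs, labs))
      clades <- c(clades, stats::setNames(rep(paste0("clade", ci),
                                              haplotypes_per_clade), labs))
      clade_newick[ci] <- if (haplotypes_per_clade == 1)
        sprintf("%s:%g", labs[1], between_clade_div)
      else
        sprintf("(%s):%g",
                paste(sprintf("%s:%g", labs, within_clade_div), collapse = ","),
                between_clade_div)
    }
    tree <- paste0("(", paste(clade_newick, collapse = ","), ");")
    structure(list(alignment = haps, clades = clades, tree = tree),
              class = "clade_panel")
  })
}

#' @export
print.clade_panel <- function(x, ...) {
  cat("<clade_panel> ", length(x$alignment), " haplotypes, ",
      nchar(x$alignment[[1]]), " aligned sites, ",
      length(unique(x$clades)), " clades\n", sep = "")
  print(table(x$clades))
  invisible(x)
}

# 5' C->T damage along a vector of read-oriented sequences; returns the
# modified sequences and per-read flip counts
apply_ct_damage <- function(seqs, p0, lambda) {
  n_flip <- integer(length(seqs))
  if (p0 <= 0 || !length(seqs)) return(list(seqs = seqs, n_flip = n_flip))
  lens <- nchar(seqs)
  for (i in seq_len(max(lens))) {
    p <- p0 * exp(-lambda * (i - 1))
    if (p < 1e-12) break
    cand <- which(lens >= i & substr(seqs, i, i) == "C")
    if (!length(cand)) next
    flip <- cand[stats::runif(length(cand)) < p]
    if (length(flip)) {
      substr(seqs[flip], i, i) <- "T"
      n_flip[flip] <- n_flip[flip] + 1L
    }
  }
  list(seqs = seqs, n_flip = n_flip)
}

#' Simulate an ancient-DNA-like read set from a reference panel
#'
#' Fragments are sampled from the donor genome (or the contaminant genome,
#' per-read Bernoulli with probability `1 - endogenous_frac`), with lengths
#' from a truncated normal, uniform start positions and uniform strand.
#' Deamination is applied after fragment extraction, in read orientation:
#' each C at 0-based 5' position `i` flips to T with probability
#' `damage_p0 * exp(-damage_lambda * i)`, and symmetrically each G at 3'
#' position `j` flips to A (double-stranded model). Base qualities are a
#' constant Q30. Ground-truth labels (donor, source sequence, 0-based start,
#' strand, number of damaged sites) are recorded per read.
#'
#' @param panel a `reference_panel`.
#' @param donor name of the donor genome in `panel`.
#' @param config a [simulation_config()].
#' @return an object of class `read_set`: `$reads` (data.frame with columns
#'   `id`, `seq`, `qual`) and `$truth` (data.frame of per-read truth labels).
#' @export
simulate_reads <- function(panel, donor, config) {
  stopifnot(inherits(panel, "reference_panel"),
            inherits(config, "simulation_config"))
  if (!donor %in% names(panel$genomes))
    stop("donor genome '", donor, "' is not in the panel")
  contaminant <- config$contaminant
  if (is.null(contaminant)) contaminant <- most_divergent_genome(panel, donor)
  if (!contaminant %in% names(panel$genomes))
    stop("contaminant genome '", contaminant, "' is not in the panel")
  n <- config$n_reads
  if (n <= 0) stop("n_reads must be positive")

  with_seed(config$seed, {
    endo <- stats::runif(n) < config$endogenous_frac
    src_genome <- ifelse(endo, donor, contaminant)

    lens <- pmax(config$min_len,
                 round(stats::rnorm(n, config$mean_len, config$len_sd)))
    seqs <- character(n)
    src_seq <- character(n)
    starts <- integer(n)
    strands <- sample(c("+", "-"), n, replace = TRUE)

    for (g in unique(src_genome)) {
      gi <- which(src_genome == g)
      gseqs <- panel$genomes[[g]]
      w <- nchar(gseqs)
      if (!is.null(config$copy_number)) {
        cn <- config$copy_number[names(gseqs)]
        cn[is.na(cn)] <- 1
        w <- w * cn
      }
      pick <- sample.int(length(gseqs), length(gi), replace = TRUE,
                         prob = w / sum(w))
      for (s in unique(pick)) {
        si <- gi[pick == s]
        L <- nchar(gseqs[[s]])
        li <- pmin(lens[si], L)
        lens[si] <- li
        st <- floor(stats::runif(length(si)) * (L - li + 1))
        starts[si] <- as.integer(st)
        src_seq[si] <- names(gseqs)[s]
        seqs[si] <- substring(gseqs[[s]], st + 1, st + li)
      }
    }
    minus <- strands == "-"
    if (any(minus)) seqs[minus] <- revcomp(seqs[minus])

    # 5' C->T, then 3' G->A via the reverse-complement identity
    d5 <- apply_ct_damage(seqs, config$damage_p0, config$damage_lambda)
    d3 <- apply_ct_damage(revcomp(d5$seqs), config$damage_p0,
                          config$damage_lambda)
    seqs <- revcomp(d3$seqs)
    n_damaged <- d5$n_flip + d3$n_flip

    ids <- sprintf("read_%06d", seq_len(n))
    reads <- data.frame(id = ids, seq = seqs,
                        qual = strrep("?", nchar(seqs)))
    truth <- data.frame(id = ids, donor = src_genome, seq_name = src_seq,
                        start = starts, strand = strands,
                        n_damaged = n_damaged)
    structure(list(reads = reads, truth = truth), class = "read_set")
  })
}

# panel genome with the largest Hamming distance to the donor, compared over
# sequences of matching name and length (falls back to the last non-donor
# genome when nothing is comparable)
most_divergent_genome <- function(panel, donor) {
  others <- setdiff(names(panel$genomes), donor)
  if (!length(others)) return(donor)
  dref <- panel$genomes[[donor]]
  divs <- vapply(others, function(g) {
    gs <- panel$genomes[[g]]
    shared <- intersect(names(dref), names(gs))
    shared <- shared[nchar(dref[shared]) == nchar(gs[shared])]
    if (!length(shared)) return(NA_real_)
    mism <- sum(vapply(shared, function(s)
      hamming_mismatches(dref[[s]], gs[[s]]), numeric(1)))
    mism / sum(nchar(dref[shared]))
  }, numeric(1))
  if (all(is.na(divs))) return(others[length(others)])
  names(which.max(divs))
}

# mismatch count between two equal-length strings
hamming_mismatches <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(utf8ToInt(a) != utf8ToInt(b))
}

#' Construct a read set from explicit reads
#'
#' @param id,seq,qual character vectors of equal length; `qual` defaults to
#'   constant Q30.
#' @param truth optional truth data.frame as produced by [simulate_reads()].
#' @return a `read_set`.
#' @export
read_set <- function(id, seq, qual = strrep("?", nchar(seq)), truth = NULL) {
  stopifnot(length(id) == length(seq), length(seq) == length(qual))
  if (anyDuplicated(id)) stop("read ids must be unique")
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad))
    stop("sequence/quality length mismatch for read id '", id[bad[1]], "'")
  structure(list(reads = data.frame(id = id, seq = seq, qual = qual),
                 truth = truth), class = "read_set")
}

#' @export
print.read_set <- function(x, ...) {
  n <- nrow(x$reads)
  cat("<read_set> ", n, " reads", sep = "")
  if (n) cat(", mean length ", round(mean(nchar(x$reads$seq)), 1), " bp",
             sep = "")
  cat(if (is.null(x$truth)) ", no truth labels\n" else ", with truth labels\n")
  invisible(x)
}

#' Number of reads in a read set
#' @param x a `read_set`.
#' @return integer count.
#' @export
n_reads <- function(x) nrow(x$reads)
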