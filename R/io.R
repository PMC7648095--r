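#' Write reads to a FASTQ file (Sanger/Phred+33)
#'
#' Plain four-line records; output is byte-deterministic for a given read
#' set. Truth labels, if present, are not written here — use
#' [write_truth()] for the sidecar table so the FASTQ stays standard.
#'
#' @param readset a `read_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(readset, path) {
  stopifnot(inherits(readset, "read_set"))
  r <- readset$reads
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (nrow(r))
    writeLines(as.vector(rbind(paste0("@", r$id), r$seq, "+", r$qual)),
               con, sep = "\n")
  invisible(path)
}

#' Read a FASTQ file into a read set
#'
#' Validates the four-line record structure and reports malformed records
#' with their line numbers; a sequence/quality length mismatch is reported
#' with the offending read id.
#'
#' @param path FASTQ file (uncompressed).
#' @param truth_path optional sidecar truth TSV written by [write_truth()].
#' @return a `read_set`.
#' @export
read_fastq <- function(path, truth_path = NULL) {
  lines <- readLines(path)
  if (!length(lines)) {
    warning("empty FASTQ file: ", path)
    return(read_set(character(0), character(0), character(0)))
  }
  if (length(lines) %% 4 != 0)
    stop("truncated FASTQ record at line ", length(lines) + 1, " of ", path)
  hdr <- lines[seq(1, length(lines), by = 4)]
  seqs <- lines[seq(2, length(lines), by = 4)]
  plus <- lines[seq(3, length(lines), by = 4)]
  qual <- lines[seq(4, length(lines), by = 4)]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad))
    stop("malformed FASTQ header at line ", (bad[1] - 1) * 4 + 1,
         " of ", path)
  bad <- which(!startsWith(plus, "+"))
  if (length(bad))
    stop("malformed FASTQ separator at line ", (bad[1] - 1) * 4 + 3,
         " of ", path)
  ids <- sub("\\s.*$", "", substring(hdr, 2))
  bad <- which(nchar(seqs) != nchar(qual))
  if (length(bad))
    stop("sequence/quality length mismatch for read id '", ids[bad[1]],
         "' at line ", (bad[1] - 1) * 4 + 2, " of ", path)
  if (anyDuplicated(ids))
    stop("duplicate read id '", ids[anyDuplicated(ids)], "' in ", path)
  truth <- if (!is.null(truth_path)) read_truth(truth_path) else NULL
  read_set(ids, seqs, qual, truth = truth)
}

#' Write / read the per-read ground-truth sidecar table
#'
#' @param readset a `read_set` carrying truth labels.
#' @param path TSV file.
#' @return `path` (write) or the truth data.frame (read), invisibly for the
#'   writer.
#' @export
write_truth <- function(readset, path) {
  stopifnot(inherits(readset, "read_set"))
  if (is.null(readset$truth)) stop("read set carries no truth labels")
  utils::write.table(readset$truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Write sequences to FASTA
#'
#' Accepts a named character vector, a `reference_panel` (headers
#' `genome|sequence`), or a `clade_panel` (headers are haplotype names).
#'
#' @param x sequences to write.
#' @param path output file.
#' @param ... unused.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, ...) UseMethod("write_fasta")

#' @export
write_fasta.character <- function(x, path, ...) {
  stopifnot(!is.null(names(x)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(x), path)
  invisible(path)
}

#' @export
write_fasta.reference_panel <- function(x, path, ...) {
  seqs <- unlist(lapply(names(x$genomes), function(g)
    stats::setNames(x$genomes[[g]],
                    paste0(g, "|", names(x$genomes[[g]])))))
  write_fasta.character(seqs, path)
}

#' @export
write_fasta.clade_panel <- function(x, path, ...) {
  write_fasta.character(x$alignment, path)
}

#' Read a FASTA file
#'
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  out <- as.character(s)
  names(out) <- sub("\\s.*$", "", names(s))
  out
}

#' Rebuild a reference panel from a `genome|sequence` FASTA
#'
#' @param path FASTA written by [write_fasta()] on a `reference_panel`.
#' @param sep separator between genome and sequence name in headers.
#' @return a `reference_panel`.
#' @export
panel_from_fasta <- function(path, sep = "|") {
  seqs <- read_fasta(path)
  parts <- strsplit(names(seqs), sep, fixed = TRUE)
  if (any(lengths(parts) != 2))
    stop("FASTA headers must have the form genome", sep, "sequence")
  gnames <- vapply(parts, `[`, character(1), 1)
  snames <- vapply(parts, `[`, character(1), 2)
  genomes <- lapply(split(seq_along(seqs), gnames)[unique(gnames)],
                    function(i) stats::setNames(unname(seqs[i]), snames[i]))
  reference_panel(genomes)
}

#' Rebuild a clade panel from a FASTA alignment and a clade table
#'
#' @param fasta aligned haplotype FASTA.
#' @param clades_tsv two-column TSV (haplotype, clade).
#' @param tree optional newick file with the reference topology.
#' @return a `clade_panel`.
#' @export
clade_panel_from_files <- function(fasta, clades_tsv, tree = NULL) {
  aln <- read_fasta(fasta)
  if (length(unique(nchar(aln))) != 1)
    stop("aligned haplotypes must all have the same length")
  cl <- utils::read.table(clades_tsv, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  clades <- stats::setNames(cl[[2]], cl[[1]])
  if (!all(names(aln) %in% names(clades)))
    stop("every haplotype needs exactly one clade label")
  nwk <- if (!is.null(tree)) paste(readLines(tree), collapse = "") else NULL
  structure(list(alignment = aln, clades = clades[names(aln)], tree = nwk),
            class = "clade_panel")
}

#' Export mapped hits as a minimal SAM file
#'
#' Unsorted single-end records with flags 0/16 and an NM tag; provided for
#' interoperability with samtools-style tooling, not used internally.
#'
#' @param hits data.frame of hits (columns `read_id`, `seq_name`, `start`
#'   0-based, `strand`, `mismatches`).
#' @param readset the `read_set` the hits refer to.
#' @param panel the `reference_panel` mapped against.
#' @param genome genome whose sequences form the header.
#' @param path output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(hits, readset, panel, genome, path) {
  seqs <- panel$genomes[[genome]]
  if (is.null(seqs)) stop("genome '", genome, "' is not in the panel")
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqs), nchar(seqs)))
  r <- readset$reads[match(hits$read_id, readset$reads$id), ]
  flag <- ifelse(hits$strand == "-", 16L, 0L)
  seq_out <- ifelse(hits$strand == "-", revcomp(r$seq), r$seq)
  qual_out <- ifelse(hits$strand == "-",
                     vapply(strsplit(r$qual, ""), function(q)
                       paste(rev(q), collapse = ""), character(1)),
                     r$qual)
  rec <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s\tNM:i:%d",
                 hits$read_id, flag, hits$seq_name, hits$start + 1L,
                 nchar(r$seq), seq_out, qual_out, hits$mismatches)
  writeLines(c(hdr, rec), path)
  invisible(path)
}
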