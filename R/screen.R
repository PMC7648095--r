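#' Competitive screen of reads across all panel genomes
#'
#' Classifies every mapped (read, genome) pair into the four
#' FastQ-Screen-style categories: A — maps uniquely and to this genome only;
#' B — maps to multiple loci of this genome only; C — maps uniquely in this
#' genome but also somewhere in at least one other genome; D — maps to
#' multiple loci here and also elsewhere. Unmapped reads are counted once
#' globally. Percentages are taken over all retained input reads.
#'
#' @param mapping a `mapping_result` computed against the full panel with a
#'   single parameter set.
#' @return an object of class `screen_table`: per-genome counts and
#'   percentages of A-D, the one-genome-only share (A+B) and total mapped
#'   share, plus attributes `n_reads` and `n_unmapped`.
#' @export
screen_reads <- function(mapping) {
  stopifnot(inherits(mapping, "mapping_result"))
  s <- data.table::copy(mapping$summary)
  n_total <- mapping$n_reads
  all_genomes <- mapping$genomes %||% unique(s$genome)
  tab <- data.frame(genome = all_genomes, n_A = 0L, n_B = 0L, n_C = 0L,
                    n_D = 0L, n_mapped = 0L, stringsAsFactors = FALSE)
  if (nrow(s)) {
    s[, n_genomes := .N, by = read_id]
    s[, category := data.table::fcase(
      unique_in_genome & n_genomes == 1L, "A",
      !unique_in_genome & n_genomes == 1L, "B",
      unique_in_genome & n_genomes > 1L, "C",
      default = "D")]
    agg <- s[, .(n_A = sum(category == "A"), n_B = sum(category == "B"),
                 n_C = sum(category == "C"), n_D = sum(category == "D"),
                 n_mapped = .N), by = genome]
    idx <- match(agg$genome, tab$genome)
    cols <- c("n_A", "n_B", "n_C", "n_D", "n_mapped")
    for (col in cols) tab[[col]][idx] <- agg[[col]]
  }
  for (col in c("A", "B", "C", "D")) {
    tab[[paste0("pct_", col)]] <- 100 * tab[[paste0("n_", col)]] / n_total
  }
  tab$n_one_genome_only <- tab$n_A + tab$n_B
  tab$pct_one_genome_only <- 100 * tab$n_one_genome_only / n_total
  tab$pct_mapped <- 100 * tab$n_mapped / n_total
  n_mapped_reads <- if (nrow(s)) length(unique(s$read_id)) else 0L
  structure(tab,
            n_reads = n_total, n_unmapped = n_total - n_mapped_reads,
            class = c("screen_table", "data.frame"))
}

#' @export
print.screen_table <- function(x, digits = 2, ...) {
  cat("<screen_table> ", attr(x, "n_reads"), " reads, ",
      attr(x, "n_unmapped"), " unmapped\n", sep = "")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Species assignment from a screen table
#'
#' The candidate is the genome with the highest one-genome-only percentage
#' (categories A+B). It is assigned when its lead over the runner-up is at
#' least `min_margin` percentage points, otherwise the call is
#' `"ambiguous"`. Both the one-genome-only and the total-mapped rankings are
#' reported.
#'
#' @param table a `screen_table` over at least two genomes.
#' @param min_margin minimum lead, in percentage points.
#' @return list with `assigned` (genome name or `"ambiguous"`), `margin`,
#'   `min_margin`, and `ranking` (data.frame sorted by one-genome-only
#'   share).
#' @export
assign_species <- function(table, min_margin = 2) {
  stopifnot(inherits(table, "screen_table"))
  if (nrow(table) < 2) stop("need at least two screened genomes")
  ord <- order(-table$pct_one_genome_only, table$genome)
  rk <- data.frame(genome = table$genome[ord],
                   pct_one_genome_only = table$pct_one_genome_only[ord],
                   pct_mapped = table$pct_mapped[ord])
  margin <- rk$pct_one_genome_only[1] - rk$pct_one_genome_only[2]
  assigned <- if (rk$pct_one_genome_only[1] <= 0 || margin < min_margin)
    "ambiguous" else rk$genome[1]
  list(assigned = assigned, margin = margin, min_margin = min_margin,
       ranking = rk)
}

#' Concordance check between nuclear and mitochondrial species screens
#'
#' A conplastic or hybrid individual carries the mitochondrial genome of one
#' species with the nuclear genome of another, so a discordant pair of
#' screens is flagged for an f3 admixture follow-up.
#'
#' @param nuclear,mito either `screen_table`s (assigned internally with
#'   `min_margin`) or assignment lists from [assign_species()].
#' @param min_margin margin used when tables are passed.
#' @return list with `status` (`"concordant"`, `"discordant"` or
#'   `"indeterminate"`), the two assignments, and a human-readable `note`.
#' @export
conplastic_check <- function(nuclear, mito, min_margin = 2) {
  as_assignment <- function(x)
    if (inherits(x, "screen_table")) assign_species(x, min_margin) else x
  na <- as_assignment(nuclear)
  ma <- as_assignment(mito)
  if (identical(na$assigned, "ambiguous") ||
      identical(ma$assigned, "ambiguous")) {
    status <- "indeterminate"
    note <- "at least one screen is ambiguous"
  } else if (identical(na$assigned, ma$assigned)) {
    status <- "concordant"
    note <- sprintf("nuclear and mitochondrial screens both assign %s",
                    na$assigned)
  } else {
    status <- "discordant"
    note <- sprintf(paste0("mito assigns %s but nuclear assigns %s - ",
                           "possible conplastic/hybrid; run f3"),
                    ma$assigned, na$assigned)
  }
  list(status = status, nuclear = na$assigned, mito = ma$assigned,
       note = note)
}
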