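#' Majority-rule consensus with a minimum site-depth mask
#'
#' Per site: depth below `min_depth` gives `N`; otherwise the strict
#' majority base is called, with exact ties masked to `N` (default policy).
#' The output has reference length: no insertions are called by the
#' ungapped mapper, and deletions appear as depth gaps, hence `N`.
#'
#' @param pileup a `pileup` over one reference sequence.
#' @param min_depth minimum site depth to call a base.
#' @param tie_policy only `"N"` is implemented: exact count ties are
#'   masked rather than resolved to an IUPAC code, so downstream distance
#'   computation can treat `N` uniformly as missing.
#' @return an object of class `consensus_seq`: `seq` (string over ACGTN),
#'   `depth`, `min_depth`, `missing_frac`, and the mask decomposition
#'   (`n_low_depth`, `n_tie_masked`).
#' @export
call_consensus <- function(pileup, min_depth = 1L, tie_policy = "N") {
  stopifnot(inherits(pileup, "pileup"))
  tie_policy <- match.arg(tie_policy, "N")
  counts <- pileup$counts
  depth <- pileup$depth
  L <- length(depth)
  if (all(depth == 0)) warning("empty pileup: consensus is all N")
  maxc <- do.call(pmax, as.data.frame(counts))
  n_max <- rowSums(counts == maxc)
  best <- max.col(counts, ties.method = "first")
  callable <- depth >= min_depth
  tie <- callable & n_max > 1L
  out <- rep("N", L)
  ok <- callable & !tie
  out[ok] <- DNA_BASES[best[ok]]
  structure(list(seq = paste(out, collapse = ""), depth = depth,
                 min_depth = as.integer(min_depth),
                 missing_frac = mean(out == "N"),
                 n_low_depth = sum(!callable),
                 n_tie_masked = sum(tie)),
            class = "consensus_seq")
}

#' @export
print.consensus_seq <- function(x, ...) {
  cat("<consensus_seq> ", nchar(x$seq), " bp at min_depth=", x$min_depth,
      "; ", fmt_pct(100 * x$missing_frac), " N (",
      x$n_low_depth, " low-depth + ", x$n_tie_masked, " tie-masked)\n",
      sep = "")
  invisible(x)
}

#' Consensus and coverage summary over depth thresholds
#'
#' Reports the mean depth, the percentage of zero-depth sites, the
#' percentage of sites below each threshold, and the missing fraction of
#' the consensus called at each threshold. Optionally writes the consensus
#' variants to FASTA (headers record `min_depth` and %N).
#'
#' @param pileup a `pileup`.
#' @param depths depth thresholds (the classical "with and without
#'   filtering" pair is `c(1, 3)`).
#' @param fasta optional output FASTA path for the consensus variants.
#' @param name sequence name stem for FASTA headers.
#' @return list with `mean_depth`, `pct_zero`, a data.frame `by_depth`
#'   (`min_depth`, `pct_below`, `pct_N`), and the `consensus_seq` objects.
#' @export
consensus_report <- function(pileup, depths = c(1, 3), fasta = NULL,
                             name = "consensus") {
  cs <- coverage_stats(pileup, depths)
  cons <- lapply(depths, function(d) call_consensus(pileup, min_depth = d))
  by_depth <- data.frame(min_depth = depths,
                         pct_below = unname(cs$pct_below),
                         pct_N = vapply(cons, function(x)
                           100 * x$missing_frac, numeric(1)))
  if (!is.null(fasta)) {
    seqs <- stats::setNames(
      vapply(cons, `[[`, character(1), "seq"),
      sprintf("%s_d%d pctN=%.2f", name, depths, by_depth$pct_N))
    write_fasta(seqs, fasta)
  }
  list(mean_depth = cs$mean_depth, pct_zero = cs$pct_zero,
       by_depth = by_depth, consensus = stats::setNames(cons,
                                                        paste0("d", depths)))
}
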