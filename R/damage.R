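#' Positional deamination profile from uniquely mapped reads
#'
#' Post-mortem cytosine deamination reads as C->T mismatches concentrated at
#' 5' fragment ends (and G->A at 3' ends under a double-stranded library).
#' For every unique, deduplicated hit the read is compared to the reference
#' at its mapped coordinates (minus-strand hits are handled in read
#' orientation, i.e. against the reverse-complemented reference window) and
#' ref-C / C->T events are tallied per 5' offset, ref-G / G->A per 3'
#' offset. Reads shorter than `2 * max_pos` contribute to both windows with
#' overlap; all other mismatch classes are pooled into a background rate.
#'
#' @param hits deduplicated unique hits (e.g. [unique_hits()] then
#'   [remove_duplicates()]), restricted to one genome.
#' @param readset the mapped `read_set`.
#' @param panel the `reference_panel` mapped against.
#' @param genome genome the hits refer to.
#' @param max_pos number of terminal positions profiled from each end.
#' @return an object of class `damage_profile`: data.frames `five_prime`
#'   (`pos` 0-based, `ref_c`, `ct`, `freq`), `three_prime` (`pos`, `ref_g`,
#'   `ga`, `freq`), `background_rate` (non-CT/GA mismatch frequency),
#'   `length_stats` (mean/median/sd/n). Positions with zero denominator have
#'   `freq = NA`.
#' @export
estimate_damage <- function(hits, readset, panel, genome, max_pos = 25L) {
  if (is.list(hits) && !is.data.frame(hits) && !is.null(hits$hits))
    hits <- hits$hits
  h <- as.data.frame(hits)
  if (!nrow(h)) stop("no unique hits to profile")
  gseqs <- panel$genomes[[genome]]
  if (is.null(gseqs)) stop("genome '", genome, "' is not in the panel")

  reads <- readset$reads$seq[match(h$read_id, readset$reads$id)]
  refwin <- character(nrow(h))
  for (s in unique(h$seq_name)) {
    i <- which(h$seq_name == s)
    refwin[i] <- substring(gseqs[[s]], h$start[i] + 1, h$start[i] + h$len[i])
  }
  # read orientation: flip the reference window for minus-strand hits
  minus <- h$strand == "-"
  refwin[minus] <- revcomp(refwin[minus])

  lens <- nchar(reads)
  ct <- ref_c <- ga <- ref_g <- integer(max_pos)
  other_mm <- other_n <- 0
  for (p in seq_len(max_pos)) {
    sel <- lens >= p
    rb5 <- substr(refwin[sel], p, p)
    qb5 <- substr(reads[sel], p, p)
    ref_c[p] <- sum(rb5 == "C")
    ct[p] <- sum(rb5 == "C" & qb5 == "T")
    p3 <- lens[sel] - p + 1L
    rb3 <- substr(refwin[sel], p3, p3)
    qb3 <- substr(reads[sel], p3, p3)
    ref_g[p] <- sum(rb3 == "G")
    ga[p] <- sum(rb3 == "G" & qb3 == "A")
    # background: mismatches at these offsets that are not C->T / G->A
    other_mm <- other_mm +
      sum(rb5 != qb5 & !(rb5 == "C" & qb5 == "T")) +
      sum(rb3 != qb3 & !(rb3 == "G" & qb3 == "A"))
    other_n <- other_n + sum(rb5 != "C") + sum(rb3 != "G")
  }
  five <- data.frame(pos = 0:(max_pos - 1), ref_c = ref_c, ct = ct,
                     freq = ifelse(ref_c > 0, ct / ref_c, NA_real_))
  three <- data.frame(pos = 0:(max_pos - 1), ref_g = ref_g, ga = ga,
                      freq = ifelse(ref_g > 0, ga / ref_g, NA_real_))
  structure(list(
    five_prime = five, three_prime = three,
    background_rate = if (other_n > 0) other_mm / other_n else NA_real_,
    length_stats = list(mean = mean(lens), median = stats::median(lens),
                        sd = stats::sd(lens), n = length(lens))),
    class = "damage_profile")
}

#' @export
print.damage_profile <- function(x, ...) {
  cat("<damage_profile> n=", x$length_stats$n, " reads, mean length ",
      round(x$length_stats$mean, 2), " bp\n", sep = "")
  cat(sprintf("  5' C->T at position 0: %s   3' G->A at position 0: %s\n",
              format(round(x$five_prime$freq[1], 4)),
              format(round(x$three_prime$freq[1], 4))))
  cat(sprintf("  background (non-deamination) mismatch rate: %s\n",
              format(round(x$background_rate, 4))))
  invisible(x)
}

#' Authenticate a damage profile as degraded DNA
#'
#' The verdict is `"consistent with degraded DNA"` iff (i) the 5' position-0
#' C->T frequency is at least `t_damage`, (ii) that terminal frequency
#' exceeds the mean frequency over interior positions 10-24, and (iii) the
#' mean read length is at most `t_len` bp. All three sub-checks are
#' reported.
#'
#' @param profile a `damage_profile`.
#' @param t_damage minimum terminal C->T frequency (default 0.05, common
#'   ancient-DNA practice).
#' @param t_len maximum mean read length in bp (default 100).
#' @return list with `verdict`, logical `checks`, and the numbers behind
#'   them.
#' @export
authenticate_damage <- function(profile, t_damage = 0.05, t_len = 100) {
  stopifnot(inherits(profile, "damage_profile"))
  p0 <- profile$five_prime$freq[1]
  if (is.na(p0)) stop("position-0 C->T frequency is undefined (no ref C)")
  interior <- profile$five_prime$freq[profile$five_prime$pos >= 10]
  interior_mean <- mean(interior, na.rm = TRUE)
  checks <- c(terminal_damage = p0 >= t_damage,
              terminal_exceeds_interior = p0 > interior_mean,
              short_fragments = profile$length_stats$mean <= t_len)
  list(verdict = if (all(checks)) "consistent with degraded DNA"
                 else "not consistent",
       checks = checks,
       terminal_freq = p0, interior_mean = interior_mean,
       mean_length = profile$length_stats$mean,
       thresholds = c(t_damage = t_damage, t_len = t_len))
}
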