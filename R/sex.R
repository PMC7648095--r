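#' Chromosome-length-normalized X/autosome read ratio
#'
#' Genetic sex from a genome skim: reads uniquely mapped to the X chromosome
#' and to a size-matched autosome are converted to per-bp densities and
#' their quotient taken. A female (two X copies) gives a ratio near 1, a
#' male (one X copy) near 0.5, because the autosome is diploid in both.
#'
#' @param reads_x,reads_a uniquely mapped, deduplicated read counts on the X
#'   chromosome and the autosome.
#' @param len_x,len_a chromosome lengths in bp.
#' @return the ratio `(reads_x/len_x) / (reads_a/len_a)` at full precision
#'   (round for display).
#' @export
#' @examples
#' # a worked example from an elephantid genome skim:
#' round(normalized_ratio(51140, 59480, 120050768, 128409435), 2)  # 0.92
normalized_ratio <- function(reads_x, reads_a, len_x, len_a) {
  if (len_x <= 0 || len_a <= 0) stop("chromosome lengths must be positive")
  if (reads_a <= 0)
    stop("zero autosomal reads: the normalized ratio is undefined")
  if (reads_x < 0) stop("negative read count")
  (reads_x / len_x) / (reads_a / len_a)
}

#' Call genetic sex from a normalized X/autosome ratio
#'
#' @param ratio normalized ratio from [normalized_ratio()].
#' @param female_min ratio at or above which the call is `"female"`.
#' @param male_max ratio at or below which the call is `"male"`.
#' @return list with `call` (`"female"`, `"male"` or `"ambiguous"`) and the
#'   thresholds used; ratios in `(male_max, female_min)` abstain.
#' @export
call_sex <- function(ratio, female_min = 0.8, male_max = 0.6) {
  stopifnot(ratio >= 0, male_max < female_min)
  call <- if (ratio >= female_min) "female"
          else if (ratio <= male_max) "male"
          else "ambiguous"
  list(call = call, ratio = ratio,
       thresholds = c(female_min = female_min, male_max = male_max))
}

#' Genetic sex from a mapping result
#'
#' Counts reads whose unique, deduplicated best placement lies on the named
#' X and autosome sequences of one genome, then applies
#' [normalized_ratio()] and [call_sex()]. Below `min_total` combined reads
#' the call is forced to `"ambiguous"` (the sampling noise of the ratio
#' would exceed the calling band).
#'
#' @param mapping a `mapping_result`.
#' @param panel the mapped `reference_panel`.
#' @param genome genome carrying the two sequences.
#' @param x_name,autosome_name sequence names of the X chromosome and the
#'   comparison autosome.
#' @param female_min,male_max calling thresholds, see [call_sex()].
#' @param min_total minimum combined read count for a non-ambiguous call.
#' @return an object of class `sex_result` with the counts, lengths, ratio,
#'   thresholds and call.
#' @export
sex_from_mapping <- function(mapping, panel, genome, x_name, autosome_name,
                             female_min = 0.8, male_max = 0.6,
                             min_total = 200) {
  gseqs <- panel$genomes[[genome]]
  if (is.null(gseqs)) stop("genome '", genome, "' is not in the panel")
  for (nm in c(x_name, autosome_name))
    if (!nm %in% names(gseqs))
      stop("sequence '", nm, "' is not in genome '", genome, "'")
  dd <- remove_duplicates(unique_hits(mapping, genome))$hits
  reads_x <- sum(dd$seq_name == x_name)
  reads_a <- sum(dd$seq_name == autosome_name)
  len_x <- nchar(gseqs[[x_name]])
  len_a <- nchar(gseqs[[autosome_name]])
  low_count <- (reads_x + reads_a) < min_total
  if (reads_a == 0) {
    ratio <- NA_real_
    call <- "ambiguous"
    warning("zero autosomal reads; call is ambiguous")
  } else {
    ratio <- normalized_ratio(max(reads_x, 0), reads_a, len_x, len_a)
    call <- call_sex(ratio, female_min, male_max)$call
    if (low_count) {
      call <- "ambiguous"
      warning("fewer than ", min_total,
              " informative reads; call forced to ambiguous")
    }
    if (reads_x == 0)
      warning("zero X-chromosome reads; ratio 0 — verify mapping")
  }
  structure(list(reads_x = reads_x, reads_a = reads_a,
                 len_x = len_x, len_a = len_a, ratio = ratio,
                 call = call, low_count = low_count,
                 thresholds = c(female_min = female_min,
                                male_max = male_max,
                                min_total = min_total)),
            class = "sex_result")
}

#' @export
print.sex_result <- function(x, ...) {
  cat("<sex_result> X: ", x$reads_x, " reads / ", x$len_x, " bp;  autosome: ",
      x$reads_a, " reads / ", x$len_a, " bp\n", sep = "")
  cat(sprintf("  normalized ratio = %.2f (full precision %.6g) -> %s\n",
              x$ratio, x$ratio, x$call))
  cat(sprintf("  thresholds: female >= %.2f, male <= %.2f, min reads %d\n",
              x$thresholds[["female_min"]], x$thresholds[["male_max"]],
              as.integer(x$thresholds[["min_total"]])))
  invisible(x)
}
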