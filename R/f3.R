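#' Pseudo-haploid base calls from a pileup
#'
#' Standard single-specimen ancient-DNA practice: at every site with depth
#' at least `min_depth`, one read-supported base is sampled uniformly
#' (weights proportional to the base counts); other sites are missing.
#'
#' @param pileup a `pileup`.
#' @param seed integer RNG seed.
#' @param min_depth minimum site depth.
#' @return character vector of length `length(pileup$depth)` over
#'   A/C/G/T/NA.
#' @export
pseudo_haploidize <- function(pileup, seed = 1L, min_depth = 1L) {
  counts <- pileup$counts
  depth <- pileup$depth
  out <- rep(NA_character_, length(depth))
  ok <- which(depth >= min_depth & depth > 0)
  if (!length(ok)) return(out)
  with_seed(seed, {
    cum <- counts[ok, , drop = FALSE] / depth[ok]
    cum <- t(apply(cum, 1, cumsum))
    r <- stats::runif(length(ok))
    pick <- 1L + (r > cum[, 1]) + (r > cum[, 2]) + (r > cum[, 3])
    out[ok] <- DNA_BASES[pick]
  })
  out
}

#' Construct an allele matrix
#'
#' Per-site derived-allele frequencies for a set of populations, with the
#' per-population allele sample sizes needed for sampling-bias corrections.
#' A pseudo-haploid sample uses frequencies in `{0, 1, NA}` and sample size
#' 1.
#'
#' @param seq sequence (chromosome) name per site.
#' @param pos 0-based position per site; strictly increasing within each
#'   sequence.
#' @param freqs named list/data.frame, one numeric column per population
#'   with derived-allele frequencies in `[0, 1]` (`NA` = missing).
#' @param n named vector of allele sample sizes, one per population.
#' @param class site class, `"ts"` (transition) or `"tv"` (transversion).
#' @return data.frame of class `allele_matrix` with attribute
#'   `sample_sizes`.
#' @export
allele_matrix <- function(seq, pos, freqs, n, class) {
  freqs <- as.data.frame(freqs)
  stopifnot(length(seq) == length(pos), nrow(freqs) == length(pos),
            length(class) == length(pos),
            all(class %in% c("ts", "tv")),
            all(names(freqs) %in% names(n)))
  for (p in names(freqs)) {
    v <- freqs[[p]]
    if (any(v < 0 | v > 1, na.rm = TRUE))
      stop("frequencies of population '", p, "' must lie in [0, 1]")
  }
  for (s in unique(seq)) {
    if (is.unsorted(pos[seq == s], strictly = TRUE))
      stop("positions must be strictly increasing within sequence '", s, "'")
  }
  out <- data.frame(seq = seq, pos = pos, class = class, freqs,
                    check.names = FALSE)
  attr(out, "sample_sizes") <- n
  class(out) <- c("allele_matrix", "data.frame")
  out
}

# usable-site mask and per-site (corrected) products shared by
# f3_statistic() and block_jackknife()
f3_site_values <- function(matrix, A, B, C, transversions_only) {
  for (p in c(A, B, C))
    if (!p %in% names(matrix)) stop("population '", p, "' not in matrix")
  use <- stats::complete.cases(matrix[, c(A, B, C)])
  if (transversions_only) use <- use & matrix$class == "tv"
  a <- matrix[[A]][use]; b <- matrix[[B]][use]; c_ <- matrix[[C]][use]
  v <- (c_ - a) * (c_ - b)
  n <- attr(matrix, "sample_sizes")
  n_c <- if (!is.null(n) && C %in% names(n)) n[[C]] else 1
  # unbiased removal of the target's allele-sampling variance; undefined
  # (and not applied) for a single pseudo-haploid target
  if (n_c >= 2) v <- v - c_ * (1 - c_) / (n_c - 1)
  list(values = v, use = which(use), n_c = n_c)
}

#' f3 statistic: is target C admixed between sources A and B?
#'
#' Computes the mean over usable sites of `(c - a)(c - b)`, where a, b, c
#' are the derived-allele frequencies of the two sources and the target. A
#' significantly negative value indicates that C is admixed between A and
#' B. When the target column carries a sample size of at least 2, the
#' unbiased correction `c(1-c)/(n_C - 1)` for the target's allele-sampling
#' variance is subtracted per site; for a single pseudo-haploid target the
#' correction is undefined and the raw (upward-biased, hence conservative)
#' product is used. Usable sites have all three populations non-missing;
#' transitions are excluded by default because deamination inflates them in
#' ancient DNA.
#'
#' @param matrix an `allele_matrix`.
#' @param A,B,C population column names (target is `C`).
#' @param transversions_only drop transition sites.
#' @return list with `f3`, `n_sites`, and `n_C`.
#' @export
f3_statistic <- function(matrix, A, B, C, transversions_only = TRUE) {
  sv <- f3_site_values(matrix, A, B, C, transversions_only)
  if (!length(sv$values)) stop("zero usable sites")
  list(f3 = mean(sv$values), n_sites = length(sv$values), n_C = sv$n_c)
}

#' f3 with a weighted block-jackknife standard error
#'
#' Sites are partitioned into contiguous physical blocks of `block_size_bp`
#' within each sequence; the delete-one-block estimates feed a weighted
#' jackknife (weights = usable sites per block) giving a standard error
#' robust to linkage, and `Z = f3 / SE`.
#'
#' @inheritParams f3_statistic
#' @param block_size_bp physical block size in bp.
#' @return an object of class `f3_result`: `f3`, `se`, `Z`, `n_sites`,
#'   `n_blocks`, `block_size`, `filter`.
#' @export
block_jackknife <- function(matrix, A, B, C, block_size_bp = 5000,
                            transversions_only = TRUE) {
  sv <- f3_site_values(matrix, A, B, C, transversions_only)
  if (!length(sv$values)) stop("zero usable sites")
  block <- paste0(matrix$seq[sv$use], "#",
                  matrix$pos[sv$use] %/% block_size_bp)
  m <- tapply(sv$values, block, length)
  if (length(m) < 2) stop("need at least 2 non-empty blocks")
  g <- length(m)
  n <- length(sv$values)
  total <- sum(sv$values)
  block_sums <- tapply(sv$values, block, sum)
  theta <- total / n
  theta_del <- (total - block_sums) / (n - m)     # delete-one-block means
  h <- n / m
  tau <- h * theta - (h - 1) * theta_del          # pseudovalues
  theta_J <- g * theta - sum((1 - m / n) * theta_del)
  var_J <- sum((tau - theta_J)^2 / (h - 1)) / g
  se <- sqrt(var_J)
  if (se == 0) stop("degenerate jackknife: all blocks carry identical signal")
  structure(list(f3 = theta, se = se, Z = theta / se,
                 n_sites = n, n_blocks = g, block_size = block_size_bp,
                 filter = if (transversions_only) "transversions only"
                          else "all sites",
                 n_C = sv$n_c),
            class = "f3_result")
}

#' @export
print.f3_result <- function(x, ...) {
  cat(sprintf(
    "<f3_result> f3 = %.6g; Z-score = %.6g (SE %.3g)\n  %d sites in %d blocks of %g bp (%s)\n",
    x$f3, x$Z, x$se, x$n_sites, x$n_blocks, x$block_size, x$filter))
  invisible(x)
}

#' Interpret an f3 result
#'
#' @param result an `f3_result` (or any list with `f3` and `Z`).
#' @param z_threshold Z at or below which a negative f3 is called
#'   significant.
#' @return list with `verdict` (`"admixed"` or
#'   `"no evidence of admixture"`) and the inputs.
#' @export
interpret_f3 <- function(result, z_threshold = -3) {
  admixed <- result$f3 < 0 && result$Z <= z_threshold
  list(verdict = if (admixed) "admixed" else "no evidence of admixture",
       f3 = result$f3, Z = result$Z, z_threshold = z_threshold)
}

#' Simulate an allele matrix with known admixture status
#'
#' Source populations A and B drift from a common ancestral frequency under
#' a Balding-Nichols model with differentiation `fst`; observed source
#' frequencies are binomial samples of `n_hap["A"]`/`n_hap["B"]` alleles.
#' The target C is a panel of `n_hap["C"]` haplotypes that are either block
#' mosaics of A- and B-ancestry (scenario `"admixed"`, admixture fraction
#' `alpha`, independent ancestry per haplotype per physical block) or drawn
#' entirely from A's population (scenario `"null"`).
#'
#' @param n_sites number of variable sites.
#' @param length_bp genome length over which sites are placed.
#' @param fst differentiation between the two source populations.
#' @param alpha A-ancestry fraction of the admixed target.
#' @param n_hap named vector of allele sample sizes for A, B, C.
#' @param scenario `"admixed"` or `"null"`.
#' @param block_bp ancestry block length of the mosaic target.
#' @param seed integer RNG seed.
#' @return an `allele_matrix` with populations `A`, `B`, `C`.
#' @export
simulate_f3_matrix <- function(n_sites = 2000, length_bp = 1e5, fst = 0.2,
                               alpha = 0.5, n_hap = c(A = 10, B = 10, C = 10),
                               scenario = c("admixed", "null"),
                               block_bp = 1000, seed = 1L) {
  scenario <- match.arg(scenario)
  stopifnot(fst > 0, fst < 1, alpha >= 0, alpha <= 1, all(n_hap >= 1))
  with_seed(seed, {
    pos <- sort(sample.int(length_bp, n_sites)) - 1L
    x <- stats::runif(n_sites, 0.05, 0.95)
    shape <- (1 - fst) / fst
    p <- stats::rbeta(n_sites, x * shape, (1 - x) * shape)
    q <- stats::rbeta(n_sites, x * shape, (1 - x) * shape)
    a <- stats::rbinom(n_sites, n_hap[["A"]], p) / n_hap[["A"]]
    b <- stats::rbinom(n_sites, n_hap[["B"]], q) / n_hap[["B"]]
    nc <- n_hap[["C"]]
    blk <- pos %/% block_bp + 1L
    n_blocks <- max(blk)
    cmat <- matrix(0L, nrow = n_sites, ncol = nc)
    for (hpl in seq_len(nc)) {
      from_a <- if (scenario == "null") rep(TRUE, n_blocks)
                else stats::runif(n_blocks) < alpha
      pr <- ifelse(from_a[blk], p, q)
      cmat[, hpl] <- stats::rbinom(n_sites, 1L, pr)
    }
    cfreq <- rowMeans(cmat)
    class <- sample(c("ts", "tv"), n_sites, replace = TRUE)
    allele_matrix(seq = rep("sim", n_sites), pos = pos,
                  freqs = list(A = a, B = b, C = cfreq),
                  n = n_hap, class = class)
  })
}

#' Single-specimen f3 test against two screened reference genomes
#'
#' Operationalizes the hybrid check for one pseudo-haploid specimen: sites
#' are the positions where the two candidate reference genomes carry
#' different bases (their sequences must be coordinate-matched, as produced
#' by [make_reference_panel()]); small within-species source panels with
#' incomplete-lineage-sorting noise `within_div` are simulated around each
#' reference to provide source frequencies; the specimen contributes its
#' pseudo-haploid call (derived allele = genome B's base). With a single
#' uncorrected target the per-site products are non-negative for an
#' unadmixed specimen, so the test is sign-conservative: it reports
#' "admixed" only on clearly negative, significant f3.
#'
#' @param panel a `reference_panel` with coordinate-matched genomes.
#' @param genome_a,genome_b the two candidate source genomes.
#' @param calls named list: per sequence name (on `genome_a` coordinates), a
#'   pseudo-haploid base vector from [pseudo_haploidize()].
#' @param n_panel simulated source-panel size (alleles).
#' @param within_div probability a source-panel haplotype carries the other
#'   species' allele at a differential site.
#' @param block_size_bp jackknife block size.
#' @param transversions_only drop transition sites.
#' @param z_threshold significance threshold for [interpret_f3()].
#' @param seed integer RNG seed for the source panels.
#' @return list with the `allele_matrix` (`matrix`), the `f3_result`
#'   (`result`) and the interpretation (`verdict`).
#' @export
f3_specimen_test <- function(panel, genome_a, genome_b, calls,
                             n_panel = 10, within_div = 0.01,
                             block_size_bp = 5000, transversions_only = TRUE,
                             z_threshold = -3, seed = 1L) {
  ga <- panel$genomes[[genome_a]]
  gb <- panel$genomes[[genome_b]]
  if (is.null(ga) || is.null(gb)) stop("both genomes must be in the panel")
  shared <- intersect(names(calls), intersect(names(ga), names(gb)))
  if (!length(shared)) stop("no shared sequences between calls and genomes")
  rows <- list()
  for (s in shared) {
    if (nchar(ga[[s]]) != nchar(gb[[s]]))
      stop("sequences '", s, "' are not coordinate-matched")
    av <- strsplit(ga[[s]], "")[[1]]
    bv <- strsplit(gb[[s]], "")[[1]]
    diff <- which(av != bv & av %in% DNA_BASES & bv %in% DNA_BASES)
    if (!length(diff)) next
    cv <- calls[[s]][diff]
    rows[[s]] <- data.frame(seq = s, pos = diff - 1L,
                            a_allele = av[diff], b_allele = bv[diff],
                            call = cv, stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no differential sites between the two genomes")
  d <- do.call(rbind, rows)
  is_ts <- (d$a_allele == "A" & d$b_allele == "G") |
           (d$a_allele == "G" & d$b_allele == "A") |
           (d$a_allele == "C" & d$b_allele == "T") |
           (d$a_allele == "T" & d$b_allele == "C")
  cfreq <- ifelse(is.na(d$call), NA_real_,
                  ifelse(d$call == d$b_allele, 1,
                         ifelse(d$call == d$a_allele, 0, NA_real_)))
  ns <- nrow(d)
  with_seed(seed, {
    afreq <- stats::rbinom(ns, n_panel, within_div) / n_panel
    bfreq <- 1 - stats::rbinom(ns, n_panel, within_div) / n_panel
  })
  m <- allele_matrix(seq = d$seq, pos = d$pos,
                     freqs = list(A = afreq, B = bfreq, C = cfreq),
                     n = c(A = n_panel, B = n_panel, C = 1),
                     class = ifelse(is_ts, "ts", "tv"))
  res <- block_jackknife(m, "A", "B", "C", block_size_bp,
                         transversions_only)
  list(matrix = m, result = res,
       verdict = interpret_f3(res, z_threshold))
}
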