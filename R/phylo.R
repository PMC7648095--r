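#' @rdname pairwise_distance
#' @export
encode_alignment <- function(aln) {
  if (inherits(aln, "clade_panel")) aln <- aln$alignment
  if (is.matrix(aln)) return(aln)
  stopifnot(is.character(aln), !is.null(names(aln)))
  if (length(unique(nchar(aln))) != 1)
    stop("aligned sequences must all have the same length")
  chars <- strsplit(toupper(aln), "", fixed = TRUE)
  enc <- t(vapply(chars, function(x) match(x, DNA_BASES),
                  integer(nchar(aln[[1]]))))
  rownames(enc) <- names(aln)
  enc
}

# purines code 1 (A) and 3 (G); pyrimidines 2 (C) and 4 (T)
is_transition_pair <- function(x, y) {
  (x %% 2L) == (y %% 2L)   # same parity = same base class (A/G or C/T)
}

#' Pairwise distances under missing data
#'
#' p-distance or Kimura two-parameter (K2P) distance between aligned
#' sequences with pairwise deletion: each pair is compared only over sites
#' where both sequences carry an unambiguous base (`N` and `-` are
#' missing). K2P: `d = -1/2 ln((1 - 2P - Q) sqrt(1 - 2Q))` with P, Q the
#' transition and transversion proportions.
#'
#' @param aln named character vector of aligned sequences (alphabet
#'   A/C/G/T/-/N), a `clade_panel`, or an integer matrix from
#'   `encode_alignment()`.
#' @param model `"p"` or `"K2P"`.
#' @return an object of class `distance_matrix`: `d` (symmetric matrix of
#'   substitutions/site), `usable` (per-pair usable-site counts), `model`,
#'   `labels`.
#' @export
pairwise_distance <- function(aln, model = c("K2P", "p")) {
  model <- match.arg(model)
  enc <- encode_alignment(aln)
  n <- nrow(enc)
  labs <- rownames(enc)
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  usable <- matrix(0L, n, n, dimnames = list(labs, labs))
  diag(usable) <- as.integer(rowSums(!is.na(enc)))
  for (i in seq_len(n - 1)) {
    xi <- enc[i, ]
    for (j in (i + 1):n) {
      xj <- enc[j, ]
      ok <- !is.na(xi) & !is.na(xj)
      u <- sum(ok)
      if (u == 0)
        stop("zero usable sites for pair (", labs[i], ", ", labs[j], ")")
      diffs <- ok & (xi != xj)
      ts <- sum(diffs & is_transition_pair(xi, xj), na.rm = TRUE)
      tv <- sum(diffs) - ts
      dij <- if (model == "p") (ts + tv) / u else {
        P <- ts / u; Q <- tv / u
        a1 <- 1 - 2 * P - Q
        a2 <- 1 - 2 * Q
        if (a1 <= 0 || a2 <= 0)
          stop("K2P distance undefined for pair (", labs[i], ", ",
               labs[j], "): log argument is not positive")
        -0.5 * log(a1 * sqrt(a2))
      }
      d[i, j] <- d[j, i] <- dij
      usable[i, j] <- usable[j, i] <- u
    }
  }
  structure(list(d = d, usable = usable, model = model, labels = labs),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat("<distance_matrix> ", length(x$labels), " taxa, model ", x$model,
      "\n", sep = "")
  print(round(x$d, 4))
  invisible(x)
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration minimizing
#' `Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)`. Ties in Q are
#' broken deterministically by the lexicographically smallest pair of
#' subtree keys (the minimal leaf label of each subtree). Negative branch
#' lengths are clamped to zero and the total deficit is recorded in the
#' `"clamp_deficit"` attribute. On an additive distance matrix the
#' generating topology and branch lengths are recovered exactly.
#'
#' @param dist a `distance_matrix` or a symmetric numeric matrix with
#'   labelled dimnames.
#' @return an unrooted `phylo` tree (ape).
#' @export
neighbor_joining <- function(dist) {
  D <- if (inherits(dist, "distance_matrix")) dist$d else as.matrix(dist)
  labs <- rownames(D)
  if (is.null(labs)) stop("distance matrix must carry labels")
  if (!isTRUE(all.equal(D, t(D), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  n <- nrow(D)
  if (n < 3) stop("neighbor joining needs at least 3 taxa")
  reps <- labs                 # newick fragment per active node
  keys <- labs                 # minimal leaf label per subtree
  deficit <- 0
  clamp <- function(b) {
    if (b < 0) { deficit <<- deficit - b; 0 } else b
  }
  fmt <- function(b) sprintf("%.12g", b)
  while (n > 3) {
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 & upper.tri(Q), arr.ind = TRUE)
    if (nrow(cand) > 1) {
      pk <- apply(cand, 1, function(ij) {
        k <- sort(c(keys[ij[1]], keys[ij[2]]))
        paste(k, collapse = "\r")
      })
      cand <- cand[order(pk)[1], , drop = FALSE]
    }
    i <- cand[1, 1]; j <- cand[1, 2]
    bi <- clamp(0.5 * D[i, j] + (r[i] - r[j]) / (2 * (n - 2)))
    bj <- clamp(D[i, j] - (0.5 * D[i, j] + (r[i] - r[j]) / (2 * (n - 2))))
    newrep <- sprintf("(%s:%s,%s:%s)", reps[i], fmt(bi), reps[j], fmt(bj))
    newkey <- min(keys[i], keys[j])
    du <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
                c(du[keep], 0))
    reps <- c(reps[keep], newrep)
    keys <- c(keys[keep], newkey)
    D <- D2
    n <- n - 1
  }
  b1 <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  b2 <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  b3 <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);", reps[1], fmt(b1), reps[2], fmt(b2),
                 reps[3], fmt(b3))
  tree <- ape::read.tree(text = nwk)
  attr(tree, "clamp_deficit") <- deficit
  tree
}

# non-trivial bipartitions of an unrooted tree as canonical keys:
# the tip set on the side NOT containing the alphabetically first tip,
# sorted and joined with "|"
tree_splits <- function(tree) {
  tree <- ape::unroot(tree)
  nt <- length(tree$tip.label)
  labs <- tree$tip.label
  ref <- sort(labs)[1]
  ne <- nrow(tree$edge)
  desc <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) desc[[i]] <- labs[i]
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  keys <- character(0)
  nodes <- integer(0)
  for (e in seq_len(ne)) {
    ch <- tree$edge[e, 2]
    if (ch <= nt) next                       # trivial split
    side <- desc[[ch]]
    if (length(side) < 2 || length(side) > nt - 2) next
    if (ref %in% side) side <- setdiff(labs, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
    nodes <- c(nodes, ch)
  }
  list(keys = keys, nodes = nodes, desc = desc, tree = tree)
}

#' Nonparametric bootstrap support for a neighbor-joining tree
#'
#' Alignment columns are resampled with replacement (seeded); distances and
#' the NJ tree are recomputed per replicate, and the support of every
#' internal edge of the full-data tree is the percentage of successful
#' replicates containing the same bipartition. Replicates whose distance
#' computation fails (K2P domain violation or an empty pair) are dropped
#' and counted.
#'
#' @param aln alignment as in [pairwise_distance()].
#' @param model distance model.
#' @param replicates number of bootstrap replicates.
#' @param seed integer RNG seed.
#' @return an object of class `bootstrap_result`: `tree` (full-data NJ
#'   tree, node labels carry supports), `supports` (named by bipartition),
#'   `replicates`, `n_dropped`, `model`.
#' @export
bootstrap_support <- function(aln, model = c("K2P", "p"), replicates = 100,
                              seed = 1L) {
  model <- match.arg(model)
  stopifnot(replicates >= 1)
  enc <- encode_alignment(aln)
  n <- nrow(enc)
  L <- ncol(enc)
  labs <- rownames(enc)

  main <- neighbor_joining(pairwise_distance(enc, model))
  sp <- tree_splits(main)
  counts <- stats::setNames(numeric(length(sp$keys)), sp$keys)

  # per-pair per-column event indicators so each replicate is two
  # matrix-vector products instead of a full alignment scan
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  np <- nrow(pairs)
  use_m <- ts_m <- tv_m <- matrix(0, np, L)
  for (p in seq_len(np)) {
    xi <- enc[pairs[p, 1], ]; xj <- enc[pairs[p, 2], ]
    ok <- !is.na(xi) & !is.na(xj)
    diffs <- ok & (xi != xj)
    ts <- diffs & is_transition_pair(xi, xj)
    ts[is.na(ts)] <- FALSE
    use_m[p, ] <- as.numeric(ok)
    ts_m[p, ] <- as.numeric(ts)
    tv_m[p, ] <- as.numeric(diffs & !ts)
  }

  n_dropped <- 0L
  with_seed(seed, {
    for (rep in seq_len(replicates)) {
      mult <- tabulate(sample.int(L, L, replace = TRUE), nbins = L)
      u <- as.vector(use_m %*% mult)
      ts <- as.vector(ts_m %*% mult)
      tv <- as.vector(tv_m %*% mult)
      if (any(u == 0)) { n_dropped <- n_dropped + 1L; next }
      dvec <- if (model == "p") (ts + tv) / u else {
        P <- ts / u; Q <- tv / u
        a1 <- 1 - 2 * P - Q; a2 <- 1 - 2 * Q
        if (any(a1 <= 0 | a2 <= 0)) { NULL } else -0.5 * log(a1 * sqrt(a2))
      }
      if (is.null(dvec)) { n_dropped <- n_dropped + 1L; next }
      D <- matrix(0, n, n, dimnames = list(labs, labs))
      D[pairs] <- dvec
      D <- D + t(D)
      rep_tree <- neighbor_joining(D)
      rk <- tree_splits(rep_tree)$keys
      hit <- names(counts) %in% rk
      counts[hit] <- counts[hit] + 1
    }
  })
  n_ok <- replicates - n_dropped
  supports <- if (n_ok > 0) 100 * counts / n_ok else counts * NA_real_
  # attach supports as internal node labels of the full-data tree
  nl <- rep("", sp$tree$Nnode)
  nt <- length(sp$tree$tip.label)
  nl[sp$nodes - nt] <- sprintf("%d", as.integer(round(supports[sp$keys])))
  sp$tree$node.label <- nl
  structure(list(tree = sp$tree, supports = supports,
                 replicates = replicates, n_dropped = n_dropped,
                 model = model),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("<bootstrap_result> ", length(x$tree$tip.label), " taxa, ",
      x$replicates, " replicates (", x$n_dropped, " dropped), model ",
      x$model, "\n", sep = "")
  if (length(x$supports))
    cat("  internal-edge supports: ",
        paste(round(sort(unname(x$supports))), collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

#' Assign a query leaf to a reference clade
#'
#' The query's clade is the label of the minimal bipartition (smallest leaf
#' set) that contains the query together with leaves of exactly one clade;
#' if no such monochromatic bipartition exists the query is
#' `"unresolved"`. The bootstrap support of that bipartition is reported
#' when a `bootstrap_result` is supplied.
#'
#' @param tree a `phylo` tree or a `bootstrap_result`.
#' @param clades named vector: clade label per non-query leaf.
#' @param query query leaf label.
#' @return an object of class `placement_result`: `clade`, `support`,
#'   `newick`, `candidates` (all monochromatic bipartitions containing the
#'   query), `query`.
#' @export
assign_clade <- function(tree, clades, query) {
  boot <- NULL
  if (inherits(tree, "bootstrap_result")) { boot <- tree; tree <- tree$tree }
  if (!query %in% tree$tip.label) stop("query '", query, "' not in tree")
  others <- setdiff(tree$tip.label, query)
  missing <- setdiff(others, names(clades))
  if (length(missing))
    stop("leaves without clade label: ", paste(missing, collapse = ", "))
  sp <- tree_splits(tree)
  labs <- tree$tip.label
  cand <- list()
  for (k in seq_along(sp$keys)) {
    side <- strsplit(sp$keys[k], "|", fixed = TRUE)[[1]]
    if (!query %in% side) side <- setdiff(labs, side)
    members <- setdiff(side, query)
    if (!length(members)) next
    cl <- unique(clades[members])
    if (length(cl) == 1)
      cand[[length(cand) + 1]] <- data.frame(
        clade = cl, size = length(side), key = sp$keys[k],
        stringsAsFactors = FALSE)
  }
  if (!length(cand)) {
    res <- list(clade = "unresolved", support = NA_real_,
                newick = ape::write.tree(tree), candidates = NULL,
                query = query)
    class(res) <- "placement_result"
    return(res)
  }
  cdf <- do.call(rbind, cand)
  cdf <- cdf[order(cdf$size, cdf$clade), , drop = FALSE]
  if (!is.null(boot))
    cdf$support <- unname(boot$supports[cdf$key])
  else cdf$support <- NA_real_
  assigned <- cdf$clade[1]
  # support quoted for the query-in-clade grouping: the bipartition holding
  # the query together with the whole assigned clade, when the tree has it;
  # otherwise the minimal bipartition's own support
  full_size <- 1L + sum(clades[others] == assigned)
  full <- which(cdf$clade == assigned & cdf$size == full_size)
  support <- if (length(full)) cdf$support[full[1]] else cdf$support[1]
  res <- list(clade = assigned, support = support,
              newick = ape::write.tree(tree), candidates = cdf,
              query = query)
  class(res) <- "placement_result"
  res
}

#' @export
print.placement_result <- function(x, ...) {
  cat("<placement_result> query '", x$query, "' -> ", x$clade, sep = "")
  if (!is.na(x$support)) cat(" (support ", round(x$support), ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Place a consensus sequence among labelled reference haplotypes
#'
#' Convenience wrapper: appends the query to the aligned panel (strict
#' same-length check — haplotypes are assumed pre-aligned), computes
#' distances with pairwise deletion, builds the NJ tree, bootstraps it, and
#' assigns the query to a clade.
#'
#' @param panel a `clade_panel`.
#' @param query query sequence (reference-length consensus; `N` = missing).
#' @param query_name leaf label for the query.
#' @param model distance model.
#' @param replicates bootstrap replicates.
#' @param seed integer RNG seed.
#' @return a `placement_result`; the `bootstrap_result` is attached as
#'   attribute `"bootstrap"`.
#' @export
place_query <- function(panel, query, query_name = "query",
                        model = c("K2P", "p"), replicates = 100, seed = 1L) {
  stopifnot(inherits(panel, "clade_panel"))
  if (nchar(query) != nchar(panel$alignment[[1]]))
    stop("query length (", nchar(query), ") does not match the alignment (",
         nchar(panel$alignment[[1]]), ")")
  if (query_name %in% names(panel$alignment))
    stop("query name collides with a panel haplotype")
  aln <- c(panel$alignment, stats::setNames(query, query_name))
  boot <- bootstrap_support(aln, model = model, replicates = replicates,
                            seed = seed)
  res <- assign_clade(boot, panel$clades, query_name)
  attr(res, "bootstrap") <- boot
  res
}
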