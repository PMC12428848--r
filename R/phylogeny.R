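#' Poisson-corrected neighbor-joining phylogeny
#'
#' Builds the allele tree the way the field's standard desktop tools do:
#' pairwise p-distances on aligned C2--C5 amino-acid sequences, Poisson
#' correction to substitutions per site, Saitou--Nei neighbor joining, and
#' column-resampling bootstrap supports. Newick I/O and tree containers use
#' \pkg{ape}; the distance and joining steps are implemented here.
#'
#' @name phylogeny
NULL

#' Proportion of differing sites between two aligned rows
#'
#' Only pairwise-complete sites (both rows non-gap) are compared.
#'
#' @param x,y equal-length aligned sequence strings
#' @param gap gap symbol (default `"-"`)
#' @return proportion of mismatches among comparable sites, in \[0, 1\]
#' @examples
#' p_distance("A-AA", "AGAT")  # 1/3
#' @export
p_distance <- function(x, y, gap = "-") {
  cx <- strsplit(x, "")[[1]]; cy <- strsplit(y, "")[[1]]
  if (length(cx) != length(cy)) stop("aligned rows must have equal length")
  ok <- cx != gap & cy != gap
  if (!any(ok)) stop("no pairwise-complete sites")
  mean(cx[ok] != cy[ok])
}

#' Poisson correction of a p-distance
#'
#' Converts an observed amino-acid difference proportion into an estimated
#' number of substitutions per site: `d = -ln(1 - p)`. Monotone increasing
#' and never below `p`.
#'
#' @param p proportion(s) in \[0, 1)
#' @return corrected distance(s)
#' @examples
#' poisson_correct(0.05)  # 0.05129...
#' @export
poisson_correct <- function(p) {
  if (any(p < 0 | p >= 1)) stop("p must lie in [0, 1) (p = 1 is saturated)")
  -log(1 - p)
}

#' Pairwise distance matrix from an alignment
#'
#' @param aln named character vector of equal-length aligned sequences
#'   (3 or more for tree building)
#' @param correction `"poisson"` (default) or `"none"` (raw p-distance)
#' @param deletion `"pairwise"` (default; per-pair complete sites, which
#'   preserves signal from short RHV indels) or `"complete"` (columns with
#'   any gap dropped for all pairs)
#' @param gap gap symbol
#' @return symmetric distance matrix with zero diagonal
#' @export
distance_matrix <- function(aln, correction = c("poisson", "none"),
                            deletion = c("pairwise", "complete"), gap = "-") {
  correction <- match.arg(correction)
  deletion <- match.arg(deletion)
  if (is.null(names(aln)) || any(!nzchar(names(aln)))) {
    stop("alignment rows must be named")
  }
  if (length(unique(nchar(aln))) != 1L) stop("rows must have equal length")
  m <- do.call(rbind, strsplit(aln, ""))
  if (deletion == "complete") {
    keep <- colSums(m == gap) == 0L
    if (!any(keep)) stop("no gap-free columns under complete deletion")
    m <- m[, keep, drop = FALSE]
  }
  n <- length(aln)
  d <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  nogap <- m != gap
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- nogap[i, ] & nogap[j, ]
      if (!any(ok)) stop("no pairwise-complete sites between ",
                         names(aln)[i], " and ", names(aln)[j])
      p <- sum(m[i, ok] != m[j, ok]) / sum(ok)
      d[i, j] <- d[j, i] <- if (correction == "poisson") poisson_correct(p) else p
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Standard Saitou--Nei agglomeration: at each step the pair minimizing the
#' Q-criterion is joined, branch lengths are computed from net divergences,
#' and the matrix is reduced. Ties are broken by the lexicographically
#' smallest pair of cluster labels (a cluster is labeled by its smallest
#' leaf), so the output is deterministic and invariant under reordering of
#' the input taxa. Negative branch lengths are clamped to zero with the
#' total deficit recorded in the `clamped` attribute. The result is an
#' unrooted tree stored with an arbitrary trifurcating root.
#'
#' @param dm symmetric distance matrix with labeled rows (n >= 3)
#' @return an \pkg{ape} `phylo` object
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 3L) stop("neighbor joining needs at least 3 taxa")
  if (!isSymmetric(unname(dm), tol = 1e-8)) stop("distance matrix must be symmetric")
  if (any(dm < 0)) stop("distances must be nonnegative")
  labels <- rownames(dm)
  if (is.null(labels)) stop("distance matrix must have row labels")

  fmt <- function(x) sprintf("%.12g", x)
  clamp <- function(x) max(x, 0)
  deficit <- 0
  sub <- as.list(labels)              # growing newick fragment per cluster
  keys <- labels                      # canonical label: smallest member leaf
  d <- dm
  while (length(sub) > 3L) {
    r <- nrow(d)
    R <- rowSums(d)
    q <- (r - 2) * d - outer(R, R, "+")
    diag(q) <- Inf
    hit <- which(q == min(q), arr.ind = TRUE)
    hit <- hit[hit[, 1] < hit[, 2], , drop = FALSE]
    # ties: lexicographically smallest (sorted) pair of cluster labels
    k1 <- pmin(keys[hit[, 1]], keys[hit[, 2]])
    k2 <- pmax(keys[hit[, 1]], keys[hit[, 2]])
    hit <- hit[order(k1, k2), , drop = FALSE]
    i <- hit[1, 1]; j <- hit[1, 2]
    li <- d[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- d[i, j] - li
    deficit <- deficit + abs(min(li, 0)) + abs(min(lj, 0))
    li <- clamp(li); lj <- clamp(lj)
    merged <- sprintf("(%s:%s,%s:%s)", sub[[i]], fmt(li), sub[[j]], fmt(lj))
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    d <- d2
    keys <- c(keys[keep], min(keys[i], keys[j]))
    sub <- c(sub[keep], merged)
  }
  # resolve the final three clusters at a trifurcating root
  la <- clamp((d[1, 2] + d[1, 3] - d[2, 3]) / 2)
  lb <- clamp((d[1, 2] + d[2, 3] - d[1, 3]) / 2)
  lc <- clamp((d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  deficit <- deficit +
    abs(min((d[1, 2] + d[1, 3] - d[2, 3]) / 2, 0)) +
    abs(min((d[1, 2] + d[2, 3] - d[1, 3]) / 2, 0)) +
    abs(min((d[1, 3] + d[2, 3] - d[1, 2]) / 2, 0))
  nwk <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 sub[[1]], fmt(la), sub[[2]], fmt(lb), sub[[3]], fmt(lc))
  tree <- ape::read.tree(text = nwk)
  attr(tree, "clamped") <- deficit
  tree
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Alignment columns are resampled with replacement `reps` times; each
#' replicate alignment is run through the same distance + NJ pipeline, and
#' each internal bipartition of the original tree is labeled with the
#' percentage of replicates containing it. The same seed always yields
#' identical supports.
#'
#' @inheritParams distance_matrix
#' @param reps number of bootstrap replicates (>= 1)
#' @param seed RNG seed for the resampling (recorded in the result's
#'   `seed` attribute)
#' @return the full-alignment `phylo` tree with node labels set to integer
#'   support percentages (root label empty); attributes `seed` and `reps`
#' @export
bootstrap_tree <- function(aln, reps, seed, correction = "poisson",
                           deletion = "pairwise", gap = "-") {
  stopifnot(reps >= 1)
  main <- nj_tree(distance_matrix(aln, correction, deletion, gap))
  len <- nchar(aln[[1]])
  chars <- strsplit(aln, "")
  btrees <- with_seed(seed, {
    lapply(seq_len(reps), function(k) {
      cols <- sample.int(len, len, replace = TRUE)
      res <- vapply(chars, function(ch) paste(ch[cols], collapse = ""), character(1))
      nj_tree(distance_matrix(res, correction, deletion, gap))
    })
  })
  counts <- ape::prop.clades(main, btrees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  supports <- round_half_up(100 * counts / reps)
  supports <- pmin(pmax(supports, 0), 100)
  main$node.label <- as.character(supports)
  main$node.label[1L] <- ""             # trifurcating root: trivial split
  attr(main, "seed") <- seed
  attr(main, "reps") <- reps
  main
}

#' Read an aligned FASTA of amino-acid sequences
#'
#' @param path FASTA file
#' @return named character vector of aligned rows
#' @export
read_alignment <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  out <- as.character(aa)
  if (length(unique(nchar(out))) != 1L) {
    stop("sequences are not aligned (unequal lengths)")
  }
  out
}

#' Write a tree to a newick file
#'
#' Internal node labels (bootstrap supports) are preserved.
#'
#' @param tree `phylo` object
#' @param path output file
#' @return `path`, invisibly
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
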