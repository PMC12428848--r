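# Independent brute-force oracles and shared fixtures for the suite.
# The oracles deliberately re-derive results from first principles and do
# not call the package's scanning/splicing code paths.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"),
  D = c("A", "G", "T"), B = c("C", "G", "T"),
  N = c("A", "C", "G", "T")
)

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", M = "K", R = "Y", W = "W",
            S = "S", Y = "R", K = "M", V = "B", H = "D", D = "H", B = "V",
            N = "N")
  paste(rev(comp[strsplit(x, "")[[1]]]), collapse = "")
}

# Exhaustive per-offset scan of a degenerate primer over a template.
oracle_sites <- function(template, primer, max_mm = 0,
                         strand = c("forward", "reverse")) {
  strand <- match.arg(strand)
  q <- if (strand == "forward") primer else oracle_revcomp(primer)
  qs <- strsplit(q, "")[[1]]
  ts <- strsplit(template, "")[[1]]
  if (length(ts) < length(qs)) {
    return(data.frame(start = integer(), mismatches = integer()))
  }
  hits <- list()
  for (s in 0:(length(ts) - length(qs))) {
    mm <- 0L
    for (i in seq_along(qs)) {
      tb <- ts[s + i]
      if (!(tb == "N" || tb %in% ORACLE_IUPAC[[qs[i]]])) mm <- mm + 1L
    }
    if (mm <= max_mm) hits[[length(hits) + 1L]] <- c(s, mm)
  }
  if (!length(hits)) return(data.frame(start = integer(), mismatches = integer()))
  m <- do.call(rbind, hits)
  data.frame(start = m[, 1], mismatches = m[, 2])
}

# All fwd x rev site combinations, fwd footprint strictly upstream.
oracle_amplicons <- function(template, fwd, rev, max_mm = 0) {
  f <- oracle_sites(template, fwd, max_mm, "forward")
  r <- oracle_sites(template, rev, max_mm, "reverse")
  sizes <- integer()
  for (i in seq_len(nrow(f))) {
    for (j in seq_len(nrow(r))) {
      fe <- f$start[i] + nchar(fwd)
      re <- r$start[j] + nchar(rev)
      if (fe <= r$start[j]) sizes <- c(sizes, re - f$start[i])
    }
  }
  sort(sizes)
}

# Enumerate every GT..AG split of the required intron length and score the
# concatenated exons against the coding reference by exact identity.
oracle_splice <- function(genomic, coding_ref) {
  gch <- strsplit(genomic, "")[[1]]
  cch <- strsplit(coding_ref, "")[[1]]
  L <- length(gch) - length(cch)
  best <- NULL; best_score <- -1
  for (s in 0:length(cch)) {
    intron <- gch[(s + 1):(s + L)]
    if (intron[1] == "G" && intron[2] == "T" &&
        intron[L - 1] == "A" && intron[L] == "G") {
      exons <- if (s == 0) gch[(L + 1):length(gch)]
               else if (s == length(cch)) gch[seq_len(s)]
               else c(gch[seq_len(s)], gch[(s + L + 1):length(gch)])
      score <- sum(exons == cch)
      if (score > best_score) { best_score <- score; best <- s }
    }
  }
  list(start = best, identity = best_score / length(cch))
}

# Shared fixtures, built once per suite run.
ref_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_reference()
    cache
  }
})

genotype_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_genotypes()
    cache
  }
})

# The synthetic allele library is expensive; build it lazily and share.
library_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_allele_library(ref_fixture(), seed = 1)
    cache
  }
})
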