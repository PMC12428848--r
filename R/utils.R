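#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going up (0.5 -> 1), the
#' convention used for the printed percentage tables, rather than R's
#' round-half-even.
#'
#' @param x numeric vector
#' @param digits integer number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  floor(x * m + 0.5) / m
}

#' Reverse complement of a DNA string
#'
#' IUPAC ambiguity codes are complemented correctly (e.g. M -> K).
#'
#' @param x single DNA string
#' @return reverse-complemented string
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Run code with a temporary RNG state seeded from `seed`; the caller's
# RNG stream is untouched.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Natural sort order for S-allele labels: numeric base, then suffix
# ("S14" < "S14a" < "S18-1" < "S18-2" < "S93").
s_allele_order <- function(labels) {
  if (length(labels) == 0L) return(integer(0))
  base <- suppressWarnings(as.integer(sub("^S(\\d+).*$", "\\1", labels)))
  base[is.na(base)] <- Inf  # non-numeric labels (e.g. "SC") sort last
  suffix <- sub("^S\\d+", "", labels)
  order(base, suffix, labels)
}

#' Sort S-allele labels naturally
#'
#' @param labels character vector of allele labels
#' @return sorted character vector
#' @export
sort_alleles <- function(labels) labels[s_allele_order(labels)]

#' Path to a packaged fixture file
#'
#' @param name file name under the package's extdata directory; with no
#'   argument, lists the available fixtures.
#' @return absolute path (or vector of file names)
#' @export
srt_fixture <- function(name = NULL) {
  if (is.null(name)) {
    return(dir(system.file("extdata", package = "SRNaseTyper")))
  }
  path <- system.file("extdata", name, package = "SRNaseTyper")
  if (!nzchar(path)) stop("no packaged fixture named '", name, "'")
  path
}
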