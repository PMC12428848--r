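#' In-silico PCR with IUPAC-degenerate primers
#'
#' Emulates the five-primer screening electronically: degenerate primers are
#' matched against a template by IUPAC set-membership and all
#' forward/reverse site combinations yield predicted amplicon sizes, which
#' can then be compared with the reference fragment-size table.
#'
#' @name insilico_pcr
NULL

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
  S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
  V = c("A", "C", "G"), H = c("A", "C", "T"),
  D = c("A", "G", "T"), B = c("C", "G", "T"),
  N = c("A", "C", "G", "T")
)

check_dna <- function(x, what, alphabet) {
  if (!is.character(x) || length(x) != 1L || !nzchar(x)) {
    stop(what, " must be a single non-empty string")
  }
  if (!grepl(paste0("^[", alphabet, "]+$"), x)) {
    stop(what, " contains characters outside {", alphabet, "}")
  }
}

#' Match a degenerate primer against a template
#'
#' A position matches when the template base is a member of the primer
#' base's IUPAC set (an `N` in the template matches anything); a site is
#' reported when at most `max_mismatch` positions fail. For
#' `strand = "reverse"` the reverse complement of the primer is matched,
#' i.e. sites where the primer would anneal to the plus strand's complement.
#' The scan is exhaustive over the template.
#'
#' @param template DNA string over {A,C,G,T,N}
#' @param primer IUPAC DNA string
#' @param max_mismatch maximum tolerated failing positions (default 0: the
#'   universal primers' degeneracy already encodes the tolerance)
#' @param strand `"forward"` or `"reverse"`
#' @return data.frame with 0-based half-open `start`/`end`, `strand` and
#'   `mismatches`, ordered by start
#' @examples
#' match_primer("AATCACAATCCATGGCCTATGGTT", "TCACMATYCATGGCCTATGG")
#' @export
match_primer <- function(template, primer, max_mismatch = 0,
                         strand = c("forward", "reverse")) {
  strand <- match.arg(strand)
  check_dna(template, "template", "ACGTN")
  check_dna(primer, "primer", "ACGTMRWSYKVHDBN")
  stopifnot(max_mismatch >= 0)
  query <- if (strand == "forward") primer else revcomp(primer)
  hits <- Biostrings::matchPattern(
    Biostrings::DNAString(query), Biostrings::DNAString(template),
    max.mismatch = max_mismatch, fixed = FALSE
  )
  starts <- BiocGenerics::start(hits)
  if (length(starts) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), mismatches = integer(),
                      stringsAsFactors = FALSE))
  }
  qs <- strsplit(query, "")[[1]]
  mm <- vapply(starts, function(s) {
    ts <- strsplit(substr(template, s, s + length(qs) - 1L), "")[[1]]
    sum(vapply(seq_along(qs), function(i) {
      !(ts[i] == "N" || ts[i] %in% IUPAC_SETS[[qs[i]]])
    }, logical(1)))
  }, integer(1))
  data.frame(start = starts - 1L, end = starts - 1L + length(qs),
             strand = strand, mismatches = mm, stringsAsFactors = FALSE)
}

#' Predict amplicons for a primer pair on a template
#'
#' Enumerates every combination of a forward-primer site with a downstream
#' reverse-primer site; the amplicon size is inclusive of both primer
#' footprints (`rev_end - fwd_start`), matching how the reference table's
#' fragment sizes relate to intron plus exon remainder. Combinations whose
#' primer footprints overlap are discarded.
#'
#' @param template DNA string over {A,C,G,T,N}
#' @param pair one row of a primer table (with `forward` and `reverse`
#'   columns), or a list with those elements
#' @param max_mismatch per-primer mismatch tolerance
#' @param max_products keep at most this many products (smallest first)
#' @return data.frame of products (`fwd_start`, `fwd_end`, `rev_start`,
#'   `rev_end`, `size`; 0-based half-open), size ascending
#' @export
amplicons <- function(template, pair, max_mismatch = 0, max_products = Inf) {
  fwd <- match_primer(template, pair$forward, max_mismatch, "forward")
  rev <- match_primer(template, pair$reverse, max_mismatch, "reverse")
  out <- data.frame(fwd_start = integer(), fwd_end = integer(),
                    rev_start = integer(), rev_end = integer(),
                    size = integer(), stringsAsFactors = FALSE)
  if (nrow(fwd) && nrow(rev)) {
    grid <- expand.grid(f = seq_len(nrow(fwd)), r = seq_len(nrow(rev)))
    keep <- fwd$end[grid$f] <= rev$start[grid$r]  # non-overlapping, fwd upstream
    grid <- grid[keep, , drop = FALSE]
    if (nrow(grid)) {
      out <- data.frame(
        fwd_start = fwd$start[grid$f], fwd_end = fwd$end[grid$f],
        rev_start = rev$start[grid$r], rev_end = rev$end[grid$r],
        stringsAsFactors = FALSE
      )
      out$size <- out$rev_end - out$fwd_start
      out <- out[order(out$size, out$fwd_start, out$rev_start), , drop = FALSE]
      if (is.finite(max_products)) out <- utils::head(out, max_products)
      rownames(out) <- NULL
    }
  }
  out
}

#' Predicted fragment sizes for every primer pair
#'
#' Convenience wrapper running [amplicons()] for each pair of a primer
#' table, the electronic analogue of running a template through the gel
#' screen.
#'
#' @param template DNA string
#' @param primers primer table from [load_primers()]
#' @param max_mismatch per-primer mismatch tolerance
#' @return data.frame with columns `primer_pair` and `size`
#' @export
screen_template <- function(template, primers = load_primers(),
                            max_mismatch = 0) {
  res <- lapply(seq_len(nrow(primers)), function(i) {
    amp <- amplicons(template, primers[i, ], max_mismatch)
    if (nrow(amp) == 0L) return(NULL)
    data.frame(primer_pair = primers$name[i], size = amp$size,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) {
    out <- data.frame(primer_pair = character(), size = integer(),
                      stringsAsFactors = FALSE)
  }
  out
}
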