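#' S-RNase genomic annotation
#'
#' Locates the second intron of an S-RNase amplicon by the conserved GT/AG
#' splicing rule against a coding reference, deduces the protein, detects
#' the conserved C2/C3/RC4/C5 domain blocks, and extracts the hypervariable
#' region (RHV) lying between C2 and C3 -- the segment whose length and
#' sequence polymorphism distinguishes alleles.
#'
#' All coordinates are 0-based half-open.
#'
#' @name srnase_annotation
NULL

#' Locate the second intron by the GT/AG rule
#'
#' Under the single-intron model, the genomic sequence splits as
#' exon1 + intron + exon2 with the intron length fixed at
#' `nchar(genomic) - nchar(coding_ref)`. Every candidate split whose intron
#' starts `GT` and ends `AG` is scored by exact identity of the concatenated
#' exons to the coding reference; the best-scoring split wins, leftmost on
#' ties. Identity below `min_identity` raises a "no valid splice" error.
#'
#' @param genomic genomic DNA string (longer than the coding reference)
#' @param coding_ref intron-less coding reference DNA string
#' @param min_identity identity floor over exonic positions (default 0.95;
#'   same-allele sequence calls in practice show 99--100% similarity, the
#'   looser floor tolerates simulation noise)
#' @return list with `exon_spans` (two-row matrix), `intron_span`,
#'   `intron_len`, and `identity`
#' @examples
#' g <- paste0("ATGGCC", "GTAAAAAG", "TTTGGC")
#' find_intron(g, "ATGGCCTTTGGC")$intron_len  # 8
#' @export
find_intron <- function(genomic, coding_ref, min_identity = 0.95) {
  check_dna(genomic, "genomic", "ACGTN")
  check_dna(coding_ref, "coding_ref", "ACGTN")
  ng <- nchar(genomic); nc <- nchar(coding_ref)
  if (ng <= nc) stop("genomic must be longer than coding_ref")
  L <- ng - nc
  if (L < 4L) stop("no valid splice: intron shorter than GT..AG")
  gch <- strsplit(genomic, "")[[1]]
  cch <- strsplit(coding_ref, "")[[1]]
  # candidate 0-based intron starts s: genomic[s..s+2) == "GT",
  # genomic[s+L-2..s+L) == "AG"; exon1 = genomic[0..s), exon2 = genomic[s+L..)
  starts <- which(gch[seq_len(ng - 1L)] == "G" & gch[-1L] == "T") - 1L
  starts <- starts[starts <= nc]
  starts <- starts[gch[starts + L - 1L] == "A" & gch[starts + L] == "G"]
  if (length(starts) == 0L) stop("no valid splice: no GT..AG split of length ", L)
  # prefix/suffix cumulative exact matches against the reference
  pm <- cumsum(gch[seq_len(nc)] == cch)                       # pm[i]: first i
  sm <- cumsum(rev(gch[(ng - nc + 1L):ng] == cch))            # sm[k]: last k
  score <- ifelse(starts > 0L, pm[pmax(starts, 1L)] * (starts > 0L), 0L) +
           ifelse(starts < nc, sm[pmax(nc - starts, 1L)] * (starts < nc), 0L)
  best <- which(score == max(score))[1L]                      # leftmost tie
  identity <- score[best] / nc
  if (identity < min_identity) {
    stop(sprintf("no valid splice: best exon identity %.3f below floor %.3f",
                 identity, min_identity))
  }
  s <- starts[best]
  list(
    exon_spans = rbind(c(0L, s), c(s + L, ng)),
    intron_span = c(s, s + L),
    intron_len = L,
    identity = identity
  )
}

# Splice the exons out of a genomic string given find_intron() spans.
splice_exons <- function(genomic, spans) {
  paste0(substr(genomic, spans$exon_spans[1, 1] + 1L, spans$exon_spans[1, 2]),
         substr(genomic, spans$exon_spans[2, 1] + 1L, spans$exon_spans[2, 2]))
}

#' Translate a spliced coding sequence
#'
#' Standard-code translation of the concatenated exons from the given frame;
#' the trailing partial codon is dropped and a terminal stop codon is
#' trimmed. With an explicit `frame`, internal stop codons are flagged (kept
#' as `*` with their 0-based protein offsets in the `stops` attribute)
#' rather than silently truncated. With `frame = NULL` the unique internally
#' stop-free frame is selected automatically; if several frames are
#' stop-free the lowest is used, and if none is, an error lists the stop
#' offsets per frame.
#'
#' @param spliced spliced coding DNA string (exon1 + exon2)
#' @param frame 0, 1, 2 or `NULL` for auto-selection
#' @return amino-acid string, with attribute `frame`
#' @export
deduce_protein <- function(spliced, frame = NULL) {
  check_dna(spliced, "spliced", "ACGTN")
  translate_frame <- function(f) {
    sub <- substr(spliced, f + 1L, nchar(spliced))
    sub <- substr(sub, 1L, (nchar(sub) %/% 3L) * 3L)
    if (nchar(sub) == 0L) return(list(aa = "", stops = integer()))
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(sub), if.fuzzy.codon = "solve"))
    aach <- strsplit(aa, "")[[1]]
    stops <- which(aach == "*")
    if (length(stops) && stops[length(stops)] == length(aach)) {
      aach <- aach[-length(aach)]          # terminal stop: trim, not internal
      stops <- stops[-length(stops)]
    }
    list(aa = paste(aach, collapse = ""), stops = stops)
  }
  if (!is.null(frame)) {
    stopifnot(frame %in% 0:2)
    tr <- translate_frame(frame)
    # internal stops are flagged ('*' retained, offsets in the `stops`
    # attribute), never silently truncated
    return(structure(tr$aa, frame = frame, stops = tr$stops - 1L))
  }
  trs <- lapply(0:2, translate_frame)
  free <- which(vapply(trs, function(t) length(t$stops) == 0L, logical(1)))
  if (length(free) == 0L) {
    msg <- vapply(0:2, function(f) {
      sprintf("frame %d: %s", f, paste(trs[[f + 1]]$stops - 1L, collapse = ","))
    }, character(1))
    stop("all three frames contain internal stops (protein offsets) -- ",
         paste(msg, collapse = "; "))
  }
  f <- free[1L] - 1L
  structure(trs[[free[1L]]]$aa, frame = f)
}

# Parse a motif pattern like "TIHGLWPSN[YF]" into a list of allowed-set
# character vectors, one per position.
parse_motif <- function(pattern) {
  chars <- strsplit(pattern, "")[[1]]
  sets <- list(); i <- 1L
  while (i <= length(chars)) {
    if (chars[i] == "[") {
      j <- i + 1L
      while (chars[j] != "]") j <- j + 1L
      sets[[length(sets) + 1L]] <- chars[(i + 1L):(j - 1L)]
      i <- j + 1L
    } else {
      sets[[length(sets) + 1L]] <- chars[i]
      i <- i + 1L
    }
  }
  sets
}

#' Load the conserved-domain models
#'
#' The C2/C3/RC4/C5 blocks ship as an editable fixture of position-specific
#' allowed-set patterns (square brackets denote alternatives) with a
#' per-domain mismatch allowance. The packaged consensus blocks echo the
#' translations of the universal primer annealing regions, so synthetic
#' sequences built from them are structurally faithful.
#'
#' @param path CSV with columns `name,pattern,max_mismatch`
#' @return list of domain models (`name`, `sets`, `length`, `max_mismatch`)
#' @export
load_domain_models <- function(path = srt_fixture("domain_motifs.csv")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  models <- lapply(seq_len(nrow(df)), function(i) {
    sets <- parse_motif(df$pattern[i])
    if (length(sets) < 5L) stop("domain pattern shorter than 5: ", df$name[i])
    list(name = df$name[i], sets = sets, length = length(sets),
         max_mismatch = df$max_mismatch[i])
  })
  names(models) <- df$name
  models
}

#' Scan a protein for the conserved domains
#'
#' Each domain gets at most one hit: the best-scoring placement (fewest
#' positions outside the allowed sets), leftmost on ties, and only if the
#' mismatch count stays within the model's allowance. Hits must then be
#' non-overlapping and ordered C2 < C3 < RC4 < C5 along the protein; a hit
#' violating the order is dropped and reported in the `dropped` attribute.
#'
#' @param protein amino-acid string
#' @param models domain models from [load_domain_models()]
#' @return named list of 0-based half-open `c(start, end)` spans for the
#'   domains found, ordered C2, C3, RC4, C5; attribute `dropped` names any
#'   order-violating hits that were discarded
#' @export
scan_domains <- function(protein, models = load_domain_models()) {
  if (!nzchar(protein)) stop("protein must be non-empty")
  aach <- strsplit(protein, "")[[1]]
  np <- length(aach)
  hit_one <- function(model) {
    k <- model$length
    if (np < k) return(NULL)
    best_mm <- Inf; best_at <- NA_integer_
    for (s in seq_len(np - k + 1L)) {
      mm <- 0L
      for (j in seq_len(k)) {
        if (!(aach[s + j - 1L] %in% model$sets[[j]])) {
          mm <- mm + 1L
          if (mm > model$max_mismatch || mm >= best_mm) break
        }
      }
      if (mm <= model$max_mismatch && mm < best_mm) {
        best_mm <- mm; best_at <- s
      }
    }
    if (is.na(best_at)) return(NULL)
    c(best_at - 1L, best_at - 1L + k)     # 0-based half-open
  }
  hits <- Filter(Negate(is.null), lapply(models, hit_one))
  canonical <- c("C2", "C3", "RC4", "C5")
  hits <- hits[intersect(canonical, names(hits))]
  # enforce left-to-right, non-overlapping canonical order
  dropped <- character()
  kept <- list(); cursor <- 0L               # next allowed start
  for (nm in names(hits)) {
    if (hits[[nm]][1] >= cursor) {
      kept[[nm]] <- hits[[nm]]
      cursor <- hits[[nm]][2]
    } else {
      dropped <- c(dropped, nm)
    }
  }
  structure(kept, dropped = dropped)
}

#' Extract the hypervariable region between C2 and C3
#'
#' @param protein amino-acid string
#' @param domain_hits output of [scan_domains()]; C2 and C3 must be present
#' @return list with 0-based half-open `span` (C2 end to C3 start), `length`
#'   and the RHV `seq` itself
#' @export
extract_rhv <- function(protein, domain_hits) {
  if (is.null(domain_hits$C2) || is.null(domain_hits$C3)) {
    stop("RHV extraction requires both C2 and C3 hits")
  }
  a <- domain_hits$C2[2]; b <- domain_hits$C3[1]
  if (b < a) stop("C3 hit precedes C2 end")  # defensive; scan enforces order
  list(span = c(a, b), length = b - a,
       seq = substr(protein, a + 1L, b))
}

#' Annotate an S-RNase genomic sequence end to end
#'
#' Runs intron location, translation, domain scanning and RHV extraction,
#' returning the complete annotation record.
#'
#' @inheritParams find_intron
#' @param frame translation frame, or `NULL` to auto-select
#' @param models domain models (default: packaged fixture)
#' @return object of class `srt_annotation`: `genomic`, `exon_spans`,
#'   `intron_span`, `intron_len`, `identity`, `protein`, `frame`,
#'   `domain_hits`, `rhv` (or `NULL` when C2/C3 missing)
#' @export
annotate_srnase <- function(genomic, coding_ref, min_identity = 0.95,
                            frame = NULL, models = load_domain_models()) {
  spans <- find_intron(genomic, coding_ref, min_identity)
  spliced <- splice_exons(genomic, spans)
  protein <- deduce_protein(spliced, frame)
  hits <- scan_domains(as.character(protein), models)
  rhv <- if (!is.null(hits$C2) && !is.null(hits$C3)) {
    extract_rhv(as.character(protein), hits)
  }
  structure(
    list(genomic = genomic, exon_spans = spans$exon_spans,
         intron_span = spans$intron_span, intron_len = spans$intron_len,
         identity = spans$identity, protein = as.character(protein),
         frame = attr(protein, "frame"), domain_hits = hits, rhv = rhv),
    class = "srt_annotation"
  )
}

#' @export
print.srt_annotation <- function(x, ...) {
  cat(sprintf("S-RNase annotation: %d bp genomic, intron [%d,%d) = %d bp, exon identity %.1f%%\n",
              nchar(x$genomic), x$intron_span[1], x$intron_span[2],
              x$intron_len, 100 * x$identity))
  cat(sprintf("protein: %d aa (frame %d); domains: %s\n",
              nchar(x$protein), x$frame,
              paste(names(x$domain_hits), collapse = ", ")))
  if (!is.null(x$rhv)) {
    cat(sprintf("RHV [%d,%d): %s\n", x$rhv$span[1], x$rhv$span[2], x$rhv$seq))
  }
  invisible(x)
}
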