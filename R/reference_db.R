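#' Allele reference, primer set and genotype table
#'
#' The package ships a curated reference of apricot S-RNase alleles:
#' 31 previously published alleles plus 15 novel ones (S93--S107), each with
#' its PCR fragment size and second-intron size per primer pair and its
#' GenBank accession label; the five universal Prunus primer pairs; and the
#' S-genotypes of 168 apricot cultivars (133 Chinese, 35 foreign) with
#' province/country of origin and geographic area.
#'
#' @name reference_db
NULL

AREA_LEVELS <- c("NorthChina", "CentralChina", "EastChina", "NortheastChina",
                 "NorthwestChina", "Xinjiang", "UnclearChina", "Foreign")

#' Load an allele reference table
#'
#' Reads a long-format CSV (`label,status,accession,primer_pair,fragment_bp,
#' intron_bp`; one row per allele x primer pair) and validates it: every
#' fragment must be longer than its intron, both positive, and a label may
#' not be profiled twice for the same primer pair or change status/accession
#' between rows. `"SC"` is a reserved genotype-only label and may not appear
#' in a reference.
#'
#' @param path CSV file; defaults to the packaged reference transcribed from
#'   the published allele tables.
#' @return a data.frame of class `srt_reference` with one row per
#'   (label, primer_pair) profile.
#' @examples
#' ref <- load_reference()
#' length(unique(ref$label))  # 46 alleles
#' @export
load_reference <- function(path = srt_fixture("alleles.csv")) {
  if (!file.exists(path)) stop("reference file not found: ", path)
  ref <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "status", "accession", "primer_pair",
            "fragment_bp", "intron_bp")
  if (!all(need %in% names(ref))) {
    stop("malformed reference: expected columns ", paste(need, collapse = ", "))
  }
  if (nrow(ref) == 0L) stop("malformed reference: no data rows")
  bad <- which(is.na(ref$label) | !nzchar(ref$label) |
               is.na(ref$fragment_bp) | is.na(ref$intron_bp))
  if (length(bad)) stop("malformed reference row(s): ", paste(bad, collapse = ", "))
  if (!all(ref$status %in% c("known", "novel"))) {
    stop("status must be 'known' or 'novel'")
  }
  if (any(ref$label == "SC")) {
    stop("'SC' is a reserved genotype-only label and cannot be a reference allele")
  }
  if (!all(ref$fragment_bp > ref$intron_bp & ref$intron_bp > 0)) {
    off <- ref$label[!(ref$fragment_bp > ref$intron_bp & ref$intron_bp > 0)]
    stop("fragment_bp > intron_bp > 0 violated for: ", paste(off, collapse = ", "))
  }
  key <- paste(ref$label, ref$primer_pair)
  if (anyDuplicated(key)) {
    stop("duplicate label/primer profile: ", paste(unique(key[duplicated(key)]), collapse = ", "))
  }
  for (col in c("status", "accession")) {
    per <- tapply(ref[[col]], ref$label, function(v) length(unique(v)))
    if (any(per > 1L)) {
      stop("label with inconsistent ", col, ": ",
           paste(names(per)[per > 1L], collapse = ", "))
    }
  }
  class(ref) <- c("srt_reference", "data.frame")
  ref
}

#' Write an allele reference table
#'
#' Inverse of [load_reference()]: the written file reloads field-for-field.
#'
#' @param ref `srt_reference` data.frame
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_reference <- function(ref, path) {
  utils::write.csv(as.data.frame(ref), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' One-row-per-allele view of a reference
#'
#' @param ref `srt_reference` data.frame
#' @return data.frame with label, status, accession, n_profiles, and the
#'   canonical intron length (the first listed profile's intron size).
#' @export
allele_records <- function(ref) {
  first <- !duplicated(ref$label)
  out <- data.frame(
    label = ref$label[first],
    status = ref$status[first],
    accession = ref$accession[first],
    intron_bp = ref$intron_bp[first],
    n_profiles = as.vector(table(ref$label)[ref$label[first]]),
    stringsAsFactors = FALSE
  )
  out[s_allele_order(out$label), , drop = FALSE]
}

#' Load the primer set
#'
#' @param path CSV with columns `name,forward,reverse,source`; defaults to
#'   the packaged five universal Prunus pairs.
#' @return data.frame of primer pairs; sequences are IUPAC DNA
#'   (M = A/C, Y = C/T, W = A/T, R = A/G, ...).
#' @export
load_primers <- function(path = srt_fixture("primers.csv")) {
  pr <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "forward", "reverse")
  if (!all(need %in% names(pr))) stop("malformed primer file")
  ok <- function(s) nzchar(s) & grepl("^[ACGTMRWSYKVHDBN]+$", s)
  if (!all(ok(pr$forward) & ok(pr$reverse))) {
    stop("primer sequences must be non-empty IUPAC DNA")
  }
  pr
}

#' Load a genotype table
#'
#' Reads `cultivar,origin,area,allele1,allele2` rows (allele2 empty for
#' mono-allelic accessions). Areas form a closed vocabulary; allele labels
#' must resolve against the reference or equal the reserved self-compatible
#' label `"SC"`. A cultivar is Chinese iff its area is not `Foreign`.
#'
#' @param path CSV file; defaults to the packaged table of 168 cultivars.
#' @param ref optional `srt_reference` to validate labels against (defaults
#'   to the packaged reference; pass `NULL` to skip label validation).
#' @return data.frame of class `srt_genotypes` with columns cultivar,
#'   origin, area, allele1, allele2 (`NA` when mono-allelic) and sc_flag.
#' @export
load_genotypes <- function(path = srt_fixture("genotypes.csv"),
                           ref = load_reference()) {
  g <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  need <- c("cultivar", "origin", "area", "allele1", "allele2")
  if (!all(need %in% names(g))) stop("malformed genotype file")
  if (nrow(g) == 0L) stop("malformed genotype file: no data rows")
  bad_area <- setdiff(unique(g$area), AREA_LEVELS)
  if (length(bad_area)) {
    stop("unknown area(s): ", paste(bad_area, collapse = ", "))
  }
  if (any(is.na(g$allele1))) {
    stop("allele1 missing for: ",
         paste(g$cultivar[is.na(g$allele1)], collapse = ", "))
  }
  if (!is.null(ref)) {
    legal <- c(unique(ref$label), "SC")
    used <- c(g$allele1, g$allele2[!is.na(g$allele2)])
    off <- setdiff(unique(used), legal)
    if (length(off)) {
      stop("allele label(s) absent from reference: ", paste(off, collapse = ", "))
    }
  }
  g$sc_flag <- g$allele1 == "SC" | (!is.na(g$allele2) & g$allele2 == "SC")
  class(g) <- c("srt_genotypes", "data.frame")
  g
}

#' Alleles of each genotype, as a list
#'
#' @param genotypes `srt_genotypes` data.frame
#' @return named list (by cultivar) of 1- or 2-element character vectors
#' @export
genotype_alleles <- function(genotypes) {
  out <- mapply(function(a, b) if (is.na(b)) a else c(a, b),
                genotypes$allele1, genotypes$allele2,
                SIMPLIFY = FALSE, USE.NAMES = FALSE)
  names(out) <- genotypes$cultivar
  out
}

#' Look up reference alleles by observed fragment size
#'
#' Intron-length polymorphism is the genotyping handle: a gel-derived
#' fragment size on one primer pair shortlists the alleles whose reference
#' size lies within `tol` bp. Results are sorted by absolute size difference,
#' then label.
#'
#' @param ref `srt_reference` data.frame
#' @param primer primer-pair name (must exist in the reference)
#' @param size observed fragment size, bp
#' @param tol nonnegative tolerance, bp
#' @return subset of `ref` rows for that primer pair within tolerance
#' @examples
#' ref <- load_reference()
#' lookup_by_fragment(ref, "Pru-C2/Amy-C5", 827, 5)$label  # "S8"
#' @export
lookup_by_fragment <- function(ref, primer, size, tol = 0) {
  stopifnot(tol >= 0, size > 0)
  if (!primer %in% ref$primer_pair) stop("unknown primer pair: ", primer)
  sub <- ref[ref$primer_pair == primer, , drop = FALSE]
  d <- abs(sub$fragment_bp - size)
  sub <- sub[d <= tol, , drop = FALSE]
  d <- d[d <= tol]
  sub[order(d, sub$label), , drop = FALSE]
}

#' Lint a reference/genotype pair for known transcription quirks
#'
#' Reports, without resolving, the oddities of the published tables: GenBank
#' accessions shared by different allele labels, intron sizes that disagree
#' across primer pairs for one allele, and genotype labels used but never
#' profiled. These are surfaced so downstream users do not mistake them for
#' package bugs.
#'
#' @param ref `srt_reference`
#' @param genotypes optional `srt_genotypes`
#' @return character vector of human-readable notes (possibly empty)
#' @export
lint_reference <- function(ref, genotypes = NULL) {
  notes <- character()
  rec <- ref[!duplicated(ref$label), c("label", "accession")]
  dup <- rec$accession[duplicated(rec$accession)]
  for (acc in unique(dup)) {
    labs <- rec$label[rec$accession == acc]
    notes <- c(notes, sprintf("accession %s shared by alleles %s",
                              acc, paste(labs, collapse = ", ")))
  }
  spread <- tapply(ref$intron_bp, ref$label, function(v) diff(range(v)))
  for (lab in names(spread)[spread > 0]) {
    vals <- ref$intron_bp[ref$label == lab]
    notes <- c(notes, sprintf("allele %s intron size differs across primer pairs: %s",
                              lab, paste(vals, collapse = "/")))
  }
  if (!is.null(genotypes)) {
    used <- unique(unlist(genotype_alleles(genotypes)))
    orphan <- setdiff(used, c(ref$label, "SC"))
    if (length(orphan)) {
      notes <- c(notes, sprintf("genotype labels without reference profile: %s",
                                paste(orphan, collapse = ", ")))
    }
  }
  notes
}
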