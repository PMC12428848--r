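#' Allele calling from fragment sizes and sequences
#'
#' Assigns 1--2 S-allele labels per cultivar from per-primer fragment sizes,
#' using sequence identity to settle fragment-size ties; classifies and
#' names novel alleles; and resolves the self-compatible S_C haplotype from
#' the SFB fragment-size assay (the S_C and S_8 RNase coding regions are
#' identical, so the RNase alone cannot separate them).
#'
#' @name allele_calling
NULL

# Percent identity between two DNA strings. Equal strings short-circuit to
# 100; otherwise a global pairwise alignment's percent identity is used.
seq_identity <- function(a, b) {
  if (identical(a, b)) return(100)
  aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                       Biostrings::DNAString(b),
                                       type = "global")
  Biostrings::pid(aln)
}

# Best identity of `seq` against a set of reference sequences: exact string
# equality is checked first (the common case for clone-consensus data),
# alignments only where needed.
best_identity <- function(seq, ref_seqs) {
  if (length(ref_seqs) == 0L) return(list(label = NA_character_, identity = -Inf))
  exact <- names(ref_seqs)[!is.na(ref_seqs) & ref_seqs == seq]
  if (length(exact)) return(list(label = exact[1L], identity = 100))
  ids <- vapply(ref_seqs, function(r) seq_identity(seq, r), numeric(1))
  list(label = names(ref_seqs)[which.max(ids)], identity = max(ids))
}

#' Call S-alleles for cultivars from fragment observations
#'
#' Each observation (cultivar, primer pair, size, optional product
#' sequence) is matched against the reference: alleles within `size_tol` bp
#' on that primer pair are candidates. Without sequence evidence the
#' unique nearest size wins; equally near candidates are a genuine tie.
#' When a sequence is supplied, candidates must also reach `id_threshold`
#' percent identity to the allele's reference sequence and the
#' best-identity candidate wins. A fragment-size tie is never silently
#' broken:
#' the observation, and hence the cultivar, is flagged ambiguous. When the
#' sequence rejects every size-shortlisted allele but matches another
#' reference allele, the sequence prevails (`sequence_only` evidence, as
#' when a gel size drifts out of tolerance); if a size shortlist existed,
#' the cultivar is additionally flagged as a fragment/sequence conflict.
#' Cultivars with more than two surviving labels are flagged ambiguous
#' rather than truncated.
#'
#' @param obs data.frame with columns `cultivar`, `primer_pair`, `size` and
#'   optionally `seq` (product sequence; `NA` where unsequenced)
#' @param ref `srt_reference` allele table
#' @param ref_seqs optional named character vector of reference allele
#'   sequences (names are allele labels), enabling sequence evidence
#' @param size_tol fragment-size tolerance, bp (default 5)
#' @param id_threshold minimum percent identity for a sequence-supported
#'   call (default 99)
#' @return data.frame of calls (`cultivar`, `label`, `evidence`,
#'   `identity`, `novel`), one row per called allele; unmatched
#'   observations yield `label = NA` with `novel = TRUE` (novel candidate).
#'   Attribute `flags` is a data.frame of per-cultivar statuses
#'   (`ok`, `ambiguous`, `conflict`).
#' @export
call_alleles <- function(obs, ref, ref_seqs = NULL, size_tol = 5,
                         id_threshold = 99) {
  stopifnot(size_tol >= 0, id_threshold > 0, id_threshold <= 100)
  need <- c("cultivar", "primer_pair", "size")
  if (!all(need %in% names(obs))) {
    stop("obs must have columns ", paste(need, collapse = ", "))
  }
  if (!"seq" %in% names(obs)) obs$seq <- NA_character_

  calls <- list(); flags <- list()
  for (cv in unique(obs$cultivar)) {
    sub <- obs[obs$cultivar == cv, , drop = FALSE]
    status <- "ok"
    cv_calls <- list()
    add_call <- function(label, evidence, identity = NA_real_, novel = FALSE) {
      cv_calls[[length(cv_calls) + 1L]] <<- data.frame(
        cultivar = cv, label = label, evidence = evidence,
        identity = identity, novel = novel, stringsAsFactors = FALSE)
    }
    for (i in seq_len(nrow(sub))) {
      cand <- lookup_by_fragment(ref, sub$primer_pair[i], sub$size[i], size_tol)
      has_seq <- !is.na(sub$seq[i]) && !is.null(ref_seqs)
      if (!has_seq) {
        if (nrow(cand) == 0L) {
          add_call(NA_character_, "fragment_only", novel = TRUE)
        } else {
          # the unique nearest size wins; equally near alleles are a tie
          # that only sequence evidence may break
          diffs <- abs(cand$fragment_bp - sub$size[i])
          if (sum(diffs == min(diffs)) > 1L) {
            status <- "ambiguous"
          } else {
            add_call(cand$label[which.min(diffs)], "fragment_only")
          }
        }
        next
      }
      in_cand <- ref_seqs[intersect(cand$label, names(ref_seqs))]
      hit <- best_identity(sub$seq[i], in_cand)
      if (hit$identity >= id_threshold) {
        add_call(hit$label, "fragment+sequence", hit$identity)
        next
      }
      # the sequence rejects every size candidate: let it speak for itself
      other <- best_identity(sub$seq[i],
                             ref_seqs[setdiff(names(ref_seqs), names(in_cand))])
      if (other$identity >= id_threshold) {
        add_call(other$label, "sequence_only", other$identity)
        # a size shortlist the sequence contradicts is a genuine conflict;
        # an out-of-tolerance gel size alone is not
        if (nrow(cand) > 0L) status <- "conflict"
      } else {
        add_call(NA_character_, "fragment+sequence", novel = TRUE)
        if (nrow(cand) > 0L) status <- "conflict"
      }
    }
    got <- do.call(rbind, cv_calls)
    if (!is.null(got)) {
      # one row per called label; every unmatched (novel-candidate)
      # observation is kept, as distinct observations may be distinct alleles
      got <- got[is.na(got$label) | !duplicated(got$label), , drop = FALSE]
      labels <- unique(got$label[!is.na(got$label)])
      if (length(labels) > 2L) status <- "ambiguous"
      calls[[cv]] <- got
    }
    flags[[cv]] <- data.frame(cultivar = cv, status = status,
                              stringsAsFactors = FALSE)
  }
  out <- if (length(calls)) do.call(rbind, calls) else
    data.frame(cultivar = character(), label = character(),
               evidence = character(), identity = numeric(),
               novel = logical(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  flags <- do.call(rbind, flags)
  rownames(flags) <- NULL
  structure(out, flags = flags)
}

#' Classify an annotated sequence as a known or novel allele
#'
#' A sequence is a bona fide novel allele only when it has the full
#' S-RNase architecture (all four conserved domains present) AND its intron
#' length matches no reference allele within `size_tol` AND its RHV string
#' differs from every reference RHV on record. Incomplete domain structure
#' gives status `"unclassifiable"`, never novel; otherwise the best
#' reference match (smallest intron-length difference, RHV-equal preferred)
#' is returned.
#'
#' @param ann `srt_annotation` from [annotate_srnase()]
#' @param ref `srt_reference`
#' @param ref_rhv optional named character vector of reference RHV protein
#'   strings by allele label
#' @param size_tol intron-length tolerance, bp (default 5)
#' @return list with `status` (`"match"`, `"novel"` or `"unclassifiable"`),
#'   `label` (for matches) and `evidence`
#' @export
classify_novel <- function(ann, ref, ref_rhv = NULL, size_tol = 5) {
  stopifnot(inherits(ann, "srt_annotation"))
  domains <- names(ann$domain_hits)
  if (!all(c("C2", "C3", "RC4", "C5") %in% domains)) {
    return(list(status = "unclassifiable",
                evidence = paste("domains missing:",
                                 paste(setdiff(c("C2", "C3", "RC4", "C5"), domains),
                                       collapse = ", "))))
  }
  rec <- ref[!duplicated(ref$label), , drop = FALSE]
  diffs <- vapply(rec$label, function(l) {
    min(abs(ref$intron_bp[ref$label == l] - ann$intron_len))
  }, numeric(1))
  size_hit <- diffs <= size_tol
  rhv <- if (!is.null(ann$rhv)) ann$rhv$seq else ""
  rhv_equal <- if (is.null(ref_rhv)) rep(FALSE, nrow(rec)) else {
    !is.na(ref_rhv[rec$label]) & ref_rhv[rec$label] == rhv
  }
  if (!any(size_hit) && !any(rhv_equal)) {
    return(list(status = "novel",
                evidence = sprintf("intron %d bp and RHV '%s' match no reference allele",
                                   ann$intron_len, rhv)))
  }
  pool <- which(size_hit | rhv_equal)
  pool <- pool[order(!rhv_equal[pool], diffs[pool], rec$label[pool])]
  list(status = "match", label = rec$label[pool[1L]],
       evidence = sprintf("intron diff %d bp, RHV %s", diffs[pool[1L]],
                          if (rhv_equal[pool[1L]]) "identical" else "differs"))
}

#' Mint the next novel allele name
#'
#' Continues the existing numbering: suffixed labels ("S14a") and split
#' labels ("S18-1") map to their base numbers, and the successor of the
#' maximum base number is returned.
#'
#' @param existing character vector of existing allele labels
#' @return the new label, e.g. `"S108"` after a set ending at S107
#' @export
name_novel <- function(existing) {
  base <- suppressWarnings(as.integer(sub("^S(\\d+).*$", "\\1", existing)))
  base <- base[!is.na(base)]
  if (length(base) == 0L) stop("no numeric allele labels to continue from")
  paste0("S", max(base) + 1L)
}

#' Resolve S_C versus S_8 from the SFB fragment assay
#'
#' The S_C and S_8 RNases are identical in coding sequence; the haplotypes
#' differ by a 358 bp insertion in the pollen-side SFB gene. The two-step
#' assay first amplifies the shared S_C/S_8 RNase; positives are then
#' separated by SFB product size: about 500 bp marks SFB_C (self-compatible
#' haplotype) and about 150 bp marks SFB_8.
#'
#' @param rnase_positive did the S_C/S_8 RNase-specific PCR amplify?
#' @param sfb_size SFB product size in bp, or `NA` when absent
#' @param tol size tolerance, bp (default 50, absorbing "approximately")
#' @return one of `"SC"`, `"S8"`, `"neither"`, `"indeterminate"`
#' @examples
#' resolve_sc(TRUE, 500)    # "SC"  (as for Bora, Bergeron, Ninfa)
#' resolve_sc(TRUE, 150)    # "S8"
#' resolve_sc(FALSE, NA)    # "neither" (negative control)
#' @export
resolve_sc <- function(rnase_positive, sfb_size = NA, tol = 50) {
  stopifnot(is.logical(rnase_positive), length(rnase_positive) == 1L, tol >= 0)
  if (!rnase_positive) return("neither")
  if (is.na(sfb_size)) return("indeterminate")
  if (abs(sfb_size - 500) <= tol) return("SC")
  if (abs(sfb_size - 150) <= tol) return("S8")
  "indeterminate"
}
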