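#' Cross-(in)compatibility classification
#'
#' Under gametophytic self-incompatibility a pollen grain is rejected iff
#' its single S-haplotype matches either pistil allele. Two complete
#' genotypes sharing no allele are fully cross-compatible; sharing one
#' allele leaves half the pollen compatible (semi-compatible); sharing both
#' makes the cross incompatible -- such cultivars cannot pollinate each
#' other and form a cross-incompatibility group. The self-compatible S_C
#' haplotype is universally accepted pollen.
#'
#' @name compatibility
NULL

#' Classify one cross
#'
#' `pistil` x `pollen` direction matters only through S_C: S_C in the
#' pollen parent's genotype makes the cross fully compatible regardless of
#' sharing. With both genotypes complete, the shared-allele count decides
#' (0 = fully compatible, 1 = semi-compatible, 2 = incompatible). With an
#' incomplete (mono-allelic) genotype the relation is undetermined unless
#' two known alleles are shared (then incompatible).
#'
#' @param pistil,pollen 1- or 2-element character vectors of allele labels
#'   (or single rows of an `srt_genotypes` table)
#' @return list with `relation` (`fully_compatible`, `semi_compatible`,
#'   `incompatible`, `undetermined`) and `shared` labels
#' @examples
#' classify_pair(c("S8", "S53"), c("S8", "S11"))$relation  # semi_compatible
#' @export
classify_pair <- function(pistil, pollen) {
  as_alleles <- function(x) {
    if (is.data.frame(x)) x <- unlist(genotype_alleles(x), use.names = FALSE)
    stopifnot(is.character(x), length(x) %in% 1:2)
    x
  }
  a <- as_alleles(pistil); b <- as_alleles(pollen)
  shared <- intersect(setdiff(a, "SC"), setdiff(b, "SC"))
  if ("SC" %in% b) {
    return(list(relation = "fully_compatible", shared = shared))
  }
  complete <- length(a) == 2L && length(b) == 2L
  relation <- if (length(shared) == 2L) {
    "incompatible"
  } else if (complete) {
    c("fully_compatible", "semi_compatible")[length(shared) + 1L]
  } else {
    "undetermined"
  }
  list(relation = relation, shared = shared)
}

#' Pairwise compatibility matrix
#'
#' Rows are pistil (seed) parents, columns pollen parents. Cells are coded
#' F (fully compatible), S (semi-compatible), I (incompatible),
#' U (undetermined); undetermined relations are never silently promoted.
#'
#' @param genotypes `srt_genotypes` data.frame
#' @return character matrix with cultivar dimnames
#' @export
compatibility_matrix <- function(genotypes) {
  alleles <- genotype_alleles(genotypes)
  n <- length(alleles)
  code <- c(fully_compatible = "F", semi_compatible = "S",
            incompatible = "I", undetermined = "U")
  m <- matrix("", n, n, dimnames = list(genotypes$cultivar, genotypes$cultivar))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      m[i, j] <- code[[classify_pair(alleles[[i]], alleles[[j]])$relation]]
    }
  }
  m
}

#' Cross-incompatibility groups
#'
#' Cultivars with identical complete two-allele genotypes share a group:
#' members cannot pollinate each other. Mono-allelic cultivars each form a
#' singleton provisional group, since the undetected allele could place
#' them anywhere.
#'
#' @param genotypes `srt_genotypes` data.frame
#' @return data.frame (cultivar, genotype, group, provisional), with group
#'   ids assigned in order of first appearance
#' @export
incompatibility_groups <- function(genotypes) {
  alleles <- genotype_alleles(genotypes)
  key <- vapply(alleles, function(a) {
    if (length(a) == 2L) paste(sort_alleles(a), collapse = "|") else NA_character_
  }, character(1))
  provisional <- is.na(key)
  key[provisional] <- paste0("provisional:", genotypes$cultivar[provisional])
  group <- match(key, unique(key))
  data.frame(cultivar = genotypes$cultivar,
             genotype = vapply(alleles, paste, character(1), collapse = " "),
             group = group, provisional = provisional,
             stringsAsFactors = FALSE)
}

#' Flag self-compatible cultivars
#'
#' A cultivar is flagged self-compatible iff its genotype contains the S_C
#' haplotype.
#'
#' @param genotypes `srt_genotypes` data.frame
#' @return data.frame (cultivar, area, flag)
#' @export
self_compatibility_flags <- function(genotypes) {
  data.frame(cultivar = genotypes$cultivar, area = genotypes$area,
             flag = genotypes$sc_flag, stringsAsFactors = FALSE)
}

#' Check parent--offspring S-allele consistency
#'
#' With two parents, a complete child genotype is consistent iff its two
#' alleles can be assigned one from each parent; a mono-allelic child is
#' consistent iff its allele occurs in either parent. With a single parent,
#' at least one child allele must come from that parent.
#'
#' @param child,p1,p2 allele label vectors (1--2 labels); `p2` may be `NULL`
#' @return list with `consistent` and, when consistent with two parents and
#'   a complete child, the `assignment` of child alleles to parents
#' @examples
#' check_parentage(c("S9", "S36"), c("S9", "S16"), c("S36", "S102"))
#' @export
check_parentage <- function(child, p1, p2 = NULL) {
  stopifnot(length(child) %in% 1:2)
  if (is.null(p2)) {
    hit <- intersect(child, p1)
    return(list(consistent = length(hit) > 0L,
                assignment = if (length(hit)) stats::setNames(hit[1L], "p1")))
  }
  if (length(child) == 1L) {
    from1 <- child %in% p1; from2 <- child %in% p2
    return(list(consistent = from1 || from2,
                assignment = if (from1) stats::setNames(child, "p1")
                             else if (from2) stats::setNames(child, "p2")))
  }
  if (child[1] %in% p1 && child[2] %in% p2) {
    return(list(consistent = TRUE,
                assignment = stats::setNames(child, c("p1", "p2"))))
  }
  if (child[1] %in% p2 && child[2] %in% p1) {
    return(list(consistent = TRUE,
                assignment = stats::setNames(child[2:1], c("p1", "p2"))))
  }
  list(consistent = FALSE, assignment = NULL)
}
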