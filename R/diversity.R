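#' Allele diversity statistics
#'
#' Counts, relative frequencies, heterozygosity and distinct-allele
#' inventories over the genotype table, overall and stratified by origin
#' group or geographic area. The frequency denominator is the total number
#' of DETECTED allele occurrences in the stratum (not twice the accession
#' count): mono-allelic accessions contribute one occurrence, heterozygous
#' ones two. That convention is what reproduces the published regional
#' percentages.
#'
#' @name diversity_stats
NULL

# Resolve a stratum filter to a logical row mask.
#  - NULL: everything
#  - "Chinese"/"Foreign": national split (Chinese = every non-Foreign area)
#  - an area name: that area
#  - a logical vector: used as-is
stratum_mask <- function(genotypes, stratum) {
  if (is.null(stratum)) return(rep(TRUE, nrow(genotypes)))
  if (is.logical(stratum)) {
    stopifnot(length(stratum) == nrow(genotypes))
    return(stratum)
  }
  stopifnot(is.character(stratum), length(stratum) == 1L)
  if (stratum == "Chinese") return(genotypes$area != "Foreign")
  if (stratum %in% AREA_LEVELS) return(genotypes$area == stratum)
  stop("unknown stratum: ", stratum)
}

#' Allele counts and frequencies for a stratum
#'
#' An allele occurring in a genotype counts once per accession. The
#' percentage of each allele is its count over the stratum's total detected
#' allele occurrences, rounded half-up to the nearest integer.
#'
#' @param genotypes `srt_genotypes` data.frame
#' @param stratum `NULL` (all), `"Chinese"`, `"Foreign"`, an area name, or
#'   a logical row mask
#' @return object of class `srt_freqtable`: list with `stratum`,
#'   `n_accessions`, `n_allele_obs`, `counts` (named, sorted by decreasing
#'   count then allele order) and `freq_pct`
#' @examples
#' g <- load_genotypes()
#' allele_counts(g, "Chinese")$counts[c("S11", "S8")]  # 26, 23
#' @export
allele_counts <- function(genotypes, stratum = NULL) {
  mask <- stratum_mask(genotypes, stratum)
  if (!any(mask)) {
    stop("empty stratum: ", if (is.character(stratum)) stratum else "<mask>")
  }
  sub <- genotypes[mask, , drop = FALSE]
  alleles <- unlist(genotype_alleles(sub), use.names = FALSE)
  t0 <- table(alleles)
  tab <- as.vector(t0); names(tab) <- names(t0)
  allele_rank <- order(s_allele_order(names(tab)))  # inverse permutation
  tab <- tab[order(-tab, allele_rank)]
  n_obs <- length(alleles)
  structure(
    list(stratum = if (is.character(stratum)) stratum else
           if (is.null(stratum)) "All" else "<mask>",
         n_accessions = nrow(sub),
         n_allele_obs = n_obs,
         counts = tab,
         freq_pct = round_half_up(100 * tab / n_obs)),
    class = "srt_freqtable"
  )
}

#' Recompute percentage frequencies from a frequency table
#'
#' @param table `srt_freqtable` from [allele_counts()]
#' @return named vector of integer percentages (half-up rounding)
#' @export
allele_frequencies <- function(table) {
  stopifnot(inherits(table, "srt_freqtable"), table$n_allele_obs > 0)
  round_half_up(100 * table$counts / table$n_allele_obs)
}

#' @export
print.srt_freqtable <- function(x, ...) {
  cat(sprintf("Stratum %s: %d accessions, %d detected allele occurrences\n",
              x$stratum, x$n_accessions, x$n_allele_obs))
  df <- data.frame(allele = names(x$counts), count = as.vector(x$counts),
                   freq_pct = as.vector(x$freq_pct))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Heterozygosity summary
#'
#' Partitions accessions into two-allele (heterozygous at the S locus) and
#' mono-allelic (single detectable allele; whether the cause is a large
#' intron, a complex background or homozygosity is left undetermined).
#'
#' @param genotypes `srt_genotypes` data.frame
#' @return list with `n_two_allele`, `n_one_allele` and `pct_two`
#'   (one-decimal percentage of two-allele accessions)
#' @export
heterozygosity_summary <- function(genotypes) {
  stopifnot(nrow(genotypes) >= 1L)
  two <- !is.na(genotypes$allele2)
  list(n_two_allele = sum(two), n_one_allele = sum(!two),
       pct_two = round_half_up(100 * sum(two) / nrow(genotypes), 1))
}

#' Distinct alleles present in a set of genotypes
#'
#' @param genotypes `srt_genotypes` data.frame (possibly a stratum subset)
#' @param include_sc include the reserved self-compatible label `"SC"`?
#' @return sorted character vector of allele labels
#' @export
distinct_alleles <- function(genotypes, include_sc = FALSE) {
  labels <- as.character(unique(unlist(genotype_alleles(genotypes),
                                       use.names = FALSE)))
  if (!include_sc) labels <- setdiff(labels, "SC")
  sort_alleles(labels)
}

#' Regional frequency profiles
#'
#' One frequency table per named Chinese production region. `UnclearChina`
#' rows count toward national Chinese statistics but are excluded here, as
#' the regional profiles cover the five named regions plus Xinjiang.
#'
#' @param genotypes `srt_genotypes` data.frame
#' @param regions area names to profile (default: the five named regions
#'   and Xinjiang)
#' @return named list of `srt_freqtable`s
#' @export
regional_profiles <- function(genotypes,
                              regions = c("NorthChina", "CentralChina",
                                          "EastChina", "NortheastChina",
                                          "NorthwestChina", "Xinjiang")) {
  out <- lapply(regions, function(r) allele_counts(genotypes, r))
  names(out) <- regions
  out
}

#' Long-format frequency table across strata
#'
#' @param genotypes `srt_genotypes`
#' @param strata character vector of strata (default: national split plus
#'   the regional profiles)
#' @return data.frame (stratum, allele, count, freq_pct)
#' @export
frequency_long <- function(genotypes,
                           strata = c("Chinese", "Foreign", "NorthChina",
                                      "CentralChina", "EastChina",
                                      "NortheastChina", "NorthwestChina",
                                      "Xinjiang")) {
  do.call(rbind, lapply(strata, function(s) {
    ft <- allele_counts(genotypes, s)
    data.frame(stratum = s, allele = names(ft$counts),
               count = as.vector(ft$counts),
               freq_pct = as.vector(ft$freq_pct),
               stringsAsFactors = FALSE)
  }))
}
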