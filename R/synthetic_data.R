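#' Synthetic S-RNase data generation
#'
#' Stands in for the wet-lab steps (DNA extraction, PCR, cloning, gel
#' sizing, sequencing) with fully controlled ground truth: genomic allele
#' sequences carrying the canonical S-RNase architecture -- two exons
#' flanking one GT..AG second intron inside the RHV-encoding region, with
#' the conserved C2/C3/RC4/C5 blocks -- plus cultivar panels drawn from
#' stated allele-frequency vectors and per-primer fragment-size
#' observations with optional integer-rounded Gaussian measurement noise.
#' Every generator is a pure function of its spec and seed.
#'
#' @name synthetic_data
NULL

# Fixed reverse-translation codon choices (never a stop codon).
CODON_OF <- c(
  A = "GCT", R = "CGT", N = "AAC", D = "GAT", C = "TGC", Q = "CAA",
  E = "GAA", G = "GGT", H = "CAT", I = "ATT", L = "CTT", K = "AAG",
  M = "ATG", F = "TTC", P = "CCA", S = "TCT", T = "ACT", W = "TGG",
  Y = "TAC", V = "GTT"
)
FILLER_AA <- setdiff(names(CODON_OF), c("W", "M"))  # unremarkable filler

revtrans <- function(aa) {
  chars <- strsplit(aa, "")[[1]]
  bad <- setdiff(chars, names(CODON_OF))
  if (length(bad)) stop("cannot reverse-translate: ", paste(bad, collapse = ","))
  paste(CODON_OF[chars], collapse = "")
}

# All concrete expansions of an IUPAC primer (degenerate positions only).
expand_iupac <- function(primer) {
  sets <- IUPAC_SETS[strsplit(primer, "")[[1]]]
  if (prod(lengths(sets)) > 256L) stop("primer too degenerate to enumerate")
  out <- ""
  for (s in sets) out <- as.vector(outer(out, s, paste0))
  out
}

# Reading phases phi (offset of the first full codon inside `seq`, given
# the global codon grid) at which no complete codon inside `seq` is a stop.
safe_phases <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  ok <- logical(3)
  for (phi in 0:2) {
    n_cod <- (length(chars) - phi) %/% 3L
    stops <- FALSE
    if (n_cod > 0L) {
      for (k in seq_len(n_cod)) {
        cod <- paste(chars[phi + (3L * k - 2L):(3L * k)], collapse = "")
        if (cod %in% c("TAA", "TAG", "TGA")) { stops <- TRUE; break }
      }
    }
    ok[phi + 1L] <- !stops
  }
  which(ok) - 1L
}

# Smallest pad length >= 3 giving `start + pad` the residue `res` mod 3.
pad_to <- function(start, res = 0L) {
  p <- 3L
  while ((start + p) %% 3L != res %% 3L) p <- p + 1L
  p
}

random_nt <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_aa <- function(n) paste(sample(FILLER_AA, n, replace = TRUE), collapse = "")

# Concrete amino-acid form of a domain model (first allowed letter at
# set positions) and its fixed coding DNA.
domain_block <- function(model) {
  aa <- paste(vapply(model$sets, `[`, character(1), 1L), collapse = "")
  list(aa = aa, nt = revtrans(aa))
}

#' Specify a synthetic allele
#'
#' @param label allele label
#' @param intron_len designed second-intron length, bp (>= 4)
#' @param primer_pair primer-pair name for the embedded amplification site
#' @param amplicon_size designed amplicon size, bp; must exceed
#'   `intron_len` by the exonic footprint the layout needs
#' @param rhv_protein amino-acid string for the hypervariable region, or
#'   `NULL` to let the generator invent one (required for footprints too
#'   small to keep the primers out of the RHV)
#' @param rhv_len length of an invented RHV, amino acids
#' @return an `srt_allele_spec` list
#' @export
allele_spec <- function(label, intron_len, primer_pair, amplicon_size,
                        rhv_protein = NULL, rhv_len = 8L) {
  stopifnot(intron_len >= 4L, amplicon_size > intron_len)
  structure(list(label = label, intron_len = as.integer(intron_len),
                 primer_pair = primer_pair,
                 amplicon_size = as.integer(amplicon_size),
                 rhv_protein = rhv_protein, rhv_len = as.integer(rhv_len)),
            class = "srt_allele_spec")
}

# Pick primer expansions and a forward-slot phase such that no complete
# codon inside either primer footprint is a stop. phiR is forced relative
# to phiF by the exonic footprint geometry.
choose_primer_phasing <- function(fwd, rev, footprint) {
  fexps <- expand_iupac(fwd)
  rexps <- vapply(expand_iupac(rev), revcomp, character(1))
  p2 <- nchar(rev)
  for (fe in fexps) {
    safe_f <- safe_phases(fe)
    for (re in rexps) {
      safe_r <- safe_phases(re)
      for (phiF in safe_f) {
        phiR <- ((phiF - (footprint - p2)) %% 3L + 3L) %% 3L
        if (phiR %in% safe_r) {
          return(list(fwd_site = fe, rev_site = re, phiF = phiF))
        }
      }
    }
  }
  stop("infeasible layout: no stop-free primer phasing for this footprint")
}

# Assemble segments (list of lists with nt, mutable, role) into a record.
assemble_segments <- function(segs) {
  nt <- paste(vapply(segs, `[[`, character(1), "nt"), collapse = "")
  lens <- vapply(segs, function(s) nchar(s$nt), integer(1))
  ends <- cumsum(lens)
  starts <- ends - lens            # 0-based starts
  roles <- vapply(segs, `[[`, character(1), "role")
  mutable <- rep(vapply(segs, `[[`, logical(1), "mutable"), lens)
  list(nt = nt, starts = stats::setNames(starts, roles),
       ends = stats::setNames(ends, roles), mutable = mutable,
       roles = roles)
}

# Replace frame-0 stop codons in the spliced sequence by mutating one
# mutable genomic position to C. Positions inside primers, domain blocks,
# the designed RHV and the intron ends are immutable by construction.
fix_stops <- function(genomic, intron_span, mutable) {
  g <- strsplit(genomic, "")[[1]]
  spliced_idx <- c(seq_len(intron_span[1]),
                   seq((intron_span[2] + 1L), length(g)))  # 1-based genomic
  repeat {
    sp <- g[spliced_idx]
    n_cod <- length(sp) %/% 3L
    changed <- FALSE
    for (k in seq_len(n_cod)) {
      idx <- (3L * k - 2L):(3L * k)
      cod <- paste(sp[idx], collapse = "")
      if (cod %in% c("TAA", "TAG", "TGA")) {
        gpos <- spliced_idx[idx]
        open <- gpos[mutable[gpos]]
        if (length(open) == 0L) {
          stop("internal error: unfixable stop codon in immutable region")
        }
        g[open[1L]] <- "C"
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  paste(g, collapse = "")
}

#' Generate a synthetic S-RNase genomic sequence with ground truth
#'
#' Builds a genomic record that carries a designed GT..AG second intron of
#' exactly `intron_len` bp inside the RHV-encoding region, the four
#' conserved domain blocks in order, and an amplification site for the
#' spec's primer pair whose product size is exactly `amplicon_size`
#' (`= intron_len +` exonic footprint). Large footprints place the primers
#' outside the C2..C3 (or C2..C5) core; footprints too small for that
#' embed the primer sites inside the RHV-coding DNA itself, mirroring how
#' the universal primers anneal within the conserved regions, in which case
#' the generator composes the RHV and reports it in the truth record.
#' Annotation of the result recovers the designed intron length, domain
#' offsets and RHV exactly; the same seed always yields the same sequence.
#'
#' @param spec `srt_allele_spec` from [allele_spec()]
#' @param seed integer seed
#' @param models domain models (default: packaged fixture)
#' @param primers primer table (default: packaged fixture)
#' @return list with `seq`, `coding_ref`, `intron_span` (0-based half-open,
#'   genomic), `intron_len`, `exon_spans`, `frame` (always 0), `protein`,
#'   `domain_offsets` (0-based aa starts), `rhv`, `amplicon`
#'   (`fwd_start`, `rev_end`, `size`), `label`, `primer_pair`, `layout`
#' @export
make_allele_sequence <- function(spec, seed, models = load_domain_models(),
                                 primers = load_primers()) {
  stopifnot(inherits(spec, "srt_allele_spec"))
  pri <- primers[primers$name == spec$primer_pair, , drop = FALSE]
  if (nrow(pri) != 1L) stop("unknown primer pair: ", spec$primer_pair)
  p1 <- nchar(pri$forward); p2 <- nchar(pri$reverse)
  L <- spec$intron_len
  F_ <- spec$amplicon_size - L
  blocks <- lapply(models[c("C2", "C3", "RC4", "C5")], domain_block)
  b30 <- vapply(blocks, function(b) nchar(b$nt), integer(1))

  rhv_nt_designed <- if (!is.null(spec$rhv_protein)) revtrans(spec$rhv_protein)
  need_long  <- p1 + p2 + sum(b30) + 3L * 10L +
    ifelse(is.null(spec$rhv_protein), 3L * spec$rhv_len, nchar(rhv_nt_designed))
  need_short <- p1 + p2 + b30[["C2"]] + b30[["C3"]] + 3L * 4L +
    ifelse(is.null(spec$rhv_protein), 3L * spec$rhv_len, nchar(rhv_nt_designed))
  layout <- if (F_ >= need_long) "flank_long"
            else if (F_ >= need_short) "flank_short"
            else if (is.null(spec$rhv_protein) && F_ >= p1 + p2) "embedded"
            else stop("infeasible layout: footprint ", F_,
                      " bp cannot accommodate the primer sites",
                      if (!is.null(spec$rhv_protein)) " with a fixed RHV")
  phasing <- choose_primer_phasing(pri$forward, pri$reverse, F_)

  for (attempt in 1:8) {
    res <- with_seed(seed * 131L + attempt, {
      build_record(spec, layout, phasing, blocks, p1, p2, F_, L)
    })
    # verification: the designed annotation must be recovered exactly
    spans <- tryCatch(find_intron(res$seq, res$coding_ref),
                      error = function(e) NULL)
    ok <- !is.null(spans) &&
      identical(spans$intron_span, res$intron_span) &&
      spans$identity == 1
    if (ok) {
      prot <- deduce_protein(splice_exons(res$seq, spans), frame = 0L)
      hits <- scan_domains(as.character(prot), models)
      rhv <- if (!is.null(hits$C2) && !is.null(hits$C3)) {
        extract_rhv(as.character(prot), hits)
      }
      ok <- all(c("C2", "C3", "RC4", "C5") %in% names(hits)) &&
        !is.null(rhv) && identical(rhv$seq, res$rhv) &&
        identical(unname(vapply(hits, `[`, integer(1), 1L)),
                  unname(res$domain_offsets))
    }
    if (ok) {
      amp <- amplicons(res$seq, pri)
      ok <- spec$amplicon_size %in% amp$size
    }
    if (ok) {
      res$protein <- as.character(prot)
      res$label <- spec$label
      res$primer_pair <- spec$primer_pair
      res$layout <- layout
      res$frame <- 0L
      return(res)
    }
  }
  stop("could not realize a unique, recoverable layout for ", spec$label)
}

# One construction attempt; runs under a seeded RNG stream.
build_record <- function(spec, layout, phasing, blocks, p1, p2, F_, L) {
  fwd <- phasing$fwd_site; rev <- phasing$rev_site; phiF <- phasing$phiF
  seg <- function(nt, mutable, role) list(nt = nt, mutable = mutable, role = role)
  intron_nt <- paste0("GT", random_nt(L - 4L), "AG")
  segs <- list()
  if (layout %in% c("flank_long", "flank_short")) {
    rhv_aa <- if (is.null(spec$rhv_protein)) random_aa(spec$rhv_len) else spec$rhv_protein
    rhv_nt <- revtrans(rhv_aa)
    f5 <- 6L + ((3L - phiF) %% 3L)
    pad_a <- pad_to(f5 + p1, 0L)
    core <- p1 + pad_a + nchar(blocks$C2$nt) + nchar(rhv_nt) + nchar(blocks$C3$nt) + p2
    if (layout == "flank_long") {
      pad_b <- 6L; pad_c <- 6L
      pad_d <- F_ - core - pad_b - pad_c -
        nchar(blocks$RC4$nt) - nchar(blocks$C5$nt)
    } else {
      pad_b <- F_ - core
    }
    # split the RHV coding region around the intron at a codon boundary
    cut <- 3L * (nchar(rhv_nt) %/% 6L)
    segs <- c(segs, list(
      seg(random_nt(f5), TRUE, "f5"),
      seg(fwd, FALSE, "fwd"),
      seg(random_nt(pad_a), TRUE, "pad_a"),
      seg(blocks$C2$nt, FALSE, "C2"),
      seg(substr(rhv_nt, 1L, cut), FALSE, "rhv1"),
      seg(intron_nt, FALSE, "intron"),
      seg(substr(rhv_nt, cut + 1L, nchar(rhv_nt)), FALSE, "rhv2"),
      seg(blocks$C3$nt, FALSE, "C3")
    ))
    if (layout == "flank_long") {
      segs <- c(segs, list(
        seg(random_nt(pad_b), TRUE, "pad_b"),
        seg(blocks$RC4$nt, FALSE, "RC4"),
        seg(random_nt(pad_c), TRUE, "pad_c"),
        seg(blocks$C5$nt, FALSE, "C5"),
        seg(random_nt(pad_d), TRUE, "pad_d"),
        seg(rev, FALSE, "rev"),
        seg(random_nt(6L), TRUE, "f3")
      ))
    } else {
      segs <- c(segs, list(
        seg(random_nt(pad_b), TRUE, "pad_b"),
        seg(rev, FALSE, "rev"),
        seg("", TRUE, "pad_c_marker"),  # placeholder, resolved after layout
        seg(blocks$RC4$nt, FALSE, "RC4"),
        seg(random_nt(6L), TRUE, "pad_d_pre"),
        seg(blocks$C5$nt, FALSE, "C5"),
        seg(random_nt(6L), TRUE, "f3")
      ))
    }
  } else {  # embedded: primers inside the RHV-coding region
    f5 <- 6L
    nC2 <- nchar(blocks$C2$nt)
    ra <- pad_to(f5 + nC2, (3L - phiF) %% 3L)
    rb <- (F_ - p1 - p2) %/% 2L
    rc <- F_ - p1 - p2 - rb
    rd <- pad_to(f5 + nC2 + ra + p1 + rb + rc + p2, 0L)
    segs <- list(
      seg(random_nt(f5), TRUE, "f5"),
      seg(blocks$C2$nt, FALSE, "C2"),
      seg(random_nt(ra), TRUE, "rhv_ra"),
      seg(fwd, FALSE, "fwd"),
      seg(random_nt(rb), TRUE, "rhv_rb"),
      seg(intron_nt, FALSE, "intron"),
      seg(random_nt(rc), TRUE, "rhv_rc"),
      seg(rev, FALSE, "rev"),
      seg(random_nt(rd), TRUE, "rhv_rd"),
      seg(blocks$C3$nt, FALSE, "C3"),
      seg(random_nt(6L), TRUE, "pad_b"),
      seg(blocks$RC4$nt, FALSE, "RC4"),
      seg(random_nt(6L), TRUE, "pad_c"),
      seg(blocks$C5$nt, FALSE, "C5"),
      seg(random_nt(6L), TRUE, "f3")
    )
  }
  asm <- assemble_segments(segs)
  if (layout == "flank_short") {
    # RC4/C5 sit downstream of the rev slot, whose end is not on the codon
    # grid; the placeholder pad grows to restore 0 mod 3 for RC4 (C5 then
    # follows aligned, as the pads and blocks between are multiples of 3)
    i_marker <- which(asm$roles == "pad_c_marker")
    spliced_start <- function(g0) g0 - ifelse(g0 >= asm$ends[["intron"]], L, 0L)
    need <- (3L - (spliced_start(asm$starts[["RC4"]]) + 3L) %% 3L) %% 3L
    segs[[i_marker]]$nt <- random_nt(3L + need)
    asm <- assemble_segments(segs)
  }
  intron_span <- c(asm$starts[["intron"]], asm$ends[["intron"]])
  genomic <- fix_stops(asm$nt, intron_span, asm$mutable)
  ng <- nchar(genomic)
  coding_ref <- paste0(substr(genomic, 1L, intron_span[1]),
                       substr(genomic, intron_span[2] + 1L, ng))
  spliced_pos <- function(g0) g0 - ifelse(g0 >= intron_span[2], L, 0L)
  aa_off <- function(role) as.integer(spliced_pos(asm$starts[[role]]) %/% 3L)
  prot <- as.character(deduce_protein(coding_ref, frame = 0L))
  rhv_span <- c(spliced_pos(asm$ends[["C2"]]) %/% 3L,
                spliced_pos(asm$starts[["C3"]]) %/% 3L)
  rhv_seq <- substr(prot, rhv_span[1] + 1L, rhv_span[2])
  list(
    seq = genomic,
    coding_ref = coding_ref,
    intron_span = as.integer(intron_span),
    intron_len = L,
    exon_spans = rbind(c(0L, intron_span[1]), c(intron_span[2], ng)),
    protein = prot,
    domain_offsets = vapply(c("C2", "C3", "RC4", "C5"), aa_off, integer(1)),
    rhv = rhv_seq,
    rhv_span = as.integer(rhv_span),
    amplicon = c(fwd_start = unname(asm$starts[["fwd"]]),
                 rev_end = unname(asm$ends[["rev"]]),
                 size = unname(asm$ends[["rev"]] - asm$starts[["fwd"]]))
  )
}

#' Synthetic allele specs mirroring the packaged reference
#'
#' One spec per reference allele, using its first listed primer-pair
#' profile as the designed amplification site and its published intron
#' size. RHVs are generator-invented (deterministically per seed) so that
#' every allele has a distinct hypervariable region.
#'
#' @param ref `srt_reference`
#' @param seed integer seed
#' @return named list of `srt_allele_spec`s
#' @export
make_reference_specs <- function(ref, seed = 1L) {
  first <- ref[!duplicated(ref$label), , drop = FALSE]
  specs <- lapply(seq_len(nrow(first)), function(i) {
    allele_spec(first$label[i], first$intron_bp[i], first$primer_pair[i],
                first$fragment_bp[i], rhv_protein = NULL, rhv_len = 8L)
  })
  names(specs) <- first$label
  specs
}

#' Generate the full synthetic allele library
#'
#' @param ref `srt_reference`
#' @param seed integer seed
#' @return list with `truths` (per-allele ground-truth records), `seqs`
#'   (named character vector of genomic sequences) and `rhv` (named RHV
#'   strings)
#' @export
make_allele_library <- function(ref, seed = 1L) {
  specs <- make_reference_specs(ref, seed)
  models <- load_domain_models()
  primers <- load_primers()
  truths <- lapply(seq_along(specs), function(i) {
    make_allele_sequence(specs[[i]], seed + 7919L * i, models, primers)
  })
  names(truths) <- names(specs)
  list(truths = truths,
       seqs = vapply(truths, `[[`, character(1), "seq"),
       rhv = vapply(truths, `[[`, character(1), "rhv"))
}

#' Simulate a cultivar panel with fragment observations
#'
#' Each accession draws two alleles independently from the frequency
#' vector (Hardy--Weinberg-like); identical draws collapse to a single
#' listed allele, mimicking mono-allelic table rows, unless `force_het`
#' resamples to distinct pairs. Fragment sizes are the reference designed
#' sizes plus integer-rounded Gaussian noise (gels report whole base
#' pairs). A truth table is emitted alongside the observations.
#'
#' @param n_accessions number of accessions (>= 1)
#' @param freq named probability vector over reference allele labels
#'   (must sum to 1)
#' @param ref `srt_reference`
#' @param seed integer seed
#' @param noise_sd fragment-size noise standard deviation, bp
#' @param force_het resample identical draws into heterozygous pairs?
#' @param library optional [make_allele_library()] result; when given,
#'   each observation carries the allele's genomic sequence as sequencing
#'   evidence
#' @param region_label stratum label recorded on the truth table
#' @return list with `truth` (an `srt_genotypes`-shaped data.frame) and
#'   `obs` (cultivar, primer_pair, size, seq)
#' @export
make_panel <- function(n_accessions, freq, ref, seed, noise_sd = 0,
                       force_het = FALSE, library = NULL,
                       region_label = "Synthetic") {
  stopifnot(n_accessions >= 1L, abs(sum(freq) - 1) < 1e-8,
            all(names(freq) %in% ref$label))
  with_seed(seed, {
    draws <- replicate(n_accessions, {
      a <- sample(names(freq), 2L, replace = TRUE, prob = freq)
      if (force_het) while (a[1] == a[2]) {
        a <- sample(names(freq), 2L, replace = TRUE, prob = freq)
      }
      a
    })
    cultivar <- sprintf("ACC%04d", seq_len(n_accessions))
    collapsed <- draws[1, ] == draws[2, ]
    truth <- data.frame(
      cultivar = cultivar, origin = region_label, area = "UnclearChina",
      allele1 = draws[1, ],
      allele2 = ifelse(collapsed, NA_character_, draws[2, ]),
      stringsAsFactors = FALSE
    )
    truth$sc_flag <- FALSE
    class(truth) <- c("srt_genotypes", "data.frame")
    obs <- do.call(rbind, lapply(seq_len(n_accessions), function(i) {
      alleles <- unique(draws[, i])
      do.call(rbind, lapply(alleles, function(a) {
        prof <- ref[ref$label == a, , drop = FALSE]
        data.frame(
          cultivar = cultivar[i], allele = a,
          primer_pair = prof$primer_pair,
          size = as.integer(prof$fragment_bp +
                            round(stats::rnorm(nrow(prof), 0, noise_sd))),
          seq = if (is.null(library)) NA_character_ else
            unname(library$seqs[a]),
          stringsAsFactors = FALSE
        )
      }))
    }))
    list(truth = truth, obs = obs)
  })
}

#' Genotype recovery rate of calls against a panel truth table
#'
#' @param calls output of [call_alleles()]
#' @param truth truth table from [make_panel()]
#' @return fraction of accessions whose called label set equals the truth
#'   label set exactly
#' @export
genotype_recovery <- function(calls, truth) {
  truth_sets <- genotype_alleles(truth)
  hit <- vapply(names(truth_sets), function(cv) {
    got <- calls$label[calls$cultivar == cv & !is.na(calls$label)]
    setequal(unique(got), unique(truth_sets[[cv]]))
  }, logical(1))
  mean(hit)
}
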