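make_gene <- function(e1, intron_body, e2) {
  list(genomic = paste0(e1, "GT", intron_body, "AG", e2),
       coding = paste0(e1, e2),
       intron_len = nchar(intron_body) + 4L)
}

test_that("find_intron recovers constructed GT..AG introns exactly", {
  set.seed(501)
  g <- make_gene("ATGGCCAATCTT", paste(sample(c("A","C"), 406, TRUE), collapse = ""),
                 "TTCGGCAATTGA")
  fi <- find_intron(g$genomic, g$coding)
  expect_equal(fi$intron_len, 410)
  expect_equal(fi$identity, 1)
  expect_equal(fi$intron_span, c(12, 12 + 410))
  # a 90 bp insert
  g2 <- make_gene("ATGGCCAATCTT", strrep("C", 86), "TTCGGCAAT")
  expect_equal(find_intron(g2$genomic, g2$coding)$intron_len, 90)
  # no GT anywhere: no candidate split
  expect_error(find_intron(paste0("AAAA", strrep("C", 50), "AAAA"),
                           paste0("AAAA", "AAAA")),
               "no valid splice")
})

test_that("splice placement equals brute-force enumeration on random genes", {
  set.seed(502)
  nt <- c("A", "C", "G", "T")
  for (k in 1:25) {
    e1 <- paste(sample(nt, sample(30:120, 1), TRUE), collapse = "")
    e2 <- paste(sample(nt, sample(30:120, 1), TRUE), collapse = "")
    body <- paste(sample(nt, sample(20:200, 1), TRUE), collapse = "")
    g <- make_gene(e1, body, e2)
    fi <- find_intron(g$genomic, g$coding, min_identity = 0)
    want <- oracle_splice(g$genomic, g$coding)
    expect_equal(fi$intron_span[1], want$start)
    expect_equal(fi$identity, want$identity)
  }
})

test_that("translation honours frames, trims terminal stops and flags internal ones", {
  expect_equal(as.character(deduce_protein("ATGGCCAAA", frame = 0)), "MAK")
  # trailing partial codon dropped
  expect_equal(as.character(deduce_protein("ATGGCCAAAC", frame = 0)), "MAK")
  # terminal stop trimmed
  expect_equal(as.character(deduce_protein("ATGGCCTAA", frame = 0)), "MA")
  # explicit frame flags internal stops without truncation
  p <- deduce_protein("ATGTAAGCC", frame = 0)
  expect_equal(as.character(p), "M*A")
  expect_equal(attr(p, "stops"), 1L)
  # auto-selection: frame 0 has an internal stop, frames 1 and 2 are clean,
  # so the lowest stop-free frame (1) is selected
  expect_equal(attr(deduce_protein("TAAATGGCC"), "frame"), 1L)
  # every frame carries an internal stop: auto-selection errors with offsets
  allstop <- "TAAATAAATAAATGGGGGG"
  expect_error(deduce_protein(allstop), "all three frames")
})

test_that("domain scan places packaged blocks at designed offsets with tie and order rules", {
  models <- load_domain_models()
  blocks <- vapply(models, function(m) {
    paste(vapply(m$sets, `[`, character(1), 1L), collapse = "")
  }, character(1))
  prot <- paste0("AAAAA", blocks["C2"], "DDDDDDD", blocks["C3"], "EEE",
                 blocks["RC4"], "FFFF", blocks["C5"], "GG")
  hits <- scan_domains(prot, models)
  expect_equal(names(hits), c("C2", "C3", "RC4", "C5"))
  expect_equal(hits$C2[1], 5)
  expect_equal(hits$C3[1], 5 + 10 + 7)
  # missing C5: only three hits
  prot2 <- paste0("AAAAA", blocks["C2"], "DDDDDDD", blocks["C3"], "EEE",
                  blocks["RC4"], "FFFF")
  expect_equal(names(scan_domains(prot2, models)), c("C2", "C3", "RC4"))
  # two equally scoring placements: leftmost wins
  prot3 <- paste0(blocks["C2"], "XX", blocks["C2"])
  expect_equal(scan_domains(prot3, models["C2"])$C2[1], 0)
})

test_that("RHV extraction spans exactly from C2 end to C3 start", {
  hits <- list(C2 = c(30L, 40L), C3 = c(67L, 77L))
  prot <- paste(rep("A", 100), collapse = "")
  rhv <- extract_rhv(prot, hits)
  expect_equal(rhv$span, c(40, 67))
  expect_equal(rhv$length, 27)
  # adjacent domains: empty RHV
  expect_equal(extract_rhv(prot, list(C2 = c(10L, 20L), C3 = c(20L, 30L)))$length, 0)
  expect_error(extract_rhv(prot, list(C2 = c(10L, 20L))), "C2 and C3")
  # two alleles differing only inside the RHV share domain hits
  models <- load_domain_models()
  blocks <- vapply(models, function(m) {
    paste(vapply(m$sets, `[`, character(1), 1L), collapse = "")
  }, character(1))
  mk <- function(rhv) paste0("AAAA", blocks["C2"], rhv, blocks["C3"], "EE",
                             blocks["RC4"], "FF", blocks["C5"])
  h1 <- scan_domains(mk("QQQQQ"), models)
  h2 <- scan_domains(mk("HHHHH"), models)
  expect_equal(h1, h2)
  expect_equal(extract_rhv(mk("QQQQQ"), h1)$seq, "QQQQQ")
  expect_equal(extract_rhv(mk("HHHHH"), h2)$seq, "HHHHH")
})
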