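test_that("fragment sizes matching unique reference entries call directly", {
  ref <- ref_fixture()
  obs <- data.frame(cultivar = "Honghebao",
                    primer_pair = "Pru-C2/Amy-C5",
                    size = c(885, 700))
  calls <- call_alleles(obs, ref, size_tol = 5)
  got <- calls$label[calls$cultivar == "Honghebao"]
  expect_setequal(got, c("S9", "S16"))
  expect_true(all(calls$evidence == "fragment_only"))
  expect_equal(attr(calls, "flags")$status, "ok")
  # a single observation yields a single (mono-allelic style) call
  one <- call_alleles(data.frame(cultivar = "Dabada",
                                 primer_pair = "Pru-C2/Amy-C5", size = 718),
                      ref, size_tol = 5)
  expect_equal(one$label, "S36")
})

test_that("fragment-size ties require sequence evidence and flag ambiguity otherwise", {
  ref <- ref_fixture()
  # 702 bp sits between S16 (700) and S66 (704) on this pair
  obs <- data.frame(cultivar = "X", primer_pair = "Pru-C2/Amy-C5", size = 702)
  amb <- call_alleles(obs, ref, size_tol = 5)
  expect_equal(attr(amb, "flags")$status, "ambiguous")
  # with the true sequence attached, the tie resolves
  lib <- library_fixture()
  obs$seq <- unname(lib$seqs["S16"])
  fixed <- call_alleles(obs, ref, ref_seqs = lib$seqs, size_tol = 5)
  expect_equal(fixed$label, "S16")
  expect_equal(fixed$evidence, "fragment+sequence")
  expect_equal(fixed$identity, 100)
  expect_equal(attr(fixed, "flags")$status, "ok")
})

test_that("sequence contradicting the fragment size raises a conflict", {
  ref <- ref_fixture()
  lib <- library_fixture()
  # size says S8 (827) but the product sequence is S53's
  obs <- data.frame(cultivar = "X", primer_pair = "Pru-C2/Amy-C5",
                    size = 827, seq = unname(lib$seqs["S53"]))
  res <- call_alleles(obs, ref, ref_seqs = lib$seqs, size_tol = 5)
  expect_equal(attr(res, "flags")$status, "conflict")
})

test_that("unmatched fragments become novel candidates, never truncated calls", {
  ref <- ref_fixture()
  obs <- data.frame(cultivar = "X", primer_pair = "Pru-C2/Amy-C5",
                    size = 2600)
  res <- call_alleles(obs, ref, size_tol = 5)
  expect_true(is.na(res$label))
  expect_true(res$novel)
})

test_that("novel classification demands full architecture and unseen intron plus RHV", {
  ref <- ref_fixture()
  lib <- library_fixture()
  # an intron length absent from the whole reference with a fresh RHV
  spec <- allele_spec("X1", 2000, "Pru-C2/Amy-C5", 2000 + 417)
  tr <- make_allele_sequence(spec, 99)
  ann <- annotate_srnase(tr$seq, tr$coding_ref, frame = tr$frame)
  verdict <- classify_novel(ann, ref, ref_rhv = lib$rhv)
  expect_equal(verdict$status, "novel")
  # the same record re-classified against a reference that now carries its
  # intron and RHV returns a match instead (idempotence of minting)
  ref2 <- ref
  ref2 <- rbind(as.data.frame(ref2),
                data.frame(label = "S108", status = "novel", accession = "X",
                           primer_pair = "Pru-C2/Amy-C5",
                           fragment_bp = 2417, intron_bp = 2000))
  class(ref2) <- c("srt_reference", "data.frame")
  verdict2 <- classify_novel(ann, ref2, ref_rhv = c(lib$rhv, S108 = tr$rhv))
  expect_equal(verdict2$status, "match")
  expect_equal(verdict2$label, "S108")
  # S8's own annotation matches S8, not novel (negative control)
  s8 <- lib$truths$S8
  ann8 <- annotate_srnase(s8$seq, s8$coding_ref, frame = s8$frame)
  v8 <- classify_novel(ann8, ref, ref_rhv = lib$rhv)
  expect_equal(v8$status, "match")
  expect_equal(v8$label, "S8")
})

test_that("incomplete domain structure is unclassifiable, never novel", {
  ref <- ref_fixture()
  # hand-build an annotation lacking C5
  spec <- allele_spec("X2", 2200, "Pru-C2/Amy-C5", 2200 + 417)
  tr <- make_allele_sequence(spec, 100)
  ann <- annotate_srnase(tr$seq, tr$coding_ref, frame = tr$frame)
  ann$domain_hits$C5 <- NULL
  verdict <- classify_novel(ann, ref)
  expect_equal(verdict$status, "unclassifiable")
  expect_match(verdict$evidence, "C5")
})

test_that("novel names continue the numbering over suffixed and split labels", {
  ref <- ref_fixture()
  expect_equal(name_novel(unique(ref$label)), "S108")
  expect_equal(name_novel(c("S1", "S2")), "S3")
  expect_equal(name_novel(c("S13", "S14a")), "S15")
  expect_equal(name_novel(c("S17", "S18-1", "S18-2")), "S19")
})

test_that("the SFB assay partitions outcomes exactly as published", {
  expect_equal(resolve_sc(TRUE, 500), "SC")      # Bora / Bergeron / Ninfa
  expect_equal(resolve_sc(TRUE, 150), "S8")      # H-48 / Zhupishui / 99-31
  expect_equal(resolve_sc(FALSE, NA), "neither") # Hargrand-style negative
  expect_equal(resolve_sc(TRUE, NA), "indeterminate")
  expect_equal(resolve_sc(TRUE, 320), "indeterminate")
  # tolerance edges
  expect_equal(resolve_sc(TRUE, 550, tol = 50), "SC")
  expect_equal(resolve_sc(TRUE, 551, tol = 50), "indeterminate")
  # exactly one outcome over a grid of the whole input space
  for (pos in c(TRUE, FALSE)) for (sz in c(NA, seq(0, 800, by = 25))) {
    out <- resolve_sc(pos, sz)
    expect_length(out, 1)
    expect_true(out %in% c("SC", "S8", "neither", "indeterminate"))
  }
})
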