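test_that("generated alleles are deterministic and carry their designed architecture", {
  spec <- allele_spec("S8", 410, "Pru-C2/Amy-C5", 827)
  a <- make_allele_sequence(spec, 42)
  b <- make_allele_sequence(spec, 42)
  expect_identical(a$seq, b$seq)
  c2 <- make_allele_sequence(spec, 43)
  expect_false(identical(a$seq, c2$seq))
  # designed intron: GT..AG of exactly the designed length
  expect_equal(a$intron_len, 410)
  ibody <- substr(a$seq, a$intron_span[1] + 1, a$intron_span[2])
  expect_equal(nchar(ibody), 410)
  expect_equal(substr(ibody, 1, 2), "GT")
  expect_equal(substr(ibody, 409, 410), "AG")
  # designed amplicon present at exactly the designed size
  pr <- load_primers()
  amp <- amplicons(a$seq, pr[pr$name == "Pru-C2/Amy-C5", ])
  expect_true(827 %in% amp$size)
  # designed size = intron + exonic footprint
  expect_equal(827 - 410, unname(a$amplicon["size"]) - a$intron_len)
})

test_that("annotation round-trips every designed quantity", {
  cases <- list(
    allele_spec("long", 1214, "Pru-C2/Amy-C5", 1214 + 411),
    allele_spec("short", 90, "EM-PC2consFD/EM-PC3consRD", 90 + 183),
    allele_spec("fixed-rhv", 300, "Pru-C2/Amy-C5", 300 + 400,
                rhv_protein = "QQHNTKD")
  )
  for (i in seq_along(cases)) {
    tr <- make_allele_sequence(cases[[i]], 1000 + i)
    ann <- annotate_srnase(tr$seq, tr$coding_ref, frame = tr$frame)
    expect_equal(ann$intron_len, cases[[i]]$intron_len)
    expect_equal(ann$intron_span, tr$intron_span)
    expect_equal(names(ann$domain_hits), c("C2", "C3", "RC4", "C5"))
    expect_equal(unname(vapply(ann$domain_hits, `[`, integer(1), 1)),
                 unname(tr$domain_offsets))
    expect_equal(ann$rhv$seq, tr$rhv)
  }
  # a user-fixed RHV is honoured verbatim in flanking layouts
  tr3 <- make_allele_sequence(cases[[3]], 1003)
  expect_equal(tr3$rhv, "QQHNTKD")
  # an infeasible footprint errors rather than silently shrinking
  expect_error(make_allele_sequence(
    allele_spec("tiny", 300, "Pru-C2/Amy-C5", 330), 1),
    "infeasible")
})

test_that("panels are pure functions of the seed with designed fragment sizes", {
  ref <- ref_fixture()
  freq <- c(S8 = 0.5, S11 = 0.3, S53 = 0.2)
  p1 <- make_panel(25, freq, ref, seed = 5, noise_sd = 0)
  p2 <- make_panel(25, freq, ref, seed = 5, noise_sd = 0)
  expect_identical(p1, p2)
  # noise_sd = 0: sizes equal the designed reference sizes exactly
  merged <- merge(p1$obs, as.data.frame(ref),
                  by.x = c("allele", "primer_pair"),
                  by.y = c("label", "primer_pair"))
  expect_equal(merged$size, merged$fragment_bp)
  # n = 1 gives exactly one genotype
  expect_equal(nrow(make_panel(1, freq, ref, seed = 1)$truth), 1)
  # force_het never collapses
  ph <- make_panel(60, freq, ref, seed = 9, force_het = TRUE)
  expect_true(all(!is.na(ph$truth$allele2)))
})

test_that("empirical panel frequencies recover the design vector", {
  ref <- ref_fixture()
  # Xinjiang-like vector over that region's 14 alleles
  labels <- c("S66", "S49", "S14", "S11", "S12", "S13", "S14a", "S16",
              "S18-2", "S24", "S52", "S53", "S8", "S102")
  freq <- c(0.25, 0.22, 0.11, rep(0.42 / 11, 11))
  names(freq) <- labels
  pan <- make_panel(1000, freq, ref, seed = 31, noise_sd = 0)
  ft <- allele_counts(pan$truth)
  est <- unname(ft$counts["S66"] / ft$n_allele_obs)
  se <- sqrt(0.25 * 0.75 / 2000)
  expect_lt(abs(est - 0.25), 3 * se + 0.02)  # + small collapse bias allowance
})

test_that("noise-free end-to-end calling recovers a small panel perfectly", {
  ref <- ref_fixture()
  lib <- library_fixture()
  freq <- c(S8 = 0.25, S9 = 0.25, S16 = 0.25, S66 = 0.25)
  pan <- make_panel(30, freq, ref, seed = 17, noise_sd = 0, library = lib)
  calls <- call_alleles(pan$obs, ref, ref_seqs = lib$seqs)
  expect_equal(genotype_recovery(calls, pan$truth), 1)
})

test_that("the reference-derived library is complete and structurally sound", {
  lib <- library_fixture()
  ref <- ref_fixture()
  expect_setequal(names(lib$seqs), unique(ref$label))
  expect_equal(anyDuplicated(lib$rhv), 0)
  for (lab in c("S8", "S10", "S20")) {
    tr <- lib$truths[[lab]]
    first <- ref[ref$label == lab, ][1, ]
    expect_equal(tr$intron_len, first$intron_bp)
    expect_equal(unname(tr$amplicon["size"]), first$fragment_bp)
  }
})
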