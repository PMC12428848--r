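test_that("p-distance counts mismatches over pairwise-complete sites", {
  expect_equal(p_distance("AAAA", "AAAA"), 0)
  expect_equal(p_distance("AAAA", "AAAT"), 0.25)
  # gap column excluded: 3 comparable sites, 1 mismatch
  expect_equal(p_distance("A-AA", "AGAT"), 1 / 3)
  expect_error(p_distance("---", "AAA"), "no pairwise-complete")
  expect_error(p_distance("AA", "AAA"), "equal length")
})

test_that("Poisson correction follows the closed form and its monotonicity", {
  expect_equal(poisson_correct(0), 0)
  expect_equal(poisson_correct(0.05), -log(0.95))
  expect_equal(poisson_correct(0.99), -log(0.01), tolerance = 1e-12)
  expect_error(poisson_correct(1), "saturated")
  p <- seq(0, 0.95, by = 0.05)
  d <- poisson_correct(p)
  expect_true(all(diff(d) > 0))
  expect_true(all(d >= p))
})

test_that("three taxa resolve by the closed-form star formulas", {
  d <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  lens <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(lens[c("a", "b", "c")], c(a = 0.5, b = 1.5, c = 2.5))
})

test_that("additive matrices are recovered exactly (topology and lengths)", {
  set.seed(601)
  for (k in 1:30) {
    n <- sample(4:8, 1)
    true_tree <- ape::rtree(n)
    dm <- stats::cophenetic(true_tree)
    est <- nj_tree(dm)
    expect_equal(ape::dist.topo(ape::unroot(true_tree), est), 0,
                 ignore_attr = TRUE)
    # path lengths reproduce the input matrix within numerical tolerance
    back <- stats::cophenetic(est)[rownames(dm), colnames(dm)]
    expect_equal(back, dm, tolerance = 1e-9)
  }
})

test_that("NJ agrees with the independent ape implementation on noisy matrices", {
  set.seed(602)
  for (k in 1:10) {
    n <- sample(5:9, 1)
    m <- as.matrix(stats::dist(matrix(stats::runif(n * 4), n)))
    dimnames(m) <- list(letters[1:n], letters[1:n])
    expect_equal(ape::dist.topo(nj_tree(m), ape::nj(m)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("degenerate all-equal distances give a deterministic lowest-index join", {
  d <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  t1 <- ape::write.tree(nj_tree(d))
  t2 <- ape::write.tree(nj_tree(d))
  expect_identical(t1, t2)
  # taxa a and b (the lowest index pair) were joined first
  expect_match(t1, "\\(a:[0-9.]+,b:")
  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
  d_asym <- d; d_asym[1, 2] <- 5
  expect_error(nj_tree(d_asym), "symmetric")
})

test_that("bootstrap supports are deterministic per seed and saturate on strong splits", {
  # 10 columns separate the wx and yz pairs; 39 conserved columns keep
  # every resampled pair far from saturation; the last column is
  # all-distinct, giving terminal branch length without split signal
  common <- strrep("Q", 39)
  aln <- c(w = paste0(strrep("A", 10), common, "C"),
           x = paste0(strrep("A", 10), common, "D"),
           y = paste0(strrep("T", 10), common, "E"),
           z = paste0(strrep("T", 10), common, "F"))
  b1 <- bootstrap_tree(aln, reps = 100, seed = 7)
  b2 <- bootstrap_tree(aln, reps = 100, seed = 7)
  expect_identical(ape::write.tree(b1), ape::write.tree(b2))
  labs <- b1$node.label[nzchar(b1$node.label)]
  expect_equal(as.numeric(labs), 100)  # wx|yz split in every replicate
  # a single replicate can only give 0 or 100
  one <- bootstrap_tree(aln, reps = 1, seed = 3)
  vals <- as.numeric(one$node.label[nzchar(one$node.label)])
  expect_true(all(vals %in% c(0, 100)))
})

test_that("supports are invariant under leaf-order permutation of the alignment", {
  set.seed(603)
  base <- c(a = "MKLVVQQAAHHT", b = "MKLVVQQAAHHA",
            c = "MKLTTQQAAGHT", d = "MKLTTQQAAGHA", e = "MKITTQQAVGHA")
  aln <- vapply(base, function(s) strrep(s, 5), character(1))
  b1 <- bootstrap_tree(aln, reps = 50, seed = 11)
  b2 <- bootstrap_tree(aln[c(3, 1, 5, 2, 4)], reps = 50, seed = 11)
  support_of <- function(tr) {
    parts <- ape::prop.part(tr)
    lab <- as.numeric(ifelse(nzchar(tr$node.label), tr$node.label, NA))
    out <- lapply(seq_along(parts), function(i) {
      sort(attr(parts, "labels")[parts[[i]]])
    })
    setNames(lab, vapply(out, paste, character(1), collapse = "|"))
  }
  s1 <- support_of(b1); s2 <- support_of(b2)
  common <- intersect(names(s1), names(s2))
  expect_true(length(common) >= 2)
  expect_equal(s1[common], s2[common])
})

test_that("alignment IO round-trips and rejects ragged input", {
  tmp <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "MKLV", ">b", "MKIV"), tmp)
  aln <- read_alignment(tmp)
  expect_equal(aln, c(a = "MKLV", b = "MKIV"))
  bad <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "MKLV", ">b", "MK"), bad)
  expect_error(read_alignment(bad), "not aligned")
  # newick out preserves support labels
  commonT <- strrep("Q", 20)
  alnT <- c(w = paste0(strrep("A", 10), commonT, "C"),
            x = paste0(strrep("A", 10), commonT, "G"),
            y = paste0(strrep("T", 10), commonT, "C"),
            z = paste0(strrep("T", 10), commonT, "G"))
  tr <- bootstrap_tree(alnT, reps = 10, seed = 2)
  out <- tempfile(fileext = ".nwk")
  write_newick(tr, out)
  expect_true(grepl("\\)100:", readLines(out)[1]) ||
              grepl("\\)100;", readLines(out)[1]))
})
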