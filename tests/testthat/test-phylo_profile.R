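test_that("p-distance matches hand values and the brute-force oracle", {
  aln <- labelled_alignment(c(a = "ACGT", b = "ACGT", c = "ACGA"))
  d <- pairwise_distance_matrix(aln)
  expect_equal(d["a", "b"], 0)
  expect_equal(d["a", "c"], 0.25)
  expect_true(isSymmetric(d))

  set.seed(7)
  aln <- random_alignment(5, 100)
  for (mode in c("pairwise_deletion", "gap_fifth_state")) {
    d <- pairwise_distance_matrix(aln, mode)
    for (i in 1:4) for (j in (i + 1):5)
      expect_equal(d[i, j],
                   oracle_pdist(aln$seq[[i]], aln$seq[[j]],
                                fifth_state = (mode == "gap_fifth_state")))
  }

  bad <- labelled_alignment(c(a = "A---", b = "-CGT", c = "ACGT"))
  expect_error(pairwise_distance_matrix(bad), "a / b")
})

test_that("neighbour joining solves the 3-taxon case in closed form", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- build_nj_tree(d)
  len <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(len[c("a", "b", "c")]), c(1, 2, 3))
  expect_error(build_nj_tree(d[1:2, 1:2]), ">= 3 taxa")
  expect_error(build_nj_tree(-d), "negative")
})

test_that("neighbour joining recovers additive 4-taxon trees exactly", {
  true <- ape::read.tree(text = "((a:1,b:2):1,(c:3,d:4):0);")
  d <- cophenetic(true)
  tr <- build_nj_tree(d)
  expect_equal(ape::dist.topo(ape::unroot(true), ape::unroot(tr)), 0,
               ignore_attr = TRUE)
  # additivity: the fitted tree reproduces the input distances
  expect_equal(cophenetic(tr)[rownames(d), colnames(d)], d,
               tolerance = 1e-10)
})

test_that("tied Q values join the lowest-index pair first", {
  d <- matrix(2, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  tr <- build_nj_tree(d)
  # the a,b pair must form a cherry
  cherries <- ape::prop.part(tr)
  pair <- tr$edge[, 2][tr$edge[, 1] == tr$edge[1, 1]]
  mrca_ab <- ape::getMRCA(tr, c("a", "b"))
  kids <- tr$edge[tr$edge[, 1] == mrca_ab, 2]
  expect_setequal(tr$tip.label[kids[kids <= 4]], c("a", "b"))
})

test_that("agreement with ape::nj on tie-free random matrices", {
  set.seed(11)
  for (rep in 1:5) {
    n <- 8
    x <- matrix(runif(n * n), n)
    d <- (x + t(x)) / 2; diag(d) <- 0
    dimnames(d) <- list(letters[1:n], letters[1:n])
    expect_equal(ape::dist.topo(ape::unroot(ape::nj(d)),
                                ape::unroot(build_nj_tree(d))), 0,
                 ignore_attr = TRUE)
  }
})

test_that("change counting matches hand-built cases", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  aln <- labelled_alignment(c(a = "AAAA", b = "AAGA", c = "AGC-", d = "AGC-"))
  cc <- count_changes(aln, tr)
  expect_s3_class(cc, "change_counts")
  expect_equal(cc$total, c(0, 1, 2, 1))       # invariant column counts 0
  expect_equal(cc$transitions[2], 1)          # A<->G on one edge
  # column 3 has states A,G,C on the two cherries: one transition plus one
  # transversion under the deterministic labelling
  expect_equal(cc$transitions[3], 1)
  expect_equal(cc$transversions[3], 1)
  expect_equal(cc$deletions[4], 1)            # root A, cd clade gapped
  expect_equal(sum(cc$insertions), 0)
  expect_error(count_changes(labelled_alignment(c(a = "A", b = "A", c = "A")),
                             tr), "without sequence")
})

test_that("Ns are ignored at their tip", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  aln <- labelled_alignment(c(a = "N", b = "A", c = "A", d = "A"))
  expect_equal(count_changes(aln, tr)$total, 0)
})

test_that("parsimony counts equal exhaustive enumeration on random trees", {
  set.seed(23)
  for (rep in 1:30) {
    ntip <- sample(4:7, 1)
    tr <- ape::rtree(ntip)
    m <- matrix(sample(c(1:5, NA), ntip * 20, replace = TRUE,
                       prob = c(rep(0.18, 5), 0.1)), ntip, 20)
    seqs <- apply(m, 1, function(r)
      paste(c("A", "C", "G", "T", "-", "N")[ifelse(is.na(r), 6, r)],
            collapse = ""))
    names(seqs) <- tr$tip.label
    cc <- count_changes(labelled_alignment(seqs), tr)
    oracle <- vapply(seq_len(20), function(j)
      oracle_min_changes(tr, m[, j]), numeric(1))
    expect_equal(cc$total, as.integer(oracle))
  }
})

test_that("binning tiles the alignment and conserves totals", {
  cc <- data.frame(total = rep(0L, 12))
  cc$total[7] <- 5L
  b <- bin_changes(cc, 6)
  expect_equal(nrow(b), 2)
  expect_equal(b$n_changes, c(0, 5))
  expect_equal(bin_changes(cc, 1)$n_changes, cc$total)   # passthrough
  set.seed(3)
  cc <- data.frame(total = rpois(100, 2))
  for (w in c(1, 6, 7, 30, 100, 999))
    expect_equal(sum(bin_changes(cc, w)$n_changes), sum(cc$total))
  # last bin may be short but tiling is exact
  b <- bin_changes(cc, 30)
  expect_equal(b$start_col, c(1, 31, 61, 91))
  expect_equal(b$end_col, c(30, 60, 90, 100))
})

test_that("rate calibration scales densities to the supplied mean rate", {
  flat <- data.frame(total = rep(2L, 120))
  rb <- calibrate_rates(flat, 30, calibration_rate = 24)
  expect_equal(rb$rate_pct_per_myr, rep(24, 4))

  cc <- data.frame(total = rep(1L, 120))
  cc$total[31:60] <- 4L                       # one bin at 4x density
  rb <- calibrate_rates(cc, 30, 24)
  expect_equal(rb$rate_pct_per_myr[2] / rb$rate_pct_per_myr[1], 4)
  # length-weighted mean equals the calibration rate
  w <- rb$end_col - rb$start_col + 1
  expect_equal(sum(rb$rate_pct_per_myr * w) / sum(w), 24, tolerance = 1e-9)
  # linear in the calibration rate; invariant to count rescaling
  expect_equal(calibrate_rates(cc, 30, 48)$rate_pct_per_myr,
               2 * rb$rate_pct_per_myr)
  cc3 <- data.frame(total = cc$total * 3L)
  expect_equal(calibrate_rates(cc3, 30, 24)$rate_pct_per_myr,
               rb$rate_pct_per_myr)
  expect_error(calibrate_rates(data.frame(total = rep(0L, 60)), 30, 24),
               "zero total")
})
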