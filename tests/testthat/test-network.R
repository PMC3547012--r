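catalog_from_strings <- function(seqs, species = "sp", freq = NULL) {
  labs <- paste0("H", seq_along(seqs))
  occ <- if (is.null(freq)) {
    data.frame(sample_id = labs, haplotype_label = labs, species = species,
               locality_name = NA_character_)
  } else {
    data.frame(sample_id = paste0("s", seq_len(sum(freq))),
               haplotype_label = rep(labs, freq), species = species,
               locality_name = NA_character_)
  }
  haplotype_catalog(
    entries = data.frame(haplotype_label = labs, sequence = seqs,
                         species = species),
    occurrences = occ)
}

test_that("fifth-state distance counts gaps and skips Ns", {
  expect_equal(hap_distance("ACGT", "ACGT"), 0)
  expect_equal(hap_distance("AC-T", "ACGT"), 1)
  expect_equal(hap_distance("ANGT", "ACGT"), 0)
  expect_error(hap_distance("ACG", "ACGT"), "length mismatch")
  set.seed(17)
  for (rep in 1:20) {
    a <- paste(sample(c("A", "C", "G", "T", "-", "N"), 40, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T", "-", "N"), 40, TRUE), collapse = "")
    av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
    ok <- av != "N" & bv != "N"
    expect_equal(hap_distance(a, b), sum(av[ok] != bv[ok]))
  }
})

test_that("fifth-state distance is a metric on N-free strings", {
  set.seed(19)
  for (rep in 1:20) {
    s <- replicate(3, paste(sample(c("A", "C", "G", "T", "-"), 25, TRUE),
                            collapse = ""))
    expect_equal(hap_distance(s[1], s[1]), 0)
    expect_equal(hap_distance(s[1], s[2]), hap_distance(s[2], s[1]))
    expect_lte(hap_distance(s[1], s[3]),
               hap_distance(s[1], s[2]) + hap_distance(s[2], s[3]))
  }
})

test_that("size classes follow the display convention", {
  expect_equal(size_class(c(1, 2, 4, 5, 10, 11, 40)),
               c("small", "medium", "medium", "large", "large", "largest",
                 "largest"))
  expect_error(size_class(0), ">= 1")
})

test_that("minimum spanning networks keep equal-cost alternatives", {
  expect_equal(nrow(build_msn(catalog_from_strings("AAAA"), "sp")$edges), 0)
  # three haplotypes at mutual distance 1: full triangle retained
  net <- build_msn(catalog_from_strings(c("AAAA", "AAAC", "AAAG")), "sp")
  expect_equal(nrow(net$edges), 3)
  expect_equal(sum(net$edges$alternative), 1)
  expect_true(all(net$edges$steps == 1))
})

test_that("the network always contains a minimum-weight spanning tree", {
  set.seed(29)
  for (rep in 1:30) {
    n <- sample(3:8, 1)
    seqs <- replicate(n, paste(sample(c("A", "C", "G", "T", "-"), 12, TRUE),
                               collapse = ""))
    while (anyDuplicated(seqs))
      seqs <- replicate(n, paste(sample(c("A", "C", "G", "T", "-"), 12, TRUE),
                                 collapse = ""))
    net <- build_msn(catalog_from_strings(seqs), "sp")
    tree_w <- sum(net$edges$steps[!net$edges$alternative])
    d <- outer(seqs, seqs, Vectorize(hap_distance))
    g <- igraph::graph_from_adjacency_matrix(d, weighted = TRUE,
                                             mode = "undirected")
    ref_w <- sum(igraph::E(igraph::mst(g, weights = igraph::E(g)$weight))$weight)
    expect_equal(tree_w, ref_w)
    if (n <= 6)
      expect_equal(tree_w, oracle_mst_weight_exhaustive(d))
    # non-alternative edges span all haplotypes
    comp <- igraph::components(igraph::graph_from_data_frame(
      net$edges[!net$edges$alternative, 1:2], directed = FALSE,
      vertices = net$nodes$haplotype_label))
    expect_equal(comp$no, 1)
  }
})

test_that("node frequencies and locality composition track occurrences", {
  cat0 <- catalog_from_strings(c("AAAA", "CCCC"), freq = c(3, 12))
  net <- build_msn(cat0, "sp")
  expect_equal(sum(net$nodes$frequency), nrow(cat0$occurrences))
  expect_equal(net$nodes$size_class, c("medium", "largest"))
  expect_equal(unname(unlist(lapply(net$nodes$locality_composition,
                                    function(x) x[["unknown"]]))), c(3, 12))
})

test_that("step limits prune edges and report components", {
  # chain H1-H2 (1 step), H2-H3 (3), H3-H4 (1)
  seqs <- c("AAAAAA", "AAAAAT", "TTTAAT", "TTTAAA")
  net <- build_msn(catalog_from_strings(seqs), "sp")
  full <- apply_step_limit(net, Inf)
  expect_equal(nrow(full$edges), nrow(net$edges))
  expect_equal(max(full$components), 1)
  cut2 <- apply_step_limit(net, 2)
  expect_equal(max(cut2$components), 2)
  expect_setequal(split(names(cut2$components), cut2$components)[[1]],
                  c("H1", "H2"))
  cut1 <- apply_step_limit(net, 1)
  expect_equal(max(cut1$components), 2)
})

test_that("the experimental parsimony limit behaves sanely", {
  lim <- parsimony_limit(30)
  expect_true(lim >= 1 && lim <= 30)
  expect_gte(parsimony_limit(600), parsimony_limit(30))   # monotone in sites
})

test_that("networks serialise to GML and TSV", {
  net <- build_msn(catalog_from_strings(c("AAAA", "AAAC", "GGGG")), "sp")
  gml <- withr::local_tempfile(fileext = ".gml")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, gml, tsv)
  expect_true(file.size(gml) > 0)
  back <- utils::read.delim(tsv)
  expect_equal(nrow(back), nrow(net$edges))
})
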