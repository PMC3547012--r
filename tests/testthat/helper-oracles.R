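# Independent oracles used across the suite. These deliberately share no
# code with the implementation paths they check.

# Brute-force minimum-mutation count for one column on a rooted tree:
# enumerate every 5-state labelling of the internal nodes. Tip states are
# integers 1..5 or NA (missing: contributes no cost).
oracle_min_changes <- function(tree, tip_states) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  nnode <- tr$Nnode
  grid <- as.matrix(expand.grid(rep(list(1:5), nnode)))  # labellings x nodes
  cost <- numeric(nrow(grid))
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1] - ntip
    ch <- tr$edge[e, 2]
    if (ch <= ntip) {
      s <- tip_states[ch]
      if (!is.na(s)) cost <- cost + (grid[, p] != s)
    } else {
      cost <- cost + (grid[, p] != grid[, ch - ntip])
    }
  }
  min(cost)
}

# Brute-force p-distance via per-character comparison of two strings.
oracle_pdist <- function(a, b, fifth_state = FALSE) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  if (fifth_state) {
    ok <- av != "N" & bv != "N"
  } else {
    ok <- av %in% c("A", "C", "G", "T") & bv %in% c("A", "C", "G", "T")
  }
  sum(av[ok] != bv[ok]) / sum(ok)
}

# Exhaustive minimum-spanning-tree weight via Pruefer-sequence enumeration
# (exact for small n).
oracle_mst_weight_exhaustive <- function(d) {
  n <- nrow(d)
  stopifnot(n >= 3, n <= 6)
  seqs <- as.matrix(expand.grid(rep(list(1:n), n - 2)))
  best <- Inf
  for (r in seq_len(nrow(seqs))) {
    prufer <- seqs[r, ]
    degree <- rep(1L, n) + tabulate(prufer, n)
    w <- 0
    pf <- prufer
    for (k in seq_along(pf)) {
      leaf <- which(degree == 1L)[1]
      w <- w + d[leaf, pf[k]]
      degree[leaf] <- 0L
      degree[pf[k]] <- degree[pf[k]] - 1L
    }
    last <- which(degree == 1L)
    w <- w + d[last[1], last[2]]
    best <- min(best, w)
  }
  best
}

random_alignment <- function(n, L, gap_prob = 0.05, n_prob = 0.02,
                             alphabet = c("A", "C", "G", "T")) {
  seqs <- vapply(seq_len(n), function(i) {
    s <- sample(alphabet, L, replace = TRUE)
    s[stats::runif(L) < gap_prob] <- "-"
    s[stats::runif(L) < n_prob] <- "N"
    paste(s, collapse = "")
  }, character(1))
  names(seqs) <- sprintf("s%02d", seq_len(n))
  labelled_alignment(seqs)
}
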