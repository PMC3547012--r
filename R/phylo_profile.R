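#' Pairwise p-distance matrix
#'
#' Proportion of mismatching sites per pair. Under the default
#' \code{"pairwise_deletion"} mode, alignment columns with a gap or N in
#' either sequence of a pair are excluded from the comparison. Under
#' \code{"gap_fifth_state"} the gap is compared as an ordinary fifth symbol
#' and only N columns are excluded.
#'
#' @param aln a [labelled_alignment()].
#' @param mode gap handling, see above.
#' @return symmetric numeric matrix with zero diagonal, dimnames = sample ids.
#' @export
pairwise_distance_matrix <- function(aln,
                                     mode = c("pairwise_deletion",
                                              "gap_fifth_state")) {
  mode <- match.arg(mode)
  m <- aln_matrix(aln)
  n <- nrow(m)
  if (n < 2) stop("need >= 2 sequences")
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1)) {
    xi <- m[i, ]
    for (j in (i + 1):n) {
      xj <- m[j, ]
      if (mode == "pairwise_deletion") {
        ok <- !is.na(xi) & !is.na(xj) & xi != 5L & xj != 5L
      } else {
        ok <- !is.na(xi) & !is.na(xj)
      }
      nc <- sum(ok)
      if (nc == 0)
        stop("zero comparable sites for pair ", rownames(m)[i], " / ",
             rownames(m)[j])
      d[i, j] <- d[j, i] <- sum(xi[ok] != xj[ok]) / nc
    }
  }
  d
}

#' Neighbour-joining tree with a deterministic tie-break
#'
#' Standard Saitou–Nei agglomeration. When several pairs share the minimal
#' Q criterion the pair with the lowest (row, column) index is joined first,
#' so the output is fully deterministic. Negative branch lengths are clamped
#' to zero with the difference transferred to the sister branch (their sum is
#' preserved).
#'
#' @param d symmetric distance matrix (or \code{dist}) over >= 3 taxa.
#' @return an unrooted \code{ape::phylo} tree with branch lengths.
#' @export
build_nj_tree <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-8)
    stop("distance matrix must be square and symmetric")
  if (any(d < 0)) stop("negative distances not allowed")
  n <- nrow(d)
  if (n < 3) stop("neighbour joining needs >= 3 taxa")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))

  active <- seq_len(n)            # node ids of live clusters
  D <- unname(d)
  parent <- integer(0); child <- integer(0); elen <- numeric(0)
  next_node <- n + 1L

  while (length(active) > 3L) {
    m <- length(active)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    Q[lower.tri(Q, diag = TRUE)] <- Inf
    qmin <- min(Q)
    idx <- which(Q <= qmin + 1e-12, arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]

    li <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }

    parent <- c(parent, next_node, next_node)
    child <- c(child, active[i], active[j])
    elen <- c(elen, li, lj)

    dn <- (D[i, ] + D[j, ] - D[i, j]) / 2
    dn <- dn[-j]
    D <- D[-j, -j, drop = FALSE]
    k <- if (j < i) i - 1L else i
    D[k, ] <- dn; D[, k] <- dn; D[k, k] <- 0
    active <- active[-j]
    active[k] <- next_node
    next_node <- next_node + 1L
  }

  ## final trifurcation (three-point formulas)
  l1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  l2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  l3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  parent <- c(parent, rep(next_node, 3))
  child <- c(child, active)
  elen <- c(elen, pmax(c(l1, l2, l3), 0))

  ## ape convention: root node is n+1; remap internal ids (root was created
  ## last)
  root <- next_node
  remap <- function(v) ifelse(v == root, n + 1L,
                              ifelse(v > n, v + 1L, v))
  tr <- list(edge = cbind(remap(parent), remap(child)),
             edge.length = elen, tip.label = labels, Nnode = n - 2L)
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}

#' Per-column change counts by minimum-mutation parsimony
#'
#' For every alignment column the minimum number of state changes over the
#' 5-state alphabet \{A, C, G, T, gap\} is found by unit-cost Sankoff
#' parsimony on the given tree (exact Fitch minimum; the Sankoff recursion is
#' used so the trifurcating root of an unrooted NJ tree is handled exactly).
#' One deterministic optimal ancestral labelling — ties broken towards the
#' state earliest in the order A < C < G < T < gap, the tree rooted at its
#' first internal node — is then traversed edge by edge and every change is
#' classified: purine-purine or pyrimidine-pyrimidine substitutions are
#' transitions, other base-base substitutions transversions, base-to-gap
#' deletions and gap-to-base insertions. N is treated as missing at that tip.
#' The per-column change totals are labelling-independent; only the split by
#' type depends on the tie-break.
#'
#' @param aln a [labelled_alignment()].
#' @param tree an \code{ape::phylo}; tips must be a subset of the alignment
#'   ids. Defaults to the NJ tree of the pairwise-deletion p-distances.
#' @return A \code{change_counts} data.frame with one row per column and
#'   integer columns \code{transitions}, \code{transversions},
#'   \code{insertions}, \code{deletions}, \code{total}.
#' @export
count_changes <- function(aln, tree = NULL) {
  if (is.null(tree)) tree <- build_nj_tree(pairwise_distance_matrix(aln))
  stopifnot(inherits(tree, "phylo"))
  missing_tips <- setdiff(tree$tip.label, names(aln$seq))
  if (length(missing_tips))
    stop("tree tip(s) without sequence: ", paste(missing_tips, collapse = ", "))
  m <- aln_matrix(aln)[tree$tip.label, , drop = FALSE]
  L <- ncol(m)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  tr <- ape::reorder.phylo(tree, "postorder")
  edge <- tr$edge

  BIG <- 1e6
  ## S[[v]] is a 5 x L cost matrix for node v
  S <- vector("list", nnode)
  for (v in seq_len(ntip)) {
    mat <- matrix(BIG, 5, L)
    st <- m[v, ]
    obs <- !is.na(st)
    mat[cbind(st[obs], which(obs))] <- 0
    mat[, !obs] <- 0                       # N: missing, no constraint
    S[[v]] <- mat
  }
  colmin5 <- function(mat) pmin(mat[1, ], mat[2, ], mat[3, ], mat[4, ], mat[5, ])
  for (v in (ntip + 1):nnode) S[[v]] <- matrix(0, 5, L)
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1]; ch <- edge[e, 2]
    cm <- colmin5(S[[ch]])
    contrib <- pmin(S[[ch]], rep(cm + 1, each = 5))
    S[[p]] <- S[[p]] + contrib
  }
  root <- ntip + 1L
  total_min <- colmin5(S[[root]])

  ## deterministic backtrace, preorder
  state <- matrix(NA_integer_, nnode, L)
  state[root, ] <- max.col(t(-S[[root]]), ties.method = "first")
  counts <- matrix(0L, L, 4,
                   dimnames = list(NULL, c("transitions", "transversions",
                                           "insertions", "deletions")))
  is_purine <- c(TRUE, FALSE, TRUE, FALSE, FALSE)   # A, C, G, T, gap
  for (e in rev(seq_len(nrow(edge)))) {             # preorder = reversed postorder
    p <- edge[e, 1]; ch <- edge[e, 2]
    s <- state[p, ]
    score <- S[[ch]] + 1
    score[cbind(s, seq_len(L))] <- score[cbind(s, seq_len(L))] - 1
    t_opt <- max.col(t(-score), ties.method = "first")
    state[ch, ] <- t_opt
    changed <- which(t_opt != s)
    if (length(changed)) {
      sp <- s[changed]; tp <- t_opt[changed]
      del <- sp != 5L & tp == 5L
      ins <- sp == 5L & tp != 5L
      sub <- !del & !ins
      ts <- sub & (is_purine[sp] == is_purine[tp])
      tv <- sub & !ts
      counts[changed[ts], "transitions"] <- counts[changed[ts], "transitions"] + 1L
      counts[changed[tv], "transversions"] <- counts[changed[tv], "transversions"] + 1L
      counts[changed[ins], "insertions"] <- counts[changed[ins], "insertions"] + 1L
      counts[changed[del], "deletions"] <- counts[changed[del], "deletions"] + 1L
    }
  }
  out <- as.data.frame(counts)
  out$total <- as.integer(round(total_min))
  stopifnot(all(rowSums(counts) == out$total))
  class(out) <- c("change_counts", "data.frame")
  out
}

#' Bin per-column change totals
#'
#' Bin k covers columns \code{[(k-1)*width + 1, k*width]} (1-based,
#' inclusive); the last bin may be short. A bin's total is the sum of all
#' change types over its columns.
#'
#' @param counts a \code{change_counts} data.frame from [count_changes()], or
#'   any data.frame with a \code{total} column.
#' @param width bin width in columns (>= 1); the display convention is 6.
#' @return data.frame with \code{start_col}, \code{end_col}, \code{n_changes}.
#' @export
bin_changes <- function(counts, width = 6L) {
  stopifnot(width >= 1)
  tot <- counts$total
  L <- length(tot)
  starts <- seq(1L, L, by = width)
  ends <- pmin(starts + width - 1L, L)
  data.frame(start_col = starts, end_col = ends,
             n_changes = vapply(seq_along(starts), function(k)
               sum(tot[starts[k]:ends[k]]), numeric(1)))
}

#' Calibrate binned mutation rates in %/Myr
#'
#' Converts relative per-bin change densities into absolute rates by scaling
#' so the length-weighted mean over bins equals a user-supplied control-region
#' calibration rate (percent change per million years; a published
#' control-region rate estimate must be supplied — none is built in). The
#' rate of bin b is \code{calibration_rate * density(b) / mean density},
#' where density is changes per site.
#'
#' @param counts a \code{change_counts} data.frame.
#' @param width rate-bin width in columns; the display convention is 30.
#' @param calibration_rate alignment-wide mean rate in %/Myr (> 0).
#' @return data.frame with \code{start_col}, \code{end_col}, \code{n_changes},
#'   \code{rate_pct_per_myr}.
#' @export
calibrate_rates <- function(counts, width = 30L, calibration_rate) {
  stopifnot(width >= 1, calibration_rate > 0)
  bins <- bin_changes(counts, width)
  total <- sum(bins$n_changes)
  if (total == 0) stop("zero total changes: no calibration possible")
  L <- sum(bins$end_col - bins$start_col + 1)
  mean_density <- total / L
  density <- bins$n_changes / (bins$end_col - bins$start_col + 1)
  bins$rate_pct_per_myr <- calibration_rate * density / mean_density
  bins
}

#' Full variation profile of an alignment
#'
#' Convenience wrapper: NJ tree (unless given), parsimony change counts,
#' 6-column change bins and, when a calibration rate is supplied, 30-column
#' calibrated rate bins.
#'
#' @inheritParams count_changes
#' @param calibration_rate optional %/Myr calibration (see
#'   [calibrate_rates()]).
#' @param w_changes,w_rate bin widths for change counts and rates.
#' @return list of class \code{variation_profile} with elements
#'   \code{counts}, \code{change_bins}, \code{rate_bins} (NULL when no
#'   calibration rate given), \code{tree}, \code{calibration_rate}.
#' @export
variation_profile <- function(aln, tree = NULL, calibration_rate = NULL,
                              w_changes = 6L, w_rate = 30L) {
  if (is.null(tree)) tree <- build_nj_tree(pairwise_distance_matrix(aln))
  counts <- count_changes(aln, tree)
  rate_bins <- if (!is.null(calibration_rate))
    calibrate_rates(counts, w_rate, calibration_rate) else NULL
  structure(list(counts = counts,
                 change_bins = bin_changes(counts, w_changes),
                 rate_bins = rate_bins, tree = tree,
                 calibration_rate = calibration_rate),
            class = "variation_profile")
}

#' @export
print.variation_profile <- function(x, ...) {
  cat("variation_profile over", nrow(x$counts), "columns;",
      sum(x$counts$total), "changes\n")
  if (!is.null(x$rate_bins)) {
    hot <- x$rate_bins[which.max(x$rate_bins$rate_pct_per_myr), ]
    cat(sprintf("  hottest rate bin: cols %d-%d at %.2f %%/Myr\n",
                hot$start_col, hot$end_col, hot$rate_pct_per_myr))
  }
  invisible(x)
}
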