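#' Haplotype distance with gap as the fifth state
#'
#' Count of positions at which two equal-length strings differ, with the gap
#' \code{-} compared as an ordinary fifth symbol; positions with N in either
#' sequence are skipped.
#'
#' @param seq_a,seq_b equal-length strings over \{A,C,G,T,-,N\}.
#' @return integer step count.
#' @export
hap_distance <- function(seq_a, seq_b) {
  if (nchar(seq_a) != nchar(seq_b))
    stop("length mismatch: ", nchar(seq_a), " vs ", nchar(seq_b))
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  ok <- a != "N" & b != "N"
  sum(a[ok] != b[ok])
}

#' Size class of a haplotype node
#'
#' Display convention for network plots: 1 occurrence is \code{small},
#' 2–4 \code{medium}, 5–10 \code{large}, more than 10 \code{largest}.
#'
#' @param frequency occurrence count (>= 1); vectorised.
#' @return character vector of classes.
#' @export
size_class <- function(frequency) {
  if (any(frequency < 1)) stop("frequency must be >= 1")
  cut(frequency, breaks = c(0, 1, 4, 10, Inf),
      labels = c("small", "medium", "large", "largest")) |> as.character()
}

#' Minimum spanning haplotype network for one species
#'
#' Kruskal-style growth over pairwise fifth-state distances
#' ([hap_distance()]). At the moment two components are joined, every edge
#' of that same minimal weight joining the two components is retained; edges
#' beyond the first are flagged \code{alternative} (the "possible additional
#' linkages" of spanning-network plots). Candidate edges are processed in
#' (weight, label_a, label_b) lexicographic order, so the output is
#' deterministic. Edge \code{steps} above 1 represent intermediate, as yet
#' undetected haplotypes.
#'
#' @param catalog a [haplotype_catalog()].
#' @param species species whose haplotypes to connect.
#' @param grouping optional [group_localities()] output for the locality
#'   composition of nodes; occurrences without a locality fall in an
#'   explicit \code{"unknown"} group.
#' @return object of class \code{haplotype_network}: list with \code{nodes}
#'   (haplotype_label, frequency, size_class, locality_composition list
#'   column) and \code{edges} (label_a, label_b, steps, alternative).
#' @export
build_msn <- function(catalog, species, grouping = NULL) {
  entries <- catalog$entries[catalog$entries$species == species, ]
  if (!nrow(entries)) stop("no haplotypes for species ", species)
  entries <- entries[order(entries$haplotype_label), ]
  labs <- entries$haplotype_label
  n <- nrow(entries)

  occ <- catalog$occurrences[catalog$occurrences$species == species, ]
  freq <- vapply(labs, function(l) max(1L, sum(occ$haplotype_label == l)),
                 integer(1))
  locs <- lapply(labs, function(l) {
    g <- locality_groups_of(occ$locality_name[occ$haplotype_label == l],
                            grouping)
    g[is.na(g)] <- "unknown"
    table(g)
  })
  nodes <- data.frame(haplotype_label = labs, frequency = freq,
                      size_class = size_class(freq))
  nodes$locality_composition <- locs

  edges <- data.frame(label_a = character(0), label_b = character(0),
                      steps = integer(0), alternative = logical(0))
  if (n > 1) {
    cand <- utils::combn(n, 2)
    w <- apply(cand, 2, function(p)
      hap_distance(entries$sequence[p[1]], entries$sequence[p[2]]))
    ord <- order(w, labs[cand[1, ]], labs[cand[2, ]])
    cand <- cand[, ord, drop = FALSE]; w <- w[ord]

    comp <- seq_len(n)                 # union-find by relabel
    for (wt in unique(w)) {
      sel <- which(w == wt)
      comp_at_start <- comp            # equal-cost alternatives judged here
      for (k in sel) {
        i <- cand[1, k]; j <- cand[2, k]
        if (comp_at_start[i] != comp_at_start[j]) {
          alt <- comp[i] == comp[j]    # already joined within this weight class
          edges <- rbind(edges,
                         data.frame(label_a = labs[i], label_b = labs[j],
                                    steps = wt, alternative = alt))
          if (!alt) comp[comp == comp[j]] <- comp[i]
        }
      }
    }
  }
  structure(list(nodes = nodes, edges = edges, species = species),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat("haplotype_network (", x$species, "): ", nrow(x$nodes), " haplotypes, ",
      nrow(x$edges), " edges (", sum(x$edges$alternative),
      " alternative)\n", sep = "")
  invisible(x)
}

#' Convert a haplotype network to igraph
#' @param net a \code{haplotype_network}.
#' @return an \code{igraph} graph with node attributes frequency and
#'   size_class, edge attributes steps and alternative.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "haplotype_network"))
  edges <- net$edges
  if (nrow(edges)) edges$alternative <- as.integer(edges$alternative)  # GML has no booleans
  g <- igraph::graph_from_data_frame(
    if (nrow(edges)) edges else
      data.frame(label_a = character(0), label_b = character(0)),
    directed = FALSE,
    vertices = data.frame(name = net$nodes$haplotype_label,
                          frequency = net$nodes$frequency,
                          size_class = net$nodes$size_class))
  g
}

#' Apply a parsimony step limit to a network
#'
#' Removes every edge whose step count exceeds \code{max_steps} and reports
#' the resulting connected components. \code{max_steps = Inf} leaves the
#' network unchanged. This stands in for a statistical-parsimony connection
#' limit; see [parsimony_limit()] for an (experimental) way to pick one.
#'
#' @param net a \code{haplotype_network}.
#' @param max_steps maximum allowed steps per edge.
#' @return the pruned network, with a \code{components} element: integer
#'   membership vector named by haplotype label.
#' @export
apply_step_limit <- function(net, max_steps = Inf) {
  stopifnot(inherits(net, "haplotype_network"))
  net$edges <- net$edges[net$edges$steps <= max_steps, , drop = FALSE]
  comp <- igraph::components(as_igraph(net))$membership
  net$components <- comp[net$nodes$haplotype_label]
  net
}

#' Experimental statistical-parsimony step limit
#'
#' Heuristic stand-in for a coalescent-based connection limit: per differing
#' site, the probability that the difference arose by a single hit is
#' estimated under a Jukes–Cantor correction of the per-site divergence
#' implied by \code{j} steps over \code{n_sites}; the limit is the largest
#' \code{j} whose joint single-hit probability still reaches
#' \code{confidence}. This is a rough approximation, not the published TCS
#' computation — treat it as experimental and prefer a user-fixed
#' \code{max_steps} for publication-grade analyses.
#'
#' @param n_sites number of compared sites (>= 1).
#' @param confidence required joint single-hit probability (default 0.95).
#' @return integer maximum step count (possibly 0).
#' @export
parsimony_limit <- function(n_sites, confidence = 0.95) {
  stopifnot(n_sites >= 1, confidence > 0, confidence < 1)
  p_single <- function(j) {
    p <- j / n_sites
    if (p >= 0.75) return(0)
    lam <- -0.75 * log(1 - 4 * p / 3)          # JC expected hits per site
    if (lam == 0) return(1)
    lam * exp(-lam) / (1 - exp(-lam))          # P(1 hit | >= 1 hit), Poisson
  }
  j <- 0L
  while (j < n_sites && p_single(j + 1L)^(j + 1L) >= confidence) j <- j + 1L
  j
}

#' Write a haplotype network as GML and/or edge-list TSV
#' @param net a \code{haplotype_network}.
#' @param gml_path optional GML output path.
#' @param tsv_path optional edge-list TSV output path.
#' @return invisibly, \code{net}.
#' @export
write_network <- function(net, gml_path = NULL, tsv_path = NULL) {
  if (!is.null(gml_path))
    igraph::write_graph(as_igraph(net), gml_path, format = "gml")
  if (!is.null(tsv_path))
    utils::write.table(net$edges, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(net)
}
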