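#' Simulation configuration
#'
#' Defaults emulate the kind of data the pipeline targets: a ~683-column
#' control-region alignment of ~100 samples from 9 species, with a planted
#' 30-column mutational hotspot at columns 554–583 running at 4x the
#' background rate, transition-dominated substitutions (odds 10:1), sparse
#' indels, and moderate geographic structure.
#'
#' @param n_samples total samples across species (default 100).
#' @param seq_len alignment columns (default 683).
#' @param background_rate expected substitutions per site per unit branch
#'   length (coalescent time units; default 0.0045, giving ~1.5%
#'   intraspecific and ~10% interspecific p-distance, typical of
#'   control-region HVRI data).
#' @param hot_window integer c(start, end) of the hotspot (default
#'   c(554, 583)).
#' @param hot_factor rate multiplier inside the hotspot (default 4).
#' @param flank_len,flank_factor width and rate multiplier of the two
#'   conserved blocks bracketing the hotspot (defaults 20 and 0.05),
#'   emulating the conserved motifs (TAS upstream, F box downstream) between
#'   which the real hyper-variable segment sits and on which flanking
#'   primers rely.
#' @param titv_ratio odds of a transition over any transversion (default 10).
#' @param indel_prob per-site indel event rate per unit branch length
#'   (default 5e-4).
#' @param n_species number of species (default 9, the number of recognised
#'   moa species covered by control-region reference alignments).
#' @param species_depth stem length from the common ancestor to each
#'   species' root, in coalescent units (default 10; sized so that a
#'   typical 30-column background window separates only a minority of
#'   species pairs while the 4x hotspot separates nearly all of them — the
#'   defining property of a usable snippet).
#' @param n_localities number of sampling localities, laid out > 25 km apart
#'   (default 12).
#' @param geo_structure in [0,1]: probability a sample sits at its
#'   haplotype's home locality rather than a uniform one (0 panmictic, 1
#'   fully confined; default 0.8).
#' @param frag_len_logmean,frag_len_logsd lognormal fragment-length
#'   parameters (defaults 4.0 and 0.6: median ~55 nt, typical of degraded
#'   bone).
#' @param seed RNG seed.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(n_samples = 100L, seq_len = 683L,
                       background_rate = 0.0045,
                       hot_window = c(554L, 583L), hot_factor = 4,
                       flank_len = 20L, flank_factor = 0.05,
                       titv_ratio = 10, indel_prob = 5e-4,
                       n_species = 9L, species_depth = 10,
                       n_localities = 12L, geo_structure = 0.8,
                       frag_len_logmean = 4.0, frag_len_logsd = 0.6,
                       seed = 1L) {
  stopifnot(n_samples >= 2, seq_len >= 1,
            hot_window[1] >= 1, hot_window[1] <= hot_window[2],
            hot_window[2] <= seq_len, hot_factor >= 1,
            titv_ratio > 0, indel_prob >= 0, indel_prob <= 1,
            geo_structure >= 0, geo_structure <= 1, n_species >= 1)
  structure(as.list(environment()), class = "sim_config")
}

BASES <- c("A", "C", "G", "T")
TRANSITION_OF <- c(A = "G", G = "A", C = "T", T = "C")

## evolve one sequence along a branch: substitution events at rate[site] * t,
## indel events at indel_rate * t; substitutions no-op on gap states
evolve_branch <- function(seq_chars, t, rates, titv_ratio, indel_rate) {
  n_sub <- stats::rpois(length(seq_chars), rates * t)
  n_ind <- stats::rpois(length(seq_chars), indel_rate * t)
  for (i in which(n_sub + n_ind > 0)) {
    events <- sample(rep(c("sub", "ind"), c(n_sub[i], n_ind[i])))
    for (ev in events) {
      cur <- seq_chars[i]
      if (ev == "ind") {
        seq_chars[i] <- if (cur == "-") sample(BASES, 1) else "-"
      } else if (cur != "-") {
        if (stats::runif(1) < titv_ratio / (titv_ratio + 1)) {
          seq_chars[i] <- TRANSITION_OF[[cur]]
        } else {
          seq_chars[i] <- sample(setdiff(BASES, c(cur, TRANSITION_OF[[cur]])), 1)
        }
      }
    }
  }
  seq_chars
}

## localities on a coarse grid, ~55 km apart, so each is its own 25-km group
make_localities <- function(n) {
  rows <- ceiling(sqrt(n))
  idx <- seq_len(n) - 1L
  data.frame(locality_name = sprintf("loc%02d", seq_len(n)),
             lat = -44 + (idx %/% rows) * 0.5,
             lon = 168 + (idx %% rows) * 0.7)
}

#' Simulate a labelled control-region alignment with a planted hotspot
#'
#' Each species gets a Kingman coalescent genealogy (\code{ape::rcoal})
#' hanging off a stem of length \code{species_depth} below a shared ancestral
#' sequence. Substitutions are placed Poisson along branches at
#' \code{background_rate} per site, multiplied by \code{hot_factor} inside
#' \code{hot_window}; transitions are chosen over transversions with odds
#' \code{titv_ratio}; indel events toggle a site to/from the gap state at
#' rate \code{indel_prob}. Samples are assigned to localities with
#' haplotype-level fidelity \code{geo_structure}. Deterministic given
#' \code{cfg$seed}.
#'
#' @param cfg a [sim_config()].
#' @return a [labelled_alignment()] with a \code{truth} attribute: list with
#'   \code{hot_window}, \code{hap_label} (true per-sample hotspot-window
#'   haplotype labels) and \code{localities} (the locality table).
#' @export
simulate_alignment <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_samples < 2) stop("degenerate config: n_samples < 2")
  set.seed(cfg$seed)
  rates <- rep(cfg$background_rate, cfg$seq_len)
  if (cfg$hot_window[1] > 1)
    rates[max(1L, cfg$hot_window[1] - cfg$flank_len):(cfg$hot_window[1] - 1L)] <-
      cfg$background_rate * cfg$flank_factor
  if (cfg$hot_window[2] < cfg$seq_len)
    rates[(cfg$hot_window[2] + 1L):min(cfg$seq_len, cfg$hot_window[2] + cfg$flank_len)] <-
      cfg$background_rate * cfg$flank_factor
  rates[cfg$hot_window[1]:cfg$hot_window[2]] <-
    cfg$background_rate * cfg$hot_factor
  root <- sample(BASES, cfg$seq_len, replace = TRUE)

  per_sp <- diff(round(seq(0, cfg$n_samples, length.out = cfg$n_species + 1)))
  localities <- make_localities(cfg$n_localities)
  seqs <- character(0); sp_vec <- character(0); ids <- character(0)
  for (s in seq_len(cfg$n_species)) {
    ns <- per_sp[s]
    if (ns == 0) next
    anc <- evolve_branch(root, cfg$species_depth, rates, cfg$titv_ratio,
                         cfg$indel_prob)
    sp_name <- sprintf("species_%d", s)
    if (ns == 1) {
      tip_seqs <- list(evolve_branch(anc, 1, rates, cfg$titv_ratio,
                                     cfg$indel_prob))
      names(tip_seqs) <- paste0(sp_name, "_01")
    } else {
      tr <- ape::rcoal(ns)
      tr <- ape::reorder.phylo(tr, "postorder")
      ntip <- ns
      node_seq <- vector("list", ntip + tr$Nnode)
      node_seq[[ntip + 1L]] <- anc           # root of the species tree
      for (e in rev(seq_len(nrow(tr$edge)))) {   # preorder
        p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
        node_seq[[ch]] <- evolve_branch(node_seq[[p]], tr$edge.length[e],
                                        rates, cfg$titv_ratio, cfg$indel_prob)
      }
      tip_seqs <- node_seq[seq_len(ntip)]
      names(tip_seqs) <- sprintf("%s_%02d", sp_name, seq_len(ntip))
    }
    seqs <- c(seqs, vapply(tip_seqs, paste, character(1), collapse = ""))
    ids <- c(ids, names(tip_seqs))
    sp_vec <- c(sp_vec, rep(sp_name, ns))
  }

  ## true haplotypes = distinct hotspot-window strings, per species
  win <- substr(seqs, cfg$hot_window[1], cfg$hot_window[2])
  hap_label <- character(length(seqs))
  for (sp in unique(sp_vec)) {
    ii <- sp_vec == sp
    hap_label[ii] <- paste0(sp, "_h", match(win[ii], unique(win[ii])))
  }

  ## geographic placement: haplotype home locality + fidelity geo_structure
  home <- stats::setNames(sample(localities$locality_name,
                                 length(unique(hap_label)), replace = TRUE),
                          unique(hap_label))
  at_home <- stats::runif(length(seqs)) < cfg$geo_structure
  loc <- ifelse(at_home, home[hap_label],
                sample(localities$locality_name, length(seqs), replace = TRUE))

  md <- data.frame(sample_id = ids, species = sp_vec, tissue = "bone",
                   source = "unknown", locality_name = loc,
                   lat = localities$lat[match(loc, localities$locality_name)],
                   lon = localities$lon[match(loc, localities$locality_name)],
                   haplotype_label = hap_label)
  aln <- labelled_alignment(stats::setNames(seqs, ids), md)
  attr(aln, "truth") <- list(hot_window = cfg$hot_window,
                             hap_label = stats::setNames(hap_label, ids),
                             localities = localities)
  aln
}

#' Simulate post-mortem fragmentation of each sample's DNA
#'
#' Per sample, \code{n_fragments} surviving template molecules get lognormal
#' lengths and uniform positions on the sequence. An amplicon succeeds for a
#' sample iff some fragment fully spans it, so success is non-increasing in
#' amplicon length.
#'
#' @param aln a [labelled_alignment()] (only ids and length are used).
#' @param cfg a [sim_config()] (fragment-length parameters and seed).
#' @param n_fragments surviving template molecules per sample (default 30).
#' @return data.frame with sample_id, start, end, length.
#' @export
degrade_fragments <- function(aln, cfg, n_fragments = 30L) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 1L)
  ids <- rep(names(aln$seq), each = n_fragments)
  len <- pmin(aln$length,
              pmax(1L, round(stats::rlnorm(length(ids), cfg$frag_len_logmean,
                                           cfg$frag_len_logsd))))
  start <- vapply(len, function(l) sample.int(aln$length - l + 1L, 1L),
                  integer(1))
  data.frame(sample_id = ids, start = start, end = start + len - 1L,
             length = len)
}

#' Per-sample amplification success of an amplicon interval
#'
#' @param fragments data.frame from [degrade_fragments()].
#' @param start,end amplicon interval, 1-based inclusive.
#' @return named logical vector, one entry per sample.
#' @export
amplicon_success <- function(fragments, start, end) {
  spans <- fragments$start <= start & fragments$end >= end
  vapply(split(spans, fragments$sample_id), any, logical(1))
}

#' Simulate three-step W/autosomal sexing assays
#'
#' Females yield a positive W assay with probability \code{1 - dropout_w} per
#' attempt (males never do); the autosomal control is positive with
#' probability \code{1 - dropout_auto} for either sex. The retest is only run
#' for W-negative, autosomal-positive samples, per protocol.
#'
#' @param true_sexes character vector of "female"/"male".
#' @param dropout_w per-attempt W amplification failure probability.
#' @param dropout_auto autosomal amplification failure probability.
#' @param seed RNG seed.
#' @return data.frame with sample_id, true_sex, w_assay, autosomal_assay,
#'   w_retest.
#' @export
simulate_assays <- function(true_sexes, dropout_w = 0.3, dropout_auto = 0,
                            seed = 1L) {
  stopifnot(all(true_sexes %in% c("female", "male")),
            dropout_w >= 0, dropout_w <= 1, dropout_auto >= 0,
            dropout_auto <= 1)
  set.seed(seed)
  n <- length(true_sexes)
  female <- true_sexes == "female"
  w1 <- ifelse(female & stats::runif(n) >= dropout_w, "positive", "negative")
  auto <- rep("not_done", n)
  retest <- rep("not_done", n)
  need_auto <- w1 == "negative"
  auto[need_auto] <- ifelse(stats::runif(sum(need_auto)) >= dropout_auto,
                            "positive", "negative")
  need_retest <- need_auto & auto == "positive"
  retest[need_retest] <- ifelse(female[need_retest] &
                                  stats::runif(sum(need_retest)) >= dropout_w,
                                "positive", "negative")
  data.frame(sample_id = paste0("S", seq_len(n)), true_sex = true_sexes,
             w_assay = w1, autosomal_assay = auto, w_retest = retest)
}
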