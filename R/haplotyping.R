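#' Haplotype catalog
#'
#' Maps haplotype labels to snippet-window sequences, per species (the same
#' window string in two species keeps both species' labels, following the
#' per-species label series D*, Dr*, E*, A*, P* used for moa), and records
#' occurrences of each label in samples and localities.
#'
#' @param entries data.frame with columns \code{haplotype_label},
#'   \code{sequence}, \code{species}.
#' @param occurrences data.frame with columns \code{sample_id},
#'   \code{haplotype_label}, \code{species}, \code{locality_name} (may have 0
#'   rows).
#' @return object of class \code{haplotype_catalog}.
#' @export
haplotype_catalog <- function(entries = NULL, occurrences = NULL) {
  if (is.null(entries))
    entries <- data.frame(haplotype_label = character(0),
                          sequence = character(0), species = character(0))
  if (is.null(occurrences))
    occurrences <- data.frame(sample_id = character(0),
                              haplotype_label = character(0),
                              species = character(0),
                              locality_name = character(0))
  for (sp in unique(entries$species)) {
    es <- entries[entries$species == sp, ]
    if (anyDuplicated(es$sequence))
      stop("duplicate window sequence within species ", sp)
    if (anyDuplicated(es$haplotype_label))
      stop("duplicate haplotype label within species ", sp)
  }
  orphans <- setdiff(paste(occurrences$species, occurrences$haplotype_label),
                     paste(entries$species, entries$haplotype_label))
  if (length(orphans))
    stop("occurrence(s) with label absent from entries: ",
         paste(orphans, collapse = ", "))
  structure(list(entries = entries, occurrences = occurrences),
            class = "haplotype_catalog")
}

#' @export
print.haplotype_catalog <- function(x, ...) {
  cat("haplotype_catalog:", nrow(x$entries), "haplotypes in",
      length(unique(x$entries$species)), "species;",
      nrow(x$occurrences), "occurrences\n")
  invisible(x)
}

## label prefixes of the moa haplotype series; unknown species fall back to
## the genus initial
species_prefix <- function(species) {
  known <- c("D. novaezealandiae" = "D", "D. robustus" = "Dr",
             "E. curtus" = "E", "A. didiformis" = "A",
             "P. geranoides" = "P")
  ifelse(species %in% names(known), known[species],
         toupper(substr(species, 1, 1)))
}

#' Build a haplotype catalog from an alignment window
#'
#' Labels the distinct window strings (aligned columns, gaps retained so the
#' fifth-state network distances stay meaningful) per species, in order of
#' first appearance, using the species prefix plus an integer. Samples whose
#' window is entirely gaps carry no sequence there and are skipped.
#'
#' @param aln a [labelled_alignment()] whose metadata has \code{species} and
#'   \code{locality_name} columns.
#' @param start,end window columns, 1-based inclusive.
#' @return a [haplotype_catalog()].
#' @export
catalog_from_alignment <- function(aln, start, end) {
  md <- aln$metadata[match(names(aln$seq), aln$metadata$sample_id), ]
  win <- substr(aln$seq, start, end)
  keep <- !is.na(md$species) & grepl("[^-]", win)
  entries <- NULL; occurrences <- NULL
  for (sp in unique(md$species[keep])) {
    ii <- which(keep & md$species == sp)
    uw <- unique(win[ii])
    labs <- paste0(unname(species_prefix(sp)), seq_along(uw))
    entries <- rbind(entries,
                     data.frame(haplotype_label = labs, sequence = uw,
                                species = sp))
    occurrences <- rbind(occurrences,
                         data.frame(sample_id = md$sample_id[ii],
                                    haplotype_label = labs[match(win[ii], uw)],
                                    species = sp,
                                    locality_name = md$locality_name[ii]))
  }
  haplotype_catalog(entries, occurrences)
}

## N-tolerant exact match of equal-length strings
frag_matches <- function(frag, entry) {
  if (nchar(frag) != nchar(entry)) return(FALSE)
  a <- strsplit(frag, "")[[1]]; b <- strsplit(entry, "")[[1]]
  all(a == b | a == "N" | b == "N")
}

#' Assign a short fragment to a haplotype
#'
#' Exact-string typing against the per-species catalog: the degapped catalog
#' entries are compared position-by-position with N matching anything. A
#' unique match returns the existing label; no match mints a new label
#' (species prefix + next unused integer) and extends the catalog; a
#' fragment whose Ns make it compatible with several entries is an error
#' listing the candidates.
#'
#' @param fragment_seq fragment sequence over \{A,C,G,T,N\}, covering the full
#'   window.
#' @param catalog a [haplotype_catalog()].
#' @param species species of the fragment (selects the label series).
#' @param sample_id,locality_name optional occurrence bookkeeping.
#' @return list with \code{label}, \code{new} (logical) and the updated
#'   \code{catalog}.
#' @export
assign_haplotype <- function(fragment_seq, catalog, species,
                             sample_id = NA_character_,
                             locality_name = NA_character_) {
  stopifnot(inherits(catalog, "haplotype_catalog"))
  fragment_seq <- toupper(fragment_seq)
  if (grepl("[^ACGTN]", fragment_seq))
    stop("fragment alphabet outside {A,C,G,T,N}")
  entries <- catalog$entries[catalog$entries$species == species, ]
  if (nrow(entries) && nchar(fragment_seq) < min(nchar(gsub("-", "", entries$sequence))))
    stop("fragment (", nchar(fragment_seq),
         " nt) shorter than the catalog window")
  hit <- which(vapply(gsub("-", "", entries$sequence, fixed = TRUE),
                      function(e) frag_matches(fragment_seq, e), logical(1)))
  if (length(hit) > 1)
    stop("ambiguous fragment (N at a diagnostic site?): matches ",
         paste(entries$haplotype_label[hit], collapse = ", "))
  if (length(hit) == 1) {
    label <- entries$haplotype_label[hit]
    new <- FALSE
  } else {
    prefix <- unname(species_prefix(species))
    nums <- suppressWarnings(as.integer(sub(paste0("^", prefix), "",
                                            entries$haplotype_label)))
    label <- paste0(prefix, max(0L, nums[!is.na(nums)]) + 1L)
    catalog$entries <- rbind(catalog$entries,
                             data.frame(haplotype_label = label,
                                        sequence = fragment_seq,
                                        species = species))
    new <- TRUE
  }
  catalog$occurrences <- rbind(catalog$occurrences,
                               data.frame(sample_id = sample_id,
                                          haplotype_label = label,
                                          species = species,
                                          locality_name = locality_name))
  list(label = label, new = new, catalog = catalog)
}

#' Great-circle distance in km (haversine)
#' @param lat1,lon1,lat2,lon2 decimal degrees; vectorised.
#' @return distance(s) in kilometres.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  2 * 6371 * asin(pmin(1, sqrt(a)))
}

#' Group sampling localities closer than a distance threshold
#'
#' Single-linkage grouping: two localities fall in the same group iff they
#' are linked by a chain of pairwise great-circle distances strictly below
#' \code{threshold_km} (default 25 km, the resolution at which nearby sites
#' are treated as one sampling location). Localities without coordinates are
#' grouped by exact name match only.
#'
#' @param records data.frame with \code{locality_name}, \code{lat},
#'   \code{lon} (lat/lon may be NA).
#' @param threshold_km strict upper bound on within-group link distances.
#' @return object of class \code{locality_grouping}: data.frame
#'   \code{locality_name} -> \code{group_id}, with the threshold as an
#'   attribute.
#' @export
group_localities <- function(records, threshold_km = 25) {
  loc <- unique(records[, c("locality_name", "lat", "lon")])
  loc <- loc[!is.na(loc$locality_name), , drop = FALSE]
  loc <- loc[!duplicated(loc$locality_name), , drop = FALSE]
  n <- nrow(loc)
  group <- seq_len(n)
  has_xy <- !is.na(loc$lat) & !is.na(loc$lon)
  idx <- which(has_xy)
  if (length(idx) >= 2) {
    g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
    cmb <- utils::combn(length(idx), 2)
    dd <- haversine_km(loc$lat[idx[cmb[1, ]]], loc$lon[idx[cmb[1, ]]],
                       loc$lat[idx[cmb[2, ]]], loc$lon[idx[cmb[2, ]]])
    close <- dd < threshold_km
    if (any(close))
      g <- igraph::add_edges(g, as.vector(cmb[, close, drop = FALSE]))
    comp <- igraph::components(g)$membership
    group[idx] <- n + comp        # distinct id space, renumbered below
  }
  gid <- match(group, unique(group))
  out <- data.frame(locality_name = loc$locality_name,
                    group_id = paste0("G", gid))
  attr(out, "threshold_km") <- threshold_km
  class(out) <- c("locality_grouping", "data.frame")
  out
}

## map locality names to group ids; names absent from the grouping become
## their own name-keyed groups
locality_groups_of <- function(names_vec, grouping = NULL) {
  if (is.null(grouping))
    return(ifelse(is.na(names_vec), "unknown", names_vec))
  gid <- grouping$group_id[match(names_vec, grouping$locality_name)]
  ifelse(is.na(gid), ifelse(is.na(names_vec), "unknown", names_vec), gid)
}

#' Phylogeographic diversity ratio
#'
#' Distinct haplotypes of a species divided by distinct occupied locality
#' groups — a crude but assumption-light index of phylogeographic structure
#' when most locations carry only one or two samples (high values mean many
#' haplotypes per sampled location).
#'
#' @param catalog a [haplotype_catalog()] with occurrences.
#' @param grouping optional [group_localities()] output; without it each
#'   distinct locality name is its own group.
#' @param species species to summarise.
#' @return the ratio (numeric scalar).
#' @export
diversity_ratio <- function(catalog, grouping = NULL, species) {
  occ <- catalog$occurrences[catalog$occurrences$species == species, ]
  if (!nrow(occ)) stop("no occurrences for species ", species)
  groups <- unique(locality_groups_of(occ$locality_name, grouping))
  if (!length(groups)) stop("zero occupied localities for species ", species)
  length(unique(occ$haplotype_label)) / length(groups)
}

#' Summary of the Tiniroto swamp fragment table
#'
#' @param records data.frame from \code{load_fixture_table("table2")} (or any
#'   table with \code{sample_id}, \code{species}, \code{haplotype_label}).
#' @return list with \code{n_samples}, \code{n_haplotypes}, \code{n_species},
#'   \code{haplotype_list}.
#' @export
tiniroto_summary <- function(records) {
  haps <- sort(unique(stats::na.omit(records$haplotype_label)))
  list(n_samples = nrow(records),
       n_haplotypes = length(haps),
       n_species = length(unique(stats::na.omit(records$species))),
       haplotype_list = haps)
}
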