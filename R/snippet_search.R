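## map alignment columns to coordinates on the reference row (NA at columns
## where the reference row is gapped)
reference_coordinates <- function(aln) {
  if (is.null(aln$reference_id)) return(rep(NA_integer_, aln$length))
  s <- strsplit(aln$seq[[aln$reference_id]], "", fixed = TRUE)[[1]]
  nongap <- s != "-"
  pos <- rep(NA_integer_, aln$length)
  pos[nongap] <- seq_len(sum(nongap)) + aln$ref_offset - 1L
  pos
}

window_strings <- function(aln, start, end) {
  substr(aln$seq, start, end)
}

#' Discriminatory power of an alignment window
#'
#' Two groups are "separated" by a window iff no window string (the exact
#' substring over the window columns, gaps included) occurs in both groups.
#' Samples whose window is entirely gaps carry no sequence there and are
#' excluded (with a warning); samples with no group label are ignored.
#'
#' @param aln a [labelled_alignment()].
#' @param start,end 1-based inclusive alignment columns.
#' @param group_by metadata column defining the groups (default
#'   \code{"species"}).
#' @return list with \code{fraction} (separated pairs / all group pairs) and
#'   \code{haplotype_count} (distinct window strings over all samples).
#' @export
window_discrimination <- function(aln, start, end, group_by = "species") {
  if (start < 1 || end > aln$length || start > end)
    stop("window [", start, ",", end, "] outside alignment of length ",
         aln$length)
  res <- discrimination_impl(aln$seq, aln$metadata[[group_by]], start, end,
                             warn = TRUE)
  res
}

discrimination_impl <- function(seqs, groups, start, end, warn = FALSE) {
  ws <- substr(seqs, start, end)
  allgap <- !grepl("[^-]", ws)
  if (any(allgap) && warn)
    warning("excluding sample(s) with gap-only window: ",
            paste(names(seqs)[allgap], collapse = ", "))
  keep <- !allgap & !is.na(groups)
  ws <- ws[keep]; groups <- as.character(groups[keep])
  glev <- unique(groups)
  if (length(glev) < 2) stop("need >= 2 groups under group_by")
  sets <- lapply(split(ws, groups), unique)
  pairs <- utils::combn(length(sets), 2)
  sep <- apply(pairs, 2, function(p)
    length(intersect(sets[[p[1]]], sets[[p[2]]])) == 0)
  list(fraction = mean(sep), haplotype_count = length(unique(ws)))
}

## per-column frequency of the modal non-N symbol (gap counts as a symbol);
## columns with no observed symbol count as fully conserved
modal_frequencies <- function(aln) {
  m <- aln_matrix(aln)
  apply(m, 2, function(col) {
    col <- col[!is.na(col)]
    if (!length(col)) return(1)
    max(tabulate(col, 5)) / length(col)
  })
}

#' Conservation of the primer flanks of a window
#'
#' Conservation of a flank is the mean, over its columns, of the frequency of
#' the modal non-N symbol (gap counted as a symbol). Flanks truncated by the
#' alignment edge are computed over the available columns and flagged.
#'
#' @param aln a [labelled_alignment()].
#' @param window integer vector \code{c(start, end)} of the snippet window.
#' @param primer_len flank width in columns (default 20, matching typical
#'   primer lengths of 18–26 nt).
#' @return list with \code{left}, \code{right} (fractions in [0, 1]) and
#'   \code{truncated} (logical).
#' @export
flank_conservation <- function(aln, window, primer_len = 20L) {
  mf <- modal_frequencies(aln)
  flank_impl(mf, window[1], window[2], primer_len, aln$length)
}

flank_impl <- function(mf, start, end, primer_len, L) {
  lcols <- max(1L, start - primer_len):(start - 1L)
  rcols <- (end + 1L):min(L, end + primer_len)
  truncated <- (start - primer_len < 1L) || (end + primer_len > L) ||
    start == 1L || end == L
  left <- if (start == 1L) NA_real_ else mean(mf[lcols])
  right <- if (end == L) NA_real_ else mean(mf[rcols])
  list(left = left, right = right, truncated = truncated)
}

#' Scan an alignment for candidate snippet windows
#'
#' Scores every window of \code{window_len} columns: group discrimination
#' (see [window_discrimination()]), distinct-haplotype count, and
#' conservation of the two primer flanks. The composite score is
#' \code{discrimination * min(left, right flank conservation)}; candidates
#' are ranked by composite score, then haplotype count (higher first), then
#' leftmost start. Windows whose flanks are truncated by the alignment edge
#' are flagged and score 0 on the missing flank.
#'
#' @param aln a [labelled_alignment()].
#' @param window_len snippet width in columns (default 30).
#' @param primer_len flank width (default 20).
#' @param max_amplicon maximum amplicon length \code{window_len +
#'   2*primer_len} (default 70); exceed it only via \code{relax_amplicon}.
#' @param group_by metadata column defining groups (default species).
#' @param relax_amplicon set TRUE to allow amplicons above the bound.
#' @return data.frame of class \code{snippet_candidates}, sorted best-first,
#'   with columns start_col, end_col, ref_start, ref_end, window_len,
#'   species_discrimination, haplotype_count, left_flank_conservation,
#'   right_flank_conservation, flank_truncated, amplicon_len,
#'   composite_score.
#' @export
scan_snippets <- function(aln, window_len = 30L, primer_len = 20L,
                          max_amplicon = 70L, group_by = "species",
                          relax_amplicon = FALSE) {
  amplicon_len <- window_len + 2L * primer_len
  if (amplicon_len > max_amplicon && !relax_amplicon)
    stop("amplicon length ", amplicon_len, " exceeds max_amplicon ",
         max_amplicon, " (set relax_amplicon = TRUE to override)")
  if (aln$length < amplicon_len)
    stop("alignment (", aln$length, " cols) shorter than amplicon (",
         amplicon_len, ")")
  L <- aln$length
  mf <- modal_frequencies(aln)
  cmf <- cumsum(mf)
  flank_mean <- function(a, b) {           # mean modal frequency over [a, b]
    (cmf[b] - if (a > 1) cmf[a - 1] else 0) / (b - a + 1)
  }
  refpos <- reference_coordinates(aln)
  groups <- aln$metadata[[group_by]][match(names(aln$seq),
                                           aln$metadata$sample_id)]

  keep0 <- !is.na(groups)
  grp <- as.character(groups[keep0])
  glev <- unique(grp)
  if (length(glev) < 2) stop("need >= 2 groups under group_by")
  gidx <- split(seq_along(grp), grp)
  pairs <- utils::combn(length(gidx), 2)
  seqs <- aln$seq[keep0]

  starts <- seq_len(L - window_len + 1L)
  nw <- length(starts)
  disc_frac <- hap_n <- lflank <- rflank <- numeric(nw)
  trunc <- logical(nw)
  rstart <- rend <- rep(NA_integer_, nw)
  for (w in seq_len(nw)) {
    s <- starts[w]; e <- s + window_len - 1L
    ws <- substr(seqs, s, e)
    nongap <- grepl("[^-]", ws)
    sets <- lapply(gidx, function(ii) unique(ws[ii[nongap[ii]]]))
    disc_frac[w] <- mean(apply(pairs, 2, function(p)
      length(intersect(sets[[p[1]]], sets[[p[2]]])) == 0))
    hap_n[w] <- length(unique(ws[nongap]))
    lflank[w] <- if (s > 1L) flank_mean(max(1L, s - primer_len), s - 1L) else 0
    rflank[w] <- if (e < L) flank_mean(e + 1L, min(L, e + primer_len)) else 0
    trunc[w] <- (s - primer_len < 1L) || (e + primer_len > L)
    rp <- refpos[s:e]
    if (!all(is.na(rp))) {
      rstart[w] <- min(rp, na.rm = TRUE); rend[w] <- max(rp, na.rm = TRUE)
    }
  }
  out <- data.frame(start_col = starts, end_col = starts + window_len - 1L,
                    ref_start = rstart, ref_end = rend,
                    window_len = window_len,
                    species_discrimination = disc_frac,
                    haplotype_count = hap_n,
                    left_flank_conservation = lflank,
                    right_flank_conservation = rflank,
                    flank_truncated = trunc,
                    amplicon_len = amplicon_len,
                    composite_score = disc_frac * pmin(lflank, rflank))
  out <- out[order(-out$composite_score, -out$haplotype_count, out$start_col), ]
  rownames(out) <- NULL
  class(out) <- c("snippet_candidates", "data.frame")
  out
}

#' Write ranked snippet candidates as TSV
#' @param x a \code{snippet_candidates} data.frame.
#' @param path output path.
#' @return invisibly, \code{x}.
#' @export
write_snippets <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}
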