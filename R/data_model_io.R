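#' @keywords internal
"_PACKAGE"

SEQ_ALPHABET <- c("A", "C", "G", "T", "-", "N")

SOURCE_DOMAIN <- c("midden", "swamp", "cave", "peat bog", "reservoir", "unknown")

## canonical column set of a sample-metadata table; extra columns are kept
SAMPLE_COLUMNS <- c("sample_id", "species", "tissue", "source",
                    "locality_name", "lat", "lon", "age_yrBP",
                    "haplotype_label", "notes")

#' Labelled alignment container
#'
#' Bundles an aligned sequence matrix (equal-length strings over
#' \code{A,C,G,T,-,N}) with a per-sample metadata table. This is the substrate
#' for variation profiling and snippet scanning.
#'
#' @param sequences named character vector of aligned sequences (names are
#'   sample ids).
#' @param metadata data.frame with at least a \code{sample_id} column; one row
#'   per sequence. Missing columns of the canonical set are filled with NA.
#' @param reference_id optional sample id whose row defines reference
#'   (non-gap) coordinates, 1-based.
#' @param ref_offset reference coordinate of the reference row's first non-gap
#'   base (defaults to 1).
#' @return An object of class \code{labelled_alignment}: a list with elements
#'   \code{seq}, \code{length}, \code{metadata}, \code{reference_id},
#'   \code{ref_offset}.
#' @export
labelled_alignment <- function(sequences, metadata = NULL, reference_id = NULL,
                               ref_offset = 1L) {
  stopifnot(is.character(sequences), length(sequences) >= 1)
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("sequences must be uniquely named by sample id")
  sequences <- toupper(sequences)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    bad <- names(sequences)[lens != stats::median(lens)]
    stop("ragged alignment: record(s) with deviant length: ",
         paste(bad, collapse = ", "))
  }
  bad_chars <- grepl(paste0("[^", paste(c("ACGTN", "-"), collapse = ""), "]"),
                     sequences)
  if (any(bad_chars))
    stop("sequence alphabet outside {A,C,G,T,-,N} in record(s): ",
         paste(names(sequences)[bad_chars], collapse = ", "))
  if (is.null(metadata))
    metadata <- data.frame(sample_id = names(sequences),
                           stringsAsFactors = FALSE)
  metadata <- validate_metadata(metadata)
  orphan_seq <- setdiff(names(sequences), metadata$sample_id)
  if (length(orphan_seq))
    stop("sequence id(s) absent from metadata: ",
         paste(orphan_seq, collapse = ", "))
  if (!is.null(reference_id) && !reference_id %in% names(sequences))
    stop("reference_id '", reference_id, "' has no sequence row")
  structure(list(seq = sequences, length = unname(lens[1]),
                 metadata = metadata, reference_id = reference_id,
                 ref_offset = as.integer(ref_offset)),
            class = "labelled_alignment")
}

validate_metadata <- function(md) {
  stopifnot(is.data.frame(md))
  if (!"sample_id" %in% names(md)) stop("metadata lacks a sample_id column")
  md$sample_id <- as.character(md$sample_id)
  if (anyDuplicated(md$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(md$sample_id[duplicated(md$sample_id)]), collapse = ", "))
  for (col in setdiff(SAMPLE_COLUMNS, names(md))) md[[col]] <- NA
  md$lat <- suppressWarnings(as.numeric(md$lat))
  md$lon <- suppressWarnings(as.numeric(md$lon))
  md$age_yrBP <- suppressWarnings(as.numeric(md$age_yrBP))
  if (any(!is.na(md$lat) & (md$lat < -90 | md$lat > 90)))
    stop("latitude outside [-90, 90]")
  if (any(!is.na(md$lon) & (md$lon < -180 | md$lon > 180)))
    stop("longitude outside [-180, 180]")
  if (any(!is.na(md$age_yrBP) & md$age_yrBP < 0))
    stop("age_yrBP must be >= 0")
  md$source <- canonical_source(md$source)
  md
}

canonical_source <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x %in% c("", "–", "-")] <- "unknown"
  x <- tolower(trimws(x))
  x[x == "reservior"] <- "reservoir"   # printed typo in the museum table
  bad <- !x %in% SOURCE_DOMAIN
  if (any(bad)) stop("unknown source value(s): ",
                     paste(unique(x[bad]), collapse = ", "))
  x
}

#' @export
print.labelled_alignment <- function(x, ...) {
  cat("labelled_alignment:", length(x$seq), "sequences x", x$length,
      "columns\n")
  sp <- x$metadata$species
  if (!all(is.na(sp)))
    cat("  species:", paste(names(table(sp)), table(sp), collapse = ", "),
        "\n")
  if (!is.null(x$reference_id))
    cat("  reference row:", x$reference_id, "\n")
  invisible(x)
}

#' Read an aligned FASTA plus a sample-metadata TSV
#'
#' @param fasta_path path to an aligned FASTA file (gap character \code{-}).
#' @param metadata_path optional path to a tab-separated metadata table with a
#'   header row including \code{sample_id}. Missing values may be empty or the
#'   en-dash used in printed museum tables.
#' @param reference_id,ref_offset see [labelled_alignment()].
#' @return A [labelled_alignment()].
#' @export
read_alignment <- function(fasta_path, metadata_path = NULL,
                           reference_id = NULL, ref_offset = 1L) {
  dna <- suppressWarnings(ape::read.FASTA(fasta_path))
  if (is.null(dna) || length(dna) == 0)
    stop("empty or unreadable FASTA: ", fasta_path)
  seqs <- vapply(as.character(dna), function(s) paste(toupper(s), collapse = ""),
                 character(1))
  md <- if (!is.null(metadata_path)) read_metadata(metadata_path) else NULL
  labelled_alignment(seqs, md, reference_id = reference_id,
                     ref_offset = ref_offset)
}

#' Read a sample-metadata TSV
#'
#' Empty cells and the typographic en-dash map to NA. Unknown extra columns
#' are preserved.
#' @param path path to a UTF-8 TSV with a header row.
#' @return data.frame of sample records.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          na.strings = c("", "NA", "–"),
                          fileEncoding = "UTF-8", check.names = FALSE,
                          fill = TRUE)
  validate_metadata(md)
}

#' Write a labelled alignment back to FASTA (+ optional metadata TSV)
#'
#' @param aln a [labelled_alignment()].
#' @param fasta_path output FASTA path.
#' @param metadata_path optional output TSV path.
#' @return invisibly, the input.
#' @export
write_alignment <- function(aln, fasta_path, metadata_path = NULL) {
  stopifnot(inherits(aln, "labelled_alignment"))
  lines <- character(0)
  for (id in names(aln$seq))
    lines <- c(lines, paste0(">", id), aln$seq[[id]])
  writeLines(lines, fasta_path, useBytes = TRUE)
  if (!is.null(metadata_path))
    utils::write.table(aln$metadata, metadata_path, sep = "\t",
                       quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(aln)
}

#' Load a packaged museum table fixture
#'
#' \code{"table1"} is the set of newly typed moa bones from across New
#' Zealand (47 records); \code{"table2"} is the 24 bone fragments recovered
#' from Tiniroto swamp, with a molecular-sexing column. Table 2 records get
#' tissue "bone", source "swamp" and locality "Tiniroto" filled in, since the
#' printed table states these once for all rows.
#'
#' @param name "table1" or "table2".
#' @return data.frame of sample records (table2 carries an extra \code{sex}
#'   column with values F/M/NA).
#' @export
load_fixture_table <- function(name = c("table1", "table2")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".tsv"), package = "snippetr")
  if (path == "") stop("fixture not found: ", name)
  md <- read_metadata(path)
  if (name == "table2") {
    md$tissue <- "bone"
    md$source <- "swamp"
    md$locality_name <- "Tiniroto"
    md$sex <- as.character(md$sex)
  }
  md
}

## integer encoding of aligned sequences: A=1 C=2 G=3 T=4 -=5 N=NA
aln_matrix <- function(aln) {
  stopifnot(inherits(aln, "labelled_alignment"))
  chars <- strsplit(aln$seq, "", fixed = TRUE)
  m <- matrix(match(unlist(chars), c("A", "C", "G", "T", "-")),
              nrow = length(chars), byrow = TRUE)
  rownames(m) <- names(aln$seq)
  m
}
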