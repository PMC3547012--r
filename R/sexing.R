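#' W-specific and autosomal sexing primers
#'
#' Documentation constants for the three-step molecular sexing assay: a
#' 58 bp W-chromosome product (W present only in females under avian ZW
#' genetics) and a 72 bp autosomal control product confirming amplifiable
#' nuclear DNA.
#' @format named character vector.
#' @export
SEXING_PRIMERS <- c(
  moaWF  = "CACTGTTTTCTTACTAATAGCGAAGT",
  moaWR  = "ATGTTAAGCAATGCTCTATGACA",
  msox9F = "CTGCTCCTTGAATCTGATGA",
  msox9R = "CTTAGGCCAACGATACGAAA"
)

ASSAY_LEVELS <- c("positive", "negative", "not_done")

check_assay <- function(x, what) {
  x <- as.character(x)
  x[is.na(x)] <- "not_done"
  bad <- !x %in% ASSAY_LEVELS
  if (any(bad)) stop("invalid ", what, " value(s): ",
                     paste(unique(x[bad]), collapse = ", "))
  x
}

#' Call sex from a three-step W/autosomal assay record
#'
#' Decision logic: a positive W assay (initial test or retest) calls female;
#' a sample negative for W on both attempts but positive for the autosomal
#' control calls male (nuclear DNA amplifies, W absent); a sample whose
#' autosomal control fails is unknown (no amplifiable nuclear DNA, so W
#' absence is uninformative). Records showing a W retest without a positive
#' autosomal assay violate the protocol and are flagged in the evidence.
#'
#' @param w_assay,autosomal_assay,w_retest vectors over
#'   \{positive, negative, not_done\}; vectorised over records.
#' @param sample_id optional ids carried through.
#' @return data.frame of class \code{sex_calls} with \code{sample_id},
#'   \code{call} (female/male/unknown) and \code{evidence}.
#' @export
call_sex <- function(w_assay, autosomal_assay = "not_done",
                     w_retest = "not_done", sample_id = NULL) {
  n <- length(w_assay)
  w <- check_assay(w_assay, "w_assay")
  a <- rep_len(check_assay(autosomal_assay, "autosomal_assay"), n)
  r <- rep_len(check_assay(w_retest, "w_retest"), n)
  if (any(w == "not_done")) stop("w_assay must be done for every record")
  if (is.null(sample_id)) sample_id <- paste0("S", seq_len(n))

  call <- rep("unknown", n)
  evidence <- character(n)
  female <- w == "positive" | r == "positive"
  male <- !female & w == "negative" & a == "positive" & r == "negative"
  nodna <- !female & a == "negative"
  call[female] <- "female"
  call[male] <- "male"
  evidence[w == "positive"] <- "W+ on first test"
  evidence[w != "positive" & r == "positive"] <- "W- then W+ on retest"
  evidence[male] <- "W- twice, autosomal+"
  evidence[nodna] <- "no amplifiable nuclear DNA"
  evidence[call == "unknown" & !nodna] <- "incomplete assay record"
  protocol_violation <- r != "not_done" & a != "positive"
  evidence[protocol_violation] <- paste0(evidence[protocol_violation],
                                         " [retest without autosomal+]")
  out <- data.frame(sample_id = sample_id, call = call, evidence = evidence)
  class(out) <- c("sex_calls", "data.frame")
  out
}

#' Sex-ratio summary of a set of calls
#'
#' @param calls a \code{sex_calls} data.frame from [call_sex()], or a
#'   character vector of calls (female/male/unknown; "F"/"M" accepted).
#' @return list with \code{n_male}, \code{n_female}, \code{n_unknown} and
#'   \code{ratio_text} ("1:x", male count reduced to 1 when males are
#'   present, otherwise "0:n").
#' @export
sex_ratio <- function(calls) {
  v <- if (is.data.frame(calls)) calls$call else as.character(calls)
  v <- tolower(v)
  v[v %in% c("f")] <- "female"
  v[v %in% c("m")] <- "male"
  v[is.na(v) | v %in% c("", "–", "-")] <- "unknown"
  bad <- !v %in% c("female", "male", "unknown")
  if (any(bad)) stop("invalid call(s): ", paste(unique(v[bad]), collapse = ", "))
  nm <- sum(v == "male"); nf <- sum(v == "female"); nu <- sum(v == "unknown")
  ratio_text <- if (nm >= 1) {
    x <- nf / nm
    paste0("1:", if (x == round(x)) format(round(x)) else format(round(x, 1)))
  } else paste0("0:", nf)
  list(n_male = nm, n_female = nf, n_unknown = nu, ratio_text = ratio_text)
}
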