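# Reference sequence context for the EGFR beta3/alphaC region.

# Canonical one-letter sequence of human EGFR (UniProt P00533, precursor
# numbering) for residues 740-770: end of strand beta3 through helix alphaC.
.EGFR_REF_SEQ <- "IPVAIKELREATSPKANKEILDEAYVMASVD"
.EGFR_REF_START <- 740L

#' Reference context for the EGFR beta3/alphaC region
#'
#' Builds the reference against which exon 19 variant descriptors are parsed
#' and validated. Residue numbering follows the EGFR precursor protein
#' (UniProt P00533, including the 24-residue signal peptide); mature-protein
#' numbers are 24 lower. The default sequence covers precursor residues
#' 740-770 (strand beta3 through the C-terminal end of helix alphaC),
#' including the catalytic lysine K745 and the salt-bridge glutamate E762.
#'
#' @param loop_start,loop_end Inclusive precursor-numbering bounds of the
#'   beta3/alphaC loop window used for classification. The default window
#'   E746-I759 covers every exon 19 deletion variant reported in lung cancer
#'   cohorts analysed by this package.
#' @param sequence One-letter amino-acid string for the reference interval.
#' @param seq_start Precursor residue number of the first letter of
#'   `sequence`.
#' @return An object of class `egfr_reference` with fields
#'   `sequence`, `seq_start`, `seq_end`, `loop_start`, `loop_end`.
#' @examples
#' ctx <- egfr_reference()
#' ref_residue(ctx, 747) # "L"
#' @export
egfr_reference <- function(loop_start = 746L, loop_end = 759L,
                           sequence = NULL, seq_start = NULL) {
  if (is.null(sequence)) {
    sequence <- .EGFR_REF_SEQ
    seq_start <- .EGFR_REF_START
  }
  if (is.null(seq_start)) {
    stop("`seq_start` must be given when a custom `sequence` is supplied")
  }
  seq_start <- as.integer(seq_start)
  sequence <- toupper(gsub("\\s", "", sequence))
  if (!grepl("^[A-Z]+$", sequence)) {
    stop("reference sequence must contain only amino-acid letters")
  }
  seq_end <- seq_start + nchar(sequence) - 1L
  loop_start <- as.integer(loop_start)
  loop_end <- as.integer(loop_end)
  if (loop_start > loop_end) stop("loop_start must be <= loop_end")
  if (loop_start < seq_start || loop_end > seq_end) {
    stop("loop window must lie inside the reference sequence interval")
  }
  structure(
    list(sequence = sequence, seq_start = seq_start, seq_end = seq_end,
         loop_start = loop_start, loop_end = loop_end),
    class = "egfr_reference"
  )
}

#' @export
print.egfr_reference <- function(x, ...) {
  cat("EGFR reference context (precursor numbering)\n")
  cat(sprintf("  sequence: %s (%d-%d)\n", x$sequence, x$seq_start, x$seq_end))
  cat(sprintf("  beta3/alphaC loop window: %d-%d\n", x$loop_start, x$loop_end))
  invisible(x)
}

#' Look up a reference residue identity
#'
#' @param context An [egfr_reference()] object.
#' @param position Precursor residue number(s).
#' @return One-letter residue code(s).
#' @export
ref_residue <- function(context, position) {
  stopifnot(inherits(context, "egfr_reference"))
  position <- as.integer(position)
  if (any(position < context$seq_start | position > context$seq_end)) {
    stop(sprintf("position outside reference interval %d-%d",
                 context$seq_start, context$seq_end))
  }
  idx <- position - context$seq_start + 1L
  vapply(idx, function(i) substr(context$sequence, i, i), character(1))
}

#' Convert between precursor and mature EGFR residue numbering
#'
#' EGFR precursor numbering (UniProt P00533) includes the 24-residue signal
#' peptide, so precursor numbers are 24 greater than mature-protein numbers.
#'
#' @param index Residue index (vectorised).
#' @param direction `"precursor_to_mature"` or `"mature_to_precursor"`.
#' @return Converted residue index.
#' @examples
#' convert_numbering(746, "precursor_to_mature") # 722
#' @export
convert_numbering <- function(index,
                              direction = c("precursor_to_mature",
                                            "mature_to_precursor")) {
  direction <- match.arg(direction)
  index <- as.integer(index)
  if (any(index <= 0L)) stop("residue index must be positive")
  out <- if (direction == "precursor_to_mature") index - 24L else index + 24L
  if (any(out <= 0L)) {
    stop("converted residue index is not positive; index precedes the mature N-terminus")
  }
  out
}
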