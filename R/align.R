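#' Affine-gap alignment scoring parameters
#'
#' @param match Match score (default +1).
#' @param mismatch Mismatch score (default -2).
#' @param gap_open Gap opening score; a gap of length `k` scores
#'   `gap_open + k * gap_extend` (default -4).
#' @param gap_extend Per-base gap extension score (default -1).
#' @param max_length Longest sequence the aligner accepts; longer inputs
#'   should be supplied pre-aligned (aligned-FASTA).
#' @return A list of class `alignment_scoring`.
#' @export
alignment_scoring <- function(match = 1L, mismatch = -2L,
                              gap_open = -4L, gap_extend = -1L,
                              max_length = 5000L) {
  stopifnot(match > mismatch, gap_extend <= 0, gap_open <= 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 max_length = as.integer(max_length)),
            class = "alignment_scoring")
}

#' Globally align a read to a reference
#'
#' Optimal global (end-to-end) alignment under affine gap scoring, computed
#' with a three-state dynamic program. Ties are broken deterministically:
#' an aligned pair is preferred over a gap in the read, which is preferred
#' over a gap in the reference, and gap runs are extended greedily so that
#' equivalent-score gap placements resolve to a fixed layout.
#'
#' @param read Read sequence (character scalar, `A/C/G/T/N`).
#' @param reference Reference sequence (character scalar).
#' @param scoring An [alignment_scoring()] object.
#' @return A list of class `pairwise_alignment` with gapped strings `ref`
#'   and `read` (equal length) and the alignment `score`.
#' @export
align_to_reference <- function(read, reference, scoring = alignment_scoring()) {
  stopifnot(is.character(read), length(read) == 1L,
            is.character(reference), length(reference) == 1L)
  if (!nzchar(read) || !nzchar(reference))
    stop("sequences must be non-empty")
  if (nchar(read) > scoring$max_length || nchar(reference) > scoring$max_length)
    stop("sequence exceeds the aligner length bound (", scoring$max_length,
         " nt); supply pre-aligned input (aligned-FASTA) instead")
  read <- normalize_alphabet(read)
  reference <- normalize_alphabet(reference)
  res <- .gotoh_align(reference, read, scoring$match, scoring$mismatch,
                      scoring$gap_open, scoring$gap_extend)
  structure(list(ref = res$ref, read = res$read, score = res$score),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("<pairwise_alignment> score", x$score, "\n")
  cat("  ref : ", substr(x$ref, 1, 60), if (nchar(x$ref) > 60) "..." else "", "\n", sep = "")
  cat("  read: ", substr(x$read, 1, 60), if (nchar(x$read) > 60) "..." else "", "\n", sep = "")
  invisible(x)
}
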