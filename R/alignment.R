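# Read-to-amplicon alignment. Global (Needleman-Wunsch) alignment with affine
# gaps via Biostrings::pairwiseAlignment; a gap of length L costs
# gap_open + L * gap_extend. Defaults: match +2, mismatch -3, open 8, extend 1.

#' Reference amplicon for genotyping
#'
#' @param sequence Amplicon DNA (the study amplified regions of roughly
#'   200 bp around each target site).
#' @param cut_site 1-based index of the last base 5' of the Cas9 cut.
#' @param quantification_window Half-width in bp of the window around the cut
#'   site inside which edits are counted (default 10). Edits wholly outside
#'   the window are treated as sequencing noise.
#' @return An `amplicon_ref` list.
#' @export
amplicon_ref <- function(sequence, cut_site, quantification_window = 10L) {
  sequence <- as_dna_string(sequence, "sequence")
  L <- nchar(sequence)
  if (!is_count(cut_site) || cut_site < 1 || cut_site >= L)
    stop("cut_site must lie inside the sequence", call. = FALSE)
  w <- as.integer(quantification_window)
  if (w < 0 || cut_site - w + 1L < 1L || cut_site + w > L)
    stop("quantification window must lie fully inside the sequence",
         call. = FALSE)
  structure(list(sequence = sequence, cut_site = as.integer(cut_site),
                 quantification_window = w),
            class = "amplicon_ref")
}

#' Alignment scoring parameters
#'
#' @param match,mismatch,gap_open,gap_extend Scores; a gap of length L
#'   costs `gap_open + L * gap_extend`.
#' @param min_identity Reads whose alignment identity (matches / alignment
#'   columns) falls below this are flagged for discard (default 0.6).
#' @return An `align_params` list.
#' @export
align_params <- function(match = 2, mismatch = -3, gap_open = 8,
                         gap_extend = 1, min_identity = 0.6) {
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, min_identity = min_identity),
            class = "align_params")
}

#' @noRd
editscan_sub_matrix <- function(params) {
  bases <- c(DNA_BASES, "N")
  m <- matrix(params$mismatch, 5, 5, dimnames = list(bases, bases))
  diag(m)[1:4] <- params$match  # N never matches, even N vs N
  m
}

#' Globally align reads to a reference amplicon
#'
#' Vectorized over reads; returns one `read_alignment` per read. Reads with
#' identity below `params$min_identity` are flagged `discard` (they typically
#' arise from primer artefacts or contaminating templates, not from editing).
#'
#' @param reads Character vector (or `DNAStringSet`) of reads over
#'   A/C/G/T/N.
#' @param ref An [amplicon_ref()].
#' @param params An [align_params()].
#' @return A list of `read_alignment` objects, each with `score`,
#'   `aligned_read`, `aligned_ref`, `identity`, `discard`.
#' @export
align_reads <- function(reads, ref, params = align_params()) {
  stopifnot(inherits(ref, "amplicon_ref"))
  if (inherits(reads, "DNAStringSet")) reads <- as.character(reads)
  if (!length(reads)) return(list())
  if (any(!nzchar(reads))) stop("empty read", call. = FALSE)
  reads <- toupper(reads)
  if (any(grepl("[^ACGTN]", reads)))
    stop("reads must be over A/C/G/T/N", call. = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(reads), Biostrings::DNAString(ref$sequence),
    type = "global", substitutionMatrix = editscan_sub_matrix(params),
    gapOpening = params$gap_open, gapExtension = params$gap_extend)
  # for a global alignment pattern()/subject() carry the gapped strings
  ap <- as.character(Biostrings::pattern(aln))
  as <- as.character(Biostrings::subject(aln))
  scores <- Biostrings::score(aln)
  lapply(seq_along(reads), function(i) {
    pc <- strsplit(ap[i], "")[[1]]
    sc <- strsplit(as[i], "")[[1]]
    ident <- sum(pc == sc) / length(pc)
    structure(list(score = scores[i], aligned_read = ap[i],
                   aligned_ref = as[i], identity = ident,
                   discard = ident < params$min_identity),
              class = "read_alignment")
  })
}

#' Globally align one read to a reference amplicon
#'
#' @inheritParams align_reads
#' @param read A single read.
#' @return A `read_alignment` object.
#' @examples
#' ref <- amplicon_ref(strrep("ACGT", 25), 50)
#' align_read(strrep("ACGT", 25), ref)$score
#' @export
align_read <- function(read, ref, params = align_params()) {
  align_reads(read, ref, params)[[1]]
}

#' @export
print.read_alignment <- function(x, ...) {
  cat(sprintf("Global alignment: score %g, identity %.1f%%%s\n", x$score,
              100 * x$identity, if (x$discard) " [discard]" else ""))
  cat(" read:", x$aligned_read, "\n")
  cat(" ref: ", x$aligned_ref, "\n")
  invisible(x)
}
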