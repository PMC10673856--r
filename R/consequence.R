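# Protein-consequence prediction for edit signatures: rebuild the edited CDS,
# translate to the first stop, and report frameshift status, the chimeric
# residue structure (identical residues before divergence, novel residues
# before termination), lost conserved cysteines and in-frame deleted residues.
#
# A frameshift typically yields a chimera: an N-terminal stretch of
# gene-specific residues followed by novel residues read in the shifted frame
# until a premature stop — and when the shift precedes the fourth conserved
# cysteine codon, that cysteine is lost, which is expected to abolish NCR
# function.

#' Protein annotation for consequence prediction
#'
#' @param cds_cut_site 1-based position of the last base 5' of the Cas9 cut
#'   within the CDS (maps signature offsets into CDS coordinates).
#' @param signal_end Number of residues in the signal peptide (0 when the
#'   protein has none); mature-peptide residue numbering starts after it.
#' @param conserved_cys 1-based residue indices (in the full protein) of the
#'   four conserved motif cysteines.
#' @return A `protein_annotation` list.
#' @export
protein_annotation <- function(cds_cut_site, signal_end = 0L,
                               conserved_cys = integer(0)) {
  if (!is_count(cds_cut_site) || cds_cut_site < 1)
    stop("cds_cut_site must be a positive integer", call. = FALSE)
  structure(list(cds_cut_site = as.integer(cds_cut_site),
                 signal_end = as.integer(signal_end),
                 conserved_cys = as.integer(sort(conserved_cys))),
            class = "protein_annotation")
}

#' @noRd
translate_to_stop <- function(cds) {
  n <- 3L * (nchar(cds) %/% 3L)
  if (n == 0L) return(list(protein = "", stop_position = NA_integer_))
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(substring(cds, 1L, n)), no.init.codon = TRUE))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0)
    list(protein = substring(aa, 1L, stop_at - 1L),
         stop_position = as.integer(stop_at))
  else list(protein = aa, stop_position = NA_integer_)
}

#' Predict the protein consequence of an edit signature
#'
#' The edited CDS is built by applying the signature's operations (offsets
#' relative to the cut site, as produced by [call_allele()]), translated with
#' the standard genetic code up to the first stop codon, and compared to the
#' wild-type protein.
#'
#' @param ref_cds Wild-type coding sequence (beginning at the start codon;
#'   a terminal stop codon may be included).
#' @param signature An `edit_signature` from [call_allele()], or a list of
#'   [edit_op()]s.
#' @param protein_annot A [protein_annotation()].
#' @return A `consequence_report` list: `frameshift` (net indel not a
#'   multiple of 3), `start_lost`, `identical_residues_before_divergence`,
#'   `novel_residues_before_stop`, `stop_position` (1-based residue index of
#'   the first stop codon in the mutant translation, `NA` when none is
#'   reached), `lost_conserved_cys` (indices among the annotated motif
#'   cysteines, wild-type numbering), `inframe_deleted_residues` (data frame
#'   `residue`, `position_mature` for clean in-frame losses),
#'   `mutant_protein`, `wt_protein`.
#' @examples
#' cds <- paste0("ATG", strrep("GAA", 20), "TGTTAA")  # Met + 20xGlu + Cys
#' sig <- list(edit_op("del", at = 0, length = 3))
#' predict_consequence(cds, sig, protein_annotation(cds_cut_site = 30))
#' @export
predict_consequence <- function(ref_cds, signature, protein_annot) {
  stopifnot(inherits(protein_annot, "protein_annotation"))
  ref_cds <- check_dna_strict(ref_cds, "ref_cds")
  ops <- signature_ops(signature)
  cut <- protein_annot$cds_cut_site

  # reuse the simulator's edit engine to build the mutant CDS
  edits <- lapply(seq_len(nrow(ops)), function(i)
    edit_op(ops$kind[i], at = ops$offset[i], length = ops$length[i],
            seq = ops$seq[i]))
  net <- if (nrow(ops))
    sum(ops$length[ops$kind == "ins"]) - sum(ops$length[ops$kind == "del"])
  else 0L

  # an edit touching the start codon aborts translation
  touches_start <- nrow(ops) > 0 && any(
    ifelse(ops$kind == "ins", cut + ops$offset < 3L,
           cut + ops$offset + 1L <= 3L))
  if (touches_start) {
    return(structure(list(frameshift = net %% 3L != 0L, start_lost = TRUE,
                          identical_residues_before_divergence = 0L,
                          novel_residues_before_stop = 0L,
                          stop_position = NA_integer_,
                          lost_conserved_cys = integer(0),
                          inframe_deleted_residues =
                            data.frame(residue = character(0),
                                       position_mature = integer(0)),
                          mutant_protein = NA_character_,
                          wt_protein = translate_to_stop(ref_cds)$protein),
                     class = "consequence_report"))
  }
  mut_cds <- apply_edits(ref_cds, cut, edits)

  wt <- translate_to_stop(ref_cds)
  mut <- translate_to_stop(mut_cds)
  wt_aa <- strsplit(wt$protein, "")[[1]]
  mut_aa <- strsplit(mut$protein, "")[[1]]

  nw <- length(wt_aa); nm <- length(mut_aa)
  prefix <- 0L
  while (prefix < min(nw, nm) && wt_aa[prefix + 1L] == mut_aa[prefix + 1L])
    prefix <- prefix + 1L
  suffix <- 0L
  while (suffix < min(nw, nm) - prefix &&
         wt_aa[nw - suffix] == mut_aa[nm - suffix])
    suffix <- suffix + 1L

  # a wild-type residue survives iff it sits in the common prefix or suffix
  lost_cys <- protein_annot$conserved_cys[
    protein_annot$conserved_cys > prefix &
      protein_annot$conserved_cys <= nw - suffix]

  frameshift <- net %% 3L != 0L
  inframe_del <- if (!frameshift && net < 0L && nm < nw) {
    pos <- seq.int(prefix + 1L, nw - suffix)
    data.frame(residue = wt_aa[pos],
               position_mature = pos - protein_annot$signal_end,
               stringsAsFactors = FALSE)
  } else data.frame(residue = character(0), position_mature = integer(0))

  structure(list(frameshift = frameshift, start_lost = FALSE,
                 identical_residues_before_divergence = prefix,
                 novel_residues_before_stop = nm - prefix,
                 stop_position = mut$stop_position,
                 lost_conserved_cys = lost_cys,
                 inframe_deleted_residues = inframe_del,
                 mutant_protein = mut$protein, wt_protein = wt$protein),
            class = "consequence_report")
}

#' @noRd
signature_ops <- function(signature) {
  if (inherits(signature, "edit_signature")) return(signature$ops)
  if (inherits(signature, "edit_op")) signature <- list(signature)
  if (is.list(signature) && all(vapply(signature, inherits, TRUE, "edit_op")))
    return(data.frame(
      kind = vapply(signature, `[[`, "", "kind"),
      offset = vapply(signature, `[[`, 0L, "at"),
      length = vapply(signature, `[[`, 0L, "length"),
      seq = vapply(signature, `[[`, "", "seq"), stringsAsFactors = FALSE))
  stop("signature must be an edit_signature or a list of edit_op",
       call. = FALSE)
}

#' @export
print.consequence_report <- function(x, ...) {
  if (x$start_lost) { cat("Start codon lost; no translation\n")
    return(invisible(x)) }
  cat(sprintf("Frameshift: %s\n", x$frameshift))
  cat(sprintf("Identical residues before divergence: %d\n",
              x$identical_residues_before_divergence))
  cat(sprintf("Novel residues before stop: %d (stop at residue %s)\n",
              x$novel_residues_before_stop,
              ifelse(is.na(x$stop_position), "none",
                     as.character(x$stop_position))))
  if (length(x$lost_conserved_cys))
    cat("Lost conserved Cys at:", paste(x$lost_conserved_cys,
                                        collapse = ", "), "\n")
  if (nrow(x$inframe_deleted_residues)) {
    cat("In-frame deleted residues (mature-peptide numbering):\n")
    print(x$inframe_deleted_residues)
  }
  invisible(x)
}
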