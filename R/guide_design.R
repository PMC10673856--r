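# SpCas9 guide-site design: protospacer enumeration, placement and 5'-base
# constraints, and minimum off-target mismatch search against a genome.
#
# Coordinates are 1-based, fully closed, always on the plus strand of the
# queried sequence. `cut_site` is the index of the last base 5' of the blunt
# cut (SpCas9 cuts 3 bp 5' of the PAM, between protospacer positions 17/18).

#' Enumerate all SpCas9 protospacers in a DNA sequence
#'
#' Every 20-mer immediately followed by an NGG PAM, on either strand, is
#' returned with no constraints evaluated. Reverse-strand candidates report
#' plus-strand coordinates: `start` is always the leftmost plus-strand
#' position of the protospacer, and `cut_site` the plus-strand index of the
#' base 5' of the cut. On the plus strand `cut_site = start + 16`; on the
#' minus strand `cut_site = start + 2`.
#'
#' @param gene_sequence DNA string over A/C/G/T (a `DNAString` is accepted);
#'   ambiguous bases are an error.
#' @return A data frame of class `guide_candidates`: `protospacer`, `pam`,
#'   `strand`, `start`, `cut_site`, `five_prime_class` (G / A / other),
#'   sorted by `start` then strand (`+` before `-`).
#' @examples
#' enumerate_protospacers(paste0("G", strrep("A", 19), "AGG"))
#' @export
enumerate_protospacers <- function(gene_sequence) {
  seq <- check_dna_strict(gene_sequence, "gene_sequence")
  L <- nchar(seq)
  if (L < 23) stop("gene_sequence must be at least 23 bp", call. = FALSE)
  ch <- strsplit(seq, "")[[1]]
  s <- seq_len(L - 22L)  # window starts

  plus <- s[ch[s + 21L] == "G" & ch[s + 22L] == "G"]
  minus <- s[ch[s] == "C" & ch[s + 1L] == "C"]

  win <- function(i, a, b) substring(seq, i + a, i + b)
  cand <- rbind(
    if (length(plus)) data.frame(
      protospacer = win(plus, 0L, 19L), pam = win(plus, 20L, 22L),
      strand = "+", start = plus, cut_site = plus + 16L,
      stringsAsFactors = FALSE),
    if (length(minus)) data.frame(
      protospacer = vapply(win(minus, 3L, 22L), revcomp, character(1),
                           USE.NAMES = FALSE),
      pam = vapply(win(minus, 0L, 2L), revcomp, character(1),
                   USE.NAMES = FALSE),
      strand = "-", start = minus + 3L, cut_site = minus + 5L,
      stringsAsFactors = FALSE)
  )
  if (is.null(cand))
    cand <- data.frame(protospacer = character(0), pam = character(0),
                       strand = character(0), start = integer(0),
                       cut_site = integer(0), stringsAsFactors = FALSE)
  cand <- cand[order(cand$start, cand$strand), , drop = FALSE]
  first <- substring(cand$protospacer, 1L, 1L)
  cand$five_prime_class <- ifelse(first == "G", "G",
                                  ifelse(first == "A", "A", "other"))
  rownames(cand) <- NULL
  class(cand) <- c("guide_candidates", "data.frame")
  cand
}

#' Gene annotation for guide-placement constraints
#'
#' @param cys4_codon_start 1-based position (in the gene sequence) of the
#'   first base of the codon of the fourth conserved cysteine.
#' @param mature_start 1-based position of the first base of the first codon
#'   of the mature peptide (used for the distance ranking; defaults to 1).
#' @param cds_intervals Optional list/matrix of 1-based closed `c(start, end)`
#'   coding intervals, sorted and non-overlapping; `cys4_codon_start` must
#'   fall inside one of them when they are given.
#' @return A `gene_annotation` list.
#' @export
gene_annotation <- function(cys4_codon_start, mature_start = 1L,
                            cds_intervals = NULL) {
  if (!is_count(cys4_codon_start) || cys4_codon_start < 1)
    stop("cys4_codon_start must be a positive integer", call. = FALSE)
  if (!is.null(cds_intervals)) {
    iv <- do.call(rbind, lapply(cds_intervals, as.integer))
    if (any(iv[, 1] > iv[, 2])) stop("malformed cds interval", call. = FALSE)
    if (is.unsorted(iv[, 1]) ||
        any(iv[-1, 1] <= iv[-nrow(iv), 2] & nrow(iv) > 1))
      stop("cds_intervals must be sorted and non-overlapping", call. = FALSE)
    inside <- any(cys4_codon_start >= iv[, 1] & cys4_codon_start <= iv[, 2])
    if (!inside)
      stop("cys4_codon_start must lie inside a cds interval", call. = FALSE)
  }
  structure(list(cys4_codon_start = as.integer(cys4_codon_start),
                 mature_start = as.integer(mature_start),
                 cds_intervals = cds_intervals),
            class = "gene_annotation")
}

#' Apply placement and 5'-base constraints and rank guide candidates
#'
#' A candidate is `upstream_of_cys4` when its cut falls strictly upstream of
#' the first base of the fourth conserved cysteine codon (a cut immediately
#' before that base does not count as upstream). Ranking order: upstream
#' candidates first; then 5' base G before A before other (the U6-type
#' polymerase-III promoters used to express sgRNAs strongly prefer a 5' G,
#' and a 5' C was observed to nearly abolish editing); then ascending distance
#' of the cut site from the mature-peptide start; ties broken by ascending
#' `start`. Candidates cutting at or downstream of the fourth cysteine codon
#' are retained but flagged.
#'
#' @param candidates A `guide_candidates` data frame from
#'   [enumerate_protospacers()].
#' @param annot A [gene_annotation()].
#' @return The candidates with `upstream_of_cys4`, `dist_to_mature_start` and
#'   `rank` columns added, sorted by rank.
#' @export
apply_constraints <- function(candidates, annot) {
  if (!inherits(annot, "gene_annotation"))
    stop("annot must be a gene_annotation", call. = FALSE)
  if (!all(c("protospacer", "start", "cut_site", "strand") %in%
           names(candidates)))
    stop("candidates must come from enumerate_protospacers()", call. = FALSE)
  cand <- candidates
  # strict: the cut (after base cut_site) must leave >= 1 gene base before
  # the cys4 codon, i.e. first base after the cut precedes cys4_codon_start
  cand$upstream_of_cys4 <- (cand$cut_site + 1L) < annot$cys4_codon_start
  cand$dist_to_mature_start <- abs(cand$cut_site - annot$mature_start)
  cls <- match(cand$five_prime_class, c("G", "A", "other"))
  ord <- order(!cand$upstream_of_cys4, cls, cand$dist_to_mature_start,
               cand$start, cand$strand)
  cand <- cand[ord, , drop = FALSE]
  cand$rank <- seq_len(nrow(cand))
  rownames(cand) <- NULL
  class(cand) <- c("guide_candidates", "data.frame")
  cand
}

#' Minimum off-target mismatch count for a protospacer
#'
#' Scans a genome for every 20-mer adjacent to an NGG PAM on either strand,
#' excludes the on-target site, and returns the minimum Hamming distance
#' between the protospacer and those sites. Guide-selection practice in the
#' study required at least two mismatches at every potential off-target
#' site; [passes_offtarget_rule()] applies that predicate.
#'
#' Splitting the genome into multiple FASTA records or reordering contigs
#' does not change the result (sites never span record boundaries).
#'
#' @param protospacer 20-base DNA string.
#' @param genome Named character vector of contig sequences, or a
#'   `DNAStringSet`, or the path to a FASTA file.
#' @param target_locus The on-target site to exclude: a list with `contig`,
#'   `start` (1-based plus-strand protospacer start, as reported by
#'   [enumerate_protospacers()]) and `strand`. `NULL` excludes nothing.
#' @param include_nag Also scan NAG PAMs (off by default; the mismatch rule
#'   as stated concerns NGG sites).
#' @return Minimum mismatch count over all off-target sites, or `Inf` when
#'   the genome contains no PAM-adjacent site other than the target.
#' @export
min_offtarget_mismatches <- function(protospacer, genome,
                                     target_locus = NULL,
                                     include_nag = FALSE) {
  protospacer <- as_dna_string(protospacer, "protospacer")
  if (nchar(protospacer) != 20L)
    stop("protospacer must be exactly 20 bases", call. = FALSE)
  genome <- load_genome(genome)
  pr_raw <- charToRaw(protospacer)
  best <- Inf
  for (contig in names(genome)) {
    sites <- pam_adjacent_sites(genome[[contig]], include_nag)
    if (!nrow(sites)) next
    if (!is.null(target_locus) && identical(target_locus$contig, contig)) {
      keep <- !(sites$start == target_locus$start &
                  sites$strand == target_locus$strand)
      sites <- sites[keep, , drop = FALSE]
    }
    for (s in sites$protospacer) {
      d <- sum(charToRaw(s) != pr_raw)
      if (d < best) best <- d
      if (best == 0) return(0L)
    }
  }
  best
}

#' @noRd
load_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (inherits(genome, "DNAStringSet")) {
    nm <- sub("\\s.*$", "", names(genome))
    genome <- setNames(as.character(genome), nm)
  }
  if (!is.character(genome) || is.null(names(genome)))
    stop("genome must be a named character vector, DNAStringSet or FASTA path",
         call. = FALSE)
  toupper(genome)
}

#' All PAM-adjacent 20-mers in one contig, both strands, plus-strand coords
#' @noRd
pam_adjacent_sites <- function(seq, include_nag = FALSE) {
  L <- nchar(seq)
  empty <- data.frame(protospacer = character(0), start = integer(0),
                      strand = character(0), stringsAsFactors = FALSE)
  if (L < 23) return(empty)
  ch <- strsplit(seq, "")[[1]]
  s <- seq_len(L - 22L)
  p3 <- ch[s + 22L]; p2 <- ch[s + 21L]
  plus <- s[p3 == "G" & (p2 == "G" | (include_nag & p2 == "A"))]
  m1 <- ch[s]; m2 <- ch[s + 1L]
  minus <- s[m1 == "C" & (m2 == "C" | (include_nag & m2 == "T"))]
  rbind(
    if (length(plus)) data.frame(
      protospacer = substring(seq, plus, plus + 19L),
      start = plus, strand = "+", stringsAsFactors = FALSE),
    if (length(minus)) data.frame(
      protospacer = vapply(substring(seq, minus + 3L, minus + 22L), revcomp,
                           character(1), USE.NAMES = FALSE),
      start = minus + 3L, strand = "-", stringsAsFactors = FALSE),
    empty
  )
}

#' Does a guide satisfy the minimum off-target mismatch rule?
#'
#' @param protospacer,genome,target_locus,include_nag See
#'   [min_offtarget_mismatches()].
#' @param min_mismatches Required minimum (default 2).
#' @return `TRUE` when every off-target site differs by at least
#'   `min_mismatches` bases.
#' @export
passes_offtarget_rule <- function(protospacer, genome, target_locus = NULL,
                                  min_mismatches = 2L, include_nag = FALSE) {
  min_offtarget_mismatches(protospacer, genome, target_locus,
                           include_nag) >= min_mismatches
}

#' @export
print.guide_candidates <- function(x, ...) {
  cat(sprintf("%d SpCas9 guide candidate(s)\n", nrow(x)))
  NextMethod()
}
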