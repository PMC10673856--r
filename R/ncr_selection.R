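# Candidate-gene selection: conserved-cysteine motif scan, isoelectric point,
# charge class, expression filter and the per-stage funnel report.

AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R",
                 "S","T","V","W","Y")

#' Load a side-chain pKa table
#'
#' Returns the named pKa set used for isoelectric-point calculation. The only
#' set shipped with the package is `"emboss"` (the EMBOSS defaults). The table
#' identity travels with every pI value so that reports can record which pKa
#' model produced them; published NCR pI ranges depend on the pKa model and
#' are not comparable across models.
#'
#' @param name Name of the pKa set (currently only `"emboss"`).
#' @return A list with elements `name`, `nterm`, `cterm` (numeric pKa values)
#'   and `sidechain` (named numeric vector over D, E, C, Y, H, K, R).
#' @examples
#' pka_table()$sidechain[["K"]]
#' @export
pka_table <- function(name = "emboss") {
  name <- match.arg(tolower(name), "emboss")
  path <- system.file("extdata", paste0("pka_", name, ".tsv"),
                      package = "editscan", mustWork = TRUE)
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  pka <- setNames(tab$pka, tab$group)
  side <- pka[setdiff(names(pka), c("Nterm", "Cterm"))]
  list(name = name, nterm = unname(pka[["Nterm"]]),
       cterm = unname(pka[["Cterm"]]), sidechain = side)
}

#' Scan a mature peptide for the conserved four-cysteine NCR motif
#'
#' Searches for four cysteines spaced C-X5-C-Xn-C-X4-C: exactly 5 residues
#' between the first and second cysteine, at least `gap2_min` between the
#' second and third, and exactly 4 between the third and fourth. The leftmost
#' (lexicographically smallest position quadruple) match is reported. With
#' `require_exact_four_cys = TRUE` (the default) a mature peptide containing
#' any number of cysteines other than four fails regardless of spacing,
#' mirroring the restriction of the canonical NCR class to four conserved
#' cysteines (six-cysteine NCRs are a distinct class).
#'
#' @param mature_peptide Uppercase amino-acid string (the mature peptide,
#'   i.e. after signal-peptide cleavage).
#' @param gap1,gap3 Exact inter-cysteine gaps (defaults 5 and 4).
#' @param gap2_min Minimum middle gap (default 1, unconstrained above).
#' @param require_exact_four_cys Fail peptides whose mature sequence does not
#'   contain exactly four cysteines.
#' @return A list with `match` (logical), `cys_positions` (1-based residue
#'   indices of the four matched cysteines, or integer(0)) and
#'   `n_additional_matches` (count of further, non-reported matches).
#' @examples
#' scan_cys_motif("NNCDEFGHCNNNCIKLMCNN")$cys_positions  # 3 9 13 18
#' @export
scan_cys_motif <- function(mature_peptide, gap1 = 5L, gap3 = 4L,
                           gap2_min = 1L, require_exact_four_cys = TRUE) {
  if (!is.character(mature_peptide) || length(mature_peptide) != 1L)
    stop("mature_peptide must be a single string", call. = FALSE)
  if (gap1 < 0 || gap3 < 0 || gap2_min < 0)
    stop("gap constraints must be >= 0", call. = FALSE)
  aa <- strsplit(mature_peptide, "")[[1]]
  if (length(aa) && any(!aa %in% AA_ALPHABET))
    stop("mature_peptide contains non-amino-acid characters", call. = FALSE)
  no_match <- list(match = FALSE, cys_positions = integer(0),
                   n_additional_matches = 0L)
  cys <- which(aa == "C")
  if (require_exact_four_cys && length(cys) != 4L) return(no_match)
  if (length(cys) < 4L) return(no_match)

  # all position quadruples satisfying the gap pattern, in leftmost order
  hits <- list()
  for (i in seq_along(cys)) {
    j_ok <- cys[cys == cys[i] + gap1 + 1L]
    for (j in j_ok) {
      k_ok <- cys[cys >= j + gap2_min + 1L]
      for (k in k_ok) {
        l_ok <- cys[cys == k + gap3 + 1L]
        for (l in l_ok) hits[[length(hits) + 1L]] <- c(cys[i], j, k, l)
      }
    }
  }
  if (!length(hits)) return(no_match)
  ord <- order(vapply(hits, `[`, 0, 1), vapply(hits, `[`, 0, 2),
               vapply(hits, `[`, 0, 3), vapply(hits, `[`, 0, 4))
  list(match = TRUE, cys_positions = as.integer(hits[[ord[1]]]),
       n_additional_matches = length(hits) - 1L)
}

#' Henderson-Hasselbalch net charge of a peptide at a given pH
#'
#' Positive groups (N-terminus, K, R, H) contribute `n / (1 + 10^(pH - pKa))`;
#' negative groups (C-terminus, D, E, C, Y) contribute
#' `-n / (1 + 10^(pKa - pH))`.
#'
#' @param peptide Amino-acid string.
#' @param pH Numeric vector of pH values.
#' @param pka A pKa table from [pka_table()].
#' @return Net charge, one value per element of `pH`.
#' @export
net_charge <- function(peptide, pH, pka = pka_table()) {
  aa <- strsplit(toupper(peptide), "")[[1]]
  if (!length(aa)) stop("peptide must be non-empty", call. = FALSE)
  counts <- table(factor(aa, levels = AA_ALPHABET))
  pos_pka <- c(pka$nterm, pka$sidechain[c("K", "R", "H")])
  pos_n <- c(1, counts[c("K", "R", "H")])
  neg_pka <- c(pka$cterm, pka$sidechain[c("D", "E", "C", "Y")])
  neg_n <- c(1, counts[c("D", "E", "C", "Y")])
  vapply(pH, function(p) {
    sum(pos_n / (1 + 10^(p - pos_pka))) - sum(neg_n / (1 + 10^(neg_pka - p)))
  }, numeric(1))
}

#' Isoelectric point of a peptide by bisection
#'
#' Finds the pH in \[0, 14\] at which the Henderson-Hasselbalch net charge is
#' zero, by bisection to a bracket width of `tol` (default 1e-4). For display
#' the value is conventionally rounded to 2 decimals; the full-precision value
#' is returned.
#'
#' @inheritParams net_charge
#' @param tol Bisection tolerance in pH units.
#' @return The pI in pH units, with attribute `pka_set` recording the pKa
#'   table used.
#' @examples
#' compute_pI("ACDEFGHIK")
#' @export
compute_pI <- function(peptide, pka = pka_table(), tol = 1e-4) {
  if (!is.character(peptide) || length(peptide) != 1L || !nzchar(peptide))
    stop("peptide must be a single non-empty string", call. = FALSE)
  lo <- 0; hi <- 14
  f_lo <- net_charge(peptide, lo, pka)
  if (f_lo <= 0) return(structure(lo, pka_set = pka$name))
  if (net_charge(peptide, hi, pka) >= 0) return(structure(hi, pka_set = pka$name))
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (net_charge(peptide, mid, pka) > 0) lo <- mid else hi <- mid
  }
  structure((lo + hi) / 2, pka_set = pka$name)
}

#' Charge-class boundaries
#'
#' The study classifies mature NCR peptides as anionic, neutral or cationic
#' by isoelectric point. No published boundary values exist for this
#' classification, so the defaults (anionic at pI <= 6.5, cationic at
#' pI >= 7.5) are explicit, configurable package choices recorded in every
#' report.
#'
#' @param anionic_max Upper pI bound (inclusive) for the anionic class.
#' @param cationic_min Lower pI bound (inclusive) for the cationic class.
#' @return A `charge_boundaries` list.
#' @export
charge_boundaries <- function(anionic_max = 6.5, cationic_min = 7.5) {
  if (!(anionic_max < cationic_min))
    stop("anionic_max must be < cationic_min", call. = FALSE)
  structure(list(anionic_max = anionic_max, cationic_min = cationic_min),
            class = "charge_boundaries")
}

#' Classify a peptide's charge from its isoelectric point
#'
#' @param pI Isoelectric point(s) in \[0, 14\].
#' @param boundaries A [charge_boundaries()] object.
#' @return Character vector over `{"anionic", "neutral", "cationic"}`.
#' @export
classify_charge <- function(pI, boundaries = charge_boundaries()) {
  if (any(pI < 0 | pI > 14)) stop("pI must lie in [0, 14]", call. = FALSE)
  ifelse(pI <= boundaries$anionic_max, "anionic",
         ifelse(pI >= boundaries$cationic_min, "cationic", "neutral"))
}

#' Expression-filter thresholds for candidate selection
#'
#' @param min_total_reads Genes are retained only when their total nodule
#'   read count strictly exceeds this (default 10,000, the study's cutoff).
#' @param pseudogene_reads Total read count at or below which a gene is
#'   counted as pseudogene-like (default 0: no reads at all).
#' @return A `selection_thresholds` list.
#' @export
selection_thresholds <- function(min_total_reads = 10000L,
                                 pseudogene_reads = 0L) {
  if (pseudogene_reads > min_total_reads)
    stop("pseudogene_reads must be <= min_total_reads", call. = FALSE)
  structure(list(min_total_reads = min_total_reads,
                 pseudogene_reads = pseudogene_reads),
            class = "selection_thresholds")
}

#' Run the candidate-selection funnel over an annotated peptide family
#'
#' Applies, in order: the signal-peptide annotation filter, the conserved
#' four-cysteine motif scan on the mature peptide, and the expression filter
#' (total reads strictly greater than `thresholds$min_total_reads`). Within
#' the motif-passing stage, genes with `pseudogene_reads` or fewer total reads
#' are reported as pseudogene-like and genes above that but at or below the
#' expression cutoff as low-expression. Selection is a pure filter: input
#' records are not modified.
#'
#' @param records A data frame with columns `gene_id`, `full_peptide`,
#'   `has_signal_peptide` (logical annotation, e.g. from SignalP),
#'   `signal_cleavage_site` (1-based index of the last signal-peptide residue,
#'   `NA` when there is none) and `total_reads` (or supply `expression`).
#'   When absent, `mature_peptide` is derived from the cleavage site (the
#'   whole peptide is taken as mature when no signal peptide is annotated).
#' @param expression Optional expression table (as from
#'   [gen_expression_table()]) with columns `gene_id` and `total_reads`,
#'   joined on `gene_id`. Every record must have expression data.
#' @param thresholds A [selection_thresholds()] object.
#' @param motif Arguments for [scan_cys_motif()] as a list, e.g.
#'   `list(gap1 = 5, gap3 = 4, gap2_min = 1, require_exact_four_cys = TRUE)`.
#' @param boundaries A [charge_boundaries()] object used to annotate retained
#'   records with a charge class.
#' @param pka A pKa table from [pka_table()].
#' @return A list of class `selection_result` with `selected` (data frame of
#'   retained records annotated with `mature_peptide`, `cys_positions`, `pI`,
#'   `charge_class`) and `funnel` (a `funnel_report`).
#' @export
select_candidates <- function(records, expression = NULL,
                              thresholds = selection_thresholds(),
                              motif = list(),
                              boundaries = charge_boundaries(),
                              pka = pka_table()) {
  need <- c("gene_id", "full_peptide", "has_signal_peptide")
  if (!is.data.frame(records) || !all(need %in% names(records)))
    stop("records must be a data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!is.null(expression)) {
    idx <- match(records$gene_id, expression$gene_id)
    if (anyNA(idx)) {
      missing <- records$gene_id[which(is.na(idx))[1]]
      stop("no expression data for record '", missing, "'", call. = FALSE)
    }
    records$total_reads <- expression$total_reads[idx]
  }
  if (is.null(records$total_reads) || anyNA(records$total_reads)) {
    bad <- if (is.null(records$total_reads)) records$gene_id[1] else
      records$gene_id[which(is.na(records$total_reads))[1]]
    stop("no expression data for record '", bad, "'", call. = FALSE)
  }
  n <- nrow(records)
  if (is.null(records$mature_peptide)) {
    cleave <- records$signal_cleavage_site %||% rep(NA_integer_, n)
    records$mature_peptide <- vapply(seq_len(n), function(i) {
      if (isTRUE(records$has_signal_peptide[i]) && !is.na(cleave[i]))
        substring(records$full_peptide[i], cleave[i] + 1L)
      else records$full_peptide[i]
    }, character(1))
  }

  pass_sp <- isTRUE_vec(records$has_signal_peptide)
  scans <- lapply(records$mature_peptide, function(p)
    do.call(scan_cys_motif, c(list(p), motif)))
  pass_motif <- pass_sp & vapply(scans, `[[`, TRUE, "match")
  zero_reads <- pass_motif & records$total_reads <= thresholds$pseudogene_reads
  retained <- pass_motif & records$total_reads > thresholds$min_total_reads
  low_expr <- pass_motif & !zero_reads & !retained

  funnel <- structure(list(
    input = n,
    signal_peptide = sum(pass_sp),
    motif = sum(pass_motif),
    zero_reads = sum(zero_reads),
    low_expression = sum(low_expr),
    retained = sum(retained),
    min_total_reads = thresholds$min_total_reads,
    pka_set = pka$name
  ), class = "funnel_report")

  sel <- records[retained, , drop = FALSE]
  if (nrow(sel)) {
    sel$cys_positions <- I(lapply(scans[retained], `[[`, "cys_positions"))
    sel$pI <- vapply(sel$mature_peptide, function(p)
      as.numeric(compute_pI(p, pka)), numeric(1), USE.NAMES = FALSE)
    sel$charge_class <- classify_charge(sel$pI, boundaries)
  }
  rownames(sel) <- NULL
  structure(list(selected = sel, funnel = funnel), class = "selection_result")
}

#' @noRd
isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' @export
print.funnel_report <- function(x, ...) {
  cat("NCR candidate-selection funnel\n")
  cat(sprintf("  input genes:                %6d\n", x$input))
  cat(sprintf("  with signal peptide:        %6d\n", x$signal_peptide))
  cat(sprintf("  with conserved Cys motif:   %6d\n", x$motif))
  cat(sprintf("    pseudogene-like (0 reads):%6d\n", x$zero_reads))
  cat(sprintf("    low expression (<= %d): %6d\n",
              x$min_total_reads, x$low_expression))
  cat(sprintf("  retained (> %d reads):   %6d\n",
              x$min_total_reads, x$retained))
  cat(sprintf("  [pKa set: %s]\n", x$pka_set))
  invisible(x)
}

#' @export
print.selection_result <- function(x, ...) {
  print(x$funnel)
  if (nrow(x$selected)) {
    cat("\nRetained candidates (first rows):\n")
    cols <- intersect(c("gene_id", "pI", "charge_class", "total_reads"),
                      names(x$selected))
    print(utils::head(x$selected[, cols, drop = FALSE]))
  }
  invisible(x)
}
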