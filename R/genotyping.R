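# Per-nodule allele calling and genotype classification. Reads are collapsed
# by their edit signature inside the quantification window around the cut
# site, so PCR/sequencing noise far from the cut cannot split alleles; the
# resulting allele table drives the wild-type / chimeric / mutant-majority /
# fully-mutant classification and the editing-efficiency summary.

#' Extract the in-window edit signature from an alignment
#'
#' Walks the aligned read/reference pair, collects deletion, insertion and
#' substitution operations in reference coordinates, merges adjacent
#' same-kind operations, and keeps only those intersecting the quantification
#' window (`cut_site` +/- `quantification_window`). Offsets in the signature
#' are relative to the cut site with the same convention as [edit_op()]: a
#' deletion/substitution starting at reference base `cut_site + k + 1` has
#' offset `k`; an insertion after base `cut_site + k` has offset `k`, so an
#' insertion exactly at the cut has offset 0.
#'
#' @param alignment A `read_alignment` from [align_read()] against `ref`.
#' @param ref The same [amplicon_ref()].
#' @return An `edit_signature` list: `ops` (data frame `kind`, `offset`,
#'   `length`, `seq`), `net_indel` (signed bp), `classification`
#'   (`"WT"`, `"indel"` or `"mismatch_only"`), `signature` (canonical string
#'   key used to collapse reads into alleles).
#' @examples
#' ref <- amplicon_ref(strrep("ACGT", 25), 50)
#' mut <- apply_edits(ref$sequence, 50, edit_op("ins", 0, seq = "A"))
#' call_allele(align_read(mut, ref), ref)$signature
#' @export
call_allele <- function(alignment, ref) {
  stopifnot(inherits(alignment, "read_alignment"),
            inherits(ref, "amplicon_ref"))
  pc <- strsplit(alignment$aligned_read, "")[[1]]
  sc <- strsplit(alignment$aligned_ref, "")[[1]]
  cut <- ref$cut_site
  w <- ref$quantification_window

  # per-column state, then runs of identical state = merged same-kind ops;
  # ref_pos[j] is the number of reference bases consumed up to column j, so
  # for an insertion column it equals the gap position after which it sits
  state <- ifelse(sc == "-", "ins",
                  ifelse(pc == "-", "del", ifelse(pc != sc, "sub", "m")))
  ref_pos <- cumsum(sc != "-")
  runs <- rle(state)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L
  op_i <- which(runs$values != "m")
  kind <- runs$values[op_i]
  start <- ref_pos[run_start[op_i]]
  end <- ref_pos[run_end[op_i]]
  seqs <- vapply(seq_along(op_i), function(r) {
    if (kind[r] == "del") return("")
    cols <- run_start[op_i[r]]:run_end[op_i[r]]
    paste(pc[cols], collapse = "")
  }, character(1))

  if (length(kind)) {
    in_win <- ifelse(kind == "ins",
                     start >= cut - w & start <= cut + w,
                     end >= cut - w + 1L & start <= cut + w)
    kind <- kind[in_win]; start <- start[in_win]; end <- end[in_win]
    seqs <- seqs[in_win]
  }
  len <- ifelse(kind == "ins", nchar(seqs), end - start + 1L)
  offset <- ifelse(kind == "ins", start - cut, start - cut - 1L)
  ops <- data.frame(kind = kind, offset = as.integer(offset),
                    length = as.integer(len), seq = seqs,
                    stringsAsFactors = FALSE)
  net <- sum(len[kind == "ins"]) - sum(len[kind == "del"])
  classification <- if (!nrow(ops)) "WT"
    else if (any(kind %in% c("ins", "del"))) "indel" else "mismatch_only"
  sig <- if (!nrow(ops)) "WT" else
    paste(sprintf("%s%+d:%d%s", kind, offset, len,
                  ifelse(nzchar(seqs), paste0(":", seqs), "")),
          collapse = ";")
  structure(list(ops = ops, net_indel = as.integer(net),
                 classification = classification, signature = sig),
            class = "edit_signature")
}

#' @export
print.edit_signature <- function(x, ...) {
  cat(sprintf("Edit signature: %s (net indel %+d, %s)\n", x$signature,
              x$net_indel, x$classification))
  invisible(x)
}

#' Classification thresholds for nodule genotypes
#'
#' @param wt_max_for_mutant_majority A nodule is at most mutant-majority
#'   (not wild-type or merely chimeric) when its wild-type allele fraction is
#'   at or below this (default 0.50, the "max. 50% WT allele" convention of
#'   the editing-efficiency table; the boundary is inclusive).
#' @param wt_max_for_fully_mutant Wild-type fraction at or below which a
#'   nodule counts as fully mutant (default 0.05: residual wild-type reads at
#'   trace level are attributed to sporadic wild-type cells or contamination).
#' @param min_allele_frequency Alleles below this frequency are pooled into
#'   an `"other"` row that is excluded from classification (default 0.01;
#'   suppresses error-derived pseudo-alleles).
#' @return A `classification_thresholds` list.
#' @export
classification_thresholds <- function(wt_max_for_mutant_majority = 0.50,
                                      wt_max_for_fully_mutant = 0.05,
                                      min_allele_frequency = 0.01) {
  if (wt_max_for_fully_mutant > wt_max_for_mutant_majority)
    stop("fully-mutant threshold must be <= mutant-majority threshold",
         call. = FALSE)
  structure(list(wt_max_for_mutant_majority = wt_max_for_mutant_majority,
                 wt_max_for_fully_mutant = wt_max_for_fully_mutant,
                 min_allele_frequency = min_allele_frequency),
            class = "classification_thresholds")
}

#' Collapse a nodule's reads into an allele-frequency table
#'
#' Reads are aligned, low-identity reads discarded, and retained reads
#' collapsed by identical in-window edit signature. Rows below
#' `thresholds$min_allele_frequency` are merged into an `"other"` row that is
#' counted in the totals but excluded from genotype classification. Rows are
#' sorted by descending frequency, then signature.
#'
#' @param reads Character vector or `DNAStringSet` of reads (or a path to a
#'   FASTQ file), e.g. one nodule's amplicon sequencing.
#' @param ref An [amplicon_ref()].
#' @param thresholds A [classification_thresholds()].
#' @param params An [align_params()].
#' @param nodule_id Label carried through to reports.
#' @return An `allele_table`: `nodule_id`, `alleles` (data frame `signature`,
#'   `classification`, `net_indel`, `reads`, `frequency`), `total_reads`
#'   (retained), `discarded_reads`, `input_reads`, `thresholds`.
#' @export
build_allele_table <- function(reads, ref,
                               thresholds = classification_thresholds(),
                               params = align_params(),
                               nodule_id = "nodule") {
  stopifnot(inherits(ref, "amplicon_ref"),
            inherits(thresholds, "classification_thresholds"))
  if (is.character(reads) && length(reads) == 1L && file.exists(reads))
    reads <- read_fastq(reads)
  if (inherits(reads, "DNAStringSet")) reads <- as.character(reads)
  n_input <- length(reads)
  if (!n_input) stop("no reads supplied", call. = FALSE)

  # collapse identical reads before aligning
  counts <- table(reads)
  uniq <- names(counts)
  alns <- align_reads(uniq, ref, params)
  discard <- vapply(alns, `[[`, TRUE, "discard")
  n_discard <- sum(counts[discard])
  if (all(discard)) stop("no reads retained after identity filter",
                         call. = FALSE)
  keep <- which(!discard)
  details <- lapply(alns[keep], call_allele, ref = ref)
  sigs <- vapply(details, `[[`, character(1), "signature")

  agg <- tapply(as.integer(counts[keep]), sigs, sum)
  sig_info <- details[match(names(agg), sigs)]
  tab <- data.frame(
    signature = names(agg),
    classification = vapply(sig_info, `[[`, "", "classification"),
    net_indel = vapply(sig_info, `[[`, 0L, "net_indel"),
    reads = as.integer(agg), stringsAsFactors = FALSE)
  total <- sum(tab$reads)
  tab$frequency <- tab$reads / total

  low <- tab$frequency < thresholds$min_allele_frequency &
    tab$signature != "WT"
  if (any(low)) {
    other <- data.frame(signature = "other", classification = "other",
                        net_indel = NA_integer_, reads = sum(tab$reads[low]),
                        frequency = sum(tab$frequency[low]),
                        stringsAsFactors = FALSE)
    tab <- rbind(tab[!low, , drop = FALSE], other)
  }
  tab <- tab[order(-tab$frequency, tab$signature), , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(nodule_id = nodule_id, alleles = tab,
                 total_reads = total, discarded_reads = as.integer(n_discard),
                 input_reads = n_input, thresholds = thresholds),
            class = "allele_table")
}

#' @export
print.allele_table <- function(x, ...) {
  cat(sprintf("Allele table for %s: %d retained / %d discarded of %d reads\n",
              x$nodule_id, x$total_reads, x$discarded_reads, x$input_reads))
  print(x$alleles, digits = 3)
  invisible(x)
}

#' Classify one nodule's genotype from its allele table
#'
#' Classification (thresholds from [classification_thresholds()]):
#' * `fully_mutant_indel_only` / `fully_mutant_with_mismatch` — wild-type
#'   fraction at or below `wt_max_for_fully_mutant`; `indel_only` when every
#'   retained mutant allele is an indel allele.
#' * `mutant_majority` — wild-type fraction at or below
#'   `wt_max_for_mutant_majority`.
#' * `heterozygous_chimeric` — wild-type majority but at least one retained
#'   mutant allele (nodules on hairy roots frequently descend from multiple
#'   founder cells, so mixed genotypes are expected).
#' * `wild_type` — otherwise.
#'
#' @param table An [build_allele_table()] result.
#' @param thresholds A [classification_thresholds()]; defaults to the ones
#'   stored in `table`.
#' @param phenotype_label Optional nodule phenotype:
#'   `"pink_elongated"` (Fix+), `"white_undeveloped"` (Fix-) or
#'   `"unscored"`.
#' @return A `nodule_genotype` list: `nodule_id`, `class`, `wt_fraction`,
#'   `n_alleles` (retained non-"other" rows), `phenotype_label`.
#' @export
classify_nodule <- function(table, thresholds = NULL,
                            phenotype_label = c("unscored", "pink_elongated",
                                                "white_undeveloped")) {
  stopifnot(inherits(table, "allele_table"))
  phenotype_label <- match.arg(phenotype_label)
  th <- thresholds %||% table$thresholds
  tab <- table$alleles
  core <- tab[tab$signature != "other", , drop = FALSE]
  wt_fraction <- if ("WT" %in% core$signature)
    core$frequency[core$signature == "WT"] else 0
  mutant <- core[core$signature != "WT", , drop = FALSE]

  cls <- if (wt_fraction <= th$wt_max_for_fully_mutant && nrow(mutant)) {
    if (all(mutant$classification == "indel")) "fully_mutant_indel_only"
    else "fully_mutant_with_mismatch"
  } else if (wt_fraction <= th$wt_max_for_mutant_majority && nrow(mutant)) {
    "mutant_majority"
  } else if (nrow(mutant)) {
    "heterozygous_chimeric"
  } else "wild_type"

  structure(list(nodule_id = table$nodule_id, class = cls,
                 wt_fraction = wt_fraction, n_alleles = nrow(core),
                 phenotype_label = phenotype_label),
            class = "nodule_genotype")
}

#' @export
print.nodule_genotype <- function(x, ...) {
  cat(sprintf("%s: %s (WT fraction %.3f, %d allele(s), phenotype %s)\n",
              x$nodule_id, x$class, x$wt_fraction, x$n_alleles,
              x$phenotype_label))
  invisible(x)
}

#' Summarize editing efficiency per construct
#'
#' Reproduces the editing-efficiency table layout of the study: per construct
#' (split by phenotype label when any nodule in the construct is scored),
#' the number of nodules sequenced, the number carrying at most 50% wild-type
#' allele, the number fully mutant (mismatch or indel), the number fully
#' mutant with indel alleles only, and the percentage of nodule samples
#' carrying only indel alleles (fully mutant indel-only / sequenced, rounded
#' half-up to integer percent).
#'
#' @param genotypes A data frame with columns `construct`, `class`,
#'   `wt_fraction` and optionally `phenotype_label`; or a list of
#'   `nodule_genotype` objects plus a `construct` vector.
#' @param construct When `genotypes` is a list of `nodule_genotype`s, the
#'   construct label for each.
#' @param wt_max Wild-type-fraction ceiling for the "max. 50% WT" row
#'   (inclusive, default 0.50).
#' @return A data frame of class `editing_summary` with one row per construct
#'   (x phenotype) group. Empty groups are dropped with a warning.
#' @examples
#' g <- data.frame(construct = "NCR068",
#'                 class = c(rep("fully_mutant_indel_only", 7),
#'                           rep("fully_mutant_with_mismatch", 7),
#'                           "mutant_majority"),
#'                 wt_fraction = c(rep(0, 14), 0.4))
#' summarize_editing(g)$pct_indel_only  # 47
#' @export
summarize_editing <- function(genotypes, construct = NULL, wt_max = 0.50) {
  if (!is.data.frame(genotypes)) {
    stopifnot(all(vapply(genotypes, inherits, TRUE, "nodule_genotype")))
    genotypes <- data.frame(
      construct = if (is.null(construct)) "construct" else construct,
      nodule_id = vapply(genotypes, `[[`, "", "nodule_id"),
      class = vapply(genotypes, `[[`, "", "class"),
      wt_fraction = vapply(genotypes, `[[`, 0, "wt_fraction"),
      phenotype_label = vapply(genotypes, `[[`, "", "phenotype_label"),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(c("construct", "class", "wt_fraction") %in% names(genotypes)))
  if (is.null(genotypes$phenotype_label))
    genotypes$phenotype_label <- "unscored"
  if (!nrow(genotypes)) {
    warning("empty genotype set: nothing to summarize")
    return(structure(data.frame(), class = c("editing_summary",
                                             "data.frame")))
  }

  # constructs with no scored phenotype collapse into one "all" group
  eff_pheno <- genotypes$phenotype_label
  for (cs in unique(genotypes$construct)) {
    i <- genotypes$construct == cs
    if (all(genotypes$phenotype_label[i] == "unscored")) eff_pheno[i] <- "all"
  }
  groups <- split(seq_len(nrow(genotypes)),
                  paste(genotypes$construct, eff_pheno, sep = "\r"),
                  drop = TRUE)
  rows <- lapply(groups, function(idx) {
    df <- genotypes[idx, , drop = FALSE]
    fully <- df$class %in% c("fully_mutant_indel_only",
                             "fully_mutant_with_mismatch")
    indel_only <- df$class == "fully_mutant_indel_only"
    data.frame(construct = df$construct[1], phenotype = eff_pheno[idx[1]],
               n_sequenced = nrow(df),
               n_wt_le_max = sum(df$wt_fraction <= wt_max),
               n_fully_mutant = sum(fully),
               n_fully_mutant_indel_only = sum(indel_only),
               pct_indel_only = as.integer(
                 round_half_up(100 * sum(indel_only) / nrow(df))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$construct, out$phenotype), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("editing_summary", "data.frame")
  out
}

#' @export
print.editing_summary <- function(x, ...) {
  cat("Editing-efficiency summary (percent = fully mutant, indel only / sequenced):\n")
  NextMethod()
}
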