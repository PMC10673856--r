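# Mixed-allele amplicon read simulator. Each nodule's read set is a
# multinomial mixture of a wild-type allele and one or more edited alleles at
# a Cas9 cut site, with a simple per-base error model (uniform substitutions,
# 1-bp indel errors) layered on top. The allele of origin of every read is
# recorded in a truth table so recovery can be tested exactly.

DNA_BASES <- c("A", "C", "G", "T")

#' Describe one edit of an allele
#'
#' Positions are relative to the cut site: a deletion or substitution with
#' `at = k` starts at reference base `cut_site + k + 1`; an insertion with
#' `at = k` is placed immediately after reference base `cut_site + k` (so
#' `at = 0` inserts exactly at the cut).
#'
#' @param kind One of `"del"`, `"ins"`, `"sub"`.
#' @param at Signed offset relative to the cut site (see above).
#' @param length Edit length in bp (>= 1). For insertions and substitutions
#'   it must equal `nchar(seq)`.
#' @param seq Inserted bases (`ins`) or replacement bases (`sub`); empty for
#'   deletions.
#' @return An `edit_op` list.
#' @examples
#' edit_op("del", at = 0, length = 7)
#' edit_op("ins", at = 0, seq = "A")
#' @export
edit_op <- function(kind = c("del", "ins", "sub"), at = 0L, length = NULL,
                    seq = "") {
  kind <- match.arg(kind)
  seq <- toupper(seq)
  if (kind == "del") {
    length <- length %||% 1L
    if (nzchar(seq)) stop("deletions carry no sequence", call. = FALSE)
  } else {
    if (!nzchar(seq) || grepl("[^ACGT]", seq))
      stop(kind, " requires a non-empty A/C/G/T seq", call. = FALSE)
    length <- length %||% nchar(seq)
    if (length != nchar(seq))
      stop("length must equal nchar(seq) for ", kind, call. = FALSE)
  }
  if (!is_count(length) || length < 1)
    stop("edit length must be >= 1", call. = FALSE)
  structure(list(kind = kind, at = as.integer(at), length = as.integer(length),
                 seq = seq), class = "edit_op")
}

#' Describe one allele of a nodule as a set of edits plus its fraction
#'
#' @param edits List of [edit_op()]s (empty list for the wild-type allele).
#'   Edits must not overlap.
#' @param fraction Proportion of the nodule's reads drawn from this allele.
#' @param id Allele label; defaults to `"WT"` for an empty edit list, else a
#'   signature-like label built from the edits.
#' @return An `allele_spec` list.
#' @export
allele_spec <- function(edits = list(), fraction = 1, id = NULL) {
  if (inherits(edits, "edit_op")) edits <- list(edits)
  stopifnot(all(vapply(edits, inherits, TRUE, "edit_op")))
  if (!is.numeric(fraction) || fraction < 0 || fraction > 1)
    stop("fraction must lie in [0, 1]", call. = FALSE)
  if (is.null(id))
    id <- if (!length(edits)) "WT" else
      paste(vapply(edits, function(e)
        sprintf("%s%+d:%d%s", e$kind, e$at, e$length,
                if (nzchar(e$seq)) paste0(":", e$seq) else ""),
        character(1)), collapse = ";")
  structure(list(edits = edits, fraction = fraction, id = id),
            class = "allele_spec")
}

#' Apply a set of edits to a reference amplicon
#'
#' @param ref_amplicon Reference DNA string.
#' @param cut_site 1-based index of the last base 5' of the cut.
#' @param edits List of [edit_op()]s; applied right-to-left so stated
#'   coordinates all refer to the unedited reference.
#' @return The edited sequence.
#' @export
apply_edits <- function(ref_amplicon, cut_site, edits) {
  seq <- check_dna_strict(ref_amplicon, "ref_amplicon")
  L <- nchar(seq)
  if (!is_count(cut_site) || cut_site < 1 || cut_site >= L)
    stop("cut_site must lie inside the amplicon", call. = FALSE)
  cut_site <- as.integer(cut_site)
  if (inherits(edits, "edit_op")) edits <- list(edits)
  if (!length(edits)) return(seq)
  starts <- vapply(edits, function(e)
    cut_site + e$at + if (e$kind == "ins") 0L else 1L, integer(1))
  for (i in order(starts, decreasing = TRUE)) {
    e <- edits[[i]]
    if (e$kind == "ins") {
      pos <- cut_site + e$at  # insert after this base
      if (pos < 0 || pos > L)
        stop("edit outside amplicon bounds", call. = FALSE)
      seq <- paste0(substring(seq, 1L, pos), e$seq, substring(seq, pos + 1L))
    } else {
      from <- cut_site + e$at + 1L
      to <- from + e$length - 1L
      if (from < 1 || to > L)
        stop("edit outside amplicon bounds", call. = FALSE)
      mid <- if (e$kind == "del") "" else e$seq
      seq <- paste0(substring(seq, 1L, from - 1L), mid, substring(seq, to + 1L))
    }
  }
  seq
}

#' Read-simulation configuration
#'
#' @param n_reads Reads per nodule (>= 1; the study sequenced about 10,000
#'   reads per sample).
#' @param read_length Read length in bp; `NULL` (default) sequences each
#'   allele's full edited amplicon.
#' @param substitution_error_rate,indel_error_rate Per-base error
#'   probabilities, each in \[0, 0.1\]. Substitution errors replace a base
#'   uniformly with one of the three alternatives; indel errors insert or
#'   delete a single base at a uniform position.
#' @param seed Integer seed.
#' @return A `read_sim_config` list.
#' @export
read_sim_config <- function(n_reads = 10000L, read_length = NULL,
                            substitution_error_rate = 0,
                            indel_error_rate = 0, seed = 1L) {
  if (!is_count(n_reads) || n_reads < 1)
    stop("n_reads must be >= 1", call. = FALSE)
  for (r in c(substitution_error_rate, indel_error_rate))
    if (!is.numeric(r) || r < 0 || r > 0.1)
      stop("error rates must lie in [0, 0.1]", call. = FALSE)
  structure(list(n_reads = as.integer(n_reads), read_length = read_length,
                 substitution_error_rate = substitution_error_rate,
                 indel_error_rate = indel_error_rate, seed = seed),
            class = "read_sim_config")
}

#' Simulate a mixed-allele amplicon read set with recorded truth
#'
#' Each read is drawn from one allele's edited sequence (a multinomial draw
#' over the allele fractions), then passed through the error model. The true
#' allele of every read is recorded in the `truth` table, and the realized
#' per-allele counts of the multinomial draw in `alleles$n_true`.
#'
#' @param ref_amplicon Reference amplicon sequence (around 200 bp in the
#'   study's assays).
#' @param cut_site 1-based index of the last base 5' of the Cas9 cut.
#' @param alleles List of [allele_spec()]s whose fractions sum to 1.
#' @param cfg A [read_sim_config()].
#' @return An `amplicon_sim` list: `reads` (named character vector),
#'   `truth` (data frame `read_id`, `allele_id`), `alleles` (data frame
#'   `allele_id`, `fraction`, `sequence`, `n_true`), `ref`, `cut_site`, `cfg`.
#' @examples
#' sim <- gen_amplicon_reads(strrep("ACGT", 25), 50,
#'   list(allele_spec(fraction = 0.5),
#'        allele_spec(edit_op("del", 0, 7), fraction = 0.5)),
#'   read_sim_config(n_reads = 100, seed = 3))
#' table(sim$truth$allele_id)
#' @export
gen_amplicon_reads <- function(ref_amplicon, cut_site, alleles,
                               cfg = read_sim_config()) {
  stopifnot(inherits(cfg, "read_sim_config"))
  if (inherits(alleles, "allele_spec")) alleles <- list(alleles)
  stopifnot(all(vapply(alleles, inherits, TRUE, "allele_spec")))
  fr <- vapply(alleles, `[[`, numeric(1), "fraction")
  if (abs(sum(fr) - 1) > 1e-9)
    stop("allele fractions must sum to 1", call. = FALSE)
  ids <- vapply(alleles, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("allele ids must be unique", call. = FALSE)
  ref <- check_dna_strict(ref_amplicon, "ref_amplicon")
  seqs <- setNames(vapply(alleles, function(a)
    apply_edits(ref, cut_site, a$edits), character(1)), ids)

  with_seed(cfg$seed, {
    assignment <- sample(ids, cfg$n_reads, replace = TRUE, prob = fr)
    reads <- unname(seqs[assignment])
    reads <- inject_errors(reads, cfg$substitution_error_rate,
                           cfg$indel_error_rate)
    if (!is.null(cfg$read_length))
      reads <- substring(reads, 1L, cfg$read_length)
    read_ids <- sprintf("read%06d", seq_len(cfg$n_reads))
    structure(list(
      reads = setNames(reads, read_ids),
      truth = data.frame(read_id = read_ids, allele_id = assignment,
                         stringsAsFactors = FALSE),
      alleles = data.frame(allele_id = ids, fraction = fr,
                           sequence = unname(seqs),
                           n_true = as.integer(table(factor(assignment,
                                                            levels = ids))),
                           stringsAsFactors = FALSE),
      ref = ref, cut_site = as.integer(cut_site), cfg = cfg),
      class = "amplicon_sim")
  })
}

#' @noRd
inject_errors <- function(reads, sub_rate, indel_rate) {
  n <- length(reads)
  if (sub_rate > 0) {
    k <- rbinom(n, nchar(reads), sub_rate)
    for (i in which(k > 0)) {
      ch <- strsplit(reads[i], "")[[1]]
      pos <- sample.int(length(ch), k[i])
      for (p in pos) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
      reads[i] <- paste(ch, collapse = "")
    }
  }
  if (indel_rate > 0) {
    k <- rbinom(n, nchar(reads), indel_rate)
    for (i in which(k > 0)) {
      for (ev in seq_len(k[i])) {
        L <- nchar(reads[i])
        p <- sample.int(L, 1L)
        if (runif(1) < 0.5 && L > 1) {  # 1-bp deletion
          reads[i] <- paste0(substring(reads[i], 1L, p - 1L),
                             substring(reads[i], p + 1L))
        } else {                        # 1-bp insertion after p
          reads[i] <- paste0(substring(reads[i], 1L, p),
                             sample(DNA_BASES, 1L),
                             substring(reads[i], p + 1L))
        }
      }
    }
  }
  reads
}

#' @export
print.amplicon_sim <- function(x, ...) {
  cat(sprintf("Simulated amplicon read set: %d reads, %d allele(s), cut site %d\n",
              length(x$reads), nrow(x$alleles), x$cut_site))
  print(x$alleles[, c("allele_id", "fraction", "n_true")])
  invisible(x)
}

#' Write simulated reads to FASTQ (Phred+33, fixed quality) plus truth TSV
#'
#' @param sim An `amplicon_sim` from [gen_amplicon_reads()].
#' @param dir Output directory.
#' @param name Base name for the files (`<name>.fastq`, `<name>.truth.tsv`).
#' @return Invisibly, the paths written.
#' @export
write_amplicon_sim <- function(sim, dir, name = "nodule") {
  stopifnot(inherits(sim, "amplicon_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fq <- file.path(dir, paste0(name, ".fastq"))
  tsv <- file.path(dir, paste0(name, ".truth.tsv"))
  dss <- Biostrings::DNAStringSet(sim$reads)
  quals <- Biostrings::BStringSet(vapply(nchar(sim$reads), strrep,
                                         character(1), x = "I"))
  Biostrings::writeXStringSet(dss, fq, format = "fastq", qualities = quals)
  utils::write.table(sim$truth, tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fastq = fq, truth = tsv))
}

#' Read an amplicon FASTQ into a named character vector
#'
#' @param path FASTQ file path.
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  dss <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(dss), sub("\\s.*$", "", names(dss)))
}
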