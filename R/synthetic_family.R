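# Simulators for NCR-like peptide families and zone-wise expression tables.
# These stand in for the published NCR catalogue and the laser-capture RNAseq
# expression table, which are not reproduced here; ground-truth labels are
# recorded so the selection funnel can be tested for exact recovery.

NODULE_ZONES <- c("IID", "IIP", "IZ", "ZIII")
HYDROPHOBIC_AA <- c("A", "L", "V", "I", "F", "M", "W")

#' Run code with a private, restored RNG state
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else if (exists(".Random.seed", globalenv(), inherits = FALSE))
              rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
  }
  force(code)
}

#' Generate a synthetic NCR-like peptide family with known ground truth
#'
#' Each generated gene encodes a peptide that optionally starts with a
#' synthetic signal peptide (15-25 residues, at least 70% drawn from the
#' hydrophobic set A/L/V/I/F/M/W — a generator convenience only; the analytic
#' modules never infer signal peptides, they read the annotation). The mature
#' peptide either contains exactly four cysteines in the conserved
#' C-X5-C-Xn-C-X4-C spacing (motif-positive) or is built to fail the motif
#' scan (wrong first gap, or fewer than four cysteines). The ground-truth
#' labels are stored alongside the sequences.
#'
#' @param n_genes Number of genes (>= 1).
#' @param frac_with_signal_peptide,frac_with_motif Fractions in \[0, 1\];
#'   exactly `round(frac * n_genes)` genes get the feature, chosen at random.
#' @param mature_length_range Two-element residue-count range for the mature
#'   peptide (minimum allowed is 20, enough to hold the motif).
#' @param seed Integer seed; the generator is a pure function of its
#'   arguments and the seed.
#' @return An object of class `ncr_family`: a list with `records` (data frame
#'   with `gene_id`, `full_peptide`, `has_signal_peptide`,
#'   `signal_cleavage_site`, `mature_peptide`, `has_motif`) and `spec`.
#' @examples
#' fam <- gen_ncr_family(5, frac_with_motif = 1, seed = 1)
#' fam$records$has_motif
#' @export
gen_ncr_family <- function(n_genes, frac_with_signal_peptide = 1,
                           frac_with_motif = 1,
                           mature_length_range = c(30L, 60L), seed = 1L) {
  if (!is_count(n_genes) || n_genes < 1)
    stop("n_genes must be a positive integer", call. = FALSE)
  for (f in c(frac_with_signal_peptide, frac_with_motif))
    if (!is.numeric(f) || length(f) != 1L || is.na(f) || f < 0 || f > 1)
      stop("fractions must lie in [0, 1]", call. = FALSE)
  rng <- as.integer(mature_length_range)
  if (length(rng) != 2L || rng[1] > rng[2] || rng[1] < 20L)
    stop("mature_length_range must be an increasing range with minimum >= 20",
         call. = FALSE)

  with_seed(seed, {
    n_sp <- round_half_up(frac_with_signal_peptide * n_genes)
    n_motif <- round_half_up(frac_with_motif * n_genes)
    sp_idx <- sample.int(n_genes, n_sp)
    motif_idx <- sample.int(n_genes, n_motif)
    has_sp <- seq_len(n_genes) %in% sp_idx
    has_motif <- seq_len(n_genes) %in% motif_idx

    records <- lapply(seq_len(n_genes), function(i) {
      mat <- gen_mature_peptide(sample(rng[1]:rng[2], 1L), has_motif[i])
      if (has_sp[i]) {
        sp <- gen_signal_peptide()
        data.frame(gene_id = sprintf("gene%04d", i),
                   full_peptide = paste0(sp, mat),
                   has_signal_peptide = TRUE,
                   signal_cleavage_site = nchar(sp),
                   mature_peptide = mat, has_motif = has_motif[i],
                   stringsAsFactors = FALSE)
      } else {
        data.frame(gene_id = sprintf("gene%04d", i), full_peptide = mat,
                   has_signal_peptide = FALSE,
                   signal_cleavage_site = NA_integer_,
                   mature_peptide = mat, has_motif = has_motif[i],
                   stringsAsFactors = FALSE)
      }
    })
    structure(list(records = do.call(rbind, records),
                   spec = list(n_genes = n_genes,
                               frac_with_signal_peptide = frac_with_signal_peptide,
                               frac_with_motif = frac_with_motif,
                               mature_length_range = rng, seed = seed)),
              class = "ncr_family")
  })
}

#' @noRd
gen_mature_peptide <- function(len, motif_positive) {
  non_cys <- setdiff(AA_ALPHABET, "C")
  draw <- function(k) paste(sample(non_cys, k, replace = TRUE), collapse = "")
  if (motif_positive) {
    gap1 <- 5L
  } else if (runif(1) < 0.5) {
    # exactly four cysteines, but a first gap that violates the motif
    gap1 <- sample(setdiff(0:10, 5L), 1L)
  } else {
    # too few cysteines to ever match
    body <- draw(len)
    k <- sample(0:2, 1L)
    if (k > 0) {
      pos <- sample(len, k)
      body <- strsplit(body, "")[[1]]
      body[pos] <- "C"
      body <- paste(body, collapse = "")
    }
    return(body)
  }
  core <- gap1 + 4L + 4L  # gaps 1 and 3 plus the four cysteines
  spare <- len - core - 1L  # gap2 takes at least 1
  gap2 <- 1L + sample.int(max(spare - 1L, 1L), 1L) - 1L
  spare <- spare - gap2 + 1L
  lead <- sample.int(spare + 1L, 1L) - 1L
  trail <- spare - lead
  paste0(draw(lead), "C", draw(gap1), "C", draw(gap2), "C", draw(4L), "C",
         draw(trail))
}

#' @noRd
gen_signal_peptide <- function() {
  len <- sample(15:25, 1L)
  n_hydro <- max(ceiling(0.7 * len), ceiling(runif(1, 0.7, 0.95) * len))
  aa <- sample(setdiff(AA_ALPHABET, c("C", HYDROPHOBIC_AA)), len,
               replace = TRUE)
  aa[sample(len, n_hydro)] <- sample(HYDROPHOBIC_AA, n_hydro, replace = TRUE)
  paste(aa, collapse = "")
}

#' @export
print.ncr_family <- function(x, ...) {
  cat(sprintf("Synthetic NCR-like family: %d genes (%d signal peptide, %d motif), seed %s\n",
              nrow(x$records), sum(x$records$has_signal_peptide),
              sum(x$records$has_motif), format(x$spec$seed)))
  invisible(x)
}

#' Write a synthetic family to FASTA + annotation TSV
#'
#' @param family An `ncr_family` from [gen_ncr_family()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written (`peptides.fa`, `annotation.tsv`).
#' @export
write_family <- function(family, dir) {
  stopifnot(inherits(family, "ncr_family"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "peptides.fa")
  tsv <- file.path(dir, "annotation.tsv")
  seqs <- Biostrings::AAStringSet(setNames(family$records$full_peptide,
                                           family$records$gene_id))
  Biostrings::writeXStringSet(seqs, fa)
  utils::write.table(family$records[, c("gene_id", "has_signal_peptide",
                                        "signal_cleavage_site", "has_motif")],
                     tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fa, annotation = tsv))
}

#' Generate a zone-wise nodule expression table
#'
#' Emulates a laser-capture-microdissection RNAseq table over the four nodule
#' zones (IID and IIP, distal and proximal infection zone; IZ, interzone;
#' ZIII, nitrogen-fixation zone). Counts are negative-binomial around each
#' gene's per-zone mean; `total_reads` is the row sum.
#'
#' @param records An `ncr_family`, or a data frame with a `gene_id` column,
#'   or a character vector of gene ids.
#' @param zone_profiles Named list of expression profiles; each profile is a
#'   named numeric vector of per-zone mean counts over exactly the zones
#'   IID, IIP, IZ, ZIII. Unknown zone labels are a configuration error.
#' @param profiles Character vector assigning one profile label per gene
#'   (recycled if length 1; defaults to the first profile).
#' @param dispersion Negative-binomial size parameter (default 5).
#' @param seed Integer seed.
#' @return Data frame with `gene_id`, one count column per zone, and
#'   `total_reads`.
#' @examples
#' zp <- list(high = c(IID = 5e3, IIP = 1e4, IZ = 2e4, ZIII = 15e3))
#' gen_expression_table(c("g1", "g2"), zp, seed = 1)
#' @export
gen_expression_table <- function(records, zone_profiles,
                                 profiles = NULL, dispersion = 5,
                                 seed = 1L) {
  gene_ids <- if (inherits(records, "ncr_family")) records$records$gene_id
    else if (is.data.frame(records)) records$gene_id
    else as.character(records)
  if (!length(gene_ids)) stop("no gene ids supplied", call. = FALSE)
  if (!is.list(zone_profiles) || is.null(names(zone_profiles)))
    stop("zone_profiles must be a named list of per-zone mean vectors",
         call. = FALSE)
  for (nm in names(zone_profiles)) {
    zp <- zone_profiles[[nm]]
    if (!setequal(names(zp), NODULE_ZONES))
      stop("unknown zone label in profile '", nm, "': zones must be ",
           paste(NODULE_ZONES, collapse = ", "), call. = FALSE)
    if (any(zp < 0)) stop("zone means must be non-negative", call. = FALSE)
  }
  profiles <- profiles %||% names(zone_profiles)[1]
  profiles <- rep_len(as.character(profiles), length(gene_ids))
  if (!all(profiles %in% names(zone_profiles)))
    stop("profiles must name entries of zone_profiles", call. = FALSE)

  with_seed(seed, {
    counts <- t(vapply(profiles, function(p) {
      mu <- zone_profiles[[p]][NODULE_ZONES]
      vapply(mu, function(m)
        if (m == 0) 0L else as.integer(rnbinom(1L, mu = m, size = dispersion)),
        integer(1))
    }, integer(length(NODULE_ZONES))))
    tab <- data.frame(gene_id = gene_ids, counts, row.names = NULL,
                      stringsAsFactors = FALSE)
    names(tab)[-1] <- NODULE_ZONES
    tab$total_reads <- rowSums(tab[, NODULE_ZONES])
    tab
  })
}
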