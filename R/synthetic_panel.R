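# Whole-study simulation: a panel of nodules with randomized allele mixtures
# spanning the genotype classes observed in edited hairy-root nodules
# (pure wild type, chimeric mixtures, mutant-majority, and fully mutant
# nodules with or without substitution alleles), plus the recovery driver
# that runs the genotyper over the panel and scores it against the truth.

#' Simulate a panel of nodules with randomized allele mixtures
#'
#' Each nodule gets its own random amplicon and a mixture design drawn from
#' the five genotype classes. Wild-type fractions are drawn well inside each
#' class's thresholds (fully mutant <= 0.03, mutant-majority 0.15-0.45,
#' chimeric 0.6-0.9) and every mutant allele is given at least 5% of the
#' reads, mirroring the handful-of-alleles structure seen in per-nodule
#' amplicon pies. The intended genotype of each nodule is computed from the
#' *realized* multinomial draw (not the nominal fractions) with the standard
#' classification thresholds.
#'
#' @param n_nodules Number of nodules (default 100).
#' @param n_reads Reads per nodule (default 5,000).
#' @param amplicon_length,cut_site,quantification_window Amplicon geometry
#'   (defaults 200 bp with the cut at base 100, window +/- 10).
#' @param substitution_error_rate,indel_error_rate Per-base error rates
#'   (defaults 0.001 each).
#' @param seed Integer seed.
#' @return A `nodule_panel`: list of per-nodule entries, each with `sim`
#'   (an `amplicon_sim`), `ref` (an [amplicon_ref()]), `intended_class`,
#'   `design` and `truth_fractions` (realized fraction per allele id).
#' @export
gen_nodule_panel <- function(n_nodules = 100L, n_reads = 5000L,
                             amplicon_length = 200L, cut_site = 100L,
                             quantification_window = 10L,
                             substitution_error_rate = 0.001,
                             indel_error_rate = 0.001, seed = 1L) {
  classes <- c("wild_type", "heterozygous_chimeric", "mutant_majority",
               "fully_mutant_indel_only", "fully_mutant_with_mismatch")
  with_seed(seed, {
    panel <- lapply(seq_len(n_nodules), function(i) {
      ref_seq <- paste(sample(DNA_BASES, amplicon_length, TRUE),
                       collapse = "")
      design <- sample(classes, 1L)
      alleles <- draw_nodule_design(design, ref_seq, cut_site)
      sim <- gen_amplicon_reads(
        ref_seq, cut_site, alleles,
        read_sim_config(n_reads = n_reads,
                        substitution_error_rate = substitution_error_rate,
                        indel_error_rate = indel_error_rate,
                        seed = sample.int(.Machine$integer.max, 1L)))
      truth_frac <- setNames(sim$alleles$n_true / sum(sim$alleles$n_true),
                             sim$alleles$allele_id)
      kinds <- vapply(alleles, allele_kind, character(1))
      names(kinds) <- sim$alleles$allele_id
      list(sim = sim,
           ref = amplicon_ref(ref_seq, cut_site, quantification_window),
           design = design,
           intended_class = intended_class(truth_frac, kinds),
           truth_fractions = truth_frac)
    })
    structure(panel, class = "nodule_panel")
  })
}

#' @noRd
allele_kind <- function(a) {
  if (!length(a$edits)) return("WT")
  if (any(vapply(a$edits, `[[`, "", "kind") %in% c("del", "ins"))) "indel"
  else "mismatch_only"
}

#' Intended genotype from realized fractions, standard threshold cascade
#' @noRd
intended_class <- function(fracs, kinds,
                           th = classification_thresholds()) {
  wt <- sum(fracs[kinds == "WT"])
  mut <- fracs[kinds != "WT" & fracs >= th$min_allele_frequency]
  mut_kinds <- kinds[names(mut)]
  if (wt <= th$wt_max_for_fully_mutant && length(mut)) {
    if (all(mut_kinds == "indel")) "fully_mutant_indel_only"
    else "fully_mutant_with_mismatch"
  } else if (wt <= th$wt_max_for_mutant_majority && length(mut))
    "mutant_majority"
  else if (length(mut)) "heterozygous_chimeric"
  else "wild_type"
}

#' Random allele mixture for one design class
#' @noRd
draw_nodule_design <- function(design, ref_seq, cut_site) {
  rand_indel <- function() {
    if (runif(1) < 0.6)
      edit_op("del", at = sample(-3:3, 1), length = sample(1:10, 1))
    else
      edit_op("ins", at = sample(-3:3, 1),
              seq = paste(sample(DNA_BASES, sample(1:3, 1), TRUE),
                          collapse = ""))
  }
  rand_sub <- function() {
    at <- sample(-5:5, 1)
    len <- sample(1:2, 1)
    from <- cut_site + at + 1L
    orig <- strsplit(substring(ref_seq, from, from + len - 1L), "")[[1]]
    alt <- vapply(orig, function(b) sample(setdiff(DNA_BASES, b), 1L), "")
    edit_op("sub", at = at, seq = paste(alt, collapse = ""))
  }
  distinct <- function(makers, fracs) {
    repeat {
      al <- Map(function(mk, f) allele_spec(mk(), fraction = f),
                makers, fracs)
      if (!anyDuplicated(vapply(al, `[[`, "", "id"))) return(al)
    }
  }
  split2 <- function(total) {  # one or two mutant alleles, each >= 0.05
    if (total >= 0.15 && runif(1) < 0.5) {
      a <- runif(1, 0.05, total - 0.05); c(a, total - a)
    } else total
  }
  switch(design,
    wild_type = list(allele_spec(fraction = 1)),
    heterozygous_chimeric = {
      wt <- runif(1, 0.6, 0.9)
      f <- split2(1 - wt)
      c(list(allele_spec(fraction = wt)),
        distinct(rep(list(rand_indel), length(f)), f))
    },
    mutant_majority = {
      wt <- runif(1, 0.15, 0.45)
      f <- split2(1 - wt)
      c(list(allele_spec(fraction = wt)),
        distinct(rep(list(rand_indel), length(f)), f))
    },
    fully_mutant_indel_only = {
      wt <- sample(c(0, runif(1, 0.005, 0.03)), 1L)
      f <- split2(1 - wt)
      al <- distinct(rep(list(rand_indel), length(f)), f)
      if (wt > 0) c(list(allele_spec(fraction = wt)), al) else al
    },
    fully_mutant_with_mismatch = {
      wt <- sample(c(0, runif(1, 0.005, 0.03)), 1L)
      rest <- 1 - wt
      sub_f <- runif(1, 0.1, rest - 0.1)
      al <- c(distinct(list(rand_sub), sub_f),
              distinct(list(rand_indel), rest - sub_f))
      if (wt > 0) c(list(allele_spec(fraction = wt)), al) else al
    },
    stop("unknown design ", design))
}

#' Run the genotyper over a simulated nodule panel and score recovery
#'
#' For every nodule the reads are aligned, collapsed into an allele table and
#' classified; the called genotype is compared with the intended genotype,
#' and measured allele frequencies are compared with the realized truth.
#' Frequencies are compared after renormalizing over the true alleles'
#' signatures: sequencing errors deplete every allele by the same expected
#' factor, and the relative allele ratios are the quantity the per-nodule
#' read pies report.
#'
#' @param panel A `nodule_panel` from [gen_nodule_panel()].
#' @param thresholds A [classification_thresholds()].
#' @param params An [align_params()].
#' @return A list: `results` (data frame `nodule`, `design`, `intended`,
#'   `called`, `wt_fraction`, `correct`), `accuracy`, `freq_rmse`,
#'   `freq_errors` (per-allele vector).
#' @export
recover_nodule_panel <- function(panel,
                                 thresholds = classification_thresholds(),
                                 params = align_params()) {
  stopifnot(inherits(panel, "nodule_panel"))
  rows <- vector("list", length(panel))
  errs <- numeric(0)
  for (i in seq_along(panel)) {
    nod <- panel[[i]]
    tab <- build_allele_table(nod$sim$reads, nod$ref, thresholds, params,
                              nodule_id = sprintf("nodule%03d", i))
    geno <- classify_nodule(tab, thresholds)

    # map each true allele to its called signature via its pure sequence
    sig_of <- vapply(nod$sim$alleles$sequence, function(s)
      call_allele(align_read(s, nod$ref, params), nod$ref)$signature,
      character(1), USE.NAMES = FALSE)
    truth_by_sig <- tapply(nod$truth_fractions[nod$sim$alleles$allele_id],
                           sig_of, sum)
    meas <- tab$alleles$frequency[match(names(truth_by_sig),
                                        tab$alleles$signature)]
    meas[is.na(meas)] <- 0
    if (sum(meas) > 0) meas <- meas / sum(meas)
    errs <- c(errs, meas - as.numeric(truth_by_sig))

    rows[[i]] <- data.frame(
      nodule = i, design = nod$design, intended = nod$intended_class,
      called = geno$class, wt_fraction = geno$wt_fraction,
      correct = geno$class == nod$intended_class,
      stringsAsFactors = FALSE)
  }
  results <- do.call(rbind, rows)
  list(results = results,
       accuracy = mean(results$correct),
       freq_rmse = sqrt(mean(errs^2)),
       freq_errors = errs)
}

#' @export
print.nodule_panel <- function(x, ...) {
  cat(sprintf("Simulated nodule panel: %d nodules x %d reads\n", length(x),
              length(x[[1]]$sim$reads)))
  print(table(vapply(x, `[[`, "", "intended_class")))
  invisible(x)
}
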