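# Alignment, allele calling, allele tables, nodule classification,
# consequence prediction and the editing-efficiency summary.

test_that("alignment of exact and edited reads behaves as expected", {
  ref <- make_ref_unambiguous(200, 100, seed = 41)
  a <- align_read(ref$sequence, ref)
  expect_equal(a$score, 2 * 200)
  expect_false(grepl("-", a$aligned_read))
  expect_false(a$discard)

  del7 <- apply_edits(ref$sequence, 100, edit_op("del", 0, 7))
  ad <- align_read(del7, ref)
  expect_equal(ad$score, 2 * 193 - (8 + 7))
  sig <- call_allele(ad, ref)
  expect_equal(sig$signature, "del+0:7")
  expect_equal(sig$net_indel, -7L)
  expect_equal(sig$classification, "indel")

  expect_error(align_read("", ref), "empty")
  junk <- align_read(strrep("T", 200), ref)
  expect_true(junk$identity < 0.6 || !junk$discard)  # consistency
})

test_that("alignment scores equal the Gotoh DP oracle on short random pairs", {
  set.seed(42)
  for (i in 1:200) {
    n1 <- sample(5:30, 1); n2 <- sample(5:30, 1)
    a <- random_dna(n1); b <- random_dna(n2)
    ref <- amplicon_ref(b, max(1, n2 %/% 2), quantification_window = 0)
    got <- align_read(a, ref)$score
    expect_equal(got, align_score_oracle(a, b), info = paste(a, b))
  }
})

test_that("allele calling respects the quantification window and merges ops", {
  ref <- make_ref_unambiguous(200, 100, window = 10, seed = 43)
  # substitution 30 bp from the cut is outside the window -> WT
  far <- apply_edits(ref$sequence, 100, edit_op("sub", 30, seq =
    flip_base(substring(ref$sequence, 131, 131))))
  expect_equal(call_allele(align_read(far, ref), ref)$signature, "WT")
  # the same substitution 2 bp from the cut is kept
  near_base <- flip_base(substring(ref$sequence, 103, 103))
  near <- apply_edits(ref$sequence, 100, edit_op("sub", 2, seq = near_base))
  sig <- call_allele(align_read(near, ref), ref)
  expect_equal(sig$signature, paste0("sub+2:1:", near_base))
  expect_equal(sig$classification, "mismatch_only")
  expect_equal(sig$net_indel, 0L)

  # 1-bp insertion at the cut: signature (ins, 0, 1, base)
  ins <- apply_edits(ref$sequence, 100, edit_op("ins", 0, seq = "G"))
  isig <- call_allele(align_read(ins, ref), ref)
  expect_equal(isig$ops$kind, "ins")
  expect_equal(isig$ops$offset, 0L)
  expect_equal(isig$ops$length, 1L)
  expect_equal(isig$net_indel, 1L)

  # two reads differing only outside the window collapse to one allele
  r1 <- apply_edits(ref$sequence, 100, edit_op("del", -2, 4))
  r2 <- apply_edits(r1, 100, edit_op("sub", 40, seq =
    flip_base(substring(r1, 141, 141))))
  tab <- build_allele_table(c(r1, r2, r1, r2), ref)
  expect_equal(nrow(tab$alleles), 1)
  expect_equal(tab$alleles$frequency, 1)
})

test_that("allele tables are conservative and frequencies normalized", {
  set.seed(44)
  ref <- make_ref(200, 100)
  reads <- rep(ref$sequence, 100)
  tab <- build_allele_table(reads, ref)
  expect_equal(nrow(tab$alleles), 1)
  expect_equal(tab$alleles$signature, "WT")
  expect_equal(tab$alleles$frequency, 1.0)

  sim <- gen_amplicon_reads(ref$sequence, 100,
    list(allele_spec(fraction = 0.3),
         allele_spec(edit_op("del", 0, 7), fraction = 0.4),
         allele_spec(edit_op("ins", 0, seq = "A"), fraction = 0.3)),
    read_sim_config(n_reads = 10000, substitution_error_rate = 0.001,
                    seed = 45))
  tab <- build_allele_table(sim$reads, ref)
  expect_equal(tab$total_reads + tab$discarded_reads, tab$input_reads)
  expect_equal(sum(tab$alleles$frequency), 1, tolerance = 1e-9)
  truth_frac <- sim$alleles$n_true / sum(sim$alleles$n_true)
  sig_of <- vapply(sim$alleles$sequence, function(s)
    call_allele(align_read(s, ref), ref)$signature, character(1))
  got <- tab$alleles$frequency[match(sig_of, tab$alleles$signature)]
  expect_true(all(abs(got - truth_frac) < 0.02))
  # sorted by frequency
  expect_true(!is.unsorted(rev(tab$alleles$frequency)))
  expect_error(build_allele_table(character(0), ref), "no reads")
})

test_that("nodule classification follows the threshold cascade", {
  mk_table <- function(freqs) {
    # freqs: named vector signature -> frequency, "WT" special
    cls <- ifelse(names(freqs) == "WT", "WT",
                  ifelse(grepl("sub", names(freqs)), "mismatch_only",
                         "indel"))
    structure(list(nodule_id = "n", alleles = data.frame(
      signature = names(freqs), classification = cls,
      net_indel = 0L, reads = as.integer(freqs * 1000),
      frequency = as.numeric(freqs), stringsAsFactors = FALSE),
      total_reads = 1000L, discarded_reads = 0L, input_reads = 1000L,
      thresholds = classification_thresholds()), class = "allele_table")
  }
  expect_equal(classify_nodule(mk_table(c(WT = 1.0)))$class, "wild_type")
  expect_equal(classify_nodule(mk_table(
    c(WT = 0.02, "del+0:7" = 0.49, "ins+0:1:A" = 0.49)))$class,
    "fully_mutant_indel_only")
  expect_equal(classify_nodule(mk_table(
    c(WT = 0.02, "del+0:7" = 0.49, "sub+1:1:T" = 0.49)))$class,
    "fully_mutant_with_mismatch")
  expect_equal(classify_nodule(mk_table(
    c(WT = 0.45, "del+0:4" = 0.55)))$class, "mutant_majority")
  expect_equal(classify_nodule(mk_table(
    c(WT = 0.60, "del+0:4" = 0.40)))$class, "heterozygous_chimeric")
  # boundary: exactly 50% WT counts as mutant-majority (inclusive)
  expect_equal(classify_nodule(mk_table(
    c(WT = 0.50, "del+0:4" = 0.50)))$class, "mutant_majority")
  g <- classify_nodule(mk_table(c(WT = 1.0)),
                       phenotype_label = "pink_elongated")
  expect_equal(g$phenotype_label, "pink_elongated")
  expect_equal(g$wt_fraction, 1.0)
})

test_that("consequence prediction matches the translate-and-diff oracle", {
  set.seed(46)
  code_ok <- function(cds) !grepl("TAA|TAG|TGA",
                                  substring(cds, 1, nchar(cds) - 3))
  for (i in 1:60) {
    # random CDS: ATG + 30-60 non-stop codons + TAA
    repeat {
      n_codons <- sample(30:60, 1)
      body <- paste(replicate(n_codons, random_codon()), collapse = "")
      cds <- paste0("ATG", body, "TAA")
      if (code_ok(cds)) break
    }
    cut <- sample(10:(nchar(cds) - 15), 1)
    kind <- sample(c("del", "ins", "sub"), 1)
    len <- sample(1:6, 1)
    op <- switch(kind,
      del = edit_op("del", 0, len),
      ins = edit_op("ins", 0, seq = random_dna(len)),
      sub = edit_op("sub", 0, seq = random_dna(len)))
    rep_ <- predict_consequence(cds, list(op), protein_annotation(cut))
    net <- switch(kind, del = -len, ins = len, sub = 0L)
    expect_identical(rep_$frameshift, net %% 3L != 0L)

    # oracle: independent CDS surgery + codon-loop translation + diff
    mut_cds <- switch(kind,
      del = edit_cds_oracle(cds, "del", cut + 1, len),
      ins = edit_cds_oracle(cds, "ins", cut, len, op$seq),
      sub = edit_cds_oracle(cds, "sub", cut + 1, len, op$seq))
    wt_o <- translate_oracle(cds); mut_o <- translate_oracle(mut_cds)
    d <- diff_proteins_oracle(wt_o$protein, mut_o$protein)
    expect_identical(rep_$identical_residues_before_divergence, d$prefix)
    expect_identical(rep_$novel_residues_before_stop, d$novel)
    expect_identical(rep_$stop_position, mut_o$stop_position)

    # lost conserved cysteines: survive iff inside common prefix or suffix
    cys <- which(strsplit(wt_o$protein, "")[[1]] == "C")
    if (length(cys)) {
      annot <- protein_annotation(cut, conserved_cys = cys)
      rep2 <- predict_consequence(cds, list(op), annot)
      nw <- nchar(wt_o$protein)
      want_lost <- cys[cys > d$prefix & cys <= nw - d$suffix]
      expect_identical(rep2$lost_conserved_cys, as.integer(want_lost))
    }
  }
})

test_that("a 3-bp in-frame deletion removes one residue; WT is silent; start loss is flagged", {
  cds <- paste0("ATG", strrep("GAA", 20), "TGTTAA")
  # deletion of one GAA codon at the cut after base 30
  rep_ <- predict_consequence(cds, list(edit_op("del", 0, 3)),
                              protein_annotation(30, signal_end = 1))
  expect_false(rep_$frameshift)
  expect_equal(nrow(rep_$inframe_deleted_residues), 1)
  expect_equal(rep_$inframe_deleted_residues$residue, "E")

  wt <- predict_consequence(cds, list(), protein_annotation(30))
  expect_false(wt$frameshift)
  expect_equal(wt$novel_residues_before_stop, 0L)
  expect_equal(wt$mutant_protein, wt$wt_protein)

  start <- predict_consequence(cds, list(edit_op("del", -29, 3)),
                               protein_annotation(30))
  expect_true(start$start_lost)
})

test_that("editing summary reproduces count-based percentages with half-up rounding", {
  mk <- function(construct, indel_only, with_mis, majority, chimera = 0,
                 wildtype = 0, pheno = "unscored") {
    cls <- c(rep("fully_mutant_indel_only", indel_only),
             rep("fully_mutant_with_mismatch", with_mis),
             rep("mutant_majority", majority),
             rep("heterozygous_chimeric", chimera),
             rep("wild_type", wildtype))
    wt <- c(rep(0.01, indel_only + with_mis), rep(0.45, majority),
            rep(0.7, chimera), rep(1, wildtype))
    data.frame(construct = construct, class = cls, wt_fraction = wt,
               phenotype_label = pheno, stringsAsFactors = FALSE)
  }
  g <- rbind(mk("NCR068", 7, 7, 1),
             mk("NCR089", 13, 0, 0),
             mk("NCR128", 9, 0, 1),
             mk("NCR161", 12, 0, 7, 1))
  s <- summarize_editing(g)
  expect_equal(s$pct_indel_only[s$construct == "NCR068"], 47L)  # 7/15
  expect_equal(s$pct_indel_only[s$construct == "NCR089"], 100L)
  expect_equal(s$pct_indel_only[s$construct == "NCR128"], 90L)
  expect_equal(s$pct_indel_only[s$construct == "NCR161"], 60L)
  expect_equal(s$n_sequenced[s$construct == "NCR161"], 20L)
  expect_equal(s$n_wt_le_max[s$construct == "NCR161"], 19L)

  # phenotype split within one construct
  g169 <- rbind(mk("NCR169", 3, 0, 0, pheno = "white_undeveloped"),
                mk("NCR169", 0, 0, 1, 1, 1, pheno = "pink_elongated"))
  s169 <- summarize_editing(g169)
  expect_equal(nrow(s169), 2)
  expect_equal(s169$pct_indel_only[s169$phenotype == "white_undeveloped"],
               100L)
  expect_equal(s169$pct_indel_only[s169$phenotype == "pink_elongated"], 0L)
  expect_warning(summarize_editing(g[0, ]), "empty")
})
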