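# The simulators must be deterministic in their seed and their recorded
# ground truth must agree with the analytic modules at zero noise.

test_that("family generation is deterministic and labels match the scanner", {
  fam1 <- gen_ncr_family(30, frac_with_signal_peptide = 0.7,
                         frac_with_motif = 0.5, seed = 42)
  fam2 <- gen_ncr_family(30, frac_with_signal_peptide = 0.7,
                         frac_with_motif = 0.5, seed = 42)
  expect_identical(fam1$records, fam2$records)

  d1 <- tempfile(); d2 <- tempfile()
  write_family(fam1, d1); write_family(fam2, d2)
  expect_identical(readBin(file.path(d1, "peptides.fa"), "raw", 1e6),
                   readBin(file.path(d2, "peptides.fa"), "raw", 1e6))

  # generator labels vs the independent motif scanner
  scanned <- vapply(fam1$records$mature_peptide,
                    function(p) scan_cys_motif(p)$match, TRUE,
                    USE.NAMES = FALSE)
  expect_identical(scanned, fam1$records$has_motif)
  expect_equal(sum(fam1$records$has_motif), 15)

  # motif-positive mature peptides carry exactly four cysteines
  ncys <- nchar(gsub("[^C]", "", fam1$records$mature_peptide))
  expect_true(all(ncys[fam1$records$has_motif] == 4))

  # full peptide = signal + mature for annotated records
  sp <- fam1$records[fam1$records$has_signal_peptide, ]
  expect_true(all(substring(sp$full_peptide,
                            sp$signal_cleavage_site + 1) == sp$mature_peptide))
  expect_error(gen_ncr_family(10, frac_with_motif = 1.5), "fraction")
})

test_that("scanner-positive count equals the generated ground-truth count at scale", {
  fam <- gen_ncr_family(200, frac_with_signal_peptide = 1,
                        frac_with_motif = 0.5, seed = 7)
  scanned <- sum(vapply(fam$records$mature_peptide,
                        function(p) scan_cys_motif(p)$match, TRUE))
  expect_equal(scanned, sum(fam$records$has_motif))
  expect_equal(scanned, 100)
})

test_that("expression tables honour zone profiles, zero case and the seed", {
  zp <- list(high = c(IID = 5e3, IIP = 1e4, IZ = 2e4, ZIII = 15e3),
             zero = c(IID = 0, IIP = 0, IZ = 0, ZIII = 0))
  tab <- gen_expression_table(c("g1", "g2"), zp,
                              profiles = c("high", "zero"), seed = 3)
  expect_equal(tab$total_reads, rowSums(tab[, c("IID", "IIP", "IZ", "ZIII")]))
  expect_equal(tab$total_reads[2], 0)  # pseudogene-like
  expect_true(all(tab[, c("IID", "IIP", "IZ", "ZIII")] >= 0))
  tab2 <- gen_expression_table(c("g1", "g2"), zp,
                               profiles = c("high", "zero"), seed = 3)
  expect_identical(tab, tab2)
  expect_error(
    gen_expression_table("g1", list(bad = c(IID = 1, IIP = 1, IZ = 1,
                                            weird = 1))),
    "zone")
})

test_that("a high-expression profile clears the read threshold across seeds", {
  zp <- list(high = c(IID = 5e3, IIP = 1e4, IZ = 2e4, ZIII = 15e3))
  totals <- vapply(1:100, function(s)
    gen_expression_table("g", zp, seed = s)$total_reads, numeric(1))
  # negative binomial with mu 50,000 and size 5 essentially never drops
  # below 10,000 (that is ~4.7 sd below the mean on the log scale)
  expect_true(all(totals > 10000))
})

test_that("read simulation records an exact multinomial truth table", {
  ref <- random_dna(200)
  alleles <- list(allele_spec(fraction = 0.5),
                  allele_spec(edit_op("del", 0, 7), fraction = 0.5))
  sim <- gen_amplicon_reads(ref, 100, alleles,
                            read_sim_config(n_reads = 10000, seed = 5))
  expect_length(sim$reads, 10000)
  expect_equal(sum(sim$alleles$n_true), 10000)
  expect_identical(as.integer(table(sim$truth$allele_id)[sim$alleles$allele_id]),
                   sim$alleles$n_true)
  # zero error: every read is exactly its allele's edited sequence
  expect_identical(unname(sim$reads),
                   unname(sim$alleles$sequence[
                     match(sim$truth$allele_id, sim$alleles$allele_id)]))
  # about half the reads from each allele
  expect_gt(min(sim$alleles$n_true), 4700)

  sim2 <- gen_amplicon_reads(ref, 100, alleles,
                             read_sim_config(n_reads = 10000, seed = 5))
  expect_identical(sim$reads, sim2$reads)

  wt_only <- gen_amplicon_reads(ref, 100, list(allele_spec(fraction = 1)),
                                read_sim_config(n_reads = 50, seed = 1))
  expect_true(all(wt_only$reads == ref))
  expect_error(
    gen_amplicon_reads(ref, 100, list(allele_spec(fraction = 0.7))),
    "sum to 1")
  expect_error(
    gen_amplicon_reads(ref, 195,
                       list(allele_spec(edit_op("del", 0, 20), 1))),
    "bounds")
})

test_that("a pure 1-bp insertion allele is recovered end to end at low error", {
  ref <- make_ref_unambiguous(200, 100, seed = 9)
  sim <- gen_amplicon_reads(ref$sequence, 100,
                            list(allele_spec(edit_op("ins", 0, seq = "G"),
                                             fraction = 1)),
                            read_sim_config(n_reads = 2000,
                                            substitution_error_rate = 0.001,
                                            seed = 9))
  tab <- build_allele_table(sim$reads, ref)
  expect_equal(tab$alleles$signature[1], "ins+0:1:G")
  # per-read recovery: the genotyper sees the insertion in >= 99% of reads
  counts <- table(sim$reads)
  alns <- align_reads(names(counts), ref)
  has_ins <- vapply(alns, function(a) {
    ops <- call_allele(a, ref)$ops
    any(ops$kind == "ins" & ops$offset == 0L & ops$length == 1L)
  }, TRUE)
  expect_gte(sum(counts[has_ins]) / sum(counts), 0.99)
})

test_that("trace generation is deterministic and exact at zero noise", {
  seq <- random_dna(240)
  tp <- gen_trace(seq, data.frame(shift = 0, fraction = 1))
  expect_identical(tp$edited, tp$control)  # single unshifted component
  expect_true(all(as.matrix(tp$control[, c("A","C","G","T")]) >= 0))
  # channel of the called base carries the peak
  base_idx <- match(strsplit(seq, "")[[1]], c("A","C","G","T"))
  m <- as.matrix(tp$control[, c("A","C","G","T")])
  expect_true(all(m[cbind(seq_len(240), base_idx)] == 100))

  tp1 <- gen_trace(seq, data.frame(shift = c(0, -7), fraction = c(.6, .4)),
                   noise_sd = 2, seed = 11)
  tp2 <- gen_trace(seq, data.frame(shift = c(0, -7), fraction = c(.6, .4)),
                   noise_sd = 2, seed = 11)
  expect_identical(tp1$edited, tp2$edited)
  expect_true(all(tp1$edited[, c("A","C","G","T")] >= 0))
  expect_error(gen_trace(seq, data.frame(shift = 0, fraction = 0.9)),
               "sum to 1")
  expect_error(gen_trace(seq, data.frame(shift = 40, fraction = 1)),
               "max_shift")
})

test_that("fastq round trip preserves reads and ids", {
  ref <- random_dna(120)
  sim <- gen_amplicon_reads(ref, 60, list(allele_spec(fraction = 1)),
                            read_sim_config(n_reads = 25, seed = 2))
  d <- tempfile()
  paths <- write_amplicon_sim(sim, d, name = "nod1")
  back <- read_fastq(paths[["fastq"]])
  expect_identical(back, sim$reads)
  truth <- read.delim(paths[["truth"]], stringsAsFactors = FALSE)
  expect_identical(truth, sim$truth)
})
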