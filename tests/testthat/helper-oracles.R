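# Independent oracles used across the suite. Each deliberately re-derives the
# quantity with a different method than the package (regex vs combinatorial
# scan, grid scan vs bisection, plain DP vs library alignment, codon loop vs
# translate()), so agreement is informative.

AA20 <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R",
          "S","T","V","W","Y")
BASES <- c("A", "C", "G", "T")

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE),
                                collapse = "")

# peptides with elevated cysteine content so the motif scan is exercised
random_peptide <- function(n, cys_prob = 0.15) {
  w <- rep((1 - cys_prob) / 19, 20)
  w[AA20 == "C"] <- cys_prob
  paste(sample(AA20, n, replace = TRUE, prob = w), collapse = "")
}

# ---- motif oracle: pure regex ------------------------------------------
motif_oracle <- function(pep, require_exact_four = TRUE) {
  if (require_exact_four &&
      nchar(gsub("[^C]", "", pep)) != 4L) return(FALSE)
  grepl("C.{5}C.+C.{4}C", pep)
}

# ---- pI oracle: dense pH-grid scan -------------------------------------
# precomputed contribution of one copy of each ionizable group at each pH
PI_GRID <- seq(0, 14, by = 5e-4)
pi_grid_matrix <- local({
  pka <- editscan::pka_table()
  pos <- c(Nterm = pka$nterm, pka$sidechain[c("K", "R", "H")])
  neg <- c(Cterm = pka$cterm, pka$sidechain[c("D", "E", "C", "Y")])
  cbind(
    vapply(pos, function(k) 1 / (1 + 10^(PI_GRID - k)),
           numeric(length(PI_GRID))),
    vapply(neg, function(k) -1 / (1 + 10^(k - PI_GRID)),
           numeric(length(PI_GRID))))
})
pi_oracle <- function(pep) {
  aa <- strsplit(pep, "")[[1]]
  counts <- c(1, sum(aa == "K"), sum(aa == "R"), sum(aa == "H"),
              1, sum(aa == "D"), sum(aa == "E"), sum(aa == "C"),
              sum(aa == "Y"))
  charge <- as.vector(pi_grid_matrix %*% counts)
  PI_GRID[which.min(abs(charge))]
}

# ---- alignment oracle: Gotoh affine-gap DP in plain R ------------------
# gap of length L costs open + L * ext; score = max over the three states
align_score_oracle <- function(a, b, match = 2, mismatch = -3,
                               open = 8, ext = 1) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  Ix <- matrix(NEG, n + 1, m + 1)  # gap in b (x aligned to '-')
  Iy <- matrix(NEG, n + 1, m + 1)  # gap in a
  M[1, 1] <- 0
  for (i in seq_len(n)) Ix[i + 1, 1] <- -(open + i * ext)
  for (j in seq_len(m)) Iy[1, j + 1] <- -(open + j * ext)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (x[i] == y[j]) match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], Ix[i, j], Iy[i, j]) + s
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - open - ext,
                              Ix[i, j + 1] - ext,
                              Iy[i, j + 1] - open - ext)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - open - ext,
                              Iy[i + 1, j] - ext,
                              Ix[i + 1, j] - open - ext)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

# ---- protospacer oracle: brute-force window scan -----------------------
revcomp_chr <- function(s) {
  ch <- rev(strsplit(s, "")[[1]])
  paste(c(A = "T", C = "G", G = "C", T = "A")[ch], collapse = "")
}
brute_protospacers <- function(seq) {
  L <- nchar(seq)
  out <- list()
  for (s in seq_len(max(L - 22L, 0L))) {
    w <- substring(seq, s, s + 22L)
    if (substring(w, 22L, 23L) == "GG")
      out[[length(out) + 1L]] <- data.frame(
        protospacer = substring(w, 1L, 20L), pam = substring(w, 21L, 23L),
        strand = "+", start = s, stringsAsFactors = FALSE)
    if (substring(w, 1L, 2L) == "CC")
      out[[length(out) + 1L]] <- data.frame(
        protospacer = revcomp_chr(substring(w, 4L, 23L)),
        pam = revcomp_chr(substring(w, 1L, 3L)),
        strand = "-", start = s + 3L, stringsAsFactors = FALSE)
  }
  df <- if (length(out)) do.call(rbind, out) else
    data.frame(protospacer = character(0), pam = character(0),
               strand = character(0), start = integer(0))
  df[order(df$start, df$strand), , drop = FALSE]
}

hamming <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])

# ---- consequence oracle: codon-loop translate and diff -----------------
translate_oracle <- function(cds) {
  code <- Biostrings::GENETIC_CODE
  n <- nchar(cds) %/% 3L
  aa <- character(0)
  for (i in seq_len(n)) {
    codon <- substring(cds, 3L * i - 2L, 3L * i)
    r <- code[[codon]]
    if (r == "*") return(list(protein = paste(aa, collapse = ""),
                              stop_position = i))
    aa <- c(aa, r)
  }
  list(protein = paste(aa, collapse = ""), stop_position = NA_integer_)
}

diff_proteins_oracle <- function(wt, mut) {
  w <- strsplit(wt, "")[[1]]; m <- strsplit(mut, "")[[1]]
  nw <- length(w); nm <- length(m)
  pre <- 0L
  while (pre < min(nw, nm) && w[pre + 1L] == m[pre + 1L]) pre <- pre + 1L
  suf <- 0L
  while (suf < min(nw, nm) - pre && w[nw - suf] == m[nm - suf])
    suf <- suf + 1L
  list(prefix = pre, suffix = suf, novel = nm - pre)
}

# edit a CDS with plain substring surgery, independent of apply_edits()
edit_cds_oracle <- function(cds, kind, start, len, seq = "") {
  if (kind == "del")
    paste0(substring(cds, 1, start - 1), substring(cds, start + len))
  else if (kind == "ins")  # insert after position `start`
    paste0(substring(cds, 1, start), seq, substring(cds, start + 1))
  else
    paste0(substring(cds, 1, start - 1), seq, substring(cds, start + len))
}

flip_base <- function(b) setdiff(BASES, b)[1]

random_codon <- function() {
  repeat {
    c3 <- random_dna(3)
    if (!c3 %in% c("TAA", "TAG", "TGA")) return(c3)
  }
}

# ---- shared fixtures ----------------------------------------------------
# a random amplicon with the cut in the middle
make_ref <- function(len = 200L, cut = len %/% 2L, window = 10L,
                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  editscan::amplicon_ref(random_dna(len), cut, window)
}

# as make_ref, but with a fixed non-repetitive context around the cut so that
# indel alignments near the cut have a unique optimal placement
make_ref_unambiguous <- function(len = 200L, cut = 100L, window = 10L,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  seq <- strsplit(random_dna(len), "")[[1]]
  seq[(cut - 1):(cut + 9)] <- c("T","A","C","G","T","A","C","G","T","G","T")
  editscan::amplicon_ref(paste(seq, collapse = ""), cut, window)
}
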