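# Synthetic 4-channel Sanger chromatograms. The model is deliberately simple:
# one peak value per channel per position (no peak-shape convolution). A mixed
# ("edited") trace is the fraction-weighted sum of copies of the control trace
# displaced by each component's indel shift, plus Gaussian noise truncated at
# zero — exactly the signal model the decomposition inverts.

#' Generate a control/edited chromatogram pair from a known mixture
#'
#' The control trace assigns `peak_height` to the channel of the base called
#' at each position and 0 to the other three. The edited trace at position
#' `p` is `sum_k fraction_k * control[p - shift_k]` (positions displaced out
#' of range contribute 0), with optional truncated Gaussian noise. A negative
#' shift corresponds to a deletion of that many bases, a positive shift to an
#' insertion.
#'
#' @param control_sequence DNA string of the unedited amplicon (Sanger
#'   read region).
#' @param mixture Data frame (or list coercible to one) with columns `shift`
#'   (signed bp) and `fraction`; fractions must sum to 1 and shifts must lie
#'   within `max_shift`.
#' @param noise_sd Standard deviation of additive Gaussian noise, in signal
#'   units (`peak_height` units are arbitrary; 2 corresponds to 2% of the
#'   default peak height).
#' @param seed Integer seed (only the noise is random).
#' @param peak_height Peak signal value (default 100).
#' @param max_shift Largest indel magnitude the traces are expected to carry
#'   (validation bound for `mixture$shift`, default 10).
#' @return A `trace_pair` list: `control` and `edited` (data frames with
#'   columns `pos`, `A`, `C`, `G`, `T`), plus the `mixture` truth.
#' @examples
#' tp <- gen_trace(strrep("ACGT", 50),
#'                 data.frame(shift = c(0, -7), fraction = c(0.6, 0.4)))
#' head(tp$edited)
#' @export
gen_trace <- function(control_sequence, mixture, noise_sd = 0, seed = 1L,
                      peak_height = 100, max_shift = 10L) {
  seq <- check_dna_strict(control_sequence, "control_sequence")
  mixture <- as.data.frame(mixture)
  stopifnot(all(c("shift", "fraction") %in% names(mixture)))
  if (abs(sum(mixture$fraction) - 1) > 1e-9)
    stop("mixture fractions must sum to 1", call. = FALSE)
  if (any(abs(mixture$shift) > max_shift))
    stop("mixture shifts must lie within +/- max_shift", call. = FALSE)
  L <- nchar(seq)
  control <- matrix(0, nrow = L, ncol = 4,
                    dimnames = list(NULL, DNA_BASES))
  base_idx <- match(strsplit(seq, "")[[1]], DNA_BASES)
  control[cbind(seq_len(L), base_idx)] <- peak_height

  edited <- matrix(0, nrow = L, ncol = 4, dimnames = list(NULL, DNA_BASES))
  for (i in seq_len(nrow(mixture))) {
    k <- as.integer(mixture$shift[i])
    src <- seq_len(L) - k
    ok <- src >= 1L & src <= L
    edited[ok, ] <- edited[ok, ] + mixture$fraction[i] * control[src[ok], ]
  }
  if (noise_sd > 0) {
    edited <- edited + with_seed(seed, matrix(rnorm(4L * L, sd = noise_sd),
                                              nrow = L))
    edited[edited < 0] <- 0
  }

  as_trace <- function(m) data.frame(pos = seq_len(L), m)
  structure(list(control = as_trace(control), edited = as_trace(edited),
                 mixture = mixture),
            class = "trace_pair")
}

#' @export
print.trace_pair <- function(x, ...) {
  cat(sprintf("Chromatogram pair: %d positions; true mixture:\n",
              nrow(x$control)))
  print(x$mixture)
  invisible(x)
}

#' Write a chromatogram trace to TSV (columns pos, A, C, G, T)
#'
#' @param trace A trace data frame (e.g. `gen_trace(...)$edited`).
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_trace_tsv <- function(trace, path) {
  stopifnot(all(c("pos", DNA_BASES) %in% names(trace)))
  utils::write.table(trace[, c("pos", DNA_BASES)], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a chromatogram trace TSV
#'
#' @param path TSV with columns `pos`, `A`, `C`, `G`, `T`.
#' @return A trace data frame.
#' @export
read_trace_tsv <- function(path) {
  tr <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("pos", DNA_BASES) %in% names(tr)))
    stop("trace TSV must have columns pos, A, C, G, T", call. = FALSE)
  tr
}
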