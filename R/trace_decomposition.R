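# TIDE-style decomposition of a mixed Sanger chromatogram. Downstream of the
# Cas9 cut a mixed template population produces superimposed, mutually
# shifted copies of the control signal; non-negative least squares over
# shifted control traces recovers the indel-size spectrum.

#' Decompose a mixed chromatogram into an indel-size spectrum
#'
#' For every shift `k` in `-max_shift ... +max_shift` the control's four
#' channel signals are displaced by `k` positions over the decomposition
#' window and stacked into one design column; non-negative least squares
#' (Lawson-Hanson active set, via [pracma::lsqnonneg()]) then fits the edited
#' trace as a weighted sum of these shifted controls. Weights are rounded at
#' 1e-6 (for deterministic tie handling) and normalized to fractions.
#'
#' The window defaults to the 50 positions starting 5 bp downstream of the
#' cut, avoiding the heterogeneous junction right at the break site, and is
#' clipped so that every shifted copy stays inside the trace.
#'
#' @param control,edited Chromatogram traces: data frames with columns
#'   `pos`, `A`, `C`, `G`, `T` (as from [gen_trace()] or [read_trace_tsv()]),
#'   covering the same positions.
#' @param cut_site 1-based index of the last base 5' of the cut.
#' @param max_shift Largest indel size considered, in bp (>= 1).
#' @param window Optional 1-based closed `c(from, to)` decomposition window
#'   overriding the default.
#' @param window_length Length of the default window (default 50).
#' @return A `trace_spectrum`: `shifts` (`-max_shift:max_shift`),
#'   `fractions` (non-negative, summing to 1), `r_squared`,
#'   `decomposition_window`.
#' @examples
#' tp <- gen_trace(strrep("ACGTTGCA", 30),
#'                 data.frame(shift = c(0, -7), fraction = c(0.6, 0.4)))
#' decompose_trace(tp$control, tp$edited, cut_site = 120)
#' @export
decompose_trace <- function(control, edited, cut_site, max_shift = 10L,
                            window = NULL, window_length = 50L) {
  for (tr in list(control, edited))
    if (!all(c("pos", DNA_BASES) %in% names(tr)))
      stop("traces must have columns pos, A, C, G, T", call. = FALSE)
  if (!is_count(max_shift) || max_shift < 1)
    stop("max_shift must be >= 1", call. = FALSE)
  if (!identical(control$pos, edited$pos))
    stop("control and edited traces must cover the same positions",
         call. = FALSE)
  cm <- as.matrix(control[, DNA_BASES])
  em <- as.matrix(edited[, DNA_BASES])
  if (any(cm < 0) || any(em < 0))
    stop("channel intensities must be non-negative", call. = FALSE)
  L <- nrow(cm)

  if (is.null(window)) {
    from <- cut_site + 5L
    to <- from + window_length - 1L
  } else { from <- window[1]; to <- window[2] }
  # clip so every shifted copy of the control stays inside the trace
  from <- max(from, 1L + max_shift)
  to <- min(to, L - max_shift)
  if (from > to)
    stop("decomposition window lies outside trace coverage", call. = FALSE)
  win <- from:to

  shifts <- seq.int(-max_shift, max_shift)
  A <- vapply(shifts, function(k) as.vector(cm[win - k, , drop = FALSE]),
              numeric(4L * length(win)))
  if (all(A == 0))
    stop("control trace is all zero over the decomposition window",
         call. = FALSE)
  b <- as.vector(em[win, , drop = FALSE])

  fit <- pracma::lsqnonneg(A, b)
  w <- round(fit$x / 1e-6) * 1e-6
  if (sum(w) == 0)
    stop("degenerate decomposition: all weights zero", call. = FALSE)
  fractions <- w / sum(w)
  resid <- b - A %*% fit$x
  ss_res <- sum(resid^2)
  ss_tot <- sum((b - mean(b))^2)
  r2 <- if (ss_tot == 0) as.numeric(ss_res == 0) else 1 - ss_res / ss_tot
  structure(list(shifts = shifts, fractions = as.numeric(fractions),
                 r_squared = min(max(r2, 0), 1),
                 decomposition_window = c(from, to)),
            class = "trace_spectrum")
}

#' @export
print.trace_spectrum <- function(x, ...) {
  cat(sprintf("Indel spectrum over window %d-%d (R^2 = %.4f):\n",
              x$decomposition_window[1], x$decomposition_window[2],
              x$r_squared))
  nz <- x$fractions > 0.001
  if (any(nz)) {
    df <- data.frame(shift = x$shifts[nz],
                     percent = round(100 * x$fractions[nz], 1))
    print(df, row.names = FALSE)
  } else cat("  (no component above 0.1%)\n")
  invisible(x)
}

#' @export
plot.trace_spectrum <- function(x, ...) {
  graphics::barplot(100 * x$fractions, names.arg = x$shifts,
                    xlab = "indel size (bp)", ylab = "percent of signal",
                    main = sprintf("Indel spectrum (R^2 = %.3f)",
                                   x$r_squared), ...)
  invisible(x)
}
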