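#' Greedy LD pruning of a dosage matrix
#'
#' Selects an approximately independent subset of variants by a greedy
#' left-to-right scan: a variant is retained if and only if its squared
#' Pearson correlation with every previously retained variant inside the
#' trailing window is below the threshold. The result is deterministic
#' given the column order, which is assumed to follow genomic position.
#'
#' @param dosages Numeric matrix, individuals in rows and variants in
#'   columns ordered by position; column names are used as variant ids
#'   when present.
#' @param r2_threshold Squared-correlation threshold in (0, 1]; a pair at
#'   or above the threshold is considered linked. Default 0.1.
#' @param window Number of preceding variants against which each candidate
#'   is tested. Default 250.
#'
#' @return Character vector of retained variant ids (or column indices as
#'   character when the matrix has no column names).
#' @export
greedy_ld_prune <- function(dosages, r2_threshold = 0.1, window = 250) {
  stopifnot(is.matrix(dosages), r2_threshold > 0, r2_threshold <= 1,
            window >= 1)
  m <- ncol(dosages)
  ids <- colnames(dosages)
  if (is.null(ids)) ids <- as.character(seq_len(m))

  centred <- sweep(dosages, 2, colMeans(dosages))
  norms <- sqrt(colSums(centred^2))
  degenerate <- norms == 0
  if (any(degenerate)) {
    warning(sum(degenerate),
            " zero-variance column(s) excluded from pruning")
  }

  kept <- integer(0)
  for (j in seq_len(m)) {
    if (degenerate[j]) next
    in_window <- kept[kept >= j - window]
    ok <- TRUE
    if (length(in_window)) {
      r <- crossprod(centred[, in_window, drop = FALSE],
                     centred[, j]) / (norms[in_window] * norms[j])
      ok <- all(r^2 < r2_threshold)
    }
    if (ok) kept <- c(kept, j)
  }
  ids[kept]
}
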