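# Reads-per-million normalization. Each sample's counts are divided by
# that sample's library size (the total over all features of the same
# matrix) and multiplied by 1e6, so every non-degenerate column sums to
# one million.

#' RPM (reads per million) normalization
#'
#' `rpm[i, s] = counts[i, s] / sum(counts[, s]) * 1e6`. A sample whose
#' library size is 0 stays all-zero and triggers a warning.
#'
#' @param x a non-negative count matrix or a
#'   [PairedExpressionSet-class].
#' @param ... unused.
#' @return for a matrix, the RPM matrix with the same dimnames; for a
#'   `PairedExpressionSet`, the same object with an `rpm` assay added.
#' @examples
#' m <- matrix(c(1, 3), 2, 1, dimnames = list(c("a", "b"), "s1"))
#' rpmNormalize(m)  # 250000, 750000
#' @rdname rpmNormalize
#' @export
setMethod("rpmNormalize", "matrix", function(x, ...) {
  if (any(x < 0)) stop("counts must be non-negative")
  tot <- colSums(x)
  zero <- tot == 0
  if (any(zero)) {
    warning(sum(zero), " sample(s) with zero library size left all-zero: ",
            paste(colnames(x)[zero], collapse = ", "))
    tot[zero] <- 1
  }
  sweep(x, 2L, tot, "/") * 1e6
})

#' @rdname rpmNormalize
#' @export
setMethod("rpmNormalize", "PairedExpressionSet", function(x, ...) {
  SummarizedExperiment::assay(x, "rpm") <- rpmNormalize(counts(x))
  x
})

#' @describeIn rpmNormalize accessor for the `rpm` assay (computing it
#'   on the fly if absent).
#' @export
rpm <- function(x) {
  if ("rpm" %in% SummarizedExperiment::assayNames(x))
    SummarizedExperiment::assay(x, "rpm")
  else rpmNormalize(counts(x))
}
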