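#' @rdname pairing
#' @export
setGeneric("pairing", function(x) standardGeneric("pairing"))

#' @rdname targetsOf
#' @export
setGeneric("targetsOf", function(x, mirna) standardGeneric("targetsOf"))

#' @rdname targetsOf
#' @export
setGeneric("regulatorsOf", function(x, gene) standardGeneric("regulatorsOf"))

#' @rdname rpmNormalize
#' @export
setGeneric("rpmNormalize", function(x, ...) standardGeneric("rpmNormalize"))

#' @rdname pairedDeltas
#' @export
setGeneric("pairedDeltas", function(x, ...) standardGeneric("pairedDeltas"))

#' @rdname writeReport
#' @export
setGeneric("writeReport", function(report, out_dir, ...)
  standardGeneric("writeReport"))
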