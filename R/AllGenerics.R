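#' @rdname AmpliconReference-class
#' @param x an object.
#' @export
setGeneric("refSequence", function(x) standardGeneric("refSequence"))

#' @rdname AmpliconReference-class
#' @export
setGeneric("frameOffset", function(x) standardGeneric("frameOffset"))

#' @rdname AmpliconReference-class
#' @export
setGeneric("targetedPositions",
           function(x) standardGeneric("targetedPositions"))

#' @rdname AmpliconReference-class
#' @export
setGeneric("codonWindows", function(x) standardGeneric("codonWindows"))

#' @rdname VariantLibrary-class
#' @param x an object.
#' @export
setGeneric("variantLabels", function(x) standardGeneric("variantLabels"))

#' @rdname VariantLibrary-class
#' @export
setGeneric("theoreticalSize", function(x) standardGeneric("theoreticalSize"))

#' @rdname VariantCounts-class
#' @param x an object.
#' @export
setGeneric("variantFrequencies",
           function(x) standardGeneric("variantFrequencies"))

#' @rdname VariantCounts-class
#' @export
setGeneric("roundTotals", function(x) standardGeneric("roundTotals"))

#' @rdname CoverageTrialSet-class
#' @param x an object.
#' @export
setGeneric("detectionProbability",
           function(x) standardGeneric("detectionProbability"))
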