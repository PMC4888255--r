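#' @rdname SpliceWindowSet
#' @param x,object a `SpliceWindowSet`
#' @export
setGeneric("windowSequences", function(x) standardGeneric("windowSequences"))

#' @rdname SpliceWindowSet
#' @export
setGeneric("siteLabels", function(x) standardGeneric("siteLabels"))

#' @rdname SpliceWindowSet
#' @export
setGeneric("sourceIds", function(x) standardGeneric("sourceIds"))

#' @rdname SpliceWindowSet
#' @export
setGeneric("sourceCoords", function(x) standardGeneric("sourceCoords"))

#' @rdname SpliceWindowSet
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))

#' @rdname SpliceWindowSet
#' @export
setGeneric("rejections", function(x) standardGeneric("rejections"))

#' @rdname FeatureSetManifest
#' @param x a `FeatureSetManifest`
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' @rdname FeatureSetManifest
#' @export
setGeneric("manifestId", function(x) standardGeneric("manifestId"))

#' @rdname EvalDesign
#' @export
setGeneric("splitWindows",
    function(design, set, fold) standardGeneric("splitWindows"))

#' @rdname EvalResult
#' @export
setGeneric("perFold", function(x) standardGeneric("perFold"))
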