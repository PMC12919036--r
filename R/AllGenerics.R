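#' @rdname PanelData-accessors
#' @export
setGeneric("batch", function(x) standardGeneric("batch"))

#' @rdname PanelData-accessors
#' @export
setGeneric("batch<-", function(x, value) standardGeneric("batch<-"))

#' @rdname PanelData-accessors
#' @export
setGeneric("covariates", function(x) standardGeneric("covariates"))

#' @rdname PanelData-accessors
#' @export
setGeneric("metricNames", function(x) standardGeneric("metricNames"))

#' @rdname PanelData-accessors
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname PanelData-accessors
#' @export
setGeneric("nSubjects", function(x) standardGeneric("nSubjects"))

#' @rdname PanelData-accessors
#' @export
setGeneric("nFeatures", function(x) standardGeneric("nFeatures"))

#' @rdname PanelData-accessors
#' @export
setGeneric("nMetrics", function(x) standardGeneric("nMetrics"))

#' @rdname panelArray
#' @export
setGeneric("panelArray", function(x) standardGeneric("panelArray"))
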