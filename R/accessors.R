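## Accessor generics for the central containers (slot access is internal).

#' @rdname SessionRecording-class
#' @param object,x a package object.
#' @export
setGeneric("emgTrace", function(object) standardGeneric("emgTrace"))
#' @rdname SessionRecording-class
#' @export
setMethod("emgTrace", "SessionRecording", function(object) object@emg)

#' @rdname SessionRecording-class
#' @export
setGeneric("emgRate", function(object) standardGeneric("emgRate"))
#' @rdname SessionRecording-class
#' @export
setMethod("emgRate", "SessionRecording", function(object) object@emgRate)

#' @rdname SessionRecording-class
#' @export
setGeneric("wiAngles", function(object) standardGeneric("wiAngles"))
#' @rdname SessionRecording-class
#' @export
setMethod("wiAngles", "SessionRecording", function(object) object@wi)

#' @rdname SessionRecording-class
#' @export
setGeneric("wiTimestamps", function(object) standardGeneric("wiTimestamps"))
#' @rdname SessionRecording-class
#' @export
setMethod("wiTimestamps", "SessionRecording", function(object) object@wiTime)

#' @rdname SessionRecording-class
#' @export
setGeneric("sessionEvents", function(object) standardGeneric("sessionEvents"))
#' @rdname SessionRecording-class
#' @export
setMethod("sessionEvents", "SessionRecording", function(object) object@events)

#' @rdname SessionRecording-class
#' @export
setGeneric("subjectProfile", function(object) standardGeneric("subjectProfile"))
#' @rdname SessionRecording-class
#' @export
setMethod("subjectProfile", "SessionRecording", function(object) object@subject)

#' @rdname SessionRecording-class
#' @export
setGeneric("interferenceTruth",
           function(object) standardGeneric("interferenceTruth"))
#' @rdname SessionRecording-class
#' @export
setMethod("interferenceTruth", "SessionRecording",
          function(object) object@interferenceTruth)

#' @rdname SwallowSegment-class
#' @export
setGeneric("segmentSamples", function(object) standardGeneric("segmentSamples"))
#' @rdname SwallowSegment-class
#' @export
setMethod("segmentSamples", "SwallowSegment", function(object) object@samples)

#' @rdname SwallowSegment-class
#' @export
setGeneric("mamClass", function(object) standardGeneric("mamClass"))
#' @rdname SwallowSegment-class
#' @export
setMethod("mamClass", "SwallowSegment", function(object) object@mamClass)

#' @rdname SwallowSegment-class
#' @export
setGeneric("segmentLabel", function(object) standardGeneric("segmentLabel"))
#' @rdname SwallowSegment-class
#' @export
setMethod("segmentLabel", "SwallowSegment", function(object) object@label)

#' @rdname SwallowSegment-class
#' @export
setGeneric("segmentAmount", function(object) standardGeneric("segmentAmount"))
#' @rdname SwallowSegment-class
#' @export
setMethod("segmentAmount", "SwallowSegment", function(object) object@amount)

#' @rdname EvaluationReport-class
#' @export
setGeneric("reportTable", function(object) standardGeneric("reportTable"))
#' @rdname EvaluationReport-class
#' @export
setMethod("reportTable", "EvaluationReport", function(object) object@results)
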