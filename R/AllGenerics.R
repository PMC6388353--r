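## Accessor generics.  Slot access stays internal; users go through these.

#' @rdname MRDecomposition-class
#' @param x,object An object.
#' @export
setGeneric("mrNodes", function(x) standardGeneric("mrNodes"))

#' @rdname MRDecomposition-class
#' @export
setGeneric("mrDepth", function(x) standardGeneric("mrDepth"))

#' @rdname MRDecomposition-class
#' @param i Level (0 = root).
#' @param j Node index within the level, 0-based.
#' @export
setGeneric("mrNode", function(x, i, j) standardGeneric("mrNode"))

#' @rdname PredictionProfileSet-class
#' @export
setGeneric("nodeProbs", function(x) standardGeneric("nodeProbs"))

#' @rdname PredictionProfileSet-class
#' @export
setGeneric("combinedProbs", function(x) standardGeneric("combinedProbs"))

#' @rdname PredictionProfileSet-class
#' @export
setGeneric("assignedLocus", function(x) standardGeneric("assignedLocus"))

#' @rdname PredictionProfileSet-class
#' @export
setGeneric("accepted", function(x) standardGeneric("accepted"))

#' @rdname PredictionProfileSet-class
#' @export
setGeneric("mrScores", function(x) standardGeneric("mrScores"))

#' @rdname IterationState-class
#' @export
setGeneric("trainingSet", function(x) standardGeneric("trainingSet"))

#' @rdname IterationState-class
#' @export
setGeneric("trainingLoci", function(x) standardGeneric("trainingLoci"))

#' @rdname IterationState-class
#' @export
setGeneric("discoveries", function(x) standardGeneric("discoveries"))

#' @rdname IterationState-class
#' @export
setGeneric("iterationIndex", function(x) standardGeneric("iterationIndex"))

#' @rdname MRDecomposition-class
#' @export
setMethod("mrNodes", "MRDecomposition", function(x) x@nodes)

#' @rdname MRDecomposition-class
#' @export
setMethod("mrDepth", "MRDecomposition", function(x) x@depth)

#' @rdname MRDecomposition-class
#' @export
setMethod("mrNode", "MRDecomposition", function(x, i, j) {
  nm <- .nodeName(i, j)
  if (is.null(x@nodes[[nm]])) stop("no node (", i, ", ", j, ") at depth ", x@depth)
  x@nodes[[nm]]
})

#' @rdname PredictionProfileSet-class
#' @export
setMethod("nodeProbs", "PredictionProfileSet", function(x) x@probs)

#' @rdname PredictionProfileSet-class
#' @export
setMethod("combinedProbs", "PredictionProfileSet", function(x) x@combined)

#' @rdname PredictionProfileSet-class
#' @export
setMethod("assignedLocus", "PredictionProfileSet", function(x) x@assigned)

#' @rdname PredictionProfileSet-class
#' @export
setMethod("accepted", "PredictionProfileSet", function(x) x@accepted)

#' @rdname PredictionProfileSet-class
#' @export
setMethod("mrScores", "PredictionProfileSet", function(x) x@mrScore)

#' @rdname IterationState-class
#' @export
setMethod("trainingSet", "IterationState", function(x) x@training)

#' @rdname IterationState-class
#' @export
setMethod("trainingLoci", "IterationState", function(x) x@locus)

#' @rdname IterationState-class
#' @export
setMethod("discoveries", "IterationState", function(x) x@discoveries)

#' @rdname IterationState-class
#' @export
setMethod("iterationIndex", "IterationState", function(x) x@t)
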