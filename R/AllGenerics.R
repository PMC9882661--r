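#' @include AllClasses.R
NULL

#' Accessors for beat datasets and related objects
#'
#' @param x,object a \linkS4class{BeatDataset} (or, where noted, another
#'   pinnBP object).
#' @return \code{waveforms}: the N x R waveform matrix. \code{beatFeatures}:
#'   the R x 3 feature matrix (u1, u2, u3). \code{bpLabels}: numeric vector
#'   of reference BP labels (mmHg, \code{NA} where unlabeled).
#'   \code{sessionIds}: character vector of session labels.
#'   \code{normStats}: the standardisation statistics list (or \code{NULL}).
#'   \code{isStandardized}: logical flag. \code{nBeats}: number of beats.
#' @name BeatDataset-accessors
#' @aliases waveforms beatFeatures bpLabels sessionIds normStats
#'   isStandardized nBeats
NULL

#' @rdname BeatDataset-accessors
#' @export
setGeneric("waveforms", function(x) standardGeneric("waveforms"))

#' @rdname BeatDataset-accessors
#' @export
setGeneric("beatFeatures", function(x) standardGeneric("beatFeatures"))

#' @rdname BeatDataset-accessors
#' @export
setGeneric("bpLabels", function(x) standardGeneric("bpLabels"))

#' @rdname BeatDataset-accessors
#' @export
setGeneric("sessionIds", function(x) standardGeneric("sessionIds"))

#' @rdname BeatDataset-accessors
#' @export
setGeneric("normStats", function(x) standardGeneric("normStats"))

#' @rdname BeatDataset-accessors
#' @export
setGeneric("isStandardized", function(x) standardGeneric("isStandardized"))

#' @rdname BeatDataset-accessors
#' @export
setGeneric("nBeats", function(x) standardGeneric("nBeats"))

#' Split accessors
#'
#' @param x a \linkS4class{SplitSpec}.
#' @return integer beat indices.
#' @name SplitSpec-accessors
#' @aliases trainIdx testIdx
NULL

#' @rdname SplitSpec-accessors
#' @export
setGeneric("trainIdx", function(x) standardGeneric("trainIdx"))

#' @rdname SplitSpec-accessors
#' @export
setGeneric("testIdx", function(x) standardGeneric("testIdx"))

#' Training report of a model
#'
#' @param x a \linkS4class{PinnModel}.
#' @return the report list (epochs, converged, final LossBundle, history,
#'   seed, lambdaPhys, stopLoss).
#' @export
setGeneric("trainReport", function(x) standardGeneric("trainReport"))

#' Predict blood pressure for a beat dataset
#'
#' @param object a trained \linkS4class{PinnModel}.
#' @param ds a standardized \linkS4class{BeatDataset}.
#' @return numeric vector of predictions in mmHg.
#' @export
setGeneric("predictBP", function(object, ds) standardGeneric("predictBP"))
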