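#' @name alphabet-accessors
#' @title Accessors for AlphabetModel and MarkovBackground objects
#' @description Slot access for the S4 model classes.  `alphabetLetters`
#'   returns the letter names, `alphabetSize` the number of letters,
#'   `letterClasses` the per-letter secondary-structure class,
#'   `emissionMeans`/`emissionCovs` the Gaussian emission parameters,
#'   `transitionMatrix` the (conditional) transition matrix and
#'   `initialProbs` the initial letter distribution.
#' @param object an [AlphabetModel-class] or [MarkovBackground-class].
#' @param value replacement value (for `letterClasses<-`: a character
#'   vector over `helix`/`strand`/`loop`, recycled if named subset).
#' @return the corresponding slot content.
NULL

#' @rdname alphabet-accessors
#' @export
setGeneric("alphabetLetters", function(object) standardGeneric("alphabetLetters"))
#' @rdname alphabet-accessors
#' @export
setGeneric("alphabetSize", function(object) standardGeneric("alphabetSize"))
#' @rdname alphabet-accessors
#' @export
setGeneric("letterClasses", function(object) standardGeneric("letterClasses"))
#' @rdname alphabet-accessors
#' @export
setGeneric("letterClasses<-", function(object, value) standardGeneric("letterClasses<-"))
#' @rdname alphabet-accessors
#' @export
setGeneric("emissionMeans", function(object) standardGeneric("emissionMeans"))
#' @rdname alphabet-accessors
#' @export
setGeneric("emissionCovs", function(object) standardGeneric("emissionCovs"))
#' @rdname alphabet-accessors
#' @export
setGeneric("transitionMatrix", function(object) standardGeneric("transitionMatrix"))
#' @rdname alphabet-accessors
#' @export
setGeneric("initialProbs", function(object) standardGeneric("initialProbs"))

#' @rdname alphabet-accessors
setMethod("alphabetLetters", "AlphabetModel", function(object) object@letters)
#' @rdname alphabet-accessors
setMethod("alphabetSize", "AlphabetModel", function(object) length(object@letters))
#' @rdname alphabet-accessors
setMethod("letterClasses", "AlphabetModel", function(object) object@letterClass)
#' @rdname alphabet-accessors
setMethod("letterClasses<-", "AlphabetModel", function(object, value) {
  if (!is.null(names(value))) {
    cls <- object@letterClass
    cls[names(value)] <- value
    value <- cls
  }
  object@letterClass <- setNames(as.character(value), object@letters)
  validObject(object)
  object
})
#' @rdname alphabet-accessors
setMethod("emissionMeans", "AlphabetModel", function(object) object@emissionMean)
#' @rdname alphabet-accessors
setMethod("emissionCovs", "AlphabetModel", function(object) object@emissionCov)
#' @rdname alphabet-accessors
setMethod("transitionMatrix", "AlphabetModel", function(object) object@transition)
#' @rdname alphabet-accessors
setMethod("initialProbs", "AlphabetModel", function(object) object@initial)

#' @rdname alphabet-accessors
setMethod("alphabetLetters", "MarkovBackground", function(object) object@letters)
#' @rdname alphabet-accessors
setMethod("alphabetSize", "MarkovBackground", function(object) length(object@letters))
#' @rdname alphabet-accessors
setMethod("transitionMatrix", "MarkovBackground", function(object) object@transition)
#' @rdname alphabet-accessors
setMethod("initialProbs", "MarkovBackground", function(object) object@initial)

#' @rdname alphabet-accessors
#' @export
setGeneric("backgroundOrder", function(object) standardGeneric("backgroundOrder"))
#' @rdname alphabet-accessors
setMethod("backgroundOrder", "MarkovBackground", function(object) object@order)
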