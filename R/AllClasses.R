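#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib retroclock, .registration = TRUE
NULL

CLASS_VOCAB <- c("HERV", "LINE", "LTR", "SINE", "DNA", "Unknown")

#' Age transform between chronological years and the training response scale
#'
#' Human clocks are trained directly on chronological age (`identity`).
#' Cross-species clocks are trained on a relative-age scale,
#' `log(age + offset)` with a 2-year default offset, which compresses the
#' wide range of mammalian lifespans and keeps age 0 finite.
#'
#' @slot kind `"identity"` or `"log_offset"`.
#' @slot offset Offset in years added before the natural log (log_offset
#'   only; must be strictly positive).
#'
#' @seealso [transformAge()], [inverseTransformAge()]
#' @export
setClass("AgeTransform",
  representation(kind = "character", offset = "numeric"),
  prototype(kind = "identity", offset = 2))

setValidity("AgeTransform", function(object) {
  if (length(object@kind) != 1L ||
      !object@kind %in% c("identity", "log_offset"))
    return("kind must be 'identity' or 'log_offset'")
  if (object@kind == "log_offset" &&
      (length(object@offset) != 1L || !is.finite(object@offset) ||
       object@offset <= 0))
    return("log_offset transform requires a finite offset > 0")
  TRUE
})

#' Construct an AgeTransform
#'
#' @param kind `"identity"` (train on age in years) or `"log_offset"`
#'   (train on `log(age + offset)`, the relative-age scale used for
#'   pan-mammalian clocks).
#' @param offset Years added before the log; default 2.
#' @return An [AgeTransform-class] object.
#' @examples
#' transformAge(0, ageTransform("log_offset"))  # log(2)
#' @export
ageTransform <- function(kind = c("identity", "log_offset"), offset = 2) {
  kind <- match.arg(kind)
  new("AgeTransform", kind = kind, offset = offset)
}

#' A fitted retroelement epigenetic clock
#'
#' A sparse penalized linear predictor of (transformed) chronological age
#' from CpG beta values. Only nonzero coefficients are stored; the CpGs
#' carrying them are the clock's CpG set. Training means of those CpGs are
#' kept so that missing probes can be mean-imputed at prediction time,
#' which leaves the linear predictor unbiased at the training centroid.
#'
#' @slot name Clock name.
#' @slot platform Array platform tag (e.g. `"EPICv1"`, `"custom"`).
#' @slot intercept Intercept on the response (possibly transformed) scale.
#' @slot coefficients Named numeric vector of nonzero CpG coefficients.
#' @slot transform [AgeTransform-class] mapping years to the response scale.
#' @slot trainingMeans Named numeric vector of training-set mean betas for
#'   the coefficient CpGs (may be empty, in which case imputation is
#'   disabled).
#' @slot nTrain Number of training samples.
#' @slot seed Seed the training run was keyed to.
#'
#' @seealso [trainClock()], [predictAge()], [readClockModel()]
#' @export
setClass("ClockModel",
  representation(name = "character", platform = "character",
    intercept = "numeric", coefficients = "numeric",
    transform = "AgeTransform", trainingMeans = "numeric",
    nTrain = "integer", seed = "integer"))

setValidity("ClockModel", function(object) {
  msg <- character()
  if (length(object@intercept) != 1L || !is.finite(object@intercept))
    msg <- c(msg, "intercept must be a single finite number")
  cf <- object@coefficients
  if (length(cf)) {
    if (is.null(names(cf)) || anyNA(names(cf)) || any(names(cf) == ""))
      msg <- c(msg, "coefficients must be named by probe id")
    if (anyDuplicated(names(cf)))
      msg <- c(msg, "duplicate probe ids among coefficients")
    if (any(cf == 0))
      msg <- c(msg, "coefficients must be nonzero (sparsity is explicit)")
  }
  tm <- object@trainingMeans
  if (length(tm) && !all(names(cf) %in% names(tm)))
    msg <- c(msg,
      "when training means are present, every coefficient CpG needs one")
  if (length(msg)) msg else TRUE
})

ClockModel <- function(name, platform, intercept, coefficients, transform,
                       trainingMeans = numeric(), nTrain = NA_integer_,
                       seed = NA_integer_) {
  new("ClockModel", name = name, platform = platform,
      intercept = as.numeric(intercept),
      coefficients = coefficients, transform = transform,
      trainingMeans = trainingMeans, nTrain = as.integer(nTrain),
      seed = as.integer(seed))
}

#' @describeIn ClockModel-class Named vector of nonzero CpG coefficients.
#' @param object,model A `ClockModel`.
#' @export
clockCoefficients <- function(model) model@coefficients

#' @describeIn ClockModel-class The clock's CpG identifiers.
#' @export
clockCpGs <- function(model) names(model@coefficients)

#' @describeIn ClockModel-class Intercept on the response scale.
#' @export
clockIntercept <- function(model) model@intercept

#' @describeIn ClockModel-class The clock's [AgeTransform-class].
#' @export
clockTransform <- function(model) model@transform

#' @describeIn ClockModel-class Training-set mean betas of the clock CpGs
#'   (empty when deployment-time imputation is disabled).
#' @export
trainingMeans <- function(model) model@trainingMeans

setMethod("show", "ClockModel", function(object) {
  cat("ClockModel '", object@name, "' (", object@platform, ")\n", sep = "")
  cat("  ", length(object@coefficients), " CpGs, intercept ",
      format(object@intercept, digits = 5), "\n", sep = "")
  cat("  transform: ", object@transform@kind,
      if (object@transform@kind == "log_offset")
        paste0(" (offset ", object@transform@offset, " y)") else "",
      "\n", sep = "")
  if (!is.na(object@nTrain))
    cat("  trained on ", object@nTrain, " samples\n", sep = "")
  if (!length(object@trainingMeans))
    cat("  (no training means: imputation disabled)\n")
})

setMethod("show", "AgeTransform", function(object) {
  if (object@kind == "identity") cat("AgeTransform: identity (years)\n")
  else cat("AgeTransform: log(age + ", object@offset, ")\n", sep = "")
})

#' Cross-validation result for an elastic-net clock fit
#'
#' @slot lambdaPath Decreasing vector of penalty values.
#' @slot cvMean Mean cross-validated squared error per lambda (response
#'   scale).
#' @slot cvSE Standard error of the fold errors per lambda.
#' @slot chosenLambda Penalty selected by the selection rule.
#' @slot selectionRule `"lambda_min"` or `"lambda_1se"`.
#' @slot foldAssignments Integer fold id per training sample.
#' @slot nonzero Number of nonzero coefficients per lambda in the full fit.
#' @export
setClass("ClockCV",
  representation(lambdaPath = "numeric", cvMean = "numeric", cvSE = "numeric",
    chosenLambda = "numeric", selectionRule = "character",
    foldAssignments = "integer", nonzero = "integer"))

setValidity("ClockCV", function(object) {
  lp <- object@lambdaPath
  if (length(lp) && any(diff(lp) >= 0))
    return("lambdaPath must be strictly decreasing")
  if (length(object@chosenLambda) == 1L && length(lp) &&
      !object@chosenLambda %in% lp)
    return("chosenLambda must lie on the lambda path")
  TRUE
})

setMethod("show", "ClockCV", function(object) {
  cat("ClockCV: ", length(object@lambdaPath), " lambdas, ",
      max(object@foldAssignments), " folds\n", sep = "")
  i <- match(object@chosenLambda, object@lambdaPath)
  cat("  chosen lambda (", object@selectionRule, "): ",
      format(object@chosenLambda, digits = 4), " with ",
      object@nonzero[i], " nonzero coefficients\n", sep = "")
})
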