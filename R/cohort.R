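#' Classify MRD values into response groups
#'
#' Applies the clinical response-group definitions used throughout the
#' package, on the fraction scale (10\% = 0.10, 0.1\% = 0.001):
#' \describe{
#'   \item{mid}{\code{fast} iff MRD < 0.10, else \code{slow}.}
#'   \item{eoi}{\code{slow} iff MRD >= 0.001; \code{fast} iff MRD == 0;
#'     \code{intermediate} otherwise (0 < MRD < 0.001).}
#'   \item{eoc}{\code{negative} iff MRD == 0, else \code{positive}.}
#' }
#' Missing MRD propagates to a missing label; the patient is simply excluded
#' from that timepoint's analyses.
#'
#' @param timepoint One of \code{"mid"}, \code{"eoi"}, \code{"eoc"}.
#' @param mrd Numeric vector of MRD fractions in [0, 1]; NA allowed. Names,
#'   if present, are used in error messages and carried to the result.
#' @return A factor of response labels with timepoint-specific levels
#'   (\code{mid}: fast/slow; \code{eoi}: fast/intermediate/slow;
#'   \code{eoc}: negative/positive).
#' @examples
#' classifyResponse("eoi", c(0, 0.0005, 0.001, NA))
#' classifyResponse("mid", c(0.0999, 0.10))
#' @export
classifyResponse <- function(timepoint, mrd) {
  timepoint <- match.arg(timepoint, c("mid", "eoi", "eoc"))
  mrd <- setNames(as.numeric(mrd), names(mrd))
  bad <- !is.na(mrd) & (mrd < 0 | mrd > 1)
  if (any(bad)) {
    who <- if (!is.null(names(mrd))) names(mrd)[bad] else which(bad)
    stop(sprintf("MRD outside [0,1] at timepoint '%s' for: %s",
                 timepoint, paste(who, collapse = ", ")))
  }
  lab <- switch(timepoint,
    mid = ifelse(mrd < 0.10, "fast", "slow"),
    eoi = ifelse(mrd >= 0.001, "slow", ifelse(mrd == 0, "fast", "intermediate")),
    eoc = ifelse(mrd == 0, "negative", "positive")
  )
  lev <- switch(timepoint,
    mid = c("fast", "slow"),
    eoi = c("fast", "intermediate", "slow"),
    eoc = c("negative", "positive")
  )
  out <- factor(lab, levels = lev)
  names(out) <- names(mrd)
  out
}

#' @describeIn MRDCohort Response labels of every patient at one timepoint
#'   (see \code{\link{classifyResponse}}).
#' @export
setMethod("responseLabels", "MRDCohort", function(x, timepoint) {
  classifyResponse(timepoint, mrdValues(x, timepoint))
})

.dichotomy_schemes <- list(
  slow_vs_rest     = list(timepoint = "eoi", a = "slow",     a_name = "slow",     b_name = "fast+intermediate"),
  fast_vs_rest     = list(timepoint = "eoi", a = "fast",     a_name = "fast",     b_name = "slow+intermediate"),
  eoc_pos_vs_neg   = list(timepoint = "eoc", a = "positive", a_name = "positive", b_name = "negative"),
  mid_slow_vs_fast = list(timepoint = "mid", a = "slow",     a_name = "slow",     b_name = "fast")
)

#' Dichotomization schemes
#'
#' Names of the supported two-group splits of the response labels, each tied
#' to a single timepoint: \code{slow_vs_rest} and \code{fast_vs_rest} split
#' the EOI three-group classification, \code{eoc_pos_vs_neg} the EOC status,
#' and \code{mid_slow_vs_fast} the mid-induction classification.
#'
#' @return Character vector of scheme names.
#' @export
dichotomySchemes <- function() names(.dichotomy_schemes)

#' @describeIn MRDCohort Two-group split of the cohort under a named scheme.
#'   Returns a factor (levels = the two groups, first level is the highlighted
#'   group, e.g. slow in \code{slow_vs_rest}) named by patient, NA where the
#'   timepoint's MRD is missing, with attributes \code{timepoint} and
#'   \code{group_sizes}.
#' @param scheme One of \code{\link{dichotomySchemes}()}.
#' @export
setMethod("dichotomize", "MRDCohort", function(x, scheme) {
  scheme <- match.arg(scheme, names(.dichotomy_schemes))
  sc <- .dichotomy_schemes[[scheme]]
  lab <- responseLabels(x, sc$timepoint)
  dichotomizeLabels(lab, scheme)
})

#' Dichotomize response labels directly
#'
#' Lower-level companion to the \code{MRDCohort} method, operating on a factor
#' of response labels (all from one timepoint).
#'
#' @param labels Factor as returned by \code{\link{classifyResponse}}.
#' @param scheme One of \code{\link{dichotomySchemes}()}; its timepoint must
#'   match the vocabulary of \code{labels}.
#' @return Named factor with two levels; NA propagates. Attributes:
#'   \code{timepoint}, \code{group_sizes} (non-missing count per level).
#' @export
dichotomizeLabels <- function(labels, scheme) {
  scheme <- match.arg(scheme, names(.dichotomy_schemes))
  sc <- .dichotomy_schemes[[scheme]]
  expected <- levels(classifyResponse(sc$timepoint, numeric(0)))
  if (!identical(levels(labels), expected))
    stop(sprintf("scheme '%s' expects %s labels (levels %s)", scheme,
                 sc$timepoint, paste(expected, collapse = "/")))
  grp <- ifelse(is.na(labels), NA_character_,
                ifelse(labels == sc$a, sc$a_name, sc$b_name))
  out <- factor(grp, levels = c(sc$a_name, sc$b_name))
  names(out) <- names(labels)
  attr(out, "timepoint") <- sc$timepoint
  attr(out, "group_sizes") <- setNames(as.integer(table(out)), levels(out))
  out
}
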