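## Scoring mutations and classifying predicted DGJ responsiveness.

#' Score a missense mutation against a PSSM
#'
#' Returns the matrix element for the \emph{mutant} residue at the mutated
#' position: the matrix already encodes wild-type conservation, so a
#' substitution toward a residue seen in homologs scores less negatively.
#' With \code{delta = TRUE} the wild-type residue's score is subtracted
#' instead (a non-default variant; the plain mutant lookup is the method's
#' convention). When \code{checkWildtype} is set, the query residue at the
#' position must match the mutation's stated wild type.
#'
#' @param x A [PSSM-class], or a sparse score table: a data frame with
#'   columns \code{position}, \code{wt}, \code{mut} and \code{score} (see
#'   [fixtureScoreTable()]).
#' @param mutation A [MissenseMutation-class] with a non-missing mutant
#'   residue, or a string parseable by [parseMutation()].
#' @param checkWildtype Verify the stated wild-type residue against the
#'   reference (default \code{TRUE}).
#' @param delta Return mutant minus wild-type score instead of the plain
#'   mutant lookup (PSSM method only; default \code{FALSE}).
#' @return Integer score. Mutations flagged as hitting the active site are
#'   expected to be non-responsive regardless of score; that annotation is
#'   carried by the panel records, not by the score.
#' @examples
#' scoreMutation(fixtureScoreTable(), "p.A230T")
#' @export
setGeneric("scoreMutation",
           function(x, mutation, checkWildtype = TRUE, ...)
               standardGeneric("scoreMutation"))

.asMutation <- function(mutation) {
    if (is.character(mutation)) mutation <- parseMutation(mutation)
    stopifnot(is(mutation, "MissenseMutation"))
    if (is.na(mutation@mut))
        stop("mutation ", formatMutation(mutation),
             " has no mutant residue; cannot score")
    mutation
}

#' @rdname scoreMutation
#' @param ... Passed between methods.
#' @export
setMethod("scoreMutation", "PSSM",
    function(x, mutation, checkWildtype = TRUE, delta = FALSE) {
        mutation <- .asMutation(mutation)
        pos <- mutation@position
        L <- nchar(x@query)
        if (pos > L)
            stop(sprintf("position %d out of range: query has %d residues",
                         pos, L))
        qres <- substr(x@query, pos, pos)
        if (checkWildtype && qres != mutation@wt)
            stop(sprintf(
                "wild-type mismatch at position %d: mutation states %s but the reference has %s",
                pos, mutation@wt, qres))
        s <- x@scores[pos, mutation@mut]
        if (delta) s <- s - x@scores[pos, mutation@wt]
        as.integer(s)
    })

#' @rdname scoreMutation
#' @export
setMethod("scoreMutation", "data.frame",
    function(x, mutation, checkWildtype = TRUE) {
        stopifnot(all(c("position", "wt", "mut", "score") %in% names(x)))
        mutation <- .asMutation(mutation)
        hit <- which(x$position == mutation@position & x$mut == mutation@mut)
        if (length(hit) == 0L)
            stop("no score tabulated for ", formatMutation(mutation))
        if (checkWildtype && x$wt[hit[1L]] != mutation@wt)
            stop(sprintf(
                "wild-type mismatch at position %d: mutation states %s but the table has %s",
                mutation@position, mutation@wt, x$wt[hit[1L]]))
        as.integer(x$score[hit[1L]])
    })

#' Classify a PSSM score as predicted responsive or not
#'
#' Two published rules:
#' \describe{
#'   \item{three_zone}{score > -2 responsive; score == -2 twilight (no
#'     confident call); score < -2 non-responsive.}
#'   \item{binary_ge_minus1}{score >= -1 responsive, else non-responsive
#'     (the original benchmarked threshold; coincides with the three-zone
#'     rule on integers except that -2 is called non-responsive rather than
#'     twilight).}
#' }
#' Both thresholds are inclusive as published.
#'
#' @param score Numeric vector of PSSM scores.
#' @param rule \code{"three_zone"} (default) or \code{"binary_ge_minus1"}.
#' @return Character vector over \code{"responsive"}, \code{"twilight"},
#'   \code{"non_responsive"}.
#' @examples
#' classifyScore(c(0, -1, -2, -5))
#' classifyScore(c(0, -1, -2, -5), rule = "binary_ge_minus1")
#' @export
classifyScore <- function(score, rule = c("three_zone", "binary_ge_minus1")) {
    rule <- match.arg(rule)
    stopifnot(is.numeric(score))
    if (rule == "three_zone")
        ifelse(score > -2, "responsive",
               ifelse(score == -2, "twilight", "non_responsive"))
    else
        ifelse(score >= -1, "responsive", "non_responsive")
}

#' Responsiveness call from chaperone-treated enzyme activity
#'
#' A mutant is called responsive when its activity under DGJ treatment
#' reaches at least 15\% of wild type. The threshold derives from the
#' residual-activity level separating classic from attenuated phenotypes
#' (about 12\%), rounded up for assay error; it is inclusive ("15\% or
#' more") and configurable.
#'
#' @param activityPctWt Activity with the chaperone, as percent of wild
#'   type (>= 0); vectorized.
#' @param threshold Percent-of-wild-type cutoff (default 15).
#' @return Logical vector: \code{TRUE} when responsive.
#' @examples
#' activityCall(c(15, 14.9))
#' @export
activityCall <- function(activityPctWt, threshold = 15) {
    stopifnot(is.numeric(activityPctWt))
    if (any(activityPctWt < 0))
        stop("activity must be >= 0 (percent of wild type)")
    activityPctWt >= threshold
}

#' Fold increase of enzyme activity under chaperone treatment
#'
#' @param activityWith Activity with DGJ.
#' @param activityWithout Baseline activity without DGJ (> 0).
#' @return \code{activityWith / activityWithout}.
#' @examples
#' foldIncrease(58, 10)
#' @export
foldIncrease <- function(activityWith, activityWithout) {
    if (any(activityWithout <= 0))
        stop("baseline activity must be > 0 to form a ratio")
    activityWith / activityWithout
}

#' Predict responsiveness for a set of mutations
#'
#' Convenience wrapper: scores each mutation with [scoreMutation()] and
#' classifies it with [classifyScore()]. Mutations whose record flags the
#' active site get a warning annotation — active-site lesions are expected
#' not to bind the chaperone — but the numeric call is never overridden.
#'
#' @param x A [PSSM-class] or sparse score table (see [scoreMutation()]).
#' @param mutations Character vector of mutation notations or a list of
#'   [MissenseMutation-class] objects.
#' @param rule Classification rule, see [classifyScore()].
#' @param checkWildtype Passed to [scoreMutation()].
#' @param activeSite Optional logical vector marking active-site mutations.
#' @return Data frame with columns \code{mutation}, \code{score},
#'   \code{call} and \code{active_site_warning}.
#' @export
predictResponsiveness <- function(x, mutations,
                                  rule = c("three_zone", "binary_ge_minus1"),
                                  checkWildtype = TRUE, activeSite = NULL) {
    rule <- match.arg(rule)
    muts <- if (is.character(mutations)) lapply(mutations, parseMutation)
            else mutations
    scores <- vapply(muts, function(m)
        scoreMutation(x, m, checkWildtype = checkWildtype), integer(1))
    warn <- if (is.null(activeSite)) rep(FALSE, length(muts))
            else as.logical(activeSite)
    data.frame(mutation = vapply(muts, formatMutation, character(1)),
               score = scores, call = classifyScore(scores, rule),
               active_site_warning = warn, stringsAsFactors = FALSE)
}
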