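## Accessors for the S4 containers; user code should never reach into slots.

#' Aligned sequences of a ProteinAlignment
#'
#' @param x A [ProteinAlignment-class].
#' @return Named character vector of aligned residue strings.
#' @export
alnSequences <- function(x) {
    stopifnot(is(x, "ProteinAlignment"))
    x@sequences
}

#' Index of the query sequence
#'
#' @param x A [ProteinAlignment-class].
#' @return Integer index of the reference sequence.
#' @export
queryIndex <- function(x) {
    stopifnot(is(x, "ProteinAlignment"))
    x@queryIndex
}

#' Ungapped query sequence
#'
#' @param x A [ProteinAlignment-class] or [PSSM-class].
#' @return Single string: the reference sequence with gaps removed.
#' @export
querySequence <- function(x) {
    if (is(x, "PSSM")) return(x@query)
    stopifnot(is(x, "ProteinAlignment"))
    gsub("-", "", x@sequences[[x@queryIndex]], fixed = TRUE)
}

#' Number of aligned columns
#'
#' @param x A [ProteinAlignment-class].
#' @return Integer alignment width.
#' @export
alnWidth <- function(x) {
    stopifnot(is(x, "ProteinAlignment"))
    nchar(x@sequences[[1L]])
}

#' Integer score matrix of a PSSM
#'
#' @param x A [PSSM-class].
#' @return Integer matrix, query positions x 20 residues.
#' @export
pssmScores <- function(x) {
    stopifnot(is(x, "PSSM"))
    x@scores
}

#' Smoothed per-position probabilities of a PSSM
#'
#' @param x A [PSSM-class].
#' @return Numeric matrix, rows summing to 1 (all-NA when the PSSM was read
#'   from a scores-only file).
#' @export
pssmProbs <- function(x) {
    stopifnot(is(x, "PSSM"))
    x@probs
}

#' Construction parameters of a PSSM
#'
#' @param x A [PSSM-class].
#' @return The [PssmParams-class] used to build the matrix, or \code{NULL}.
#' @export
pssmParams <- function(x) {
    stopifnot(is(x, "PSSM"))
    x@params
}

#' Profile probability matrix
#'
#' @param x A [GeneratingProfile-class].
#' @return Numeric matrix, positions x 20 residues.
#' @export
profileProbs <- function(x) {
    stopifnot(is(x, "GeneratingProfile"))
    x@probs
}

#' Fields of a MissenseMutation
#'
#' @param x A [MissenseMutation-class].
#' @return `mutationWt`/`mutationMut`: one-letter residue (`mutationMut`
#'   may be `NA`); `mutationPosition`: 1-based protein position;
#'   `mutationCdna`: cDNA notation or `NA`.
#' @name mutation-accessors
NULL

#' @rdname mutation-accessors
#' @export
mutationWt <- function(x) { stopifnot(is(x, "MissenseMutation")); x@wt }

#' @rdname mutation-accessors
#' @export
mutationPosition <- function(x) { stopifnot(is(x, "MissenseMutation")); x@position }

#' @rdname mutation-accessors
#' @export
mutationMut <- function(x) { stopifnot(is(x, "MissenseMutation")); x@mut }

#' @rdname mutation-accessors
#' @export
mutationCdna <- function(x) { stopifnot(is(x, "MissenseMutation")); x@cdna }
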