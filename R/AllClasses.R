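#' @import methods
NULL

#' The 20-residue amino acid alphabet
#'
#' One-letter codes in the conventional PSSM column order
#' (A R N D C Q E G H I L K M F P S T W Y V).
#'
#' @format A character vector of length 20.
#' @export
AMINO_ACIDS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

.AA3 <- c(Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
          Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
          Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
          Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V")

setClassUnion("characterOrNULL", c("character", "NULL"))

#' ProteinAlignment: a gapped protein multiple sequence alignment
#'
#' Holds aligned protein sequences over the 20 amino acids plus the gap
#' character \code{-} and the ambiguity code \code{X}, together with the
#' index of the query (reference) sequence. The ungapped query defines the
#' 1-based coordinate system of any PSSM built from the alignment.
#'
#' @slot sequences Named character vector of equal-length aligned residue
#'   strings (uppercase; gaps as \code{-}).
#' @slot queryIndex Integer index of the query sequence.
#'
#' @seealso [readAlignment()], [buildPSSM()], [sampleAlignment()]
#' @export
setClass("ProteinAlignment",
         representation(sequences = "character", queryIndex = "integer"))

setValidity("ProteinAlignment", function(object) {
    s <- object@sequences
    if (length(s) == 0L)
        return("alignment contains no sequences")
    w <- nchar(s)
    if (any(w != w[1L]) || w[1L] < 1L)
        return("aligned sequences must all have the same positive length")
    bad <- grepl(paste0("[^", paste(AMINO_ACIDS, collapse = ""), "X-]"), s)
    if (any(bad))
        return(sprintf("sequence %d contains characters outside {20 aa, '-', 'X'}",
                       which(bad)[1L]))
    qi <- object@queryIndex
    if (length(qi) != 1L || is.na(qi) || qi < 1L || qi > length(s))
        return("queryIndex must address one of the sequences")
    TRUE
})

#' PssmParams: parameters of PSSM construction
#'
#' @slot background Named numeric vector of 20 background residue
#'   frequencies (sums to 1).
#' @slot pseudocountWeight Non-negative pseudocount constant (the
#'   PSI-BLAST-style \emph{beta}); 0 disables smoothing.
#' @slot substitutionPrior 20 x 20 matrix of conditional substitution
#'   probabilities P(a | b) with rows (b) summing to 1; used to push
#'   observed frequencies toward plausible substitutions.
#' @slot scale Positive log-odds scale applied before integer rounding
#'   (default half-bit units, 2/ln 2).
#' @slot weighting Sequence weighting scheme, \code{"henikoff"} or
#'   \code{"uniform"}.
#' @slot scoreFloor Finite floor for log-odds of zero-probability residues.
#'
#' @seealso [PssmParams()], [buildPSSM()]
#' @export
setClass("PssmParams",
         representation(background = "numeric",
                        pseudocountWeight = "numeric",
                        substitutionPrior = "matrix",
                        scale = "numeric",
                        weighting = "character",
                        scoreFloor = "numeric"))

setValidity("PssmParams", function(object) {
    bg <- object@background
    if (length(bg) != 20L || is.null(names(bg)) ||
        !identical(sort(names(bg)), sort(AMINO_ACIDS)))
        return("background must be a named 20-vector over the amino acid alphabet")
    if (any(bg <= 0))
        return("background frequencies must be strictly positive")
    if (abs(sum(bg) - 1) > 1e-6)
        return("background frequencies must sum to 1")
    pr <- object@substitutionPrior
    if (!all(dim(pr) == c(20L, 20L)))
        return("substitutionPrior must be 20 x 20")
    if (any(abs(rowSums(pr) - 1) > 1e-6))
        return("each row of substitutionPrior must sum to 1")
    if (object@pseudocountWeight < 0)
        return("pseudocountWeight must be >= 0")
    if (object@scale <= 0)
        return("scale must be > 0")
    if (!object@weighting %in% c("henikoff", "uniform"))
        return("weighting must be 'henikoff' or 'uniform'")
    TRUE
})

#' PSSM: position-specific substitution matrix
#'
#' Integer log-odds scores for each of the 20 amino acids at every position
#' of an ungapped query sequence, with the smoothed per-position residue
#' probabilities retained unrounded.
#'
#' @slot query Single string: the ungapped query (reference) sequence.
#' @slot scores Integer matrix, one row per query position, 20 named
#'   residue columns.
#' @slot probs Numeric matrix of the smoothed probabilities behind the
#'   scores (rows sum to 1); may be all-\code{NA} for matrices read from a
#'   scores-only file.
#' @slot params The [PssmParams-class] used for construction, or \code{NULL}.
#'
#' @seealso [buildPSSM()], [scoreMutation()], [writePSSM()]
#' @export
setClass("PSSM",
         representation(query = "character", scores = "matrix",
                        probs = "matrix", params = "ANY"))

setValidity("PSSM", function(object) {
    L <- nchar(object@query)
    if (length(object@query) != 1L || L < 1L)
        return("query must be a single non-empty string")
    if (grepl("-", object@query, fixed = TRUE))
        return("query must be ungapped")
    sc <- object@scores
    if (nrow(sc) != L || ncol(sc) != 20L ||
        !identical(colnames(sc), AMINO_ACIDS))
        return("scores must be L x 20 with standard residue columns")
    pr <- object@probs
    if (!all(dim(pr) == dim(sc)))
        return("probs must have the same shape as scores")
    ok <- stats::complete.cases(pr)
    if (any(ok) && any(abs(rowSums(pr[ok, , drop = FALSE]) - 1) > 1e-9))
        return("per-position probabilities must sum to 1 (tol 1e-9)")
    TRUE
})

#' MissenseMutation: a single amino acid substitution
#'
#' A protein-level missense change in HGVS style ("p.A230T"): wild-type
#' residue, 1-based protein position, mutant residue, and optionally the
#' underlying cDNA change. The mutant residue may be \code{NA} for
#' incompletely reported mutations (these are excluded from score lookups).
#'
#' @slot wt One-letter wild-type residue.
#' @slot position 1-based protein coordinate.
#' @slot mut One-letter mutant residue, or \code{NA}.
#' @slot cdna Optional cDNA notation such as "c.688G>A", or \code{NA}.
#'
#' @seealso [parseMutation()], [scoreMutation()]
#' @export
setClass("MissenseMutation",
         representation(wt = "character", position = "integer",
                        mut = "character", cdna = "character"))

setValidity("MissenseMutation", function(object) {
    if (!object@wt %in% AMINO_ACIDS)
        return("wt must be a one-letter amino acid code")
    if (is.na(object@position) || object@position < 1L)
        return("position must be >= 1")
    if (!is.na(object@mut)) {
        if (!object@mut %in% AMINO_ACIDS)
            return("mut must be a one-letter amino acid code or NA")
        if (object@mut == object@wt)
            return("wild-type and mutant residues must differ")
    }
    TRUE
})

#' GeneratingProfile: ground-truth residue profile for simulation
#'
#' A per-position categorical distribution over the 20 amino acids from
#' which synthetic alignments are sampled; the profile is the known truth
#' that PSSM construction should recover.
#'
#' @slot probs Numeric matrix, one row per position, 20 named residue
#'   columns, each row summing to 1.
#' @slot conservation Numeric vector in [0,1], one value per position;
#'   1 means a point mass on the dominant residue.
#'
#' @seealso [makeProfile()], [sampleAlignment()]
#' @export
setClass("GeneratingProfile",
         representation(probs = "matrix", conservation = "numeric"))

setValidity("GeneratingProfile", function(object) {
    p <- object@probs
    if (ncol(p) != 20L || !identical(colnames(p), AMINO_ACIDS))
        return("probs must have 20 standard residue columns")
    if (any(p < 0) || any(abs(rowSums(p) - 1) > 1e-9))
        return("each row of probs must be a probability vector")
    cons <- object@conservation
    if (length(cons) != nrow(p) || any(cons < 0 | cons > 1))
        return("conservation must be one value in [0,1] per position")
    TRUE
})

## ---- show methods -----------------------------------------------------

setMethod("show", "ProteinAlignment", function(object) {
    cat(sprintf("ProteinAlignment: %d sequences x %d columns (query: %s)\n",
                length(object@sequences), nchar(object@sequences[1L]),
                names(object@sequences)[object@queryIndex]))
})

setMethod("show", "PSSM", function(object) {
    cat(sprintf("PSSM over %d query positions (scores %d..%d)\n",
                nchar(object@query), min(object@scores), max(object@scores)))
})

setMethod("show", "MissenseMutation", function(object) {
    cat(formatMutation(object))
    if (!is.na(object@cdna)) cat(" [", object@cdna, "]", sep = "")
    cat("\n")
})

setMethod("show", "GeneratingProfile", function(object) {
    cat(sprintf("GeneratingProfile: %d positions, mean conservation %.2f\n",
                nrow(object@probs), mean(object@conservation)))
})
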