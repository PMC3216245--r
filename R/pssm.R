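## PSSM construction: Henikoff weighting, pseudocount smoothing, scaled
## integer log-odds.

# BLOSUM62 marginal residue frequencies (Henikoff & Henikoff block data);
# sums to 1 exactly at this printed precision.
.BLOSUM62_BG <- c(A = 0.074, R = 0.052, N = 0.045, D = 0.054, C = 0.025,
                  Q = 0.034, E = 0.054, G = 0.074, H = 0.026, I = 0.068,
                  L = 0.099, K = 0.058, M = 0.025, F = 0.047, P = 0.039,
                  S = 0.057, T = 0.051, W = 0.013, Y = 0.032, V = 0.073)

#' BLOSUM62 background residue frequencies
#'
#' @return Named numeric 20-vector summing to 1.
#' @export
blosum62Background <- function() .BLOSUM62_BG

#' Conditional substitution prior derived from BLOSUM62
#'
#' Inverts the integer BLOSUM62 log-odds scores back to substitution
#' probabilities: P(a | b) is proportional to p(a) * exp(lambda * s(b, a)),
#' with rows normalized to 1. lambda = ln(2)/2 matches the half-bit scale of
#' the published matrix.
#'
#' @param background Named 20-vector of residue frequencies.
#' @param lambda Score-to-nats conversion factor.
#' @return 20 x 20 matrix; rows (wild-type context b) sum to 1.
#' @export
blosum62SubstitutionPrior <- function(background = blosum62Background(),
                                      lambda = log(2) / 2) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    s <- e$BLOSUM62[AMINO_ACIDS, AMINO_ACIDS]
    prior <- sweep(exp(lambda * s), 2L, background[AMINO_ACIDS], `*`)
    prior / rowSums(prior)
}

#' Parameters controlling PSSM construction
#'
#' @param background Background residue frequencies (default BLOSUM62
#'   marginals).
#' @param pseudocountWeight Pseudocount constant beta >= 0 (default 10, the
#'   customary PSI-BLAST value); mixed against alpha = n_eff - 1.
#' @param substitutionPrior 20 x 20 conditional substitution probability
#'   table (default derived from BLOSUM62).
#' @param scale Log-odds scale before integer rounding; default 2/ln(2)
#'   (half-bit units), which places conserved-position scores in the small
#'   integer range familiar from sequence-profile tools.
#' @param weighting \code{"henikoff"} (position-based, default) or
#'   \code{"uniform"}.
#' @param scoreFloor Floor for the log-odds of zero-probability residues
#'   (default -16), keeping scores finite when smoothing is disabled.
#' @return A validated [PssmParams-class].
#' @examples
#' p <- PssmParams(pseudocountWeight = 0)
#' @export
PssmParams <- function(background = blosum62Background(),
                       pseudocountWeight = 10,
                       substitutionPrior = blosum62SubstitutionPrior(background),
                       scale = 2 / log(2),
                       weighting = c("henikoff", "uniform"),
                       scoreFloor = -16) {
    weighting <- match.arg(weighting)
    new("PssmParams", background = background[AMINO_ACIDS],
        pseudocountWeight = pseudocountWeight,
        substitutionPrior = substitutionPrior, scale = scale,
        weighting = weighting, scoreFloor = scoreFloor)
}

.alnMatrix <- function(aln) {
    m <- do.call(rbind, strsplit(alnSequences(aln), ""))
    rownames(m) <- names(alnSequences(aln))
    m
}

#' Per-sequence weights for profile construction
#'
#' Position-based (Henikoff) weighting: every column distributes one unit of
#' mass equally among the residue types present, and each type's share
#' equally among the sequences carrying it; a sequence's raw weight is its
#' summed mass. Raw weights are normalized to sum to the effective sequence
#' count n_eff, taken as the mean number of distinct residue types per
#' column, so that fully redundant alignments collapse toward a single
#' effective sequence. Uniform weighting assigns every sequence weight 1
#' (n_eff equals the sequence count). Gaps and 'X' carry no mass.
#'
#' @param aln A [ProteinAlignment-class].
#' @param scheme \code{"henikoff"} or \code{"uniform"}.
#' @return Numeric vector of positive weights, one per sequence, summing to
#'   the number of effective sequences.
#' @examples
#' aln <- ProteinAlignment(c("ACDE", "ACDE"))
#' sequenceWeights(aln, "henikoff")  # two copies: 0.5 each, n_eff = 1
#' @export
sequenceWeights <- function(aln, scheme = c("henikoff", "uniform")) {
    scheme <- match.arg(scheme)
    n <- length(alnSequences(aln))
    if (scheme == "uniform")
        return(rep(1, n))
    m <- .alnMatrix(aln)
    raw <- numeric(n)
    ntypes <- numeric(0)
    for (j in seq_len(ncol(m))) {
        col <- m[, j]
        keep <- col %in% AMINO_ACIDS
        if (!any(keep)) next
        tt <- table(col[keep])
        r <- length(tt)
        ntypes <- c(ntypes, r)
        raw[keep] <- raw[keep] + 1 / (r * as.numeric(tt[col[keep]]))
    }
    if (length(ntypes) == 0L || all(raw == 0))
        stop("alignment has no residue-bearing columns")
    neff <- mean(ntypes)
    raw / sum(raw) * neff
}

#' Weighted residue frequencies per query position
#'
#' Alignment columns where the query holds a gap are dropped; the remaining
#' columns map one-to-one onto the 1-based positions of the ungapped query.
#' Gaps and 'X' are excluded from the denominator. A column with no residue
#' mass at all (all gaps/'X') yields an all-\code{NA} row and a warning.
#'
#' @param aln A [ProteinAlignment-class].
#' @param weights Per-sequence weights, e.g. from [sequenceWeights()].
#' @return Numeric matrix, query positions x 20 residues, rows summing to 1
#'   (or all \code{NA} where flagged).
#' @export
columnFrequencies <- function(aln, weights) {
    m <- .alnMatrix(aln)
    if (length(weights) != nrow(m))
        stop("weights must match the number of sequences")
    qcols <- which(m[queryIndex(aln), ] != "-")
    out <- matrix(0, length(qcols), 20L,
                  dimnames = list(seq_along(qcols), AMINO_ACIDS))
    for (k in seq_along(qcols)) {
        col <- m[, qcols[k]]
        keep <- col %in% AMINO_ACIDS
        if (!any(keep)) {
            warning("query position ", k,
                    ": column holds no residues (all gaps/'X'); flagged")
            out[k, ] <- NA_real_
            next
        }
        w <- weights[keep]
        f <- vapply(AMINO_ACIDS,
                    function(a) sum(w[col[keep] == a]), numeric(1))
        out[k, ] <- f / sum(f)
    }
    out
}

#' Pseudocount smoothing of observed residue frequencies
#'
#' PSI-BLAST-style mixing: smoothed = (alpha * observed + beta * g) /
#' (alpha + beta) with alpha = n_eff - 1, beta the pseudocount weight, and
#' pseudo-frequencies g(a) = sum_b observed(b) * P(a | b) obtained by
#' pushing the observed frequencies through the conditional substitution
#' prior. With beta = 0 the observed frequencies pass through unchanged;
#' with n_eff = 1 the output is the pseudo-frequency vector alone.
#'
#' @param freqs Numeric 20-vector or positions x 20 matrix of observed
#'   frequencies (rows summing to 1).
#' @param params A [PssmParams-class].
#' @param neff Effective sequence count (>= 1), e.g.
#'   \code{sum(sequenceWeights(aln, scheme))}.
#' @return Smoothed frequencies of the same shape, rows summing to 1.
#' @export
applyPseudocounts <- function(freqs, params, neff) {
    stopifnot(is(params, "PssmParams"), neff >= 1)
    vec <- is.null(dim(freqs))
    f <- if (vec) matrix(freqs, 1L, 20L, dimnames = list(NULL, names(freqs)))
         else freqs
    alpha <- neff - 1
    beta <- params@pseudocountWeight
    if (alpha + beta == 0) {
        out <- f
    } else {
        g <- f %*% params@substitutionPrior   # g[, a] = sum_b f_b P(a|b)
        out <- (alpha * f + beta * g) / (alpha + beta)
    }
    dimnames(out) <- dimnames(f)
    if (vec) out[1L, ] else out
}

.roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Build a position-specific substitution matrix
#'
#' Constructs integer log-odds scores for every residue at every ungapped
#' query position: sequences are weighted ([sequenceWeights()]), weighted
#' column frequencies are smoothed with substitution-prior pseudocounts
#' ([applyPseudocounts()]), and score(pos, a) = round(scale * ln(p(pos, a) /
#' background(a))), rounded half away from zero after scaling. Residues
#' with zero smoothed probability are floored at \code{scoreFloor}.
#' Identical inputs and parameters give bit-identical matrices.
#'
#' @param aln A [ProteinAlignment-class]; sequence \code{queryIndex(aln)}
#'   is the reference whose ungapped coordinates index the matrix.
#' @param params A [PssmParams-class]; default [PssmParams()].
#' @return A [PSSM-class].
#' @examples
#' aln <- ProteinAlignment(c(q = "ACDEF", h1 = "ACDEW", h2 = "ACDEY"))
#' p <- buildPSSM(aln)
#' pssmScores(p)[5, c("F", "W", "Y", "P")]
#' @export
buildPSSM <- function(aln, params = PssmParams()) {
    stopifnot(is(aln, "ProteinAlignment"), is(params, "PssmParams"))
    if (any(params@background == 0))
        stop("configuration error: background frequency of 0")
    w <- sequenceWeights(aln, params@weighting)
    neff <- sum(w)
    f <- columnFrequencies(aln, w)
    sm <- applyPseudocounts(f, params, max(neff, 1))
    flagged <- !stats::complete.cases(sm)
    if (any(flagged))  # no usable residue mass: fall back to background
        sm[flagged, ] <- rep(params@background, each = sum(flagged))
    lo <- params@scale * log(sweep(sm, 2L, params@background, `/`))
    lo[!is.finite(lo)] <- params@scoreFloor
    scores <- .roundHalfAway(lo)
    scores <- pmax(scores, params@scoreFloor)
    mode(scores) <- "integer"
    q <- querySequence(aln)
    dimnames(scores) <- list(seq_len(nchar(q)), AMINO_ACIDS)
    dimnames(sm) <- dimnames(scores)
    new("PSSM", query = q, scores = scores, probs = sm, params = params)
}
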