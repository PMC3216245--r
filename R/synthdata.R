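## Synthetic alignments and mutation panels with known ground truth.

#' Create a generating profile
#'
#' Per-position residue distributions of the form
#' conservation * pointmass(dominant) + (1 - conservation) * uniform,
#' i.e. the dominant residue has probability c + (1 - c)/20 and every other
#' residue (1 - c)/20. Dominant residues are drawn uniformly at random.
#'
#' @param length Number of positions.
#' @param conservation Scalar or per-position vector in [0, 1]; 1 gives a
#'   point mass.
#' @param seed Integer seed for the dominant-residue draw (0 is valid).
#' @return A [GeneratingProfile-class].
#' @examples
#' prof <- makeProfile(10, conservation = 0.9, seed = 1)
#' @export
makeProfile <- function(length, conservation, seed = 0L) {
    stopifnot(length >= 1, all(conservation >= 0 & conservation <= 1))
    conservation <- rep_len(conservation, length)
    set.seed(seed)
    dominant <- sample.int(20L, length, replace = TRUE)
    p <- matrix(rep((1 - conservation) / 20, 20L), length, 20L,
                dimnames = list(seq_len(length), AMINO_ACIDS))
    p[cbind(seq_len(length), dominant)] <-
        p[cbind(seq_len(length), dominant)] + conservation
    new("GeneratingProfile", probs = p, conservation = conservation)
}

#' Sample a synthetic alignment from a generating profile
#'
#' Each sequence is drawn i.i.d. per position from the profile; gaps are
#' then injected independently at \code{gapRate}, never into the query
#' (sequence 1), so the PSSM coordinate system is stable. Deterministic
#' under a fixed seed.
#'
#' @param profile A [GeneratingProfile-class].
#' @param nSequences Number of sequences (>= 1); sequence 1 is the query.
#' @param gapRate Per-cell gap probability in [0, 0.5).
#' @param seed Integer seed (0 is valid).
#' @return A [ProteinAlignment-class] with \code{queryIndex = 1}.
#' @examples
#' aln <- sampleAlignment(makeProfile(20, 0.9, seed = 1), 13, seed = 2)
#' @export
sampleAlignment <- function(profile, nSequences, gapRate = 0, seed = 0L) {
    stopifnot(is(profile, "GeneratingProfile"), nSequences >= 1,
              gapRate >= 0, gapRate < 0.5)
    p <- profileProbs(profile)
    L <- nrow(p)
    set.seed(seed)
    chars <- matrix("", nSequences, L)
    for (j in seq_len(L))
        chars[, j] <- sample(AMINO_ACIDS, nSequences, replace = TRUE,
                             prob = p[j, ])
    if (gapRate > 0 && nSequences > 1L) {
        gap <- matrix(stats::runif((nSequences - 1L) * L) < gapRate,
                      nSequences - 1L, L)
        chars[-1L, ][gap] <- "-"
    }
    seqs <- apply(chars, 1L, paste, collapse = "")
    names(seqs) <- c("query", paste0("homolog", seq_len(nSequences - 1L)))[
        seq_len(nSequences)]
    ProteinAlignment(seqs, queryIndex = 1L)
}

#' Sample a labeled mutation panel with a planted score-response link
#'
#' Draws mutations uniformly over the query positions and non-wild-type
#' residues of a PSSM, looks up their scores, and assigns each a responsive
#' label from Bernoulli(plogis(slope * score + intercept)). A steep slope
#' produces labels perfectly separated by score; slope 0 with a large
#' positive intercept makes every mutation responsive.
#'
#' @param pssm A [PSSM-class].
#' @param n Panel size (>= 1).
#' @param slope,intercept Logistic response model on the integer score.
#' @param seed Integer seed (0 is valid).
#' @return Data frame with columns \code{mutation}, \code{wt},
#'   \code{position}, \code{mut}, \code{pssm_score}, \code{responsive}.
#' @export
sampleMutationPanel <- function(pssm, n, slope = 1, intercept = 0,
                                seed = 0L) {
    stopifnot(is(pssm, "PSSM"), n >= 1)
    q <- strsplit(pssm@query, "")[[1L]]
    set.seed(seed)
    pos <- sample.int(length(q), n, replace = TRUE)
    mut <- vapply(pos, function(i)
        sample(setdiff(AMINO_ACIDS, q[i]), 1L), character(1))
    score <- pssm@scores[cbind(pos, match(mut, AMINO_ACIDS))]
    responsive <- stats::runif(n) < stats::plogis(slope * score + intercept)
    data.frame(mutation = paste0("p.", q[pos], pos, mut),
               wt = q[pos], position = pos, mut = mut,
               pssm_score = as.integer(score), responsive = responsive,
               stringsAsFactors = FALSE)
}
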