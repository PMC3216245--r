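# Independent oracle implementations used to cross-check the package.
# These deliberately share no code with R/: plain loops, no vectorization.

# Naive profile construction from first principles.
naivePSSM <- function(seqs, queryIndex, params) {
    chars <- lapply(seqs, function(s) strsplit(s, "")[[1]])
    n <- length(chars)
    L <- length(chars[[1]])
    aa <- FabryPSSM::AMINO_ACIDS

    # Henikoff/uniform weights, column by column
    if (params@weighting == "uniform") {
        w <- rep(1, n)
        neff <- n
    } else {
        raw <- rep(0, n)
        types_per_col <- c()
        for (j in 1:L) {
            col <- sapply(chars, function(x) x[j])
            res_idx <- which(col %in% aa)
            if (length(res_idx) == 0) next
            types <- unique(col[res_idx])
            types_per_col <- c(types_per_col, length(types))
            for (i in res_idx) {
                n_same <- sum(col[res_idx] == col[i])
                raw[i] <- raw[i] + 1 / (length(types) * n_same)
            }
        }
        neff <- mean(types_per_col)
        w <- raw / sum(raw) * neff
    }

    qchars <- chars[[queryIndex]]
    qcols <- which(qchars != "-")
    alpha <- neff - 1
    beta <- params@pseudocountWeight
    scores <- matrix(NA_integer_, length(qcols), 20,
                     dimnames = list(seq_along(qcols), aa))
    probs <- matrix(NA_real_, length(qcols), 20,
                    dimnames = list(seq_along(qcols), aa))
    for (k in seq_along(qcols)) {
        col <- sapply(chars, function(x) x[qcols[k]])
        f <- rep(0, 20); names(f) <- aa
        tot <- 0
        for (i in 1:n) {
            if (col[i] %in% aa) {
                f[col[i]] <- f[col[i]] + w[i]
                tot <- tot + w[i]
            }
        }
        f <- f / tot
        g <- rep(0, 20); names(g) <- aa
        for (a in aa)
            for (b in aa)
                g[a] <- g[a] + f[b] * params@substitutionPrior[b, a]
        sm <- if (alpha + beta == 0) f else (alpha * f + beta * g) / (alpha + beta)
        probs[k, ] <- sm
        for (a in aa) {
            lo <- params@scale * log(sm[a] / params@background[a])
            if (!is.finite(lo)) lo <- params@scoreFloor
            sc <- sign(lo) * floor(abs(lo) + 0.5)   # half away from zero
            scores[k, a] <- as.integer(max(sc, params@scoreFloor))
        }
    }
    list(scores = scores, probs = probs, weights = w, neff = neff)
}

# Exact two-tailed Fisher p by enumerating every table with the observed
# margins, probabilities from choose() directly.
enumFisherP <- function(a, b, c, d) {
    m <- a + b; n <- c + d; k <- a + c; N <- m + n
    if (m == 0 || n == 0 || k == 0 || b + d == 0) return(1)
    support <- max(0, k - n):min(k, m)
    p <- sapply(support, function(i)
        choose(m, i) * choose(n, k - i) / choose(N, k))
    pobs <- p[match(a, support)]
    sum(p[p <= pobs * (1 + 1e-7)])
}

# Small aligned FASTA written to a temp file.
writeTempFasta <- function(seqs, names = paste0("s", seq_along(seqs))) {
    f <- tempfile(fileext = ".fasta")
    writeLines(as.vector(rbind(paste0(">", names), seqs)), f)
    f
}
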