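test_that("sequence weights behave per the position-based recipe", {
    # two identical sequences: each gets half of every column's unit mass
    twin <- ProteinAlignment(c("ACDE", "ACDE"))
    expect_equal(sequenceWeights(twin, "henikoff"), c(0.5, 0.5))

    # 4x6 toy: one sequence unique at every column gets the maximal weight;
    # raw masses are (1,1,1,3)/6 scaled to n_eff = 2 (oracle: per-column
    # bookkeeping done by hand: shared 'A' gets (1/2)/3, the unique residue 1/2)
    toy <- ProteinAlignment(c("AAAAAA", "AAAAAA", "AAAAAA", "CDEFGH"))
    w <- sequenceWeights(toy, "henikoff")
    expect_equal(w, c(1, 1, 1, 3) / 6 * 2)
    expect_equal(which.max(w), 4L)

    expect_equal(sequenceWeights(toy, "uniform"), rep(1, 4))
})

test_that("column frequencies exclude gaps and X and honor weights", {
    aln <- ProteinAlignment(c(q = "AAA", h1 = "AAX", h2 = "CA-", h3 = "-AC"))
    f <- columnFrequencies(aln, rep(1, 4))
    expect_equal(unname(f[1, "A"]), 2/3)   # column "AAC-"
    expect_equal(unname(f[1, "C"]), 1/3)
    expect_equal(unname(f[2, "A"]), 1)      # fully conserved
    expect_equal(rowSums(f), setNames(rep(1, 3), rownames(f)))

    # weighted column: weights (2,1,1) over residues A, A, C -> f(A) = 3/4
    aln2 <- ProteinAlignment(c("A", "A", "C"))
    f2 <- columnFrequencies(aln2, c(2, 1, 1))
    expect_equal(unname(f2[1, "A"]), 3/4)
})

test_that("pseudocount mixing has the documented limits and formula", {
    params0 <- PssmParams(pseudocountWeight = 0)
    obs <- setNames(c(0.7, 0.3, rep(0, 18)),
                    c("A", "C", setdiff(AMINO_ACIDS, c("A", "C"))))[AMINO_ACIDS]
    expect_equal(applyPseudocounts(obs, params0, neff = 5), obs)

    params <- PssmParams(pseudocountWeight = 10)
    pureA <- setNames(as.numeric(AMINO_ACIDS == "A"), AMINO_ACIDS)
    # n_eff = 1 (alpha = 0): output is the pushed prior alone
    expect_equal(applyPseudocounts(pureA, params, neff = 1),
                 params@substitutionPrior["A", ])
    # beta = 10, n_eff = 11: equal mix, computed by direct formula evaluation
    expected <- (10 * pureA + 10 * params@substitutionPrior["A", ]) / 20
    got <- applyPseudocounts(pureA, params, neff = 11)
    expect_equal(got, expected)
    expect_equal(sum(got), 1, tolerance = 1e-12)
})

test_that("degenerate and uniform-column matrices score as expected", {
    # query-only 'alignment', no smoothing: the observed residue scores
    # round(scale * log(1/bg)); everything unobserved sits at the floor
    params0 <- PssmParams(pseudocountWeight = 0, weighting = "uniform")
    p <- buildPSSM(ProteinAlignment(c(q = "AW")), params0)
    expect_equal(pssmScores(p)[1, "A"],
                 round(params0@scale * log(1 / params0@background["A"])),
                 ignore_attr = TRUE)
    expect_true(all(pssmScores(p)[1, AMINO_ACIDS != "A"] == -16L))
    expect_true(all(pssmScores(p)[2, AMINO_ACIDS != "W"] == -16L))

    # every column holding all 20 residues once, uniform background: log(1) = 0
    paramsU <- PssmParams(
        background = setNames(rep(0.05, 20), AMINO_ACIDS),
        pseudocountWeight = 0, weighting = "uniform")
    aln20 <- ProteinAlignment(setNames(AMINO_ACIDS, paste0("s", 1:20)))
    p20 <- buildPSSM(aln20, paramsU)
    expect_true(all(pssmScores(p20) == 0L))
})

test_that("construction matches a naive loop-based oracle row for row", {
    prof <- makeProfile(50, runif(50, 0.5, 0.95), seed = 11)
    aln <- sampleAlignment(prof, 13, gapRate = 0.08, seed = 12)
    for (scheme in c("henikoff", "uniform")) {
        params <- PssmParams(weighting = scheme)
        p <- buildPSSM(aln, params)
        oracle <- naivePSSM(alnSequences(aln), queryIndex(aln), params)
        expect_equal(unname(sequenceWeights(aln, scheme)),
                     unname(oracle$weights), tolerance = 1e-12)
        expect_identical(unname(pssmScores(p)), unname(oracle$scores))
        expect_equal(unname(pssmProbs(p)), unname(oracle$probs),
                     tolerance = 1e-12)
    }
})

test_that("identical inputs give bit-identical matrices", {
    prof <- makeProfile(20, 0.9, seed = 3)
    aln <- sampleAlignment(prof, 10, gapRate = 0.05, seed = 4)
    expect_identical(pssmScores(buildPSSM(aln)), pssmScores(buildPSSM(aln)))
})

test_that("raising a residue's observed frequency never lowers its score", {
    params <- PssmParams(weighting = "uniform")
    # columns with k of 12 sequences carrying W, the rest A
    scoreW <- sapply(0:12, function(k) {
        seqs <- c(rep("W", k), rep("A", 12 - k))
        aln <- ProteinAlignment(setNames(seqs, paste0("s", 1:12)),
                                queryIndex = 1L)
        pssmScores(buildPSSM(aln, params))[1, "W"]
    })
    expect_true(all(diff(scoreW) >= 0))
    # observed in all homologs never scores below a residue observed in none
    expect_gt(scoreW[13], scoreW[1])
})

test_that("query gap columns are dropped from the coordinate system", {
    aln <- ProteinAlignment(c(q = "AC-DE", h1 = "ACWDE", h2 = "ACW-E"))
    p <- buildPSSM(aln)
    expect_equal(querySequence(p), "ACDE")
    expect_equal(nrow(pssmScores(p)), 4)
})
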