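test_that("aligned FASTA is read, normalized and validated", {
    f <- writeTempFasta(c("acd.efghik", "ACD-EFGHIK", "ACDWEFGHIK"))
    aln <- readAlignment(f, "fasta")
    expect_s4_class(aln, "ProteinAlignment")
    expect_length(alnSequences(aln), 3)
    expect_equal(alnWidth(aln), 10)
    # '.' gaps normalized, residues uppercased
    expect_equal(unname(alnSequences(aln)[1]), "ACD-EFGHIK")
    expect_equal(querySequence(aln), "ACDEFGHIK")

    ragged <- writeTempFasta(c("ACDEF", "ACD", "ACDEF"))
    expect_error(readAlignment(ragged, "fasta"), "record 2")
    empty <- tempfile(); file.create(empty)
    expect_error(readAlignment(empty, "fasta"), "empty|no sequences")
})

test_that("Stockholm input yields only '-' gaps", {
    f <- tempfile(fileext = ".sto")
    writeLines(c("# STOCKHOLM 1.0",
                 "seq1 ACD.EF",
                 "seq2 ACDWEF",
                 "seq3 AC..EF",
                 "//"), f)
    aln <- readAlignment(f, "stockholm")
    expect_false(any(grepl(".", alnSequences(aln), fixed = TRUE)))
    expect_equal(unname(alnSequences(aln)[3]), "AC--EF")
})

test_that("mutation notation parses in one- and three-letter form", {
    m <- parseMutation("p.A230T")
    expect_equal(mutationWt(m), "A")
    expect_equal(mutationPosition(m), 230L)
    expect_equal(mutationMut(m), "T")
    m3 <- parseMutation("p.Ala230Thr")
    expect_equal(formatMutation(m3), "p.A230T")
    # whitespace and missing "p." prefix tolerated
    expect_equal(formatMutation(parseMutation(" L300F ")), "p.L300F")

    expect_error(parseMutation("p.L166"), "no mutant residue")
    expect_error(parseMutation("p.A230A"), "identical")
    expect_error(parseMutation("p.B230T"), "unknown")
    expect_error(parseMutation("p.AT"), "parse")
})

test_that("formatting a parsed mutation is canonical (left inverse)", {
    cases <- c("p.A230T", "A230T", "p.Ala230Thr", " p.Q280K", "p.arg301pro")
    canon <- c("p.A230T", "p.A230T", "p.A230T", "p.Q280K", "p.R301P")
    for (i in seq_along(cases))
        expect_equal(formatMutation(parseMutation(cases[i])), canon[i])
})

test_that("packaged panel fixtures load with locked counts and values", {
    t1 <- loadFixtureTable("table1")
    expect_equal(nrow(t1), 9)
    l310 <- t1[t1$mutation == "p.L310F", ]
    expect_equal(l310$fold_increase, 8.9)
    expect_equal(l310$pssm_score, 0L)
    # phenotype "?" for L300F maps to missing
    expect_true(is.na(t1$phenotype[t1$mutation == "p.L300F"]))

    t2 <- loadFixtureTable("table2")
    expect_equal(nrow(t2), 19)
    c142 <- t2[t2$mutation == "p.C142W", ]
    expect_equal(c142$pssm_score, -7L)
    expect_false(c142$responsive)
    expect_equal(sum(t2$responsive), 11)
    expect_equal(sum(!t2$responsive), 8)
    # NA annotation cells stay missing, never zero
    a20 <- t2[t2$position == 20, ]
    expect_true(is.na(a20$sdm) && is.na(a20$psa_mc) && is.na(a20$sec_stru))
    # incompletely reported p.L166: score kept, mutant residue missing
    l166 <- t2[t2$position == 166, ]
    expect_true(is.na(l166$mut))
    expect_equal(l166$pssm_score, 0L)

    t3 <- loadFixtureTable("table3")
    expect_equal(nrow(t3), 10)
    expect_true(all(grepl("^[ACGT]+$", t3$forward)))
})

test_that("PSSM ASCII round trip preserves scores and query exactly", {
    aln <- ProteinAlignment(c(q = "MKT", h1 = "MRT", h2 = "MKS"))
    p <- buildPSSM(aln)
    f <- tempfile()
    writePSSM(p, f)
    p2 <- readPSSM(f)
    expect_identical(pssmScores(p2), pssmScores(p))
    expect_identical(querySequence(p2), querySequence(p))

    # a file with 19 score columns is rejected
    lines <- readLines(f)
    bad <- tempfile()
    writeLines(sapply(strsplit(lines, "\t"),
                      function(x) paste(x[-length(x)], collapse = "\t")), bad)
    expect_error(readPSSM(bad), "20")
})

test_that("the sparse fixture score table answers published lookups", {
    st <- fixtureScoreTable()
    expect_equal(nrow(st), 27)  # 28 printed scores minus incomplete p.L166
    expect_equal(scoreMutation(st, "p.A230T"), 0L)
    expect_equal(scoreMutation(st, "p.C142W"), -7L)
})
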