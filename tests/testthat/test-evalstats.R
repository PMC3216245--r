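test_that("literature panel bins reproduce the published zone counts", {
    bins <- binByScore(loadFixtureTable("table2"))
    z <- bins$zones
    expect_equal(z$n_responsive, c(5L, 4L, 2L))
    expect_equal(z$n_total, c(5L, 6L, 8L))
    # zone totals account for every labeled record
    expect_equal(sum(z$n_total), 19)
    expect_equal(sum(bins$perScore$n_total), 19)
    # response rate falls with distance below the threshold
    expect_gt(z$pct_responsive[1], z$pct_responsive[3])
})

test_that("records without labels are excluded with a warning", {
    panel <- data.frame(pssm_score = c(0L, -3L, -1L),
                        responsive = c(TRUE, FALSE, NA))
    expect_warning(bins <- binByScore(panel), "excluded")
    expect_equal(sum(bins$zones$n_total), 2)
})

test_that("predicted-positive response rate matches the published figures", {
    t1 <- loadFixtureTable("table1")
    t2 <- loadFixtureTable("table2")
    pooled <- rbind(t1[c("pssm_score", "responsive")],
                    t2[c("pssm_score", "responsive")])
    ppr <- predictedPositiveRate(pooled, "three_zone")
    expect_equal(ppr$k, 12L)
    expect_equal(ppr$n, 14L)
    expect_equal(round(ppr$pct), 86)

    # the newly tested panel alone: all nine score 0 or -1, all predicted
    ppr1 <- predictedPositiveRate(t1, "three_zone")
    expect_equal(ppr1$n, 9L)
    expect_equal(ppr1$k, 7L)

    all_resp <- data.frame(pssm_score = c(0L, 1L), responsive = TRUE)
    expect_equal(predictedPositiveRate(all_resp)$pct, 100)
    none_pos <- data.frame(pssm_score = -5L, responsive = FALSE)
    expect_error(predictedPositiveRate(none_pos), "undefined")
})

test_that("Fisher exact test matches enumeration, symmetry and edge cases", {
    # frozen oracle value, computed by hypergeometric enumeration
    expect_equal(fisherExact(matrix(c(1, 11, 9, 3), 2)), 0.002759456,
                 tolerance = 1e-6)
    # zero margin: a single possible table
    expect_equal(fisherExact(matrix(c(0, 0, 5, 7), 2)), 1)
    # transpose invariance
    m <- matrix(c(4, 2, 1, 8), 2)
    expect_equal(fisherExact(m), fisherExact(t(m)))

    # property: agreement with brute-force enumeration (and fisher.test)
    # over random tables with N <= 60
    set.seed(7)
    for (rep in 1:60) {
        x <- as.integer(rmultinom(1, sample(4:60, 1), rep(0.25, 4)))
        tab <- matrix(x, 2)
        p <- fisherExact(tab)
        expect_equal(p, enumFisherP(x[1], x[3], x[2], x[4]),
                     tolerance = 1e-10)
        expect_equal(p, stats::fisher.test(tab)$p.value, tolerance = 1e-8)
    }
})

test_that("Pearson correlation matches the t-test formula and cor.test", {
    expect_equal(pearsonR(1:5, 2 * (1:5) + 3)$r, 1.0)
    expect_equal(pearsonR(c(0, 1, 2), c(0, 1, 0))$r, 0)

    x <- c(-4, -3, -2, -1, 0, 1)
    y <- c(0, 14, 33, 67, 95, 100)
    got <- pearsonR(x, y)
    ct <- stats::cor.test(x, y)
    expect_equal(got$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(got$p, ct$p.value, tolerance = 1e-12)

    # affine invariance (sign-preserving) of r and p
    got2 <- pearsonR(10 * x + 7, 0.2 * y - 3)
    expect_equal(got2$r, got$r, tolerance = 1e-12)
    expect_equal(got2$p, got$p, tolerance = 1e-12)

    expect_error(pearsonR(c(1, 1, 1), c(1, 2, 3)), "zero variance")
    expect_error(pearsonR(1:2, 2:3), "3 points")
})

test_that("accuracy counts hits under the chosen rule and twilight policy", {
    perfect <- data.frame(pssm_score = c(0L, -5L), responsive = c(TRUE, FALSE))
    expect_equal(panelAccuracy(perfect), 100)

    # literature panel, binary rule: hand enumeration gives TP = 5
    # (S65T, M72V, A156V, L166, M290L) and TN = 8 over all 19 labeled,
    # scored records -> 100 * 13/19
    t2 <- loadFixtureTable("table2")
    expect_equal(panelAccuracy(t2, "binary_ge_minus1"), 100 * 13 / 19)
    # twilight-as-non-responsive coincides with the binary rule
    expect_equal(panelAccuracy(t2, "three_zone", "non_responsive"),
                 panelAccuracy(t2, "binary_ge_minus1"))
    # excluding the six twilight records: TP = 5, TN = 6 of 13
    expect_equal(panelAccuracy(t2, "three_zone", "exclude"), 100 * 11 / 13)

    expect_error(panelAccuracy(data.frame(pssm_score = integer(),
                                          responsive = logical())),
                 "empty")
})
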