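## Re-derives the published validation numbers from the packaged panels.

.roundHalfAwayInt <- function(x) as.integer(sign(x) * floor(abs(x) + 0.5))

#' Recompute the published validation numbers from the packaged panels
#'
#' Loads the two packaged AGAL mutation panels and recomputes, from the
#' records alone: the responsive counts of the literature panel, the
#' response rate per decision zone, the pooled predicted-positive response
#' rate, the count of newly tested mutations clearing the 15\% activity
#' rule, and the agreement of [scoreMutation()] lookups with every fully
#' specified printed score. Each quantity is compared with its published
#' value; percentages are rounded half away from zero before comparison, as
#' printed.
#'
#' @param rule Classification rule for the predicted-positive rate.
#' @return List with \code{checklist} (data frame: check, observed,
#'   expected, pass), \code{zones} (the literature-panel zone table) and
#'   \code{perScore} (response rate by integer score on the pooled panels,
#'   the in-package analogue of the published score-response curve).
#' @examples
#' rep <- reproducePaper()
#' rep$checklist
#' @export
reproducePaper <- function(rule = "three_zone") {
    t1 <- loadFixtureTable("table1")
    t2 <- loadFixtureTable("table2")
    pooled <- rbind(t1[c("pssm_score", "responsive")],
                    t2[c("pssm_score", "responsive")])

    zones <- binByScore(t2)$zones
    ppr <- predictedPositiveRate(pooled, rule)
    st <- fixtureScoreTable()
    lookups <- vapply(seq_len(nrow(st)), function(i) {
        m <- new("MissenseMutation", wt = st$wt[i],
                 position = st$position[i], mut = st$mut[i],
                 cdna = NA_character_)
        scoreMutation(st, m) == st$score[i]
    }, logical(1))

    checklist <- data.frame(
        check = c(
            "literature panel: responsive count",
            "literature panel: non-responsive count",
            "zone > -2: responsive / total",
            "zone == -2: responsive / total",
            "zone < -2: responsive / total",
            "pooled predicted-positive: responsive / predicted",
            "pooled predicted-positive: percent responsive (rounded)",
            "new panel: responsive under 15% activity rule",
            "score lookups matching printed values"),
        observed = c(
            sum(t2$responsive), sum(!t2$responsive),
            sprintf("%d/%d", zones$n_responsive[1], zones$n_total[1]),
            sprintf("%d/%d", zones$n_responsive[2], zones$n_total[2]),
            sprintf("%d/%d", zones$n_responsive[3], zones$n_total[3]),
            sprintf("%d/%d", ppr$k, ppr$n),
            .roundHalfAwayInt(ppr$pct),
            sum(t1$responsive),
            sprintf("%d/%d", sum(lookups), length(lookups))),
        expected = c("11", "8", "5/5", "4/6", "2/8", "12/14", "86", "7",
                     sprintf("%d/%d", length(lookups), length(lookups))),
        stringsAsFactors = FALSE)
    checklist$pass <- checklist$observed == checklist$expected

    list(checklist = checklist, zones = zones,
         perScore = binByScore(pooled)$perScore)
}
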