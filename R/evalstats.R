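## Panel evaluation: score-bin response rates, exact Fisher test, Pearson
## correlation, classification accuracy.

.checkPanel <- function(records) {
    stopifnot(is.data.frame(records),
              all(c("pssm_score", "responsive") %in% names(records)))
    drop <- is.na(records$responsive) | is.na(records$pssm_score)
    if (any(drop)) {
        warning(sum(drop), " record(s) without a responsiveness label or ",
                "score excluded")
        records <- records[!drop, ]
    }
    records
}

#' Bin a mutation panel by PSSM score
#'
#' Counts responsive and total mutations per integer score, and aggregated
#' over the three decision zones (score > -2, score == -2, score < -2).
#' Records lacking a responsiveness label are excluded with a warning.
#'
#' @param records Data frame with integer \code{pssm_score} and logical
#'   \code{responsive} columns, e.g. from [loadFixtureTable()].
#' @return List with two data frames: \code{perScore} (score,
#'   n_responsive, n_total, pct_responsive) and \code{zones} (zone,
#'   n_responsive, n_total, pct_responsive).
#' @examples
#' binByScore(loadFixtureTable("table2"))$zones
#' @export
binByScore <- function(records) {
    records <- .checkPanel(records)
    s <- records$pssm_score
    r <- records$responsive
    scores <- sort(unique(s))
    perScore <- data.frame(
        score = scores,
        n_responsive = vapply(scores, function(k) sum(r[s == k]), integer(1)),
        n_total = vapply(scores, function(k) sum(s == k), integer(1)))
    perScore$pct_responsive <- 100 * perScore$n_responsive / perScore$n_total
    zone <- factor(classifyScore(s, "three_zone"),
                   levels = c("responsive", "twilight", "non_responsive"))
    zones <- data.frame(
        zone = c("score > -2", "score == -2", "score < -2"),
        n_responsive = as.integer(tapply(r, zone, sum, default = 0L)),
        n_total = as.integer(table(zone)))
    zones$pct_responsive <- ifelse(zones$n_total > 0,
                                   100 * zones$n_responsive / zones$n_total,
                                   NA_real_)
    list(perScore = perScore, zones = zones)
}

#' Response rate among mutations predicted responsive
#'
#' Applies a classification rule to the panel's scores and reports how many
#' of the predicted-responsive mutations were actually responsive.
#'
#' @param records Data frame with \code{pssm_score} and \code{responsive}.
#' @param rule See [classifyScore()].
#' @return List: \code{k} (responsive among predicted positive), \code{n}
#'   (predicted positive), \code{pct} (100 k / n).
#' @examples
#' panel <- rbind(loadFixtureTable("table1")[c("pssm_score", "responsive")],
#'                loadFixtureTable("table2")[c("pssm_score", "responsive")])
#' predictedPositiveRate(panel)
#' @export
predictedPositiveRate <- function(records,
                                  rule = c("three_zone", "binary_ge_minus1")) {
    rule <- match.arg(rule)
    records <- .checkPanel(records)
    pos <- classifyScore(records$pssm_score, rule) == "responsive"
    n <- sum(pos)
    if (n == 0L)
        stop("no predicted-responsive records: rate undefined")
    k <- sum(records$responsive[pos])
    list(k = as.integer(k), n = as.integer(n), pct = 100 * k / n)
}

#' Two-tailed Fisher exact test for a 2 x 2 table
#'
#' Exact p-value under the hypergeometric null with fixed margins, using
#' the standard two-sided convention: the probabilities of all tables no
#' more likely than the observed one are summed. Probabilities are computed
#' with log-factorials for numerical stability; a table with a zero margin
#' admits a single configuration and returns p = 1.
#'
#' @param table 2 x 2 matrix (or length-4 vector, column-major) of
#'   non-negative integer counts.
#' @return Two-tailed p-value in [0, 1].
#' @examples
#' fisherExact(matrix(c(1, 11, 9, 3), 2))
#' @export
fisherExact <- function(table) {
    x <- as.vector(table)
    stopifnot(length(x) == 4L, all(x >= 0), all(x == round(x)))
    a <- x[1L]; c_ <- x[2L]; b <- x[3L]; d <- x[4L]
    m <- a + b            # first row total
    n <- c_ + d           # second row total
    k <- a + c_           # first column total
    if (m == 0 || n == 0 || k == 0 || b + d == 0)
        return(1)
    support <- max(0, k - n):min(k, m)
    logp <- function(i) {
        lgamma(m + 1) - lgamma(i + 1) - lgamma(m - i + 1) +
        lgamma(n + 1) - lgamma(k - i + 1) - lgamma(n - k + i + 1) -
        (lgamma(m + n + 1) - lgamma(k + 1) - lgamma(m + n - k + 1))
    }
    lp <- vapply(support, logp, numeric(1))
    p <- exp(lp)
    pobs <- exp(logp(a))
    min(1, sum(p[p <= pobs * (1 + 1e-7)]))
}

#' Pearson correlation with two-tailed t-test p-value
#'
#' Sample correlation r of the supplied points and the p-value of
#' t = r * sqrt((n - 2) / (1 - r^2)) against the t distribution with n - 2
#' degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero variance.
#' @return List: \code{r}, \code{p}, \code{n}.
#' @examples
#' pearsonR(-4:1, c(0, 14, 25, 67, 100, 100))
#' @export
pearsonR <- function(x, y) {
    stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
    n <- length(x)
    if (n < 3L)
        stop("need at least 3 points")
    if (stats::var(x) == 0 || stats::var(y) == 0)
        stop("undefined correlation: zero variance")
    r <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    if (abs(r) >= 1) {
        p <- 0
    } else {
        t <- r * sqrt((n - 2) / (1 - r^2))
        p <- 2 * stats::pt(-abs(t), df = n - 2)
    }
    list(r = r, p = p, n = n)
}

#' Classification accuracy of score-based calls against observed labels
#'
#' 100 * (TP + TN) / N where predictions come from [classifyScore()] and
#' truth from the panel's \code{responsive} labels. Twilight calls under
#' the three-zone rule are resolved by \code{twilightPolicy}: counted as
#' non-responsive (default, conservative), as responsive, or excluded.
#'
#' @param records Data frame with \code{pssm_score} and \code{responsive}.
#' @param rule See [classifyScore()].
#' @param twilightPolicy \code{"non_responsive"}, \code{"responsive"} or
#'   \code{"exclude"}.
#' @return Accuracy as a percentage.
#' @export
panelAccuracy <- function(records,
                          rule = c("three_zone", "binary_ge_minus1"),
                          twilightPolicy = c("non_responsive", "responsive",
                                             "exclude")) {
    rule <- match.arg(rule)
    twilightPolicy <- match.arg(twilightPolicy)
    records <- .checkPanel(records)
    if (nrow(records) == 0L)
        stop("empty panel: accuracy undefined")
    call <- classifyScore(records$pssm_score, rule)
    if (twilightPolicy == "exclude") {
        keep <- call != "twilight"
        call <- call[keep]
        records <- records[keep, ]
        if (nrow(records) == 0L)
            stop("no records left after excluding twilight calls")
    } else {
        call[call == "twilight"] <- twilightPolicy
    }
    pred <- call == "responsive"
    100 * mean(pred == records$responsive)
}
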