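## Sequence, PSSM and fixture I/O.

#' Construct a ProteinAlignment
#'
#' @param sequences Character vector of aligned residue strings (optionally
#'   named); gaps may be \code{-} or \code{.}, case is ignored.
#' @param queryIndex Index of the query (reference) sequence.
#' @return A validated [ProteinAlignment-class]; gap characters are
#'   normalized to \code{-} and residues uppercased.
#' @examples
#' aln <- ProteinAlignment(c(q = "AC-DE", h1 = "ACYDE"), queryIndex = 1)
#' querySequence(aln)
#' @export
ProteinAlignment <- function(sequences, queryIndex = 1L) {
    if (length(sequences) == 0L)
        stop("empty input: no sequences")
    if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
        names(sequences) <- paste0("seq", seq_along(sequences))
    sequences <- chartr(".", "-", toupper(sequences))
    w <- nchar(sequences)
    if (any(w != w[1L])) {
        bad <- which(w != w[1L])[1L]
        stop(sprintf(
            "ragged alignment: record %d ('%s') has length %d, expected %d",
            bad, names(sequences)[bad], w[bad], w[1L]))
    }
    new("ProteinAlignment", sequences = sequences,
        queryIndex = as.integer(queryIndex))
}

#' Read a protein multiple sequence alignment
#'
#' Reads an aligned FASTA or Stockholm file into a [ProteinAlignment-class].
#' Gap characters \code{.} are normalized to \code{-} and residues
#' uppercased. Ragged FASTA input raises an error naming the offending
#' record.
#'
#' @param path Path to the alignment file.
#' @param format \code{"fasta"} or \code{"stockholm"}.
#' @param queryIndex Index of the query (reference) sequence; default the
#'   first record.
#' @return A [ProteinAlignment-class].
#' @export
readAlignment <- function(path, format = c("fasta", "stockholm"),
                          queryIndex = 1L) {
    format <- match.arg(format)
    if (!file.exists(path))
        stop("file not found: ", path)
    if (format == "fasta") {
        ss <- Biostrings::readBStringSet(path, format = "fasta")
        if (length(ss) == 0L)
            stop("empty input: no sequences in ", path)
        seqs <- stats::setNames(as.character(ss), names(ss))
    } else {
        ma <- Biostrings::readAAMultipleAlignment(path, format = "stockholm")
        ss <- as(ma, "AAStringSet")
        if (length(ss) == 0L)
            stop("empty input: no sequences in ", path)
        seqs <- stats::setNames(as.character(ss), names(ss))
    }
    ProteinAlignment(seqs, queryIndex = queryIndex)
}

#' Write a ProteinAlignment as aligned FASTA
#'
#' @param aln A [ProteinAlignment-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
writeAlignment <- function(aln, path) {
    stopifnot(is(aln, "ProteinAlignment"))
    ss <- Biostrings::BStringSet(alnSequences(aln))
    Biostrings::writeXStringSet(ss, filepath = path)
    invisible(path)
}

.parseResidue <- function(code, what) {
    if (nchar(code) == 1L) {
        r <- toupper(code)
        if (!r %in% AMINO_ACIDS)
            stop(sprintf("unknown %s residue code '%s'", what, code))
        return(r)
    }
    r <- .AA3[match(tolower(code), tolower(names(.AA3)))]
    if (is.na(r))
        stop(sprintf("unknown %s residue code '%s'", what, code))
    unname(r)
}

#' Parse HGVS-style protein mutation notation
#'
#' Accepts "p.A230T", "A230T" and three-letter forms such as
#' "p.Ala230Thr"; internal whitespace is tolerated. A missing mutant
#' residue (e.g. "p.L166") or identical wild-type and mutant residues is an
#' error.
#'
#' @param text Mutation string.
#' @param cdna Optional cDNS notation ("c.688G>A") to attach; not validated
#'   against any transcript.
#' @return A [MissenseMutation-class].
#' @examples
#' parseMutation("p.A230T")
#' parseMutation("p.Ala230Thr")
#' @export
parseMutation <- function(text, cdna = NA_character_) {
    s <- gsub("[[:space:]]", "", text)
    s <- sub("^p\\.", "", s)
    m <- regmatches(s, regexec("^([A-Za-z]{1,3})([0-9]+)([A-Za-z]{0,3})$", s))[[1L]]
    if (length(m) == 0L)
        stop("cannot parse mutation notation: '", text, "'")
    if (!nzchar(m[3L]))
        stop("cannot parse mutation notation: '", text, "' (missing position)")
    if (!nzchar(m[4L]))
        stop("no mutant residue in '", text, "'")
    wt <- .parseResidue(m[2L], "wild-type")
    mut <- .parseResidue(m[4L], "mutant")
    if (wt == mut)
        stop("wild-type and mutant residues are identical in '", text, "'")
    if (!is.na(cdna)) cdna <- gsub("[[:space:]]", "", cdna)
    new("MissenseMutation", wt = wt, position = as.integer(m[3L]),
        mut = mut, cdna = as.character(cdna))
}

#' Canonical protein notation for a mutation
#'
#' Left inverse of [parseMutation()]: formatting a parsed mutation yields
#' the canonical one-letter form.
#'
#' @param mutation A [MissenseMutation-class].
#' @return String such as "p.A230T" ("p.L166" when the mutant residue is
#'   missing).
#' @export
formatMutation <- function(mutation) {
    stopifnot(is(mutation, "MissenseMutation"))
    paste0("p.", mutation@wt, mutation@position,
           ifelse(is.na(mutation@mut), "", mutation@mut))
}

## fixture bookkeeping: row counts and md5 sums lock the transcriptions
.FIXTURES <- list(
    table1 = list(file = "table1_cos7_panel.tsv", rows = 9L,
                  md5 = "975dfded0aaed5029a3328dd377fa642"),
    table2 = list(file = "table2_literature_panel.tsv", rows = 19L,
                  md5 = "a887d5ef01b5406435842581e44b96cc"),
    table3 = list(file = "table3_mutagenesis_primers.tsv", rows = 11L,
                  md5 = "6d902be91b667093a2f10450b8d97f27"))

.fixturePath <- function(name) {
    system.file("extdata", .FIXTURES[[name]]$file, package = "FabryPSSM",
                mustWork = TRUE)
}

#' Load a packaged mutation-panel or primer fixture
#'
#' The package ships transcriptions of two published AGAL mutation panels
#' and the site-directed mutagenesis primer table:
#' \describe{
#'   \item{table1}{9 mutations expressed in COS-7 cells, with DGJ fold
#'     increase, PSSM score, stability and structure annotations, and the
#'     responsiveness call under the 15\%-of-wild-type activity rule (all
#'     responsive except A230T and E341D).}
#'   \item{table2}{19 mutations gathered from the literature with the same
#'     annotations plus the reported responsiveness (11 responsive, 8 not).
#'     The incompletely reported p.L166 keeps its printed score but has a
#'     missing mutant residue.}
#'   \item{table3}{10 primer pairs (the two outermost cloning oligos are
#'     combined into one pair).}
#' }
#' File integrity is verified against stored MD5 sums and row counts.
#'
#' @param name One of \code{"table1"}, \code{"table2"}, \code{"table3"}.
#' @return For the mutation panels, a data frame with one row per mutation:
#'   \code{mutation} (canonical notation), \code{wt}, \code{position},
#'   \code{mut} (\code{NA} for p.L166), \code{cdna}, \code{pssm_score}
#'   (integer), \code{mupro}, \code{sdm}, \code{psa_mc}, \code{psa_sc},
#'   \code{sec_stru}, \code{domain}, \code{active_site} (logical),
#'   \code{phenotype} (table1 only), \code{fold_increase} (table1 only),
#'   \code{responsive} (logical) and \code{source}. For table3, a data
#'   frame of primer pairs.
#' @examples
#' t2 <- loadFixtureTable("table2")
#' sum(t2$responsive)
#' @export
loadFixtureTable <- function(name = c("table1", "table2", "table3")) {
    name <- match.arg(name)
    fx <- .FIXTURES[[name]]
    path <- .fixturePath(name)
    md5 <- unname(tools::md5sum(path))
    if (!identical(md5, fx$md5))
        stop("fixture integrity failure for ", fx$file,
             ": checksum mismatch (expected ", fx$md5, ", got ", md5, ")")
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             na.strings = "NA")
    if (nrow(tab) != fx$rows)
        stop("fixture integrity failure for ", fx$file, ": expected ",
             fx$rows, " rows, got ", nrow(tab))
    if (name == "table3") {
        outer <- data.frame(
            pair = "outer_cloning",
            forward = tab$forward[tab$oligo == "ECOR1_FORWARD"],
            reverse = tab$reverse[tab$oligo == "XHO1_REVERSE"],
            stringsAsFactors = FALSE)
        mut <- tab[!tab$oligo %in% c("ECOR1_FORWARD", "XHO1_REVERSE"), ]
        return(rbind(outer, data.frame(pair = mut$oligo,
                                       forward = mut$forward,
                                       reverse = mut$reverse,
                                       stringsAsFactors = FALSE)))
    }
    parsed <- lapply(tab$amino_acid, function(s) {
        tryCatch(parseMutation(s), error = function(e) {
            # incompletely reported mutation (no target residue): keep the
            # wild-type residue and position, mutant residue missing
            m <- regmatches(s, regexec("^p\\.([A-Za-z])([0-9]+)$", s))[[1L]]
            if (length(m) == 0L) stop(e)
            new("MissenseMutation", wt = toupper(m[2L]),
                position = as.integer(m[3L]), mut = NA_character_,
                cdna = NA_character_)
        })
    })
    out <- data.frame(
        mutation = vapply(parsed, formatMutation, character(1)),
        wt = vapply(parsed, function(m) m@wt, character(1)),
        position = vapply(parsed, function(m) m@position, integer(1)),
        mut = vapply(parsed, function(m) m@mut, character(1)),
        cdna = tab$nucleotide,
        pssm_score = as.integer(tab$pssm),
        mupro = tab$mupro,
        sdm = tab$sdm,
        psa_mc = tab$psa_mc,
        psa_sc = tab$psa_sc,
        sec_stru = tab$sec_stru,
        domain = tab$domain,
        active_site = tab$active_site == "Yes",
        stringsAsFactors = FALSE)
    if (name == "table1") {
        out$phenotype <- tab$phenotype
        out$fold_increase <- tab$fold_increase
        if (any(!is.na(out$fold_increase) & out$fold_increase <= 0))
            stop("fixture integrity failure: non-positive fold increase")
    }
    out$responsive <- tab$responsive == "Yes"
    out$source <- name
    out
}

#' Sparse score table of the published per-mutation PSSM values
#'
#' Realizes the printed PSSM column of the two packaged panels as a sparse
#' lookup table usable by [scoreMutation()]: one row per fully specified
#' mutation with its position, wild-type residue, mutant residue and
#' integer score. The incompletely reported p.L166 is excluded.
#'
#' @return Data frame with columns \code{position}, \code{wt}, \code{mut},
#'   \code{score}.
#' @examples
#' st <- fixtureScoreTable()
#' scoreMutation(st, parseMutation("p.A230T"))
#' @export
fixtureScoreTable <- function() {
    recs <- rbind(
        loadFixtureTable("table1")[c("position", "wt", "mut", "pssm_score")],
        loadFixtureTable("table2")[c("position", "wt", "mut", "pssm_score")])
    recs <- recs[!is.na(recs$mut), ]
    data.frame(position = recs$position, wt = recs$wt, mut = recs$mut,
               score = recs$pssm_score, row.names = NULL,
               stringsAsFactors = FALSE)
}

#' Write a PSSM as an ASCII table
#'
#' NCBI-style layout: a header line of the 20 residue letters, then one row
#' per query position holding the 1-based index, the query residue and 20
#' integer scores. Probabilities and parameters are not serialized; a
#' read-back matrix carries the scores and query only.
#'
#' @param pssm A [PSSM-class].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [readPSSM()]
#' @export
writePSSM <- function(pssm, path) {
    stopifnot(is(pssm, "PSSM"))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste(c("pos", "res", AMINO_ACIDS), collapse = "\t"), con)
    qres <- strsplit(pssm@query, "")[[1L]]
    for (i in seq_len(nrow(pssm@scores)))
        writeLines(paste(c(i, qres[i], pssm@scores[i, ]), collapse = "\t"),
                   con)
    invisible(path)
}

#' Read a PSSM from an ASCII table
#'
#' @param path Path to a file written by [writePSSM()] (or any table in the
#'   same layout).
#' @return A [PSSM-class] with integer scores and query; probabilities are
#'   \code{NA} and params \code{NULL}.
#' @export
readPSSM <- function(path) {
    if (!file.exists(path))
        stop("file not found: ", path)
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) < 2L)
        stop("malformed PSSM file: no data rows in ", path)
    header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
    if (length(header) != 22L || !identical(header[-(1:2)], AMINO_ACIDS))
        stop("malformed PSSM file: expected 20 residue score columns, got ",
             length(header) - 2L)
    rows <- strsplit(lines[-1L], "\t", fixed = TRUE)
    bad <- which(lengths(rows) != 22L)
    if (length(bad))
        stop("malformed PSSM file: row ", bad[1L], " has ",
             lengths(rows)[bad[1L]] - 2L, " score columns, expected 20")
    qres <- vapply(rows, `[`, character(1), 2L)
    scores <- t(vapply(rows,
                       function(r) as.integer(r[3:22]), integer(20)))
    colnames(scores) <- AMINO_ACIDS
    rownames(scores) <- seq_len(nrow(scores))
    probs <- matrix(NA_real_, nrow(scores), 20L,
                    dimnames = dimnames(scores))
    new("PSSM", query = paste(qres, collapse = ""), scores = scores,
        probs = probs, params = NULL)
}
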