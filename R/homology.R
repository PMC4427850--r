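#' Optimal local alignment of two protein sequences
#'
#' Smith-Waterman local alignment under affine gap penalties (a gap of
#' length g costs \code{gapOpen + (g - 1) * gapExtend}). The alignment
#' engine is \code{Biostrings::pairwiseAlignment}; this wrapper converts
#' the gap convention, reports 1-based inclusive spans of one optimal
#' alignment and clamps the degenerate all-negative case to a score of 0
#' with an empty alignment.
#'
#' @param a,b protein sequences (single character strings) over the 20
#'   amino-acid letters plus X.
#' @param scheme a \linkS4class{ScoringScheme}.
#' @return a list with elements \code{score} (integer, >= 0),
#'   \code{qstart}, \code{qend} (span in \code{a}), \code{sstart},
#'   \code{send} (span in \code{b}; all \code{NA} for an empty alignment)
#'   and \code{identity} (fraction of identical aligned positions).
#' @examples
#' smithWaterman("HEAGAWGHEE", "HEAGAWGHEE")$score
#' smithWaterman("AAAA", "WWWW")$score  # 0: no positive-scoring pair
#' @export
smithWaterman <- function(a, b, scheme = scoringScheme()) {
    if (!nzchar(a) || !nzchar(b))
        stop("sequences must be non-empty")
    aln <- Biostrings::pairwiseAlignment(
        pattern = Biostrings::AAString(a), subject = Biostrings::AAString(b),
        type = "local", substitutionMatrix = scheme@matrix,
        gapOpening = scheme@gapOpen - scheme@gapExtend,
        gapExtension = scheme@gapExtend)
    sc <- Biostrings::score(aln)
    if (sc <= 0)
        return(list(score = 0L, qstart = NA_integer_, qend = NA_integer_,
                    sstart = NA_integer_, send = NA_integer_, identity = 0))
    list(score = as.integer(round(sc)),
         qstart = Biostrings::start(Biostrings::pattern(aln)),
         qend = Biostrings::end(Biostrings::pattern(aln)),
         sstart = Biostrings::start(Biostrings::subject(aln)),
         send = Biostrings::end(Biostrings::subject(aln)),
         identity = Biostrings::pid(aln) / 100)
}

#' Karlin-Altschul E-value of a raw alignment score
#'
#' \eqn{E = K m n e^{-\lambda S}}: the expected number of chance local
#' alignments scoring at least \eqn{S} between a query of length \eqn{m}
#' and a database of \eqn{n} total residues. Strictly decreasing in the
#' score and linear in both lengths. The built-in engine uses the
#' published gapped BLOSUM62/11/1 constants by default (see
#' \linkS4class{ScoringScheme}); no edge-effect or composition corrections
#' are applied, so absolute values differ from BLAST's while preserving
#' the cutoff semantics.
#'
#' @param score raw alignment score(s).
#' @param queryLength query length m, residues.
#' @param dbLength effective database length n, total residues.
#' @param scheme a \linkS4class{ScoringScheme} supplying lambda and K.
#' @return numeric E-value(s).
#' @examples
#' evalueOf(40, 100, 10000)
#' @export
evalueOf <- function(score, queryLength, dbLength, scheme = scoringScheme()) {
    if (queryLength <= 0 || dbLength <= 0)
        stop("lengths must be positive")
    scheme@K * queryLength * dbLength * exp(-scheme@lambda * score)
}

#' All-vs-all local-alignment search with an E-value cutoff
#'
#' Aligns every query against every database sequence with the built-in
#' Smith-Waterman engine and keeps hits with \code{evalue <= cutoff}. The
#' effective database length is the total residue count of
#' \code{database}; at most one hit (the optimal alignment) is reported
#' per (query, subject) pair. The result is ordered by query id, then
#' E-value ascending, then subject id, so identical inputs always give
#' byte-identical hit tables.
#'
#' @param queries,database \linkS4class{Proteome} objects (both non-empty).
#' @param cutoff E-value cutoff (inclusive).
#' @param scheme a \linkS4class{ScoringScheme}.
#' @return a hit \code{DataFrame} (see [readBlastTabular()] for columns).
#' @export
searchProteins <- function(queries, database, cutoff,
                           scheme = scoringScheme()) {
    if (length(queries) == 0L)
        stop("empty query set")
    if (length(database) == 0L)
        stop("empty database")
    n <- sum(Biostrings::width(database))
    db <- as(database, "AAStringSet")
    mcols(db) <- NULL
    out <- vector("list", length(queries))
    for (i in seq_along(queries)) {
        q <- queries[[i]]
        m <- length(q)
        aln <- Biostrings::pairwiseAlignment(
            pattern = db, subject = q, type = "local",
            substitutionMatrix = scheme@matrix,
            gapOpening = scheme@gapOpen - scheme@gapExtend,
            gapExtension = scheme@gapExtend)
        sc <- Biostrings::score(aln)
        ev <- evalueOf(sc, m, n, scheme)
        keep <- which(sc > 0 & ev <= cutoff)
        if (length(keep) == 0L)
            next
        kept <- aln[keep]
        out[[i]] <- DataFrame(
            query = rep(names(queries)[i], length(keep)),
            subject = names(database)[keep],
            score = round(sc[keep]),
            evalue = ev[keep],
            qstart = Biostrings::start(Biostrings::subject(kept)),
            qend = Biostrings::end(Biostrings::subject(kept)),
            sstart = Biostrings::start(Biostrings::pattern(kept)),
            send = Biostrings::end(Biostrings::pattern(kept)),
            identity = Biostrings::pid(kept) / 100)
    }
    out <- out[!vapply(out, is.null, logical(1L))]
    if (length(out) == 0L)
        return(.emptyHits())
    .orderHits(do.call(rbind, out))
}

#' Search backends
#'
#' A search backend produces E-value-ranked hit tables for the three
#' searches the pipeline performs: \code{"forward"} (TF queries against
#' the sub-550-aa partition), \code{"small"} (TF queries against the
#' sub-200-aa partition) and \code{"reverse"} (permissive-tier subjects
#' back against the TF set). The built-in backend computes them with
#' [searchProteins()]; the precomputed backend replays hit tables parsed
#' from BLAST tabular files, filtered to the requested query/database ids
#' and cutoff. Pipeline results depend only on the hits returned, never
#' on which backend produced them.
#'
#' @name SearchBackend
#' @exportClass SearchBackend
setClass("SearchBackend", representation("VIRTUAL"))

#' @rdname SearchBackend
#' @exportClass BuiltinSearchBackend
setClass("BuiltinSearchBackend", contains = "SearchBackend",
         representation(scheme = "ScoringScheme"))

#' @rdname SearchBackend
#' @exportClass PrecomputedSearchBackend
setClass("PrecomputedSearchBackend", contains = "SearchBackend",
         representation(hits = "list"))

setValidity("PrecomputedSearchBackend", function(object) {
    need <- c("forward", "small", "reverse")
    if (!all(need %in% names(object@hits)))
        return("hits must contain 'forward', 'small' and 'reverse' tables")
    TRUE
})

#' @rdname SearchBackend
#' @param scheme a \linkS4class{ScoringScheme} for the built-in engine.
#' @return \code{builtinBackend}: a \code{BuiltinSearchBackend};
#'   \code{precomputedBackend}: a \code{PrecomputedSearchBackend}.
#' @export
builtinBackend <- function(scheme = scoringScheme()) {
    new("BuiltinSearchBackend", scheme = scheme)
}

#' @rdname SearchBackend
#' @param forward,small,reverse hit \code{DataFrame}s (from
#'   [readBlastTabular()] or [searchProteins()]) or paths to BLAST
#'   tabular files for the three pipeline searches.
#' @export
precomputedBackend <- function(forward, small, reverse) {
    asHits <- function(x) {
        if (is.character(x)) x <- readBlastTabular(x)
        .bestHitPerPair(x)
    }
    new("PrecomputedSearchBackend",
        hits = list(forward = asHits(forward), small = asHits(small),
                    reverse = asHits(reverse)))
}

#' Run one backend search
#'
#' @param backend a \linkS4class{SearchBackend}.
#' @param role one of \code{"forward"}, \code{"small"}, \code{"reverse"}.
#' @param queries,database \linkS4class{Proteome} objects.
#' @param cutoff E-value cutoff (inclusive).
#' @return a hit \code{DataFrame}.
#' @export
setGeneric("backendSearch", function(backend, role, queries, database,
                                     cutoff) standardGeneric("backendSearch"))

#' @rdname backendSearch
setMethod("backendSearch", "BuiltinSearchBackend",
    function(backend, role, queries, database, cutoff) {
        searchProteins(queries, database, cutoff, backend@scheme)
    })

#' @rdname backendSearch
setMethod("backendSearch", "PrecomputedSearchBackend",
    function(backend, role, queries, database, cutoff) {
        role <- match.arg(role, c("forward", "small", "reverse"))
        h <- backend@hits[[role]]
        keep <- h$query %in% proteinIds(queries) &
            h$subject %in% proteinIds(database) & h$evalue <= cutoff
        .orderHits(h[keep, , drop = FALSE])
    })

#' Check precomputed hits against the sequence universe
#'
#' Every query and subject id in a precomputed backend's hit tables must
#' name a protein present in the proteome or the TF set; unknown ids are
#' a hard error listing the offenders. The built-in backend passes
#' trivially.
#'
#' @param backend a \linkS4class{SearchBackend}.
#' @param proteome,tfs \linkS4class{Proteome} objects defining the known
#'   ids.
#' @return invisibly, \code{TRUE}.
#' @export
validateBackend <- function(backend, proteome, tfs) {
    if (is(backend, "PrecomputedSearchBackend")) {
        known <- c(proteinIds(proteome), proteinIds(tfs))
        seen <- unique(unlist(lapply(backend@hits,
            function(h) c(h$query, h$subject)), use.names = FALSE))
        unknown <- setdiff(seen, known)
        if (length(unknown))
            stop("precomputed hits reference unknown id(s): ",
                 paste(sort(unknown), collapse = ", "))
    }
    invisible(TRUE)
}
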