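#' Scan a proteome with a consensus-motif domain library
#'
#' Emits one hit for every occurrence (including overlapping occurrences)
#' of a library pattern in a sequence; \code{.} in a pattern matches any
#' residue. Hits are ordered by proteome record order, then library
#' order, then match start, so identical inputs give identical tables.
#' This built-in scanner serves self-contained runs and the synthetic
#' benchmark; annotations from InterProScan are imported with
#' [readInterproTsv()] and feed the identical downstream filters.
#'
#' @param proteome a \linkS4class{Proteome}.
#' @param library a non-empty \linkS4class{DomainLibrary}.
#' @return a \code{DataFrame} of domain hits with columns \code{protein},
#'   \code{domain}, \code{start}, \code{end} (1-based inclusive spans).
#' @examples
#' lib <- domainLibrary("PPI01", "RRK.KK")
#' scanDomains(Proteome(c(p1 = "AARRKWKKAA")), lib)
#' @export
scanDomains <- function(proteome, library) {
    if (length(library) == 0L)
        stop("empty domain library")
    seqs <- as.character(proteome)
    rows <- list()
    for (i in seq_along(seqs)) {
        for (j in seq_along(library@accession)) {
            pat <- library@pattern[[j]]
            # lookahead so overlapping occurrences are all reported
            m <- gregexpr(paste0("(?=", pat, ")"), seqs[[i]], perl = TRUE)[[1L]]
            starts <- as.integer(m[m > 0L])
            if (length(starts))
                rows[[length(rows) + 1L]] <- DataFrame(
                    protein = rep(names(seqs)[i], length(starts)),
                    domain = rep(library@accession[[j]], length(starts)),
                    start = starts,
                    end = starts + nchar(pat) - 1L)
        }
    }
    if (length(rows) == 0L)
        return(DataFrame(protein = character(), domain = character(),
                         start = integer(), end = integer()))
    do.call(rbind, rows)
}

#' Domain architecture of one or more proteins
#'
#' The domain architecture of a protein is the deduplicated, unordered
#' set of domain accessions annotated on it; multiplicity and order are
#' deliberately ignored because the downstream filters are set-membership
#' tests. Proteins absent from the hit table get the empty set.
#'
#' @param ids character vector of protein ids to report on.
#' @param hits a domain-hit \code{DataFrame} from [scanDomains()] or
#'   [readInterproTsv()].
#' @return a \code{CharacterList} of sorted accession sets, one element
#'   per id, named by id.
#' @export
architectureOf <- function(ids, hits) {
    sets <- split(hits$domain, factor(hits$protein, levels = unique(ids)))
    out <- lapply(ids, function(id) {
        s <- sets[[id]]
        if (is.null(s)) character(0L) else sort(unique(s))
    })
    names(out) <- ids
    CharacterList(out)
}

#' Does an architecture contain an unwanted domain?
#'
#' \code{TRUE} for each architecture whose accession set intersects the
#' unwanted set (typically DNA-binding domains); the empty architecture
#' never does.
#'
#' @param architectures a \code{CharacterList} from [architectureOf()].
#' @param unwanted character vector of unwanted accessions (see
#'   [readUnwantedDomains()]).
#' @return named logical vector, parallel to \code{architectures}.
#' @export
containsUnwanted <- function(architectures, unwanted) {
    out <- vapply(as.list(architectures),
                  function(s) any(s %in% unwanted), logical(1L))
    names(out) <- names(architectures)
    out
}
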