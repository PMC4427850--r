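#' Read a proteome from a FASTA file
#'
#' Parses a protein FASTA file into a \linkS4class{Proteome}. The record id
#' is the first whitespace-delimited token after \code{>} (the BLAST seqid
#' convention, so hits from precomputed tabular files join cleanly); the
#' remainder of the header becomes the description. Multi-line sequences
#' are concatenated, letters are uppercased and a single trailing stop
#' character \code{*} is stripped. Records are returned in file order.
#'
#' Duplicate ids, internal \code{*} characters and residues outside the
#' 20 amino-acid letters plus \code{X} are hard errors naming the
#' offending record; an empty file yields an empty proteome with a
#' warning.
#'
#' @param path path to a FASTA file.
#' @return a \linkS4class{Proteome} in file order.
#' @seealso [writeProteome()]
#' @export
readProteome <- function(path) {
    raw <- Biostrings::readBStringSet(path)
    if (length(raw) == 0L) {
        warning("empty FASTA file: ", path)
        return(Proteome())
    }
    headers <- names(raw)
    ids <- sub("[[:space:]].*$", "", headers)
    desc <- sub("^[^[:space:]]*[[:space:]]*", "", headers)
    if (any(!nzchar(ids)))
        stop("FASTA record with empty id in ", path)
    if (anyDuplicated(ids))
        stop("duplicate FASTA id(s): ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    seqs <- toupper(as.character(raw))
    seqs <- sub("\\*$", "", seqs)
    bad <- regmatches(seqs, regexpr(sprintf("[^%s]", paste(PROTEIN_ALPHABET,
                                                           collapse = "")),
                                    seqs))
    hit <- which(lengths(regmatches(seqs,
        gregexpr(sprintf("[^%s]", paste(PROTEIN_ALPHABET, collapse = "")),
                 seqs))) > 0L)
    if (length(hit)) {
        ch <- substring(bad[1L], 1L, 1L)
        stop("invalid residue '", ch, "' in record '", ids[hit[1L]], "'")
    }
    names(seqs) <- ids
    Proteome(seqs, descriptions = desc)
}

#' Write a proteome to a FASTA file
#'
#' Headers are \code{id description} (the description omitted when empty),
#' so [readProteome()] round-trips ids, descriptions, sequences and order
#' exactly.
#'
#' @param x a \linkS4class{Proteome}.
#' @param path output path.
#' @param width line width for wrapped sequences.
#' @return invisibly, \code{path}.
#' @export
writeProteome <- function(x, path, width = 60L) {
    desc <- proteinDescriptions(x)
    out <- as(x, "AAStringSet")
    names(out) <- ifelse(nzchar(desc), paste(names(x), desc), names(x))
    Biostrings::writeXStringSet(out, filepath = path, width = width)
    invisible(path)
}

#' Read a list of unwanted domain accessions
#'
#' One accession token per line; \code{#} starts a comment (whole-line or
#' trailing) and blank lines are skipped. A non-comment line containing
#' internal whitespace is a parse error reported with its line number.
#' The typical content is a set of DNA-binding-domain accessions: the
#' domain class whose absence defines a microProtein.
#'
#' @param path path to the accession list.
#' @return deduplicated character vector of accessions.
#' @export
readUnwantedDomains <- function(path) {
    lines <- readLines(path)
    body <- sub("#.*$", "", lines)
    trimmed <- trimws(body)
    keep <- nzchar(trimmed)
    if (any(grepl("[[:space:]]", trimmed[keep])))
        stop("unwanted-domain list ", path, ": whitespace inside token at line ",
             which(keep & grepl("[[:space:]]", trimmed))[1L])
    out <- unique(trimmed[keep])
    if (length(lines) > 0L && length(out) == 0L)
        warning("unwanted-domain list ", path, " contains no accessions")
    out
}

BLAST_COLUMNS <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                   "gapopen", "qstart", "qend", "sstart", "send",
                   "evalue", "bitscore")

#' Read BLAST tabular search hits
#'
#' Parses the standard 12-column BLAST+ tabular dialect (\code{-outfmt 6}:
#' qseqid, sseqid, pident, length, mismatch, gapopen, qstart, qend,
#' sstart, send, evalue, bitscore). When the same (query, subject) pair
#' occurs on several lines (multiple HSPs) only the minimum-E-value line
#' is kept, ties broken by higher score then first occurrence. Wrong
#' column counts and unparseable E-values are hard errors with the line
#' number.
#'
#' @param path path to a tab-separated hit file.
#' @return a \code{DataFrame} with columns \code{query}, \code{subject},
#'   \code{score} (the bitscore column), \code{evalue}, \code{qstart},
#'   \code{qend}, \code{sstart}, \code{send}, \code{identity} (fraction in
#'   \code{[0, 1]}), one row per (query, subject) pair.
#' @seealso [writeBlastTabular()], [precomputedBackend()]
#' @export
readBlastTabular <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0L)
        return(.emptyHits())
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != 12L))
        stop("BLAST tabular ", path, ": expected 12 columns, got ",
             nf[nf != 12L][1L], " at line ", which(nf != 12L)[1L])
    m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
    evalue <- suppressWarnings(as.numeric(m[, 11L]))
    if (any(is.na(evalue)))
        stop("BLAST tabular ", path, ": unparseable E-value at line ",
             which(is.na(evalue))[1L])
    hits <- DataFrame(query = m[, 1L], subject = m[, 2L],
                      score = as.numeric(m[, 12L]), evalue = evalue,
                      qstart = as.integer(m[, 7L]), qend = as.integer(m[, 8L]),
                      sstart = as.integer(m[, 9L]), send = as.integer(m[, 10L]),
                      identity = as.numeric(m[, 3L]) / 100)
    .bestHitPerPair(hits)
}

.emptyHits <- function() {
    DataFrame(query = character(), subject = character(),
              score = numeric(), evalue = numeric(),
              qstart = integer(), qend = integer(),
              sstart = integer(), send = integer(), identity = numeric())
}

.bestHitPerPair <- function(hits) {
    if (nrow(hits) <= 1L)
        return(hits)
    key <- paste(hits$query, hits$subject, sep = "\r")
    ord <- order(key, hits$evalue, -hits$score, seq_len(nrow(hits)))
    hits <- hits[ord, , drop = FALSE]
    hits <- hits[!duplicated(paste(hits$query, hits$subject, sep = "\r")), ,
                 drop = FALSE]
    .orderHits(hits)
}

.orderHits <- function(hits) {
    hits[order(hits$query, hits$evalue, hits$subject), , drop = FALSE]
}

#' Write search hits in BLAST tabular format
#'
#' Emits the 12-column dialect read back by [readBlastTabular()]: E-values
#' are written at full precision so that replaying a file through the
#' precomputed backend reproduces the built-in engine's decisions exactly.
#' The mismatch and gapopen columns are derived approximations (the hit
#' table does not retain per-column alignment detail).
#'
#' @param hits a hit \code{DataFrame} as returned by [searchProteins()] or
#'   [readBlastTabular()].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeBlastTabular <- function(hits, path) {
    alen <- pmax(hits$qend - hits$qstart + 1L, 0L)
    lines <- paste(hits$query, hits$subject,
                   sprintf("%.2f", 100 * hits$identity), alen,
                   pmax(alen - round(hits$identity * alen), 0L), 0L,
                   hits$qstart, hits$qend, hits$sstart, hits$send,
                   format(hits$evalue, digits = 17L, scientific = TRUE,
                          trim = TRUE),
                   format(hits$score, trim = TRUE),
                   sep = "\t")
    writeLines(lines, path)
    invisible(path)
}

#' Read domain annotations from an InterProScan TSV file
#'
#' Parses the InterProScan tab-separated dialect: at least 11 columns,
#' column 1 the protein id, columns 7 and 8 the match coordinates and
#' column 12, when present and not \code{"-"}, the integrated InterPro
#' accession. Only rows carrying an integrated accession produce a hit;
#' member-database signatures without one are skipped. Rows with fewer
#' than 11 columns are hard errors with the line number.
#'
#' @param path path to an InterProScan TSV file.
#' @return a \code{DataFrame} of domain hits with columns \code{protein},
#'   \code{domain}, \code{start}, \code{end} (coordinates \code{NA} when
#'   unparseable).
#' @export
readInterproTsv <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    empty <- DataFrame(protein = character(), domain = character(),
                       start = integer(), end = integer())
    if (length(lines) == 0L)
        return(empty)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 11L))
        stop("InterProScan TSV ", path, ": expected >= 11 columns, got ",
             nf[nf < 11L][1L], " at line ", which(nf < 11L)[1L])
    acc <- vapply(fields, function(f) if (length(f) >= 12L) f[[12L]] else "-",
                  character(1L))
    keep <- !is.na(acc) & nzchar(acc) & acc != "-"
    if (!any(keep))
        return(empty)
    fields <- fields[keep]
    DataFrame(protein = vapply(fields, `[[`, character(1L), 1L),
              domain = acc[keep],
              start = suppressWarnings(
                  as.integer(vapply(fields, `[[`, character(1L), 7L))),
              end = suppressWarnings(
                  as.integer(vapply(fields, `[[`, character(1L), 8L))))
}

#' Read / write a domain library
#'
#' Two-column tab-separated file (accession, consensus pattern); \code{#}
#' starts a comment and blank lines are skipped.
#'
#' @param path file path.
#' @return \code{readDomainLibrary}: a \linkS4class{DomainLibrary}.
#' @export
readDomainLibrary <- function(path) {
    lines <- readLines(path)
    body <- trimws(sub("#.*$", "", lines))
    keep <- which(nzchar(body))
    fields <- strsplit(body[keep], "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != 2L))
        stop("domain library ", path, ": expected 2 tab-separated columns ",
             "at line ", keep[nf != 2L][1L])
    domainLibrary(vapply(fields, `[[`, character(1L), 1L),
                  vapply(fields, `[[`, character(1L), 2L))
}

#' @rdname readDomainLibrary
#' @param library a \linkS4class{DomainLibrary}.
#' @export
writeDomainLibrary <- function(library, path) {
    writeLines(paste(library@accession, library@pattern, sep = "\t"), path)
    invisible(path)
}

PREDICTION_COLUMNS <- c("mip_id", "mip_length", "target_tfs",
                        "target_lengths", "domains", "tier")

#' Write the prediction table
#'
#' Writes one tab-separated row per predicted miP: its id and length, the
#' semicolon-joined ids and lengths of its surviving target TFs, the
#' semicolon-joined domain accessions it carries (\code{-} when none were
#' mapped) and the provenance tier (\code{tier1} = stringent search,
#' \code{tier2} = permissive search with reverse rescue). Rows are sorted
#' by miP id so repeated runs are byte-identical; [readPredictions()]
#' round-trips the table losslessly.
#'
#' @param predictions a prediction \code{DataFrame} as returned by
#'   [runPipeline()].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writePredictions <- function(predictions, path) {
    stopifnot(all(PREDICTION_COLUMNS %in% colnames(predictions)))
    p <- predictions[order(predictions$mip_id), , drop = FALSE]
    join <- function(x) vapply(x, function(v)
        if (length(v)) paste(v, collapse = ";") else "-", character(1L))
    lines <- paste(p$mip_id, p$mip_length,
                   join(as.list(p$target_tfs)),
                   join(as.list(p$target_lengths)),
                   join(as.list(p$domains)),
                   p$tier, sep = "\t")
    writeLines(c(paste(PREDICTION_COLUMNS, collapse = "\t"), lines), path)
    invisible(path)
}

#' Read a prediction table written by [writePredictions()]
#'
#' @param path path to the tab-delimited prediction file.
#' @return a prediction \code{DataFrame} (see [runPipeline()]).
#' @export
readPredictions <- function(path) {
    lines <- readLines(path)
    if (length(lines) == 0L ||
        !identical(lines[[1L]], paste(PREDICTION_COLUMNS, collapse = "\t")))
        stop("not a prediction table: ", path)
    body <- lines[-1L]
    if (length(body) == 0L)
        return(.emptyPredictions())
    fields <- strsplit(body, "\t", fixed = TRUE)
    if (any(lengths(fields) != 6L))
        stop("prediction table ", path, ": malformed row ",
             which(lengths(fields) != 6L)[1L] + 1L)
    splitList <- function(x) strsplit(x, ";", fixed = TRUE)
    col <- function(i) vapply(fields, `[[`, character(1L), i)
    dom <- splitList(col(5L))
    dom[col(5L) == "-"] <- list(character(0L))
    named <- function(x) stats::setNames(x, col(1L))
    DataFrame(mip_id = col(1L), mip_length = as.integer(col(2L)),
              target_tfs = CharacterList(named(splitList(col(3L)))),
              target_lengths = IntegerList(named(lapply(splitList(col(4L)),
                                                        as.integer))),
              domains = CharacterList(named(dom)), tier = col(6L))
}

.emptyPredictions <- function() {
    DataFrame(mip_id = character(), mip_length = integer(),
              target_tfs = CharacterList(), target_lengths = IntegerList(),
              domains = CharacterList(), tier = character())
}
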