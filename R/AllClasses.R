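#' @import methods
#' @importClassesFrom Biostrings AAStringSet
#' @importFrom S4Vectors DataFrame metadata metadata<- mcols mcols<-
#' @importFrom IRanges CharacterList IntegerList
NULL

AMINO_ACIDS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
PROTEIN_ALPHABET <- c(AMINO_ACIDS, "X")

#' Proteome: a set of identified protein sequences
#'
#' A \code{Proteome} is an \linkS4class{AAStringSet} whose names are unique,
#' whitespace-free protein identifiers and whose sequences are restricted to
#' the 20 standard amino-acid letters plus \code{X} (ambiguity). Free-text
#' descriptions (the remainder of a FASTA header) live in
#' \code{mcols(x)$description}.
#'
#' @slot .Data inherited from \code{AAStringSet}.
#' @seealso [readProteome()], [writeProteome()], [proteinIds()]
#' @exportClass Proteome
setClass("Proteome", contains = "AAStringSet")

setValidity("Proteome", function(object) {
    msg <- character()
    n <- length(object)
    ids <- names(object)
    if (n > 0L) {
        if (is.null(ids) || any(is.na(ids)) || any(!nzchar(ids)))
            msg <- c(msg, "all records must have non-empty ids")
        else {
            if (anyDuplicated(ids))
                msg <- c(msg, paste0("duplicate protein id(s): ",
                    paste(unique(ids[duplicated(ids)]), collapse = ", ")))
            if (any(grepl("[[:space:]]", ids)))
                msg <- c(msg, "protein ids must not contain whitespace")
        }
        if (any(Biostrings::width(object) == 0L))
            msg <- c(msg, "zero-length sequences are not allowed")
        bad <- .invalidResidues(object)
        if (length(bad))
            msg <- c(msg, paste0("invalid residue(s) in record(s): ",
                paste(names(bad), " ('", bad, "')", sep = "", collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
})

.invalidResidues <- function(x) {
    freq <- Biostrings::alphabetFrequency(x)
    extra <- setdiff(colnames(freq), PROTEIN_ALPHABET)
    offending <- freq[, extra, drop = FALSE]
    hit <- which(rowSums(offending) > 0L)
    vapply(hit, function(i) {
        colnames(offending)[which(offending[i, ] > 0L)[1L]]
    }, character(1L), USE.NAMES = FALSE) -> chars
    names(chars) <- names(x)[hit]
    chars
}

#' Construct a Proteome
#'
#' @param x a named character vector or a named \code{AAStringSet}; names are
#'   the protein ids.
#' @param descriptions optional character vector of free-text descriptions,
#'   parallel to \code{x}.
#' @return a \linkS4class{Proteome}.
#' @examples
#' p <- Proteome(c(tf1 = "MKVLLAGHEE", p2 = "MKWWAX"))
#' proteinLengths(p)
#' @export
Proteome <- function(x = character(), descriptions = NULL) {
    if (is.character(x))
        x <- Biostrings::AAStringSet(x)
    x <- as(x, "AAStringSet")
    if (is.null(descriptions))
        descriptions <- rep("", length(x))
    out <- new("Proteome", x)
    mcols(out) <- DataFrame(description = as.character(descriptions))
    validObject(out)
    out
}

#' @describeIn Proteome subsetting preserves the class and descriptions.
#' @param i index (integer, logical or id character).
#' @param j,...,drop ignored.
#' @export
setMethod("[", "Proteome", function(x, i, j, ..., drop = FALSE) {
    new("Proteome", callNextMethod())
})

#' Accessors for Proteome objects
#'
#' @param x a \linkS4class{Proteome}.
#' @return \code{proteinIds}: character vector of ids;
#'   \code{proteinLengths}: integer vector of residue counts, named by id;
#'   \code{proteinDescriptions}: character vector of header descriptions.
#' @export
proteinIds <- function(x) names(x)

#' @rdname proteinIds
#' @export
proteinLengths <- function(x) {
    out <- Biostrings::width(x)
    names(out) <- names(x)
    out
}

#' @rdname proteinIds
#' @export
proteinDescriptions <- function(x) {
    d <- mcols(x)$description
    if (is.null(d)) d <- rep("", length(x))
    names(d) <- names(x)
    d
}

setMethod("show", "Proteome", function(object) {
    cat("Proteome with", length(object), "protein(s)\n")
    if (length(object))
        cat("  lengths:", min(Biostrings::width(object)), "-",
            max(Biostrings::width(object)), "aa\n")
    invisible(NULL)
})

#' Scoring scheme for the built-in local-alignment search engine
#'
#' Bundles a symmetric amino-acid substitution matrix, affine gap penalties
#' (a gap of length g costs \code{gapOpen + (g - 1) * gapExtend}, the BLAST
#' convention) and the Karlin-Altschul parameters lambda and K used to turn
#' raw alignment scores into E-values. Defaults are BLOSUM62 with gap
#' open/extend 11/1 and the published gapped-search constants
#' lambda = 0.267, K = 0.041. \code{X} is scored as the worst-case
#' substitution (the matrix minimum) against every residue.
#'
#' @slot matrix symmetric integer substitution matrix over the 20 amino
#'   acids plus X.
#' @slot gapOpen,gapExtend positive integer gap penalties,
#'   \code{gapOpen >= gapExtend >= 1}.
#' @slot lambda,K positive Karlin-Altschul calibration constants.
#' @exportClass ScoringScheme
setClass("ScoringScheme",
    representation(matrix = "matrix", gapOpen = "integer",
                   gapExtend = "integer", lambda = "numeric", K = "numeric"))

setValidity("ScoringScheme", function(object) {
    msg <- character()
    m <- object@matrix
    if (!identical(rownames(m), colnames(m)))
        msg <- c(msg, "substitution matrix must have identical row/col names")
    else if (!isTRUE(all.equal(m, t(m))))
        msg <- c(msg, "substitution matrix must be symmetric")
    if (!all(PROTEIN_ALPHABET %in% rownames(m)))
        msg <- c(msg, "matrix must cover the 20 amino acids plus X")
    if (length(object@gapOpen) != 1L || length(object@gapExtend) != 1L ||
        object@gapExtend < 1L || object@gapOpen < object@gapExtend)
        msg <- c(msg, "need gapOpen >= gapExtend >= 1")
    if (object@lambda <= 0 || object@K <= 0)
        msg <- c(msg, "lambda and K must be positive")
    if (length(msg)) msg else TRUE
})

.blosum62x <- function() {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    full <- e$BLOSUM62
    m <- full[AMINO_ACIDS, AMINO_ACIDS]
    worst <- min(m)
    out <- matrix(worst, 21L, 21L,
                  dimnames = list(PROTEIN_ALPHABET, PROTEIN_ALPHABET))
    out[AMINO_ACIDS, AMINO_ACIDS] <- m
    out
}

#' Construct a ScoringScheme
#'
#' @param matrix \code{"BLOSUM62"} (the only built-in) or a symmetric
#'   numeric matrix covering the 20 amino acids plus X.
#' @param gapOpen,gapExtend affine gap penalties (BLAST convention).
#' @param lambda,K Karlin-Altschul constants matching the matrix and gap
#'   penalties.
#' @return a \linkS4class{ScoringScheme}.
#' @examples
#' sch <- scoringScheme()
#' sch
#' @export
scoringScheme <- function(matrix = "BLOSUM62", gapOpen = 11L, gapExtend = 1L,
                          lambda = 0.267, K = 0.041) {
    if (is.character(matrix)) {
        if (!identical(matrix, "BLOSUM62"))
            stop("only the built-in BLOSUM62 matrix is available by name")
        matrix <- .blosum62x()
    }
    new("ScoringScheme", matrix = matrix,
        gapOpen = as.integer(gapOpen), gapExtend = as.integer(gapExtend),
        lambda = lambda, K = K)
}

setMethod("show", "ScoringScheme", function(object) {
    cat("ScoringScheme: ", nrow(object@matrix), "-letter matrix, gap ",
        object@gapOpen, "/", object@gapExtend,
        ", lambda=", object@lambda, ", K=", object@K, "\n", sep = "")
    invisible(NULL)
})

#' Pipeline configuration
#'
#' Tunable thresholds of the miP prediction pipeline. Defaults are the
#' recall-calibrated values of the published procedure: candidates are
#' sought among proteins shorter than 550 aa (stringent tier, E <= 1e-7)
#' and, for small proteins shorter than 200 aa, at a permissive cutoff
#' (E <= 0.5) rescued by a reverse search against the query TFs
#' (E <= 0.1); surviving miPs may be at most 1.1 times the length of a
#' target.
#'
#' @slot maxMipLength stringent-tier subject length bound, residues
#'   (strict \code{<}).
#' @slot smallProteinLength permissive-tier subject length bound, residues
#'   (strict \code{<}).
#' @slot tier1Cutoff,tier2Cutoff,reverseCutoff E-value cutoffs (inclusive).
#' @slot lengthRatio maximum miP/target length ratio (inclusive).
#' @exportClass MipConfig
setClass("MipConfig",
    representation(maxMipLength = "integer", smallProteinLength = "integer",
                   tier1Cutoff = "numeric", tier2Cutoff = "numeric",
                   reverseCutoff = "numeric", lengthRatio = "numeric"))

setValidity("MipConfig", function(object) {
    msg <- character()
    if (object@smallProteinLength <= 0L ||
        object@smallProteinLength > object@maxMipLength)
        msg <- c(msg, "need 0 < smallProteinLength <= maxMipLength")
    if (object@tier1Cutoff > object@tier2Cutoff)
        msg <- c(msg, "need tier1Cutoff <= tier2Cutoff")
    if (any(c(object@tier1Cutoff, object@tier2Cutoff,
              object@reverseCutoff) <= 0))
        msg <- c(msg, "E-value cutoffs must be positive")
    if (object@lengthRatio < 1)
        msg <- c(msg, "lengthRatio must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Construct a MipConfig
#'
#' @param maxMipLength,smallProteinLength,tier1Cutoff,tier2Cutoff,reverseCutoff,lengthRatio
#'   see \linkS4class{MipConfig}.
#' @return a \linkS4class{MipConfig}.
#' @examples
#' mipConfig()
#' mipConfig(tier1Cutoff = 1e-10)
#' @export
mipConfig <- function(maxMipLength = 550L, smallProteinLength = 200L,
                      tier1Cutoff = 1e-7, tier2Cutoff = 0.5,
                      reverseCutoff = 0.1, lengthRatio = 1.1) {
    new("MipConfig", maxMipLength = as.integer(maxMipLength),
        smallProteinLength = as.integer(smallProteinLength),
        tier1Cutoff = tier1Cutoff, tier2Cutoff = tier2Cutoff,
        reverseCutoff = reverseCutoff, lengthRatio = lengthRatio)
}

setMethod("show", "MipConfig", function(object) {
    cat("MipConfig: subjects <", object@maxMipLength, "aa (tier 1), <",
        object@smallProteinLength, "aa (tier 2)\n  cutoffs: tier1 <=",
        object@tier1Cutoff, ", tier2 <=", object@tier2Cutoff,
        ", reverse <=", object@reverseCutoff, "\n  length ratio <=",
        object@lengthRatio, "\n")
    invisible(NULL)
})

#' Domain library for the built-in consensus scanner
#'
#' A set of (accession, pattern) pairs. Patterns are exact consensus
#' strings over the amino-acid letters with \code{.} matching any single
#' residue; every occurrence (including overlapping ones) counts as a hit.
#' This is the self-contained stand-in for an external domain annotation
#' such as InterProScan; imported annotations go through
#' [readInterproTsv()] instead.
#'
#' @slot accession unique domain accession tokens.
#' @slot pattern parallel consensus patterns, each at least 6 characters.
#' @exportClass DomainLibrary
setClass("DomainLibrary",
    representation(accession = "character", pattern = "character"))

setValidity("DomainLibrary", function(object) {
    msg <- character()
    if (length(object@accession) != length(object@pattern))
        msg <- c(msg, "accession and pattern must be parallel")
    if (anyDuplicated(object@accession))
        msg <- c(msg, "duplicate domain accessions")
    if (length(object@pattern)) {
        if (any(nchar(object@pattern) < 6L))
            msg <- c(msg, "patterns must be at least 6 characters")
        if (any(!grepl("^[A-Z.]+$", object@pattern)))
            msg <- c(msg, "patterns may contain only A-Z and '.'")
        if (any(grepl("[[:space:]]", object@accession)) ||
            any(!nzchar(object@accession)))
            msg <- c(msg, "accessions must be non-empty, whitespace-free")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a DomainLibrary
#'
#' @param accession character vector of unique accession tokens.
#' @param pattern parallel character vector of consensus patterns
#'   (amino-acid letters, \code{.} = any residue, length >= 6).
#' @return a \linkS4class{DomainLibrary}.
#' @examples
#' domainLibrary(c("DBD01", "PPI01"), c("WRKYGQKW", "LEDLEDL"))
#' @export
domainLibrary <- function(accession = character(), pattern = character()) {
    new("DomainLibrary", accession = as.character(accession),
        pattern = as.character(pattern))
}

#' @rdname domainLibrary
#' @param x a \code{DomainLibrary}.
#' @export
domainAccessions <- function(x) x@accession

#' @rdname domainLibrary
#' @export
domainPatterns <- function(x) {
    out <- x@pattern
    names(out) <- x@accession
    out
}

setMethod("length", "DomainLibrary", function(x) length(x@accession))

setMethod("show", "DomainLibrary", function(object) {
    cat("DomainLibrary with", length(object), "motif(s)\n")
    invisible(NULL)
})
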