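#' Length partition of a proteome
#'
#' Returns exactly the records strictly shorter than \code{limit}
#' residues, in their original order. The pipeline applies this to
#' subjects only: the stringent tier searches proteins shorter than
#' 550 aa (every microProtein characterized to date is smaller) and the
#' permissive tier proteins shorter than 200 aa (the typical miP size).
#'
#' @param proteome a \linkS4class{Proteome}.
#' @param limit residue bound (strict \code{<}), positive.
#' @return a \linkS4class{Proteome} subset.
#' @examples
#' p <- Proteome(c(a = paste(rep("A", 10), collapse = ""), b = "MKVL"))
#' proteinIds(partitionByLength(p, 5))
#' @export
partitionByLength <- function(proteome, limit) {
    stopifnot(limit > 0)
    proteome[Biostrings::width(proteome) < limit]
}

.emptyCandidates <- function() {
    DataFrame(mip = character(), tf = character(), evalue = numeric(),
              tier = character())
}

.orderCandidates <- function(x) {
    x[order(x$mip, x$tf), , drop = FALSE]
}

.hitsToCandidates <- function(hits, tfIds, tier, mipFromQuery = FALSE) {
    if (mipFromQuery)
        cand <- DataFrame(mip = hits$query, tf = hits$subject,
                          evalue = hits$evalue, tier = rep(tier, nrow(hits)))
    else
        cand <- DataFrame(mip = hits$subject, tf = hits$query,
                          evalue = hits$evalue, tier = rep(tier, nrow(hits)))
    cand <- cand[!(cand$mip %in% tfIds), , drop = FALSE]
    .orderCandidates(cand)
}

#' Stringent-tier candidate generation
#'
#' Searches the TF queries against the sub-\code{maxMipLength} partition
#' of the proteome at \code{tier1Cutoff}. Every hit subject becomes a
#' candidate miP with the querying TF as a target, carrying the hit's
#' E-value as evidence. Proteome records whose id equals any query-TF id
#' are never candidates (otherwise every sub-550-aa TF would trivially
#' report itself).
#'
#' @param tfs,proteome non-empty \linkS4class{Proteome} objects.
#' @param config a \linkS4class{MipConfig}.
#' @param backend a \linkS4class{SearchBackend}.
#' @return a candidate \code{DataFrame} with columns \code{mip},
#'   \code{tf}, \code{evalue}, \code{tier}; one row per (miP, target)
#'   pair.
#' @export
tier1Candidates <- function(tfs, proteome, config = mipConfig(),
                            backend = builtinBackend()) {
    if (length(tfs) == 0L)
        stop("tier1 search: empty query set")
    db <- partitionByLength(proteome, config@maxMipLength)
    if (length(db) == 0L)
        return(.emptyCandidates())
    hits <- backendSearch(backend, "forward", tfs, db, config@tier1Cutoff)
    .hitsToCandidates(hits, proteinIds(tfs), "tier1")
}

#' Permissive-tier candidate generation with reverse rescue
#'
#' Searches the TF queries against the sub-\code{smallProteinLength}
#' partition at the permissive \code{tier2Cutoff}, then uses each forward
#' hit subject as a query in a reverse search against the full TF set at
#' \code{reverseCutoff}. Subjects with no reverse hit are discarded;
#' survivors become tier-2 candidates whose targets are the TFs found in
#' the reverse search (with the reverse E-values as evidence) -- the
#' forward hit establishes candidacy, the reverse search defines which
#' TFs the candidate credibly matches.
#'
#' @inheritParams tier1Candidates
#' @return a candidate \code{DataFrame} (see [tier1Candidates()]).
#' @export
tier2Candidates <- function(tfs, proteome, config = mipConfig(),
                            backend = builtinBackend()) {
    if (length(tfs) == 0L)
        stop("tier2 search: empty query set")
    db <- partitionByLength(proteome, config@smallProteinLength)
    if (length(db) == 0L)
        return(.emptyCandidates())
    fwd <- backendSearch(backend, "small", tfs, db, config@tier2Cutoff)
    subjects <- setdiff(unique(fwd$subject), proteinIds(tfs))
    if (length(subjects) == 0L)
        return(.emptyCandidates())
    rev <- backendSearch(backend, "reverse", proteome[subjects], tfs,
                         config@reverseCutoff)
    .hitsToCandidates(rev, character(0L), "tier2", mipFromQuery = TRUE)
}

#' Merge stringent- and permissive-tier candidates
#'
#' Union keyed by miP id: a protein found by both tiers keeps
#' \code{tier1} provenance and the union of its targets, with the
#' minimum evidence E-value per (miP, TF) pair.
#'
#' @param t1,t2 candidate \code{DataFrame}s from [tier1Candidates()] and
#'   [tier2Candidates()].
#' @return a merged candidate \code{DataFrame}.
#' @export
mergeCandidates <- function(t1, t2) {
    all <- rbind(t1, t2)
    if (nrow(all) == 0L)
        return(.emptyCandidates())
    tier1Mips <- unique(all$mip[all$tier == "tier1"])
    key <- paste(all$mip, all$tf, sep = "\r")
    ord <- order(key, all$evalue, match(all$tier, c("tier1", "tier2")))
    all <- all[ord, , drop = FALSE]
    all <- all[!duplicated(paste(all$mip, all$tf, sep = "\r")), , drop = FALSE]
    all$tier <- ifelse(all$mip %in% tier1Mips, "tier1", "tier2")
    .orderCandidates(all)
}

#' Remove candidates carrying unwanted domains
#'
#' Drops every candidate whose domain architecture intersects the
#' unwanted set -- by definition a microProtein lacks the DNA-binding
#' domain of its TF class. Candidates with no mapped domains pass: the
#' filter can only act on mapped domains.
#'
#' @param candidates a candidate \code{DataFrame}.
#' @param architectures a \code{CharacterList} from [architectureOf()]
#'   covering at least all candidate ids.
#' @param unwanted character vector of unwanted accessions.
#' @return the filtered candidate \code{DataFrame}.
#' @export
filterUnwantedDomains <- function(candidates, architectures, unwanted) {
    if (nrow(candidates) == 0L)
        return(candidates)
    ids <- unique(candidates$mip)
    if (!all(ids %in% names(architectures)))
        stop("architectures missing for candidate(s): ",
             paste(setdiff(ids, names(architectures)), collapse = ", "))
    bad <- ids[containsUnwanted(architectures[ids], unwanted)]
    candidates[!(candidates$mip %in% bad), , drop = FALSE]
}

#' Remove candidate-target pairs violating the length-ratio bound
#'
#' A miP is a truncated protein: per (miP, TF) pair the pair is dropped
#' when the candidate is longer than \code{ratio} times the target
#' (strict \code{>}, so a candidate exactly at 1.1 times survives, the
#' published 10 percent size tolerance for longer linker regions). A
#' candidate with no surviving pair is removed entirely.
#'
#' @param candidates a candidate \code{DataFrame}.
#' @param lengths named integer vector of residue counts covering all
#'   candidate and target ids (e.g. from [proteinLengths()]).
#' @param ratio maximum miP/target length ratio (inclusive).
#' @return the filtered candidate \code{DataFrame}.
#' @export
filterLengthRatio <- function(candidates, lengths, ratio = 1.1) {
    if (nrow(candidates) == 0L)
        return(candidates)
    need <- unique(c(candidates$mip, candidates$tf))
    if (!all(need %in% names(lengths)))
        stop("lengths missing for id(s): ",
             paste(setdiff(need, names(lengths)), collapse = ", "))
    keep <- !(lengths[candidates$mip] > ratio * lengths[candidates$tf])
    candidates[keep, , drop = FALSE]
}

#' Remove candidates carrying domains foreign to all their targets
#'
#' A candidate survives iff its domain set is a subset of the union of
#' its surviving targets' domain sets; a truncation bears at most the
#' domains of the proteins it arose from. Run after
#' [filterLengthRatio()] so the union ranges over surviving targets
#' only. Candidates with no mapped domains pass (the empty set is a
#' subset of anything); targets missing from the annotation contribute
#' an empty set.
#'
#' @param candidates a candidate \code{DataFrame}.
#' @param architectures a \code{CharacterList} covering candidate and
#'   target ids.
#' @return the filtered candidate \code{DataFrame}.
#' @export
filterForeignDomains <- function(candidates, architectures) {
    if (nrow(candidates) == 0L)
        return(candidates)
    archOf <- function(id) {
        if (id %in% names(architectures)) architectures[[id]] else character(0L)
    }
    ids <- unique(candidates$mip)
    keep <- vapply(ids, function(id) {
        tgt <- candidates$tf[candidates$mip == id]
        un <- unique(unlist(lapply(tgt, archOf), use.names = FALSE))
        all(archOf(id) %in% un)
    }, logical(1L))
    candidates[candidates$mip %in% ids[keep], , drop = FALSE]
}

.candidatesToPredictions <- function(candidates, lengths, architectures) {
    if (nrow(candidates) == 0L)
        return(.emptyPredictions())
    ids <- sort(unique(candidates$mip))
    rows <- lapply(ids, function(id) {
        sub <- candidates[candidates$mip == id, , drop = FALSE]
        tgt <- sort(unique(sub$tf))
        dom <- if (id %in% names(architectures)) architectures[[id]]
               else character(0L)
        DataFrame(mip_id = id,
                  mip_length = unname(lengths[id]),
                  target_tfs = CharacterList(list(tgt)),
                  target_lengths = IntegerList(list(unname(lengths[tgt]))),
                  domains = CharacterList(list(dom)),
                  tier = sub$tier[[1L]])
    })
    do.call(rbind, rows)
}

#' Run the full miP prediction pipeline
#'
#' Executes, in order: length partitions, stringent-tier search,
#' permissive-tier search with reverse rescue, candidate merge, domain
#' annotation of candidates and targets, the unwanted-domain filter, the
#' length-ratio filter and the foreign-domain filter (the filter order
#' matters: earlier filters shrink the target union the foreign-domain
#' filter compares against). Counts surviving each stage are recorded in
#' \code{metadata(result)$stageCounts} and, with \code{verbose = TRUE},
#' reported via \code{message()}.
#'
#' @param proteome a \linkS4class{Proteome}: all proteins of the genome.
#' @param tfs a \linkS4class{Proteome}: the query class (typically
#'   transcription factors) whose truncated relatives are sought.
#' @param unwanted character vector of unwanted domain accessions
#'   (typically the class's DNA-binding domains).
#' @param config a \linkS4class{MipConfig}.
#' @param backend a \linkS4class{SearchBackend}.
#' @param domainSource a \linkS4class{DomainLibrary} (scanned with
#'   [scanDomains()]) or a precomputed domain-hit \code{DataFrame} from
#'   [readInterproTsv()].
#' @param verbose emit per-stage counts as messages.
#' @return a prediction \code{DataFrame} sorted by miP id with columns
#'   \code{mip_id}, \code{mip_length}, \code{target_tfs},
#'   \code{target_lengths} (parallel lists), \code{domains} (accessions
#'   mapped on the miP) and \code{tier} (\code{tier1}/\code{tier2}
#'   provenance); write it with [writePredictions()].
#' @export
runPipeline <- function(proteome, tfs, unwanted, config = mipConfig(),
                        backend = builtinBackend(), domainSource,
                        verbose = FALSE) {
    if (length(tfs) == 0L)
        stop("empty query set")
    if (length(proteome) == 0L)
        stop("empty proteome")
    validObject(config)
    validateBackend(backend, proteome, tfs)

    say <- function(...) if (verbose) message(...)
    t1 <- tier1Candidates(tfs, proteome, config, backend)
    say("tier 1: ", length(unique(t1$mip)), " candidate(s)")
    t2 <- tier2Candidates(tfs, proteome, config, backend)
    say("tier 2: ", length(unique(t2$mip)), " candidate(s)")
    cand <- mergeCandidates(t1, t2)
    say("merged: ", length(unique(cand$mip)), " candidate(s)")

    universe <- c(proteome,
                  tfs[!(proteinIds(tfs) %in% proteinIds(proteome))])
    universe <- new("Proteome", universe)
    if (is(domainSource, "DomainLibrary"))
        domainHits <- scanDomains(universe, domainSource)
    else
        domainHits <- domainSource
    arch <- architectureOf(proteinIds(universe), domainHits)
    lens <- proteinLengths(universe)

    cand <- filterUnwantedDomains(cand, arch, unwanted)
    say("after unwanted-domain filter: ", length(unique(cand$mip)),
        " candidate(s)")
    cand <- filterLengthRatio(cand, lens, config@lengthRatio)
    say("after length-ratio filter: ", length(unique(cand$mip)),
        " candidate(s)")
    cand <- filterForeignDomains(cand, arch)
    say("after foreign-domain filter: ", length(unique(cand$mip)),
        " candidate(s)")

    out <- .candidatesToPredictions(cand, lens, arch)
    metadata(out)$stageCounts <- .stageCounts(t1, t2, arch, lens, unwanted,
                                              config, out)
    out
}

.stageCounts <- function(t1, t2, arch, lens, unwanted, config, out) {
    m <- mergeCandidates(t1, t2)
    f1 <- filterUnwantedDomains(m, arch, unwanted)
    f2 <- filterLengthRatio(f1, lens, config@lengthRatio)
    c(tier1 = length(unique(t1$mip)),
      tier2 = length(unique(t2$mip)),
      merged = length(unique(m$mip)),
      after_unwanted = length(unique(f1$mip)),
      after_length_ratio = length(unique(f2$mip)),
      predicted = nrow(out))
}

#' Audit a prediction table against the pipeline invariants
#'
#' Post-hoc check that every emitted prediction satisfies the pipeline's
#' contracts: miP length below the stringent-tier bound (and below the
#' permissive-tier bound for tier-2-only miPs), no unwanted domain on
#' any miP, every (miP, target) pair within the length-ratio bound, and
#' every miP's domain set contained in the union of its targets'
#' domain sets.
#'
#' @param predictions a prediction \code{DataFrame} from [runPipeline()].
#' @param architectures a \code{CharacterList} covering miPs and targets.
#' @param unwanted character vector of unwanted accessions.
#' @param config the \linkS4class{MipConfig} the predictions were made
#'   with.
#' @return a \code{data.frame} of violations (columns \code{mip_id},
#'   \code{check}); zero rows when all invariants hold.
#' @export
auditPredictions <- function(predictions, architectures, unwanted,
                             config = mipConfig()) {
    bad <- list()
    flag <- function(id, check)
        bad[[length(bad) + 1L]] <<- data.frame(mip_id = id, check = check)
    archOf <- function(id)
        if (id %in% names(architectures)) architectures[[id]] else character(0L)
    for (i in seq_len(nrow(predictions))) {
        id <- predictions$mip_id[[i]]
        len <- predictions$mip_length[[i]]
        if (len >= config@maxMipLength)
            flag(id, "length >= maxMipLength")
        if (predictions$tier[[i]] == "tier2" &&
            len >= config@smallProteinLength)
            flag(id, "tier2 length >= smallProteinLength")
        if (any(archOf(id) %in% unwanted))
            flag(id, "unwanted domain present")
        tlen <- predictions$target_lengths[[i]]
        if (length(tlen) == 0L)
            flag(id, "no targets")
        if (any(len > config@lengthRatio * tlen))
            flag(id, "length ratio exceeded")
        un <- unique(unlist(lapply(predictions$target_tfs[[i]], archOf),
                            use.names = FALSE))
        if (!all(predictions$domains[[i]] %in% un))
            flag(id, "foreign domain")
    }
    if (length(bad) == 0L)
        return(data.frame(mip_id = character(), check = character()))
    do.call(rbind, bad)
}
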