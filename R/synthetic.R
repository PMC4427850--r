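DECOY_CLASSES <- c("dbd_retaining", "oversized_paralog", "foreign_domain",
                   "unrelated_random", "tier2_distant")
TRUTH_CLASSES <- c("tf", "true_mip_tier1", "true_mip_tier2", "decoy_dbd",
                   "decoy_oversized", "decoy_foreign", "decoy_random")

.DBD_LEN <- 15L   # synthetic DNA-binding-domain motif length
.PPI_LEN <- 12L   # synthetic protein-protein-interaction motif length
.PPI_TAIL <- 20L  # residues between PPI motif end and TF C-terminus

#' Specification of a synthetic benchmark proteome
#'
#' Describes a proteome of synthetic TF families and planted test cases.
#' Each family carries a unique synthetic DNA-binding-domain (DBD) motif
#' and a unique protein-protein-interaction (PPI) motif embedded in random
#' flanking sequence. Planted classes:
#' \describe{
#'   \item{true miPs (stringent tier)}{TF truncations retaining the PPI
#'     motif, lacking the DBD, diverged at \code{mutationRate}.}
#'   \item{true miPs (permissive tier)}{short proteins sharing only a
#'     \code{tier2SharedLength}-residue window with their TF, diverged at
#'     \code{tier2MutationRate} -- distant enough to escape the stringent
#'     search, close enough to survive the permissive search plus reverse
#'     rescue (enforced at construction time by search-and-redraw).}
#'   \item{decoys}{DBD-retaining truncations, oversized paralogs exceeding
#'     1.1 times the family TF length, miP-like truncations carrying a
#'     foreign domain, and unrelated random sequences.}
#' }
#' All sampling derives from the single \code{seed}; equal specs generate
#' byte-identical fixtures.
#'
#' @slot nFamilies,tfsPerFamily,mipsPerFamily counts.
#' @slot tfLengthRange,mipLengthRange residue intervals
#'   (\code{c(min, max)}).
#' @slot decoyCounts named integer vector over
#'   \code{dbd_retaining, oversized_paralog, foreign_domain,
#'   unrelated_random, tier2_distant} (totals, distributed round-robin
#'   over families).
#' @slot mutationRate,tier2MutationRate per-residue substitution
#'   probabilities.
#' @slot tier2SharedLength length of the TF-derived window in a
#'   permissive-tier miP, residues.
#' @slot seed integer RNG seed.
#' @exportClass FixtureSpec
setClass("FixtureSpec", representation(
    nFamilies = "integer", tfsPerFamily = "integer",
    tfLengthRange = "integer", mipsPerFamily = "integer",
    mipLengthRange = "integer", decoyCounts = "integer",
    mutationRate = "numeric", tier2MutationRate = "numeric",
    tier2SharedLength = "integer", seed = "integer"))

setValidity("FixtureSpec", function(object) {
    msg <- character()
    if (object@nFamilies < 1L || object@tfsPerFamily < 1L)
        msg <- c(msg, "need at least one family with one TF")
    if (object@mipsPerFamily < 0L || any(object@decoyCounts < 0L))
        msg <- c(msg, "counts must be >= 0")
    if (!identical(sort(names(object@decoyCounts)), sort(DECOY_CLASSES)))
        msg <- c(msg, paste("decoyCounts must be named:",
                            paste(DECOY_CLASSES, collapse = ", ")))
    if (length(object@tfLengthRange) != 2L ||
        diff(object@tfLengthRange) < 0L || object@tfLengthRange[1L] < 100L)
        msg <- c(msg, "tfLengthRange must be an ascending interval >= 100")
    if (length(object@mipLengthRange) != 2L ||
        diff(object@mipLengthRange) < 0L ||
        object@mipLengthRange[1L] <= 0L || object@mipLengthRange[2L] >= 550L)
        msg <- c(msg, "mipLengthRange must lie within (0, 550)")
    rates <- c(object@mutationRate, object@tier2MutationRate)
    if (any(rates < 0) || any(rates >= 1))
        msg <- c(msg, "mutation rates must lie in [0, 1)")
    if (object@tier2SharedLength < 10L)
        msg <- c(msg, "tier2SharedLength must be >= 10")
    if (length(msg)) msg else TRUE
})

#' Construct a FixtureSpec
#'
#' Defaults describe the canonical benchmark: 2 TF families of 2 members
#' (350-500 aa), 3 stringent-tier miPs per family (80-180 aa, 5 percent
#' divergence), 3 permissive-tier miPs (45 percent divergence over a
#' 28-residue shared window) and 4 decoys of each remaining class.
#'
#' @param nFamilies,tfsPerFamily,tfLengthRange,mipsPerFamily,mipLengthRange,decoyCounts,mutationRate,tier2MutationRate,tier2SharedLength,seed
#'   see \linkS4class{FixtureSpec}.
#' @return a \linkS4class{FixtureSpec}.
#' @examples
#' fixtureSpec(seed = 1)
#' @export
fixtureSpec <- function(nFamilies = 2L, tfsPerFamily = 2L,
                        tfLengthRange = c(350L, 500L), mipsPerFamily = 3L,
                        mipLengthRange = c(80L, 180L),
                        decoyCounts = c(dbd_retaining = 4L,
                                        oversized_paralog = 4L,
                                        foreign_domain = 4L,
                                        unrelated_random = 4L,
                                        tier2_distant = 3L),
                        mutationRate = 0.05, tier2MutationRate = 0.45,
                        tier2SharedLength = 28L, seed = 42L) {
    new("FixtureSpec", nFamilies = as.integer(nFamilies),
        tfsPerFamily = as.integer(tfsPerFamily),
        tfLengthRange = as.integer(tfLengthRange),
        mipsPerFamily = as.integer(mipsPerFamily),
        mipLengthRange = as.integer(mipLengthRange),
        decoyCounts = vapply(decoyCounts, as.integer, integer(1L)),
        mutationRate = mutationRate, tier2MutationRate = tier2MutationRate,
        tier2SharedLength = as.integer(tier2SharedLength),
        seed = as.integer(seed))
}

setMethod("show", "FixtureSpec", function(object) {
    cat("FixtureSpec:", object@nFamilies, "TF family/ies x",
        object@tfsPerFamily, "member(s),", object@mipsPerFamily,
        "tier-1 miP(s)/family\n  decoys:",
        paste(names(object@decoyCounts), object@decoyCounts, sep = "=",
              collapse = ", "), "\n  seed:", object@seed, "\n")
    invisible(NULL)
})

#' A generated benchmark fixture
#'
#' Holds the synthetic proteome, the matching TF query set, the unwanted
#' (DBD) accession list, the domain library for the built-in scanner and
#' the per-protein ground-truth labels.
#'
#' @slot proteome,tfs \linkS4class{Proteome} objects.
#' @slot unwanted character vector of DBD accessions.
#' @slot library a \linkS4class{DomainLibrary}.
#' @slot truth data.frame with columns \code{id}, \code{class} (one of
#'   tf, true_mip_tier1, true_mip_tier2, decoy_dbd, decoy_oversized,
#'   decoy_foreign, decoy_random) and \code{expected_targets}
#'   (semicolon-joined TF ids, \code{-} for none).
#' @exportClass MipFixture
setClass("MipFixture", representation(
    proteome = "Proteome", tfs = "Proteome", unwanted = "character",
    library = "DomainLibrary", truth = "data.frame"))

#' @rdname MipFixture-class
#' @param x a \code{MipFixture}.
#' @export
fixtureProteome <- function(x) x@proteome

#' @rdname MipFixture-class
#' @export
fixtureTfs <- function(x) x@tfs

#' @rdname MipFixture-class
#' @export
fixtureUnwanted <- function(x) x@unwanted

#' @rdname MipFixture-class
#' @export
fixtureLibrary <- function(x) x@library

#' @rdname MipFixture-class
#' @export
fixtureTruth <- function(x) x@truth

setMethod("show", "MipFixture", function(object) {
    cat("MipFixture:", length(object@proteome), "protein(s),",
        length(object@tfs), "TF(s)\n")
    print(table(object@truth$class))
    invisible(NULL)
})

.withSeed <- function(seed, code) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had)
        old <- get(".Random.seed", envir = globalenv())
    on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    force(code)
}

.randomAA <- function(n) {
    paste(sample(AMINO_ACIDS, n, replace = TRUE), collapse = "")
}

.randomMotif <- function(n, taken = character()) {
    repeat {
        m <- .randomAA(n)
        if (!(m %in% taken))
            return(m)
    }
}

# substitute each unprotected residue with a different one at prob `rate`
.mutate <- function(seq, rate, protect = integer()) {
    ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
    hit <- which(stats::runif(length(ch)) < rate)
    hit <- setdiff(hit, protect)
    for (i in hit)
        ch[i] <- sample(setdiff(AMINO_ACIDS, ch[i]), 1L)
    paste(ch, collapse = "")
}

.drawLen <- function(range) {
    if (range[1L] == range[2L]) range[1L]
    else sample(range[1L]:range[2L], 1L)
}

# family blueprint: base sequence with DBD at [dbdStart, dbdEnd] and PPI
# at [ppiStart, ppiEnd]
.makeFamily <- function(f, spec, taken) {
    len <- .drawLen(spec@tfLengthRange)
    dbd <- .randomMotif(.DBD_LEN, taken)
    ppi <- .randomMotif(.PPI_LEN, c(taken, dbd))
    base <- .randomAA(len)
    dbdStart <- 30L
    ppiEnd <- len - .PPI_TAIL
    ppiStart <- ppiEnd - .PPI_LEN + 1L
    substr(base, dbdStart, dbdStart + .DBD_LEN - 1L) <- dbd
    substr(base, ppiStart, ppiEnd) <- ppi
    list(id = f, len = len, base = base, dbd = dbd, ppi = ppi,
         dbdStart = dbdStart, dbdEnd = dbdStart + .DBD_LEN - 1L,
         ppiStart = ppiStart, ppiEnd = ppiEnd)
}

.makeTf <- function(fam, spec) {
    protect <- c(fam$dbdStart:fam$dbdEnd, fam$ppiStart:fam$ppiEnd)
    .mutate(fam$base, spec@mutationRate, protect)
}

# stringent-tier miP: PPI-retaining C-terminal truncation of the family base
.makeTier1Mip <- function(fam, spec) {
    minLen <- .PPI_LEN + .PPI_TAIL + 3L
    len <- max(.drawLen(spec@mipLengthRange), minLen)
    off <- fam$len - len
    seq <- substr(fam$base, off + 1L, fam$len)
    protect <- (fam$ppiStart - off):(fam$ppiEnd - off)
    .mutate(seq, spec@mutationRate, protect)
}

# permissive-tier miP: random sequence sharing one heavily diverged window
# with the family base, placed at a random position
.makeTier2Mip <- function(fam, spec, smallLimit = 200L) {
    w <- spec@tier2SharedLength
    len <- min(.drawLen(spec@mipLengthRange), smallLimit - 1L)
    len <- max(len, w + 2L)
    seq <- .randomAA(len)
    window <- .mutate(substr(fam$base, fam$ppiEnd - w + 1L, fam$ppiEnd),
                      spec@tier2MutationRate)
    at <- sample(seq_len(len - w + 1L), 1L)
    substr(seq, at, at + w - 1L) <- window
    seq
}

.makeDbdDecoy <- function(fam, spec) {
    start <- fam$dbdStart - 15L
    len <- min(.drawLen(c(120L, 250L)), fam$len - start + 1L)
    seq <- substr(fam$base, start, start + len - 1L)
    protect <- (fam$dbdStart - start + 1L):(fam$dbdEnd - start + 1L)
    .mutate(seq, spec@mutationRate, protect)
}

# full paralog exceeding 1.1x the family TF length; DBD region scrambled so
# the length-ratio filter, not the DBD filter, is what removes it. May
# exceed the 550-aa partition for long families, in which case it is
# partition-killed instead.
.makeOversizedDecoy <- function(fam, spec) {
    lenTarget <- as.integer(ceiling(1.1 * fam$len)) + 8L
    seq <- .mutate(fam$base, spec@mutationRate,
                   protect = fam$ppiStart:fam$ppiEnd)
    substr(seq, fam$dbdStart, fam$dbdEnd) <- .randomAA(.DBD_LEN)
    paste0(seq, .randomAA(lenTarget - fam$len))
}

.makeForeignDecoy <- function(fam, spec, foreignMotif) {
    paste0(.makeTier1Mip(fam, spec), foreignMotif)
}

.assembleFixture <- function(spec, smallLimit = 200L) {
    fams <- list()
    taken <- character()
    for (f in seq_len(spec@nFamilies)) {
        fams[[f]] <- .makeFamily(f, spec, taken)
        taken <- c(taken, fams[[f]]$dbd, fams[[f]]$ppi)
    }
    foreign <- character(spec@nFamilies)
    for (f in seq_len(spec@nFamilies)) {
        foreign[f] <- .randomMotif(.PPI_LEN, taken)
        taken <- c(taken, foreign[f])
    }

    seqs <- character()
    desc <- character()
    truth <- list()
    familyOf <- integer()
    addRecord <- function(id, seq, class, targets, note, family = 1L) {
        seqs[id] <<- seq
        desc[id] <<- note
        familyOf[id] <<- family
        truth[[length(truth) + 1L]] <<- data.frame(
            id = id, class = class,
            expected_targets = if (length(targets))
                paste(targets, collapse = ";") else "-")
    }
    famOf <- function(i) ((i - 1L) %% spec@nFamilies) + 1L
    tfIdsOf <- function(f) sprintf("TF%02d_%d", f, seq_len(spec@tfsPerFamily))

    for (f in seq_len(spec@nFamilies))
        for (j in seq_len(spec@tfsPerFamily))
            addRecord(sprintf("TF%02d_%d", f, j), .makeTf(fams[[f]], spec),
                      "tf", character(0L),
                      sprintf("synthetic TF, family %d", f), f)
    for (f in seq_len(spec@nFamilies))
        for (k in seq_len(spec@mipsPerFamily))
            addRecord(sprintf("MIP1_%02d_%d", f, k),
                      .makeTier1Mip(fams[[f]], spec), "true_mip_tier1",
                      tfIdsOf(f), sprintf("planted miP, family %d", f), f)
    for (i in seq_len(spec@decoyCounts[["tier2_distant"]])) {
        f <- famOf(i)
        addRecord(sprintf("MIP2_%02d_%d", f, i),
                  .makeTier2Mip(fams[[f]], spec, smallLimit),
                  "true_mip_tier2",
                  tfIdsOf(f), sprintf("planted distant miP, family %d", f), f)
    }
    for (i in seq_len(spec@decoyCounts[["dbd_retaining"]])) {
        f <- famOf(i)
        addRecord(sprintf("DECDBD%02d_%d", f, i),
                  .makeDbdDecoy(fams[[f]], spec), "decoy_dbd",
                  character(0L), "decoy: DBD-retaining truncation", f)
    }
    for (i in seq_len(spec@decoyCounts[["oversized_paralog"]])) {
        f <- famOf(i)
        addRecord(sprintf("DECBIG%02d_%d", f, i),
                  .makeOversizedDecoy(fams[[f]], spec), "decoy_oversized",
                  character(0L), "decoy: oversized paralog", f)
    }
    for (i in seq_len(spec@decoyCounts[["foreign_domain"]])) {
        f <- famOf(i)
        addRecord(sprintf("DECFOR%02d_%d", f, i),
                  .makeForeignDecoy(fams[[f]], spec, foreign[f]),
                  "decoy_foreign", character(0L),
                  "decoy: truncation with foreign domain", f)
    }
    for (i in seq_len(spec@decoyCounts[["unrelated_random"]])) {
        addRecord(sprintf("DECRND_%d", i),
                  .randomAA(.drawLen(spec@mipLengthRange)), "decoy_random",
                  character(0L), "decoy: unrelated random sequence")
    }

    truth <- do.call(rbind, truth)
    lib <- domainLibrary(
        c(sprintf("SYNDBD%02d", seq_len(spec@nFamilies)),
          sprintf("SYNPPI%02d", seq_len(spec@nFamilies)),
          sprintf("SYNFOR%02d", seq_len(spec@nFamilies))),
        c(vapply(fams, `[[`, character(1L), "dbd"),
          vapply(fams, `[[`, character(1L), "ppi"),
          foreign))
    tfIds <- truth$id[truth$class == "tf"]
    fixture <- new("MipFixture",
        proteome = Proteome(seqs, descriptions = desc),
        tfs = Proteome(seqs[tfIds], descriptions = desc[tfIds]),
        unwanted = sprintf("SYNDBD%02d", seq_len(spec@nFamilies)),
        library = lib, truth = truth)
    list(fixture = fixture, fams = fams, foreign = foreign,
         familyOf = familyOf, smallLimit = smallLimit)
}

.redrawProtein <- function(state, spec, id) {
    truth <- state$fixture@truth
    class <- truth$class[truth$id == id]
    fam <- state$fams[[state$familyOf[[id]]]]
    seq <- switch(class,
        true_mip_tier1 = .makeTier1Mip(fam, spec),
        true_mip_tier2 = .makeTier2Mip(fam, spec, state$smallLimit),
        decoy_random = .randomAA(.drawLen(spec@mipLengthRange)),
        stop("cannot redraw protein of class ", class))
    p <- state$fixture@proteome
    chars <- as.character(p)
    chars[id] <- seq
    state$fixture@proteome <- Proteome(chars,
                                       descriptions = proteinDescriptions(p))
    state
}

#' Generate a synthetic benchmark fixture
#'
#' Builds the proteome described by a \linkS4class{FixtureSpec} and then
#' enforces its detectability promises by construction-time search: the
#' assembled fixture is checked with [verifyFixture()] and any violating
#' stringent-tier miP, permissive-tier miP or random decoy is redrawn
#' (up to \code{maxRetries} rounds) until the promises hold. All
#' randomness derives from \code{spec@seed}; two calls with equal specs
#' return identical fixtures.
#'
#' @param spec a \linkS4class{FixtureSpec}.
#' @param config the \linkS4class{MipConfig} the promises are verified
#'   against.
#' @param scheme the \linkS4class{ScoringScheme} of the verification
#'   searches.
#' @param maxRetries maximum redraw rounds before giving up.
#' @return a \linkS4class{MipFixture}.
#' @examples
#' fix <- generateFixture(fixtureSpec(nFamilies = 1L, tfsPerFamily = 1L,
#'     mipsPerFamily = 1L,
#'     decoyCounts = c(dbd_retaining = 0L, oversized_paralog = 0L,
#'                     foreign_domain = 0L, unrelated_random = 0L,
#'                     tier2_distant = 0L), seed = 7L))
#' fixtureTruth(fix)
#' @export
generateFixture <- function(spec, config = mipConfig(),
                            scheme = scoringScheme(), maxRetries = 60L) {
    minLen <- .PPI_LEN + .PPI_TAIL + 3L
    if (spec@mipLengthRange[2L] < minLen)
        stop("infeasible spec: mipLengthRange cannot accommodate the ",
             "PPI motif (need at least ", minLen, " residues)")
    if (spec@tier2SharedLength > spec@mipLengthRange[2L] - 2L)
        stop("infeasible spec: tier2SharedLength exceeds mipLengthRange")
    backend <- builtinBackend(scheme)
    .withSeed(spec@seed, {
        state <- .assembleFixture(spec, config@smallProteinLength)
        for (round in seq_len(maxRetries)) {
            viol <- verifyFixture(state$fixture, config, backend)
            if (nrow(viol) == 0L)
                break
            redrawable <- unique(viol$id[viol$check != "ppi_motif_missing"])
            if (length(redrawable) == 0L)
                break
            for (id in redrawable)
                state <- .redrawProtein(state, spec, id)
        }
        viol <- verifyFixture(state$fixture, config, backend)
        if (nrow(viol) > 0L)
            stop("could not construct a fixture satisfying its ",
                 "detectability promises after ", maxRetries, " rounds: ",
                 paste(unique(viol$id), collapse = ", "))
        state$fixture
    })
}

#' Verify a fixture's detectability promises
#'
#' Re-runs the pipeline's three searches on a fixture and checks the
#' promises its construction makes: every stringent-tier miP carries its
#' family PPI motif and hits a TF of its family at the stringent cutoff;
#' every permissive-tier miP escapes the stringent search but passes the
#' permissive search and the reverse rescue; random decoys produce no
#' candidacy at all. Violations are returned as data, not raised.
#'
#' @param fixture a \linkS4class{MipFixture}.
#' @param config a \linkS4class{MipConfig}.
#' @param backend a \linkS4class{SearchBackend}.
#' @return a data.frame of violations (columns \code{id}, \code{check});
#'   zero rows when all promises hold.
#' @export
verifyFixture <- function(fixture, config = mipConfig(),
                          backend = builtinBackend()) {
    proteome <- fixture@proteome
    tfs <- fixture@tfs
    truth <- fixture@truth
    tfIds <- proteinIds(tfs)
    viol <- list()
    flag <- function(id, check)
        viol[[length(viol) + 1L]] <<- data.frame(id = id, check = check)

    p550 <- partitionByLength(proteome, config@maxMipLength)
    p200 <- partitionByLength(proteome, config@smallProteinLength)
    t1hits <- if (length(p550))
        backendSearch(backend, "forward", tfs, p550, config@tier1Cutoff)
    else .emptyHits()
    fwd <- if (length(p200))
        backendSearch(backend, "small", tfs, p200, config@tier2Cutoff)
    else .emptyHits()
    subjects <- setdiff(unique(fwd$subject), tfIds)
    rev <- if (length(subjects))
        backendSearch(backend, "reverse", proteome[subjects], tfs,
                      config@reverseCutoff)
    else .emptyHits()
    t1ids <- setdiff(unique(t1hits$subject), tfIds)

    ppiPatterns <- domainPatterns(fixture@library)
    ppiPatterns <- ppiPatterns[grepl("PPI", names(ppiPatterns))]
    seqs <- as.character(proteome)

    for (i in seq_len(nrow(truth))) {
        id <- truth$id[i]
        cls <- truth$class[i]
        expected <- strsplit(truth$expected_targets[i], ";", fixed = TRUE)[[1L]]
        if (cls == "true_mip_tier1") {
            if (length(ppiPatterns) &&
                !any(vapply(ppiPatterns, function(p) grepl(p, seqs[[id]]),
                            logical(1L))))
                flag(id, "ppi_motif_missing")
            ok <- any(t1hits$subject == id & t1hits$query %in% expected)
            if (!ok)
                flag(id, "tier1_not_detected")
        } else if (cls == "true_mip_tier2") {
            if (id %in% t1ids)
                flag(id, "tier2_detected_by_tier1")
            else if (!(id %in% fwd$subject))
                flag(id, "tier2_no_forward_hit")
            else if (!any(rev$query == id & rev$subject %in% expected))
                flag(id, "tier2_no_reverse_hit")
        } else if (cls == "decoy_random") {
            if (id %in% t1ids)
                flag(id, "random_decoy_hit_tier1")
            else if (id %in% rev$query)
                flag(id, "random_decoy_passed_tier2")
        }
    }
    if (length(viol) == 0L)
        return(data.frame(id = character(), check = character()))
    unique(do.call(rbind, viol))
}

#' Write / read a fixture directory
#'
#' Writes \code{proteome.fasta}, \code{tfs.fasta}, \code{unwanted.txt},
#' \code{domain_lib.tsv} and \code{truth.tsv} (tab-delimited id / class /
#' expected_targets) into \code{dir}; \code{readFixture} reassembles the
#' \linkS4class{MipFixture} from such a directory.
#'
#' @param fixture a \linkS4class{MipFixture}.
#' @param dir directory path (created if missing).
#' @return invisibly, \code{dir}; \code{readFixture}: a
#'   \linkS4class{MipFixture}.
#' @export
writeFixture <- function(fixture, dir) {
    if (!dir.exists(dir))
        dir.create(dir, recursive = TRUE)
    writeProteome(fixture@proteome, file.path(dir, "proteome.fasta"))
    writeProteome(fixture@tfs, file.path(dir, "tfs.fasta"))
    writeLines(fixture@unwanted, file.path(dir, "unwanted.txt"))
    writeDomainLibrary(fixture@library, file.path(dir, "domain_lib.tsv"))
    utils::write.table(fixture@truth, file.path(dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(dir)
}

#' @rdname writeFixture
#' @export
readFixture <- function(dir) {
    truth <- utils::read.table(file.path(dir, "truth.tsv"), sep = "\t",
                               header = TRUE, stringsAsFactors = FALSE)
    new("MipFixture",
        proteome = readProteome(file.path(dir, "proteome.fasta")),
        tfs = readProteome(file.path(dir, "tfs.fasta")),
        unwanted = readUnwantedDomains(file.path(dir, "unwanted.txt")),
        library = readDomainLibrary(file.path(dir, "domain_lib.tsv")),
        truth = truth)
}
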