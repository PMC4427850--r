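# Shared fixtures, built once per test session.
.fixtureCache <- new.env(parent = emptyenv())

# The canonical benchmark: default spec, seed 42.
defaultFixture <- function() {
    if (is.null(.fixtureCache$default))
        .fixtureCache$default <- generateFixture(fixtureSpec(seed = 42L))
    .fixtureCache$default
}

# A one-family miniature for cheap pipeline-operation tests.
smallFixture <- function() {
    if (is.null(.fixtureCache$small))
        .fixtureCache$small <- generateFixture(fixtureSpec(
            nFamilies = 1L, tfsPerFamily = 1L, mipsPerFamily = 2L,
            decoyCounts = c(dbd_retaining = 1L, oversized_paralog = 1L,
                            foreign_domain = 1L, unrelated_random = 1L,
                            tier2_distant = 1L),
            seed = 11L))
    .fixtureCache$small
}

defaultPredictions <- function() {
    if (is.null(.fixtureCache$predictions)) {
        fix <- defaultFixture()
        .fixtureCache$predictions <- runPipeline(
            fixtureProteome(fix), fixtureTfs(fix), fixtureUnwanted(fix),
            mipConfig(), builtinBackend(), fixtureLibrary(fix))
    }
    .fixtureCache$predictions
}

# The three search tables the pipeline performs on a fixture, at the
# cutoffs of `config` (mirrors what the precomputed backend replays).
pipelineSearchTables <- function(fix, config = mipConfig(),
                                 scheme = scoringScheme()) {
    proteome <- fixtureProteome(fix)
    tfs <- fixtureTfs(fix)
    p550 <- partitionByLength(proteome, 550L)
    p200 <- partitionByLength(proteome, 200L)
    fwd <- searchProteins(tfs, p550, config@tier1Cutoff, scheme)
    small <- searchProteins(tfs, p200, config@tier2Cutoff, scheme)
    subjects <- setdiff(unique(small$subject), proteinIds(tfs))
    rev <- if (length(subjects))
        searchProteins(proteome[subjects], tfs, config@reverseCutoff, scheme)
    else small[0L, ]
    list(forward = fwd, small = small, reverse = rev)
}

# Truth classes of a set of predicted ids.
truthClassOf <- function(ids, fix) {
    truth <- fixtureTruth(fix)
    truth$class[match(ids, truth$id)]
}

candidateFrame <- function(mip, tf, evalue, tier) {
    S4Vectors::DataFrame(mip = mip, tf = tf, evalue = evalue, tier = tier)
}
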