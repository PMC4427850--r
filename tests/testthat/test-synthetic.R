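test_that("equal specs generate byte-identical fixture directories", {
    spec <- fixtureSpec(nFamilies = 1L, tfsPerFamily = 1L, mipsPerFamily = 1L,
                        decoyCounts = c(dbd_retaining = 1L,
                                        oversized_paralog = 0L,
                                        foreign_domain = 0L,
                                        unrelated_random = 1L,
                                        tier2_distant = 1L),
                        seed = 99L)
    d1 <- withr::local_tempdir()
    d2 <- withr::local_tempdir()
    writeFixture(generateFixture(spec), d1)
    writeFixture(generateFixture(spec), d2)
    for (f in list.files(d1))
        expect_identical(readLines(file.path(d1, f)),
                         readLines(file.path(d2, f)), info = f)
    # and the generator does not disturb the caller's RNG stream
    set.seed(1)
    before <- stats::runif(1)
    set.seed(1)
    invisible(generateFixture(spec))
    expect_identical(stats::runif(1), before)
})

test_that("fixture composition matches the FixtureSpec counts and labels", {
    spec <- fixtureSpec(nFamilies = 1L, tfsPerFamily = 2L, mipsPerFamily = 2L,
                        decoyCounts = c(dbd_retaining = 0L,
                                        oversized_paralog = 0L,
                                        foreign_domain = 0L,
                                        unrelated_random = 0L,
                                        tier2_distant = 0L),
                        seed = 5L)
    fix <- generateFixture(spec)
    # zero decoys, one family: proteome = TFs + tier-1 miPs
    expect_identical(length(fixtureProteome(fix)), 4L)
    truth <- fixtureTruth(fix)
    expect_identical(nrow(truth), length(fixtureProteome(fix)))
    expect_setequal(truth$class, c("tf", "true_mip_tier1"))
    # every non-TF is labeled exactly once with resolvable targets
    expect_false(anyDuplicated(truth$id) > 0L)
    mips <- truth[truth$class == "true_mip_tier1", ]
    for (t in strsplit(mips$expected_targets, ";"))
        expect_true(all(t %in% proteinIds(fixtureTfs(fix))))
})

test_that("planted classes carry the motif structure they promise", {
    fix <- defaultFixture()
    truth <- fixtureTruth(fix)
    seqs <- as.character(fixtureProteome(fix))
    pats <- domainPatterns(fixtureLibrary(fix))
    dbd <- pats[grepl("DBD", names(pats))]
    hasAny <- function(seq, ps) any(vapply(ps, grepl, logical(1L), x = seq))
    for (i in seq_len(nrow(truth))) {
        s <- seqs[[truth$id[i]]]
        cls <- truth$class[i]
        if (cls %in% c("true_mip_tier1", "true_mip_tier2"))
            expect_false(hasAny(s, dbd), label = truth$id[i])
        if (cls %in% c("tf", "decoy_dbd"))
            expect_true(hasAny(s, dbd), label = truth$id[i])
    }
    # oversized paralogs exceed 1.1x every expected family TF length
    lens <- proteinLengths(fixtureProteome(fix))
    tfLens <- lens[truth$id[truth$class == "tf"]]
    for (id in truth$id[truth$class == "decoy_oversized"])
        expect_true(lens[[id]] > 1.1 * min(tfLens) || lens[[id]] >= 550L)
})

test_that("verifyFixture passes clean fixtures and flags doctored ones", {
    fix <- defaultFixture()
    expect_identical(nrow(verifyFixture(fix)), 0L)

    # delete the PPI motif of one stringent-tier miP: promise broken
    truth <- fixtureTruth(fix)
    mip <- truth$id[truth$class == "true_mip_tier1"][1L]
    pats <- domainPatterns(fixtureLibrary(fix))
    ppi <- pats[grepl("PPI", names(pats))]
    chars <- as.character(fixtureProteome(fix))
    doctored <- chars[[mip]]
    for (p in ppi)
        doctored <- gsub(p, paste(rep("A", nchar(p)), collapse = ""),
                         doctored)
    chars[[mip]] <- doctored
    fix2 <- new("MipFixture", proteome = Proteome(chars),
                tfs = fixtureTfs(fix), unwanted = fixtureUnwanted(fix),
                library = fixtureLibrary(fix), truth = truth)
    viol <- verifyFixture(fix2)
    expect_true(mip %in% viol$id)
    expect_true("ppi_motif_missing" %in% viol$check[viol$id == mip])
})

test_that("a fixture with zero planted miPs verifies trivially", {
    spec <- fixtureSpec(nFamilies = 1L, tfsPerFamily = 1L, mipsPerFamily = 0L,
                        decoyCounts = c(dbd_retaining = 1L,
                                        oversized_paralog = 0L,
                                        foreign_domain = 0L,
                                        unrelated_random = 1L,
                                        tier2_distant = 0L),
                        seed = 13L)
    fix <- generateFixture(spec)
    expect_identical(nrow(verifyFixture(fix)), 0L)
})

test_that("infeasible specs are rejected before generation", {
    spec <- fixtureSpec(mipLengthRange = c(10L, 20L), tier2SharedLength = 10L)
    expect_error(generateFixture(spec), "infeasible")
})

test_that("fixture directories round-trip through readFixture", {
    fix <- smallFixture()
    d <- withr::local_tempdir()
    writeFixture(fix, d)
    back <- readFixture(d)
    expect_identical(as.character(fixtureProteome(back)),
                     as.character(fixtureProteome(fix)))
    expect_identical(fixtureUnwanted(back), fixtureUnwanted(fix))
    expect_identical(domainPatterns(fixtureLibrary(back)),
                     domainPatterns(fixtureLibrary(fix)))
    expect_identical(fixtureTruth(back), fixtureTruth(fix))
})
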