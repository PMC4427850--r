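test_that("the scanner finds literal and wildcard motifs with exact spans", {
    lib <- domainLibrary(c("TESTDBD01", "PPIWILD"),
                         c("WRKYGQKW", "RRK.KK"))
    p <- Proteome(c(p1 = "AAAWRKYGQKWAAA",   # literal, once
                    p2 = "AARRKWKKAA",        # wildcard
                    p3 = "MKVLMKVL"))          # nothing
    hits <- scanDomains(p, lib)
    expect_identical(nrow(hits), 2L)
    h1 <- hits[hits$protein == "p1", ]
    expect_identical(c(h1$start, h1$end), c(4L, 11L))
    h2 <- hits[hits$protein == "p2", ]
    expect_identical(h2$domain, "PPIWILD")
    expect_identical(c(h2$start, h2$end), c(3L, 8L))
    expect_false("p3" %in% hits$protein)
})

test_that("overlapping occurrences are each reported", {
    lib <- domainLibrary("REP01", "ASASAS")
    hits <- scanDomains(Proteome(c(p1 = "CASASASASC")), lib)
    expect_identical(hits$start, c(2L, 4L))
})

test_that("adding library patterns never removes existing hits", {
    fix <- smallFixture()
    lib <- fixtureLibrary(fix)
    hits <- scanDomains(fixtureProteome(fix), lib)
    bigger <- domainLibrary(c(domainAccessions(lib), "EXTRA01"),
                            c(unname(domainPatterns(lib)), "WWWWWHHHHH"))
    hits2 <- scanDomains(fixtureProteome(fix), bigger)
    key <- function(h) paste(h$protein, h$domain, h$start)
    expect_true(all(key(hits) %in% key(hits2)))
})

test_that("architectures are deduplicated sets, empty for unseen proteins", {
    hits <- S4Vectors::DataFrame(protein = c("p1", "p1", "p1"),
                                 domain = c("D1", "D1", "D2"),
                                 start = c(1L, 10L, 20L),
                                 end = c(6L, 15L, 26L))
    arch <- architectureOf(c("p1", "p2", "p3"), hits)
    expect_identical(arch[["p1"]], c("D1", "D2"))
    expect_identical(arch[["p2"]], character(0L))
    expect_identical(arch[["p3"]], character(0L))
})

test_that("unwanted-domain membership is a set intersection test", {
    arch <- IRanges::CharacterList(a = c("D1", "DBD1"), b = "D1",
                                   c = character(0L))
    got <- containsUnwanted(arch, "DBD1")
    expect_identical(got, c(a = TRUE, b = FALSE, c = FALSE))
})

test_that("scanning and importing the scanner's own TSV agree", {
    fix <- smallFixture()
    proteome <- fixtureProteome(fix)
    hits <- scanDomains(proteome, fixtureLibrary(fix))
    # write the hits in the InterProScan TSV dialect and read them back
    lines <- sprintf(
        "%s\tmd5\t%d\tSyn\tSYNSIG\tsynthetic motif\t%d\t%d\t1e-9\tT\tdate\t%s\tdesc",
        hits$protein, unname(proteinLengths(proteome)[hits$protein]),
        hits$start, hits$end, hits$domain)
    f <- withr::local_tempfile(lines = lines)
    imported <- readInterproTsv(f)
    ids <- proteinIds(proteome)
    expect_identical(architectureOf(ids, imported),
                     architectureOf(ids, hits))
})

test_that("pipeline output is identical for scanned and imported domains", {
    fix <- smallFixture()
    proteome <- fixtureProteome(fix)
    hits <- scanDomains(proteome, fixtureLibrary(fix))
    predScan <- runPipeline(proteome, fixtureTfs(fix), fixtureUnwanted(fix),
                            mipConfig(), builtinBackend(),
                            fixtureLibrary(fix))
    predImport <- runPipeline(proteome, fixtureTfs(fix), fixtureUnwanted(fix),
                              mipConfig(), builtinBackend(), hits)
    f1 <- withr::local_tempfile()
    f2 <- withr::local_tempfile()
    writePredictions(predScan, f1)
    writePredictions(predImport, f2)
    expect_identical(readLines(f1), readLines(f2))
})
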