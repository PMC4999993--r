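## small hand-built isoform world used across these tests
isoWorld <- function() {
    catalogue <- data.frame(
        entry = c("E1", "E1", "E1", "E2", "E2", "E3", "E3"),
        isoform = c("E1-1", "E1-2", "E1-3", "E2-1", "E2-2", "E3-1", "E3-2"),
        main = c(TRUE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE),
        external = FALSE)
    seqs <- c("E1-1" = strrep("MKTA", 10), "E1-2" = strrep("MKTA", 8),
              "E1-3" = strrep("MKTA", 6), "E2-1" = strrep("LIVE", 10),
              "E2-2" = strrep("LIVE", 7), "E3-1" = strrep("GASP", 10),
              "E3-2" = strrep("GASP", 9))
    list(catalogue = catalogue, seqs = seqs)
}

test_that("isoform filters a-e apply with the main-isoform cascade", {
    w <- isoWorld()
    cat <- w$catalogue; seqs <- w$seqs
    seqs[["E1-2"]] <- strrep("A", 10)              # rule b: too short
    seqs[["E2-2"]] <- paste0(strrep("L", 20), "X") # rule d: non-standard
    cat$external[cat$isoform == "E3-2"] <- TRUE    # rule e
    seqs <- seqs[names(seqs) != "E1-3"]            # rule a: unknown seq
    ds <- filterIsoforms(cat, seqs)
    e <- isoformEntries(ds)
    ## siblings survive when an alternative is dropped
    expect_setequal(e$isoform, c("E1-1", "E2-1", "E3-1"))
    ## an overlong main removes the whole entry (cascade)
    seqs2 <- w$seqs
    seqs2[["E2-1"]] <- strrep("LIVE", 400)         # 1600 residues
    ds2 <- filterIsoforms(w$catalogue, seqs2)
    expect_false(any(isoformEntries(ds2)$entry == "E2"))
    expect_true(all(c("E2-1", "E2-2") %in%
                    setdiff(w$catalogue$isoform,
                            isoformEntries(ds2)$isoform)))
})

test_that("filtering is order-independent", {
    w <- isoWorld()
    seqs <- w$seqs
    seqs[["E1-2"]] <- strrep("A", 5)
    seqs[["E3-1"]] <- strrep("GASP", 500)
    ds1 <- filterIsoforms(w$catalogue, seqs)
    perm <- sample(nrow(w$catalogue))
    ds2 <- filterIsoforms(w$catalogue[perm, ], seqs)
    e1 <- isoformEntries(ds1); e2 <- isoformEntries(ds2)
    expect_setequal(e1$isoform, e2$isoform)
})

test_that("prediction consolidation keeps only curator-compatible calls", {
    o <- parseOBO(chainOBO())
    w <- isoWorld()
    ds <- filterIsoforms(w$catalogue, w$seqs)
    curated <- annotationTable(data.frame(
        protein = c("E1", "E2", "E3"), term = "GO:0000003",
        evidence = "IC"))
    preds <- predictionSet(data.frame(
        protein = c("E1-1", "E1-2", "E1-3", "E2-1", "E3-1"),
        term = c("GO:0000003",   # curated exactly -> kept
                 "GO:0000002",   # ancestor of curated -> implied, kept
                 "GO:0000003",   # below threshold -> dropped
                 "GO:0000001",   # root: not in root-free closure -> dropped
                 "GO:0000003"),
        score = c(0.9, 0.8, 0.2, 0.9, 0.6)))
    ds <- consolidatePredictions(ds, preds, curated, o,
                                 callThreshold = 0.5)
    calls <- isoformCalls(ds)
    expect_equal(calls[["E1-1"]], "GO:0000003")
    expect_equal(calls[["E1-2"]], "GO:0000002")
    expect_equal(calls[["E1-3"]], character())
    expect_equal(calls[["E2-1"]], character())
    ## consolidated calls are always a subset of the raw prediction terms
    raw <- split(predictionScores(preds)$term, predictionScores(preds)$protein)
    for (iso in names(calls))
        expect_true(all(calls[[iso]] %in% c(raw[[iso]], character())))
})

test_that("conservation hits its extremes and counts entries", {
    w <- isoWorld()
    ds <- filterIsoforms(w$catalogue, w$seqs)
    ## every isoform of every entry carries g -> 1
    all3 <- setIsoformCalls(ds, stats::setNames(
        rep(list("g"), 7), w$catalogue$isoform))
    expect_equal(conservation("g", all3, minEntries = 1), 1)
    ## only one isoform of each multi-isoform entry carries g -> 0
    onePer <- setIsoformCalls(ds, list(
        "E1-1" = "g", "E1-2" = character(), "E1-3" = character(),
        "E2-1" = "g", "E2-2" = character(),
        "E3-1" = "g", "E3-2" = character()))
    expect_equal(conservation("g", onePer, minEntries = 1), 0)
    ## below the reporting floor
    expect_true(is.na(conservation("g", onePer, minEntries = 20)))
})

test_that("conservation equals the planted ratio on a 20-entry catalogue", {
    ## 20 two-isoform entries; the term covers both isoforms in 13 of
    ## them and only the main isoform in the other 7 -> 13/20
    entries <- sprintf("G%02d", 1:20)
    cat <- data.frame(entry = rep(entries, each = 2),
                      isoform = paste0(rep(entries, each = 2),
                                       c("-1", "-2")),
                      main = rep(c(TRUE, FALSE), 20), external = FALSE)
    seqs <- stats::setNames(rep(strrep("MKTA", 10), nrow(cat)),
                            cat$isoform)
    ds <- filterIsoforms(cat, seqs)
    calls <- lapply(seq_len(nrow(cat)), function(i) {
        full <- match(cat$entry[[i]], entries) <= 13
        if (full || cat$main[[i]]) "g" else character()
    })
    names(calls) <- cat$isoform
    ds <- setIsoformCalls(ds, calls)
    expect_equal(conservation("g", ds, minEntries = 20), 0.65)
})

test_that("primarity satisfies the three sign cases and scale invariance", {
    w <- isoWorld()
    ds <- filterIsoforms(w$catalogue, w$seqs)
    isoforms <- isoformEntries(ds)$isoform
    mains <- isoformEntries(ds)$isoform[isoformEntries(ds)$main]
    alts <- setdiff(isoforms, mains)
    mkCalls <- function(with) stats::setNames(
        lapply(isoforms, function(i) if (i %in% with) "g" else character()),
        isoforms)
    ## on every main, no alternative -> +1
    expect_equal(primarity("g", setIsoformCalls(ds, mkCalls(mains))), 1)
    ## on all isoforms -> 0
    expect_equal(primarity("g", setIsoformCalls(ds, mkCalls(isoforms))), 0)
    ## on no main, all alternatives -> -1
    expect_equal(primarity("g", setIsoformCalls(ds, mkCalls(alts))), -1)
    ## duplicating every entry leaves the score unchanged
    e <- isoformEntries(ds)
    e2 <- rbind(e, transform(e, entry = paste0(e$entry, "b"),
                             isoform = paste0(e$isoform, "b")))
    seqs2 <- c(w$seqs, stats::setNames(w$seqs, paste0(names(w$seqs), "b")))
    dsDup <- filterIsoforms(
        data.frame(entry = e2$entry, isoform = e2$isoform,
                   main = e2$main, external = FALSE), seqs2)
    dupIso <- isoformEntries(dsDup)$isoform
    callsDup <- stats::setNames(lapply(dupIso, function(i)
        if (i %in% c(mains, paste0(mains, "b"))) "g" else character()),
        dupIso)
    expect_equal(primarity("g", setIsoformCalls(dsDup, callsDup)), 1)
})

test_that("feature enrichment maps medians through mid-rank percentiles", {
    tr <- 1:99
    ## equal medians -> 0
    expect_equal(featureEnrichment(tr, 50)$enrichment, 0)
    ## variant median above every training value -> +1
    expect_equal(featureEnrichment(tr, 1000)$enrichment, 1)
    ## below every training value -> -1
    expect_equal(featureEnrichment(tr, -5)$enrichment, -1)
    ## at the 25th percentile -> -0.5
    fe <- featureEnrichment(1:100, 25.5)
    expect_equal(fe$percentile, 25)
    expect_equal(fe$enrichment, -0.5)
    ## degenerate constant training distribution
    expect_equal(featureEnrichment(rep(2, 5), 2)$enrichment, 0)
    expect_equal(featureEnrichment(rep(2, 5), 9)$enrichment, 1)
    expect_equal(featureEnrichment(rep(2, 5), -1)$enrichment, -1)
})

test_that("feature-score correlation handles degenerate inputs", {
    f <- seq(0, 1, length.out = 20)
    expect_equal(featureScoreCorrelation(f, 2 * f + 3), 1)
    expect_equal(featureScoreCorrelation(f, -f), -1)
    set.seed(6)
    expect_lt(abs(featureScoreCorrelation(rnorm(1000), rnorm(1000))), 0.1)
    expect_true(is.na(featureScoreCorrelation(rep(1, 10), rnorm(10))))
    expect_true(is.na(featureScoreCorrelation(1:2, 2:1)))
})

test_that("group-level correlation summaries report grey cells as NA", {
    set.seed(8)
    mat <- featureMatrix(c(a = strrep("MKTA", 10), b = strrep("LIVE", 9),
                           c = strrep("GASPK", 8), d = strrep("WYFH", 9)))
    rs <- featureGroupCorrelations(mat, c(0.1, 0.9, 0.4, 0.6))
    expect_length(rs, 14L)
    expect_true(all(is.na(rs) | (rs >= -1 & rs <= 1)))
})

test_that("top-half classifier selection uses the per-domain median", {
    onto <- makeToyOntology(18, seed = 2)
    o <- parseOBO(onto$obo)
    terms <- setdiff(goTerms(o), goRoots(o))
    man <- data.frame(term = terms,
                      validationMCC = seq(0.1, 0.9,
                                          length.out = length(terms)))
    top <- topClassifiers(man, o)
    doms <- termNamespace(o, man$term)
    for (d in unique(doms)) {
        sel <- top$term[termNamespace(o, top$term) == d]
        all <- man$term[doms == d]
        expect_true(all(man$validationMCC[man$term %in% sel] >=
                        stats::median(man$validationMCC[man$term %in% all])))
        expect_gte(length(sel), length(all) %/% 2)
    }
})
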