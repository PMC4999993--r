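test_that("benchmarks filter evidence, drop protein binding and propagate", {
    obo <- c(chainOBO(), "[Term]", "id: GO:0005515",
             "name: protein binding", "namespace: molecular_function",
             "is_a: GO:0000001 ! root", "")
    o <- parseOBO(obo)
    raw <- annotationTable(data.frame(
        protein = c("P1", "P2", "P3", "P4", "P5",
                    "P1", "P2", "P3", "P4", "P5", "P1", "P2"),
        term = c("GO:0000003", "GO:0000003", "GO:0000002", "GO:0005515",
                 "GO:0000003", "GO:0000002", "GO:0005515", "GO:0000002",
                 "GO:0005515", "GO:0000002", "GO:0000002", "GO:0000002"),
        evidence = c("EXP", "IEA", "IDA", "IDA", "IPI",
                     "TAS", "EXP", "IEA", "EXP", "IEA", "IC", "IMP")))
    bench <- buildBenchmark(raw, o)
    refs <- benchmarkRefSets(bench, "molecular_function")
    ## hand count: P1 EXP/TAS/IC -> {leaf, mid}; P2 IMP -> {mid} (its leaf
    ## record is IEA, its 0005515 record is excluded); P3 IDA -> {mid};
    ## P4 only protein binding -> absent; P5 leaf via IPI (excluded) and
    ## mid via IEA (excluded) -> absent
    expect_setequal(names(refs), c("P1", "P2", "P3"))
    expect_setequal(refs$P1, c("GO:0000003", "GO:0000002"))
    expect_setequal(refs$P2, "GO:0000002")
    expect_setequal(refs$P3, "GO:0000002")
    expect_false(any(vapply(refs, function(r)
        "GO:0005515" %in% r, logical(1))))
})

test_that("per-protein set arithmetic matches the definitions", {
    expect_equal(proteinPR(c("a", "b"), c("a", "b")),
                 c(tp = 2, fp = 0, fn = 0, precision = 1, recall = 1))
    expect_equal(proteinPR(c("a", "b", "c"), c("a", "d")),
                 c(tp = 1, fp = 2, fn = 1, precision = 1 / 3,
                   recall = 1 / 2))
    empty <- proteinPR(character(), c("a"))
    expect_true(is.na(empty[["precision"]]))
    expect_equal(empty[["recall"]], 0)
})

test_that("a perfect predictor attains precision = recall = F = 1", {
    o <- parseOBO(chainOBO())
    raw <- annotationTable(data.frame(
        protein = c("P1", "P2"), term = c("GO:0000003", "GO:0000002"),
        evidence = "EXP"))
    bench <- buildBenchmark(raw, o)
    preds <- predictionSet(data.frame(
        protein = c("P1", "P2"), term = c("GO:0000003", "GO:0000002"),
        score = 1))
    curve <- prCurve(preds, bench, o, "molecular_function")
    at1 <- curve[curve$threshold == 1, ]
    expect_equal(at1$precision, 1)
    expect_equal(at1$recall, 1)
    expect_equal(at1$F, 1)
    expect_equal(fmax(curve), 1)
})

test_that("averaged metrics equal a brute-force reimplementation", {
    o <- parseOBO(flatOBO(8))
    kids <- setdiff(goTerms(o), goRoots(o))
    set.seed(13)
    proteins <- sprintf("P%d", 1:5)
    refSets <- lapply(proteins, function(p)
        sample(kids, sample(1:4, 1)))
    names(refSets) <- proteins
    raw <- annotationTable(data.frame(
        protein = rep(proteins, lengths(refSets)),
        term = unlist(refSets), evidence = "EXP"))
    bench <- buildBenchmark(raw, o)
    predRows <- do.call(rbind, lapply(proteins, function(p) {
        terms <- sample(kids, sample(2:5, 1))
        data.frame(protein = p, term = terms,
                   score = round(runif(length(terms)), 2))
    }))
    preds <- predictionSet(predRows)
    grid <- seq(0, 1, by = 0.1)
    curve <- prCurve(preds, bench, o, "molecular_function",
                     thresholds = grid)
    predSets <- split(predRows[, c("term", "score")], predRows$protein)
    for (i in seq_along(grid)) {
        want <- oraclePRF(predSets, refSets, grid[[i]])
        expect_equal(curve$precision[[i]], want[["precision"]])
        expect_equal(curve$recall[[i]], want[["recall"]])
        expect_equal(curve$F[[i]], want[["F"]])
    }
    ## per-protein counts are monotone across nested thresholds
    expect_true(all(diff(curve$tp) <= 0))
    expect_true(all(diff(curve$fp) <= 0))
    expect_true(all(diff(curve$fn) >= 0))
    expect_true(all(curve$F <= fmax(curve)))
})

test_that("tie-free top-l trimming is deterministic", {
    o <- parseOBO(flatOBO(5))
    kids <- setdiff(goTerms(o), goRoots(o))
    raw <- annotationTable(data.frame(
        protein = "P1", term = kids[1:2], evidence = "EXP"))
    bench <- buildBenchmark(raw, o)
    preds <- predictionSet(data.frame(
        protein = "P1", term = kids[1:3], score = c(0.9, 0.6, 0.3)))
    r1 <- topLEval(preds, bench, o, "molecular_function", lValues = 1,
                   replicates = 50, seed = 1, minTargets = 1)
    r2 <- topLEval(preds, bench, o, "molecular_function", lValues = 1,
                   replicates = 50, seed = 99, minTargets = 1)
    expect_equal(r1$precision, 1)    # top prediction is correct
    expect_equal(r1, r2)             # no ties, no sampling variance
    ## l = reference size with perfect ranking gives F = 1
    rn <- topLEval(preds, bench, o, "molecular_function", lValues = NA,
                   replicates = 10, seed = 1, minTargets = 1)
    expect_equal(rn$F, 1)
})

test_that("the tie sampler converges to the exchangeable expectation", {
    o <- parseOBO(flatOBO(5))
    kids <- setdiff(goTerms(o), goRoots(o))
    raw <- annotationTable(data.frame(
        protein = "P1", term = kids[1], evidence = "EXP"))
    bench <- buildBenchmark(raw, o)
    ## three all-tied predictions, exactly one correct, l = 1
    preds <- predictionSet(data.frame(
        protein = "P1", term = kids[1:3], score = 0.5))
    r <- topLEval(preds, bench, o, "molecular_function", lValues = 1,
                  replicates = 1000, seed = 4, minTargets = 1)
    sigma <- sqrt((1 / 3) * (2 / 3) / 1000)
    expect_lt(abs(r$precision - 1 / 3), 2 * sigma)
})

test_that("the 25-target reporting floor suppresses sparse rows", {
    o <- parseOBO(flatOBO(5))
    kids <- setdiff(goTerms(o), goRoots(o))
    raw <- annotationTable(data.frame(
        protein = "P1", term = kids[1], evidence = "EXP"))
    bench <- buildBenchmark(raw, o)
    preds <- predictionSet(data.frame(protein = "P1", term = kids[1],
                                      score = 1))
    r <- topLEval(preds, bench, o, "molecular_function", lValues = 1,
                  replicates = 10, seed = 1)   # default floor of 25
    expect_equal(nrow(r), 0L)
})

test_that("true-positive information sums and telescopes", {
    expect_equal(tpInformation(character(), c("a"), c(a = 1)), 0)
    expect_equal(tpInformation("t", c("t"), c(t = 2)), 2)
    expect_error(tpInformation("t", "t", c(u = 1)), "t")
    ## chain identity: summed IC of a perfectly predicted path equals the
    ## leaf's annotation surprisal
    o <- parseOBO(chainOBO())
    tab <- propagateAnnotations(annotationTable(data.frame(
        protein = sprintf("P%02d", 1:8),
        term = c(rep("GO:0000003", 2), rep("GO:0000001", 6)),
        evidence = "EXP")), o)
    path <- c("GO:0000003", "GO:0000002")
    ic <- termICs(path, tab, o)
    expect_equal(tpInformation(path, path, ic), -log2(2 / 8))
})
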