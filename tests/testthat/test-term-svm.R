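test_that("MCC matches its closed form and conventions", {
    expect_equal(mcc(10, 10, 0, 0), 1)
    expect_equal(mcc(5, 5, 5, 5), 0)
    expect_equal(mcc(50, 40, 10, 0), 0.8165, tolerance = 1e-4)
    ## any zero denominator factor yields 0 by convention
    expect_equal(mcc(0, 10, 0, 5), 0)
    expect_equal(mcc(3, 0, 0, 0), 0)
})

test_that("fold count selection is deterministic and feasibility-checked", {
    expect_equal(chooseK(200), 5L)
    expect_equal(chooseK(32), 3L)    # 32/5 and 32/4 give < 10 per fold
    expect_equal(chooseK(50), 5L)
    expect_equal(chooseK(45), 4L)
    rej <- tryCatch(chooseK(20), condition = identity)
    expect_true(isCandidateRejected(rej))
})

test_that("term datasets separate positives from same-domain negatives", {
    ## chain root <- mid <- leaf plus a sibling branch under the root
    obo <- c(chainOBO(), "[Term]", "id: GO:0000004", "name: sibling",
             "namespace: molecular_function", "is_a: GO:0000001 ! root",
             "")
    o <- parseOBO(obo)
    ## 100 proteins: 40 leaf, 30 only mid, 30 only the sibling branch
    raw <- annotationTable(data.frame(
        protein = sprintf("P%03d", 1:100),
        term = c(rep("GO:0000003", 40), rep("GO:0000002", 30),
                 rep("GO:0000004", 30)),
        evidence = "EXP"))
    tab <- propagateAnnotations(raw, o)
    ds <- assembleTermDataset("GO:0000003", tab, o, minPos = 10)
    expect_length(ds@positives, 40L)
    expect_length(ds@negatives, 60L)
    expect_length(intersect(ds@positives, ds@negatives), 0L)
    ## a protein annotated only with a descendant is positive for the parent
    ds2 <- assembleTermDataset("GO:0000002", tab, o, minPos = 10)
    expect_length(ds2@positives, 70L)
    expect_length(ds2@negatives, 30L)
    ## a term annotating nobody is rejected
    raw0 <- annotationTable(data.frame(protein = "P1",
                                       term = "GO:0000002",
                                       evidence = "EXP"))
    rej <- tryCatch(
        assembleTermDataset("GO:0000003", propagateAnnotations(raw0, o), o),
        condition = identity)
    expect_true(isCandidateRejected(rej))
    ## a term with no same-domain negatives is rejected, not trained
    rawAll <- annotationTable(data.frame(
        protein = sprintf("P%03d", 1:20), term = "GO:0000003",
        evidence = "EXP"))
    rejAll <- tryCatch(
        assembleTermDataset("GO:0000002", propagateAnnotations(rawAll, o),
                            o, minPos = 10),
        condition = identity)
    expect_true(isCandidateRejected(rejAll))
})

test_that("the 70/30 split is stratified within one protein per class", {
    ds <- new("TermDataset", term = "t",
              positives = sprintf("A%03d", 1:63),
              negatives = sprintf("B%03d", 1:117), split = character())
    ds <- splitDataset(ds, seed = 3)
    sp <- ds@split
    expect_equal(sum(sp[ds@positives] == "train"), round(0.7 * 63))
    expect_equal(sum(sp[ds@negatives] == "train"), round(0.7 * 117))
    ## same seed reproduces the same assignment
    expect_identical(splitDataset(ds, seed = 3)@split, sp)
})

test_that("training recovers a planted single-group rule", {
    w <- plantedWorld()
    expect_gte(validationMCC(w$clf), 0.5)
    expect_true("disorder" %in% selectedGroups(w$clf))
    expect_true(isRetained(w$clf))
    ## planted positives score higher than negatives end to end
    sc <- predictScores(w$clf, w$test$features)
    lab <- w$test$truth$label[match(names(sc), w$test$truth$protein)]
    expect_gt(median(sc[lab]), median(sc[!lab]))
    expect_true(all(sc >= 0 & sc <= 1))
    expect_equal(sc, round(sc, 3))  # three-decimal convention
})

test_that("backward elimination never ends below the full-set CV score", {
    ## the full-set score is re-derivable from the committed-removal rule:
    ## each commit required score >= incumbent, so the final CV score is
    ## monotone; verify on a small, fast problem with two feature groups
    set.seed(11)
    n <- 120
    X <- cbind(matrix(rnorm(n * 3), n, 3), matrix(rnorm(n * 2), n, 2))
    colnames(X) <- c(paste0("signal.", 1:3), paste0("noise.", 1:2))
    X[, "signal.1"] <- X[, "signal.1"] + rep(c(2, 0), each = n / 2)
    rownames(X) <- sprintf("P%03d", seq_len(n))
    ds <- new("TermDataset", term = "GO:0000099",
              positives = rownames(X)[1:(n / 2)],
              negatives = rownames(X)[(n / 2 + 1):n], split = character())
    clf <- trainTermClassifier(ds, X, seed = 5)
    expect_true("signal" %in% selectedGroups(clf))
    expect_gte(validationMCC(clf), 0.5)
    ## reproducibility: identical model under the same seed
    clf2 <- trainTermClassifier(ds, X, seed = 5)
    expect_identical(clf@svCoefs, clf2@svCoefs)
    expect_identical(clf@groups, clf2@groups)
    expect_identical(validationMCC(clf), validationMCC(clf2))
})

test_that("a single-point grid collapses to a direct fit", {
    set.seed(21)
    n <- 100
    X <- matrix(rnorm(n * 4), n, 4,
                dimnames = list(sprintf("Q%03d", 1:n),
                                paste0("g.", 1:4)))
    X[, 1] <- X[, 1] + rep(c(1.5, 0), each = n / 2)
    ds <- new("TermDataset", term = "GO:0000098",
              positives = rownames(X)[1:(n / 2)],
              negatives = rownames(X)[(n / 2 + 1):n], split = character())
    g1 <- svmGrid(cost = 2, gammaScale = 1)
    clf <- trainTermClassifier(ds, X, grid = g1, seed = 9)
    expect_equal(clf@cost, 2)
    expect_equal(clf@gamma, 1 / length(clf@featureNames))
})

test_that("Platt calibration maps the sigmoid midpoint to 0.5 monotonically", {
    ## hand-built classifier: single support vector at the origin, unit
    ## coefficient, rho chosen so the decision value at the origin is 0
    clf <- new("TermClassifier", term = "GO:0000097", groups = "g",
               featureNames = "g.1",
               cost = 1, gamma = 1,
               scaleMin = c(g.1 = -1), scaleMax = c(g.1 = 1),
               sv = matrix(0, 1, 1, dimnames = list(NULL, "g.1")),
               svCoefs = 1, rho = 1, plattA = -2, plattB = 0,
               validationMCC = 0.5, retained = TRUE)
    at <- function(x) predictScores(clf, matrix(x, 1, 1,
        dimnames = list("p", "g.1")))
    expect_equal(unname(at(0)), 0.5)    # decision 0 = sigmoid midpoint
    xs <- seq(-1, 1, by = 0.25)
    sc <- vapply(xs, function(x) unname(at(x)), numeric(1))
    ## decision value falls with |x| here, so scores peak at the centre
    expect_equal(which.max(sc), which(xs == 0))
    expect_true(all(diff(sc[xs >= 0]) <= 0))
    ## missing group named in the error
    expect_error(
        predictScores(clf, matrix(0, 1, 1,
                                  dimnames = list("p", "other.1"))),
        "g")
})

test_that("model libraries round-trip through the JSON store", {
    w <- plantedWorld()
    dir <- withr::local_tempdir()
    writeModelLibrary(list(w$clf), dir)
    expect_true(file.exists(file.path(dir, "manifest.tsv")))
    models <- readModelLibrary(dir)
    expect_length(models, 1L)
    back <- models[[1]]
    expect_equal(back@validationMCC, w$clf@validationMCC)
    expect_identical(back@groups, w$clf@groups)
    ## identical scores after the round trip
    sc1 <- predictScores(w$clf, w$test$features[1:10, ])
    sc2 <- predictScores(back, w$test$features[1:10, ])
    expect_equal(sc1, sc2)
})

test_that("prediction TSVs carry exactly three decimals", {
    ps <- predictionSet(data.frame(protein = c("a", "b"),
                                   term = "GO:0000002",
                                   score = c(0.3333333, 1)))
    path <- withr::local_tempfile(fileext = ".tsv")
    writePredictionTSV(ps, path)
    lines <- readLines(path)
    expect_match(lines[2], "\t0\\.333$")
    expect_match(lines[3], "\t1\\.000$")
    back <- readPredictionTSV(path)
    expect_equal(predictionScores(back), predictionScores(ps))
})
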