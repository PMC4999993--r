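#' @include AllClasses.R AllGenerics.R ontology.R features.R
NULL

#' Per-term training dataset
#'
#' Positive and negative protein sets for one GO term, with the stratified
#' 70/30 train/validation assignment.
#'
#' @slot term GO identifier.
#' @slot positives,negatives character vectors of protein ids (disjoint).
#' @slot split named character (\code{"train"} / \code{"validation"}) over
#'   all proteins; empty until \code{\link{splitDataset}} is applied.
#' @exportClass TermDataset
setClass("TermDataset",
         representation(term = "character", positives = "character",
                        negatives = "character", split = "character"))

setValidity("TermDataset", function(object) {
    if (length(intersect(object@positives, object@negatives)))
        return("positives and negatives must be disjoint")
    TRUE
})

## run expr under a local RNG seed, restoring global state afterwards
.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
    expr
}

#' Matthews correlation coefficient
#'
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}}
#' with the usual convention that a zero factor in the denominator yields
#' an MCC of 0.
#'
#' @param tp,tn,fp,fn nonnegative confusion counts.
#' @return numeric in \[-1, 1\].
#' @examples
#' mcc(10, 10, 0, 0)  # 1
#' mcc(5, 5, 5, 5)    # 0
#' @export
mcc <- function(tp, tn, fp, fn) {
    stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
    den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    if (den == 0) return(0)
    (tp * tn - fp * fn) / sqrt(den)
}

.confusion <- function(truth, pred) {
    c(tp = sum(truth == "pos" & pred == "pos"),
      tn = sum(truth == "neg" & pred == "neg"),
      fp = sum(truth == "neg" & pred == "pos"),
      fn = sum(truth == "pos" & pred == "neg"))
}

#' Choose the cross-validation fold count
#'
#' Deterministically selects the largest k in \{5, 4, 3\} such that each
#' stratified fold receives at least \code{minFoldSize} positive
#' instances; the partitions are equally sized within one instance.  When
#' no k is feasible the candidate term is rejected.
#'
#' @param nPos number of positive training instances.
#' @param minFoldSize minimum positives per fold (default 10).
#' @param term term id used in the rejection message.
#' @return integer in \{3, 4, 5\}.
#' @examples
#' chooseK(200)  # 5
#' chooseK(32)   # 3: 32/5 and 32/4 fall below 10 positives per fold
#' @export
chooseK <- function(nPos, minFoldSize = 10L, term = "?") {
    for (k in c(5L, 4L, 3L))
        if (nPos %/% k >= minFoldSize) return(k)
    .rejectCandidate(term, sprintf(
        "no k in {3,4,5} gives >= %d positives per fold (%d positives)",
        minFoldSize, nPos))
}

## descendant closure of a term (excluding itself)
.descendantsOf <- function(onto, term) {
    children <- split(rep(names(onto@parents), lengths(onto@parents)),
                      unlist(onto@parents, use.names = FALSE))
    out <- character(); queue <- term
    while (length(queue)) {
        t <- queue[[1L]]; queue <- queue[-1L]
        ch <- setdiff(children[[t]], out)
        out <- c(out, ch); queue <- c(queue, ch)
    }
    out
}

#' Assemble the training dataset for one GO term
#'
#' Positives are the proteins annotated with the term after "is a"
#' propagation; negatives are proteins annotated somewhere in the same GO
#' domain but neither with the term nor with any of its descendants.
#' Terms with fewer than \code{minPos} positives are rejected with a
#' \code{candidateRejected} condition (see
#' \code{\link{isCandidateRejected}}).
#'
#' @param term GO id.
#' @param table a propagated \linkS4class{AnnotationTable}.
#' @param onto a \linkS4class{GOOntology}.
#' @param minPos minimum number of positives (default 50).
#' @return a \linkS4class{TermDataset} (split not yet assigned).
#' @export
assembleTermDataset <- function(term, table, onto, minPos = 50L) {
    stopifnot(is(table, "AnnotationTable"), isPropagated(table))
    term <- .canonicalIds(onto, term, "assembleTermDataset")
    r <- annotationRecords(table)
    dom <- onto@namespace[[term]]
    domTerms <- onto@terms[onto@namespace[onto@terms] == dom]
    byProt <- split(r$term, r$protein)
    inDomain <- names(byProt)[vapply(byProt, function(ts)
        any(ts %in% domTerms), logical(1))]
    pos <- names(byProt)[vapply(byProt, function(ts) term %in% ts,
                                logical(1))]
    if (length(pos) < minPos)
        .rejectCandidate(term, sprintf("only %d positives (minimum %d)",
                                       length(pos), minPos))
    excl <- c(term, .descendantsOf(onto, term))
    neg <- setdiff(inDomain[!vapply(byProt[inDomain], function(ts)
        any(ts %in% excl), logical(1))], pos)
    if (!length(neg))
        .rejectCandidate(term, "no same-domain negative instances")
    new("TermDataset", term = term, positives = pos, negatives = neg,
        split = character())
}

#' Assign the stratified 70/30 train/validation split
#'
#' @param ds a \linkS4class{TermDataset}.
#' @param seed integer seed controlling the assignment.
#' @param trainFrac training fraction (default 0.7).
#' @return the dataset with its \code{split} slot filled; proportions are
#'   within one protein of the requested fraction in each class.
#' @export
splitDataset <- function(ds, seed = 1L, trainFrac = 0.7) {
    stopifnot(is(ds, "TermDataset"))
    assign1 <- function(ids) {
        nTr <- round(length(ids) * trainFrac)
        tr <- .withSeed(seed + 1000L, sample(ids, nTr))
        out <- stats::setNames(rep("validation", length(ids)), ids)
        out[tr] <- "train"
        out
    }
    ds@split <- c(assign1(ds@positives), assign1(ds@negatives))
    ds
}

#' Default RBF hyperparameter grid
#'
#' Log-spaced grid over the SVM cost and the RBF width.  \code{gammaScale}
#' multiplies the dimensionality heuristic \code{1/ncol(X)}, so the grid
#' adapts to the number of features surviving group elimination.
#'
#' @param cost numeric vector of cost values.
#' @param gammaScale numeric vector of multipliers of \code{1/ncol}.
#' @return data.frame with columns \code{cost}, \code{gammaScale}.
#' @export
svmGrid <- function(cost = 2^c(-1, 1, 3), gammaScale = 4^(-1:1)) {
    expand.grid(cost = cost, gammaScale = gammaScale,
                KEEP.OUT.ATTRS = FALSE)
}

## per-column [-1,1] scaler fitted on training data
.fitScaler <- function(X) {
    list(min = apply(X, 2L, min), max = apply(X, 2L, max))
}
.applyScaler <- function(X, sc) {
    rng <- sc$max - sc$min
    out <- sweep(X, 2L, sc$min)
    out <- sweep(out, 2L, ifelse(rng > 0, rng, 1), "/") * 2 - 1
    out[, rng == 0] <- 0          # columns constant in training map to 0
    out
}

.classWeights <- function(y) {
    n <- length(y)
    c(pos = n / (2 * sum(y == "pos")), neg = n / (2 * sum(y == "neg")))
}

.fitSVM <- function(X, y, cost, gamma, fitted = FALSE) {
    e1071::svm(x = X, y = y, scale = FALSE, kernel = "radial",
               cost = cost, gamma = gamma, fitted = fitted,
               class.weights = .classWeights(y))
}

## decision values oriented so positive favours the "pos" class
.decisionValues <- function(model, X) {
    p <- stats::predict(model, X, decision.values = TRUE)
    dv <- attr(p, "decision.values")
    if (colnames(dv)[[1L]] == "neg/pos") dv <- -dv
    as.numeric(dv)
}

## stratified fold assignment; returns integer fold per row of y
.makeFolds <- function(y, k, seed) {
    .withSeed(seed, {
        fold <- integer(length(y))
        for (cl in levels(y)) {
            idx <- which(y == cl)
            fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
        }
        fold
    })
}

## grid search for one group set; per-fold scaled matrices are computed
## once and shared across all grid points.  Returns list(score, cost,
## gammaScale) with score = best mean CV MCC.
.gridSearch <- function(X, y, fold, grid) {
    k <- max(fold)
    folds <- lapply(seq_len(k), function(f) {
        tr <- fold != f
        sc <- .fitScaler(X[tr, , drop = FALSE])
        list(Xtr = .applyScaler(X[tr, , drop = FALSE], sc),
             ytr = y[tr],
             Xte = .applyScaler(X[!tr, , drop = FALSE], sc),
             yte = as.character(y[!tr]))
    })
    best <- list(score = -Inf, cost = NA_real_, gammaScale = NA_real_)
    for (i in seq_len(nrow(grid))) {
        gamma <- grid$gammaScale[[i]] / ncol(X)
        scores <- vapply(folds, function(fd) {
            m <- .fitSVM(fd$Xtr, fd$ytr, grid$cost[[i]], gamma)
            pred <- stats::predict(m, fd$Xte)
            cc <- .confusion(fd$yte, as.character(pred))
            mcc(cc[["tp"]], cc[["tn"]], cc[["fp"]], cc[["fn"]])
        }, numeric(1))
        s <- mean(scores)
        if (s > best$score)
            best <- list(score = s, cost = grid$cost[[i]],
                         gammaScale = grid$gammaScale[[i]])
    }
    best
}

## Platt's sigmoid fit (Lin, Lin & Weng's stabilised Newton iteration):
## returns c(A, B) for P(pos | d) = 1 / (1 + exp(A d + B))
.fitPlatt <- function(dec, y) {
    n1 <- sum(y == "pos"); n0 <- sum(y == "neg")
    t <- ifelse(y == "pos", (n1 + 1) / (n1 + 2), 1 / (n0 + 2))
    A <- 0; B <- log((n0 + 1) / (n1 + 1))
    fApB <- function(A, B) A * dec + B
    obj <- function(A, B) {
        z <- fApB(A, B)
        sum(ifelse(z >= 0, t * z + log1p(exp(-z)),
                   (t - 1) * z + log1p(exp(z))))
    }
    fval <- obj(A, B)
    for (it in 1:100) {
        z <- fApB(A, B)
        p <- ifelse(z >= 0, exp(-z) / (1 + exp(-z)), 1 / (1 + exp(z)))
        q <- 1 - p
        d1 <- t - p
        d2 <- p * q
        g1 <- sum(dec * d1); g2 <- sum(d1)
        if (abs(g1) < 1e-5 && abs(g2) < 1e-5) break
        h11 <- sum(dec * dec * d2) + 1e-12
        h22 <- sum(d2) + 1e-12
        h21 <- sum(dec * d2)
        det <- h11 * h22 - h21 * h21
        dA <- -(h22 * g1 - h21 * g2) / det
        dB <- -(-h21 * g1 + h11 * g2) / det
        gd <- g1 * dA + g2 * dB
        step <- 1
        repeat {
            newA <- A + step * dA; newB <- B + step * dB
            newf <- obj(newA, newB)
            if (newf < fval + 1e-4 * step * gd) {
                A <- newA; B <- newB; fval <- newf; break
            }
            step <- step / 2
            if (step < 1e-10) break
        }
        if (step < 1e-10) break
    }
    c(A = A, B = B)
}

## extract an explicit decision function from a fitted e1071 model,
## sign-normalised so positive decision values favour "pos"
.explicitModel <- function(model, Xs) {
    sv <- model$SV
    coefs <- as.numeric(model$coefs)
    rho <- as.numeric(model$rho)
    recon <- .rbfDecision(Xs[1:min(5L, nrow(Xs)), , drop = FALSE],
                          sv, coefs, rho, model$gamma)
    ref <- .decisionValues(model, Xs[1:min(5L, nrow(Xs)), , drop = FALSE])
    if (sum((recon - ref)^2) > sum((recon + ref)^2)) {
        coefs <- -coefs; rho <- -rho
    }
    list(sv = sv, coefs = coefs, rho = rho)
}

.rbfDecision <- function(X, sv, coefs, rho, gamma) {
    cross <- X %*% t(sv)
    d2 <- outer(rowSums(X^2), rowSums(sv^2), "+") - 2 * cross
    K <- exp(-gamma * pmax(d2, 0))
    as.numeric(K %*% coefs - rho)
}

#' Train one GO term's classifier
#'
#' Runs the full per-term protocol: stratified 70/30 split; fold count
#' from \code{\link{chooseK}}; grid search of the RBF hyperparameters by
#' k-fold cross-validated mean MCC on the full feature-group set; greedy
#' backward elimination of feature groups (each candidate removal gets a
#' fresh grid search; the best removal is committed while it does not
#' decrease the incumbent CV MCC, until no removal helps or one group
#' remains); refit on the 70 percent training split with the winning
#' configuration; validation MCC on the held-out 30 percent; retention iff the
#' validation MCC reaches 0.05; and, for retained terms, a refit on the
#' joint train+validation data with a Platt sigmoid fitted to internally
#' cross-validated decision values.
#'
#' Features are scaled into \[-1, 1\] columnwise using statistics of the
#' data the SVM at hand is fitted on; columns constant in training map to
#' 0.  Class imbalance is handled by per-class error weights proportional
#' to inverse class frequency.  All randomness (split, folds, one fold
#' resampling on a degenerate single-class fold) derives from \code{seed};
#' with the seed fixed the procedure is reproducible.
#'
#' @param ds a \linkS4class{TermDataset}.
#' @param features numeric feature matrix (rows = proteins, columns named
#'   \code{group.index}) covering all dataset proteins.
#' @param grid hyperparameter grid from \code{\link{svmGrid}}.
#' @param seed integer seed.
#' @param minFoldSize minimum positives per CV fold (default 10).
#' @return a \linkS4class{TermClassifier}.
#' @export
trainTermClassifier <- function(ds, features, grid = svmGrid(),
                                seed = 1L, minFoldSize = 10L) {
    stopifnot(is(ds, "TermDataset"), nrow(grid) >= 1L)
    if (!length(ds@split)) ds <- splitDataset(ds, seed)
    prots <- c(ds@positives, ds@negatives)
    missing <- setdiff(prots, rownames(features))
    if (length(missing))
        stop("feature matrix lacks rows for ",
             length(missing), " proteins (e.g. ", missing[[1L]], ")")
    y <- factor(ifelse(prots %in% ds@positives, "pos", "neg"),
                levels = c("pos", "neg"))
    names(y) <- prots
    trainIds <- prots[ds@split[prots] == "train"]
    validIds <- prots[ds@split[prots] == "validation"]
    Xtr <- features[trainIds, , drop = FALSE]
    ytr <- y[trainIds]
    if (!ncol(Xtr)) stop("empty feature matrix: no groups to train on")
    allGroups <- unique(sub("\\.[0-9]+$", "", colnames(features)))

    k <- chooseK(sum(ytr == "pos"), minFoldSize, ds@term)
    fold <- .makeFolds(ytr, k, seed + 2000L)
    degenerate <- function(f) any(vapply(seq_len(k), function(i)
        length(unique(ytr[f != i])) < 2L, logical(1)))
    if (degenerate(fold)) {
        fold <- .makeFolds(ytr, k, seed + 2001L)
        if (degenerate(fold))
            .rejectCandidate(ds@term, "degenerate single-class CV fold")
    }

    evalGroups <- function(groups) {
        cols <- .groupColumns(colnames(Xtr), groups)
        .gridSearch(Xtr[, cols, drop = FALSE], ytr, fold, grid)
    }

    ## (2) full group set, then (3) greedy backward elimination
    groups <- allGroups
    incumbent <- evalGroups(groups)
    repeat {
        if (length(groups) == 1L) break
        cand <- lapply(seq_along(groups),
                       function(i) evalGroups(groups[-i]))
        scores <- vapply(cand, `[[`, numeric(1), "score")
        bestI <- which.max(scores)
        if (scores[[bestI]] >= incumbent$score) {
            groups <- groups[-bestI]
            incumbent <- cand[[bestI]]
        } else break
    }

    ## (4) refit on the full 70% train split, (5) held-out validation MCC
    cols <- .groupColumns(colnames(features), groups)
    gamma <- incumbent$gammaScale / length(cols)
    scTr <- .fitScaler(Xtr[, cols, drop = FALSE])
    mTr <- .fitSVM(.applyScaler(Xtr[, cols, drop = FALSE], scTr), ytr,
                   incumbent$cost, gamma)
    predV <- stats::predict(
        mTr, .applyScaler(features[validIds, cols, drop = FALSE], scTr))
    cc <- .confusion(as.character(y[validIds]), as.character(predV))
    vmcc <- mcc(cc[["tp"]], cc[["tn"]], cc[["fp"]], cc[["fn"]])
    retained <- vmcc >= 0.05

    ## (7) final model: retained terms are refit on train+validation;
    ## Platt scaling always uses cross-validated decision values so the
    ## sigmoid is never fitted on training scores
    finIds <- if (retained) prots else trainIds
    Xf <- features[finIds, cols, drop = FALSE]
    yf <- y[finIds]
    scF <- .fitScaler(Xf)
    Xfs <- .applyScaler(Xf, scF)
    kp <- min(k, sum(yf == "pos"), sum(yf == "neg"))
    pFold <- .makeFolds(yf, kp, seed + 3000L)
    dec <- numeric(length(yf))
    for (f in seq_len(kp)) {
        tr <- pFold != f
        if (length(unique(yf[tr])) < 2L) { dec[!tr] <- 0; next }
        mf <- .fitSVM(Xfs[tr, , drop = FALSE], yf[tr],
                      incumbent$cost, gamma)
        dec[!tr] <- .decisionValues(mf, Xfs[!tr, , drop = FALSE])
    }
    platt <- .fitPlatt(dec, as.character(yf))
    mF <- .fitSVM(Xfs, yf, incumbent$cost, gamma)
    ex <- .explicitModel(mF, Xfs)

    new("TermClassifier", term = ds@term, groups = groups,
        featureNames = cols, cost = incumbent$cost, gamma = gamma,
        scaleMin = scF$min, scaleMax = scF$max,
        sv = ex$sv, svCoefs = ex$coefs, rho = ex$rho,
        plattA = unname(platt[["A"]]), plattB = unname(platt[["B"]]),
        validationMCC = unname(vmcc), retained = retained)
}

#' Score sequences with a trained term classifier
#'
#' Applies the stored scaling, evaluates the RBF decision function and
#' maps it through the Platt sigmoid to a posterior-style confidence,
#' rounded to three decimals.
#'
#' @param clf a \linkS4class{TermClassifier}.
#' @param features a \linkS4class{FeatureVector}, or a numeric feature
#'   matrix with the classifier's feature columns present.
#' @return named numeric vector of scores in \[0, 1\].
#' @export
predictScores <- function(clf, features) {
    stopifnot(is(clf, "TermClassifier"))
    if (is(features, "FeatureVector"))
        features <- t(as.matrix(featureValues(features)))
    missing <- setdiff(clf@featureNames, colnames(features))
    if (length(missing)) {
        grp <- unique(sub("\\.[0-9]+$", "", missing))
        stop("features lack selected group(s): ",
             paste(grp, collapse = ", "))
    }
    X <- features[, clf@featureNames, drop = FALSE]
    Xs <- .applyScaler(X, list(min = clf@scaleMin, max = clf@scaleMax))
    d <- .rbfDecision(Xs, clf@sv, clf@svCoefs, clf@rho, clf@gamma)
    score <- .round3(1 / (1 + exp(clf@plattA * d + clf@plattB)))
    names(score) <- rownames(features)
    score
}

#' @describeIn predictScores S4 predict method for TermClassifier
#' @param object a \linkS4class{TermClassifier}.
#' @param ... passed on; first argument is the feature input.
#' @export
setMethod("predict", "TermClassifier",
          function(object, ...) predictScores(object, ...))

#' Construct a PredictionSet
#' @param scores data.frame with columns protein, term, score; scores are
#'   rounded to three decimals.
#' @return a \linkS4class{PredictionSet}.
#' @export
predictionSet <- function(scores) {
    scores <- as.data.frame(scores)[, c("protein", "term", "score")]
    scores$protein <- as.character(scores$protein)
    scores$term <- as.character(scores$term)
    scores$score <- .round3(as.numeric(scores$score))
    rownames(scores) <- NULL
    new("PredictionSet", scores = scores)
}

#' Predict a term library over a feature matrix
#'
#' @param models list of \linkS4class{TermClassifier} objects.
#' @param features feature matrix (rows = proteins).
#' @param retainedOnly drop non-retained classifiers (default TRUE).
#' @return a \linkS4class{PredictionSet} with one row per
#'   (protein, term).
#' @export
predictLibrary <- function(models, features, retainedOnly = TRUE) {
    if (retainedOnly)
        models <- Filter(isRetained, models)
    pieces <- lapply(models, function(m) {
        s <- predictScores(m, features)
        data.frame(protein = rownames(features), term = m@term, score = s)
    })
    predictionSet(do.call(rbind, c(pieces, list(
        data.frame(protein = character(), term = character(),
                   score = numeric())))))
}

## ---- model store --------------------------------------------------------

#' Write a term classifier to a self-describing JSON file
#' @param clf a \linkS4class{TermClassifier}.
#' @param path file path (.json).
#' @return invisibly, the path.
#' @export
writeTermModel <- function(clf, path) {
    obj <- list(term = clf@term, groups = clf@groups,
                featureNames = clf@featureNames,
                cost = clf@cost, gamma = clf@gamma,
                scaleMin = as.list(clf@scaleMin),
                scaleMax = as.list(clf@scaleMax),
                sv = unname(apply(clf@sv, 1L, as.numeric, simplify = FALSE)),
                svCoefs = clf@svCoefs, rho = clf@rho,
                plattA = clf@plattA, plattB = clf@plattB,
                validationMCC = clf@validationMCC, retained = clf@retained)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Read a term classifier written by \code{\link{writeTermModel}}
#' @param path file path.
#' @return a \linkS4class{TermClassifier}.
#' @export
readTermModel <- function(path) {
    o <- jsonlite::read_json(path, simplifyVector = TRUE)
    sv <- if (is.list(o$sv)) do.call(rbind, o$sv) else o$sv
    sv <- matrix(as.numeric(sv), nrow = length(o$svCoefs),
                 byrow = FALSE,
                 dimnames = list(NULL, o$featureNames))
    new("TermClassifier", term = o$term, groups = o$groups,
        featureNames = o$featureNames, cost = o$cost, gamma = o$gamma,
        scaleMin = stats::setNames(as.numeric(o$scaleMin), o$featureNames),
        scaleMax = stats::setNames(as.numeric(o$scaleMax), o$featureNames),
        sv = sv, svCoefs = as.numeric(o$svCoefs), rho = o$rho,
        plattA = o$plattA, plattB = o$plattB,
        validationMCC = o$validationMCC, retained = o$retained)
}

#' Write a model library (one JSON per term plus a manifest)
#' @param models list of \linkS4class{TermClassifier}.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
writeModelLibrary <- function(models, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    rows <- lapply(models, function(m) {
        file <- paste0(gsub(":", "_", m@term), ".json")
        writeTermModel(m, file.path(dir, file))
        data.frame(term = m@term, file = file,
                   validationMCC = m@validationMCC, retained = m@retained,
                   groups = paste(m@groups, collapse = ";"))
    })
    manifest <- do.call(rbind, c(rows, list(data.frame(
        term = character(), file = character(),
        validationMCC = numeric(), retained = logical(),
        groups = character()))))
    utils::write.table(manifest, file.path(dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(dir)
}

#' Read a model library written by \code{\link{writeModelLibrary}}
#' @param dir library directory.
#' @return named list of \linkS4class{TermClassifier} objects.
#' @export
readModelLibrary <- function(dir) {
    man <- utils::read.delim(file.path(dir, "manifest.tsv"))
    models <- lapply(file.path(dir, man$file), readTermModel)
    names(models) <- man$term
    models
}

#' Write predictions as TSV with three-decimal scores
#' @param preds a \linkS4class{PredictionSet}.
#' @param path file path.
#' @return invisibly, the path.
#' @export
writePredictionTSV <- function(preds, path) {
    s <- predictionScores(preds)
    writeLines(c("protein\tterm\tscore",
                 paste(s$protein, s$term, .fmt3(s$score), sep = "\t")),
               path)
    invisible(path)
}

#' Read a prediction TSV
#' @param path file path.
#' @return a \linkS4class{PredictionSet}.
#' @export
readPredictionTSV <- function(path) {
    predictionSet(utils::read.delim(path, colClasses =
        c(protein = "character", term = "character", score = "numeric")))
}

## ---- accessors & show ----

#' @describeIn isRetained method for TermClassifier
setMethod("isRetained", "TermClassifier", function(x) x@retained)
#' @describeIn validationMCC method for TermClassifier
setMethod("validationMCC", "TermClassifier", function(x) x@validationMCC)
#' @describeIn selectedGroups method for TermClassifier
setMethod("selectedGroups", "TermClassifier", function(x) x@groups)
#' @describeIn predictionScores method for PredictionSet
setMethod("predictionScores", "PredictionSet", function(x) x@scores)

setMethod("show", "TermClassifier", function(object) {
    cat("TermClassifier for ", object@term, ": ",
        length(object@groups), " groups, validation MCC ",
        sprintf("%.3f", object@validationMCC),
        if (object@retained) " (retained)" else " (not retained)",
        "\n", sep = "")
})

setMethod("show", "TermDataset", function(object) {
    cat("TermDataset for ", object@term, ": ",
        length(object@positives), " positives, ",
        length(object@negatives), " negatives",
        if (length(object@split)) ", split assigned" else "", "\n",
        sep = "")
})

setMethod("show", "PredictionSet", function(object) {
    s <- object@scores
    cat("PredictionSet:", nrow(s), "scores for",
        length(unique(s$protein)), "proteins,",
        length(unique(s$term)), "terms\n")
})
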