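#' @include AllClasses.R AllGenerics.R ontology.R baselines.R
NULL

#' Build a benchmark of reference annotation sets
#'
#' Filters raw records to experimentally supported evidence codes, drops
#' "protein binding", propagates along "is a", removes the domain roots
#' and splits the per-protein reference sets by GO domain.  Proteins left
#' with an empty set in a domain are excluded from that domain.
#'
#' @param raw an unpropagated \linkS4class{AnnotationTable} carrying
#'   evidence codes.
#' @param onto a \linkS4class{GOOntology}.
#' @param codes accepted evidence codes (default
#'   \code{\link{benchmarkEvidenceCodes}}).
#' @return a \linkS4class{FunctionBenchmark}.
#' @export
buildBenchmark <- function(raw, onto, codes = benchmarkEvidenceCodes()) {
    stopifnot(is(raw, "AnnotationTable"), !isPropagated(raw))
    r <- annotationRecords(raw)
    r <- r[r$evidence %in% codes & r$term != proteinBindingTerm(), ,
           drop = FALSE]
    prop <- annotationRecords(propagateAnnotations(annotationTable(r), onto))
    prop <- prop[!(prop$term %in% onto@roots) &
                 prop$term != proteinBindingTerm(), , drop = FALSE]
    refSets <- list()
    for (dom in unique(onto@namespace[onto@terms])) {
        d <- prop[onto@namespace[prop$term] == dom, , drop = FALSE]
        sets <- lapply(split(d$term, d$protein), unique)
        sets <- sets[lengths(sets) > 0L]
        if (length(sets)) refSets[[dom]] <- sets
    }
    new("FunctionBenchmark", refSets = refSets)
}

#' Reference sets of a benchmark domain
#' @param bench a \linkS4class{FunctionBenchmark}.
#' @param domain GO domain name.
#' @return named list of character term sets.
#' @export
benchmarkRefSets <- function(bench, domain) {
    if (!(domain %in% names(bench@refSets)))
        stop("benchmark has no proteins in domain '", domain, "'")
    bench@refSets[[domain]]
}

#' Benchmark domains
#' @param bench a \linkS4class{FunctionBenchmark}.
#' @return character vector of domains with at least one protein.
#' @export
benchmarkDomains <- function(bench) names(bench@refSets)

#' Per-protein precision and recall counts
#'
#' Set arithmetic between one protein's predicted set \eqn{P} and
#' reference set \eqn{R} (both propagated and root-free):
#' tp = |P n R|, fp = |P \\ R|, fn = |R \\ P|;
#' precision = tp/(tp+fp) (NA when P is empty -- such proteins are
#' excluded from the precision average), recall = tp/(tp+fn).
#'
#' @param predicted character vector of predicted terms.
#' @param reference character vector of reference terms (nonempty).
#' @return named numeric: tp, fp, fn, precision, recall.
#' @examples
#' proteinPR(c("a", "b", "c"), c("a", "d"))  # tp 1, fp 2, fn 1
#' @export
proteinPR <- function(predicted, reference) {
    predicted <- unique(predicted); reference <- unique(reference)
    tp <- length(intersect(predicted, reference))
    fp <- length(setdiff(predicted, reference))
    fn <- length(setdiff(reference, predicted))
    c(tp = tp, fp = fp, fn = fn,
      precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      recall = tp / (tp + fn))
}

## propagated root-free predicted set at threshold v, memoised by caller
.predictedSetsAt <- function(predDf, v, onto, cache) {
    keep <- predDf[predDf$score >= v, , drop = FALSE]
    byProt <- split(keep$term, keep$protein)
    lapply(byProt, function(ts) {
        key <- paste(sort(unique(ts)), collapse = "|")
        hit <- cache[[key]]
        if (is.null(hit)) {
            hit <- propagateTerms(ts, onto)
            cache[[key]] <- hit
        }
        hit
    })
}

#' Protein-centric precision-recall curve
#'
#' For each threshold v, predicted sets are built from scores >= v and
#' propagated ("terms and their ancestors, different from the root").
#' Precision is averaged over the n proteins with at least one prediction
#' scoring at least v; recall is averaged over all m benchmark proteins
#' of the domain; F(v) is the harmonic mean of the two averages.  The
#' default threshold grid is the union of the distinct prediction scores
#' and the lattice \{0, 0.01, ..., 1\}.
#'
#' @param preds a \linkS4class{PredictionSet}.
#' @param bench a \linkS4class{FunctionBenchmark}.
#' @param onto a \linkS4class{GOOntology}.
#' @param domain GO domain to evaluate.
#' @param thresholds numeric grid (default as described).
#' @return data.frame with columns threshold, tp, fp, fn, np (proteins
#'   covered), precision, recall, F; attributes \code{fmax} and
#'   \code{fmaxThreshold} record the maximising point.
#' @export
prCurve <- function(preds, bench, onto, domain, thresholds = NULL) {
    refs <- benchmarkRefSets(bench, domain)
    m <- length(refs)
    s <- predictionScores(preds)
    domTerms <- onto@terms[onto@namespace[onto@terms] == domain]
    s <- s[s$protein %in% names(refs) & s$term %in% domTerms, ,
           drop = FALSE]
    if (is.null(thresholds))
        thresholds <- sort(unique(c(s$score, seq(0, 1, by = 0.01))))
    cache <- new.env(parent = emptyenv())
    rows <- lapply(thresholds, function(v) {
        psets <- .predictedSetsAt(s, v, onto, cache)
        ## n counts proteins with >= 1 raw prediction scoring >= v
        covered <- unique(s$protein[s$score >= v])
        prs <- lapply(names(refs), function(p) {
            proteinPR(if (p %in% names(psets)) psets[[p]] else character(),
                      refs[[p]])
        })
        prm <- do.call(rbind, prs)
        n <- length(covered)
        prec <- if (n > 0)
            sum(prm[match(covered, names(refs)), "precision"],
                na.rm = TRUE) / n else NA_real_
        rec <- sum(prm[, "recall"]) / m
        f <- if (!is.na(prec) && prec + rec > 0)
            2 * prec * rec / (prec + rec) else 0
        data.frame(threshold = v, tp = sum(prm[, "tp"]),
                   fp = sum(prm[, "fp"]), fn = sum(prm[, "fn"]),
                   np = n, precision = prec, recall = rec, F = f)
    })
    out <- do.call(rbind, rows)
    best <- which.max(out$F)
    attr(out, "fmax") <- out$F[[best]]
    attr(out, "fmaxThreshold") <- out$threshold[[best]]
    out
}

#' Maximum F-measure of a precision-recall curve
#' @param curve output of \code{\link{prCurve}}.
#' @return numeric Fmax.
#' @export
fmax <- function(curve) attr(curve, "fmax")

#' Summed information content of true positives
#'
#' @param predicted,reference character term sets.
#' @param ic named numeric of per-term information content (bits); must
#'   cover the intersection.
#' @return nonnegative real, the sum of ic over correctly predicted terms.
#' @export
tpInformation <- function(predicted, reference, ic) {
    tp <- intersect(unique(predicted), unique(reference))
    if (!length(tp)) return(0)
    missing <- setdiff(tp, names(ic))
    if (length(missing))
        stop("no information-content value for term(s): ",
             paste(missing, collapse = ", "))
    sum(ic[tp])
}

#' Top-l evaluation with tie resampling
#'
#' For each benchmark protein the domain predictions are ranked by score
#' and trimmed to length l; rank ties at the trim boundary are resolved
#' by uniform sampling without replacement, averaged over
#' \code{replicates} lists (when the boundary is tie-free a single
#' deterministic trim is used).  Per replicate, precision (tp / list
#' length), recall (tp / |reference|), their harmonic mean and the summed
#' information content of the true positives are computed on the trimmed
#' list as emitted (no further propagation); the replicate means are
#' averaged within each protein and then across proteins.  Setting
#' \code{l = NA} evaluates at the per-protein reference-set size
#' (reported as \code{"n"}).  A row is emitted only when at least
#' \code{minTargets} proteins qualify for it, i.e. have at least l
#' predictions and at least l reference terms.
#'
#' @param preds a \linkS4class{PredictionSet}.
#' @param bench a \linkS4class{FunctionBenchmark}.
#' @param onto a \linkS4class{GOOntology}.
#' @param domain GO domain to evaluate.
#' @param lValues integer vector of list lengths; NA means the
#'   reference-set size (default \code{c(1:5, NA)}).
#' @param replicates tie-resampling replicates (default 1000).
#' @param seed integer seed for the tie sampler.
#' @param minTargets minimum qualifying proteins per reported row
#'   (default 25).
#' @param ic optional named numeric of term information content; when
#'   supplied the mean summed true-positive IC is reported.
#' @return data.frame with columns l, targets, precision, recall, F,
#'   tpIC (NA without \code{ic}).
#' @export
topLEval <- function(preds, bench, onto, domain, lValues = c(1:5, NA),
                     replicates = 1000L, seed = 1L, minTargets = 25L,
                     ic = NULL) {
    stopifnot(replicates >= 1L)
    refs <- benchmarkRefSets(bench, domain)
    s <- predictionScores(preds)
    domTerms <- onto@terms[onto@namespace[onto@terms] == domain]
    s <- s[s$protein %in% names(refs) & s$term %in% domTerms, ,
           drop = FALSE]
    byProt <- split(s[, c("term", "score")], s$protein)
    evalProtein <- function(p, l) {
        df <- byProt[[p]]
        R <- refs[[p]]
        npred <- nrow(df)
        use <- min(l, npred)
        ord <- order(-df$score)
        sorted <- df[ord, , drop = FALSE]
        tieFree <- use == npred ||
            sorted$score[[use]] != sorted$score[[use + 1L]]
        one <- function(terms) {
            tp <- length(intersect(terms, R))
            prec <- tp / length(terms)
            rec <- tp / length(R)
            f <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
            icv <- if (is.null(ic)) NA_real_ else
                tpInformation(terms, R, ic)
            c(prec, rec, f, icv)
        }
        if (tieFree) return(one(sorted$term[seq_len(use)]))
        reps <- vapply(seq_len(replicates), function(i) {
            ord2 <- order(-df$score, sample.int(npred))
            one(df$term[ord2][seq_len(use)])
        }, numeric(4))
        rowMeans(reps)
    }
    rows <- lapply(lValues, function(l) {
        isN <- is.na(l)
        qual <- names(byProt)[vapply(names(byProt), function(p) {
            np <- nrow(byProt[[p]]); nr <- length(refs[[p]])
            if (isN) np >= 1L else (np >= l && nr >= l)
        }, logical(1))]
        if (length(qual) < minTargets) return(NULL)
        stats <- .withSeed(seed, vapply(qual, function(p)
            evalProtein(p, if (isN) length(refs[[p]]) else l),
            numeric(4)))
        data.frame(l = if (isN) "n" else as.character(l),
                   targets = length(qual),
                   precision = mean(stats[1L, ]),
                   recall = mean(stats[2L, ]),
                   F = mean(stats[3L, ]),
                   tpIC = if (is.null(ic)) NA_real_ else mean(stats[4L, ]))
    })
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(l = character(), targets = integer(),
                          precision = numeric(), recall = numeric(),
                          F = numeric(), tpIC = numeric())
    rownames(out) <- NULL
    out
}

#' Write a per-threshold metrics table
#' @param curve output of \code{\link{prCurve}}.
#' @param path file path.
#' @return invisibly, the path.
#' @export
writeMetricsTSV <- function(curve, path) {
    utils::write.table(curve, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

setMethod("show", "FunctionBenchmark", function(object) {
    cat("FunctionBenchmark:\n")
    for (dom in names(object@refSets))
        cat("  ", dom, ": ", length(object@refSets[[dom]]),
            " proteins\n", sep = "")
})
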