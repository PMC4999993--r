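#' @include AllClasses.R AllGenerics.R ontology.R svm.R
NULL

#' Read an isoform catalogue
#'
#' Tab-separated table with columns \code{entry} (gene/database entry id),
#' \code{isoform} (isoform id), \code{main} (1/0 or TRUE/FALSE) and
#' optionally \code{external} (isoform recorded in a separate database
#' entry), plus a FASTA file of isoform sequences.
#'
#' @param path catalogue TSV path.
#' @param fastaPath FASTA path of isoform sequences.
#' @return list with elements \code{catalogue} (data.frame) and
#'   \code{sequences} (\code{Biostrings::AAStringSet}).
#' @export
readIsoformCatalogue <- function(path, fastaPath) {
    cat <- utils::read.delim(path)
    cat$main <- as.logical(cat$main)
    if (is.null(cat$external)) cat$external <- FALSE
    cat$external <- as.logical(cat$external)
    list(catalogue = cat,
         sequences = Biostrings::readAAStringSet(fastaPath))
}

## which filter rule (a-e), if any, removes this isoform?
.isoformViolation <- function(iso, seqs, external,
                              minLen = 15L, maxLen = 1500L) {
    if (!(iso %in% names(seqs))) return("a")          # sequence unknown
    s <- as.character(seqs[[iso]])
    if (!nzchar(s)) return("a")
    if (nchar(s) < minLen) return("b")
    if (nchar(s) > maxLen) return("c")
    res <- strsplit(toupper(s), "")[[1L]]
    if (any(!(res %in% .AA))) return("d")
    if (external) return("e")                          # separate DB entry
    NA_character_
}

#' Filter an isoform catalogue to usable sequences
#'
#' Applies the five retention rules: an isoform is discarded if (a) its
#' sequence is unknown, (b) shorter than \code{minLen} residues, (c)
#' longer than \code{maxLen}, (d) contains non-standard residue symbols,
#' or (e) is recorded in a separate database entry.  When a main isoform
#' is excluded, all of its alternative isoforms are removed as well
#' (cascade rule); entries left without isoforms are dropped.  The final
#' dataset is independent of the order in which rules are applied.
#'
#' @param catalogue data.frame with columns entry, isoform, main and
#'   optionally external.
#' @param sequences named \code{AAStringSet} (or named character).
#' @param minLen,maxLen length bounds (defaults 15 and 1500).
#' @return an \linkS4class{IsoformDataset} (calls empty).
#' @export
filterIsoforms <- function(catalogue, sequences, minLen = 15L,
                           maxLen = 1500L) {
    cat <- as.data.frame(catalogue)
    if (is.null(cat$external)) cat$external <- FALSE
    if (is.character(sequences))
        sequences <- Biostrings::AAStringSet(sequences)
    viol <- vapply(seq_len(nrow(cat)), function(i)
        .isoformViolation(cat$isoform[[i]], sequences,
                          cat$external[[i]], minLen, maxLen),
        character(1))
    keep <- is.na(viol)
    ## cascade: excluding a main excludes its alternatives
    badEntries <- unique(cat$entry[cat$main & !keep])
    keep <- keep & !(cat$entry %in% badEntries)
    out <- cat[keep, c("entry", "isoform", "main"), drop = FALSE]
    ## entries must retain their main isoform
    withMain <- unique(out$entry[out$main])
    out <- out[out$entry %in% withMain, , drop = FALSE]
    rownames(out) <- NULL
    new("IsoformDataset", entries = out,
        sequences = sequences[out$isoform], calls = list())
}

#' Consolidate isoform predictions against curated annotations
#'
#' An isoform is called with term g iff its prediction score reaches
#' \code{callThreshold} and g lies in the propagated (root-free) curated
#' annotation set of its parent entry -- i.e. only predicted functions
#' explicitly assigned by curators or implied by the ontology are kept.
#'
#' @param ds an \linkS4class{IsoformDataset}.
#' @param preds a \linkS4class{PredictionSet} of per-isoform scores.
#' @param curated an \linkS4class{AnnotationTable} of entry-level curated
#'   annotations (raw or propagated).
#' @param onto a \linkS4class{GOOntology}.
#' @param callThreshold minimum posterior to count as assigned
#'   (default 0.5).
#' @return the dataset with its \code{calls} slot filled (a possibly
#'   empty character vector per isoform).
#' @export
consolidatePredictions <- function(ds, preds, curated, onto,
                                   callThreshold = 0.5) {
    stopifnot(is(ds, "IsoformDataset"))
    e <- ds@entries
    entryOf <- stats::setNames(e$entry, e$isoform)
    s <- predictionScores(preds)
    s <- s[s$protein %in% e$isoform, , drop = FALSE]
    unknown <- setdiff(unique(s$protein), e$isoform)
    cr <- annotationRecords(curated)
    curSets <- lapply(split(cr$term, cr$protein),
                      function(ts) propagateTerms(ts, onto))
    calls <- stats::setNames(vector("list", nrow(e)), e$isoform)
    for (iso in e$isoform) calls[[iso]] <- character()
    for (i in seq_len(nrow(s))) {
        iso <- s$protein[[i]]
        if (s$score[[i]] < callThreshold) next
        entry <- entryOf[[iso]]
        if (is.na(entry))
            stop("isoform ", iso, " has no parent entry")
        if (s$term[[i]] %in% curSets[[entry]])
            calls[[iso]] <- c(calls[[iso]], s$term[[i]])
    }
    ds@calls <- lapply(calls, unique)
    ds
}

#' Set isoform term calls directly
#' @param ds an \linkS4class{IsoformDataset}.
#' @param calls named list, isoform id -> character vector of terms;
#'   every retained isoform must be covered.
#' @return the updated dataset.
#' @export
setIsoformCalls <- function(ds, calls) {
    missing <- setdiff(ds@entries$isoform, names(calls))
    if (length(missing))
        stop("calls missing for ", length(missing), " isoform(s)")
    ds@calls <- lapply(calls[ds@entries$isoform], unique)
    ds
}

## entries where the term is called on >=1 / on all isoforms
.termCoverage <- function(term, ds) {
    e <- ds@entries
    has <- vapply(e$isoform, function(iso) term %in% ds@calls[[iso]],
                  logical(1))
    byEntry <- split(has, e$entry)
    any1 <- vapply(byEntry, any, logical(1))
    all1 <- vapply(byEntry, all, logical(1))
    list(any = sum(any1), all = sum(any1 & all1))
}

#' Conservation of a term across splice isoforms
#'
#' The ratio between the number of entries where the term is assigned to
#' all isoforms and the number of entries where it is assigned to at
#' least one.  Terms covered by fewer than \code{minEntries} entries are
#' not reported (NA).
#'
#' @param term GO id.
#' @param ds an \linkS4class{IsoformDataset} with calls.
#' @param minEntries minimum covered entries to report (default 20).
#' @return numeric in \[0, 1\], or NA when below the reporting floor.
#' @export
conservation <- function(term, ds, minEntries = 20L) {
    stopifnot(is(ds, "IsoformDataset"), length(ds@calls) > 0L)
    cov <- .termCoverage(term, ds)
    if (cov$any < minEntries) return(NA_real_)
    cov$all / cov$any
}

#' Primarity of a term: enrichment among main isoforms
#'
#' \deqn{\delta_G = m_G / n - a_G / (m - n)}
#' where m_G and a_G are the numbers of main and alternative isoforms
#' called with the term, n is the number of entries (each contributing
#' one main isoform) and m the total number of isoforms.  Positive values
#' mean the term is preferentially found among canonical isoforms,
#' negative values among alternative variants, zero means equal
#' association.
#'
#' @param term GO id.
#' @param ds an \linkS4class{IsoformDataset} with calls.
#' @return numeric in \[-1, 1\]; NA when the dataset has no alternative
#'   isoforms.
#' @export
primarity <- function(term, ds) {
    stopifnot(is(ds, "IsoformDataset"), length(ds@calls) > 0L)
    e <- ds@entries
    n <- length(unique(e$entry))
    m <- nrow(e)
    if (m == n) return(NA_real_)
    has <- vapply(e$isoform, function(iso) term %in% ds@calls[[iso]],
                  logical(1))
    mG <- sum(has & e$main)
    aG <- sum(has & !e$main)
    mG / n - aG / (m - n)
}

#' Conservation and primarity for all called terms
#'
#' @param ds an \linkS4class{IsoformDataset} with calls.
#' @param minEntries reporting floor for conservation (default 20).
#' @return data.frame with columns term, entriesCovered, conservation,
#'   primarity, mG, aG.
#' @export
termSplicingStats <- function(ds, minEntries = 20L) {
    terms <- sort(unique(unlist(ds@calls, use.names = FALSE)))
    e <- ds@entries
    rows <- lapply(terms, function(g) {
        cov <- .termCoverage(g, ds)
        has <- vapply(e$isoform, function(iso) g %in% ds@calls[[iso]],
                      logical(1))
        data.frame(term = g, entriesCovered = cov$any,
                   conservation = conservation(g, ds, minEntries),
                   primarity = primarity(g, ds),
                   mG = sum(has & e$main), aG = sum(has & !e$main))
    })
    out <- do.call(rbind, c(rows, list(
        data.frame(term = character(), entriesCovered = integer(),
                   conservation = numeric(), primarity = numeric(),
                   mG = integer(), aG = integer()))))
    rownames(out) <- NULL
    out
}

#' Feature enrichment between annotated variants and training positives
#'
#' Compares the median value of a feature in the annotated variant set
#' with the median observed in the classifier's positive training set, by
#' mapping the variant median to its percentile within the empirical
#' training distribution (mid-rank convention) and centring:
#' \deqn{E = (\hat p - 50) / 50.}
#' E is 0 iff the medians coincide, positive when the feature takes
#' higher values among the variants, negative when lower, and bounded in
#' \[-1, 1\].
#'
#' @param trainValues numeric values of the feature in the positive
#'   training set (nonempty).
#' @param variantValues numeric values in the annotated variant set
#'   (nonempty).
#' @return list with elements \code{medianTrain}, \code{medianVariant},
#'   \code{percentile} and \code{enrichment}.
#' @export
featureEnrichment <- function(trainValues, variantValues) {
    stopifnot(length(trainValues) > 0L, length(variantValues) > 0L)
    mT <- stats::median(trainValues)
    mV <- stats::median(variantValues)
    if (isTRUE(all.equal(mT, mV))) {
        p <- 50
    } else {
        n <- length(trainValues)
        p <- 100 * (sum(trainValues < mV) +
                    0.5 * sum(trainValues == mV)) / n
    }
    list(medianTrain = mT, medianVariant = mV, percentile = p,
         enrichment = (p - 50) / 50)
}

#' Pearson correlation between a feature and classifier scores
#'
#' @param featureValues numeric per-isoform feature values.
#' @param scores numeric per-isoform classifier posteriors.
#' @return Pearson r in \[-1, 1\], or NA when fewer than 3 paired
#'   observations remain or either side has zero variance (the "grey
#'   cell" case).
#' @export
featureScoreCorrelation <- function(featureValues, scores) {
    ok <- is.finite(featureValues) & is.finite(scores)
    f <- featureValues[ok]; s <- scores[ok]
    if (length(f) < 3L) return(NA_real_)
    if (stats::sd(f) == 0 || stats::sd(s) == 0) return(NA_real_)
    stats::cor(f, s)
}

#' Median feature-score correlation per feature group
#'
#' @param features feature matrix over the isoforms of interest.
#' @param scores numeric scores aligned with the matrix rows.
#' @param registry the \linkS4class{FeatureRegistry} describing the
#'   column layout.
#' @return named numeric, one median correlation per group (NA when every
#'   scalar of the group is undefined).
#' @export
featureGroupCorrelations <- function(features, scores,
                                     registry = defaultRegistry()) {
    grp <- sub("\\.[0-9]+$", "", colnames(features))
    out <- vapply(groupNames(registry), function(g) {
        cols <- which(grp == g)
        rs <- vapply(cols, function(j)
            featureScoreCorrelation(features[, j], scores), numeric(1))
        if (all(is.na(rs))) NA_real_ else stats::median(rs, na.rm = TRUE)
    }, numeric(1))
    names(out) <- groupNames(registry)
    out
}

#' Select the most reliable classifiers per domain
#'
#' Keeps, within each GO domain, the classifiers whose validation MCC is
#' at or above the domain median -- the "top 50 percent" reporting filter
#' used for the splicing heatmaps.
#'
#' @param manifest data.frame with columns term, validationMCC (e.g. the
#'   model-library manifest).
#' @param onto a \linkS4class{GOOntology}.
#' @return the manifest rows passing the filter.
#' @export
topClassifiers <- function(manifest, onto) {
    dom <- onto@namespace[manifest$term]
    keep <- unlist(lapply(split(seq_len(nrow(manifest)), dom), function(i) {
        i[manifest$validationMCC[i] >= stats::median(manifest$validationMCC[i])]
    }), use.names = FALSE)
    manifest[sort(keep), , drop = FALSE]
}

## ---- accessors & show ----

#' @describeIn isoformEntries method for IsoformDataset
setMethod("isoformEntries", "IsoformDataset", function(x) x@entries)
#' @describeIn isoformCalls method for IsoformDataset
setMethod("isoformCalls", "IsoformDataset", function(x) x@calls)

setMethod("show", "IsoformDataset", function(object) {
    e <- object@entries
    cat("IsoformDataset:", length(unique(e$entry)), "entries,",
        nrow(e), "isoforms (", sum(!e$main), "alternative );",
        if (length(object@calls)) "calls assigned" else "no calls", "\n")
})
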