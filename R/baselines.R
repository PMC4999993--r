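#' @include AllClasses.R AllGenerics.R ontology.R svm.R
NULL

#' Evidence codes accepted for the baseline annotation counts
#'
#' The experimentally supported or curator-reviewed codes used when
#' counting annotations for the naive frequency model and the sequence
#' similarity transfer: EXP, IDA, IPI, IMP, IGI, IEP, IC, TAS.
#' @return character vector.
#' @export
baselineEvidenceCodes <- function()
    c("EXP", "IDA", "IPI", "IMP", "IGI", "IEP", "IC", "TAS")

#' Evidence codes accepted for benchmark reference annotations
#'
#' Identical to \code{\link{baselineEvidenceCodes}} except that IPI
#' (inferred from physical interaction) is excluded, mirroring the
#' stricter list used when assembling evaluation references.
#' @return character vector.
#' @export
benchmarkEvidenceCodes <- function()
    c("EXP", "IDA", "IMP", "IGI", "IEP", "TAS", "IC")

#' GO id of "protein binding", excluded throughout
#' @return character scalar \code{"GO:0005515"}.
#' @export
proteinBindingTerm <- function() "GO:0005515"

#' Build the naive frequency baseline
#'
#' Counts, for every GO term, the proteins annotated with it (restricted
#' to the evidence filter, excluding "protein binding"), propagates the
#' counts along "is a" links, and scales each domain by the count of its
#' root, rounding scores to three decimals.  The resulting term/score
#' table is assigned unchanged to every query protein.
#'
#' @param table an unpropagated \linkS4class{AnnotationTable} of raw
#'   records with evidence codes.
#' @param onto a \linkS4class{GOOntology}.
#' @param evidenceFilter evidence codes to keep (default
#'   \code{\link{baselineEvidenceCodes}}).
#' @return a \linkS4class{NaiveModel}.  Domains whose root receives no
#'   annotation are omitted with a warning.
#' @export
buildNaive <- function(table, onto,
                       evidenceFilter = baselineEvidenceCodes()) {
    stopifnot(is(table, "AnnotationTable"), !isPropagated(table))
    r <- annotationRecords(table)
    r <- r[r$evidence %in% evidenceFilter &
           r$term != proteinBindingTerm(), , drop = FALSE]
    prop <- propagateAnnotations(annotationTable(r), onto)
    pr <- annotationRecords(prop)
    pr <- pr[pr$term != proteinBindingTerm(), , drop = FALSE]
    counts <- table(pr$term)
    tab <- data.frame(term = names(counts),
                      namespace = onto@namespace[names(counts)],
                      count = as.integer(counts))
    pieces <- lapply(split(tab, tab$namespace), function(d) {
        root <- intersect(onto@roots, d$term)
        if (!length(root)) {
            warning("domain ", d$namespace[[1L]],
                    " has no annotated root; omitted from naive model")
            return(NULL)
        }
        d$score <- .round3(d$count / d$count[d$term == root])
        d
    })
    out <- do.call(rbind, pieces)
    rownames(out) <- NULL
    new("NaiveModel", table = out)
}

#' Predictions of the naive model for a set of proteins
#'
#' @param model a \linkS4class{NaiveModel}.
#' @param proteins character vector of query ids.
#' @return a \linkS4class{PredictionSet} assigning the full term/score
#'   table to every query.
#' @export
predictNaive <- function(model, proteins) {
    t <- naiveTable(model)
    predictionSet(data.frame(
        protein = rep(proteins, each = nrow(t)),
        term = rep(t$term, length(proteins)),
        score = rep(t$score, length(proteins))))
}

#' Read tabular sequence-search hits
#'
#' Accepts 12-column outfmt-6 style tables (qseqid sseqid pident ...
#' evalue bitscore) or minimal 4-column tables (query, subject, pident,
#' evalue); only those four fields are consumed.
#'
#' @param path file path.
#' @return data.frame with columns query, subject, pident, evalue.
#' @export
readBlastHits <- function(path) {
    df <- utils::read.delim(path, header = FALSE)
    if (ncol(df) >= 12L) {
        out <- df[, c(1L, 2L, 3L, 11L)]
    } else if (ncol(df) >= 4L) {
        out <- df[, 1:4]
    } else stop("hit table needs at least 4 columns")
    names(out) <- c("query", "subject", "pident", "evalue")
    out$query <- as.character(out$query)
    out$subject <- as.character(out$subject)
    stopifnot(all(out$pident >= 0 & out$pident <= 100),
              all(out$evalue >= 0))
    out
}

#' Transfer annotations along sequence-search hits
#'
#' Retains hits whose E-value lies inside \code{\[evalueMin, evalueMax\]}
#' (exclusive at the lower end).  The default window keeps only hits with
#' E-value greater than 1e-03 -- the remote-homology regime, which
#' deliberately restricts transfers to distantly related proteins; set
#' \code{evalueMin = 0, evalueMax = 1e-3} for the conventional direction.
#' Each subject's filtered annotations are transferred to the query with
#' score = percent identity / 100; per (query, term) the maximum score is
#' kept, rounded to three decimals.  Hits to unannotated subjects
#' contribute nothing.  The output is invariant to hit ordering.
#'
#' @param hits data.frame as from \code{\link{readBlastHits}}.
#' @param table an unpropagated \linkS4class{AnnotationTable} of subject
#'   annotations with evidence codes.
#' @param onto a \linkS4class{GOOntology} (used to map alternative ids).
#' @param evalueMin lower E-value bound, exclusive (default 1e-03).
#' @param evalueMax upper E-value bound, inclusive (default Inf).
#' @param evidenceFilter evidence codes transferable (default
#'   \code{\link{baselineEvidenceCodes}}).
#' @return a \linkS4class{PredictionSet}.
#' @export
blastTransfer <- function(hits, table, onto, evalueMin = 1e-3,
                          evalueMax = Inf,
                          evidenceFilter = baselineEvidenceCodes()) {
    stopifnot(is(table, "AnnotationTable"))
    hits <- hits[hits$evalue > evalueMin & hits$evalue <= evalueMax, ,
                 drop = FALSE]
    r <- annotationRecords(table)
    r <- r[r$evidence %in% evidenceFilter, , drop = FALSE]
    hit <- r$term %in% names(onto@altId)
    r$term[hit] <- onto@altId[r$term[hit]]
    byProt <- split(r$term, r$protein)
    pieces <- lapply(seq_len(nrow(hits)), function(i) {
        terms <- unique(byProt[[hits$subject[[i]]]])
        if (is.null(terms) || !length(terms)) return(NULL)
        data.frame(protein = hits$query[[i]], term = terms,
                   score = hits$pident[[i]] / 100)
    })
    df <- do.call(rbind, c(pieces, list(
        data.frame(protein = character(), term = character(),
                   score = numeric()))))
    if (nrow(df)) {
        ord <- order(df$protein, df$term, -df$score)
        df <- df[ord, , drop = FALSE]
        df <- df[!duplicated(df[, c("protein", "term")]), , drop = FALSE]
    }
    predictionSet(df)
}

#' @describeIn naiveTable method for NaiveModel
setMethod("naiveTable", "NaiveModel", function(x) x@table)

setMethod("show", "NaiveModel", function(object) {
    t <- object@table
    cat("NaiveModel:", nrow(t), "term/score pairs in",
        length(unique(t$namespace)), "domains\n")
})
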