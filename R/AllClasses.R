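#' @import methods
NULL

#' Gene Ontology DAG restricted to "is a" relationships
#'
#' Holds the non-obsolete GO terms of an OBO 1.2 release, the child-to-parent
#' "is a" relation, the three domain roots and the obsolete / alternative
#' identifier bookkeeping.  Only "is a" edges are represented: annotation
#' propagation in this package follows subsumption alone.
#'
#' @slot terms character vector of canonical, non-obsolete term identifiers.
#' @slot termName named character, term id -> human-readable name.
#' @slot namespace named character, term id -> GO domain
#'   (\code{molecular_function}, \code{biological_process},
#'   \code{cellular_component}).
#' @slot parents named list, term id -> character vector of "is a" parents.
#' @slot roots character vector of domain root identifiers (no parents).
#' @slot obsolete character vector of retired identifiers (not in the DAG).
#' @slot altId named character mapping alternative ids to canonical ids.
#' @exportClass GOOntology
setClass("GOOntology",
         representation(terms = "character",
                        termName = "character",
                        namespace = "character",
                        parents = "list",
                        roots = "character",
                        obsolete = "character",
                        altId = "character"))

setValidity("GOOntology", function(object) {
    msg <- character()
    if (!all(names(object@parents) %in% object@terms))
        msg <- c(msg, "parents names must be declared terms")
    if (length(object@roots) &&
        any(lengths(object@parents[object@roots]) > 0L))
        msg <- c(msg, "roots must have no parents")
    pp <- unlist(object@parents, use.names = FALSE)
    if (length(pp) && !all(pp %in% object@terms))
        msg <- c(msg, "dangling is_a parent reference")
    ## acyclicity by iterated leaf stripping (Kahn)
    if (!.isAcyclic(object@parents, object@terms))
        msg <- c(msg, "is_a graph contains a cycle")
    if (length(msg)) msg else TRUE
})

#' Protein-to-term annotation table
#'
#' A flat table of (protein, GO term, evidence code) records, GAF-style,
#' with a flag recording whether "is a" propagation has already been
#' applied.  Counting of co-annotated proteins (the N(.) function used by
#' the information-content estimator) operates on propagated tables.
#'
#' @slot records data.frame with columns \code{protein}, \code{term},
#'   \code{evidence}.
#' @slot propagated logical scalar.
#' @exportClass AnnotationTable
setClass("AnnotationTable",
         representation(records = "data.frame", propagated = "logical"))

setValidity("AnnotationTable", function(object) {
    req <- c("protein", "term", "evidence")
    if (!all(req %in% colnames(object@records)))
        return("records needs columns protein, term, evidence")
    if (length(object@propagated) != 1L)
        return("propagated must be a logical scalar")
    TRUE
})

#' Registry of named feature groups
#'
#' Describes the layout of the feature vector sequences are encoded into:
#' an ordered list of named groups, each contributing a fixed number of
#' scalars.  The default registry has 14 groups totalling 258 scalars.
#' Individual groups can be swapped for table lookups of externally
#' computed values (e.g. outputs of dedicated structure predictors).
#'
#' @slot groups data.frame with columns \code{name}, \code{size},
#'   \code{compositional} (whether the group's scalars sum to one).
#' @slot external named list of lookup tables (protein id -> numeric row)
#'   overriding built-in extractors.
#' @exportClass FeatureRegistry
setClass("FeatureRegistry",
         representation(groups = "data.frame", external = "list"))

setValidity("FeatureRegistry", function(object) {
    g <- object@groups
    if (!all(c("name", "size", "compositional") %in% colnames(g)))
        return("groups needs columns name, size, compositional")
    if (anyDuplicated(g$name)) return("group names must be unique")
    if (any(g$size < 1L)) return("group sizes must be positive")
    bad <- setdiff(names(object@external), g$name)
    if (length(bad))
        return(paste0("external table for unknown group: ",
                      paste(bad, collapse = ", ")))
    TRUE
})

#' Feature vector of one sequence
#'
#' Named feature groups mapped to fixed-length numeric vectors for a single
#' protein sequence, laid out exactly as its registry prescribes.
#'
#' @slot id sequence identifier.
#' @slot values named list, group name -> named numeric vector.
#' @exportClass FeatureVector
setClass("FeatureVector",
         representation(id = "character", values = "list"))

setValidity("FeatureVector", function(object) {
    v <- unlist(object@values, use.names = FALSE)
    if (length(v) && !all(is.finite(v)))
        return("feature values must all be finite")
    TRUE
})

#' Trained per-term classifier
#'
#' One GO term's binary predictor after group selection, hyperparameter
#' search, validation and sigmoid calibration.  The decision function is
#' stored explicitly (support vectors, dual coefficients, offset) so that
#' scoring does not depend on the fitting backend's serialisation.
#'
#' @slot term GO identifier.
#' @slot groups selected feature group names (nonempty).
#' @slot featureNames column names of the scaled design matrix, in order.
#' @slot cost,gamma RBF-SVM hyperparameters.
#' @slot scaleMin,scaleMax per-column training statistics mapping features
#'   into \[-1, 1\]; constant columns map to 0.
#' @slot sv support vector matrix (rows = SVs, columns = featureNames).
#' @slot svCoefs dual coefficients (alpha * y).
#' @slot rho decision-function offset.
#' @slot plattA,plattB sigmoid parameters of the posterior
#'   P(positive | d) = 1 / (1 + exp(A d + B)).
#' @slot validationMCC Matthews correlation on the held-out 30 percent split.
#' @slot retained logical; TRUE iff validationMCC >= 0.05.
#' @exportClass TermClassifier
setClass("TermClassifier",
         representation(term = "character", groups = "character",
                        featureNames = "character",
                        cost = "numeric", gamma = "numeric",
                        scaleMin = "numeric", scaleMax = "numeric",
                        sv = "matrix", svCoefs = "numeric", rho = "numeric",
                        plattA = "numeric", plattB = "numeric",
                        validationMCC = "numeric", retained = "logical"))

setValidity("TermClassifier", function(object) {
    if (!length(object@groups)) return("selected groups must be nonempty")
    if (length(object@validationMCC) == 1L &&
        !identical(object@retained, object@validationMCC >= 0.05))
        return("retained flag must equal validationMCC >= 0.05")
    TRUE
})

#' Set of (protein, term, score) predictions
#'
#' Scores are posterior-style confidences in \[0, 1\], rounded to three
#' decimals on creation, matching the tool's output convention.
#'
#' @slot scores data.frame with columns \code{protein}, \code{term},
#'   \code{score}.
#' @exportClass PredictionSet
setClass("PredictionSet", representation(scores = "data.frame"))

setValidity("PredictionSet", function(object) {
    s <- object@scores
    if (!all(c("protein", "term", "score") %in% colnames(s)))
        return("scores needs columns protein, term, score")
    if (nrow(s) && (any(s$score < 0) || any(s$score > 1)))
        return("scores must lie in [0, 1]")
    TRUE
})

#' Naive frequency baseline model
#'
#' Per-domain table of term scores equal to the propagated annotation count
#' divided by the domain root count, rounded to three decimals.  The model
#' assigns this same table to every query protein.
#'
#' @slot table data.frame with columns \code{term}, \code{namespace},
#'   \code{count}, \code{score}.
#' @exportClass NaiveModel
setClass("NaiveModel", representation(table = "data.frame"))

#' Benchmark of reference annotation sets
#'
#' Per-domain propagated, root-free reference term sets for each benchmark
#' protein, built from experimentally supported annotations.
#'
#' @slot refSets named list: domain -> named list of character term sets.
#' @exportClass FunctionBenchmark
setClass("FunctionBenchmark", representation(refSets = "list"))

setValidity("FunctionBenchmark", function(object) {
    for (dom in names(object@refSets)) {
        if (any(lengths(object@refSets[[dom]]) == 0L))
            return("every benchmark protein must have a nonempty reference set")
    }
    TRUE
})

#' Splice-isoform dataset
#'
#' Genes (database entries) with one main isoform and zero or more
#' alternative isoforms that survived the sequence filters, their
#' sequences, and (optionally) per-isoform consolidated term calls.
#'
#' @slot entries data.frame with columns \code{entry}, \code{isoform},
#'   \code{main} (logical).
#' @slot sequences AAStringSet of the retained isoform sequences.
#' @slot calls named list, isoform id -> character vector of assigned terms.
#' @exportClass IsoformDataset
setClass("IsoformDataset",
         representation(entries = "data.frame", sequences = "ANY",
                        calls = "list"))

setValidity("IsoformDataset", function(object) {
    e <- object@entries
    if (!all(c("entry", "isoform", "main") %in% colnames(e)))
        return("entries needs columns entry, isoform, main")
    nMain <- tapply(e$main, e$entry, sum)
    if (length(nMain) && any(nMain != 1L))
        return("every retained entry must have exactly one main isoform")
    TRUE
})
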