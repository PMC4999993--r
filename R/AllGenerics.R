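#' @include AllClasses.R
NULL

#' Term identifiers of an ontology
#' @param x a \linkS4class{GOOntology}.
#' @return character vector of non-obsolete canonical term ids.
#' @export
setGeneric("goTerms", function(x) standardGeneric("goTerms"))

#' Domain roots of an ontology
#' @param x a \linkS4class{GOOntology}.
#' @return character vector of root term ids.
#' @export
setGeneric("goRoots", function(x) standardGeneric("goRoots"))

#' Obsolete identifiers of an ontology
#' @param x a \linkS4class{GOOntology}.
#' @return character vector of retired ids excluded from the DAG.
#' @export
setGeneric("goObsolete", function(x) standardGeneric("goObsolete"))

#' Namespace (GO domain) of terms
#' @param x a \linkS4class{GOOntology}.
#' @param ids term ids; defaults to all terms.
#' @return named character of domains.
#' @export
setGeneric("termNamespace",
           function(x, ids = goTerms(x)) standardGeneric("termNamespace"))

#' Direct "is a" parents of terms
#' @param x a \linkS4class{GOOntology}.
#' @param ids term ids.
#' @return named list of character vectors.
#' @export
setGeneric("termParents", function(x, ids) standardGeneric("termParents"))

#' Annotation records
#' @param x an \linkS4class{AnnotationTable}.
#' @return data.frame with columns protein, term, evidence.
#' @export
setGeneric("annotationRecords",
           function(x) standardGeneric("annotationRecords"))

#' Has an annotation table been propagated?
#' @param x an \linkS4class{AnnotationTable}.
#' @return logical scalar.
#' @export
setGeneric("isPropagated", function(x) standardGeneric("isPropagated"))

#' Group names of a feature registry or vector
#' @param x a \linkS4class{FeatureRegistry} or \linkS4class{FeatureVector}.
#' @return character vector of group names, in layout order.
#' @export
setGeneric("groupNames", function(x) standardGeneric("groupNames"))

#' Per-group scalar counts
#' @param x a \linkS4class{FeatureRegistry}.
#' @return named integer vector.
#' @export
setGeneric("groupSizes", function(x) standardGeneric("groupSizes"))

#' Total feature dimensionality
#' @param x a \linkS4class{FeatureRegistry}.
#' @return integer, the sum of group sizes.
#' @export
setGeneric("totalDim", function(x) standardGeneric("totalDim"))

#' Flattened feature values
#' @param x a \linkS4class{FeatureVector}.
#' @return named numeric vector with \code{group.index} names.
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' Prediction scores table
#' @param x a \linkS4class{PredictionSet}.
#' @return data.frame with columns protein, term, score.
#' @export
setGeneric("predictionScores",
           function(x) standardGeneric("predictionScores"))

#' Score table of a naive baseline model
#' @param x a \linkS4class{NaiveModel}.
#' @return data.frame with columns term, namespace, count, score.
#' @export
setGeneric("naiveTable", function(x) standardGeneric("naiveTable"))

#' Was a term's classifier retained?
#' @param x a \linkS4class{TermClassifier}.
#' @return logical; TRUE iff the validation MCC reached the 0.05 floor.
#' @export
setGeneric("isRetained", function(x) standardGeneric("isRetained"))

#' Validation MCC of a classifier
#' @param x a \linkS4class{TermClassifier}.
#' @return numeric in \[-1, 1\].
#' @export
setGeneric("validationMCC", function(x) standardGeneric("validationMCC"))

#' Selected feature groups of a classifier
#' @param x a \linkS4class{TermClassifier}.
#' @return character vector of retained group names.
#' @export
setGeneric("selectedGroups", function(x) standardGeneric("selectedGroups"))

#' Isoform table of a splice dataset
#' @param x an \linkS4class{IsoformDataset}.
#' @return data.frame with columns entry, isoform, main.
#' @export
setGeneric("isoformEntries", function(x) standardGeneric("isoformEntries"))

#' Consolidated per-isoform term calls
#' @param x an \linkS4class{IsoformDataset}.
#' @return named list, isoform id -> character vector of terms.
#' @export
setGeneric("isoformCalls", function(x) standardGeneric("isoformCalls"))
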