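#' @include AllClasses.R
NULL

#' Published benchmark summary of FFPred 3 and its baselines
#'
#' The per-domain evaluation summary published for the FFPred 3 predictor
#' and the Naive and BLAST baselines: for each method and GO domain, the
#' decision threshold maximising the F-measure, the total true positives,
#' false positives and false negatives at that threshold, the number of
#' covered proteins (NP), and the averaged precision, recall and F1.
#' Shipped so the evaluation formulas can be checked for internal
#' consistency against published numbers (the F1 column must equal the
#' harmonic mean of the precision and recall columns at their printed
#' precision).
#'
#' @return data.frame with columns domain, method, threshold, tp, fp, fn,
#'   np, precision, recall, f1.
#' @export
publishedBenchmarkSummary <- function() {
    data.frame(
        domain = rep(c("MF", "BP", "CC"), each = 3L),
        method = rep(c("FFPred", "BLAST", "Naive"), times = 3L),
        threshold = c(0.581, 0.210, 0.152,
                      0.576, 0.203, 0.273,
                      0.730, 0.204, 0.579),
        tp = c(1443L, 952L, 1081L, 5792L, 5272L, 4136L,
               3800L, 2030L, 2869L),
        fp = c(3457L, 5740L, 1643L, 13013L, 83543L, 8423L,
               7424L, 15655L, 3077L),
        fn = c(1818L, 2309L, 2180L, 14469L, 14989L, 16125L,
               4576L, 6346L, 5507L),
        np = c(427L, 216L, 454L, 655L, 345L, 661L,
               985L, 422L, 991L),
        precision = c(0.390, 0.266, 0.397, 0.353, 0.173, 0.329,
                      0.369, 0.215, 0.483),
        recall = c(0.461, 0.282, 0.391, 0.331, 0.271, 0.241,
                   0.500, 0.251, 0.340),
        f1 = c(0.422, 0.274, 0.394, 0.342, 0.211, 0.278,
               0.425, 0.232, 0.399))
}

#' Published vocabulary sizes of the FFPred 3 evaluation library
#'
#' Per-domain counts published for the intermediate classifier library
#' used in the timed benchmark (biological process, molecular function,
#' cellular component) together with the stated total, and the
#' per-domain sizes of the published Naive term/score table with its
#' stated total.  Shipped so the arithmetic can be verified.
#'
#' @return list with elements \code{classifiers} (named integer vector
#'   BP/MF/CC), \code{classifierTotal}, \code{naivePairs} (named integer
#'   vector CC/MF/BP) and \code{naivePairTotal}.
#' @export
publishedVocabularySizes <- function() {
    list(classifiers = c(BP = 400L, MF = 108L, CC = 89L),
         classifierTotal = 597L,
         naivePairs = c(CC = 469L, MF = 1268L, BP = 4767L),
         naivePairTotal = 6504L)
}
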