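## Internal helpers shared across modules.

## Kahn-style acyclicity check on a child -> parents relation.
.isAcyclic <- function(parents, terms) {
    deg <- lengths(parents[terms])
    names(deg) <- terms
    children <- split(rep(names(parents), lengths(parents)),
                      unlist(parents, use.names = FALSE))
    queue <- names(deg)[deg == 0L]
    seen <- 0L
    while (length(queue)) {
        t <- queue[[1L]]; queue <- queue[-1L]
        seen <- seen + 1L
        for (ch in children[[t]]) {
            deg[[ch]] <- deg[[ch]] - 1L
            if (deg[[ch]] == 0L) queue <- c(queue, ch)
        }
    }
    seen == length(terms)
}

## Condition raised when a GO term cannot support a classifier (too few
## positives, infeasible fold structure, degenerate folds).  Not an error
## in the pipeline sense: callers can catch and move on.
.rejectCandidate <- function(term, reason) {
    cond <- structure(class = c("candidateRejected", "error", "condition"),
                      list(message = sprintf("term %s rejected: %s",
                                             term, reason),
                           call = sys.call(-1L), term = term,
                           reason = reason))
    stop(cond)
}

#' Test whether a condition marks a rejected classifier candidate
#'
#' Training helpers signal a \code{candidateRejected} condition when a GO
#' term cannot support a classifier (too few positives, no feasible fold
#' count, degenerate folds).  Wrap calls in \code{tryCatch} and use this
#' predicate to skip such terms.
#'
#' @param x an object, typically caught by \code{tryCatch(...,
#'   condition = identity)}.
#' @return logical scalar.
#' @export
isCandidateRejected <- function(x) inherits(x, "candidateRejected")

## Round-half-up to 3 decimals, the tool's score output convention.
.round3 <- function(x) round(x + 1e-12, 3L)

## Format a score with exactly three decimals for TSV output.
.fmt3 <- function(x) sprintf("%.3f", x)
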