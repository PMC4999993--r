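#' @include AllClasses.R AllGenerics.R
NULL

#' Parse an OBO 1.2 document into a GOOntology
#'
#' Reads \code{[Term]} stanzas (fields \code{id}, \code{name},
#' \code{namespace}, \code{is_a}, \code{alt_id}, \code{is_obsolete}) and
#' builds the "is a" DAG over non-obsolete terms.  Obsolete terms are
#' recorded but excluded from the graph; alternative ids are mapped to
#' their canonical ids.  Other stanza types (\code{[Typedef]}) and
#' relationship lines other than \code{is_a} are ignored: propagation in
#' this package follows subsumption only.
#'
#' @param text character scalar or vector holding the OBO document.
#' @return a \linkS4class{GOOntology}.
#' @examples
#' obo <- makeToyOntology(12, seed = 1)$obo
#' onto <- parseOBO(obo)
#' goRoots(onto)
#' @export
parseOBO <- function(text) {
    lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n",
                             fixed = TRUE), use.names = FALSE)
    lines <- sub("\\s+$", "", lines)
    ## stanza boundaries
    starts <- grep("^\\[", lines)
    kinds <- lines[starts]
    ends <- c(starts[-1L] - 1L, length(lines))
    ids <- character(); nms <- character(); ns <- character()
    parents <- list(); obsolete <- character(); altId <- character()
    for (k in seq_along(starts)) {
        if (kinds[[k]] != "[Term]") next
        block <- lines[starts[[k]]:ends[[k]]]
        fld <- function(key) {
            v <- grep(paste0("^", key, ":\\s*"), block, value = TRUE)
            sub(paste0("^", key, ":\\s*"), "", v)
        }
        id <- fld("id")
        if (length(id) != 1L)
            stop("OBO parse error: [Term] stanza without a unique id (stanza ",
                 k, ")")
        isObs <- any(grepl("^is_obsolete:\\s*true", block))
        if (isObs) { obsolete <- c(obsolete, id); next }
        ids <- c(ids, id)
        nm <- fld("name"); nms[[id]] <- if (length(nm)) nm[[1L]] else id
        n1 <- fld("namespace"); ns[[id]] <- if (length(n1)) n1[[1L]] else NA_character_
        isa <- fld("is_a")
        isa <- sub("\\s*!.*$", "", isa)          # strip trailing comments
        parents[[id]] <- unique(isa)
        for (a in fld("alt_id")) altId[[a]] <- id
    }
    ## dangling references name the offending stanza
    for (id in ids) {
        bad <- setdiff(parents[[id]], ids)
        if (length(bad))
            stop("OBO parse error: term ", id, " has is_a reference to ",
                 "undeclared or obsolete id ", paste(bad, collapse = ", "))
    }
    if (!.isAcyclic(parents, ids))
        stop("OBO structural error: the is_a graph contains a cycle")
    roots <- ids[lengths(parents[ids]) == 0L]
    onto <- new("GOOntology", terms = ids, termName = nms,
                namespace = .fillNamespace(ns, parents, ids, roots),
                parents = parents, roots = roots,
                obsolete = unique(obsolete), altId = altId)
    .checkSingleRoot(onto)
    onto
}

## inherit missing namespaces from the (unique) reachable root
.fillNamespace <- function(ns, parents, ids, roots) {
    need <- ids[is.na(ns[ids])]
    if (!length(need)) return(ns[ids])
    anc <- .ancestorClosure(parents, ids)
    for (id in need) {
        r <- intersect(c(id, anc[[id]]), roots)
        ns[[id]] <- if (length(r) == 1L && !is.na(ns[[r]])) ns[[r]] else
            if (length(r) == 1L) r else NA_character_
    }
    ns[ids]
}

.checkSingleRoot <- function(onto) {
    anc <- .ancestorClosure(onto@parents, onto@terms)
    for (id in setdiff(onto@terms, onto@roots)) {
        r <- intersect(anc[[id]], onto@roots)
        if (length(r) != 1L)
            stop("OBO structural error: term ", id, " reaches ",
                 length(r), " domain roots (expected exactly 1)")
    }
    invisible(TRUE)
}

#' Read an OBO 1.2 file
#' @param path file path.
#' @return a \linkS4class{GOOntology}.
#' @export
readOBO <- function(path) parseOBO(readLines(path, warn = FALSE))

## memoised transitive ancestor closure (excluding the term itself)
.ancestorClosure <- function(parents, ids) {
    cache <- new.env(parent = emptyenv())
    rec <- function(id) {
        key <- id
        if (!is.null(cache[[key]])) return(cache[[key]])
        ps <- parents[[id]]
        out <- ps
        for (p in ps) out <- c(out, rec(p))
        out <- unique(out)
        cache[[key]] <- out
        out
    }
    res <- lapply(ids, rec)
    names(res) <- ids
    res
}

## map ids through alt_id table; error on unknowns naming them
.canonicalIds <- function(onto, ids, where = "term set") {
    hit <- ids %in% names(onto@altId)
    if (any(hit)) ids[hit] <- onto@altId[ids[hit]]
    unknown <- setdiff(ids, c(onto@terms, onto@obsolete))
    if (length(unknown))
        stop("unknown GO id(s) in ", where, ": ",
             paste(utils::head(unknown, 5L), collapse = ", "))
    ids
}

## ancestors (closure) of a set of canonical ids, optionally keeping roots
.ancestorsOf <- function(onto, ids, includeRoots = FALSE) {
    anc <- .ancestorClosure(onto@parents, onto@terms)
    out <- unique(c(ids, unlist(anc[ids], use.names = FALSE)))
    if (!includeRoots) out <- setdiff(out, onto@roots)
    out
}

#' Propagate a term set up the "is a" DAG
#'
#' Returns the input terms together with all their "is a" ancestors, with
#' the three domain roots removed, mirroring the convention used when
#' reference and predicted annotation sets are compared.  The operation is
#' idempotent and monotone.  Alternative ids are mapped to canonical ids
#' first; unknown ids raise an error.
#'
#' @param terms character vector of GO ids.
#' @param onto a \linkS4class{GOOntology}.
#' @return character vector (root-free ancestral closure).
#' @examples
#' onto <- parseOBO(makeToyOntology(12, seed = 1)$obo)
#' leaf <- setdiff(goTerms(onto), goRoots(onto))[1]
#' propagateTerms(leaf, onto)
#' @export
propagateTerms <- function(terms, onto) {
    stopifnot(is(onto, "GOOntology"))
    if (!length(terms)) return(character())
    ids <- .canonicalIds(onto, unique(terms))
    obs <- intersect(ids, onto@obsolete)
    if (length(obs))
        stop("cannot propagate obsolete id(s): ", paste(obs, collapse = ", "))
    .ancestorsOf(onto, ids, includeRoots = FALSE)
}

#' Construct an annotation table from records
#'
#' @param records data.frame with columns \code{protein}, \code{term},
#'   \code{evidence} (GAF-style triples).
#' @param propagated logical; whether "is a" propagation has been applied.
#' @return an \linkS4class{AnnotationTable}.
#' @export
annotationTable <- function(records, propagated = FALSE) {
    records <- as.data.frame(records)[, c("protein", "term", "evidence")]
    records$protein <- as.character(records$protein)
    records$term <- as.character(records$term)
    records$evidence <- as.character(records$evidence)
    new("AnnotationTable", records = records, propagated = propagated)
}

#' Read a GAF-style annotation file
#'
#' Tab-separated triples (protein id, GO id, evidence code); lines starting
#' with \code{!} are comments.  Full 17-column GAF fidelity is out of
#' scope: exactly three columns are expected.
#'
#' @param path file path.
#' @return an unpropagated \linkS4class{AnnotationTable}.
#' @export
readGAF <- function(path) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
    if (!length(lines))
        return(annotationTable(data.frame(protein = character(),
                                          term = character(),
                                          evidence = character())))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) < 3L))
        stop("GAF parse error: line with fewer than 3 tab-separated fields")
    annotationTable(data.frame(
        protein = vapply(parts, `[[`, "", 1L),
        term = vapply(parts, `[[`, "", 2L),
        evidence = vapply(parts, `[[`, "", 3L)))
}

#' Write a GAF-style annotation file
#' @param table an \linkS4class{AnnotationTable}.
#' @param path file path.
#' @return invisibly, the path.
#' @export
writeGAF <- function(table, path) {
    r <- annotationRecords(table)
    writeLines(c("!gaf-like: protein\tterm\tevidence",
                 paste(r$protein, r$term, r$evidence, sep = "\t")), path)
    invisible(path)
}

#' Propagate an annotation table up the "is a" DAG
#'
#' Every protein annotated with a term becomes annotated with all of the
#' term's "is a" ancestors, including the domain roots (root counts are
#' needed by the annotation-counting function and the naive baseline).
#' Records whose term is neither in the ontology nor an alternative id are
#' dropped with a warning; obsolete terms are dropped silently.
#'
#' @param table an \linkS4class{AnnotationTable}.
#' @param onto a \linkS4class{GOOntology}.
#' @return a propagated \linkS4class{AnnotationTable} (evidence column set
#'   to the originating record's code for direct records and
#'   \code{"ANC"} for inferred ancestors).
#' @export
propagateAnnotations <- function(table, onto) {
    stopifnot(is(table, "AnnotationTable"), is(onto, "GOOntology"))
    r <- annotationRecords(table)
    hit <- r$term %in% names(onto@altId)
    r$term[hit] <- onto@altId[r$term[hit]]
    unknown <- !(r$term %in% c(onto@terms, onto@obsolete))
    if (any(unknown)) {
        warning(sum(unknown), " annotation record(s) with unknown GO ids dropped")
        r <- r[!unknown, , drop = FALSE]
    }
    r <- r[r$term %in% onto@terms, , drop = FALSE]   # drop obsolete
    anc <- .ancestorClosure(onto@parents, onto@terms)
    pieces <- lapply(seq_len(nrow(r)), function(i) {
        up <- anc[[r$term[[i]]]]
        if (!length(up)) return(r[i, , drop = FALSE])
        rbind(r[i, , drop = FALSE],
              data.frame(protein = r$protein[[i]], term = up,
                         evidence = "ANC"))
    })
    out <- do.call(rbind, c(pieces,
                            list(data.frame(protein = character(),
                                            term = character(),
                                            evidence = character()))))
    out <- out[!duplicated(out[, c("protein", "term")]), , drop = FALSE]
    rownames(out) <- NULL
    annotationTable(out, propagated = TRUE)
}

#' Count proteins co-annotated with a term set
#'
#' The counting function N(.): for a set of GO terms it returns the number
#' of distinct proteins whose (propagated) annotation set contains every
#' term of the set; for the empty set it returns the total number of
#' annotated proteins.
#'
#' @param table a propagated \linkS4class{AnnotationTable}.
#' @param termSet character vector of GO ids (possibly empty).
#' @return nonnegative integer.
#' @export
countAnnotations <- function(table, termSet = character()) {
    stopifnot(is(table, "AnnotationTable"))
    r <- annotationRecords(table)
    byProt <- split(r$term, r$protein)
    if (!length(termSet)) return(length(byProt))
    sum(vapply(byProt, function(ts) all(termSet %in% ts), logical(1)))
}

#' Information content of a GO term
#'
#' Estimated in a Bayesian framework from annotation counts as the negative
#' log (base 2 by default, i.e. bits) of the probability that a protein
#' carries the term given that it carries all of the term's parents:
#' \deqn{IC(t) = -\log_2 \frac{N(\{t\} \cup P(t))}{N(P(t))}}
#' where \eqn{P(t)} is the set of direct "is a" parents of \eqn{t} and
#' \eqn{N(.)} is \code{\link{countAnnotations}}.  For a root, \eqn{P(t)}
#' is empty and the denominator is the total protein count.
#'
#' @param term a GO id.
#' @param table a propagated \linkS4class{AnnotationTable}.
#' @param onto a \linkS4class{GOOntology}.
#' @param base logarithm base (default 2, bits).
#' @return nonnegative real; 0 when every protein carrying the parents also
#'   carries the term.
#' @export
informationContent <- function(term, table, onto, base = 2) {
    stopifnot(length(term) == 1L)
    term <- .canonicalIds(onto, term, where = "information_content")
    ps <- onto@parents[[term]]
    nParent <- countAnnotations(table, ps)
    if (nParent == 0L)
        stop("information content undefined for term ", term,
             ": no protein is annotated with its parent set")
    nBoth <- countAnnotations(table, unique(c(term, ps)))
    -log(nBoth / nParent, base = base)
}

#' Information content of several terms at once
#'
#' @param terms character vector of GO ids.
#' @inheritParams informationContent
#' @return named numeric vector of IC values (bits by default).
#' @export
termICs <- function(terms, table, onto, base = 2) {
    out <- vapply(terms, informationContent, numeric(1),
                  table = table, onto = onto, base = base)
    names(out) <- terms
    out
}

## ---- accessors & show ----

#' @describeIn goTerms method for GOOntology
setMethod("goTerms", "GOOntology", function(x) x@terms)
#' @describeIn goRoots method for GOOntology
setMethod("goRoots", "GOOntology", function(x) x@roots)
#' @describeIn goObsolete method for GOOntology
setMethod("goObsolete", "GOOntology", function(x) x@obsolete)
#' @describeIn termNamespace method for GOOntology
setMethod("termNamespace", "GOOntology",
          function(x, ids = goTerms(x)) x@namespace[ids])
#' @describeIn termParents method for GOOntology
setMethod("termParents", "GOOntology", function(x, ids) x@parents[ids])
#' @describeIn annotationRecords method for AnnotationTable
setMethod("annotationRecords", "AnnotationTable", function(x) x@records)
#' @describeIn isPropagated method for AnnotationTable
setMethod("isPropagated", "AnnotationTable", function(x) x@propagated)

setMethod("show", "GOOntology", function(object) {
    cat("GOOntology with", length(object@terms), "terms,",
        length(object@roots), "roots,",
        length(object@obsolete), "obsolete ids\n")
    tab <- table(object@namespace[object@terms])
    for (nm in names(tab)) cat("  ", nm, ": ", tab[[nm]], "\n", sep = "")
})

setMethod("show", "AnnotationTable", function(object) {
    r <- object@records
    cat("AnnotationTable:", nrow(r), "records,",
        length(unique(r$protein)), "proteins,",
        length(unique(r$term)), "terms;",
        if (object@propagated) "propagated" else "raw", "\n")
})
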