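## Shared fixtures and independent oracles, built in code at test time.

## three-term chain in one domain: leaf is_a mid is_a root
chainOBO <- function() c(
    "format-version: 1.2", "",
    "[Term]", "id: GO:0000001", "name: root",
    "namespace: molecular_function", "",
    "[Term]", "id: GO:0000002", "name: mid",
    "namespace: molecular_function", "is_a: GO:0000001 ! root", "",
    "[Term]", "id: GO:0000003", "name: leaf",
    "namespace: molecular_function", "is_a: GO:0000002 ! mid", "")

## one root with n independent children (propagation is the identity on
## root-free sets): used to compare evaluation formulas without the
## confounding effect of ancestor closure
flatOBO <- function(n = 10L) {
    out <- c("format-version: 1.2", "",
             "[Term]", "id: GO:0000001", "name: root",
             "namespace: molecular_function", "")
    for (i in seq_len(n))
        out <- c(out, "[Term]", sprintf("id: GO:%07d", i + 1L),
                 sprintf("name: child %d", i),
                 "namespace: molecular_function",
                 "is_a: GO:0000001 ! root", "")
    out
}

## brute-force transitive closure over manifest edges, roots removed
bruteClosure <- function(terms, edges, roots) {
    out <- unique(terms)
    repeat {
        more <- unique(edges$parent[edges$child %in% out])
        if (all(more %in% out)) break
        out <- union(out, more)
    }
    setdiff(out, roots)
}

## independent MCC evaluation straight from the formula
oracleMCC <- function(tp, tn, fp, fn) {
    num <- tp * tn - fp * fn
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    if (den == 0) 0 else num / den
}

## independent protein-centric averaged precision/recall/F at threshold v:
## predSets = list of data.frames (term, score); refSets = list of
## character vectors; no propagation (call with a flat ontology)
oraclePRF <- function(predSets, refSets, v) {
    m <- length(refSets)
    precs <- c(); rec <- 0; n <- 0
    for (p in names(refSets)) {
        df <- predSets[[p]]
        P <- if (is.null(df)) character() else unique(df$term[df$score >= v])
        R <- refSets[[p]]
        tp <- sum(P %in% R)
        if (!is.null(df) && any(df$score >= v)) {
            n <- n + 1
            precs <- c(precs, tp / length(P))
        }
        rec <- rec + tp / length(R)
    }
    prec <- if (n > 0) sum(precs) / n else NA_real_
    rec <- rec / m
    f <- if (!is.na(prec) && prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    c(precision = prec, recall = rec, F = f)
}

## ---- memoised planted-signal world -------------------------------------
## Built once per test session: a 60-term toy ontology, a 200-protein
## proteome with one disorder rule on the deepest biological_process term
## (noise 0.1, seed 1), a classifier library trained for every BP term
## with >= 50 positives, and a held-out 100-protein test proteome with
## its benchmark.
.worldCache <- new.env(parent = emptyenv())

plantedWorld <- function() {
    if (!is.null(.worldCache$world)) return(.worldCache$world)
    .worldCache$world <- plantedBenchmarkWorld(seed = 1)
    .worldCache$world
}
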