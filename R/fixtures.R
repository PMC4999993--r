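#' @include AllClasses.R AllGenerics.R ontology.R features.R svm.R
NULL

## residue pools used to plant feature signal.  Disorder-promoting and
## order-promoting pools separate cleanly on the TOP-IDP scale; the
## neutral pool is roughly uniform.
.POOL_DISORDER <- c(P=3, E=3, S=3, K=2, Q=2, G=2, R=2, D=2, A=1)
.POOL_ORDER <- c(W=2, F=3, Y=2, I=3, L=3, V=3, M=1, C=1, N=1, T=1, H=1)
.POOL_NEUTRAL <- stats::setNames(rep(1, 20), .AA)

.samplePool <- function(n, pool) {
    sample(names(pool), n, replace = TRUE, prob = pool / sum(pool))
}

#' Describe a planted feature-to-function rule
#'
#' A rule ties a GO term to a threshold on one summary scalar of a
#' feature group; the proteome generator biases sequences so that about
#' half satisfy the predicate, then flips labels at the noise rate.
#' This embodies the premise behind feature-based function prediction:
#' proteins sharing a function share biophysical attributes.
#'
#' @param term GO id the rule annotates.
#' @param group feature group carrying the signal; built-in sequence
#'   biases exist for \code{"disorder"} (disordered-residue fraction) and
#'   \code{"transmembrane"} (helix count).
#' @param threshold decision threshold on the group's first scalar.
#' @param noise label flip rate in \[0, 0.5).
#' @return a \code{plantedRule} list.
#' @export
plantedRule <- function(term, group = "disorder", threshold = 0.4,
                        noise = 0.1) {
    stopifnot(noise >= 0, noise < 0.5,
              group %in% c("disorder", "transmembrane"))
    structure(list(term = term, group = group, threshold = threshold,
                   feature = paste0(group, ".1"), noise = noise),
              class = "plantedRule")
}

#' Generate a three-domain toy ontology
#'
#' Builds a random "is a" DAG with one root per GO domain and \code{nTerms}
#' terms in total (terms beyond the three roots are assigned to domains
#' round-robin; each attaches to up to \code{branching} earlier terms of
#' its domain).  Deterministic under \code{seed}.
#'
#' @param nTerms total number of terms including the three roots (>= 4).
#' @param branching maximum parents per term (>= 1).
#' @param seed integer seed.
#' @param nObsolete number of additional obsolete stanzas to emit.
#' @return list with elements \code{obo} (character vector of OBO 1.2
#'   lines) and \code{manifest} (list: \code{terms} data.frame with term
#'   and namespace, \code{edges} data.frame child/parent, \code{roots}).
#' @export
makeToyOntology <- function(nTerms = 30L, branching = 2L, seed = 1L,
                            nObsolete = 0L) {
    stopifnot(nTerms >= 4L, branching >= 1L)
    domains <- c("molecular_function", "biological_process",
                 "cellular_component")
    ids <- sprintf("GO:%07d", seq_len(nTerms))
    ns <- character(nTerms)
    ns[1:3] <- domains
    parents <- stats::setNames(vector("list", nTerms), ids)
    edges <- list()
    .withSeed(seed, {
        for (i in seq_len(nTerms)[-(1:3)]) {
            d <- domains[((i - 4L) %% 3L) + 1L]
            ns[[i]] <- d
            pool <- ids[seq_len(i - 1L)][ns[seq_len(i - 1L)] == d]
            k <- min(length(pool), sample.int(branching, 1L))
            ps <- sample(pool, k)
            parents[[ids[[i]]]] <- ps
            edges[[length(edges) + 1L]] <-
                data.frame(child = ids[[i]], parent = ps)
        }
    })
    obo <- c("format-version: 1.2", "")
    for (i in seq_len(nTerms)) {
        ps <- parents[[ids[[i]]]]
        obo <- c(obo, "[Term]",
                 paste0("id: ", ids[[i]]),
                 paste0("name: toy term ", i),
                 paste0("namespace: ", ns[[i]]),
                 if (length(ps)) paste0("is_a: ", ps, " ! parent"),
                 "")
    }
    if (nObsolete > 0L) {
        obsIds <- sprintf("GO:%07d", nTerms + seq_len(nObsolete))
        for (o in obsIds)
            obo <- c(obo, "[Term]", paste0("id: ", o),
                     paste0("name: retired ", o),
                     "is_obsolete: true", "")
    }
    edges <- do.call(rbind, c(edges, list(
        data.frame(child = character(), parent = character()))))
    list(obo = obo,
         manifest = list(terms = data.frame(term = ids, namespace = ns),
                         edges = edges, roots = ids[1:3]))
}

#' Generate a synthetic proteome with planted feature-to-function rules
#'
#' Sequences are sampled from residue pools biased to satisfy or violate
#' each rule's predicate (disorder rules switch between disorder- and
#' order-promoting pools; transmembrane rules insert a hydrophobic
#' stretch).  The realised label of a rule is its predicate evaluated on
#' the extracted features, flipped at the rule's noise rate.  The GAF
#' carries one record per positive rule label plus, per GO domain,
#' \code{backgroundPerDomain} uniformly drawn non-root background terms
#' per protein, so every protein carries reference annotation in every
#' domain and a constant predictor cannot be trivially perfect.  Evidence
#' codes are sampled from the experimental and electronic pools so both
#' evidence filters have work to do.  Deterministic under \code{seed}.
#'
#' @param nProteins number of proteins.
#' @param ontology output of \code{\link{makeToyOntology}} (or a
#'   compatible list with a \code{manifest}).
#' @param rules list of \code{\link{plantedRule}} objects.
#' @param seed integer seed.
#' @param lengthRange sequence length bounds (default 50-600, inside the
#'   15-1500 retention window).
#' @param backgroundPerDomain background annotations per protein and
#'   domain (default 1).
#' @param evidencePool evidence codes to sample GAF records from.
#' @return list with elements \code{sequences} (AAStringSet), \code{gaf}
#'   (data.frame protein/term/evidence), \code{truth} (data.frame with
#'   one row per protein and rule: intended, actual, label) and
#'   \code{background} (data.frame of background annotations).
#' @export
makeProteome <- function(nProteins = 200L, ontology, rules = list(),
                         seed = 1L, lengthRange = c(50L, 600L),
                         backgroundPerDomain = 1L,
                         evidencePool = c("EXP", "IDA", "IPI", "IMP",
                                          "IGI", "IEP", "TAS", "IC",
                                          "IEA")) {
    man <- ontology$manifest
    ruleTerms <- vapply(rules, `[[`, "", "term")
    bad <- setdiff(ruleTerms, man$terms$term)
    if (length(bad))
        stop("rule references unknown term(s): ", paste(bad, collapse = ", "))
    ids <- sprintf("P%05d", seq_len(nProteins))
    reg <- defaultRegistry()
    disRules <- Filter(function(r) r$group == "disorder", rules)
    tmRules <- Filter(function(r) r$group == "transmembrane", rules)
    res <- .withSeed(seed, {
        lens <- sample(lengthRange[[1L]]:lengthRange[[2L]], nProteins,
                       replace = TRUE)
        intended <- matrix(stats::runif(nProteins * length(rules)) < 0.5,
                           nProteins, max(1L, length(rules)))
        ## disorder content varies continuously: each protein draws its
        ## residues from a mixture of the disorder- and order-promoting
        ## pools with a uniform per-protein mixing weight, so the planted
        ## threshold on the realised disorder fraction is the actual
        ## label boundary rather than a pool identity
        mixw <- stats::runif(nProteins)
        pd <- .POOL_DISORDER / sum(.POOL_DISORDER)
        po <- .POOL_ORDER / sum(.POOL_ORDER)
        allRes <- union(names(pd), names(po))
        pdf <- stats::setNames(rep(0, length(allRes)), allRes)
        pof <- pdf
        pdf[names(pd)] <- pd; pof[names(po)] <- po
        seqs <- character(nProteins)
        for (i in seq_len(nProteins)) {
            pool <- .POOL_NEUTRAL
            if (length(disRules)) {
                j <- match(disRules[[1L]]$term, ruleTerms)
                pool <- mixw[[i]] * pdf + (1 - mixw[[i]]) * pof
                intended[i, j] <- mixw[[i]] > 0.5
            }
            s <- .samplePool(lens[[i]], pool)
            if (length(tmRules)) {
                j <- match(tmRules[[1L]]$term, ruleTerms)
                if (intended[i, j]) {
                    stretch <- .samplePool(25L, c(L=3, I=3, V=3, F=2, A=1))
                    at <- sample.int(length(s) - 25L, 1L)
                    s[at:(at + 24L)] <- stretch
                }
            }
            seqs[[i]] <- paste(s, collapse = "")
        }
        names(seqs) <- ids
        feats <- featureMatrix(seqs, reg)
        truthRows <- list(); gafRows <- list()
        for (j in seq_along(rules)) {
            r <- rules[[j]]
            actual <- feats[, r$feature] > r$threshold
            if (all(actual) || !any(actual))
                stop("unsatisfiable predicate for rule on ", r$term,
                     ": all proteins fall on one side of the threshold")
            flip <- stats::runif(nProteins) < r$noise
            label <- xor(actual, flip)
            truthRows[[j]] <- data.frame(protein = ids, term = r$term,
                                         intended = intended[, j],
                                         actual = actual, label = label)
            if (any(label))
                gafRows[[length(gafRows) + 1L]] <- data.frame(
                    protein = ids[label], term = r$term,
                    evidence = sample(evidencePool, sum(label),
                                      replace = TRUE))
        }
        ## per-domain background annotations; the pool excludes the rule
        ## terms and their descendants so background draws cannot
        ## propagate into a planted label
        ruleClosed <- ruleTerms
        repeat {
            more <- unique(man$edges$child[man$edges$parent %in% ruleClosed])
            if (all(more %in% ruleClosed)) break
            ruleClosed <- union(ruleClosed, more)
        }
        bgRows <- list()
        for (dom in unique(man$terms$namespace)) {
            pool <- setdiff(
                man$terms$term[man$terms$namespace == dom],
                c(man$roots, ruleClosed))
            if (!length(pool) || backgroundPerDomain < 1L) next
            for (b in seq_len(backgroundPerDomain))
                bgRows[[length(bgRows) + 1L]] <- data.frame(
                    protein = ids,
                    term = sample(pool, nProteins, replace = TRUE),
                    evidence = sample(evidencePool, nProteins,
                                      replace = TRUE))
        }
        bg <- do.call(rbind, c(bgRows, list(
            data.frame(protein = character(), term = character(),
                       evidence = character()))))
        gaf <- do.call(rbind, c(gafRows, list(bg)))
        gaf <- gaf[!duplicated(gaf[, c("protein", "term")]), , drop = FALSE]
        rownames(gaf) <- NULL
        list(sequences = Biostrings::AAStringSet(seqs), gaf = gaf,
             truth = do.call(rbind, c(truthRows, list(
                 data.frame(protein = character(), term = character(),
                            intended = logical(), actual = logical(),
                            label = logical())))),
             background = bg, features = feats)
    })
    res
}

#' Generate a synthetic isoform catalogue
#'
#' Each entry gets one main sequence plus alternatives derived from it by
#' seeded internal-segment deletions and substitutions.  With
#' \code{plantViolations}, a few isoforms deliberately break the
#' retention filters: a truncated alternative (shorter than 15 residues),
#' an alternative containing a non-standard symbol, an alternative
#' flagged as recorded in a separate database entry, and one overlong
#' main isoform (whose whole entry cascades out).
#'
#' @param nGenes number of entries.
#' @param maxAlt maximum alternative isoforms per entry (0 to
#'   \code{maxAlt}, sampled).
#' @param seed integer seed.
#' @param plantViolations plant filter violations (default TRUE).
#' @param perturbation one of \code{"delete"} (internal deletion,
#'   default) or \code{"none"} (alternatives identical to mains).
#' @return list with \code{catalogue} (data.frame entry, isoform, main,
#'   external), \code{sequences} (AAStringSet) and \code{manifest}
#'   (data.frame isoform, violation letter or NA).
#' @export
makeIsoformCatalogue <- function(nGenes = 30L, maxAlt = 3L, seed = 1L,
                                 plantViolations = TRUE,
                                 perturbation = c("delete", "none")) {
    stopifnot(nGenes >= 1L)
    perturbation <- match.arg(perturbation)
    .withSeed(seed, {
        rows <- list(); seqs <- character(); viol <- list()
        for (g in seq_len(nGenes)) {
            entry <- sprintf("E%04d", g)
            main <- paste(.samplePool(sample(60:200, 1L), .POOL_NEUTRAL),
                          collapse = "")
            isoIds <- paste0(entry, "-1")
            seqs[[isoIds]] <- main
            nAlt <- sample(0:maxAlt, 1L)
            for (a in seq_len(nAlt)) {
                iso <- paste0(entry, "-", a + 1L)
                s <- main
                if (perturbation == "delete") {
                    n <- nchar(main)
                    cut <- sort(sample(2:(n - 1L), 2L))
                    if (diff(cut) > 0.4 * n) cut[2L] <- cut[1L] + floor(0.4 * n)
                    s <- paste0(substr(main, 1L, cut[1L] - 1L),
                                substr(main, cut[2L] + 1L, n))
                }
                seqs[[iso]] <- s
                isoIds <- c(isoIds, iso)
            }
            rows[[g]] <- data.frame(entry = entry, isoform = isoIds,
                                    main = seq_along(isoIds) == 1L,
                                    external = FALSE)
        }
        cat <- do.call(rbind, rows)
        man <- data.frame(isoform = cat$isoform, violation = NA_character_)
        if (plantViolations && nGenes >= 5L) {
            alts <- cat$isoform[!cat$main]
            if (length(alts) >= 3L) {
                pick <- sample(alts, 3L)
                seqs[[pick[[1L]]]] <- substr(seqs[[pick[[1L]]]], 1L, 8L)
                man$violation[man$isoform == pick[[1L]]] <- "b"
                s2 <- seqs[[pick[[2L]]]]
                substr(s2, 5L, 5L) <- "X"
                seqs[[pick[[2L]]]] <- s2
                man$violation[man$isoform == pick[[2L]]] <- "d"
                cat$external[cat$isoform == pick[[3L]]] <- TRUE
                man$violation[man$isoform == pick[[3L]]] <- "e"
            }
            ## one overlong main: the whole entry cascades out
            mains <- cat$isoform[cat$main]
            longMain <- sample(mains, 1L)
            seqs[[longMain]] <- strrep(seqs[[longMain]],
                                       ceiling(1600 / nchar(seqs[[longMain]])))
            man$violation[man$isoform == longMain] <- "c"
        }
        rownames(cat) <- NULL
        list(catalogue = cat, sequences = Biostrings::AAStringSet(seqs),
             manifest = man)
    })
}

#' Write a complete synthetic dataset directory
#'
#' Emits OBO, FASTA, GAF, a hits TSV (random query/subject pairs in
#' outfmt-6-like 4-column form), an isoform catalogue with its FASTA, and
#' a flat key-value manifest -- everything needed to exercise the full
#' pipeline from files.
#'
#' @param dir output directory.
#' @param nTerms,nProteins,nGenes sizes passed to the generators.
#' @param rules list of \code{\link{plantedRule}}; default plants one
#'   disorder rule on the first non-root biological_process term.
#' @param seed integer seed.
#' @return invisibly, a list with the in-memory objects.
#' @export
writeFixtureDataset <- function(dir, nTerms = 30L, nProteins = 200L,
                                nGenes = 20L, rules = NULL, seed = 1L) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    onto <- makeToyOntology(nTerms, seed = seed)
    if (is.null(rules)) {
        ## plant on the deepest biological_process term so the rule has
        ## ancestors to propagate into and same-domain negatives exist
        o <- parseOBO(onto$obo)
        bp <- setdiff(onto$manifest$terms$term[
            onto$manifest$terms$namespace == "biological_process"],
            onto$manifest$roots)
        depth <- vapply(bp, function(t) length(propagateTerms(t, o)),
                        integer(1))
        rules <- list(plantedRule(bp[[which.max(depth)]]))
    }
    prot <- makeProteome(nProteins, onto, rules, seed = seed + 1L)
    iso <- makeIsoformCatalogue(nGenes, seed = seed + 2L)
    writeLines(onto$obo, file.path(dir, "ontology.obo"))
    Biostrings::writeXStringSet(prot$sequences,
                                file.path(dir, "proteome.fasta"))
    writeGAF(annotationTable(prot$gaf), file.path(dir, "annotations.gaf"))
    hits <- .withSeed(seed + 3L, {
        ids <- names(prot$sequences)
        n <- min(200L, length(ids) * 2L)
        data.frame(query = sample(ids, n, replace = TRUE),
                   subject = sample(ids, n, replace = TRUE),
                   pident = round(stats::runif(n, 20, 60), 1L),
                   evalue = signif(10^stats::runif(n, -6, 1), 3L))
    })
    utils::write.table(hits, file.path(dir, "hits.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    utils::write.table(iso$catalogue, file.path(dir, "isoforms.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    Biostrings::writeXStringSet(iso$sequences,
                                file.path(dir, "isoforms.fasta"))
    manifest <- c(
        paste0("n_terms=", nTerms),
        paste0("n_proteins=", nProteins),
        paste0("n_genes=", nGenes),
        paste0("seed=", seed),
        paste0("rule_term=", vapply(rules, `[[`, "", "term")),
        paste0("rule_group=", vapply(rules, `[[`, "", "group")))
    writeLines(manifest, file.path(dir, "manifest.txt"))
    invisible(list(ontology = onto, proteome = prot, isoforms = iso))
}

#' Build a complete planted-signal benchmark world
#'
#' The reference end-to-end experiment the package's tests and the
#' reproduction script run: a 60-term three-domain toy ontology; a
#' 200-protein training proteome with one disorder rule (threshold 0.4 on
#' the disordered-residue fraction, label noise 0.1) planted on the
#' deepest biological_process term; a classifier library trained for
#' every biological_process term with at least 50 positives; and a
#' held-out 100-protein test proteome with its evaluation benchmark.
#' The ontology is fixed (seed 1) so the planted term is stable; the
#' proteomes, splits and folds all derive from \code{seed}.
#'
#' @param seed integer seed driving the proteomes and training.
#' @return list with elements \code{onto} (generator output), \code{o}
#'   (parsed \linkS4class{GOOntology}), \code{rule}, \code{train},
#'   \code{ptab} (propagated training annotations), \code{ds} (the
#'   planted term's \linkS4class{TermDataset}), \code{models} (the
#'   trained library), \code{clf} (the planted term's classifier),
#'   \code{test} and \code{bench}.
#' @export
plantedBenchmarkWorld <- function(seed = 1L) {
    onto <- makeToyOntology(60, seed = 1)
    o <- parseOBO(onto$obo)
    man <- onto$manifest
    bp <- setdiff(man$terms$term[man$terms$namespace ==
                                 "biological_process"], man$roots)
    depth <- vapply(bp, function(t) length(propagateTerms(t, o)),
                    integer(1))
    rule <- plantedRule(bp[[which.max(depth)]], "disorder",
                        threshold = 0.4, noise = 0.1)
    train <- makeProteome(200, onto, list(rule), seed = seed)
    ptab <- propagateAnnotations(annotationTable(train$gaf), o)
    models <- list()
    for (t in bp) {
        ds <- tryCatch(assembleTermDataset(t, ptab, o, minPos = 50),
                       condition = identity)
        if (isCandidateRejected(ds)) next
        clf <- tryCatch(trainTermClassifier(ds, train$features,
                                            seed = seed),
                        condition = identity)
        if (isCandidateRejected(clf)) next
        models[[t]] <- clf
    }
    test <- makeProteome(100, onto, list(rule), seed = seed + 1)
    bench <- buildBenchmark(annotationTable(test$gaf), o)
    ds <- assembleTermDataset(rule$term, ptab, o, minPos = 50)
    list(onto = onto, o = o, rule = rule, train = train, ptab = ptab,
         ds = ds, models = models, clf = models[[rule$term]],
         test = test, bench = bench)
}
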