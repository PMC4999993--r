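test_that("OBO parsing builds the expected DAG on a minimal chain", {
    o <- parseOBO(chainOBO())
    expect_setequal(goTerms(o), c("GO:0000001", "GO:0000002", "GO:0000003"))
    expect_equal(sum(lengths(o@parents)), 2L)     # two is_a edges
    expect_equal(goRoots(o), "GO:0000001")
    expect_equal(unname(termNamespace(o, "GO:0000003")),
                 "molecular_function")
})

test_that("obsolete stanzas are flagged and excluded from the DAG", {
    obo <- c(chainOBO(), "[Term]", "id: GO:0000009",
             "name: retired", "is_obsolete: true", "")
    o <- parseOBO(obo)
    expect_true("GO:0000009" %in% goObsolete(o))
    expect_false("GO:0000009" %in% goTerms(o))
})

test_that("alt_id entries map to canonical ids", {
    obo <- sub("name: leaf", "name: leaf\nalt_id: GO:0000099",
               paste(chainOBO(), collapse = "\n"), fixed = TRUE)
    o <- parseOBO(obo)
    expect_false("GO:0000099" %in% goTerms(o))
    expect_setequal(propagateTerms("GO:0000099", o),
                    c("GO:0000003", "GO:0000002"))
})

test_that("structural defects are rejected with informative errors", {
    dangling <- c("format-version: 1.2", "", "[Term]", "id: GO:0000001",
                  "name: a", "is_a: GO:0999999 ! nowhere", "")
    expect_error(parseOBO(dangling), "GO:0999999")
    cyc <- c("format-version: 1.2", "",
             "[Term]", "id: GO:0000001", "name: a",
             "is_a: GO:0000002 ! b", "",
             "[Term]", "id: GO:0000002", "name: b",
             "is_a: GO:0000001 ! a", "")
    expect_error(parseOBO(cyc), "cycle")
})

test_that("generated toy ontologies round-trip through the parser", {
    onto <- makeToyOntology(30, seed = 1)
    o <- parseOBO(onto$obo)
    expect_equal(length(goTerms(o)), nrow(onto$manifest$terms))
    expect_setequal(goRoots(o), onto$manifest$roots)
})

test_that("propagation excludes roots and closes chains", {
    o <- parseOBO(chainOBO())
    expect_equal(propagateTerms("GO:0000001", o), character())
    expect_setequal(propagateTerms("GO:0000003", o),
                    c("GO:0000003", "GO:0000002"))
    expect_error(propagateTerms("GO:1111111", o), "unknown")
})

test_that("propagation equals brute-force closure, is idempotent and monotone", {
    for (seed in 1:5) {
        onto <- makeToyOntology(24, seed = seed)
        o <- parseOBO(onto$obo)
        nonRoot <- setdiff(goTerms(o), goRoots(o))
        set.seed(seed)
        sub <- sample(nonRoot, 5)
        got <- propagateTerms(sub, o)
        expect_setequal(got, bruteClosure(sub, onto$manifest$edges,
                                          onto$manifest$roots))
        expect_setequal(propagateTerms(got, o), got)   # idempotent
        sup <- propagateTerms(union(sub, sample(nonRoot, 2)), o)
        expect_true(all(got %in% sup))                 # monotone
    }
})

test_that("annotation counting follows the superset convention", {
    o <- parseOBO(chainOBO())
    raw <- annotationTable(data.frame(
        protein = sprintf("P%02d", 1:10),
        term = c(rep("GO:0000003", 4), rep("GO:0000002", 6)),
        evidence = "EXP"))
    tab <- propagateAnnotations(raw, o)
    expect_equal(countAnnotations(tab), 10L)
    expect_equal(countAnnotations(tab, "GO:0000003"), 4L)
    ## parent membership is implied after propagation
    expect_equal(countAnnotations(tab, c("GO:0000003", "GO:0000002")),
                 countAnnotations(tab, "GO:0000003"))
    ## N is anti-monotone in the set
    expect_lte(countAnnotations(tab, c("GO:0000003", "GO:0000002")),
               min(countAnnotations(tab, "GO:0000003"),
                   countAnnotations(tab, "GO:0000002")))
    ## a term annotating nobody
    raw2 <- annotationTable(data.frame(protein = "P01",
                                       term = "GO:0000002",
                                       evidence = "EXP"))
    tab2 <- propagateAnnotations(raw2, o)
    expect_equal(countAnnotations(tab2, "GO:0000003"), 0L)
})

test_that("information content matches the conditional-probability form", {
    o <- parseOBO(chainOBO())
    mkTab <- function(nLeaf, nMid) propagateAnnotations(annotationTable(
        data.frame(protein = sprintf("P%02d", seq_len(nLeaf + nMid)),
                   term = c(rep("GO:0000003", nLeaf),
                            rep("GO:0000002", nMid)),
                   evidence = "EXP")), o)
    ## term present in every protein carrying its parent -> 0 bits
    expect_equal(informationContent("GO:0000003", mkTab(5, 0), o), 0)
    ## present in exactly half -> 1 bit
    expect_equal(informationContent("GO:0000003", mkTab(4, 4), o), 1)
    ## N(P(t)) = 8, N({t} u P(t)) = 2 -> 2 bits
    expect_equal(informationContent("GO:0000003", mkTab(2, 6), o), 2)
    ## undefined when nobody carries the parent set
    raw <- annotationTable(data.frame(protein = "P01", term = "GO:0000001",
                                      evidence = "EXP"))
    ## GO:0000003's parent GO:0000002 annotates nobody here
    expect_error(
        informationContent("GO:0000003", propagateAnnotations(raw, o), o),
        "undefined")
})

test_that("IC telescopes along a chain to the leaf's annotation surprisal", {
    o <- parseOBO(chainOBO())
    tab <- propagateAnnotations(annotationTable(data.frame(
        protein = sprintf("P%02d", 1:16),
        term = c(rep("GO:0000003", 3), rep("GO:0000002", 5),
                 rep("GO:0000001", 8)),
        evidence = "EXP")), o)
    icSum <- informationContent("GO:0000003", tab, o) +
        informationContent("GO:0000002", tab, o)
    expect_equal(icSum, -log2(3 / 16))
    ## a direct child of the root: IC = -log2(N({child}) / N(empty))
    expect_equal(informationContent("GO:0000002", tab, o),
                 -log2(countAnnotations(tab, "GO:0000002") /
                       countAnnotations(tab)))
    ## nonnegativity across the chain
    expect_true(all(termICs(goTerms(o)[-1], tab, o) >= 0))
})

test_that("GAF reading skips comments and round-trips", {
    path <- withr::local_tempfile(fileext = ".gaf")
    writeLines(c("! comment line", "P1\tGO:0000003\tEXP",
                 "P2\tGO:0000002\tIEA"), path)
    tab <- readGAF(path)
    expect_equal(nrow(annotationRecords(tab)), 2L)
    expect_false(isPropagated(tab))
    out <- withr::local_tempfile(fileext = ".gaf")
    writeGAF(tab, out)
    expect_equal(annotationRecords(readGAF(out)), annotationRecords(tab))
})
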