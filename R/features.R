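#' @include AllClasses.R AllGenerics.R
NULL

## ---- residue property scales -------------------------------------------
## Indexed by one-letter code.  Sources: Kyte-Doolittle hydropathy,
## TOP-IDP disorder propensity, Chou-Fasman secondary-structure
## propensities, Grantham polarity, Vihinen flexibility, residue volumes,
## Eisenberg consensus hydrophobicity, residue monomer masses.

.AA <- c("A","C","D","E","F","G","H","I","K","L",
         "M","N","P","Q","R","S","T","V","W","Y")

.scaleVec <- function(...) {
    v <- c(...)
    stopifnot(setequal(names(v), .AA))
    v[.AA]
}

.KD <- .scaleVec(A=1.8,R=-4.5,N=-3.5,D=-3.5,C=2.5,Q=-3.5,E=-3.5,G=-0.4,
                 H=-3.2,I=4.5,L=3.8,K=-3.9,M=1.9,F=2.8,P=-1.6,S=-0.8,
                 T=-0.7,W=-0.9,Y=-1.3,V=4.2)
.TOPIDP <- .scaleVec(W=-0.884,F=-0.697,Y=-0.510,I=-0.486,M=-0.397,L=-0.326,
                     V=-0.121,N=0.007,C=0.020,T=0.059,A=0.060,G=0.166,
                     R=0.180,D=0.192,H=0.303,Q=0.318,K=0.586,S=0.341,
                     E=0.736,P=0.987)
.CFH <- .scaleVec(A=1.42,C=0.70,D=1.01,E=1.51,F=1.13,G=0.57,H=1.00,I=1.08,
                  K=1.16,L=1.21,M=1.45,N=0.67,P=0.57,Q=1.11,R=0.98,S=0.77,
                  T=0.83,V=1.06,W=1.08,Y=0.69)
.CFS <- .scaleVec(A=0.83,C=1.19,D=0.54,E=0.37,F=1.38,G=0.75,H=0.87,I=1.60,
                  K=0.74,L=1.30,M=1.05,N=0.89,P=0.55,Q=1.10,R=0.93,S=0.75,
                  T=1.19,V=1.70,W=1.37,Y=1.47)
.MASS <- .scaleVec(A=71.08,R=156.19,N=114.10,D=115.09,C=103.14,E=129.12,
                   Q=128.13,G=57.05,H=137.14,I=113.16,L=113.16,K=128.17,
                   M=131.19,F=147.18,P=97.12,S=87.08,T=101.10,W=186.21,
                   Y=163.18,V=99.13)
.FLEX <- .scaleVec(A=0.984,C=0.906,D=1.068,E=1.094,F=0.915,G=1.031,H=0.950,
                   I=0.927,K=1.102,L=0.935,M=0.952,N=1.048,P=1.049,Q=1.037,
                   R=1.008,S=1.046,T=0.997,V=0.931,W=0.904,Y=0.929)
.POLAR <- .scaleVec(A=8.1,R=10.5,N=11.6,D=13.0,C=5.5,Q=10.5,E=12.3,G=9.0,
                    H=10.4,I=5.2,L=4.9,K=11.3,M=5.7,F=5.2,P=8.0,S=9.2,
                    T=8.6,W=5.4,Y=6.2,V=5.9)
.VOL <- .scaleVec(A=88.6,R=173.4,N=114.1,D=111.1,C=108.5,Q=143.8,E=138.4,
                  G=60.1,H=153.2,I=166.7,L=166.7,K=168.6,M=162.9,F=189.9,
                  P=112.7,S=89.0,T=116.1,V=140.0,W=227.8,Y=193.6)
.EISEN <- .scaleVec(A=0.62,R=-2.53,N=-0.78,D=-0.90,C=0.29,Q=-0.85,E=-0.74,
                    G=0.48,H=-0.40,I=1.38,L=1.06,K=-1.50,M=0.64,F=1.19,
                    P=0.12,S=-0.18,T=-0.05,W=0.81,Y=0.26,V=1.08)

## window parameters for the built-in approximations (documented defaults)
.featOpts <- list(tmWindow = 19L, tmCutoff = 1.6,
                  disWindow = 15L, ssWindow = 7L,
                  lcWindow = 12L, lcCutoff = 2.2,
                  ccWindow = 28L, hmWindow = 11L)

## ---- small numeric helpers ---------------------------------------------

## means of all length-w windows (valid positions only); length n-w+1
.winMeans <- function(x, w) {
    n <- length(x)
    if (n < w) return(mean(x))
    cs <- cumsum(c(0, x))
    (cs[(w + 1L):(n + 1L)] - cs[1L:(n - w + 1L)]) / w
}

## centred smoothing with boundary clipping; length n
.smooth <- function(x, w) {
    n <- length(x); h <- (w - 1L) %/% 2L
    cs <- cumsum(c(0, x))
    lo <- pmax(seq_len(n) - h, 1L); hi <- pmin(seq_len(n) + h, n)
    (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

.runs <- function(flag) {
    r <- rle(flag)
    data.frame(len = r$lengths[r$values],
               start = (cumsum(r$lengths) - r$lengths + 1L)[r$values])
}

.longestRun <- function(flag) { r <- .runs(flag); if (nrow(r)) max(r$len) else 0L }

.shannon <- function(counts) {
    p <- counts[counts > 0]; p <- p / sum(p)
    -sum(p * log2(p))
}

.perHundred <- function(k, n) 100 * k / n

## ---- per-group extractors ----------------------------------------------

.fComposition <- function(res) {
    n <- length(res)
    as.numeric(table(factor(res, levels = .AA))) / n
}

.DIPCLASS <- c(A=1L,G=1L,V=1L, I=2L,L=2L,F=2L,P=2L,M=2L, Y=3L,T=3L,S=3L,
               H=4L,N=4L,Q=4L,W=4L, R=5L,K=5L, D=6L,E=6L, C=7L)

.fDipeptides <- function(res) {
    cls <- .DIPCLASS[res]
    idx <- (cls[-length(cls)] - 1L) * 7L + cls[-1L]
    as.numeric(tabulate(idx, nbins = 49L)) / (length(res) - 1L)
}

.fSequenceProperties <- function(res) {
    n <- length(res)
    cnt <- table(factor(res, levels = .AA))
    mw <- (sum(.MASS[res]) + 18.02) / 1000          # kDa
    charge <- cnt[["K"]] + cnt[["R"]] - cnt[["D"]] - cnt[["E"]]
    ai <- 100 * (cnt[["A"]] + 2.9 * cnt[["V"]] +
                 3.9 * (cnt[["I"]] + cnt[["L"]])) / n
    c(n, log10(n), mw, mw * 1000 / n, charge, charge / n,
      (cnt[["K"]] + cnt[["R"]] + cnt[["H"]]) / n,
      (cnt[["D"]] + cnt[["E"]]) / n,
      (cnt[["F"]] + cnt[["W"]] + cnt[["Y"]]) / n,
      ai, mean(.KD[res]), cnt[["C"]] / n)
}

.PCCLASSES <- list(tiny = c("A","C","G","S","T"),
                   small = c("A","C","D","G","N","P","S","T","V"),
                   aliphatic = c("A","I","L","V"),
                   aromatic = c("F","H","W","Y"),
                   nonpolar = c("A","C","F","G","I","L","M","P","V","W","Y"),
                   polar = c("D","E","H","K","N","Q","R","S","T","Y"),
                   charged = c("D","E","H","K","R"),
                   basic = c("H","K","R"),
                   acidic = c("D","E"),
                   hydrophobic = c("A","C","F","I","L","M","V"))

.fPhysicochemical <- function(res) {
    n <- length(res)
    vapply(.PCCLASSES, function(s) sum(res %in% s) / n, numeric(1),
           USE.NAMES = FALSE)
}

.fSecondaryStructure <- function(res) {
    n <- length(res)
    ph <- .smooth(.CFH[res], .featOpts$ssWindow)
    ps <- .smooth(.CFS[res], .featOpts$ssWindow)
    state <- ifelse(ph > ps & ph > 1, "H", ifelse(ps >= ph & ps > 1, "E", "C"))
    fr <- vapply(c("H","E","C"), function(s) mean(state == s), numeric(1))
    lr <- vapply(c("H","E","C"), function(s) .longestRun(state == s) / n,
                 numeric(1))
    sg <- vapply(c("H","E","C"),
                 function(s) .perHundred(nrow(.runs(state == s)), n),
                 numeric(1))
    half <- state[seq_len(ceiling(n / 2))]
    nh <- vapply(c("H","E","C"), function(s) mean(half == s), numeric(1))
    ent <- .shannon(table(factor(state, levels = c("H","E","C"))))
    c(fr, lr, sg, nh, mean(ph), mean(ps), ent)
}

## sliding hydropathy rule: a residue belongs to a putative transmembrane
## helix when it is covered by a window (length tmWindow) whose mean
## Kyte-Doolittle hydropathy reaches tmCutoff; maximal covered runs are
## counted as helices.
.fTransmembrane <- function(res) {
    n <- length(res); w <- .featOpts$tmWindow
    kd <- .KD[res]
    wm <- .winMeans(kd, w)
    covered <- rep(FALSE, n)
    if (n >= w) {
        hits <- which(wm >= .featOpts$tmCutoff)
        for (s in hits) covered[s:(s + w - 1L)] <- TRUE
    } else if (mean(kd) >= .featOpts$tmCutoff) covered[] <- TRUE
    rn <- .runs(covered)
    count <- nrow(rn)
    firstPos <- if (count) rn$start[[1L]] / n else 0
    c(count, mean(covered), max(wm), mean(kd), firstPos,
      if (count) max(rn$len) / n else 0,
      if (n >= w) mean(wm >= .featOpts$tmCutoff) else as.numeric(covered[1L]),
      as.numeric(count > 0))
}

.fDisorder <- function(res) {
    n <- length(res)
    p <- .TOPIDP[res]
    sm <- .smooth(p, .featOpts$disWindow)
    dis <- sm > 0
    rn <- .runs(dis)
    nt <- seq_len(min(30L, n)); ct <- seq.int(max(1L, n - 29L), n)
    chargedDis <- if (any(dis)) mean(res[dis] %in% c("D","E","K","R")) else 0
    c(mean(dis), if (nrow(rn)) max(rn$len) / n else 0,
      .perHundred(nrow(rn), n), mean(dis[nt]), mean(dis[ct]),
      mean(p), max(sm), min(sm),
      as.numeric(nrow(rn) > 0 && max(rn$len) >= 30L), chargedDis)
}

## N-terminal heuristic: positively charged n-region followed by a
## hydrophobic h-region, with small residues near a putative cleavage site.
.fSignalPeptide <- function(res) {
    n <- length(res)
    first6 <- res[seq_len(min(6L, n))]
    nPos <- sum(first6 %in% c("K","R"))
    nterm <- res[seq_len(min(30L, n))]
    hydRun <- .longestRun(.KD[nterm] >= 1.5)
    hyd40 <- .longestRun(.KD[res[seq_len(min(40L, n))]] >= 1.5)
    small <- c("A","G","S","C","T")
    cleave <- 0
    for (p in 12:min(35L, n))
        if (p >= 3L)
            cleave <- max(cleave,
                          (res[p - 1L] %in% small) / 2 +
                          (res[p - 3L] %in% small) / 2)
    ind <- as.numeric(nPos >= 1 && hydRun >= 7)
    c(ind, mean(.KD[res[seq_len(min(20L, n))]]), hyd40, nPos, cleave)
}

.fLowComplexity <- function(res) {
    n <- length(res); w <- .featOpts$lcWindow
    ent <- if (n >= w) {
        vapply(seq_len(n - w + 1L), function(s)
            .shannon(table(res[s:(s + w - 1L)])), numeric(1))
    } else .shannon(table(res))
    covered <- rep(FALSE, n)
    if (n >= w) {
        for (s in which(ent < .featOpts$lcCutoff))
            covered[s:(s + w - 1L)] <- TRUE
    } else covered[] <- ent < .featOpts$lcCutoff
    c(mean(covered), .longestRun(covered) / n, min(ent),
      .shannon(table(res)),
      max(rle(res)$lengths) / n)
}

.countMotif <- function(seq, pattern) {
    hits <- gregexpr(pattern, seq, perl = TRUE)[[1L]]
    sum(hits > 0L)
}

.fGlycosylation <- function(res) {
    n <- length(res); seq <- paste(res, collapse = "")
    nglyc <- .countMotif(seq, "(?=N[^P][ST])")
    st <- res %in% c("S","T")
    dens <- max(.winMeans(as.numeric(st), min(10L, n)))
    c(.perHundred(nglyc, n), as.numeric(nglyc > 0), mean(st), dens)
}

.fPhosphorylation <- function(res) {
    n <- length(res); seq <- paste(res, collapse = "")
    sty <- res %in% c("S","T","Y")
    c(mean(res == "S"), mean(res == "T"), mean(res == "Y"), mean(sty),
      .perHundred(.countMotif(seq, "(?=[RK][RK].[ST])"), n),
      .perHundred(.countMotif(seq, "(?=[ST]..[DE])"), n),
      .perHundred(.countMotif(seq, "(?=[ST]P)"), n),
      max(.winMeans(as.numeric(sty), min(10L, n))))
}

## heptad periodicity: best over the 7 frames of the fraction of a/d
## positions occupied by hydrophobic residues within a 28-residue window
.fCoiledCoil <- function(res) {
    n <- length(res); w <- .featOpts$ccWindow
    hyd <- res %in% c("L","I","V","M","F","A")
    if (n < w) {
        sc <- 0; covered <- rep(FALSE, n)
    } else {
        nw <- n - w + 1L
        sc <- numeric(nw)
        pos <- seq_len(w)
        for (s in seq_len(nw)) {
            win <- hyd[s:(s + w - 1L)]
            best <- 0
            for (f in 0:6) {
                ad <- win[(pos - 1L) %% 7L == f | (pos - 1L) %% 7L == (f + 3L) %% 7L]
                best <- max(best, mean(ad))
            }
            sc[s] <- best
        }
        covered <- rep(FALSE, n)
        for (s in which(sc >= 0.75)) covered[s:(s + w - 1L)] <- TRUE
    }
    c(max(sc), mean(covered), as.numeric(any(covered)),
      .longestRun(covered) / n)
}

.muWindow <- function(h, deltaDeg) {
    w <- length(h); ang <- (seq_len(w) - 1L) * deltaDeg * pi / 180
    sqrt(sum(h * sin(ang))^2 + sum(h * cos(ang))^2) / w
}

.fHydrophobicMoment <- function(res) {
    n <- length(res); w <- min(.featOpts$hmWindow, n)
    h <- .EISEN[res]
    nw <- n - w + 1L
    muH <- muS <- wh <- numeric(nw)
    for (s in seq_len(nw)) {
        win <- h[s:(s + w - 1L)]
        muH[s] <- .muWindow(win, 100); muS[s] <- .muWindow(win, 160)
        wh[s] <- mean(win)
    }
    c(mean(muH), max(muH), mean(muS), max(muS), mean(muH > 0.25),
      mean(h), max(wh), max(muH - abs(wh)))
}

.ACSCALES <- list(hydropathy = .KD, disorder = .TOPIDP, flexibility = .FLEX,
                  polarity = .POLAR, volume = .VOL)

.fAutocorrelation <- function(res) {
    n <- length(res)
    out <- numeric(100L)
    i <- 0L
    for (sc in .ACSCALES) {
        z <- (sc - mean(sc)) / stats::sd(sc)
        x <- z[res]
        for (d in 1:20) {
            i <- i + 1L
            out[i] <- if (n - d >= 1L)
                sum(x[seq_len(n - d)] * x[(d + 1L):n]) / (n - d) else 0
        }
    }
    out
}

.EXTRACTORS <- list(
    composition = .fComposition,
    dipeptides = .fDipeptides,
    sequence_properties = .fSequenceProperties,
    physicochemical = .fPhysicochemical,
    secondary_structure = .fSecondaryStructure,
    transmembrane = .fTransmembrane,
    disorder = .fDisorder,
    signal_peptide = .fSignalPeptide,
    low_complexity = .fLowComplexity,
    glycosylation = .fGlycosylation,
    phosphorylation = .fPhosphorylation,
    coiled_coil = .fCoiledCoil,
    hydrophobic_moment = .fHydrophobicMoment,
    autocorrelation = .fAutocorrelation)

.DEFAULT_SIZES <- c(composition = 20L, dipeptides = 49L,
                    sequence_properties = 12L, physicochemical = 10L,
                    secondary_structure = 15L, transmembrane = 8L,
                    disorder = 10L, signal_peptide = 5L,
                    low_complexity = 5L, glycosylation = 4L,
                    phosphorylation = 8L, coiled_coil = 4L,
                    hydrophobic_moment = 8L, autocorrelation = 100L)

#' Default feature registry: 14 groups, 258 scalars
#'
#' The registry describing how a sequence is encoded: amino-acid
#' composition (20), reduced-alphabet dipeptide composition (49), global
#' sequence properties (12), physicochemical class fractions (10),
#' propensity-based secondary-structure summaries (15), sliding-window
#' transmembrane-helix summaries (8), intrinsic-disorder summaries (10),
#' N-terminal signal-peptide heuristics (5), low-complexity summaries (5),
#' glycosylation motifs (4), phosphorylation motifs (8), coiled-coil
#' heptad scores (4), hydrophobic-moment summaries (8) and
#' property-autocorrelation profiles (100).
#'
#' The two composition-type groups sum to one over their scalars.  All
#' extractors are deterministic, alignment-free approximations; use
#' \code{\link{registerExternalGroup}} to substitute values from dedicated
#' structure predictors for any group.
#'
#' @return a \linkS4class{FeatureRegistry}.
#' @examples
#' reg <- defaultRegistry()
#' totalDim(reg)   # 258
#' @export
defaultRegistry <- function() {
    new("FeatureRegistry",
        groups = data.frame(name = names(.DEFAULT_SIZES),
                            size = unname(.DEFAULT_SIZES),
                            compositional = names(.DEFAULT_SIZES) %in%
                                c("composition", "dipeptides")),
        external = list())
}

## validate and split a sequence into residues
.residues <- function(seq) {
    seq <- toupper(as.character(seq))
    res <- strsplit(seq, "", fixed = TRUE)[[1L]]
    bad <- which(!(res %in% .AA))
    if (length(bad))
        stop("nonstandard residue '", res[bad[[1L]]], "' at position ",
             bad[[1L]])
    if (length(res) < 15L)
        stop("sequence length ", length(res), " below minimum of 15")
    res
}

#' Extract the feature vector of one sequence
#'
#' Encodes an amino-acid sequence (standard 20-letter alphabet, length at
#' least 15) into the named feature groups of the registry.  Groups with a
#' registered external table are looked up by sequence id instead of being
#' computed.
#'
#' @param seq character or \code{Biostrings::AAString}; one sequence.
#' @param registry a \linkS4class{FeatureRegistry}.
#' @param id sequence identifier (used for external lookups).
#' @return a \linkS4class{FeatureVector}.
#' @examples
#' v <- extractFeatures(strrep("A", 20), defaultRegistry(), id = "p1")
#' sum(featureValues(v)[paste0("composition.", 1:20)])  # 1
#' @export
extractFeatures <- function(seq, registry = defaultRegistry(), id = "seq") {
    stopifnot(is(registry, "FeatureRegistry"))
    res <- .residues(seq)
    g <- registry@groups
    vals <- vector("list", nrow(g)); names(vals) <- g$name
    for (i in seq_len(nrow(g))) {
        nm <- g$name[[i]]; k <- g$size[[i]]
        if (!is.null(registry@external[[nm]])) {
            tab <- registry@external[[nm]]
            if (!(id %in% rownames(tab)))
                stop("external group '", nm, "': no values for protein '",
                     id, "'")
            v <- as.numeric(tab[id, ])
        } else {
            fn <- .EXTRACTORS[[nm]]
            if (is.null(fn))
                stop("no built-in extractor for group '", nm,
                     "'; register an external table")
            v <- as.numeric(fn(res))
        }
        if (length(v) != k)
            stop("group '", nm, "' produced ", length(v),
                 " scalars, expected ", k)
        names(v) <- paste0(nm, ".", seq_len(k))
        vals[[i]] <- v
    }
    new("FeatureVector", id = as.character(id), values = vals)
}

#' Replace a group's extractor with a lookup table
#'
#' Substitutes externally computed values (for example the output of a
#' dedicated secondary-structure, disorder or transmembrane predictor) for
#' one feature group.  At extraction time the group is filled from the
#' table by sequence id; every encoded protein must appear in it.
#'
#' @param registry a \linkS4class{FeatureRegistry}.
#' @param name group name to replace.
#' @param valuesByProtein matrix or data.frame with protein ids as row
#'   names and exactly the group's scalar count as columns.
#' @return the modified \linkS4class{FeatureRegistry}.
#' @export
registerExternalGroup <- function(registry, name, valuesByProtein) {
    stopifnot(is(registry, "FeatureRegistry"))
    g <- registry@groups
    if (!(name %in% g$name)) stop("unknown feature group '", name, "'")
    tab <- as.matrix(valuesByProtein)
    k <- g$size[g$name == name]
    if (ncol(tab) != k)
        stop("external table for '", name, "' has ", ncol(tab),
             " columns, expected ", k)
    if (is.null(rownames(tab)))
        stop("external table must have protein ids as row names")
    registry@external[[name]] <- tab
    validObject(registry)
    registry
}

#' Restrict a feature vector to a subset of groups
#'
#' Used by the training loop to realise backward elimination of feature
#' groups.  Keeping all groups is the identity; keeping none yields an
#' empty vector, which is invalid as training input.
#'
#' @param vec a \linkS4class{FeatureVector}.
#' @param keep character vector of group names to retain.
#' @return a \linkS4class{FeatureVector} restricted to \code{keep}.
#' @export
maskGroups <- function(vec, keep) {
    stopifnot(is(vec, "FeatureVector"))
    bad <- setdiff(keep, names(vec@values))
    if (length(bad))
        stop("unknown feature group(s): ", paste(bad, collapse = ", "))
    new("FeatureVector", id = vec@id,
        values = vec@values[names(vec@values) %in% keep])
}

#' Encode many sequences into a feature matrix
#'
#' @param seqs named character vector or \code{Biostrings::AAStringSet}.
#' @param registry a \linkS4class{FeatureRegistry}.
#' @return numeric matrix, rows = sequences (row names = ids), columns
#'   named \code{group.index}.
#' @export
featureMatrix <- function(seqs, registry = defaultRegistry()) {
    ids <- names(seqs)
    if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
    rows <- lapply(seq_along(seqs), function(i)
        featureValues(extractFeatures(seqs[[i]], registry, id = ids[[i]])))
    mat <- do.call(rbind, rows)
    rownames(mat) <- ids
    mat
}

## select the columns of a feature matrix belonging to a set of groups
.groupColumns <- function(featNames, keep) {
    grp <- sub("\\.[0-9]+$", "", featNames)
    featNames[grp %in% keep]
}

#' Write a feature table to TSV
#' @param mat feature matrix from \code{\link{featureMatrix}}.
#' @param path file path; header row is \code{id} + column names.
#' @return invisibly, the path.
#' @export
writeFeatureTable <- function(mat, path) {
    df <- data.frame(id = rownames(mat), mat, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a feature table written by \code{\link{writeFeatureTable}}
#' @param path file path.
#' @return numeric matrix with protein ids as row names.
#' @export
readFeatureTable <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE)
    mat <- as.matrix(df[, -1L, drop = FALSE])
    rownames(mat) <- df$id
    mat
}

## ---- accessors & show ----

#' @describeIn groupNames method for FeatureRegistry
setMethod("groupNames", "FeatureRegistry", function(x) x@groups$name)
#' @describeIn groupNames method for FeatureVector
setMethod("groupNames", "FeatureVector", function(x) names(x@values))
#' @describeIn groupSizes method for FeatureRegistry
setMethod("groupSizes", "FeatureRegistry",
          function(x) stats::setNames(as.integer(x@groups$size), x@groups$name))
#' @describeIn totalDim method for FeatureRegistry
setMethod("totalDim", "FeatureRegistry",
          function(x) sum(as.integer(x@groups$size)))
#' @describeIn featureValues method for FeatureVector
setMethod("featureValues", "FeatureVector",
          function(x) unlist(unname(x@values)))

setMethod("show", "FeatureRegistry", function(object) {
    cat("FeatureRegistry:", nrow(object@groups), "groups,",
        totalDim(object), "scalars\n")
    ext <- names(object@external)
    if (length(ext)) cat("  external:", paste(ext, collapse = ", "), "\n")
})

setMethod("show", "FeatureVector", function(object) {
    cat("FeatureVector '", object@id, "': ", length(object@values),
        " groups, ", length(featureValues(object)), " scalars\n", sep = "")
})
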