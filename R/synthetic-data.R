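#' Specify a planted transposon family
#'
#' Describes one family for the genome simulator: its TIR seed, TSD rules,
#' size, internal sequence length, per-TIR divergence (edits applied to each
#' planted TIR copy), optionally a captured reference fragment (which makes
#' the family's members classifiable as pack or autonomous), and the fraction
#' of members placed within 100 kb of a family mate in the same orientation.
#'
#' @param superfamily family label (also used as the query superfamily).
#' @param tirSeed TIR seed planted at both element ends (inward-facing).
#' @param tsdLength TSD length in bp (ignored when `tsdMotif` given).
#' @param tsdMotif fixed TSD motif, e.g. `"TA"`.
#' @param nMembers number of family members.
#' @param internalLength length of the family's internal consensus in bp.
#' @param tirDivergence exact number of edits applied per planted TIR copy.
#'   Edits fall on interior seed positions so that the terminal base flanking
#'   the TSD stays intact -- a planted element always carries a verifiable,
#'   flush TSD, which is what "compliant" means for recovery guarantees.
#' @param tsdDivergence substitutions applied to the 3' TSD copy.
#' @param capturedSource `"none"`, `"cds"` or `"transposase"`: reference set
#'   a captured fragment is copied from.
#' @param capturedLength captured fragment length in bp.
#' @param hopFraction fraction of members placed within 100 kb of a family
#'   mate, same orientation (local hopping).
#' @param revFraction fraction of members inserted reverse-complemented
#'   (rounded to a deterministic count).
#' @return a `FamilySpec` list.
#' @export
familySpec <- function(superfamily, tirSeed, tsdLength = NULL,
                       tsdMotif = NA_character_, nMembers = 10,
                       internalLength = 600, tirDivergence = 0,
                       tsdDivergence = 0,
                       capturedSource = c("none", "cds", "transposase"),
                       capturedLength = 0, hopFraction = 0,
                       revFraction = 0.25) {
    capturedSource <- match.arg(capturedSource)
    if (is.null(tsdLength)) {
        if (is.na(tsdMotif)) stop("either tsdLength or tsdMotif must be given")
        tsdLength <- nchar(tsdMotif)
    }
    if (nchar(tirSeed) < 8L) stop("tirSeed should be at least 8 nt")
    if (tirDivergence >= nchar(tirSeed) - 2L)
        stop("tirDivergence too large for this seed")
    if (capturedSource != "none" && capturedLength < 50L)
        stop("captured fragments shorter than 50 bp are not classifiable")
    structure(list(
        superfamily = superfamily, tirSeed = toupper(tirSeed),
        tsdLength = as.integer(tsdLength), tsdMotif = toupper(tsdMotif),
        nMembers = as.integer(nMembers),
        internalLength = as.integer(internalLength),
        tirDivergence = as.integer(tirDivergence),
        tsdDivergence = as.integer(tsdDivergence),
        capturedSource = capturedSource,
        capturedLength = as.integer(capturedLength),
        hopFraction = hopFraction, revFraction = revFraction
    ), class = "FamilySpec")
}

#' Default family set of the simulator
#'
#' Six families mirroring the main Class II superfamilies with TIRs: CACTA
#' and MULE-like families carrying transposase fragments (autonomous truth),
#' hAT and PIF-like families carrying short coding-sequence fragments
#' (Pack-TYPE truth), and Mariner/Harbinger-like families with no captured
#' DNA (non-Pack truth, MITE-like). TSD conventions follow the superfamilies:
#' 8 nt for hAT, 5 nt for CACTA, the "TA" motif for Mariner and "TTA"/"TAA"
#' for the Harbinger-PIF group.
#'
#' @return list of [familySpec()] objects.
#' @export
defaultFamilies <- function() {
    list(
        familySpec("CACTA", "CACTACAA", tsdLength = 5, nMembers = 10,
                   internalLength = 1050, tirDivergence = 0,
                   capturedSource = "transposase", capturedLength = 350,
                   revFraction = 0.2),
        familySpec("MULE", "GGGAATGGCCAAGTT", tsdLength = 9, nMembers = 10,
                   internalLength = 1800, tirDivergence = 2,
                   capturedSource = "transposase", capturedLength = 400,
                   revFraction = 0.3),
        familySpec("hAT", "CAGGGATGAAA", tsdLength = 8, nMembers = 10,
                   internalLength = 800, tirDivergence = 1,
                   capturedSource = "cds", capturedLength = 180,
                   revFraction = 0.25),
        familySpec("PIF", "GGCCAGTCACAATGG", tsdMotif = "TTA", nMembers = 10,
                   internalLength = 600, tirDivergence = 2,
                   capturedSource = "cds", capturedLength = 120,
                   revFraction = 0.25),
        familySpec("Mariner", "CTCCCTCCGT", tsdMotif = "TA", nMembers = 10,
                   internalLength = 450, tirDivergence = 0,
                   revFraction = 0.3),
        familySpec("Harbinger", "GGGCGTGTTCGGT", tsdMotif = "TAA",
                   nMembers = 10, internalLength = 380, tirDivergence = 1,
                   revFraction = 0.2)
    )
}

#' Simulation configuration
#'
#' The study conditions for hermetic benchmarking: an i.i.d. background
#' genome carrying planted inward-TIR elements with TSDs (optionally with
#' captured gene fragments), outward-TIR decoys, singleton insertions and
#' N-rich elements. Identical configuration and seed reproduce the genome
#' byte for byte.
#'
#' @param seed mandatory RNG seed (integer).
#' @param genomeLength background length in bp (default 1e6).
#' @param gcContent background GC fraction (default 0.42, plant-like).
#' @param families list of [familySpec()] (default [defaultFamilies()]).
#' @param nOutwardDecoys elements with swapped (outward-facing) TIRs,
#'   assigned round-robin across families (default 20).
#' @param nSingletons single-copy insertions carrying a family's TIRs but a
#'   unique internal sequence (default 5); removed by singleton filtering.
#' @param nNRich family-derived elements whose internal sequence is 15%
#'   N (default 5); removed by the N-content filter.
#' @param decoyDivergenceOffset extra TIR edits applied to decoys on top of
#'   their family's divergence (default 0). The graded-divergence series uses
#'   a positive offset to emulate chance outward configurations that only
#'   enter at permissive budgets.
#' @return a `SimulationConfig` list.
#' @export
simulationConfig <- function(seed, genomeLength = 1e6, gcContent = 0.42,
                             families = defaultFamilies(),
                             nOutwardDecoys = 20, nSingletons = 5,
                             nNRich = 5, decoyDivergenceOffset = 0) {
    if (missing(seed)) stop("seed is mandatory")
    stopifnot(length(families) >= 1L, gcContent > 0, gcContent < 1)
    structure(list(
        seed = as.integer(seed), genomeLength = as.integer(genomeLength),
        gcContent = gcContent, families = families,
        nOutwardDecoys = as.integer(nOutwardDecoys),
        nSingletons = as.integer(nSingletons), nNRich = as.integer(nNRich),
        decoyDivergenceOffset = as.integer(decoyDivergenceOffset)
    ), class = "SimulationConfig")
}

#' Base configuration for the graded-divergence benchmark
#'
#' A smaller genome (250 kb) with three fragment-free families of five
#' members and four outward decoys, used by [gradeDivergenceSeries()] and
#' [rocSweep()]. Seeds are 15 nt so TIR budgets up to the sweep maximum stay
#' meaningful; TSDs are 9 nt (MULE-like, as in genuine recovery benchmarks)
#' and carry one substitution, matching a sweep run at a fixed TSD budget
#' of 2.
#'
#' @param seed RNG seed.
#' @return a `SimulationConfig`.
#' @export
benchmarkConfig <- function(seed) {
    fams <- list(
        familySpec("SimA", "GATTCGCAGGCCTAA", tsdLength = 9, nMembers = 5,
                   internalLength = 500, tsdDivergence = 1, revFraction = 0.2),
        familySpec("SimB", "CCATGGTGCGTTACC", tsdLength = 9, nMembers = 5,
                   internalLength = 650, tsdDivergence = 1, revFraction = 0.2),
        familySpec("SimC", "TGGCAATCGGAGCTT", tsdLength = 9, nMembers = 5,
                   internalLength = 800, tsdDivergence = 1, revFraction = 0.2)
    )
    simulationConfig(seed, genomeLength = 250000, families = fams,
                     nOutwardDecoys = 4, nSingletons = 0, nNRich = 0)
}

.DNA <- c("A", "C", "G", "T")

.randomDna <- function(n, gc) {
    if (n == 0L) return("")
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    paste(sample(.DNA, n, replace = TRUE, prob = p), collapse = "")
}

# Apply exactly n edits (sub/ins/del, uniform) at interior positions of a
# seed, validated to land at the requested Levenshtein distance.
.applyEdits <- function(seq, n) {
    if (n == 0L) return(seq)
    chars0 <- strsplit(seq, "")[[1]]
    for (attempt in seq_len(200)) {
        chars <- chars0
        for (e in seq_len(n)) {
            L <- length(chars)
            pos <- sample(2:(L - 1L), 1)
            op <- sample(c("sub", "ins", "del"), 1)
            if (op == "sub") {
                chars[pos] <- sample(setdiff(.DNA, chars[pos]), 1)
            } else if (op == "ins") {
                chars <- append(chars, sample(.DNA, 1), after = pos)
            } else {
                chars <- chars[-pos]
            }
        }
        out <- paste(chars, collapse = "")
        if (levDist(out, seq) == n) return(out)
    }
    stop("could not realise the requested TIR divergence")
}

# Neutral sequence aging: ~rate substitutions plus sparse 1 bp indels.
.mutate <- function(seq, subRate = 0.02, indelRate = 0.002) {
    chars <- strsplit(seq, "")[[1]]
    L <- length(chars)
    nSub <- stats::rbinom(1, L, subRate)
    if (nSub > 0) {
        pos <- sample.int(L, nSub)
        chars[pos] <- vapply(chars[pos],
                             function(b) sample(setdiff(.DNA, b), 1), "")
    }
    nInd <- stats::rbinom(1, L, indelRate)
    for (i in seq_len(nInd)) {
        pos <- sample.int(length(chars), 1)
        if (stats::runif(1) < 0.5 && length(chars) > 10L) {
            chars <- chars[-pos]
        } else {
            chars <- append(chars, sample(.DNA, 1), after = pos)
        }
    }
    paste(chars, collapse = "")
}

.sampleTsd <- function(fam, gc) {
    if (!is.na(fam$tsdMotif)) fam$tsdMotif else .randomDna(fam$tsdLength, gc)
}

.divergeTsd <- function(tsd, n) {
    if (n == 0L) return(tsd)
    chars <- strsplit(tsd, "")[[1]]
    pos <- sample.int(length(chars), min(n, length(chars)))
    chars[pos] <- vapply(chars[pos], function(b) sample(setdiff(.DNA, b), 1), "")
    paste(chars, collapse = "")
}

# Sequentially place units under: 100 bp padding between any two units,
# a minimum gap between units of the same family (so no spurious TIR pair
# spanning two insertions can fall inside the width window), and hop mates
# anchored 16-90 kb from their partner.
.placeUnits <- function(lens, fam, hopAnchor, L, sameGap = 15200L,
                        pad = 100L, margin = 200L) {
    n <- length(lens)
    starts <- rep(NA_integer_, n)
    ends <- rep(NA_integer_, n)
    okAt <- function(i, s) {
        e <- s + lens[i] - 1L
        if (s < margin || e > L - margin) return(FALSE)
        placed <- which(!is.na(starts))
        if (!length(placed)) return(TRUE)
        if (any(s <= ends[placed] + pad & e >= starts[placed] - pad))
            return(FALSE)
        same <- placed[fam[placed] == fam[i]]
        if (length(same) &&
            any(s <= ends[same] + sameGap & e >= starts[same] - sameGap))
            return(FALSE)
        TRUE
    }
    ord <- c(which(is.na(hopAnchor)), which(!is.na(hopAnchor)))
    for (i in ord) {
        done <- FALSE
        for (try in seq_len(2000)) {
            if (is.na(hopAnchor[i])) {
                s <- sample.int(L - lens[i] - 2L * margin, 1) + margin
            } else {
                a <- hopAnchor[i]
                gap <- sample.int(90000L - sameGap - 500L, 1) + sameGap + 500L
                s <- if (stats::runif(1) < 0.5) ends[a] + gap + 1L
                     else starts[a] - gap - lens[i]
                if (is.na(s) || s < 1L) next
            }
            if (okAt(i, s)) {
                starts[i] <- s
                ends[i] <- s + lens[i] - 1L
                done <- TRUE
                break
            }
        }
        if (!done) stop("infeasible packing: could not place all units; ",
                        "reduce element counts or enlarge the genome")
    }
    data.frame(start = starts, end = ends)
}

#' Simulate a genome with planted ground truth
#'
#' Builds an i.i.d. background genome and plants, per family: members (TSD +
#' edited TIR + internal sequence derived from a family consensus, optionally
#' containing a captured reference fragment + inverted edited TIR + TSD
#' copy), outward-facing decoys (the same construction with the TIR
#' orientations swapped), singleton insertions and N-rich elements. The
#' output bundles the genome, a truth annotation, TIR queries matching the
#' planted families, and the synthetic CDS / transposase reference sets.
#'
#' @param config a [simulationConfig()].
#' @return a [PackSimulation-class].
#' @examples
#' sim <- simulateGenome(simulationConfig(1, genomeLength = 2e5,
#'     families = defaultFamilies()[5], nOutwardDecoys = 2,
#'     nSingletons = 1, nNRich = 1))
#' sim
#' @export
simulateGenome <- function(config) {
    stopifnot(inherits(config, "SimulationConfig"))
    withr::with_seed(config$seed, .simulate(config))
}

.simulate <- function(config) {
    L <- config$genomeLength
    gc <- config$gcContent
    fams <- config$families

    cdsDb <- Biostrings::DNAStringSet(vapply(1:8, function(i) .randomDna(800, gc), ""))
    names(cdsDb) <- paste0("cds_", 1:8)
    tnpDb <- Biostrings::DNAStringSet(vapply(1:4, function(i) .randomDna(600, gc), ""))
    names(tnpDb) <- paste0("tnp_", 1:4)

    # family consensus internals (captured fragment embedded once per family)
    consensus <- lapply(fams, function(f) {
        base <- .randomDna(max(f$internalLength - f$capturedLength, 50L), gc)
        if (f$capturedSource == "none") return(base)
        db <- if (f$capturedSource == "cds") cdsDb else tnpDb
        ref <- db[[sample.int(length(db), 1)]]
        fs <- sample.int(length(ref) - f$capturedLength + 1L, 1)
        frag <- as.character(Biostrings::subseq(ref, fs, fs + f$capturedLength - 1L))
        at <- sample.int(nchar(base) - 1L, 1)
        paste0(substr(base, 1, at), frag, substr(base, at + 1L, nchar(base)))
    })

    units <- list() # per unit: family index, role, body, tsd5, tsd3, orient
    addUnit <- function(fi, role, body, tsd5, tsd3, orient, div) {
        units[[length(units) + 1L]] <<- list(fi = fi, role = role, body = body,
                                             tsd5 = tsd5, tsd3 = tsd3,
                                             orient = orient, div = div)
    }
    memberBody <- function(f, internal, div) {
        paste0(.applyEdits(f$tirSeed, div), internal,
               revComp(.applyEdits(f$tirSeed, div)))
    }

    for (fi in seq_along(fams)) {
        f <- fams[[fi]]
        nRev <- round(f$nMembers * f$revFraction)
        revIdx <- if (nRev > 0) sample.int(f$nMembers, nRev) else integer(0)
        for (m in seq_len(f$nMembers)) {
            body <- memberBody(f, .mutate(consensus[[fi]]), f$tirDivergence)
            orient <- if (m %in% revIdx) "-" else "+"
            if (orient == "-") body <- revComp(body)
            tsd5 <- .sampleTsd(f, gc)
            addUnit(fi, "member", body, tsd5,
                    .divergeTsd(tsd5, f$tsdDivergence), orient,
                    f$tirDivergence)
        }
    }
    # singletons: family TIRs and TSD rules around a unique internal sequence
    for (k in seq_len(config$nSingletons)) {
        fi <- (k - 1L) %% length(fams) + 1L
        f <- fams[[fi]]
        body <- memberBody(f, .randomDna(f$internalLength, gc), f$tirDivergence)
        tsd5 <- .sampleTsd(f, gc)
        addUnit(fi, "singleton", body, tsd5,
                .divergeTsd(tsd5, f$tsdDivergence), "+", f$tirDivergence)
    }
    # N-rich: family-derived, 15% of the internal sequence masked to N
    for (k in seq_len(config$nNRich)) {
        fi <- (k - 1L) %% length(fams) + 1L
        f <- fams[[fi]]
        internal <- strsplit(.mutate(consensus[[fi]]), "")[[1]]
        internal[sample.int(length(internal), round(0.15 * length(internal)))] <- "N"
        body <- memberBody(f, paste(internal, collapse = ""), f$tirDivergence)
        tsd5 <- .sampleTsd(f, gc)
        addUnit(fi, "n_rich", body, tsd5,
                .divergeTsd(tsd5, f$tsdDivergence), "+", f$tirDivergence)
    }
    # outward decoys: swapped TIR orientations, otherwise valid structure
    for (k in seq_len(config$nOutwardDecoys)) {
        fi <- (k - 1L) %% length(fams) + 1L
        f <- fams[[fi]]
        div <- min(f$tirDivergence + config$decoyDivergenceOffset,
                   nchar(f$tirSeed) - 3L)
        body <- paste0(revComp(.applyEdits(f$tirSeed, div)),
                       .randomDna(f$internalLength, gc),
                       .applyEdits(f$tirSeed, div))
        tsd5 <- .sampleTsd(f, gc)
        addUnit(fi, "decoy", body, tsd5, .divergeTsd(tsd5, f$tsdDivergence),
                "+", div)
    }

    famIdx <- vapply(units, function(u) u$fi, integer(1))
    roles <- vapply(units, function(u) u$role, character(1))
    tsdLens <- vapply(units, function(u) nchar(u$tsd5), integer(1))
    unitLens <- vapply(units, function(u) {
        nchar(u$body) + nchar(u$tsd5) + nchar(u$tsd3)
    }, integer(1))
    if (sum(unitLens) >= L / 2)
        stop("infeasible packing: total planted width must stay below half ",
             "the genome length")

    # local hopping: anchor a fraction of each family's members to a mate
    hopAnchor <- rep(NA_integer_, length(units))
    for (fi in seq_along(fams)) {
        f <- fams[[fi]]
        if (f$hopFraction <= 0) next
        mem <- which(famIdx == fi & roles == "member")
        nHop <- min(round(f$nMembers * f$hopFraction), length(mem) - 1L)
        if (nHop < 1L) next
        mates <- sample(mem, nHop)
        free <- setdiff(mem, mates) # anchors are freely placed members
        for (i in mates) {
            anchor <- if (length(free) == 1L) free else sample(free, 1)
            hopAnchor[i] <- anchor
            if (units[[i]]$orient != units[[anchor]]$orient) {
                # hop mates insert in their anchor's orientation
                units[[i]]$body <- revComp(units[[i]]$body)
                units[[i]]$orient <- units[[anchor]]$orient
            }
        }
    }

    pos <- .placeUnits(unitLens, famIdx, hopAnchor, L)

    genome <- .randomDna(L, gc)
    for (i in seq_along(units)) {
        u <- units[[i]]
        substr(genome, pos$start[i], pos$end[i]) <-
            paste0(u$tsd5, u$body, u$tsd3)
    }

    catOf <- function(fi, role) {
        if (role == "decoy") return(NA_character_)
        if (role == "singleton") return("non_pack")
        switch(fams[[fi]]$capturedSource,
               none = "non_pack", cds = "pack", transposase = "autonomous")
    }
    eltStart <- pos$start + tsdLens
    eltEnd <- pos$end - vapply(units, function(u) nchar(u$tsd3), integer(1))
    counter <- integer(length(fams))
    ids <- character(length(units))
    for (i in seq_along(units)) {
        counter[famIdx[i]] <- counter[famIdx[i]] + 1L
        ids[i] <- paste0("sim-", fams[[famIdx[i]]]$superfamily, "-",
                         counter[famIdx[i]])
    }
    truth <- GenomicRanges::GRanges(
        "sim1", IRanges::IRanges(eltStart, eltEnd),
        strand = vapply(units, function(u) u$orient, character(1)),
        element_id = ids,
        family = vapply(famIdx, function(fi) fams[[fi]]$superfamily, ""),
        superfamily = vapply(famIdx, function(fi) fams[[fi]]$superfamily, ""),
        role = roles,
        category = vapply(seq_along(units),
                          function(i) catOf(famIdx[i], roles[i]), ""),
        tir_divergence = vapply(units, function(u) u$div, integer(1)),
        tsd_5 = vapply(units, function(u) u$tsd5, ""),
        tsd_3 = vapply(units, function(u) u$tsd3, ""))
    truth <- truth[order(IRanges::start(truth))]

    queries <- lapply(fams, function(f) {
        TirQuery(f$superfamily, f$tirSeed, tirMismatch = f$tirDivergence,
                 tsdLength = f$tsdLength, tsdMotif = f$tsdMotif,
                 tsdMismatch = f$tsdDivergence)
    })

    new("PackSimulation",
        genome = Biostrings::DNAStringSet(c(sim1 = genome)),
        truth = truth, queries = queries, cdsDb = cdsDb,
        transposaseDb = tnpDb, config = unclass(config))
}

#' Build a graded TIR-divergence series
#'
#' For each budget, a genome is simulated whose families all carry exactly
#' that many edits per TIR; scanning the series at increasing TIR budgets
#' then recovers families whose divergence does not exceed the budget,
#' driving the ROC sweep. Decoys carry `decoyOffset` extra edits, emulating
#' chance outward configurations that only permissive budgets pick up.
#'
#' @param baseConfig a [simulationConfig()], e.g. [benchmarkConfig()].
#' @param budgets ascending integer vector of divergences.
#' @param decoyOffset extra decoy divergence (default 2).
#' @return named list (one entry per budget) of `list(budget, sim)`.
#' @export
gradeDivergenceSeries <- function(baseConfig, budgets, decoyOffset = 2) {
    stopifnot(!is.unsorted(budgets))
    out <- lapply(seq_along(budgets), function(i) {
        b <- budgets[i]
        cfg <- baseConfig
        cfg$families <- lapply(cfg$families, function(f) {
            f$tirDivergence <- as.integer(b)
            f
        })
        cfg$decoyDivergenceOffset <- as.integer(decoyOffset)
        cfg$seed <- as.integer(baseConfig$seed + 1009L * i)
        list(budget = b, sim = simulateGenome(cfg))
    })
    names(out) <- paste0("budget_", budgets)
    out
}
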