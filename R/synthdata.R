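#' @importFrom stats rpois rnbinom rbinom rlnorm rnorm runif
NULL

# deterministic sub-seed per generator so the generators can be called in
# any order yet remain individually reproducible; kept well below 2^31
.subSeed <- function(seed, k) (as.integer(seed) %% 1000000L) * 1000L + k

.geneClasses <- c("maternal", "zygotic", "maternal_zygotic",
                  "germ_plasm_stabilized", "housekeeping")

# relative expression multiplier for one gene class at stage index i of n,
# in one cell type; stage 1 is pre-ZGA
.classProfile <- function(class, cellType, i, n) {
    ramp <- if (n > 1) (i - 1) / (n - 1) else 1
    switch(class,
        maternal = 0.05^ramp,
        zygotic = if (i == 1) 5e-4 else 0.4 + 0.6 * (i - 1) / (n - 1),
        maternal_zygotic = 1 + 0.5 * ramp,
        germ_plasm_stabilized =
            if (cellType == "PGC" || i <= 2) 1 else 0.03^((i - 2) / (n - 2)),
        housekeeping = 1)
}

# per-stage nascent (unspliced) fraction by gene class; transcription of the
# zygotic classes raises intron retention after ZGA
.nascentProfile <- function(class, i) {
    if (i == 1) return(0.02)
    switch(class,
        maternal = 0.02,
        zygotic = 0.35,
        maternal_zygotic = 0.25,
        germ_plasm_stabilized = 0.30,
        housekeeping = 0.15)
}

#' Simulate a staged PGC/soma expression count matrix
#'
#' Draws negative-binomial gene counts for every (cell type, stage,
#' replicate) sample under class-specific temporal profiles: maternal
#' transcripts decay, zygotic transcripts are absent pre-ZGA (expected TPM
#' well below 2 at the first stage) and rise afterwards,
#' germ-plasm-stabilized transcripts decay in soma after ZGA but persist in
#' PGCs, housekeeping genes stay flat. ERCC-like spike-ins with counts
#' proportional to their known concentrations are appended.
#'
#' @param config a [SimConfig-class]
#' @return list with `counts` (a [CountExperiment-class], spike-ins flagged
#'   in `rowData()$spike_in`) and `truth` (list: `geneClass`,
#'   `nascentFraction` genes x stages matrix, `erccConcentration`)
#' @export
simulateExpression <- function(config) {
    methods::validObject(config)
    nG <- config@nGenes
    nS <- length(config@stages)
    withr::with_seed(.subSeed(config@seed, 1L), {
        geneClass <- sample(.geneClasses, nG, replace = TRUE,
                            prob = c(0.35, 0.15, 0.25, 0.05, 0.20))
        base <- rlnorm(nG, meanlog = 3, sdlog = 1)
        lengths <- pmax(round(rlnorm(nG, log(2000), 0.5)), 200)
        genes <- sprintf("gene%04d", seq_len(nG))
        samples <- expand.grid(replicate = seq_len(config@nReplicates),
                               stage = config@stages,
                               cell_type = config@cellTypes,
                               stringsAsFactors = FALSE)
        alpha <- config@nbDispersion
        ercc <- config@erccConcentrations
        erccFracOfLib <- 0.02
        countList <- lapply(seq_len(nrow(samples)), function(j) {
            ct <- samples$cell_type[j]
            si <- match(samples$stage[j], config@stages)
            rel <- vapply(geneClass, .classProfile, numeric(1),
                          cellType = ct, i = si, n = nS)
            mu <- base * rel
            mu <- mu / sum(mu) * config@librarySize * (1 - erccFracOfLib)
            gc <- if (alpha > 0) rnbinom(nG, mu = mu, size = 1 / alpha)
                  else rpois(nG, mu)
            emu <- ercc * config@erccLengths
            emu <- emu / sum(emu) * config@librarySize * erccFracOfLib
            c(gc, rpois(length(ercc), emu))
        })
        counts <- do.call(cbind, countList)
        rownames(counts) <- c(genes, names(ercc))
        nasc <- t(vapply(geneClass, function(cl)
            vapply(seq_len(nS), function(i) .nascentProfile(cl, i),
                   numeric(1)), numeric(nS)))
        dimnames(nasc) <- list(genes, config@stages)
        ce <- CountExperiment(
            counts,
            lengths = c(lengths, config@erccLengths[names(ercc)]),
            cellType = samples$cell_type, stage = samples$stage,
            replicate = samples$replicate,
            rowData = data.frame(
                class = c(geneClass, rep("spike_in", length(ercc))),
                spike_in = c(rep(FALSE, nG), rep(TRUE, length(ercc)))))
        list(counts = ce,
             truth = list(geneClass = stats::setNames(geneClass, genes),
                          nascentFraction = nasc,
                          erccConcentration = ercc))
    })
}

#' Simulate per-intron measurements
#'
#' For every gene, stage and cell type, draws splice-site read counts
#' around the configured coverage and an intronic depth such that the
#' realized IR ratio `D / (max(SS5, SS3) + D)` has expectation equal to the
#' gene's true nascent fraction at that stage (exactly zero depth when the
#' nascent fraction is zero).
#'
#' @param config a [SimConfig-class]
#' @param truth the `truth` component of [simulateExpression()]
#' @param intronsPerGene introns simulated per gene (default 2)
#' @return data.frame with columns `gene`, `intron`, `depth`, `ss5`, `ss3`,
#'   `sample` (sample = `celltype_stage`)
#' @export
simulateIntrons <- function(config, truth, intronsPerGene = 2L) {
    if (is.null(truth$nascentFraction))
        stop("truth from simulateExpression is required")
    nasc <- truth$nascentFraction
    genes <- rownames(nasc)
    withr::with_seed(.subSeed(config@seed, 2L), {
        grid <- expand.grid(intron = seq_len(intronsPerGene),
                            gene = genes, stage = config@stages,
                            cell_type = config@cellTypes,
                            stringsAsFactors = FALSE)
        f <- pmin(nasc[cbind(grid$gene, grid$stage)], 0.9)
        n <- nrow(grid)
        ss5 <- rpois(n, config@intronCoverage)
        ss3 <- rpois(n, config@intronCoverage)
        m <- pmax(ss5, ss3)
        depth <- rpois(n, m * f / (1 - f))
        data.frame(gene = grid$gene,
                   intron = paste0(grid$gene, ".i", grid$intron),
                   depth = depth, ss5 = ss5, ss3 = ss3,
                   sample = paste(grid$cell_type, grid$stage, sep = "_"))
    })
}

#' Simulate ATAC fragment sets with planted open-chromatin elements
#'
#' Places background fragments uniformly over the synthetic genome
#' (including a mitochondrial fraction and a low-MAPQ fraction, both meant
#' to exercise the filters) and enriches the fragment rate at planted
#' elements: `pgc_open` / `soma_open` elements in both replicates of the
#' matching cell type, `shared` elements everywhere, and
#' `irreproducible_noise` elements in a single randomly chosen sample only.
#' A catalogue of synthetic TSS positions is drawn as well; one tenth of the
#' elements are deliberately planted within 500 bp of a TSS so the cascade's
#' proximity filter has work to do.
#'
#' @param config a [SimConfig-class]
#' @return list with `fragments` (named list of data.frames `chrom`,
#'   `start`, `end`, `mapq`, 0-based half-open, one per sample),
#'   `elements` (`GRanges` with `class` column), `tss` (`GRanges`)
#' @export
simulateAtac <- function(config) {
    methods::validObject(config)
    nuclear <- intersect(nuclearChroms(), names(config@chromLengths))
    if (config@nElements * (config@elementWidth + 4000) >
        sum(config@chromLengths[nuclear]))
        stop("nElements exceeds the capacity of the synthetic genome")
    withr::with_seed(.subSeed(config@seed, 3L), {
        lens <- config@chromLengths[nuclear]
        w <- config@elementWidth
        # non-overlapping element placement by rejection
        elChrom <- sample(nuclear, config@nElements, replace = TRUE,
                          prob = lens / sum(lens))
        elStart <- integer(config@nElements)
        placed <- list()
        for (i in seq_len(config@nElements)) {
            repeat {
                s <- sample.int(lens[[elChrom[i]]] - w - 4000L, 1L) + 2000L
                prev <- placed[[elChrom[i]]]
                if (is.null(prev) || all(abs(prev - s) > w + 600L)) break
                elChrom[i] <- sample(nuclear, 1L, prob = lens / sum(lens))
            }
            elStart[i] <- s
            placed[[elChrom[i]]] <- c(placed[[elChrom[i]]], s)
        }
        elClass <- sample(c("pgc_open", "soma_open", "shared",
                            "irreproducible_noise"),
                          config@nElements, replace = TRUE,
                          prob = c(0.3, 0.3, 0.2, 0.2))
        # per-element accessibility strength, shared across samples and
        # replicates: real elements span a wide dynamic range, and this
        # shared variation is exactly what makes replicate peak scores
        # correlated (the signal the IDR model detects)
        elStrength <- rlnorm(config@nElements, 0, 0.6)
        elements <- GenomicRanges::GRanges(
            elChrom, IRanges::IRanges(elStart + 1L, elStart + w),
            class = elClass, strength = elStrength)
        # TSS catalogue; some planted right next to elements
        tssChrom <- sample(nuclear, config@nTss, replace = TRUE,
                           prob = lens / sum(lens))
        tssPos <- vapply(tssChrom, function(cn)
            sample.int(lens[[cn]], 1L), integer(1))
        nearIdx <- sample(config@nElements,
                          max(1L, config@nElements %/% 10L))
        nearPos <- elStart[nearIdx] + w %/% 2L +
            sample(-400:400, length(nearIdx), replace = TRUE)
        tss <- GenomicRanges::GRanges(
            c(tssChrom, elChrom[nearIdx]),
            IRanges::IRanges(c(tssPos, nearPos), width = 1L),
            strand = sample(c("+", "-"),
                            config@nTss + length(nearIdx), replace = TRUE))
        samples <- expand.grid(replicate = seq_len(config@nReplicates),
                               stage = config@atacStages,
                               cell_type = config@cellTypes,
                               stringsAsFactors = FALSE)
        sampleNames <- paste(samples$cell_type, samples$stage,
                             samples$replicate, sep = "_")
        noiseSample <- sample(sampleNames, config@nElements, replace = TRUE)
        genomeSize <- sum(lens)
        bgRate <- config@fragmentsPerSample / genomeSize
        muEl <- bgRate * w * config@atacEnrichment
        allChroms <- c(nuclear, "chrM")
        chromProb <- c((1 - config@mitoFraction) * lens / sum(lens),
                       config@mitoFraction)
        frags <- lapply(seq_len(nrow(samples)), function(j) {
            ct <- samples$cell_type[j]
            nBg <- rpois(1, config@fragmentsPerSample)
            bgChrom <- sample(allChroms, nBg, replace = TRUE,
                              prob = chromProb)
            bgLen <- pmin(pmax(round(rnorm(nBg, 150, 40)), 60L), 500L)
            bgStart <- floor(runif(nBg) *
                (config@chromLengths[bgChrom] - bgLen))
            active <- (elClass == "shared") |
                (elClass == "pgc_open" & ct == "PGC") |
                (elClass == "soma_open" & ct == "soma") |
                (elClass == "irreproducible_noise" &
                     noiseSample == sampleNames[j])
            nEl <- rpois(sum(active), muEl * elStrength[active])
            aChrom <- rep(elChrom[active], nEl)
            aBase <- rep(elStart[active], nEl)
            nA <- length(aChrom)
            aLen <- pmin(pmax(round(rnorm(nA, 150, 40)), 60L), 500L)
            aStart <- aBase + sample.int(w, nA, replace = TRUE) -
                aLen %/% 2L
            aStart <- pmax(aStart, 0L)
            chrom <- c(bgChrom, aChrom)
            start <- c(bgStart, aStart)
            len <- c(bgLen, aLen)
            n <- length(chrom)
            mapq <- ifelse(runif(n) < config@lowMapqFraction,
                           sample(0:9, n, replace = TRUE),
                           sample(20:42, n, replace = TRUE))
            data.frame(chrom = chrom, start = start, end = start + len,
                       mapq = mapq, row.names = NULL)
        })
        names(frags) <- sampleNames
        list(fragments = frags, elements = elements, tss = tss)
    })
}

#' Simulate per-sample CpG methylation tables
#'
#' Regions split into promoter-like (constitutively hypomethylated in both
#' cell types) and enhancer-like (progressively demethylated in somatic
#' cells across stages while staying hypermethylated in PGCs). Per-CpG
#' methylated/unmethylated counts are binomial around the region
#' trajectory; coverage is Poisson around the configured mean, with a small
#' low-coverage fraction to exercise the coverage cutoff.
#'
#' @param config a [SimConfig-class]
#' @return list with `cpgs` (named list of per-sample CpG record
#'   data.frames, unfiltered), `regions` (`GRanges` with `class` column) and
#'   `trajectory` (region x sample matrix of true methylation fractions)
#' @export
simulateMethylation <- function(config) {
    methods::validObject(config)
    nuclear <- intersect(nuclearChroms(), names(config@chromLengths))
    withr::with_seed(.subSeed(config@seed, 4L), {
        lens <- config@chromLengths[nuclear]
        nR <- config@nRegions
        regChrom <- sample(nuclear, nR, replace = TRUE,
                           prob = lens / sum(lens))
        regStart <- vapply(regChrom, function(cn)
            sample.int(lens[[cn]] - 500L, 1L), integer(1))
        regClass <- rep(c("promoter_like", "enhancer_like"), length.out = nR)
        regions <- GenomicRanges::GRanges(
            regChrom, IRanges::IRanges(regStart + 1L, regStart + 500L),
            class = regClass)
        names(regions) <- sprintf("region%03d", seq_len(nR))
        samples <- expand.grid(replicate = seq_len(config@nReplicates),
                               stage = config@stages,
                               cell_type = config@cellTypes,
                               stringsAsFactors = FALSE)
        sampleNames <- paste(samples$cell_type, samples$stage,
                             samples$replicate, sep = "_")
        nS <- length(config@stages)
        traj <- matrix(NA_real_, nR, nrow(samples),
                       dimnames = list(names(regions), sampleNames))
        for (j in seq_len(nrow(samples))) {
            si <- match(samples$stage[j], config@stages)
            somaEnh <- 0.9 - 0.7 * (si - 1) / max(nS - 1, 1)
            traj[, j] <- ifelse(regClass == "promoter_like", 0.08,
                                ifelse(samples$cell_type[j] == "PGC",
                                       0.85, somaEnh))
        }
        cpgOff <- t(vapply(seq_len(nR), function(i)
            sort(sample.int(498L, config@cpgsPerRegion)),
            integer(config@cpgsPerRegion)))
        cpgChrom <- rep(regChrom, each = config@cpgsPerRegion)
        cpgPos <- rep(regStart, each = config@cpgsPerRegion) +
            as.vector(t(cpgOff))
        regIdx <- rep(seq_len(nR), each = config@cpgsPerRegion)
        nC <- length(cpgPos)
        cpgs <- lapply(seq_len(nrow(samples)), function(j) {
            lowCov <- runif(nC) < 0.05
            cov <- ifelse(lowCov, rpois(nC, 3), rpois(nC, config@methCoverage))
            meth <- rbinom(nC, cov, traj[regIdx, j])
            data.frame(chrom = cpgChrom, start = cpgPos, end = cpgPos + 1L,
                       methylated = meth, unmethylated = cov - meth,
                       coverage = cov,
                       percent = ifelse(cov > 0, 100 * meth / cov, 0),
                       sample = sampleNames[j])
        })
        names(cpgs) <- sampleNames
        list(cpgs = cpgs, regions = regions, trajectory = traj)
    })
}

#' Simulate labeled granule/nucleus masks
#'
#' Each synthetic cell is a labeled integer grid with one square nucleus
#' (label 1) and several square granules (labels 2, 3, ...). A
#' condition-dependent fraction of granules is placed flush against a
#' straight nucleus edge (axis-aligned, so the analytic expected contact
#' ratio `side / total granule area` is exact); the rest are kept at least
#' two pixels away from the nucleus (expected ratio 0). The knockdown-like
#' condition has fewer flush granules and larger granules, emulating germ
#' plasm reaggregation away from the nuclear envelope.
#'
#' @param config a [SimConfig-class]
#' @param conditions condition labels (first = control)
#' @param flushProb per-condition probability that a granule touches the
#'   nucleus
#' @param sizeRange per-condition granule side-length ranges (list of
#'   2-vectors)
#' @return list with `cells` (list of [CellGeometry-class]), `expected`
#'   (list of per-granule expected contact ratios, `numeric(0)` for cells
#'   that ended up with no granules) and `condition` (character vector)
#' @export
simulateGranuleMasks <- function(config,
                                 conditions = c("control", "tdrd7_KD"),
                                 flushProb = c(0.7, 0.2),
                                 sizeRange = list(c(3, 6), c(5, 9))) {
    methods::validObject(config)
    withr::with_seed(.subSeed(config@seed, 5L), {
        N <- config@maskSize
        nr0 <- N %/% 3L; nr1 <- 2L * (N %/% 3L)   # nucleus square bounds
        cells <- list(); expected <- list(); condition <- character()
        for (ci in seq_along(conditions)) {
            for (cell in seq_len(config@nCellsPerCondition)) {
                mask <- matrix(0L, N, N)
                mask[nr0:nr1, nr0:nr1] <- 1L
                k <- sample(3:6, 1)
                sizes <- sample(seq(sizeRange[[ci]][1], sizeRange[[ci]][2]),
                                k, replace = TRUE)
                flush <- runif(k) < flushProb[ci]
                label <- 1L
                contacts <- numeric(0)
                areas <- numeric(0)
                for (gi in seq_len(k)) {
                    g <- sizes[gi]
                    ok <- FALSE
                    for (attempt in 1:100) {
                        if (flush[gi]) {
                            side <- sample(4, 1)
                            off <- sample(nr0:(nr1 - g + 1L), 1)
                            rc <- switch(side,
                                c(nr0 - g, off), c(nr1 + 1L, off),
                                c(off, nr0 - g), c(off, nr1 + 1L))
                        } else {
                            rc <- c(sample.int(N - g + 1L, 1),
                                    sample.int(N - g + 1L, 1))
                        }
                        r <- rc[1]; cc <- rc[2]
                        if (r < 1L || cc < 1L || r + g - 1L > N ||
                            cc + g - 1L > N) next
                        # candidate footprint plus a 1-pixel guard ring
                        gr <- max(r - 1L, 1L):min(r + g, N)
                        gc <- max(cc - 1L, 1L):min(cc + g, N)
                        ring <- mask[gr, gc]
                        if (!flush[gi] && any(ring != 0L)) next
                        if (flush[gi] &&
                            any(ring != 0L & ring != 1L)) next
                        if (flush[gi] &&
                            any(mask[r:(r + g - 1L), cc:(cc + g - 1L)] != 0L))
                            next
                        ok <- TRUE
                        break
                    }
                    if (!ok) next
                    label <- label + 1L
                    mask[r:(r + g - 1L), cc:(cc + g - 1L)] <- label
                    contacts <- c(contacts, if (flush[gi]) g else 0)
                    areas <- c(areas, g^2)
                }
                cells[[length(cells) + 1L]] <- cellGeometry(mask)
                expected[[length(expected) + 1L]] <-
                    if (length(areas)) contacts / sum(areas) else numeric(0)
                condition <- c(condition, conditions[ci])
            }
        }
        list(cells = cells, expected = expected, condition = condition)
    })
}
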