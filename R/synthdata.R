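## Synthetic-data generator. Emulates the structure of the study population
## (~1,000 genotyped cows from ~72 herd-date groups, a 50k SNP panel after QC)
## and of PTR-ToF-MS peak tables (right-skewed ppbv intensities with
## near-perfectly correlated isotope satellites), with planted ground truth
## for recovery testing.

#' SimConfig: parameters of the synthetic-data generator
#'
#' @slot nAnimals,nSnps,nTraits integer problem sizes.
#' @slot mafRange numeric length-2, per-SNP minor allele frequency range,
#'   within (0, 0.5].
#' @slot h2 numeric vector of per-trait heritabilities in [0, 1), recycled to
#'   \code{nTraits}.
#' @slot nQtl integer count of large-effect QTLs per trait (0 = pure
#'   polygenic).
#' @slot pleiotropyBlocks list of disjoint integer vectors of trait indices;
#'   traits within a block share QTL positions with correlated effects.
#' @slot qtlFracG fraction of the genetic variance carried by the planted
#'   QTLs (remainder is polygenic background).
#' @slot blockEffectCor correlation of QTL effects between traits of the same
#'   pleiotropy block.
#' @slot qtlMafRange MAF range from which QTL SNPs are drawn.
#' @slot nHerds,nParityClasses,nDimClasses integer numbers of fixed-effect
#'   levels (herd-date, parity class, 30-day days-in-milk class).
#' @slot herdSd,paritySd,dimSd standard deviations of the i.i.d. Gaussian
#'   fixed-effect level values, in phenotype-SD units.
#' @slot isotopeRate fraction of peaks given a correlated isotope satellite.
#' @slot nSubThreshold number of planted all-below-1-ppbv peaks.
#' @slot missingRate genotype missing-call rate.
#' @slot ldRho AR(1) haplotype correlation between adjacent SNPs (0 = linkage
#'   equilibrium, the default).
#' @slot nChrom number of autosomes the panel is spread over.
#' @slot seed integer; fully determines all generator output.
#' @export
setClass("SimConfig",
    slots = c(nAnimals = "integer", nSnps = "integer", nTraits = "integer",
              mafRange = "numeric", h2 = "numeric", nQtl = "integer",
              pleiotropyBlocks = "list", qtlFracG = "numeric",
              blockEffectCor = "numeric", qtlMafRange = "numeric",
              nHerds = "integer", nParityClasses = "integer",
              nDimClasses = "integer", herdSd = "numeric",
              paritySd = "numeric", dimSd = "numeric",
              isotopeRate = "numeric", nSubThreshold = "integer",
              missingRate = "numeric", ldRho = "numeric", nChrom = "integer",
              seed = "integer"))

setValidity("SimConfig", function(object) {
    msg <- character()
    if (object@nAnimals < 2) msg <- c(msg, "nAnimals must be >= 2")
    if (object@nSnps < 1) msg <- c(msg, "nSnps must be >= 1")
    if (any(object@h2 < 0 | object@h2 >= 1))
        msg <- c(msg, "every h2 must lie in [0, 1) (h2 = 1 leaves no residual variance)")
    if (length(object@mafRange) != 2 || any(object@mafRange <= 0) ||
        any(object@mafRange > 0.5) || diff(object@mafRange) < 0)
        msg <- c(msg, "mafRange must be an increasing pair within (0, 0.5]")
    blk <- unlist(object@pleiotropyBlocks)
    if (length(blk)) {
        if (anyDuplicated(blk))
            msg <- c(msg, "pleiotropyBlocks must be disjoint")
        if (any(blk < 1 | blk > object@nTraits))
            msg <- c(msg, "pleiotropyBlocks reference trait indices out of range")
    }
    if (object@missingRate < 0 || object@missingRate >= 1)
        msg <- c(msg, "missingRate must lie in [0, 1)")
    if (object@isotopeRate < 0 || object@isotopeRate > 1)
        msg <- c(msg, "isotopeRate must lie in [0, 1]")
    if (object@blockEffectCor < -1 || object@blockEffectCor > 1)
        msg <- c(msg, "blockEffectCor must lie in [-1, 1]")
    if (object@qtlFracG < 0 || object@qtlFracG > 1)
        msg <- c(msg, "qtlFracG must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Build a simulation configuration
#'
#' Defaults mirror the study design: ~1,000 animals from 72 herd-date groups,
#' a post-QC panel of 37,568 SNPs over 29 autosomes, parity classes 1/2/3/4+,
#' 30-day DIM classes, and a handful of large-effect QTLs (at modest MAF)
#' carrying most of each trait's genetic variance on top of a polygenic
#' background. Fixed-effect magnitudes are not reported by any field source,
#' so herd-date gets the largest spread (0.5 phenotype SD) and parity/DIM
#' smaller ones (0.25).
#'
#' @param nAnimals,nSnps,nTraits problem sizes.
#' @param mafRange per-SNP MAF sampling range.
#' @param h2 per-trait heritability in [0,1), recycled.
#' @param nQtl large-effect QTLs per trait.
#' @param pleiotropyBlocks list of disjoint trait-index vectors sharing QTLs.
#' @param qtlFracG fraction of genetic variance from planted QTLs.
#' @param blockEffectCor within-block QTL-effect correlation.
#' @param qtlMafRange MAF range of QTL SNPs.
#' @param nHerds,nParityClasses,nDimClasses fixed-effect level counts.
#' @param herdSd,paritySd,dimSd fixed-effect level SDs (phenotype-SD units).
#' @param isotopeRate fraction of peaks with an isotope satellite.
#' @param nSubThreshold planted peaks entirely below 1 ppbv.
#' @param missingRate genotype missing-call rate.
#' @param ldRho adjacent-SNP haplotype correlation (0 = linkage equilibrium).
#' @param nChrom number of autosomes.
#' @param seed integer master seed.
#' @return A validated \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(nAnimals = 100, nSnps = 500, nTraits = 4, seed = 7)
#' @export
simConfig <- function(nAnimals = 1011L, nSnps = 37568L, nTraits = 10L,
                      mafRange = c(0.01, 0.5), h2 = 0.15, nQtl = 5L,
                      pleiotropyBlocks = list(), qtlFracG = 0.9,
                      blockEffectCor = 0.98, qtlMafRange = c(0.04, 0.10),
                      nHerds = 72L, nParityClasses = 4L, nDimClasses = 10L,
                      herdSd = 0.5, paritySd = 0.25, dimSd = 0.25,
                      isotopeRate = 0.15, nSubThreshold = 5L,
                      missingRate = 0.01, ldRho = 0, nChrom = 29L,
                      seed = 1L) {
    new("SimConfig", nAnimals = as.integer(nAnimals),
        nSnps = as.integer(nSnps), nTraits = as.integer(nTraits),
        mafRange = mafRange, h2 = rep_len(h2, nTraits),
        nQtl = as.integer(nQtl),
        pleiotropyBlocks = lapply(pleiotropyBlocks, as.integer),
        qtlFracG = qtlFracG, blockEffectCor = blockEffectCor,
        qtlMafRange = qtlMafRange, nHerds = as.integer(nHerds),
        nParityClasses = as.integer(nParityClasses),
        nDimClasses = as.integer(nDimClasses), herdSd = herdSd,
        paritySd = paritySd, dimSd = dimSd, isotopeRate = isotopeRate,
        nSubThreshold = as.integer(nSubThreshold), missingRate = missingRate,
        ldRho = ldRho, nChrom = as.integer(nChrom), seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
    cat(sprintf("SimConfig: %d animals x %d SNPs, %d traits (h2: %s), seed %d\n",
                object@nAnimals, object@nSnps, object@nTraits,
                paste(unique(object@h2), collapse = "/"), object@seed))
})

## Deterministic per-stage child seed, so stages can be rerun in isolation.
childSeed <- function(seed, tag) {
    h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
    as.integer((abs(seed) %% 1000003L) * 2011L + h * 131L) %% 2147483647L
}

#' Simulate a genotype panel
#'
#' Per-SNP allele frequencies are drawn uniformly from \code{mafRange};
#' genotypes are Hardy-Weinberg binomial(2, p) draws (or, with
#' \code{ldRho > 0}, thresholded AR(1) Gaussian haplotypes giving block-LD
#' between adjacent SNPs). Missing calls are planted completely at random at
#' \code{missingRate}. The marker map spreads SNPs evenly over \code{nChrom}
#' autosomes with strictly increasing bp within each chromosome.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @return A \linkS4class{GenotypeData}.
#' @export
simulateGenotypes <- function(cfg) {
    stopifnot(is(cfg, "SimConfig"))
    validObject(cfg)
    set.seed(childSeed(cfg@seed, "genotypes"))
    n <- cfg@nAnimals; m <- cfg@nSnps
    p <- runif(m, cfg@mafRange[1], cfg@mafRange[2])
    if (cfg@ldRho > 0) {
        rho <- cfg@ldRho
        hap <- function() {
            z <- matrix(rnorm(n * m), n, m)
            for (j in seq_len(m)[-1])
                z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * z[, j]
            z
        }
        thr <- qnorm(p)
        d <- (t(t(hap()) < thr) + 0) + (t(t(hap()) < thr) + 0)
    } else {
        d <- matrix(rbinom(n * m, 2L, rep(p, each = n)), n, m)
    }
    storage.mode(d) <- "double"
    if (cfg@missingRate > 0) {
        nmiss <- rbinom(1L, n * m, cfg@missingRate)
        if (nmiss > 0) d[sample.int(n * m, nmiss)] <- NA_real_
    }
    chrom <- sort(rep_len(seq_len(cfg@nChrom), m))
    bp <- unlist(lapply(split(seq_len(m), chrom), function(ix)
        cumsum(sample(1000:60000, length(ix), replace = TRUE))),
        use.names = FALSE)
    mm <- data.frame(id = sprintf("snp%06d", seq_len(m)),
                     chrom = as.character(chrom), bp = bp,
                     a1 = "A", a2 = "B", stringsAsFactors = FALSE)
    GenotypeData(d, mm, sprintf("cow%05d", seq_len(n)))
}

## scale a vector to an exact empirical variance (0 variance target -> zeros)
scaleToVar <- function(x, v) {
    if (v <= 0) return(numeric(length(x)))
    s <- stats::sd(x)
    if (s == 0) return(numeric(length(x)))
    (x - mean(x)) / s * sqrt(v)
}

#' Simulate multi-trait phenotypes with planted ground truth
#'
#' Realises, generatively, the polygenic model used downstream: each trait is
#' the sum of herd-date, parity-class and DIM-class fixed effects, a planted
#' QTL term (dosage times allele-substitution effect), a polygenic term spread
#' over all SNPs, and a Gaussian residual. Component variances are rescaled to
#' hit the target heritability exactly in-sample: the genetic part (QTLs +
#' polygenic) has empirical variance \code{h2} and the residual \code{1 - h2},
#' on a unit total-variance scale. Traits within a pleiotropy block share QTL
#' positions, with effects correlated at \code{blockEffectCor} across block
#' members.
#'
#' @param geno \linkS4class{GenotypeData} from \code{\link{simulateGenotypes}}
#'   with the same config.
#' @param cfg the \linkS4class{SimConfig} used for the genotypes.
#' @return A list with \code{phenotypes} (data.frame: animal, herd_date,
#'   parity, dim_class, then one column per trait) and \code{truth} (list:
#'   qtlPositions, qtlEffects, trueH2, fixedEffectValues, geneticValues).
#' @export
simulatePhenotypes <- function(geno, cfg) {
    stopifnot(is(geno, "GenotypeData"), is(cfg, "SimConfig"))
    if (any(cfg@h2 >= 1)) stop("h2 = 1 is not simulable (zero residual variance)")
    set.seed(childSeed(cfg@seed, "phenotypes"))
    n <- nSamples(geno); m <- nSnps(geno); ntr <- cfg@nTraits
    d <- dosages(geno)
    p <- colMeans(d, na.rm = TRUE) / 2
    dimp <- d
    for (j in which(colSums(is.na(d)) > 0))
        dimp[is.na(d[, j]), j] <- 2 * p[j]
    dc <- sweep(dimp, 2, 2 * p)   # centered, mean-imputed dosages

    ## covariate structure
    herd <- factor(sample.int(cfg@nHerds, n, replace = TRUE))
    parity <- factor(sample.int(cfg@nParityClasses, n, replace = TRUE))
    dimcl <- factor(sample.int(cfg@nDimClasses, n, replace = TRUE))
    fe <- list(herd_date = rnorm(cfg@nHerds, 0, cfg@herdSd),
               parity = rnorm(cfg@nParityClasses, 0, cfg@paritySd),
               dim_class = rnorm(cfg@nDimClasses, 0, cfg@dimSd))
    feVec <- fe$herd_date[herd] + fe$parity[parity] + fe$dim_class[dimcl]

    ## QTL positions: block traits share positions, others draw their own
    maf <- pmin(p, 1 - p)
    pool <- which(maf >= cfg@qtlMafRange[1] & maf <= cfg@qtlMafRange[2])
    if (length(pool) < cfg@nQtl) pool <- order(abs(maf - mean(cfg@qtlMafRange)))[seq_len(max(cfg@nQtl, 1L))]
    blockOf <- integer(ntr)
    for (b in seq_along(cfg@pleiotropyBlocks))
        blockOf[cfg@pleiotropyBlocks[[b]]] <- b
    ## QTL positions are disjoint across blocks (and across singleton traits,
    ## pool permitting), so only planted pleiotropy creates shared signals
    avail <- pool
    drawQtl <- function() {
        take <- min(cfg@nQtl, length(avail))
        if (take < cfg@nQtl && length(pool) >= cfg@nQtl) {
            avail <<- pool
            take <- cfg@nQtl
        }
        q <- if (take > 0) sample(avail, take) else integer(0)
        avail <<- setdiff(avail, q)
        q
    }
    blockQtl <- lapply(seq_along(cfg@pleiotropyBlocks), function(b) drawQtl())
    blockBase <- lapply(blockQtl, function(q) rnorm(length(q)))

    qtlPositions <- vector("list", ntr)
    qtlEffects <- vector("list", ntr)
    G <- matrix(0, n, ntr)        # genetic values
    Y <- matrix(0, n, ntr)
    rho <- cfg@blockEffectCor
    for (t in seq_len(ntr)) {
        h2 <- cfg@h2[t]
        hasQtl <- cfg@nQtl > 0 && length(pool) > 0
        qtlVar <- if (hasQtl) cfg@qtlFracG * h2 else 0
        polyVar <- h2 - qtlVar
        qcomp <- numeric(n); eff <- numeric(0); qpos <- integer(0)
        if (hasQtl && qtlVar > 0) {
            if (blockOf[t] > 0) {
                qpos <- blockQtl[[blockOf[t]]]
                eff <- rho * blockBase[[blockOf[t]]] +
                    sqrt(1 - rho^2) * rnorm(length(qpos))
            } else {
                qpos <- drawQtl()
                eff <- rnorm(length(qpos))
            }
            raw <- dc[, qpos, drop = FALSE] %*% eff
            sc <- if (stats::sd(raw) > 0) sqrt(qtlVar) / stats::sd(raw) else 0
            eff <- eff * sc
            qcomp <- as.numeric(raw) * sc
            qcomp <- qcomp - mean(qcomp)
        }
        gpoly <- if (polyVar > 0)
            scaleToVar(as.numeric(dc %*% rnorm(m, 0, 1 / sqrt(m))), polyVar)
        else numeric(n)
        e <- scaleToVar(rnorm(n), 1 - h2)
        G[, t] <- qcomp + gpoly
        Y[, t] <- feVec + G[, t] + e
        qtlPositions[[t]] <- qpos
        qtlEffects[[t]] <- eff
    }
    traitNames <- sprintf("trait_%02d", seq_len(ntr))
    colnames(Y) <- traitNames; colnames(G) <- traitNames
    phen <- data.frame(animal = sampleIds(geno), herd_date = herd,
                       parity = parity, dim_class = dimcl,
                       stringsAsFactors = FALSE)
    phen <- cbind(phen, as.data.frame(Y))
    truth <- list(qtlPositions = qtlPositions, qtlEffects = qtlEffects,
                  trueH2 = cfg@h2, fixedEffectValues = fe, geneticValues = G)
    list(phenotypes = phen, truth = truth)
}

#' Simulate a PTR-ToF-MS peak matrix from latent trait values
#'
#' Maps each latent trait through an exponential link
#' \code{exp(location + scale * latent)} to a right-skewed positive ppbv
#' intensity, then plants (i) isotope satellites — a fraction
#' \code{isotopeRate} of peaks gets a companion at +1.00336 m/z whose
#' intensity is a fixed isotopic ratio of the parent plus small noise, so the
#' parent-satellite Pearson correlation exceeds 0.95 — and (ii)
#' \code{nSubThreshold} peaks with every value below 1 ppbv, which the
#' intensity filter must remove. Parent m/z values are laid out with spacings
#' well away from the isotope spacing so no non-satellite pair can look like
#' an isotope.
#'
#' @param pheno phenotype data.frame from \code{\link{simulatePhenotypes}}.
#' @param cfg the \linkS4class{SimConfig}.
#' @param location,scale exponential-link parameters (defaults give ~5 ppbv
#'   mean intensities, matching typical reported peak means).
#' @return A list with \code{peaks} (a \linkS4class{PeakMatrix}),
#'   \code{isotopePairs} (data.frame: parent_mz, satellite_mz, ratio) and
#'   \code{traitOfPeak} (named map from m/z label to source trait; satellites
#'   and sub-threshold peaks map to NA).
#' @export
simulatePeakMatrix <- function(pheno, cfg, location = log(5), scale = 0.25) {
    stopifnot(is(cfg, "SimConfig"))
    set.seed(childSeed(cfg@seed, "peaks"))
    traitCols <- grep("^trait_", names(pheno), value = TRUE)
    ntr <- length(traitCols)
    n <- nrow(pheno)
    lat <- base::scale(as.matrix(pheno[, traitCols, drop = FALSE]))
    inten <- exp(location + scale * lat)

    ## parent m/z grid: spacing >= 1.4 so only planted satellites sit at
    ## ~+1.003; labels carry the conventional 3 decimals
    mz <- round(40 + 1.7 * seq_len(ntr) + runif(ntr, 0, 0.25), 3)
    nsat <- floor(cfg@isotopeRate * ntr)
    satOf <- if (nsat > 0) sort(sample.int(ntr, nsat)) else integer(0)
    satMz <- round(mz[satOf] + 1.00336, 3)
    ## ratios keep satellites above the 1-ppbv intensity filter, as in real
    ## peak tables where satellites of abundant parents survive filtering
    ratio <- runif(length(satOf), 0.25, 0.5)
    satInt <- sapply(seq_along(satOf), function(k) {
        s <- inten[, satOf[k]] * ratio[k]
        s + rnorm(n, 0, 0.15 * stats::sd(s))
    })
    if (length(satOf)) satInt <- pmax(matrix(satInt, n), 0)

    nsub <- cfg@nSubThreshold
    subMz <- if (nsub > 0) round(30 + 1.7 * seq_len(nsub) + runif(nsub, 0, 0.25), 3)
             else numeric(0)
    subInt <- matrix(runif(n * nsub, 0.05, 0.8), n, nsub)

    allMz <- c(mz, satMz, subMz)
    allInt <- cbind(inten, if (length(satOf)) satInt, if (nsub > 0) subInt)
    ord <- order(allMz)
    traitOf <- c(traitCols, rep(NA_character_, length(satOf) + nsub))[ord]
    pk <- PeakMatrix(allInt[, ord, drop = FALSE], allMz[ord])
    names(traitOf) <- formatMz(allMz[ord])
    list(peaks = pk,
         isotopePairs = data.frame(parent_mz = mz[satOf],
                                   satellite_mz = satMz, ratio = ratio),
         traitOfPeak = traitOf)
}

#' Simulate gene annotation and gene sets
#'
#' Tiles each chromosome of the marker map with gene intervals separated by
#' variable gaps, so that some SNPs fall inside genes, some within the 15 kb
#' mapping window, and some farther away. Gene sets follow GMT semantics; the
#' collection contains a planted set enriched for genes near the first trait's
#' QTLs (when \code{truth} is supplied), a 5-gene set that the >10 term-size
#' filter must exclude, and random background sets.
#'
#' @param geno \linkS4class{GenotypeData} (its marker map defines chromosome
#'   extents).
#' @param cfg the \linkS4class{SimConfig}.
#' @param truth optional truth list from \code{\link{simulatePhenotypes}};
#'   enables the planted enriched set.
#' @param nSets number of random background sets.
#' @return A list with \code{genes} (a \code{GRanges} with \code{gene_id})
#'   and \code{sets} (named list of gene-id vectors; the planted set is named
#'   \code{"PLANTED_QTL_SET"}).
#' @export
simulateAnnotation <- function(geno, cfg, truth = NULL, nSets = 30L) {
    stopifnot(is(geno, "GenotypeData"))
    set.seed(childSeed(cfg@seed, "annotation"))
    mm <- markerMap(geno)
    genes <- do.call(rbind, lapply(split(mm, mm$chrom), function(sub) {
        lo <- min(sub$bp); hi <- max(sub$bp)
        starts <- integer(0); ends <- integer(0); pos <- lo
        while (pos < hi) {
            gap <- sample(c(2000:12000, 20000:80000), 1)
            w <- sample(5000:30000, 1)
            starts <- c(starts, pos + gap); ends <- c(ends, pos + gap + w)
            pos <- pos + gap + w
        }
        data.frame(chrom = sub$chrom[1], start = starts, end = ends)
    }))
    genes$gene_id <- sprintf("GENE%05d", seq_len(nrow(genes)))
    gr <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start, genes$end),
                                 gene_id = genes$gene_id)
    allIds <- genes$gene_id

    sets <- list()
    if (!is.null(truth) && length(truth$qtlPositions[[1]])) {
        qbp <- mm[truth$qtlPositions[[1]], c("chrom", "bp")]
        qgr <- GenomicRanges::GRanges(qbp$chrom,
                                      IRanges::IRanges(qbp$bp, qbp$bp))
        near <- unique(gr$gene_id[S4Vectors::subjectHits(
            GenomicRanges::findOverlaps(qgr, gr, maxgap = 15000L))])
        pad <- setdiff(allIds, near)
        want <- max(12L, length(near) + 4L)
        sets$PLANTED_QTL_SET <- c(near, sample(pad, min(want - length(near),
                                                        length(pad))))
    }
    sets$TINY_SET <- sample(allIds, min(5L, length(allIds)))
    for (k in seq_len(nSets)) {
        sz <- sample(11:60, 1)
        sets[[sprintf("RANDOM_SET_%02d", k)]] <-
            sample(allIds, min(sz, length(allIds)))
    }
    list(genes = gr, sets = sets)
}
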