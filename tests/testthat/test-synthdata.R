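test_that("generator is deterministic and honours the missing-call rate", {
    cfg <- simConfig(nAnimals = 60, nSnps = 200, nTraits = 3, seed = 11)
    g1 <- simulateGenotypes(cfg)
    g2 <- simulateGenotypes(cfg)
    expect_identical(dosages(g1), dosages(g2))
    expect_identical(markerMap(g1), markerMap(g2))
    s1 <- simulatePhenotypes(g1, cfg)
    s2 <- simulatePhenotypes(g2, cfg)
    expect_identical(s1$phenotypes, s2$phenotypes)
    p1 <- simulatePeakMatrix(s1$phenotypes, cfg)
    p2 <- simulatePeakMatrix(s2$phenotypes, cfg)
    expect_identical(intensities(p1$peaks), intensities(p2$peaks))
    a1 <- simulateAnnotation(g1, cfg, s1$truth)
    expect_identical(a1$sets,
                     simulateAnnotation(g2, cfg, s2$truth)$sets)

    cfg0 <- simConfig(nAnimals = 50, nSnps = 100, nTraits = 2,
                      missingRate = 0, seed = 2)
    expect_false(anyNA(dosages(simulateGenotypes(cfg0))))
})

test_that("per-SNP MAF follows the configured range under HWE sampling", {
    cfg <- simConfig(nAnimals = 10000, nSnps = 40, nTraits = 1,
                     mafRange = c(0.5, 0.5), missingRate = 0, seed = 4)
    g <- simulateGenotypes(cfg)
    freq <- colMeans(dosages(g)) / 2
    sdBin <- sqrt(0.5 * 0.5 / (2 * 10000))
    expect_true(all(abs(freq - 0.5) < 3 * sdBin))
    mm <- markerMap(g)
    expect_true(all(tapply(mm$bp, mm$chrom, function(b) all(diff(b) > 0))))
})

test_that("config invariants are enforced", {
    expect_error(simConfig(h2 = 1), "h2")
    expect_error(simConfig(nAnimals = 1), "nAnimals")
    expect_error(simConfig(mafRange = c(0, 0.6)), "mafRange")
    expect_error(simConfig(nTraits = 4,
                           pleiotropyBlocks = list(1:2, 2:3)), "disjoint")
    expect_error(simConfig(nTraits = 2, pleiotropyBlocks = list(1:3)),
                 "out of range")
})

test_that("trait composition matches the target heritability exactly in-sample", {
    cfg <- simConfig(nAnimals = 2000, nSnps = 500, nTraits = 4,
                     h2 = c(0, 0.1, 0.22, 0.4), nQtl = 2L, seed = 8)
    g <- simulateGenotypes(cfg)
    sim <- simulatePhenotypes(g, cfg)
    gvar <- apply(sim$truth$geneticValues, 2, var)
    ## components are rescaled in-sample: genetic variance == h2 on the
    ## unit-total scale, so empirical h2 is within tolerance of truth
    expect_equal(unname(gvar / (gvar + (1 - cfg@h2))), cfg@h2,
                 tolerance = 0.02)
    expect_true(all(sim$truth$geneticValues[, 1] == 0))
})

test_that("pleiotropy blocks share QTL positions; other traits do not", {
    cfg <- simConfig(nAnimals = 100, nSnps = 600, nTraits = 5, h2 = 0.4,
                     nQtl = 3L, pleiotropyBlocks = list(c(1L, 2L, 3L)),
                     seed = 19)
    sim <- simulatePhenotypes(simulateGenotypes(cfg), cfg)
    qp <- sim$truth$qtlPositions
    expect_identical(qp[[1]], qp[[2]])
    expect_identical(qp[[1]], qp[[3]])
    expect_length(intersect(qp[[1]], qp[[4]]), 0)
    expect_length(intersect(qp[[4]], qp[[5]]), 0)
    ## within-block effects strongly correlated by construction
    expect_gt(abs(cor(sim$truth$qtlEffects[[1]],
                      sim$truth$qtlEffects[[2]])), 0.8)
})

test_that("peak simulation plants satellites above 0.95 correlation and sub-threshold peaks", {
    cfg <- simConfig(nAnimals = 400, nSnps = 50, nTraits = 20, h2 = 0.2,
                     nQtl = 0L, isotopeRate = 0.25, nSubThreshold = 4L,
                     seed = 21)
    sim <- simulatePhenotypes(simulateGenotypes(cfg), cfg)
    pk <- simulatePeakMatrix(sim$phenotypes, cfg)
    x <- intensities(pk$peaks)
    mz <- peakLabels(pk$peaks)
    expect_true(all(x >= 0))
    for (i in seq_len(nrow(pk$isotopePairs))) {
        pair <- pk$isotopePairs[i, ]
        r <- cor(x[, match(sprintf("%.3f", pair$parent_mz), colnames(x))],
                 x[, match(sprintf("%.3f", pair$satellite_mz), colnames(x))])
        expect_gt(r, 0.95)
        expect_lt(abs(pair$satellite_mz - pair$parent_mz - 1.00336), 0.01)
    }
    sub <- colMeans(x) < 1
    expect_equal(sum(sub), 4)
    expect_equal(nPeaks(filterPeaks(pk$peaks)), 20 + nrow(pk$isotopePairs))

    ## no satellites at rate zero: no pair correlates above 0.95
    cfg0 <- simConfig(nAnimals = 400, nSnps = 50, nTraits = 20, h2 = 0.2,
                      nQtl = 0L, isotopeRate = 0, seed = 22)
    sim0 <- simulatePhenotypes(simulateGenotypes(cfg0), cfg0)
    pk0 <- simulatePeakMatrix(sim0$phenotypes, cfg0)
    cc <- cor(intensities(pk0$peaks))
    expect_lt(max(abs(cc[upper.tri(cc)])), 0.95)
})

test_that("annotation plants boundary cases for the window and size filters", {
    cfg <- simConfig(nAnimals = 80, nSnps = 400, nTraits = 2, h2 = 0.3,
                     nQtl = 4L, seed = 33)
    g <- simulateGenotypes(cfg)
    sim <- simulatePhenotypes(g, cfg)
    ann <- simulateAnnotation(g, cfg, sim$truth)
    expect_s4_class(ann$genes, "GRanges")
    expect_true(all(GenomicRanges::start(ann$genes) <
                    GenomicRanges::end(ann$genes)))
    expect_length(ann$sets$TINY_SET, 5)
    expect_true("PLANTED_QTL_SET" %in% names(ann$sets))
    expect_gte(length(ann$sets$PLANTED_QTL_SET), 12)
    ## the 5-gene set falls to the strict >10 size filter
    kept <- filterGeneSets(ann$sets, minSize = 10, maxSize = 1000)
    expect_false("TINY_SET" %in% names(kept))
})

test_that("phenotype tables round-trip losslessly through TSV", {
    cfg <- simConfig(nAnimals = 40, nSnps = 60, nTraits = 3, seed = 13)
    sim <- simulatePhenotypes(simulateGenotypes(cfg), cfg)
    f <- tempfile(fileext = ".tsv")
    writePhenotypes(sim$phenotypes, f)
    back <- readPhenotypes(f)
    expect_identical(back$trait_01, sim$phenotypes$trait_01)
    expect_identical(back$trait_03, sim$phenotypes$trait_03)
    expect_equal(as.character(back$herd_date),
                 as.character(sim$phenotypes$herd_date))
})
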