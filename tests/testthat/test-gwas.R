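test_that("residual regression matches the closed-form oracle on random instances", {
    set.seed(31)
    for (i in 1:50) {
        n <- sample(20:60, 1)
        x <- rbinom(n, 2, runif(1, 0.1, 0.5))
        if (var(x) == 0) next
        r <- rnorm(n)
        g <- tinyGeno(matrix(x, ncol = 1))
        tab <- gwasTable(grammarScan(r, g))
        ## chi2 equals the regression identity (n-2) rho^2 / (1 - rho^2)
        rho <- cor(x, r)
        expect_equal(tab$chi2_raw, (n - 2) * rho^2 / (1 - rho^2),
                     tolerance = 1e-9)
        ## beta and se match lm()
        fit <- summary(lm(r ~ x))$coefficients
        expect_equal(tab$beta, fit["x", "Estimate"], tolerance = 1e-9)
        expect_equal(tab$se, fit["x", "Std. Error"], tolerance = 1e-9)
    }
})

test_that("degenerate SNPs get the documented statistics", {
    r <- c(1, -1, 0, 0, 1, -1)
    x_orth <- c(1, 1, 0, 0, 2, 2)            # orthogonal to r
    g <- tinyGeno(cbind(x_orth, rep(1, 6), c(0, 1, 2, 0, 1, 2)))
    tab <- gwasTable(grammarScan(r, g))
    expect_equal(tab$beta[1], 0, tolerance = 1e-12)
    expect_equal(tab$chi2_raw[1], 0, tolerance = 1e-12)
    expect_true(is.na(tab$chi2_raw[2]))      # monomorphic
    ## residuals exactly equal to a dosage: perfect fit flagged as Inf
    x <- c(0, 1, 2, 0, 1, 2)
    tab2 <- gwasTable(grammarScan(x, tinyGeno(matrix(x, ncol = 1))))
    expect_true(is.infinite(tab2$chi2_raw))
    ## fewer than 3 non-missing observations
    xm <- c(0, 1, NA, NA, NA, NA)
    expect_warning(tab3 <- gwasTable(grammarScan(r, tinyGeno(matrix(xm, ncol = 1)))),
                   "non-missing")
    expect_true(is.na(tab3$chi2_raw))
})

test_that("genomic control rescales by the chi-square median and calls significance", {
    set.seed(41)
    m <- 37568
    chi2 <- rchisq(m, 1)
    g <- tinyGeno(matrix(rbinom(4 * m, 2, 0.3), 4, m))
    res <- new("GwasResult", trait = "t", lambda = NA_real_, nAnimals = 4L,
               table = data.frame(snp_id = markerMap(g)$id,
                                  chrom = markerMap(g)$chrom,
                                  bp = markerMap(g)$bp, maf = 0.3,
                                  n_obs = 4, beta = 0, se = 1,
                                  chi2_raw = chi2))
    gc1 <- genomicControl(res)
    expect_gt(gwasLambda(gc1), 0.97)
    expect_lt(gwasLambda(gc1), 1.03)
    ## doubling every statistic doubles lambda and leaves p_gc invariant
    res2 <- methods::initialize(res, table = transform(gwasTable(res),
                                                       chi2_raw = 2 * chi2))
    gc2 <- genomicControl(res2)
    expect_equal(gwasLambda(gc2), 2 * gwasLambda(gc1), tolerance = 1e-12)
    expect_equal(gwasTable(gc2)$p_gc, gwasTable(gc1)$p_gc, tolerance = 1e-12)
    ## significance is exactly the p_gc < 5e-5 rule
    tab <- gwasTable(gc1)
    expect_identical(tab$significant, tab$p_gc < 5e-5)
    ## clamp option never deflates
    expect_gte(gwasLambda(genomicControl(res, clampLambda = TRUE)), 1)
})

test_that("variance explained follows 2pqa^2", {
    g <- tinyGeno(matrix(c(0, 1, 2, 1), ncol = 1))
    res <- new("GwasResult", trait = "t", lambda = NA_real_, nAnimals = 4L,
               table = data.frame(snp_id = "s001", chrom = "1", bp = 1e5,
                                  maf = 0.5, n_obs = 4, beta = 1, se = 0.1,
                                  chi2_raw = 100))
    expect_equal(gwasTable(varianceExplained(res))$var_explained, 0.5)
    res@table$maf <- 0
    expect_equal(gwasTable(varianceExplained(res))$var_explained, 0)
    res@table$maf <- 0.5
    expect_equal(gwasTable(varianceExplained(res, proportionOf = 2))$prop_var_g,
                 0.25)
    ## gamma de-attenuation enters the effect before squaring
    expect_equal(gwasTable(varianceExplained(res, gamma = 0.5))$var_explained,
                 2)
})

test_that("flipping allele coding flips beta and preserves chi2, p and 2pqa^2", {
    set.seed(51)
    x <- rbinom(80, 2, 0.3)
    r <- 0.3 * x + rnorm(80)
    a <- varianceExplained(genomicControl(grammarScan(r, tinyGeno(matrix(x, ncol = 1)))))
    b <- varianceExplained(genomicControl(grammarScan(r, tinyGeno(matrix(2 - x, ncol = 1)))))
    ta <- gwasTable(a); tb <- gwasTable(b)
    expect_equal(tb$beta, -ta$beta, tolerance = 1e-12)
    expect_equal(tb$chi2_raw, ta$chi2_raw, tolerance = 1e-9)
    expect_equal(tb$p_gc, ta$p_gc, tolerance = 1e-9)
    expect_equal(tb$var_explained, ta$var_explained, tolerance = 1e-9)
    expect_equal(tb$maf, ta$maf)
})

test_that("region summarisation merges by gap and reports the top SNP", {
    mkres <- function(trait, chrom, bp, p, sig = p < 5e-5) {
        new("GwasResult", trait = trait, lambda = 1,
            nAnimals = 100L,
            table = data.frame(snp_id = sprintf("%s_%d", trait, seq_along(bp)),
                               chrom = chrom, bp = bp, maf = 0.2, n_obs = 100,
                               beta = 0.1, se = 0.05, chi2_raw = 1,
                               chi2_gc = 1, p_gc = p, significant = sig))
    }
    ## single significant SNP: singleton interval
    r1 <- mkres("t1", "3", c(1e6, 5e6), c(1e-6, 0.5))
    reg <- summarizeRegions(list(r1))
    expect_equal(nrow(reg), 1)
    expect_identical(reg$interval_mb, "-")
    expect_equal(reg$top_bp, 1e6)

    ## two SNPs 1 Mb apart merge under a 5 Mb gap
    r2 <- mkres("t2", "3", c(10e6, 11e6), c(1e-6, 1e-7))
    reg2 <- summarizeRegions(list(r2), gapMax = 5e6)
    expect_equal(nrow(reg2), 1)
    expect_equal(reg2$n_snps, 2)
    expect_identical(reg2$top_snp, "t2_2")
    expect_identical(reg2$interval_mb, "10.00-11.00")

    ## planted 3-SNP cluster lands in exactly one region; distant SNP separate
    r3 <- mkres("t3", "7", c(1e6, 2e6, 3e6, 60e6), c(1e-6, 1e-8, 1e-6, 1e-6))
    reg3 <- summarizeRegions(list(r3), gapMax = 5e6)
    expect_equal(nrow(reg3), 2)
    expect_equal(reg3$n_snps, c(3, 1))

    ## unmapped SNPs stay out of regions; empty input gives an empty table
    r4 <- mkres("t4", c("2", NA), c(1e6, NA), c(1e-6, 1e-6))
    expect_equal(summarizeRegions(list(r4))$n_snps, 1)
    r5 <- mkres("t5", "1", 1e6, 0.9)
    expect_equal(nrow(summarizeRegions(list(r5))), 0)
})
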