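mkGwas <- function(p, bp = NULL, chrom = "1") {
    m <- length(p)
    new("GwasResult", trait = "t", lambda = 1, nAnimals = 100L,
        table = data.frame(snp_id = sprintf("s%03d", seq_len(m)),
                           chrom = chrom,
                           bp = bp %||% seq(1e5, by = 1e5, length.out = m),
                           maf = 0.2, n_obs = 100, beta = 0.1, se = 0.05,
                           chi2_raw = 1, chi2_gc = 1, p_gc = p,
                           significant = p < 5e-5))
}

test_that("relevant-SNP selection partitions at the permissive threshold", {
    res <- mkGwas(c(0.01, 0.5, 0.049, 0.05, 1))
    part <- suppressMessages(selectRelevantSnps(res))
    expect_identical(part$relevant, c("s001", "s003"))   # strict p < 0.05
    expect_length(part$nonrelevant, 3)
    expect_identical(formals(selectRelevantSnps)$alpha, 0.05)
    ## all p = 1: nothing relevant
    p1 <- suppressMessages(selectRelevantSnps(mkGwas(rep(1, 4))))
    expect_length(p1$relevant, 0)
    ## uniform p under the null: about 5% relevant
    set.seed(101)
    pn <- suppressMessages(selectRelevantSnps(mkGwas(runif(20000))))
    expect_lt(abs(length(pn$relevant) / 20000 - 0.05), 0.01)
})

test_that("window mapping is inclusive at exactly 15 kb and strict beyond", {
    genes <- GenomicRanges::GRanges("1",
        IRanges::IRanges(c(100000, 400000), c(120000, 420000)),
        gene_id = c("G1", "G2"))
    ## SNPs: exactly 15 kb upstream of G1; 15,001 bp upstream of G1;
    ## inside G2; 15 kb downstream of G2; far away
    bp <- c(100000 - 15000, 100000 - 15001, 410000, 420000 + 15000, 900000)
    geno <- tinyGeno(matrix(rbinom(5 * 10, 2, 0.3), 10, 5), bp = bp)
    ids <- markerMap(geno)$id
    expect_identical(mapSnpsToGenes(ids[1], geno, genes), "G1")
    expect_length(mapSnpsToGenes(ids[2], geno, genes), 0)
    expect_identical(mapSnpsToGenes(ids[3], geno, genes), "G2")
    expect_identical(mapSnpsToGenes(ids[4], geno, genes), "G2")
    expect_length(mapSnpsToGenes(ids[5], geno, genes), 0)
    ## window zero assigns intragenic SNPs only
    expect_identical(mapSnpsToGenes(ids, geno, genes, window = 0L), "G2")
    ## background universe = genes with any genotyped SNP in window
    expect_identical(testableGenes(geno, genes), c("G1", "G2"))
})

test_that("term-size bounds are strict on the testable background", {
    bg <- sprintf("G%04d", 1:2000)
    sets <- list(ten = bg[1:10], eleven = bg[1:11],
                 thousand = bg[1:1000], ok = bg[1:500],
                 offbg = c(bg[1:8], paste0("X", 1:10)))
    kept <- filterGeneSets(sets, background = bg)
    expect_identical(names(kept), c("eleven", "ok"))
    expect_length(kept$eleven, 11)
    ## sizes counted after restriction to the background
    expect_false("offbg" %in% names(kept))
})

test_that("one-sided Fisher p equals hypergeometric enumeration (N <= 200 sweep)", {
    ## the worked table: k=8 of K=10 in set, n=20 of N=100 relevant
    bg <- sprintf("g%03d", 1:100)
    sets <- list(S = bg[1:10])
    res <- fisherEnrichment(bg[c(1:8, 50:61)], bg, sets)
    expect_equal(res$k, 8); expect_equal(res$n, 20)
    expect_equal(res$p_fisher, fisherEnumOracle(8, 10, 100, 20),
                 tolerance = 1e-12)
    expect_equal(res$p_fisher,
                 fisher.test(matrix(c(8, 12, 2, 78), 2),
                             alternative = "greater")$p.value,
                 tolerance = 1e-9)

    ## systematic sweep over tables with N <= 200
    for (N in c(25, 60, 137, 200)) {
        for (K in unique(pmin(c(3, 11, 25), N - 1))) {
            for (n in unique(pmin(c(5, 20, 80), N - 1))) {
                for (k in unique(pmin(c(0, 1, 3, K), min(K, n)))) {
                    expect_equal(
                        phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                        fisherEnumOracle(k, K, N, n), tolerance = 1e-10,
                        label = sprintf("N=%d K=%d n=%d k=%d", N, K, n, k))
                }
            }
        }
    }
})

test_that("odds ratios, FDR and degenerate cases follow the contract", {
    bg <- sprintf("g%03d", 1:100)
    ## same relevant fraction in set and background: odds ratio 1, no excess
    sets <- list(S = bg[1:20])
    res <- fisherEnrichment(bg[seq(1, 100, by = 5)], bg, sets)  # 4/20 = 20/100
    expect_equal(res$odds_ratio, 1)
    expect_false(res$enriched)
    ## empty relevant list: p = 1 everywhere
    res0 <- fisherEnrichment(character(0), bg, sets)
    expect_equal(res0$p_fisher, 1)
    ## q-values: BH is monotone in p-rank and q >= p
    set.seed(7)
    sets2 <- lapply(1:15, function(i) sample(bg, 20))
    names(sets2) <- paste0("S", 1:15)
    res2 <- fisherEnrichment(sample(bg, 30), bg, sets2)
    expect_true(all(res2$q_fdr >= res2$p_fisher - 1e-12))
    expect_true(all(diff(res2$q_fdr[order(res2$p_fisher)]) >= -1e-12))
    ## case normalisation and set order do not matter
    resU <- fisherEnrichment(toupper(bg[1:10]), bg, sets2)
    resL <- fisherEnrichment(bg[1:10], bg, rev(sets2))
    expect_equal(resU$p_fisher[order(resU$set)],
                 resL$p_fisher[order(resL$set)])
})

test_that("BH keeps the null discovery fraction controlled", {
    set.seed(11)
    bg <- sprintf("g%04d", 1:400)
    fracs <- replicate(20, {
        sets <- lapply(1:25, function(i) sample(bg, sample(12:40, 1)))
        names(sets) <- paste0("S", 1:25)
        rel <- sample(bg, 40)
        mean(fisherEnrichment(rel, bg, sets)$q_fdr < 0.05)
    })
    expect_lte(mean(fracs), 0.05)
})
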