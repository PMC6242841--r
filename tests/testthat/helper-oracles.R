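## Independent oracles and small fixture builders used across the suite.

## Dense-matrix REML log-likelihood: no eigendecomposition shortcut.
denseRemlLoglik <- function(y, X, K, s2g, s2e) {
    n <- length(y)
    V <- s2g * K + s2e * diag(n)
    Vi <- solve(V)
    XVX <- t(X) %*% Vi %*% X
    beta <- solve(XVX, t(X) %*% Vi %*% y)
    r <- y - X %*% beta
    as.numeric(-0.5 * ((n - ncol(X)) * log(2 * pi) +
                       determinant(V)$modulus +
                       determinant(XVX)$modulus + t(r) %*% Vi %*% r))
}

## HWE exact p by direct enumeration of all genotype tables sharing the
## observed allele counts, with probabilities from factorial arithmetic.
hweEnumOracle <- function(nAA, nAa, naa) {
    n <- nAA + nAa + naa
    nA <- 2 * nAA + nAa
    rare <- min(nA, 2 * n - nA)
    hets <- seq(rare %% 2, rare, by = 2)
    pr <- vapply(hets, function(h) {
        a <- (rare - h) / 2
        b <- n - a - h
        exp(lfactorial(n) - lfactorial(a) - lfactorial(h) - lfactorial(b)) *
            2^h * exp(lfactorial(rare) + lfactorial(2 * n - rare) -
                      lfactorial(2 * n))
    }, numeric(1))
    pr <- pr / sum(pr)
    obs <- pr[hets == nAa]
    min(1, sum(pr[pr <= obs + 1e-12]))
}

## One-sided Fisher p by summing hypergeometric point masses computed with
## choose(), from the observed k upward.
fisherEnumOracle <- function(k, K, N, n) {
    kmax <- min(K, n)
    if (k > kmax) return(0)
    sum(vapply(k:kmax, function(i)
        choose(K, i) * choose(N - K, n - i), numeric(1))) / choose(N, n)
}

## Build an EffectNetwork directly from an edge table (for cluster tests
## that need exact edge weights).
makeNet <- function(nodes, edges) {
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = data.frame(name = nodes))
    comp <- igraph::components(g)
    subs <- lapply(which(comp$csize >= 3), function(k)
        sort(nodes[comp$membership == k]))
    new("EffectNetwork", nodes = nodes, edges = edges, graph = g,
        subnetworks = unname(subs),
        clusters = data.frame(members = character(0), size = integer(0),
                              cohesiveness = numeric(0), p = numeric(0)))
}

edgeDf <- function(from, to, w) {
    data.frame(from = from, to = to, r = w, p = rep(1e-6, length(w)),
               weight = abs(w), stringsAsFactors = FALSE)
}

## Trait labels -> cluster labelling for ARI computation (first containing
## cluster wins; unclustered traits become singletons).
clusterLabels <- function(clusters, traits) {
    lab <- stats::setNames(rep(0L, length(traits)), traits)
    if (nrow(clusters)) for (k in seq_len(nrow(clusters))) {
        v <- strsplit(clusters$members[k], ",", fixed = TRUE)[[1]]
        lab[v][lab[v] == 0] <- k
    }
    lab[lab == 0] <- 100L + seq_len(sum(lab == 0))
    lab
}

## Tiny deterministic genotype panel for edge-case tests.
tinyGeno <- function(dosage, chrom = NULL, bp = NULL) {
    d <- as.matrix(dosage)
    m <- ncol(d)
    GenotypeData(d, data.frame(
        id = sprintf("s%03d", seq_len(m)),
        chrom = chrom %||% rep("1", m),
        bp = bp %||% seq(1e5, by = 1e5, length.out = m),
        a1 = "A", a2 = "B"), sprintf("an%02d", seq_len(nrow(d))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## One GRAMMAR scan for a simulated trait (shared plumbing for recovery
## tests): returns list(gwas, fit, truth, geno, covars).
scanTrait <- function(cfg, traitIndex = 1, gamma = FALSE) {
    g <- simulateGenotypes(cfg)
    sim <- simulatePhenotypes(g, cfg)
    grm <- computeGrm(g)
    ek <- grmEigen(grm)
    cv <- sim$phenotypes[, c("herd_date", "parity", "dim_class")]
    y <- sim$phenotypes[[sprintf("trait_%02d", traitIndex)]]
    fit <- fitPolygenic(y, cv, grm, ek)
    res <- polygenicResiduals(y, cv, grm, fit, ek)
    gw <- genomicControl(grammarScan(res, g))
    gam <- if (gamma) grammarGamma(g, cv, fit, ek) else NULL
    gw <- varianceExplained(gw, proportionOf = fit$sigma_g2, gamma = gam)
    list(gwas = gw, fit = fit, truth = sim$truth, geno = g, covars = cv,
         pheno = sim$phenotypes, grm = grm, eigenK = ek)
}
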