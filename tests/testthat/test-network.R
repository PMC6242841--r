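test_that("effect-matrix assembly preserves panel alignment and drops empty traits", {
    set.seed(61)
    g <- tinyGeno(matrix(rbinom(40 * 6, 2, 0.4), 40, 6))
    r1 <- rnorm(40)
    res1 <- grammarScan(r1, g, "a")
    res2 <- grammarScan(r1, g, "b")             # identical residuals
    eff <- buildEffectMatrix(list(res1, res2))
    expect_identical(dim(eff), c(6L, 2L))
    expect_equal(cor(eff[, 1], eff[, 2]), 1)
    ## a trait with mostly-NA effects is dropped with a warning
    bad <- res2
    bad@table$beta[1:4] <- NA
    expect_warning(e2 <- buildEffectMatrix(list(res1, bad)), "missing")
    expect_identical(colnames(e2), "a")
    ## panels must match
    g2 <- tinyGeno(matrix(rbinom(40 * 5, 2, 0.4), 40, 5))
    expect_error(buildEffectMatrix(list(res1, grammarScan(r1, g2, "c"))),
                 "same SNP panel")
})

test_that("the edge rule is strict in |r| and respects the significance gate", {
    set.seed(65)
    x <- rep(c(5, -5, 0, 0), 50)
    y <- rep(c(4, -4, 3, -3), 50)          # cor(x, y) = 0.8 up to rounding
    m <- cbind(t1 = x, t2 = y, t3 = x + rnorm(200, 0, 0.1),
               t4 = -x + rnorm(200, 0, 0.1))
    ## a pair whose |r| equals the threshold exactly is excluded (strict >)
    net <- correlationNetwork(m, rMin = cor(x, y), alpha = 0.01)
    e <- networkEdges(net)
    key <- paste(e$from, e$to)
    expect_false("t1 t2" %in% key)
    expect_true("t1 t3" %in% key)
    ## nudging the threshold below r admits the edge
    netEps <- correlationNetwork(m[, c("t1", "t2")],
                                 rMin = cor(x, y) - 1e-12, alpha = 0.01)
    expect_equal(nrow(networkEdges(netEps)), 1)
    ## anti-correlated pair kept with weight |r|
    expect_true("t1 t4" %in% key)
    expect_gt(e$weight[key == "t1 t4"], 0.9)
    expect_lt(e$r[key == "t1 t4"], -0.9)
})

test_that("independent effect vectors produce no edges at study-scale row counts", {
    set.seed(71)
    m <- matrix(rnorm(37568 * 8), ncol = 8,
                dimnames = list(NULL, paste0("t", 1:8)))
    net <- correlationNetwork(m)
    expect_equal(nrow(networkEdges(net)), 0)
    expect_length(subNetworks(net), 0)
})

test_that("cohesiveness clustering matches closed forms on canonical graphs", {
    ## isolated 4-clique with unit weights, penalty 0: cohesiveness 1
    cl4 <- t(combn(paste0("v", 1:4), 2))
    net <- makeNet(paste0("v", 1:5),
                   edgeDf(cl4[, 1], cl4[, 2], rep(1, 6)))
    out <- denseClusters(findDenseClusters(net, penalty = 0, minSize = 3))
    expect_equal(nrow(out), 1)
    expect_identical(out$members, "v1,v2,v3,v4")
    expect_equal(out$cohesiveness, 1)
    expect_equal(out$p, 0)                        # no boundary edges

    ## isolated 3-path with unit weights, penalty 0: whole path scores 2/2 = 1
    netp <- makeNet(c("a", "b", "c"),
                    edgeDf(c("a", "b"), c("b", "c"), c(1, 1)))
    outp <- denseClusters(findDenseClusters(netp, penalty = 0, minSize = 3))
    expect_equal(outp$cohesiveness, 1)
    expect_identical(outp$members, "a,b,c")
})

test_that("two planted cliques joined by weak edges are recovered separately", {
    skip_if_not_installed("mclust")
    ## a few weak bridges (not one) so the Mann-Whitney screen has enough
    ## boundary edges to reach significance for genuinely dense clusters
    for (seed in 1:20) {
        set.seed(seed)
        v1 <- paste0("a", 1:5); v2 <- paste0("b", 1:5)
        e1 <- t(combn(v1, 2)); e2 <- t(combn(v2, 2))
        w1 <- runif(10, 0.88, 0.99); w2 <- runif(10, 0.88, 0.99)
        edges <- rbind(edgeDf(e1[, 1], e1[, 2], w1),
                       edgeDf(e2[, 1], e2[, 2], w2),
                       edgeDf(paste0("a", 1:4), paste0("b", 1:4),
                              runif(4, 0.80, 0.82)))
        net <- findDenseClusters(makeNet(c(v1, v2), edges))
        cl <- denseClusters(net)
        expect_equal(nrow(cl), 2)
        lab <- clusterLabels(cl, c(v1, v2))
        expect_equal(mclust::adjustedRandIndex(lab, rep(1:2, each = 5)), 1)
    }
})

test_that("clustering is deterministic and clusters are locally maximal", {
    set.seed(81)
    nodes <- paste0("t", sprintf("%02d", 1:12))
    pairs <- t(combn(nodes, 2))
    keep <- runif(nrow(pairs)) < 0.4
    edges <- edgeDf(pairs[keep, 1], pairs[keep, 2],
                    runif(sum(keep), 0.8, 1))
    n1 <- findDenseClusters(makeNet(nodes, edges))
    n2 <- findDenseClusters(makeNet(nodes, edges))
    expect_identical(denseClusters(n1), denseClusters(n2))

    adj <- matrix(0, 12, 12, dimnames = list(nodes, nodes))
    adj[cbind(edges$from, edges$to)] <- edges$weight
    adj[cbind(edges$to, edges$from)] <- edges$weight
    coh <- function(v) {
        inW <- sum(adj[v, v]) / 2
        inW / (inW + sum(adj[v, !colnames(adj) %in% v]) + 2 * length(v))
    }
    cl <- denseClusters(n1)
    for (k in seq_len(nrow(cl))) {
        v <- strsplit(cl$members[k], ",")[[1]]
        expect_equal(cl$cohesiveness[k], coh(v), tolerance = 1e-12)
        for (drop1 in v)
            expect_gte(cl$cohesiveness[k], coh(setdiff(v, drop1)))
    }
})

test_that("GraphML export round-trips the network and keeps r to full precision", {
    edges <- edgeDf(c("x", "x", "y"), c("y", "z", "z"),
                    c(0.912345678901, -0.87, 0.99))
    net <- findDenseClusters(makeNet(c("x", "y", "z", "lone"), edges))
    f <- tempfile(fileext = ".graphml")
    exportNetwork(net, f, tentative = c(x = "acetoin", y = NA, z = NA,
                                        lone = NA))
    g <- igraph::read_graph(f, format = "graphml")
    expect_equal(igraph::vcount(g), 4)
    expect_equal(igraph::ecount(g), 3)
    expect_equal(sort(igraph::E(g)$r),
                 sort(edges$r), tolerance = 1e-12)
    ## empty network still writes valid GraphML
    netEmpty <- correlationNetwork(matrix(rnorm(400), 100, 4,
                                          dimnames = list(NULL, paste0("t", 1:4))))
    f2 <- tempfile(fileext = ".graphml")
    exportNetwork(netEmpty, f2)
    g2 <- igraph::read_graph(f2, format = "graphml")
    expect_equal(igraph::ecount(g2), 0)
})

test_that("trait relabelling permutes the network without changing its structure", {
    set.seed(91)
    m <- matrix(rnorm(300 * 4), ncol = 4)
    m[, 2] <- m[, 1] + rnorm(300, 0, 0.2)
    colnames(m) <- paste0("t", 1:4)
    n1 <- correlationNetwork(m)
    n2 <- correlationNetwork(m[, c(3, 1, 4, 2)])
    e1 <- networkEdges(n1); e2 <- networkEdges(n2)
    expect_equal(nrow(e1), nrow(e2))
    expect_setequal(paste(pmin(e1$from, e1$to), pmax(e1$from, e1$to)),
                    paste(pmin(e2$from, e2$to), pmax(e2$from, e2$to)))
})
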