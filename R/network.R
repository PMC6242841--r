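## Cross-trait similarity network: traits are nodes, edges join traits whose
## genome-wide SNP allele-substitution effect vectors are strongly Pearson-
## correlated; dense overlapping clusters are found by greedy cohesiveness
## maximisation (the ClusterOne formulation) with a Mann-Whitney screen.

#' Build the SNP-effect matrix across traits
#'
#' Stacks the per-trait allele-substitution effect vectors (all scanned SNPs,
#' unfiltered by significance) into a SNPs x traits matrix. NA effects
#' (monomorphic SNPs) stay missing and are excluded pairwise downstream.
#' Traits with more than half their effects missing are dropped with a
#' warning.
#'
#' @param results list of \linkS4class{GwasResult} objects over the same SNP
#'   panel (names, if set, override the stored trait labels).
#' @return Numeric matrix, rownames = SNP ids, colnames = trait labels.
#' @export
buildEffectMatrix <- function(results) {
    stopifnot(length(results) >= 1)
    snps <- gwasTable(results[[1]])$snp_id
    labs <- if (!is.null(names(results))) names(results)
            else vapply(results, gwasTrait, character(1))
    eff <- vapply(results, function(res) {
        tab <- gwasTable(res)
        if (!identical(tab$snp_id, snps))
            stop("all traits must be scanned over the same SNP panel")
        tab$beta
    }, numeric(length(snps)))
    eff <- matrix(eff, ncol = length(results),
                  dimnames = list(snps, labs))
    frac <- colMeans(is.na(eff))
    if (any(frac > 0.5)) {
        warning("dropping trait(s) with >50% missing effects: ",
                paste(labs[frac > 0.5], collapse = ", "))
        eff <- eff[, frac <= 0.5, drop = FALSE]
    }
    eff
}

#' Threshold the trait-trait effect correlations into a network
#'
#' Pairwise Pearson correlations between trait columns (pairwise-complete
#' SNPs); an edge is kept iff |r| strictly exceeds \code{rMin} AND the
#' two-sided correlation-test p (t transformation, df = complete pairs - 2)
#' is below \code{alpha}. Edge weight is |r|, so strongly negative genetic
#' correlations cluster with positive ones. Connected components with at
#' least 3 nodes are labelled sub-networks.
#'
#' @param mat SNPs x traits effect matrix from
#'   \code{\link{buildEffectMatrix}}.
#' @param rMin correlation magnitude threshold (strict; an |r| of exactly
#'   \code{rMin} is excluded).
#' @param alpha correlation-test significance threshold.
#' @return An \linkS4class{EffectNetwork}.
#' @export
correlationNetwork <- function(mat, rMin = 0.80, alpha = 0.01) {
    if (ncol(mat) < 2) stop("need at least 2 traits")
    sds <- apply(mat, 2, stats::sd, na.rm = TRUE)
    if (any(!is.na(sds) & sds == 0))
        warning("constant effect column(s): ",
                paste(colnames(mat)[which(sds == 0)], collapse = ", "),
                " cannot form edges")
    r <- suppressWarnings(stats::cor(mat, use = "pairwise.complete.obs"))
    obs <- (!is.na(mat)) + 0
    npair <- crossprod(obs)
    df <- npair - 2
    tstat <- r * sqrt(pmax(df, 0) / pmax(1 - r^2, .Machine$double.eps))
    pmat <- 2 * stats::pt(-abs(tstat), pmax(df, 1))

    labs <- colnames(mat)
    ut <- which(upper.tri(r), arr.ind = TRUE)
    keep <- !is.na(r[ut]) & abs(r[ut]) > rMin & pmat[ut] < alpha & df[ut] >= 1
    edges <- data.frame(from = labs[ut[keep, 1]], to = labs[ut[keep, 2]],
                        r = r[ut][keep], p = pmat[ut][keep],
                        weight = abs(r[ut][keep]), stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                       vertices = data.frame(name = labs))
    comp <- igraph::components(g)
    subs <- lapply(which(comp$csize >= 3), function(k)
        sort(labs[comp$membership == k]))
    new("EffectNetwork", nodes = labs, edges = edges, graph = g,
        subnetworks = unname(subs),
        clusters = data.frame(members = character(0),
                              size = integer(0), cohesiveness = numeric(0),
                              p = numeric(0)))
}

## cohesiveness of a vertex set: w_in / (w_in + w_boundary + penalty * |V|)
cohesiveness <- function(adj, members, penalty) {
    inW <- sum(adj[members, members, drop = FALSE]) / 2
    boundW <- sum(adj[members, , drop = FALSE]) - 2 * inW
    inW / (inW + boundW + penalty * length(members))
}

## Greedy cohesiveness-maximising growth from one seed. Deterministic:
## candidate actions are scored and ties broken by (addition before removal,
## then alphabetical vertex name); only strict improvements are taken.
growCluster <- function(adj, seed, penalty) {
    nodes <- rownames(adj)
    members <- seed
    f <- cohesiveness(adj, members, penalty)
    repeat {
        outside <- nodes[!(nodes %in% members)]
        nbr <- outside[colSums(adj[members, outside, drop = FALSE]) > 0]
        cand <- c(nbr, if (length(members) > 1) members)
        type <- c(rep("add", length(nbr)),
                  rep("rm", if (length(members) > 1) length(members) else 0))
        if (!length(cand)) break
        scores <- vapply(seq_along(cand), function(i) {
            v <- if (type[i] == "add") c(members, cand[i])
                 else setdiff(members, cand[i])
            cohesiveness(adj, v, penalty)
        }, numeric(1))
        ord <- order(-scores, type != "add", cand)
        best <- ord[1]
        if (scores[best] <= f + 1e-12) break
        members <- if (type[best] == "add") c(members, cand[best])
                   else setdiff(members, cand[best])
        f <- scores[best]
    }
    list(members = sort(members), cohesiveness = f)
}

#' Detect significantly dense trait clusters
#'
#' Greedy cohesiveness-maximising growth (cohesiveness of a node set V is
#' \eqn{w_{in} / (w_{in} + w_{boundary} + penalty\,|V|)}) seeded from every
#' node in alphabetical order, skipping nodes already covered. Overlapping
#' candidate clusters are merged when the overlap score
#' \eqn{|A \cap B|^2 / (|A||B|)} exceeds \code{overlapMax}; clusters smaller
#' than \code{minSize} are dropped; each surviving cluster is screened by a
#' one-sided Mann-Whitney test of its in-cluster edge weights against its
#' boundary edge weights and retained iff p < \code{alpha}. A cluster with no
#' boundary edges (an isolated component) is maximally separated and gets
#' p = 0. Deterministic for a fixed graph: alphabetical seed and tie-break
#' order.
#'
#' @param net an \linkS4class{EffectNetwork}.
#' @param penalty cohesiveness denominator penalty per node (default 2).
#' @param minSize minimum cluster size (default 3).
#' @param overlapMax overlap score above which clusters merge (default 0.8).
#' @param alpha Mann-Whitney significance threshold (default 0.05).
#' @return The \linkS4class{EffectNetwork} with its \code{clusters} slot
#'   filled (data.frame: members — comma-separated, size, cohesiveness, p).
#' @export
findDenseClusters <- function(net, penalty = 2, minSize = 3,
                              overlapMax = 0.8, alpha = 0.05) {
    stopifnot(is(net, "EffectNetwork"), minSize >= 2)
    empty <- data.frame(members = character(0), size = integer(0),
                        cohesiveness = numeric(0), p = numeric(0))
    if (!nrow(net@edges))
        return(methods::initialize(net, clusters = empty))
    labs <- sort(net@nodes)
    adj <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
    e <- net@edges
    adj[cbind(e$from, e$to)] <- e$weight
    adj[cbind(e$to, e$from)] <- e$weight

    covered <- character(0)
    cands <- list()
    for (v in labs) {
        if (v %in% covered || sum(adj[v, ]) == 0) next
        cl <- growCluster(adj, v, penalty)
        key <- paste(cl$members, collapse = ",")
        if (!key %in% names(cands)) cands[[key]] <- cl$members
        covered <- union(covered, cl$members)
    }
    if (!length(cands)) return(methods::initialize(net, clusters = empty))

    ## merge highly overlapping candidates (connected components of the
    ## overlap graph, unioned)
    sets <- unname(cands)
    repeat {
        merged <- FALSE
        for (i in seq_along(sets)) {
            for (j in seq_along(sets)) {
                if (j <= i) next
                ov <- length(intersect(sets[[i]], sets[[j]]))^2 /
                    (length(sets[[i]]) * length(sets[[j]]))
                if (ov > overlapMax) {
                    sets[[i]] <- sort(union(sets[[i]], sets[[j]]))
                    sets[[j]] <- NULL
                    merged <- TRUE
                    break
                }
            }
            if (merged) break
        }
        if (!merged) break
    }
    sets <- sets[vapply(sets, length, integer(1)) >= minSize]
    if (!length(sets)) return(methods::initialize(net, clusters = empty))

    rows <- lapply(sets, function(v) {
        inMask <- e$from %in% v & e$to %in% v
        boundMask <- xor(e$from %in% v, e$to %in% v)
        wIn <- e$weight[inMask]; wBound <- e$weight[boundMask]
        p <- if (!length(wBound)) 0
             else if (!length(wIn)) 1
             else suppressWarnings(stats::wilcox.test(
                 wIn, wBound, alternative = "greater")$p.value)
        data.frame(members = paste(v, collapse = ","), size = length(v),
                   cohesiveness = cohesiveness(adj, v, penalty), p = p,
                   stringsAsFactors = FALSE)
    })
    cl <- do.call(rbind, rows)
    cl <- cl[cl$p < alpha, , drop = FALSE]
    cl <- cl[order(-cl$cohesiveness, cl$members), , drop = FALSE]
    rownames(cl) <- NULL
    methods::initialize(net, clusters = cl)
}

#' Export the effect network
#'
#' Writes the network as GraphML (node attributes: trait label, optional
#' tentative compound id, cluster membership; edge attributes: r, weight)
#' and, optionally, the edge list and cluster table as TSV.
#'
#' @param net an \linkS4class{EffectNetwork}.
#' @param graphmlFile path of the GraphML output.
#' @param edgeTsvFile optional edge-list TSV path.
#' @param clusterTsvFile optional cluster-membership TSV path.
#' @param tentative optional named character vector mapping trait label to
#'   tentative compound id.
#' @return Invisibly, the paths written.
#' @export
exportNetwork <- function(net, graphmlFile, edgeTsvFile = NULL,
                          clusterTsvFile = NULL, tentative = NULL) {
    stopifnot(is(net, "EffectNetwork"))
    g <- net@graph
    igraph::V(g)$label <- igraph::V(g)$name
    if (!is.null(tentative))
        igraph::V(g)$tentative_id <-
            unname(tentative[igraph::V(g)$name])
    cl <- net@clusters
    memb <- rep(NA_character_, length(igraph::V(g)))
    if (nrow(cl)) for (k in seq_len(nrow(cl))) {
        v <- strsplit(cl$members[k], ",", fixed = TRUE)[[1]]
        ix <- match(v, igraph::V(g)$name)
        memb[ix] <- ifelse(is.na(memb[ix]), as.character(k),
                           paste(memb[ix], k, sep = ";"))
    }
    igraph::V(g)$cluster <- ifelse(is.na(memb), "", memb)
    igraph::write_graph(g, graphmlFile, format = "graphml")
    paths <- graphmlFile
    if (!is.null(edgeTsvFile)) {
        utils::write.table(net@edges, edgeTsvFile, sep = "\t",
                           quote = FALSE, row.names = FALSE)
        paths <- c(paths, edgeTsvFile)
    }
    if (!is.null(clusterTsvFile)) {
        utils::write.table(net@clusters, clusterTsvFile, sep = "\t",
                           quote = FALSE, row.names = FALSE)
        paths <- c(paths, clusterTsvFile)
    }
    invisible(paths)
}
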