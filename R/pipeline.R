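## Pipeline orchestration: a declarative config (YAML or list) drives the
## stages simulate -> qc -> grm -> gwas -> network -> enrich, with one master
## seed and a JSON manifest sufficient to reproduce the run.

.pipelineDefaults <- function() list(
    paths = list(genotypes = NULL, phenotypes = NULL, peaks = NULL,
                 annotation = NULL, gene_sets = NULL, out_dir = "results"),
    stages = list(simulate = TRUE, qc = TRUE, grm = TRUE, gwas = TRUE,
                  network = TRUE, enrich = TRUE),
    thresholds = list(call_rate_min = 0.95, maf_min = 0.005,
                      hwe_alpha = 0.001, peak_min_ppbv = 1.0,
                      isotope_r = 0.95, isotope_alpha = 0.001,
                      gwas_alpha = 5e-5, edge_r = 0.80, edge_alpha = 0.01,
                      cluster_alpha = 0.05, relevant_alpha = 0.05,
                      window_bp = 15000, set_min = 10, set_max = 1000,
                      fdr = 0.05),
    sim = list(nAnimals = 300, nSnps = 1000, nTraits = 8, h2 = 0.3,
               nQtl = 4, pleiotropyBlocks = list()),
    seed = 1L)

.thresholdRanges <- list(
    call_rate_min = c(0, 1), maf_min = c(0, 0.5), hwe_alpha = c(0, 1),
    peak_min_ppbv = c(0, Inf), isotope_r = c(0, 1), isotope_alpha = c(0, 1),
    gwas_alpha = c(0, 1), edge_r = c(0, 1), edge_alpha = c(0, 1),
    cluster_alpha = c(0, 1), relevant_alpha = c(0, 1),
    window_bp = c(0, Inf), set_min = c(0, Inf), set_max = c(1, Inf),
    fdr = c(0, 1))

#' Validate and complete a pipeline configuration
#'
#' Accepts a YAML file path or a (possibly partial) nested list; unknown keys
#' are rejected, thresholds are range-checked, and missing entries are filled
#' with the defaults (the standard values used throughout the package: call
#' rate 0.95, MAF 0.005, HWE alpha 0.001, 1 ppbv peak filter, isotope
#' r 0.95 / alpha 0.001, genome-wide alpha 5e-5, edge |r| 0.80 / p 0.01,
#' cluster alpha 0.05, relevance alpha 0.05, 15 kb window, term sizes
#' strictly within (10, 1000), FDR 0.05).
#'
#' @param config NULL (all defaults), a YAML path, or a nested list.
#' @return The completed, validated config list.
#' @examples
#' validateConfig(NULL)$thresholds$gwas_alpha   # 5e-5
#' @export
validateConfig <- function(config = NULL) {
    def <- .pipelineDefaults()
    if (is.character(config) && length(config) == 1)
        config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
    if (!is.list(config)) stop("config must be a list or a YAML file path")
    bad <- setdiff(names(config), names(def))
    if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
    for (grp in c("paths", "stages", "thresholds", "sim")) {
        if (!is.null(config[[grp]])) {
            bad <- setdiff(names(config[[grp]]), names(def[[grp]]))
            if (length(bad))
                stop("unknown config key(s) in ", grp, ": ",
                     paste(bad, collapse = ", "))
            def[[grp]][names(config[[grp]])] <- config[[grp]]
        }
    }
    if (!is.null(config$seed)) def$seed <- as.integer(config$seed)
    for (nm in names(.thresholdRanges)) {
        v <- def$thresholds[[nm]]
        rg <- .thresholdRanges[[nm]]
        if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < rg[1] ||
            v > rg[2])
            stop("threshold '", nm, "' outside valid range [",
                 rg[1], ", ", rg[2], "]")
    }
    def
}

## short deterministic hash of the effective configuration (DJB2 over the
## canonical JSON serialisation); file locations are not effective
## parameters and are excluded
configHash <- function(config) {
    s <- jsonlite::toJSON(config[c("stages", "thresholds", "sim", "seed")],
                          auto_unbox = TRUE, digits = NA, null = "null")
    h <- 5381
    for (v in utf8ToInt(as.character(s))) h <- (h * 33 + v) %% 2147483647
    sprintf("%08x", as.integer(h))
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order (simulate, qc, grm, gwas, network,
#' enrich), writing every tabular result to \code{out_dir} and returning a
#' manifest (also written as \code{manifest.json}) with the package version,
#' config hash, seed and per-stage row counts. A stage failure stops with an
#' error naming the stage. With the simulate stage enabled, inputs are
#' generated synthetically and also written out; otherwise genotypes
#' (PLINK), phenotypes (TSV), peaks (TSV), annotation (BED/GFF3) and gene
#' sets (GMT) are read from \code{config$paths}. Traits are the processed
#' (log-scale) peak columns; fixed effects are herd-date, parity class and
#' DIM class from the phenotype table.
#'
#' @param config as accepted by \code{\link{validateConfig}}.
#' @return Invisibly, the manifest list.
#' @export
runPipeline <- function(config = NULL) {
    cfg <- validateConfig(config)
    thr <- cfg$thresholds
    outDir <- cfg$paths$out_dir
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    counts <- list()
    inStage <- function(name, expr) {
        message("[pipeline] stage ", name)
        tryCatch(expr, error = function(e)
            stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
    }

    geno <- pheno <- peaks <- genes <- sets <- NULL
    if (isTRUE(cfg$stages$simulate)) {
        inStage("simulate", {
            sc <- do.call(simConfig, c(cfg$sim, list(seed = cfg$seed)))
            geno <- simulateGenotypes(sc)
            sim <- simulatePhenotypes(geno, sc)
            pheno <- sim$phenotypes
            pk <- simulatePeakMatrix(pheno, sc)
            peaks <- pk$peaks
            rownames(peaks@intensities) <- pheno$animal
            ann <- simulateAnnotation(geno, sc, sim$truth)
            genes <- ann$genes; sets <- ann$sets
            writePlink(geno, file.path(outDir, "genotypes"))
            writePhenotypes(pheno, file.path(outDir, "phenotypes.tsv"))
            writePeakMatrix(peaks, file.path(outDir, "peaks_raw.tsv"))
            writeGeneAnnotation(genes, file.path(outDir, "genes.bed"))
            writeGmt(sets, file.path(outDir, "gene_sets.gmt"))
            counts$simulate <- list(animals = nSamples(geno),
                                    snps = nSnps(geno), peaks = nPeaks(peaks))
        })
    } else {
        inStage("load", {
            need <- c("genotypes", "phenotypes", "peaks")
            have <- !vapply(cfg$paths[need], is.null, logical(1))
            if (!all(have))
                stop("with the simulate stage disabled, paths must name: ",
                     paste(need[!have], collapse = ", "))
            geno <- readPlink(cfg$paths$genotypes)
            pheno <- readPhenotypes(cfg$paths$phenotypes)
            peaks <- readPeakMatrix(cfg$paths$peaks)
            if (!is.null(cfg$paths$annotation))
                genes <- readGeneAnnotation(cfg$paths$annotation)
            if (!is.null(cfg$paths$gene_sets))
                sets <- readGmt(cfg$paths$gene_sets)
            counts$load <- list(animals = nSamples(geno), snps = nSnps(geno))
        })
    }

    if (isTRUE(cfg$stages$qc)) inStage("qc", {
        q <- qcGenotypes(geno, thr$call_rate_min, thr$maf_min, thr$hwe_alpha)
        geno <- q$geno
        rep <- q$report
        utils::write.table(
            data.frame(metric = c("n_snps_in", "n_snps_out",
                                  "removed_call_rate", "removed_maf",
                                  "removed_hwe"),
                       value = c(rep$n_snps_in, rep$n_snps_out,
                                 rep$removed_call_rate, rep$removed_maf,
                                 rep$removed_hwe)),
            file.path(outDir, "qc_report.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
        pk <- filterPeaks(peaks, thr$peak_min_ppbv)
        iso <- removeIsotopes(pk, thr$isotope_r, thr$isotope_alpha)
        peaks <- transformPeaks(iso$peaks)
        writePeakMatrix(peaks, file.path(outDir, "peaks_processed.tsv"))
        counts$qc <- list(snps = nSnps(geno), peaks = nPeaks(peaks),
                          isotopes_removed = nrow(iso$removed))
    })

    covars <- pheno[, intersect(c("herd_date", "parity", "dim_class"),
                                names(pheno)), drop = FALSE]
    traits <- if (peaks@scale == "log") intensities(peaks)
              else intensities(transformPeaks(peaks))
    traitNames <- colnames(traits)

    vcList <- NULL; eigenK <- NULL; grm <- NULL
    if (isTRUE(cfg$stages$grm)) inStage("grm", {
        grm <- computeGrm(geno)
        eigenK <- grmEigen(grm)
        vcList <- lapply(seq_len(ncol(traits)), function(j)
            fitPolygenic(traits[, j], covars, grm, eigenK))
        names(vcList) <- traitNames
        writeVarianceComponents(vcList, file.path(outDir, "varcomp.tsv"))
        counts$grm <- list(traits = length(vcList),
                           mean_h2 = round(mean(vapply(vcList, `[[`, 1,
                                                       "h2")), 4))
    })

    gwasList <- NULL
    if (isTRUE(cfg$stages$gwas)) inStage("gwas", {
        if (is.null(vcList)) stop("requires the grm stage")
        gwasList <- lapply(seq_len(ncol(traits)), function(j) {
            res <- polygenicResiduals(traits[, j], covars, grm, vcList[[j]],
                                      eigenK)
            r <- grammarScan(res, geno, trait = traitNames[j])
            r <- genomicControl(r, alpha = thr$gwas_alpha)
            varianceExplained(r, proportionOf = vcList[[j]]$sigma_g2)
        })
        names(gwasList) <- traitNames
        sig <- do.call(rbind, lapply(gwasList, function(r) {
            tab <- gwasTable(r)
            tab <- tab[tab$significant, , drop = FALSE]
            if (nrow(tab)) cbind(trait = gwasTrait(r), tab) else NULL
        }))
        if (is.null(sig))
            sig <- data.frame(trait = character(0), snp_id = character(0))
        utils::write.table(sig, file.path(outDir, "gwas_significant.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        reg <- summarizeRegions(gwasList)
        utils::write.table(reg, file.path(outDir, "regions.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(
            data.frame(trait = traitNames,
                       lambda_gc = vapply(gwasList, gwasLambda, numeric(1))),
            file.path(outDir, "lambda_gc.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
        counts$gwas <- list(significant = nrow(sig), regions = nrow(reg))
    })

    if (isTRUE(cfg$stages$network)) inStage("network", {
        if (is.null(gwasList)) stop("requires the gwas stage")
        eff <- buildEffectMatrix(gwasList)
        net <- correlationNetwork(eff, thr$edge_r, thr$edge_alpha)
        net <- findDenseClusters(net, alpha = thr$cluster_alpha)
        exportNetwork(net, file.path(outDir, "network.graphml"),
                      file.path(outDir, "network_edges.tsv"),
                      file.path(outDir, "network_clusters.tsv"))
        counts$network <- list(edges = nrow(networkEdges(net)),
                               subnetworks = length(subNetworks(net)),
                               clusters = nrow(denseClusters(net)))
    })

    if (isTRUE(cfg$stages$enrich)) inStage("enrich", {
        if (is.null(gwasList)) stop("requires the gwas stage")
        if (is.null(genes) || is.null(sets))
            stop("gene annotation and gene sets are required")
        enr <- do.call(rbind, lapply(gwasList, function(r)
            cbind(trait = gwasTrait(r),
                  suppressMessages(enrichTrait(
                      r, geno, genes, sets, alpha = thr$relevant_alpha,
                      window = thr$window_bp, minSize = thr$set_min,
                      maxSize = thr$set_max, fdr = thr$fdr)))))
        utils::write.table(enr, file.path(outDir, "enrichment.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        counts$enrich <- list(tests = nrow(enr),
                              enriched = sum(enr$enriched))
    })

    manifest <- list(
        package = "volatilomeGWAS",
        version = as.character(utils::packageVersion("volatilomeGWAS")),
        seed = cfg$seed, config_hash = configHash(cfg), thresholds = thr,
        counts = counts)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(manifest)
}
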