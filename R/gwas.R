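## GRAMMAR-GC association scan: single-marker regression of mixed-model
## residuals on SNP dosages, genomic-control rescaling, per-SNP variance
## explained (2pqa^2), and region summarisation.

#' GRAMMAR residual-regression scan
#'
#' Second GRAMMAR step: the mixed-model residuals (computed once per trait by
#' \code{\link{polygenicResiduals}}) are regressed on each SNP's dosage by
#' simple linear regression. Missing dosages are dropped pairwise per SNP
#' (the GRM construction mean-imputes instead; the asymmetry is deliberate).
#' Monomorphic SNPs, and SNPs with fewer than 3 non-missing observations,
#' get NA statistics. A perfect fit (zero residual variance) is flagged via
#' \code{chi2_raw = Inf}.
#'
#' @param residuals numeric vector from \code{\link{polygenicResiduals}},
#'   same animal order as \code{geno}.
#' @param geno a \linkS4class{GenotypeData}.
#' @param trait trait label carried into the result.
#' @return A \linkS4class{GwasResult} with per-SNP \code{beta} (allele
#'   substitution effect), \code{se}, \code{chi2_raw} and \code{maf};
#'   genomic control is not yet applied.
#' @export
grammarScan <- function(residuals, geno, trait = "trait") {
    stopifnot(is(geno, "GenotypeData"))
    d <- dosages(geno)
    if (length(residuals) != nrow(d))
        stop("residuals and genotypes must cover the same animals")
    obs <- !is.na(d)
    storage.mode(obs) <- "double"
    x0 <- d; x0[is.na(x0)] <- 0
    r <- as.numeric(residuals)

    nk <- colSums(obs)
    sx <- colSums(x0)
    sxx <- colSums(x0 * x0)
    sr <- drop(crossprod(obs, r))
    srr <- drop(crossprod(obs, r * r))
    sxr <- drop(crossprod(x0, r))

    vx <- sxx - sx^2 / pmax(nk, 1)            # centered sum of squares of x
    vr <- srr - sr^2 / pmax(nk, 1)
    cxr <- sxr - sx * sr / pmax(nk, 1)

    ok <- nk >= 3 & vx > 0
    nLow <- sum(nk < 3)
    if (nLow) warning(nLow, " SNP(s) with <3 non-missing observations: NA statistics")
    beta <- se <- chi2 <- rep(NA_real_, ncol(d))
    beta[ok] <- cxr[ok] / vx[ok]
    rss <- pmax(vr[ok] - beta[ok] * cxr[ok], 0)
    s2 <- rss / (nk[ok] - 2)
    se[ok] <- sqrt(s2 / vx[ok])
    chi2[ok] <- ifelse(se[ok] > 0, (beta[ok] / se[ok])^2, Inf)

    p <- sx / (2 * pmax(nk, 1))
    maf <- pmin(p, 1 - p)
    mm <- markerMap(geno)
    tab <- data.frame(snp_id = mm$id, chrom = mm$chrom, bp = mm$bp,
                      maf = maf, n_obs = nk, beta = beta, se = se,
                      chi2_raw = chi2, stringsAsFactors = FALSE)
    new("GwasResult", trait = trait, table = tab, lambda = NA_real_,
        nAnimals = nrow(d))
}

#' Per-SNP attenuation factors for GRAMMAR effect estimates
#'
#' Regressing mixed-model residuals on a SNP that is itself part of the GRM
#' shrinks the estimated allele-substitution effect by the factor
#' \eqn{\gamma_k = \sigma_e^2 \, x_k' V^{-1} x_k / (x_k' x_k)} (with
#' \eqn{V = \sigma_g^2 G + \sigma_e^2 I} at the fitted variance components
#' and \eqn{x_k} the centered dosage): the polygenic BLUP absorbs part of
#' every marker's own effect. Dividing \code{beta} by \eqn{\gamma_k}
#' (GRAMMAR-Gamma-type rescaling) restores approximately unbiased effects,
#' which matters when effects feed \eqn{2pqa^2} variance-explained
#' estimates. Missing dosages are mean-imputed here, as in the GRM.
#'
#' @param geno the scanned \linkS4class{GenotypeData}.
#' @param covariates the fixed effects used in the polygenic fit (their GLS
#'   projection also absorbs part of each SNP effect).
#' @param vc \code{VarianceComponents} of the trait.
#' @param eigenK precomputed \code{\link{grmEigen}} of the GRM used in the
#'   fit.
#' @return Numeric vector of per-SNP attenuation factors in (0, 1].
#' @export
grammarGamma <- function(geno, covariates = NULL, vc, eigenK) {
    d <- dosages(geno)
    p <- colMeans(d, na.rm = TRUE) / 2
    xc <- sweep(d, 2, 2 * p)
    xc[is.na(xc)] <- 0
    v <- vc$delta * eigenK$values + 1
    X <- buildDesign(covariates, nrow(d))
    Xt <- crossprod(eigenK$vectors, X)
    xt <- crossprod(eigenK$vectors, xc)
    ## x' P x with P = V^-1 - V^-1 X (X'V^-1X)^-1 X'V^-1  (sigma_e^2 scaled out)
    A <- crossprod(Xt / v, Xt)
    B <- crossprod(Xt / v, xt)                 # p x m
    num <- colSums(xt * xt / v) - colSums(B * solve(A, B))
    den <- colSums(xc * xc)
    g <- ifelse(den > 0, num / den, NA_real_)
    pmin(g, 1)
}

#' Genomic-control correction
#'
#' Third GRAMMAR step. The inflation factor is
#' \eqn{\lambda = \mathrm{median}(\chi^2_{raw}) / 0.4549364} (the median of a
#' 1-df chi-square); corrected statistics are \eqn{\chi^2/\lambda}, with
#' p-values from the 1-df upper tail, and significance is called at
#' \code{alpha} (default 5e-5). Because GRAMMAR residual regression is
#' conservative, \eqn{\lambda} is typically below 1 and is applied as
#' estimated — it deflates or inflates as the data dictate. Set
#' \code{clampLambda = TRUE} for the conventional max(lambda, 1) behaviour.
#'
#' @param result a \linkS4class{GwasResult} from \code{\link{grammarScan}}.
#' @param alpha per-SNP significance threshold on the corrected p-value.
#' @param clampLambda never deflate (lambda floored at 1); default FALSE.
#' @return The \linkS4class{GwasResult} with \code{chi2_gc}, \code{p_gc} and
#'   \code{significant} columns and the \code{lambda} slot filled.
#' @export
genomicControl <- function(result, alpha = 5e-5, clampLambda = FALSE) {
    stopifnot(is(result, "GwasResult"))
    tab <- gwasTable(result)
    chi2 <- tab$chi2_raw[is.finite(tab$chi2_raw)]
    if (!length(chi2)) stop("no finite chi2_raw statistics: nothing to correct")
    lambda <- stats::median(chi2) / stats::qchisq(0.5, df = 1)
    if (clampLambda) lambda <- max(lambda, 1)
    tab$chi2_gc <- tab$chi2_raw / lambda
    tab$p_gc <- pmax(stats::pchisq(tab$chi2_gc, df = 1, lower.tail = FALSE),
                     .Machine$double.xmin)   # guard underflow at extreme chi2
    tab$significant <- !is.na(tab$p_gc) & tab$p_gc < alpha
    methods::initialize(result, table = tab, lambda = lambda)
}

#' Per-SNP variance explained (2pqa^2)
#'
#' The variance contributed by a SNP with allele frequencies p, q and allele
#' substitution effect a is \eqn{2pqa^2}. With
#' \code{proportionOf = sigma_g2}, the result is instead expressed as a
#' proportion of that additive genomic variance (the scale on which
#' "fraction of genetic variance explained" statements are made).
#'
#' @param result a \linkS4class{GwasResult} with beta and maf populated.
#' @param proportionOf optional \eqn{\sigma_g^2} from
#'   \code{\link{fitPolygenic}} to divide by.
#' @param gamma optional per-SNP attenuation factors from
#'   \code{\link{grammarGamma}}; when given, the effect entering
#'   \eqn{2pqa^2} is the de-attenuated \code{beta / gamma}.
#' @return The \linkS4class{GwasResult} with a \code{var_explained} column
#'   (plus \code{prop_var_g} when \code{proportionOf} is given).
#' @export
varianceExplained <- function(result, proportionOf = NULL, gamma = NULL) {
    stopifnot(is(result, "GwasResult"))
    tab <- gwasTable(result)
    p <- tab$maf
    a <- if (is.null(gamma)) tab$beta else tab$beta / gamma
    tab$var_explained <- 2 * p * (1 - p) * a^2
    if (!is.null(proportionOf))
        tab$prop_var_g <- tab$var_explained / proportionOf
    methods::initialize(result, table = tab)
}

#' Summarise significant SNPs into chromosome regions
#'
#' Per trait and chromosome, merges significant SNPs separated by at most
#' \code{gapMax} bp into intervals, reporting the interval, the top SNP
#' (smallest corrected p), its position and MAF, and the traits involved
#' (with the top trait flagged). SNPs with unknown position (NA chromosome
#' or bp) are kept in the scan but excluded from regions. Regions from
#' several traits whose intervals overlap are merged into one row with a
#' combined trait list.
#'
#' @param results a list of \linkS4class{GwasResult} objects (one per trait)
#'   with genomic control applied.
#' @param gapMax maximum bp gap between significant SNPs in one region.
#' @return data.frame: chrom, start_bp, end_bp, interval_mb ("-" for
#'   singletons), n_snps, top_snp, top_p, top_bp, top_maf, traits, top_trait.
#' @export
summarizeRegions <- function(results, gapMax = 5e6) {
    if (is(results, "GwasResult")) results <- list(results)
    sig <- do.call(rbind, lapply(results, function(res) {
        tab <- gwasTable(res)
        if (is.null(tab$significant)) stop("apply genomicControl() first")
        s <- tab[tab$significant & !is.na(tab$chrom) & !is.na(tab$bp), ,
                 drop = FALSE]
        if (!nrow(s)) return(NULL)
        s$trait <- gwasTrait(res)
        s
    }))
    empty <- data.frame(chrom = character(0), start_bp = numeric(0),
                        end_bp = numeric(0), interval_mb = character(0),
                        n_snps = integer(0), top_snp = character(0),
                        top_p = numeric(0), top_bp = numeric(0),
                        top_maf = numeric(0), traits = character(0),
                        top_trait = character(0))
    if (is.null(sig) || !nrow(sig)) return(empty)

    out <- lapply(split(sig, sig$chrom), function(ch) {
        ch <- ch[order(ch$bp), , drop = FALSE]
        ubp <- sort(unique(ch$bp))
        grp <- cumsum(c(1, diff(ubp) > gapMax))
        ch$region <- grp[match(ch$bp, ubp)]
        do.call(rbind, lapply(split(ch, ch$region), function(rg) {
            top <- rg[which.min(rg$p_gc), ]
            span <- range(rg$bp)
            data.frame(chrom = rg$chrom[1], start_bp = span[1],
                       end_bp = span[2],
                       interval_mb = if (span[1] == span[2]) "-" else
                           sprintf("%.2f-%.2f", span[1] / 1e6, span[2] / 1e6),
                       n_snps = length(unique(rg$snp_id)),
                       top_snp = top$snp_id, top_p = top$p_gc,
                       top_bp = top$bp, top_maf = top$maf,
                       traits = paste(unique(rg$trait), collapse = ","),
                       top_trait = top$trait, stringsAsFactors = FALSE)
        }))
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out[order(suppressWarnings(as.numeric(out$chrom)), out$chrom,
              out$start_bp), ]
}
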