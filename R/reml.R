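## REML estimation of the polygenic model y = X beta + a + e with
## a ~ N(0, G sigma_g^2), e ~ N(0, I sigma_e^2), via a single
## eigendecomposition of the GRM and 1-D profiling of the variance ratio
## delta = sigma_g^2 / sigma_e^2 (the FaST-LMM/EMMA economy: the same
## decomposition is reused across every trait).

#' Precompute the GRM eigendecomposition
#'
#' The rotation shared by every trait's REML fit. Eigenvalues are clipped at
#' zero (with a message) if the GRM is numerically indefinite.
#'
#' @param grm a \linkS4class{Grm}.
#' @return A list with \code{values}, \code{vectors}, \code{sampleIds}.
#' @export
grmEigen <- function(grm) {
    stopifnot(is(grm, "Grm"))
    e <- eigen(grmMatrix(grm), symmetric = TRUE)
    if (min(e$values) < -1e-8)
        message("GRM not positive semi-definite (min eigenvalue ",
                signif(min(e$values), 3), "); clipping at zero")
    e$values <- pmax(e$values, 0)
    list(values = e$values, vectors = e$vectors, sampleIds = sampleIds(grm))
}

## Build a full-rank fixed-effects design matrix from a covariate data.frame
## (factors expand to treatment-coded dummies; rank-deficient columns are
## dropped via pivoted QR).
buildDesign <- function(covariates, n) {
    if (is.null(covariates)) return(matrix(1, n, 1,
                                           dimnames = list(NULL, "(Intercept)")))
    if (is.matrix(covariates)) {
        X <- cbind(`(Intercept)` = 1, covariates)
    } else {
        X <- stats::model.matrix(~ ., data = as.data.frame(covariates))
    }
    q <- qr(X)
    if (q$rank < ncol(X)) X <- X[, q$pivot[seq_len(q$rank)], drop = FALSE]
    X
}

## Profile REML log-likelihood at variance ratio delta, on rotated data.
## Returns loglik plus the profiled sigma_e^2 and GLS beta.
remlProfile <- function(delta, yt, Xt, d) {
    n <- length(yt); p <- ncol(Xt)
    v <- delta * d + 1
    w <- 1 / v
    XtW <- Xt * w
    A <- crossprod(XtW, Xt)
    b <- crossprod(XtW, yt)
    ch <- tryCatch(chol(A), error = function(e) NULL)
    if (is.null(ch)) return(list(ll = -Inf))
    beta <- backsolve(ch, forwardsolve(t(ch), b))
    r <- yt - Xt %*% beta
    rss <- sum(w * r * r)
    s2e <- rss / (n - p)
    ll <- -0.5 * ((n - p) * (log(2 * pi * s2e) + 1) + sum(log(v)) +
                  2 * sum(log(diag(ch))))
    list(ll = ll, s2e = s2e, beta = drop(beta), resRot = drop(r), w = w)
}

#' Fit the polygenic model by REML
#'
#' Estimates \eqn{\sigma_g^2}, \eqn{\sigma_e^2} and genomic heritability
#' \eqn{h^2 = \sigma_g^2/(\sigma_g^2+\sigma_e^2)} for one trait, given fixed
#' effects (e.g. herd-date, parity class, DIM class) and a GRM. The REML
#' criterion is profiled over the variance ratio
#' \eqn{\delta = \sigma_g^2/\sigma_e^2} on the eigenbasis of the GRM and
#' maximised by bounded 1-D optimisation of \eqn{\log\delta} over
#' [1e-6, 1e6] (tolerance 1e-8 on the log-ratio).
#'
#' Boundary estimates (h2 near 0 or 1) are returned with
#' \code{converged = FALSE} rather than as errors. A GRM with (numerically)
#' constant eigenvalues — e.g. the identity — cannot separate the two
#' variance components; the fit is returned with \code{identifiable = FALSE}.
#'
#' @param y numeric response vector (one trait), length = animals.
#' @param covariates data.frame (factors expand to dummies) or numeric
#'   matrix of fixed effects, or NULL for intercept only.
#' @param grm a \linkS4class{Grm}.
#' @param eigenK optional precomputed \code{\link{grmEigen}} result, reused
#'   across traits.
#' @return An object of class \code{VarianceComponents}: list with
#'   \code{sigma_g2}, \code{sigma_e2}, \code{h2}, \code{fixed_effects},
#'   \code{loglik}, \code{delta}, \code{converged}, \code{identifiable}.
#' @examples
#' cfg <- simConfig(nAnimals = 150, nSnps = 300, nTraits = 1, h2 = 0.4,
#'                  nQtl = 0L, missingRate = 0, seed = 3)
#' g <- simulateGenotypes(cfg)
#' sim <- simulatePhenotypes(g, cfg)
#' fit <- fitPolygenic(sim$phenotypes$trait_01,
#'                     sim$phenotypes[, c("herd_date", "parity", "dim_class")],
#'                     computeGrm(g))
#' fit$h2
#' @export
fitPolygenic <- function(y, covariates = NULL, grm, eigenK = NULL) {
    if (any(!is.finite(y))) stop("y contains non-finite values")
    if (stats::sd(y) == 0) stop("y has zero variance")
    if (is.null(eigenK)) eigenK <- grmEigen(grm)
    n <- length(y)
    if (n != length(eigenK$values))
        stop("length(y) must match the GRM dimension")
    X <- buildDesign(covariates, n)
    U <- eigenK$vectors; d <- eigenK$values
    yt <- drop(crossprod(U, y)); Xt <- crossprod(U, X)

    identifiable <- stats::sd(d) > 1e-8
    lb <- log(1e-6); ub <- log(1e6)
    opt <- stats::optimize(function(ld) remlProfile(exp(ld), yt, Xt, d)$ll,
                           c(lb, ub), maximum = TRUE, tol = 1e-8)
    delta <- exp(opt$maximum)
    fit <- remlProfile(delta, yt, Xt, d)
    atBoundary <- opt$maximum < lb + 1e-3 || opt$maximum > ub - 1e-3
    s2e <- fit$s2e; s2g <- delta * s2e
    vc <- list(sigma_g2 = s2g, sigma_e2 = s2e, h2 = s2g / (s2g + s2e),
               fixed_effects = stats::setNames(fit$beta, colnames(Xt)),
               loglik = fit$ll, delta = delta,
               converged = !atBoundary && identifiable,
               identifiable = identifiable)
    class(vc) <- "VarianceComponents"
    vc
}

#' @export
print.VarianceComponents <- function(x, ...) {
    cat(sprintf("Polygenic REML fit: sigma_g2 = %.4g, sigma_e2 = %.4g, h2 = %.3f\n",
                x$sigma_g2, x$sigma_e2, x$h2))
    if (!x$identifiable)
        cat("  warning: variance components not separately identifiable (flat GRM spectrum)\n")
    else if (!x$converged)
        cat("  note: estimate at a variance-ratio boundary\n")
    invisible(x)
}

#' Mixed-model residuals for the GRAMMAR scan
#'
#' Returns \eqn{\hat e = y - X\hat\beta - \hat a}, where \eqn{\hat a} is the
#' BLUP of the polygenic effect at the fitted variance components; these are
#' the residuals that the second GRAMMAR step regresses on each SNP. With the
#' intercept in X, the residuals sum to zero exactly; at \eqn{h^2 = 0} they
#' reduce to ordinary least-squares residuals.
#'
#' @param y numeric trait vector.
#' @param covariates as in \code{\link{fitPolygenic}}.
#' @param grm a \linkS4class{Grm}.
#' @param vc the \code{VarianceComponents} from \code{\link{fitPolygenic}}.
#' @param eigenK optional precomputed \code{\link{grmEigen}}.
#' @return Numeric residual vector (same order as \code{y}).
#' @export
polygenicResiduals <- function(y, covariates = NULL, grm, vc, eigenK = NULL) {
    if (is.null(eigenK)) eigenK <- grmEigen(grm)
    n <- length(y)
    if (n != length(eigenK$values)) stop("length(y) must match the GRM dimension")
    X <- buildDesign(covariates, n)
    U <- eigenK$vectors
    yt <- drop(crossprod(U, y)); Xt <- crossprod(U, X)
    fit <- remlProfile(vc$delta, yt, Xt, eigenK$values)
    drop(U %*% (fit$w * fit$resRot))
}
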