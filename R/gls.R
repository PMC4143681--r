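#' Build the GLS decorrelating transformation
#'
#' Constructs the transformation matrix `T` as the inverse of a
#' decomposition of the covariance model `Sigma`, so that
#' `T Sigma T' = I`. With `mode = "kinship"` (the main analysis),
#' `Sigma` is the kinship matrix rescaled to unit mean diagonal; with
#' `mode = "heritability"`, `Sigma = h2 * K + (1 - h2) * I`, the
#' heritability-weighted average of kinship and identity. Both standard
#' readings of "the decomposition" are available: Cholesky
#' (`Sigma = L L'`, `T = L^-1`) and eigen (`Sigma = U D U'`,
#' `T = D^-1/2 U'`); they whiten identically up to an orthogonal rotation,
#' so downstream test statistics agree.
#'
#' If the Cholesky factorization fails, a ridge `eps * I` is added with
#' `eps` doubling from `ridge_start` up to `ridge_max`; the amount used is
#' recorded.
#'
#' @param kinship `kinship_matrix` or symmetric matrix with id dimnames.
#' @param mode `"kinship"` or `"heritability"`.
#' @param h2 Heritability weight in `[0, 1)`; required for
#'   `mode = "heritability"` (estimate it with [estimate_heritability()]).
#' @param decomposition `"cholesky"` (default) or `"eigen"`.
#' @param ridge_start,ridge_max Ridge escalation bounds.
#' @return Object of class `decorrelator`: list with `transform` (n x n),
#'   `source`, `decomposition`, `h2`, `ridge_added`, `ids`, and for the
#'   Cholesky route the factor `L` (applications use triangular solves).
#' @export
build_decorrelator <- function(kinship, mode = c("kinship", "heritability"),
                               h2 = NULL,
                               decomposition = c("cholesky", "eigen"),
                               ridge_start = 1e-8, ridge_max = 1e-4) {
  mode <- match.arg(mode)
  decomposition <- match.arg(decomposition)
  K <- if (inherits(kinship, "kinship_matrix")) kinship$K else as.matrix(kinship)
  ids <- rownames(K)
  if (is.null(ids)) ids <- sprintf("ind%d", seq_len(nrow(K)))
  Kr <- K / mean(diag(K))
  if (mode == "heritability") {
    if (is.null(h2) || !is.finite(h2) || h2 < 0 || h2 >= 1)
      stop("mode 'heritability' needs h2 in [0, 1)")
    Sigma <- h2 * Kr + diag(1 - h2, nrow(Kr))
  } else {
    h2 <- NULL
    Sigma <- Kr
  }

  ridge <- 0
  eps <- ridge_start
  repeat {
    S <- if (ridge > 0) Sigma + diag(ridge, nrow(Sigma)) else Sigma
    dec <- try(decompose_sigma(S, decomposition), silent = TRUE)
    if (!inherits(dec, "try-error")) break
    if (ridge == 0) ridge <- eps else { eps <- eps * 2; ridge <- eps }
    if (ridge > ridge_max)
      stop("covariance matrix not positive definite even with ridge ",
           ridge_max, "; review identical twins / duplicated samples")
  }
  structure(list(transform = dec$transform, L = dec$L, source = mode,
                 decomposition = decomposition, h2 = h2,
                 ridge_added = ridge, ids = ids),
            class = "decorrelator")
}

decompose_sigma <- function(S, decomposition) {
  n <- nrow(S)
  if (decomposition == "cholesky") {
    R <- chol(S)                        # S = R'R, L = R'
    ## a numerically vanishing pivot means S is effectively semidefinite
    ## (e.g. the structural GRM null direction); force the ridge path
    if (min(diag(R))^2 <= 1e-10 * mean(diag(S)))
      stop("vanishing Cholesky pivot")
    Tm <- backsolve(R, diag(n), transpose = TRUE)
    list(transform = Tm, L = t(R))
  } else {
    e <- eigen(S, symmetric = TRUE)
    if (min(e$values) <= 1e-10 * max(e$values)) stop("non-positive eigenvalue")
    list(transform = (1 / sqrt(e$values)) * t(e$vectors), L = NULL)
  }
}

#' @export
print.decorrelator <- function(x, ...) {
  cat(sprintf("GLS decorrelator (%s, %s) over %d individuals\n",
              x$source, x$decomposition, length(x$ids)))
  if (!is.null(x$h2)) cat(sprintf("  heritability weight h2 = %.3f\n", x$h2))
  if (x$ridge_added > 0) cat(sprintf("  ridge added: %g\n", x$ridge_added))
  invisible(x)
}

#' Apply the decorrelator to phenotype, genotypes and intercept
#'
#' Jointly transforms the residual phenotype vector, the full genotype
#' matrix (all region variants, common and rare alike) and the intercept
#' column: `y~ = T y`, `G~ = T G`, `i~ = T 1`. If `y ~ N(0, Sigma)` for the
#' `Sigma` the decorrelator was built from, `y~` has identity covariance.
#'
#' @param decorrelator A `decorrelator`.
#' @param residuals Named residual vector aligned with the decorrelator's
#'   individual order.
#' @param genotypes Dosage (or any numeric) matrix, individuals x variants,
#'   with matching row names; may be NULL.
#' @return List with `y`, `G` (NULL if no genotypes) and `i`.
#' @export
apply_decorrelator <- function(decorrelator, residuals, genotypes = NULL) {
  stopifnot(inherits(decorrelator, "decorrelator"))
  ids <- decorrelator$ids
  if (length(residuals) != length(ids))
    stop("residual length does not match the decorrelator")
  if (!is.null(names(residuals)) && !identical(names(residuals), ids))
    stop("residual order does not match the kinship individual order")
  if (!is.null(genotypes)) {
    genotypes <- as.matrix(genotypes)
    if (nrow(genotypes) != length(ids))
      stop("genotype rows do not match the decorrelator")
    rn <- rownames(genotypes)
    if (!is.null(rn) && !identical(rn, ids))
      stop("genotype order does not match the kinship individual order")
  }
  n <- length(ids)
  if (!is.null(decorrelator$L)) {
    L <- decorrelator$L
    y_t <- forwardsolve(L, residuals)
    i_t <- forwardsolve(L, rep(1, n))
    G_t <- if (!is.null(genotypes)) forwardsolve(L, genotypes) else NULL
  } else {
    Tm <- decorrelator$transform
    y_t <- as.vector(Tm %*% residuals)
    i_t <- as.vector(Tm %*% rep(1, n))
    G_t <- if (!is.null(genotypes)) Tm %*% genotypes else NULL
  }
  if (!is.null(G_t)) { rownames(G_t) <- ids; colnames(G_t) <- colnames(genotypes) }
  list(y = y_t, G = G_t, i = i_t)
}

#' REML heritability from residuals and kinship
#'
#' Fits the single-random-effect variance-component model
#' `r ~ N(mu 1, sigma_g^2 K + sigma_e^2 I)` (K rescaled to unit mean
#' diagonal) by restricted maximum likelihood, profiling over
#' `delta = sigma_e^2 / sigma_g^2` on the eigenbasis of K: a log-spaced
#' grid over `[1e-5, 1e5]` locates the optimum, refined by Brent's method.
#'
#' @param residuals Numeric residual vector (length >= 10).
#' @param kinship `kinship_matrix` or symmetric matrix.
#' @return Heritability estimate `h2 = sigma_g^2 / (sigma_g^2 + sigma_e^2)`
#'   in `[0, 1)`, with attribute `delta`. An unidentifiable spectrum (K
#'   numerically proportional to the identity) returns 0 with a warning.
#' @export
estimate_heritability <- function(residuals, kinship) {
  K <- if (inherits(kinship, "kinship_matrix")) kinship$K else as.matrix(kinship)
  n <- length(residuals)
  if (n < 10L) stop("refusing to estimate heritability with n < 10")
  if (nrow(K) != n) stop("residual/kinship dimension mismatch")
  Kr <- K / mean(diag(K))
  e <- eigen(Kr, symmetric = TRUE)
  xi <- pmax(e$values, 0)
  if (max(xi) - min(xi) < 1e-8 * max(xi)) {
    warning("kinship spectrum is flat; heritability is unidentifiable, returning 0")
    return(structure(0, delta = Inf))
  }
  y <- as.vector(crossprod(e$vectors, residuals))
  x1 <- as.vector(crossprod(e$vectors, rep(1, n)))
  negll <- function(log10d) -reml_loglik(10^log10d, xi, y, x1, n)
  grid <- seq(-5, 5, length.out = 101)
  vals <- vapply(grid, negll, 0)
  k <- which.min(vals)
  lo <- grid[max(1, k - 1)]; hi <- grid[min(length(grid), k + 1)]
  opt <- stats::optimize(negll, c(lo, hi), tol = 1e-6)
  ## accept a boundary solution if the grid end wins
  delta <- 10^opt$minimum
  h2 <- 1 / (1 + delta)
  if (h2 >= 1) h2 <- 1 - 1e-8
  structure(max(h2, 0), delta = delta)
}

## Restricted log-likelihood of delta for r ~ N(mu 1, sg^2 (K + delta I)),
## on the eigenbasis of K (xi eigenvalues, y/x1 rotated data/intercept).
reml_loglik <- function(delta, xi, y, x1, n) {
  d <- xi + delta
  w <- 1 / d
  xtx <- sum(x1^2 * w)
  if (xtx <= 0) return(-Inf)
  beta <- sum(x1 * y * w) / xtx
  r <- y - x1 * beta
  rss <- sum(r^2 * w)
  nf <- n - 1L
  sg2 <- rss / nf
  -0.5 * (nf * log(2 * pi * sg2) + sum(log(d)) + log(xtx) + nf)
}
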