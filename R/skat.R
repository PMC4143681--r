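#' Minor-allele-frequency inverse variant weights
#'
#' Madsen-Browning weights `w_j = 1 / sqrt(p_j (1 - p_j))`, strictly
#' decreasing in MAF on (0, 0.5], so rare variants dominate the region
#' statistic. MAFs must be computed on the untransformed dosages.
#'
#' @param maf Folded minor allele frequencies in (0, 0.5].
#' @return Positive weight vector of the same length.
#' @examples
#' madsen_browning_weights(c(0.5, 0.01))
#' @export
madsen_browning_weights <- function(maf) {
  check_maf(maf)
  1 / sqrt(maf * (1 - maf))
}

#' Beta-density variant weights
#'
#' The Beta(1, 25) density evaluated at the MAF, the canonical SKAT-O
#' default, provided as an alternative to [madsen_browning_weights()].
#'
#' @param maf Folded minor allele frequencies in (0, 0.5].
#' @param shape1,shape2 Beta shape parameters.
#' @return Positive weight vector.
#' @export
beta_maf_weights <- function(maf, shape1 = 1, shape2 = 25) {
  check_maf(maf)
  stats::dbeta(maf, shape1, shape2)
}

check_maf <- function(maf) {
  if (length(maf) == 0L) stop("empty MAF vector")
  if (any(!is.finite(maf)) || any(maf <= 0) || any(maf > 0.5))
    stop("MAFs must lie in (0, 0.5]; drop monomorphic variants upstream")
  invisible(maf)
}

#' Score residuals under the transformed null model
#'
#' After GLS decorrelation the null model is `y~ = b0 * i~ + e`, `e ~ N(0,
#' sigma^2 I)`, where `i~` is the transformed intercept column. Returns the
#' residuals of `y~` on `i~` and the variance estimate used to scale the
#' region statistics.
#'
#' @param y_t Transformed phenotype (residual) vector.
#' @param i_t Transformed intercept column (same length).
#' @return List with `r` (score residual vector) and `sigma2`
#'   (`sum(r^2) / (n - 1)`).
#' @export
null_score <- function(y_t, i_t) {
  n <- length(y_t)
  if (n <= 1L) stop("need more than one observation")
  if (length(i_t) != n) stop("intercept/phenotype length mismatch")
  ii <- sum(i_t^2)
  if (ii <= 0) stop("transformed intercept has zero norm")
  r <- y_t - i_t * (sum(i_t * y_t) / ii)
  list(r = r, sigma2 = sum(r^2) / (n - 1))
}

#' SKAT-family region statistic at mixing parameter rho
#'
#' `Q_rho = (1 - rho) * Q_SKAT + rho * Q_burden` with
#' `Q_SKAT = sum_j (w_j g_j' r)^2` and `Q_burden = (sum_j w_j g_j' r)^2`;
#' `rho = 0` is the variance-component (SKAT) statistic and `rho = 1` the
#' weighted burden statistic.
#'
#' @param G_t Transformed genotype matrix (individuals x variants).
#' @param r Score residual vector from [null_score()].
#' @param weights Positive variant weights.
#' @param rho Mixing parameter in `[0, 1]`.
#' @return Non-negative statistic value.
#' @export
q_statistic <- function(G_t, r, weights, rho) {
  if (length(rho) != 1L || !is.finite(rho) || rho < 0 || rho > 1)
    stop("rho must be a single value in [0, 1]")
  s <- as.vector(crossprod(G_t, r)) * weights
  (1 - rho) * sum(s^2) + rho * sum(s)^2
}

## Symmetric square root of R_rho = (1-rho) I + rho 1 1', applied as
## S B S without forming S: S = a I + b 1 1'.
rho_sqrt_conjugate <- function(B, rho) {
  m <- nrow(B)
  a <- sqrt(1 - rho)
  b <- (sqrt(1 - rho + m * rho) - a) / m
  rs <- rowSums(B)
  tot <- sum(rs)
  ## S B S = a^2 B + a b (1 rs' + rs 1') + b^2 (sum B) 1 1'
  a^2 * B + a * b * (outer(rep(1, m), rs) + outer(rs, rep(1, m))) +
    b^2 * tot
}

qf_lambda <- function(A) {
  ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  ev[ev > max(ev, 0) * 1e-10 & ev > 0]
}

#' SKAT, burden and SKAT-O tests for one decorrelated gene region
#'
#' Computes the weighted variance-component (SKAT), weighted burden, and
#' optimal-combination (SKAT-O) p-values for one region from decorrelated
#' phenotype, genotype and intercept columns. Tail probabilities of the
#' quadratic forms come from [quadform_pvalue()]; the SKAT-O p-value is the
#' analytic min-p correction over the rho grid (one-dimensional integral
#' over the shared burden component).
#'
#' @param G_t Transformed genotype matrix for the region (n x m), all
#'   variants, common and rare alike.
#' @param y_t Transformed phenotype vector.
#' @param i_t Transformed intercept column.
#' @param maf Pre-transformation folded MAFs for the m variants.
#' @param weights Optional variant weights; default Madsen-Browning from
#'   `maf`.
#' @param rho_grid Grid of mixing parameters searched by SKAT-O.
#' @param acc Absolute accuracy for tail probabilities.
#' @return List with `p_skat`, `p_burden`, `p_skato`, `rho_min` (grid value
#'   attaining the minimum p), `n_variants`, and `diagnostics`.
#' @export
skat_o <- function(G_t, y_t, i_t, maf, weights = NULL,
                   rho_grid = c(0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1),
                   acc = 1e-6) {
  G_t <- as.matrix(G_t)
  m <- ncol(G_t)
  if (m == 0L) stop("region has no variants")
  if (is.null(weights)) weights <- madsen_browning_weights(maf)
  if (length(weights) != m || any(!is.finite(weights)) || any(weights <= 0))
    stop("weights must be positive, finite, one per variant")
  if (!any(rho_grid == 0) || !any(rho_grid == 1))
    rho_grid <- sort(unique(c(0, rho_grid, 1)))
  ns <- null_score(y_t, i_t)
  r <- ns$r
  sigma2 <- ns$sigma2
  n <- length(r)

  Gw <- sweep(G_t, 2L, weights, `*`)
  ## project out the transformed intercept, scale so the null is unit variance
  ii <- sum(i_t^2)
  Z <- (Gw - i_t %*% (crossprod(i_t, Gw) / ii)) / sqrt(sigma2)
  s <- as.vector(crossprod(Z, r / sqrt(sigma2)))

  qs <- (1 - rho_grid) * sum(s^2) + rho_grid * sum(s)^2
  B <- crossprod(Z)
  p_rho <- numeric(length(rho_grid))
  meth <- character(length(rho_grid))
  for (k in seq_along(rho_grid)) {
    lam <- if (rho_grid[k] == 0) qf_lambda(B) else
      qf_lambda(rho_sqrt_conjugate(B, rho_grid[k]))
    pk <- quadform_pvalue(qs[k], lam, acc = acc)
    p_rho[k] <- pk
    meth[k] <- attr(pk, "method")
  }
  p_skat <- p_rho[match(0, rho_grid)]
  p_burden <- p_rho[match(1, rho_grid)]
  minp <- min(p_rho)
  rho_min <- rho_grid[which.min(p_rho)]

  if (m == 1L) {
    ## all Q_rho coincide: SKAT-O degenerates to the single-variant test
    return(region_result(p_skat, p_burden, p_skat, rho_min, m,
                         paste(unique(meth), collapse = "+"), "single-variant"))
  }

  p_skato <- skato_level(minp, rho_grid, B, acc)
  flag <- attr(p_skato, "flag")
  p_skato <- min(max(as.numeric(p_skato), minp), 1)
  region_result(p_skat, p_burden, p_skato, rho_min, m,
                paste(unique(meth), collapse = "+"), flag)
}

region_result <- function(p_skat, p_burden, p_skato, rho_min, m, method, flag) {
  list(p_skat = as.numeric(p_skat), p_burden = as.numeric(p_burden),
       p_skato = as.numeric(p_skato), rho_min = rho_min, n_variants = m,
       diagnostics = list(tail_method = method, skato = flag))
}

## Analytic SKAT-O level of the observed min-p statistic (Lee et al. 2012
## style): decompose Z into the average-genotype (burden) direction and its
## complement, condition on the burden chi-square x, and integrate
## P(all grid statistics below their min-p quantiles | x) over x ~ chisq_1.
skato_level <- function(minp, rho_grid, B, acc = 1e-6) {
  m <- nrow(B)
  rho_c <- pmin(rho_grid, 0.999)
  ## per-rho upper quantiles of Q_rho at tail probability minp
  qmin <- vapply(rho_grid, function(rh) {
    lam <- if (rh == 0) qf_lambda(B) else qf_lambda(rho_sqrt_conjugate(B, rh))
    liu_quantile(minp, lam)
  }, 0)

  ## split around the burden direction zbar (B = Z'Z is all we need):
  ## with C = B 1 / m, cof = C / (1' B 1 / m^2) gives the projections.
  ones <- rep(1, m)
  Bo <- as.vector(B %*% ones)          # Z' (Z 1)
  zb2 <- sum(Bo) / m^2                  # ||zbar||^2
  if (zb2 <= max(diag(B)) * 1e-12) {
    ## burden direction degenerate; Bonferroni over the grid
    return(structure(min(1, minp * length(rho_grid)), flag = "bonferroni"))
  }
  cof <- Bo / (m * zb2)                 # zbar' z_j / ||zbar||^2
  ## conditional (non-burden) part: B2 = (Z - zbar cof')' (Z - zbar cof')
  B2 <- B - outer(cof, Bo / m) - outer(Bo / m, cof) + zb2 * outer(cof, cof)
  lam_cond <- qf_lambda((B2 + t(B2)) / 2)
  if (length(lam_cond) == 0L)
    return(structure(min(1, minp * length(rho_grid)), flag = "bonferroni"))
  MuQ <- sum(lam_cond)
  VarQ <- 2 * sum(lam_cond^2)
  ## cross-variance between burden and residual parts
  A1 <- zb2 * outer(cof, cof)           # item1' item1
  VarRemain <- 4 * sum(A1 * B2)
  VarTot <- VarQ + VarRemain
  tau <- (m^2 * rho_c + (1 - rho_c) * sum(cof^2)) * zb2

  shrink <- sqrt(VarQ / VarTot)
  integrand <- function(x) {
    qcond <- vapply(x, function(xx)
      min((qmin - tau * xx) / (1 - rho_c)), 0)
    out <- numeric(length(x))
    hi <- qcond > MuQ + 1e4 * sqrt(VarTot)
    lo <- qcond <= 0
    mid <- !hi & !lo
    if (any(mid)) {
      qadj <- (qcond[mid] - MuQ) * shrink + MuQ
      out[mid] <- 1 - davies_sf_batch(qadj, lam_cond, acc = acc)
    }
    out[hi] <- 1
    out * stats::dchisq(x, df = 1)
  }
  ## integrate after x = t^2 to remove the chisq_1 density singularity
  val <- gauss_panels(function(t) 2 * t * integrand(t^2),
                      breaks = c(0, 1, 2.5, 4, 6, 8.5), n_nodes = 24)
  structure(1 - val, flag = "integrated")
}

## Fixed Gauss-Legendre quadrature over consecutive panels.
gauss_panels <- function(f, breaks, n_nodes = 24) {
  gl <- gauss_legendre(n_nodes)
  tot <- 0
  for (i in seq_len(length(breaks) - 1L)) {
    a <- breaks[i]; b <- breaks[i + 1L]
    x <- (b - a) / 2 * gl$x + (a + b) / 2
    tot <- tot + (b - a) / 2 * sum(gl$w * f(x))
  }
  tot
}

## Golub-Welsch Gauss-Legendre nodes/weights on [-1, 1] (cached).
gauss_legendre <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    k <- seq_len(n - 1L)
    beta <- k / sqrt(4 * k^2 - 1)
    J <- matrix(0, n, n)
    J[cbind(k, k + 1L)] <- beta
    J[cbind(k + 1L, k)] <- beta
    e <- eigen(J, symmetric = TRUE)
    res <- list(x = e$values, w = 2 * e$vectors[1L, ]^2)
    cache[[key]] <<- res
    res
  }
})
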