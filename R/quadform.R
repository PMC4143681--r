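#' Tail probability of a positive mixture of 1-df chi-squares
#'
#' Computes `P(Q > q)` where `Q = sum_k lambda_k * chisq_1` with positive
#' weights `lambda`, the null distribution of SKAT-type quadratic-form
#' statistics. A single weight is handled by the exact scaled chi-square
#' closed form; otherwise the characteristic function is inverted
#' numerically with explicit aliasing/truncation error control, and on
#' failure a four-moment (Liu-type, skewness-matched) chi-square
#' approximation is used.
#'
#' @param q Observed statistic (scalar, `>= 0`).
#' @param lambda Numeric vector of mixture weights; at least one must be
#'   positive. Non-positive weights that are numerically negligible relative
#'   to `max(lambda)` are dropped.
#' @param acc Target absolute accuracy of the inversion integral.
#' @param lim Maximum number of integrand evaluations before falling back to
#'   the moment-matched approximation.
#' @return A probability in `(0, 1]` with attribute `method` set to one of
#'   `"exact"`, `"davies"` or `"liu"`.
#' @examples
#' quadform_pvalue(3.841459, 1)            # ~0.05, 1-df chi-square tail
#' quadform_pvalue(5, c(2, 1))
#' @export
quadform_pvalue <- function(q, lambda, acc = 1e-6, lim = 2^20) {
  stopifnot(length(q) == 1L, is.finite(q))
  lambda <- clean_lambda(lambda)
  if (q <= 0) return(structure(1, method = "exact"))
  if (length(lambda) == 1L) {
    p <- stats::pchisq(q / lambda, df = 1, lower.tail = FALSE)
    return(structure(max(p, .Machine$double.xmin), method = "exact"))
  }
  p <- davies_sf(q, lambda, acc = acc, lim = lim)
  ## the inversion is absolute-accuracy limited: anything below ~10*acc is
  ## indistinguishable from noise, so the far tail uses moment matching
  if (is.na(p) || p <= 10 * acc || p > 1) {
    p <- liu_pvalue(q, lambda)
    return(structure(min(max(p, .Machine$double.xmin), 1), method = "liu"))
  }
  structure(min(p, 1), method = "davies")
}

## Drop numerically negligible / negative weights; error if nothing positive.
clean_lambda <- function(lambda) {
  lambda <- lambda[is.finite(lambda)]
  if (length(lambda) == 0L || max(lambda) <= 0)
    stop("quadratic-form weights must contain at least one positive value")
  lambda[lambda > max(lambda) * 1e-10]
}

## Characteristic-function inversion for P(Q > q), Q = sum lambda_k chisq_1.
## Midpoint rule on  p = 1/2 + (1/pi) Int_0^Inf sin(theta(u)) / (u rho(u)) du,
##   theta(u) = 0.5 sum atan(lambda u) - 0.5 q u,
##   rho(u)   = prod (1 + lambda^2 u^2)^(1/4).
## The step is chosen so the aliasing error (mass beyond 2*pi/step - q, bounded
## by a Chernoff bound) is < acc/10; summation stops once the integrand
## envelope tail is < acc/10. Returns NA when `lim` evaluations are exceeded.
davies_sf <- function(q, lambda, acc = 1e-6, lim = 2^22) {
  s <- sum(lambda)
  lam <- lambda / s
  qs <- q / s
  step <- cf_step(qs, lam, acc)
  m2 <- max(1, length(lam) / 2)
  lmin <- min(lam)
  total <- 0
  k0 <- 0L
  block <- 256L
  repeat {
    u <- (k0 + seq_len(block) - 0.5) * step
    lu <- outer(lam, u)                      # m x block
    theta <- 0.5 * colSums(atan(lu)) - 0.5 * qs * u
    logrho <- 0.25 * colSums(log1p(lu^2))
    env <- exp(-logrho) / u
    total <- total + sum(sin(theta) * env)
    k0 <- k0 + block
    if (cf_tail_done(env[block], u[block], step, qs, lmin, m2, acc)) break
    if (k0 >= lim) return(NA_real_)
    block <- min(block * 2L, 8192L)
  }
  0.5 + (step / pi) * total
}

## Stopping rule for the inversion sum at truncation point U with envelope
## e(U) = 1/(U rho(U)). Two bounds on the dropped tail:
##   (a) crude envelope integral, e(U) * U / (m/2) / pi  (fast decay, large m);
##   (b) Abel summation over the oscillation once the atan phase has
##       saturated (lmin * U > 10): phase advances by ~q*step/2 per term, so
##       |tail sum| * step/pi <= (step/pi) * e(U) / |2 sin(q step / 4)|.
cf_tail_done <- function(env_top, u_top, step, q, lmin, m2, acc) {
  tol <- acc / 10
  if (env_top * step / pi >= tol) return(FALSE)
  bound_a <- env_top * u_top / (m2 * pi)
  bound_b <- Inf
  if (lmin * u_top > 10 && q > 0) {
    sn <- abs(2 * sin(q * step / 4))
    if (sn > 0) bound_b <- (step / pi) * env_top / sn
  }
  min(bound_a, bound_b) < tol
}

## Batched survival function: shared lambda, vector of thresholds q (on the
## same scale as lambda). One u-grid serves all thresholds; used by the
## SKAT-O level integral where hundreds of tail evaluations share weights.
davies_sf_batch <- function(q, lambda, acc = 1e-6, lim = 2^22) {
  lambda <- clean_lambda(lambda)
  s <- sum(lambda)
  lam <- lambda / s
  out <- rep(1, length(q))
  pos <- which(q > 0)
  if (length(pos) == 0L) return(out)
  qs <- q[pos] / s
  if (length(lam) == 1L) {
    out[pos] <- stats::pchisq(qs / lam, df = 1, lower.tail = FALSE)
    return(out)
  }
  step <- cf_step(max(qs), lam, acc)
  m2 <- max(1, length(lam) / 2)
  lmin <- min(lam)
  qmin <- min(qs)
  total <- numeric(length(qs))
  k0 <- 0L
  block <- 256L
  ok <- TRUE
  repeat {
    u <- (k0 + seq_len(block) - 0.5) * step
    lu <- outer(lam, u)
    a <- 0.5 * colSums(atan(lu))
    env <- exp(-0.25 * colSums(log1p(lu^2))) / u
    ## sin(a_k - 0.5 q_j u_k) summed over k, for each j
    ph <- outer(u, qs * -0.5)                # block x J
    total <- total + colSums(sin(a + ph) * env)
    k0 <- k0 + block
    if (cf_tail_done(env[block], u[block], step, qmin, lmin, m2, acc)) break
    if (k0 >= lim) { ok <- FALSE; break }
    block <- min(block * 2L, 8192L)
  }
  p <- 0.5 + (step / pi) * total
  bad <- !ok | !is.finite(p) | p <= 0 | p > 1
  if (any(bad)) p[bad] <- vapply(qs[bad] * s, liu_pvalue, 0, lambda = lambda)
  out[pos] <- pmin(pmax(p, .Machine$double.xmin), 1)
  out
}

## Midpoint step for the inversion: the periodisation error of the midpoint
## rule is bounded by the mass of Q beyond 2*pi/step - q; a Chernoff bound
## P(Q > x) <= exp(K(t) - t x), t < 1/(2 max lambda), locates x* with
## bound < acc/20 and step = 2*pi/(q + x*).
cf_step <- function(q, lam, acc) {
  lmax <- max(lam)
  t <- 0.995 / (2 * lmax)
  K <- -0.5 * sum(log1p(-2 * t * lam))
  xstar <- (K - log(acc / 20)) / t
  2 * pi / (q + xstar)
}

## Four-moment chi-square approximation of the mixture tail (Liu-type with
## the kurtosis-matched modification used in the SKAT-O literature).
liu_params <- function(lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    d <- s1 * a^3 - a^2
    l <- a^2 - 2 * d
  } else {
    l <- 1 / s2
    d <- 0
  }
  list(muQ = c1, sigmaQ = sqrt(2 * c2), muX = l + d,
       sigmaX = sqrt(2) * sqrt(l + 2 * d), df = l, ncp = d)
}

liu_pvalue <- function(q, lambda) {
  pr <- liu_params(lambda)
  x <- (q - pr$muQ) / pr$sigmaQ * pr$sigmaX + pr$muX
  stats::pchisq(x, df = pr$df, ncp = pr$ncp, lower.tail = FALSE)
}

## Upper quantile of the mixture at tail probability p (moment-matched);
## used for the per-rho quantiles inside the SKAT-O min-p correction.
liu_quantile <- function(p, lambda) {
  pr <- liu_params(lambda)
  x <- stats::qchisq(p, df = pr$df, ncp = pr$ncp, lower.tail = FALSE)
  (x - pr$muX) / pr$sigmaX * pr$sigmaQ + pr$muQ
}
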