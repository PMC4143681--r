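#' Filter genes near causal variants out of the null pool
#'
#' For pooled type-I error estimation, genes whose transcript span lies
#' within `exclusion_radius` (default 1 Mb) of any causal variant are
#' removed; the remainder are genuinely null regions.
#'
#' @param results Per-gene results (`data.frame` with `chrom`, `start`,
#'   `stop`, as produced by [gls_skat()]).
#' @param causal `data.frame` of causal variant `chrom` / `pos`; NULL or
#'   empty keeps everything.
#' @param exclusion_radius Distance cut in bp.
#' @return The retained rows of `results`.
#' @export
null_gene_filter <- function(results, causal, exclusion_radius = 1e6) {
  if (is.null(causal) || nrow(causal) == 0L) return(results)
  keep <- rep(TRUE, nrow(results))
  cc <- sub("^chr", "", as.character(causal$chrom))
  rc <- sub("^chr", "", as.character(results$chrom))
  for (k in seq_len(nrow(causal))) {
    same <- rc == cc[k]
    d <- pmax(results$start - causal$pos[k], causal$pos[k] - results$stop, 0)
    keep <- keep & !(same & d <= exclusion_radius)
  }
  results[keep, , drop = FALSE]
}

#' Pooled empirical type-I error
#'
#' Rejection rate of null p-values at each nominal level, with Wilson 95%
#' binomial confidence intervals.
#'
#' @param p Pooled null p-values.
#' @param alphas Nominal levels.
#' @return `data.frame` with `alpha`, `rate`, `lower`, `upper`, `n`.
#' @export
type_I_error <- function(p, alphas = c(0.05, 0.01, 0.001)) {
  p <- p[!is.na(p)]
  n <- length(p)
  if (n == 0L) stop("no null p-values supplied")
  rows <- lapply(alphas, function(a) {
    x <- sum(p <= a)
    ci <- wilson_ci(x, n)
    data.frame(alpha = a, rate = x / n, lower = ci[1], upper = ci[2], n = n)
  })
  do.call(rbind, rows)
}

wilson_ci <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ph <- x / n
  den <- 1 + z^2 / n
  ctr <- (ph + z^2 / (2 * n)) / den
  hw <- z * sqrt(ph * (1 - ph) / n + z^2 / (4 * n^2)) / den
  c(max(0, ctr - hw), min(1, ctr + hw))
}

#' Empirical power across alpha levels
#'
#' Fraction of replicates whose causal-gene p-value falls at or below each
#' nominal level; monotone non-increasing as alpha decreases.
#'
#' @param p One p-value per replicate for the designated causal gene.
#' @param alphas Nominal levels.
#' @return `data.frame` with `alpha`, `power`, `lower`, `upper`, `n`.
#' @export
power_curve <- function(p, alphas = c(0.05, 0.01, 0.001, 4e-5)) {
  p <- p[!is.na(p)]
  n <- length(p)
  if (n == 0L) stop("no replicate p-values supplied")
  rows <- lapply(alphas, function(a) {
    x <- sum(p <= a)
    ci <- wilson_ci(x, n)
    data.frame(alpha = a, power = x / n, lower = ci[1], upper = ci[2], n = n)
  })
  do.call(rbind, rows)
}

#' Genomic-control lambda and QQ coordinates
#'
#' Converts p-values to 1-df chi-square quantiles and reports the
#' median-based inflation factor `lambda = median(X) / qchisq(0.5, 1)`
#' together with sorted observed/expected `-log10(p)` pairs for plotting.
#'
#' @param p P-values in (0, 1].
#' @return List with `lambda` and `pairs` (`data.frame` of `expected`,
#'   `observed`).
#' @export
qq_lambda <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) == 0L) stop("no p-values supplied")
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  x <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  lambda <- stats::median(x) / stats::qchisq(0.5, df = 1)
  n <- length(p)
  pairs <- data.frame(
    expected = -log10((seq_len(n) - 0.5) / n),
    observed = -log10(sort(p))
  )
  list(lambda = lambda, pairs = pairs)
}

#' Run the GLS-SKAT pipeline over many phenotype replicates
#'
#' Evaluation driver for a workshop-style study: one fixed genotype base
#' ([simulate_study_base()]) underlies `n_replicates` phenotype draws.
#' Kinship, its eigendecomposition, the unrelated subset, region
#' assignment and the rotated genotype matrix are computed once; each
#' replicate then redraws the trait, refits the covariate model on the
#' unrelated subset, re-estimates the heritability by REML on the cached
#' spectrum, whitens with the eigen square root of
#' `h2 K + (1 - h2) I` and runs the weighted SKAT/burden/SKAT-O region
#' scan. The per-replicate results are identical to calling [gls_skat()]
#' with `mode = "heritability", decomposition = "eigen"` on the same data.
#'
#' @param base A genotype base from [simulate_study_base()].
#' @param n_replicates Number of phenotype replicates.
#' @param seed Base seed; replicate `r` draws its phenotype with
#'   `seed + r`.
#' @param covariates Covariate set for the residual model.
#' @param weights `"mb"` or `"beta"` variant weights.
#' @param rho_grid SKAT-O mixing grid.
#' @param unrelated_threshold Kinship cut for the greedy unrelated subset.
#' @param verbose Progress messages?
#' @return List with `results` (one per-gene `data.frame` per replicate),
#'   `h2` (REML estimates per replicate), `kinship_n_variants` and
#'   `n_unrelated`.
#' @export
gls_skat_study <- function(base, n_replicates = 100, seed = 1L,
                           covariates = c("sex", "age", "age2", "med", "smoke"),
                           weights = c("mb", "beta"),
                           rho_grid = c(0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1),
                           unrelated_threshold = 0.10, verbose = FALSE) {
  weights <- match.arg(weights)
  config <- base$config
  ped <- base$ped
  G <- base$G

  kin <- estimate_kinship(G)
  unrel <- select_unrelated(kin, threshold = unrelated_threshold)
  Kr <- kin$K / mean(diag(kin$K))
  eg <- eigen(Kr, symmetric = TRUE)
  xi <- pmax(eg$values, 0)
  U <- eg$vectors
  n <- nrow(Kr)
  x1r <- as.vector(crossprod(U, rep(1, n)))

  regions <- build_regions(base$genes)
  assign <- assign_variants(regions, base$variants)
  used <- sort(unique(unlist(assign)))
  remap <- match(seq_len(nrow(base$variants)), used)
  assign <- lapply(assign, function(ix) remap[ix])
  W <- crossprod(U, G[, used, drop = FALSE])
  p_obs <- colMeans(G[, used, drop = FALSE]) / 2
  maf_obs <- pmin(p_obs, 1 - p_obs)
  wfun <- if (weights == "mb") madsen_browning_weights else beta_maf_weights

  results <- vector("list", n_replicates)
  h2s <- numeric(n_replicates)
  for (r in seq_len(n_replicates)) {
    phen <- simulate_phenotype(G, ped,
                               covariate_effects = config$covariate_effects,
                               intercept = config$intercept, h2 = config$h2,
                               sigma2 = config$sigma2,
                               causal = base$causal_spec, seed = seed + r)
    model <- fit_covariate_model(phen, unrel, covariates = covariates)
    resid <- project_residuals(model, phen)
    yr <- as.vector(crossprod(U, resid))
    h2r <- reml_h2_spectrum(xi, yr, x1r, n)
    h2s[r] <- h2r
    d <- sqrt(h2r * xi + (1 - h2r))
    tr <- list(y = yr / d, G = W / d, i = x1r / d)
    results[[r]] <- region_scan(tr, regions, assign, maf_obs, wfun, rho_grid)
    if (verbose)
      message(sprintf("replicate %d/%d: h2 = %.3f", r, n_replicates, h2r))
  }
  list(results = results, h2 = h2s,
       kinship_n_variants = kin$n_variants_used, n_unrelated = length(unrel))
}

## REML h2 on a precomputed kinship spectrum (grid + Brent, as in
## estimate_heritability).
reml_h2_spectrum <- function(xi, y, x1, n) {
  negll <- function(log10d) -reml_loglik(10^log10d, xi, y, x1, n)
  grid <- seq(-5, 5, length.out = 101)
  vals <- vapply(grid, negll, 0)
  k <- which.min(vals)
  lo <- grid[max(1, k - 1)]; hi <- grid[min(length(grid), k + 1)]
  opt <- stats::optimize(negll, c(lo, hi), tol = 1e-6)
  min(max(1 / (1 + 10^opt$minimum), 0), 1 - 1e-8)
}

#' Pooled null study: type-I error of the full pipeline
#'
#' One fixed genotype base under the null (no causal gene), many phenotype
#' replicates through the complete pipeline, SKAT-O (and SKAT/burden)
#' p-values pooled across replicates — the machinery behind pooled
#' type-I-error tables and QQ/lambda summaries.
#'
#' @param n_replicates Number of phenotype replicates.
#' @param config Generator configuration ([sim_config()]); the default is
#'   the 850-individual, 1,000-gene null design.
#' @param seed Base seed: the genotype base uses `seed`, replicate `r`
#'   uses `seed + r`.
#' @param verbose Progress messages?
#' @return List with `p_skato`, `p_skat`, `p_burden` (pooled vectors),
#'   `n_tests`, `lambda_first` (lambda of replicate 1, the single-study QQ
#'   summary), `h2` estimates and `n_replicates`.
#' @export
simulate_null_study <- function(n_replicates = 100, config = sim_config(),
                                seed = 1L, verbose = FALSE) {
  stopifnot(is.null(config$causal_gene))
  base <- simulate_study_base(config, seed = seed)
  st <- gls_skat_study(base, n_replicates = n_replicates, seed = seed,
                       verbose = verbose)
  pooled <- do.call(rbind, lapply(st$results, function(res)
    res[, c("p_skat", "p_burden", "p_skato")]))
  keep <- !is.na(pooled$p_skato)
  first <- st$results[[1]]$p_skato
  list(p_skato = pooled$p_skato[keep], p_skat = pooled$p_skat[keep],
       p_burden = pooled$p_burden[keep], n_tests = sum(keep),
       lambda_first = qq_lambda(first[!is.na(first)])$lambda,
       h2 = st$h2, n_replicates = n_replicates)
}

#' Power study for a causal gene region
#'
#' One fixed genotype base carrying a causal gene, many phenotype
#' replicates through the pipeline; collects the causal gene's p-value per
#' replicate plus pooled p-values of the far-from-causal null genes (1 Mb
#' exclusion), so power and a same-design type-I reference come from the
#' same runs.
#'
#' @param n_replicates Number of phenotype replicates.
#' @param config Generator configuration; must include `causal_gene`.
#' @param seed Base seed.
#' @param verbose Progress messages?
#' @return List with `p_causal` (per replicate), `p_null` (pooled null
#'   genes outside the exclusion zone) and `n_replicates`.
#' @export
simulate_power_study <- function(n_replicates = 100,
                                 config = sim_config(
                                   n_null_genes = 150,
                                   n_background_variants = 15000,
                                   causal_gene = list(n_causal = 10,
                                                      effect_scale = 3,
                                                      max_maf = 0.05,
                                                      prop_positive = 0.8)),
                                 seed = 1L, verbose = FALSE) {
  stopifnot(!is.null(config$causal_gene))
  base <- simulate_study_base(config, seed = seed)
  st <- gls_skat_study(base, n_replicates = n_replicates, seed = seed,
                       verbose = verbose)
  causal_gene <- base$genes$gene[nrow(base$genes)]
  p_causal <- vapply(st$results, function(res)
    res$p_skato[res$gene == causal_gene], 0)
  p_null <- unlist(lapply(st$results, function(res) {
    nulls <- null_gene_filter(res[res$gene != causal_gene, ], base$causal)
    nulls$p_skato[!is.na(nulls$p_skato)]
  }))
  list(p_causal = p_causal, p_null = p_null, n_replicates = n_replicates)
}
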