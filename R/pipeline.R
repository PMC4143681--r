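#' Simulation configuration
#'
#' Collects the generator settings with defaults emulating a
#' workshop-style simulated family study: 85 three-generation 10-member families (850 genotyped
#' individuals), a sequence-like founder MAF spectrum (80% rare), 1,000
#' null gene regions of 20-40 variants, a quantitative trait driven by the
#' five standard covariates plus a kinship-structured polygenic component
#' with h2 = 0.3, and an optional causal gene whose variant effects scale
#' with `|log10(MAF)|`.
#'
#' @param n_families Number of template families.
#' @param template Pedigree template name.
#' @param n_null_genes Number of non-causal gene regions.
#' @param variants_per_gene Integer range (min, max) of variants per gene.
#' @param prop_rare,rare_range,common_range Founder MAF spectrum
#'   ([draw_founder_mafs()]).
#' @param covariate_effects Named covariate effect vector.
#' @param intercept Trait intercept.
#' @param h2 Polygenic heritability of the non-covariate variance, [0, 1).
#' @param sigma2 Non-covariate trait variance.
#' @param n_background_variants Size of the common-variant background panel
#'   (emulating the genome-wide panel used for kinship estimation; placed
#'   between gene regions so no region test consumes it).
#' @param background_maf_range Founder MAF range of the background panel.
#' @param causal_gene NULL, or list with `n_causal`, `effect_scale`
#'   (per-variant effect = `effect_scale * |log10 MAF|`), `max_maf` (causal
#'   variants drawn among those with founder MAF below this), and
#'   `prop_positive` (sign mix).
#' @param add_twin_pairs Number of identical-twin duplicates to inject
#'   (each copies one individual's genotypes under a new id).
#' @param seed Base seed; replicate `r` of a study uses `seed + r`.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_families = 85, template = "g3",
                       n_null_genes = 1000, variants_per_gene = c(20, 40),
                       prop_rare = 0.8, rare_range = c(5e-4, 0.01),
                       common_range = c(0.01, 0.5),
                       n_background_variants = 15000,
                       background_maf_range = c(0.05, 0.5),
                       covariate_effects = c(sex = 4, age = 0.5, age2 = 0.005,
                                             med = -8, smoke = 3),
                       intercept = 110, h2 = 0.3, sigma2 = 225,
                       causal_gene = NULL, add_twin_pairs = 0, seed = 1L) {
  if (!is.finite(h2) || h2 < 0 || h2 >= 1) stop("h2 must lie in [0, 1)")
  if (sigma2 <= 0) stop("sigma2 must be positive")
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate the genotype side of a study
#'
#' Generates the fixed part of a simulated study: pedigrees, gene regions
#' laid out on one chromosome (spaced so +/-20 kb flanks never overlap),
#' region variants, a common-variant background panel for kinship
#' estimation placed between the regions, gene-dropped dosages, and — when
#' `config$causal_gene` is set — the causal variant selection and effect
#' sizes carried by the last gene. Phenotype replicates are then drawn on
#' top of this fixed genotype set ([simulate_replicate()],
#' [gls_skat_study()]), mirroring workshop-style simulated data where one
#' genotype set underlies many phenotype replicates.
#'
#' @param config A [sim_config()].
#' @param seed Seed for the genotype side.
#' @return List with `ped`, `genes`, `variants` (position-sorted; `gene`
#'   is NA for background variants), `G` (dosages, one column per variant
#'   row), `causal_spec` (index/beta, NULL under the null), `causal`
#'   (chrom/pos table, NULL under the null) and `config`.
#' @export
simulate_study_base <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  ped <- build_pedigrees(config$n_families, config$template)
  n_genes <- config$n_null_genes + as.integer(!is.null(config$causal_gene))

  set.seed(seed)
  gene_len <- 30000L
  gap <- 200000L
  starts <- 100000L + (seq_len(n_genes) - 1L) * gap
  genes <- data.frame(
    gene = sprintf("G%04d", seq_len(n_genes)),
    chrom = "3",
    start = starts,
    stop = starts + gene_len - 1L
  )
  m_per <- sample(config$variants_per_gene[1]:config$variants_per_gene[2],
                  n_genes, replace = TRUE)
  gene_of <- rep(seq_len(n_genes), m_per)
  pos <- starts[gene_of] + unlist(lapply(m_per, function(k)
    sort(sample.int(gene_len, k)))) - 1L
  maf <- draw_founder_mafs(length(pos), config$prop_rare, config$rare_range,
                           config$common_range, seed = seed + 1L)
  variants <- data.frame(
    chrom = "3", pos = pos, id = sprintf("3:%d", pos),
    gene = genes$gene[gene_of], founder_maf = maf,
    stringsAsFactors = FALSE
  )

  ## background kinship panel in the uncovered inter-region gaps
  ## (region spans +/- flank cover [start-20k, stop+20k]; the gap interval
  ##  [stop+30k, stop+140k] is never assigned to a region)
  mb <- config$n_background_variants
  if (mb > 0) {
    set.seed(seed + 6L)
    gidx <- sample.int(n_genes, mb, replace = TRUE)
    cnt <- tabulate(gidx, n_genes)
    off <- unlist(lapply(cnt, function(k)
      if (k) sort(sample.int(110000L, k)) else integer()))
    bpos <- rep(genes$stop, cnt) + 30000L + off
    bmaf <- stats::runif(mb, config$background_maf_range[1],
                         config$background_maf_range[2])
    bg <- data.frame(
      chrom = "3", pos = bpos, id = sprintf("3:%d", bpos),
      gene = NA_character_, founder_maf = bmaf,
      stringsAsFactors = FALSE
    )
    variants <- rbind(variants, bg)
  }
  ord <- order(variants$pos)
  variants <- variants[ord, , drop = FALSE]
  rownames(variants) <- NULL

  G <- gene_drop(ped, variants$founder_maf, seed = seed + 2L)
  colnames(G) <- variants$id

  causal <- NULL
  causal_spec <- NULL
  if (!is.null(config$causal_gene)) {
    cg <- config$causal_gene
    idx_gene <- which(!is.na(variants$gene) &
                        variants$gene == genes$gene[n_genes])
    elig <- idx_gene[variants$founder_maf[idx_gene] <= cg$max_maf]
    if (length(elig) < cg$n_causal)
      stop("not enough variants below max_maf in the causal gene")
    set.seed(seed + 3L)
    idx <- sort(sample(elig, cg$n_causal))
    sgn <- ifelse(stats::runif(cg$n_causal) < cg$prop_positive, 1, -1)
    beta <- cg$effect_scale * abs(log10(variants$founder_maf[idx])) * sgn
    causal_spec <- list(index = idx, beta = beta)
    causal <- data.frame(chrom = "3", pos = variants$pos[idx])
  }

  list(ped = ped, genes = genes, variants = variants, G = G,
       causal_spec = causal_spec, causal = causal, config = config)
}

#' Simulate one full study replicate (genotypes + phenotype)
#'
#' Convenience wrapper: one genotype base ([simulate_study_base()]) plus
#' one phenotype draw, with optional identical-twin injection.
#'
#' @param config A [sim_config()].
#' @param seed Replicate seed (overrides `config$seed`).
#' @return List with `ped`, `genes`, `variants`, `G`, `phenotypes` and
#'   `causal` (NULL under the null).
#' @export
simulate_replicate <- function(config, seed = config$seed) {
  base <- simulate_study_base(config, seed = seed)
  ped <- base$ped
  G <- base$G
  phen <- simulate_phenotype(G, ped,
                             covariate_effects = config$covariate_effects,
                             intercept = config$intercept, h2 = config$h2,
                             sigma2 = config$sigma2, causal = base$causal_spec,
                             seed = seed + 4L)
  if (config$add_twin_pairs > 0) {
    set.seed(seed + 5L)
    src <- sample(ped$id, config$add_twin_pairs)
    for (k in seq_along(src)) {
      tid <- paste0(src[k], "_TWIN")
      row <- ped[ped$id == src[k], ]
      row$id <- tid
      ped <- rbind(ped, row)
      G <- rbind(G, G[src[k], , drop = FALSE])
      rownames(G)[nrow(G)] <- tid
      prow <- phen[phen$id == src[k], ]
      prow$id <- tid
      phen <- rbind(phen, prow)
    }
  }
  list(ped = ped, genes = base$genes, variants = base$variants, G = G,
       phenotypes = phen, causal = base$causal)
}

#' Family-based gene-region association by GLS-SKAT
#'
#' The full analysis on in-memory objects: (1) optional twin exclusion;
#' (2) empirical kinship from all dense genotypes (folded MAF >= 0.01);
#' (3) covariate model fitted on an unrelated subset and projected to all
#' individuals; (4) GLS decorrelation of residual phenotype, genotype
#' matrix and intercept by the inverse Cholesky (or eigen square-root)
#' factor of the kinship; (5) weighted SKAT / burden / SKAT-O per flanked
#' gene region, all assigned variants included, monomorphic ones dropped.
#'
#' @param genotypes Dosage matrix (individuals x variants, ids as row
#'   names) or a `genotype_matrix` from [read_vcf_dosage()].
#' @param phenotypes Phenotype table (`id`, `trait`, covariates).
#' @param genes Gene table (`gene`, `chrom`, `start`, `stop`).
#' @param variants Variant table (`chrom`, `pos`); defaults to the one
#'   embedded in a `genotype_matrix` input.
#' @param flank Region flank in bp.
#' @param covariates Covariate set for the residual model.
#' @param kinship_method `"BN"` or `"IBS"`.
#' @param kinship_maf_min MAF filter for kinship estimation only.
#' @param kinship Optional precomputed `kinship_matrix` (reused across
#'   replicates); must cover the analysis individuals.
#' @param decomposition `"cholesky"` or `"eigen"`.
#' @param mode Covariance model behind the transform. The default
#'   `"heritability"` whitens with `h2 K + (1 - h2) I`, which both matches
#'   the phenotype's covariance structure and damps kinship-estimation
#'   noise; `"kinship"` whitens with the raw (rescaled) kinship matrix,
#'   which is adequate only when the kinship panel is much larger than the
#'   sample.
#' @param h2 Heritability for `mode = "heritability"`; NULL or `"reml"`
#'   estimates it from the residuals via [estimate_heritability()].
#' @param weights `"mb"` (Madsen-Browning, default) or `"beta"`
#'   (Beta(1,25)).
#' @param rho_grid SKAT-O mixing grid.
#' @param unrelated Optional curated unrelated-id list.
#' @param unrelated_threshold Kinship cut for the greedy unrelated
#'   selection.
#' @param twin_list Optional known twin pairs (overrides detection).
#' @param detect_twins Scan for near-duplicate genotypes (concordance >=
#'   `twin_concordance`)?
#' @param twin_concordance Concordance threshold.
#' @return Object of class `gls_skat` with per-gene results (`results`),
#'   the covariate model, exclusion and selection metadata, and settings.
#' @export
gls_skat <- function(genotypes, phenotypes, genes, variants = NULL,
                     flank = 20000L,
                     covariates = c("sex", "age", "age2", "med", "smoke"),
                     kinship_method = c("BN", "IBS"), kinship_maf_min = 0.01,
                     kinship = NULL,
                     decomposition = c("cholesky", "eigen"),
                     mode = c("heritability", "kinship"), h2 = NULL,
                     weights = c("mb", "beta"),
                     rho_grid = c(0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1),
                     unrelated = NULL, unrelated_threshold = 0.10,
                     twin_list = NULL, detect_twins = TRUE,
                     twin_concordance = 0.99) {
  kinship_method <- match.arg(kinship_method)
  decomposition <- match.arg(decomposition)
  mode <- match.arg(mode)
  weights <- match.arg(weights)
  if (inherits(genotypes, "genotype_matrix")) {
    if (is.null(variants)) variants <- genotypes$variants
    genotypes <- genotypes$G
  }
  if (is.null(variants)) stop("a variant table (chrom, pos) is required")
  if (nrow(variants) != ncol(genotypes))
    stop("variant table rows must match genotype columns")

  ## align individuals
  ids <- intersect(rownames(genotypes), phenotypes$id)
  if (length(ids) == 0L) stop("no overlap between genotype and phenotype ids")
  n_input <- length(ids)
  G <- genotypes[ids, , drop = FALSE]

  ## twin exclusion
  excluded <- character()
  if (!is.null(twin_list) || detect_twins) {
    tw <- detect_and_exclude_twins(G, concordance_min = twin_concordance,
                                   twin_list = twin_list)
    G <- tw$G
    excluded <- tw$excluded
  }
  ids <- rownames(G)
  phen <- phenotypes[match(ids, phenotypes$id), , drop = FALSE]

  ## kinship
  if (is.null(kinship)) {
    kin <- estimate_kinship(G, method = kinship_method,
                            maf_min = kinship_maf_min)
  } else {
    kin <- kinship
    if (!all(ids %in% kin$ids)) stop("precomputed kinship does not cover all individuals")
    kin$K <- kin$K[ids, ids]
    kin$ids <- ids
  }
  kin$excluded <- excluded

  ## residualization on the unrelated subset
  unrel <- select_unrelated(kin, threshold = unrelated_threshold,
                            provided_list = unrelated)
  model <- fit_covariate_model(phen, unrel, covariates = covariates)
  resid <- project_residuals(model, phen)

  ## decorrelation
  if (mode == "heritability" && (is.null(h2) || identical(h2, "reml")))
    h2 <- as.numeric(estimate_heritability(resid, kin))
  dec <- build_decorrelator(kin, mode = mode, h2 = h2,
                            decomposition = decomposition)
  tr <- apply_decorrelator(dec, resid, G)

  ## regions and per-gene tests
  regions <- build_regions(genes, flank = flank)
  assign <- assign_variants(regions, variants)
  p_obs <- colMeans(G) / 2
  maf_obs <- pmin(p_obs, 1 - p_obs)
  wfun <- if (weights == "mb") madsen_browning_weights else beta_maf_weights

  res <- region_scan(tr, regions, assign, maf_obs, wfun, rho_grid)

  out <- list(
    results = res,
    residual_phenotype = resid,
    covariate_model = model,
    kinship = list(method = kin$method, n_variants_used = kin$n_variants_used,
                   excluded = excluded, mean_diag = mean(diag(kin$K))),
    decorrelator = list(source = dec$source, decomposition = dec$decomposition,
                        h2 = dec$h2, ridge_added = dec$ridge_added),
    n_input = n_input, n_analysis = length(ids), n_unrelated = length(unrel),
    unrelated = unrel,
    bonferroni = bonferroni_threshold(nrow(genes)),
    settings = list(flank = flank, weights = weights, rho_grid = rho_grid,
                    kinship_maf_min = kinship_maf_min,
                    unrelated_threshold = unrelated_threshold)
  )
  class(out) <- "gls_skat"
  out
}

## Per-region SKAT-O sweep over pre-transformed data.
region_scan <- function(tr, regions, assign, maf_obs, wfun, rho_grid) {
  n_reg <- nrow(regions)
  p_skat <- p_burden <- p_skato <- rho_min <- rep(NA_real_, n_reg)
  n_var <- integer(n_reg)
  flags <- character(n_reg)
  for (r in seq_len(n_reg)) {
    idx <- assign[[r]]
    idx <- idx[maf_obs[idx] > 0]        # monomorphic in sample: untestable
    n_var[r] <- length(idx)
    if (length(idx) == 0L) { flags[r] <- "empty"; next }
    fit <- skat_o(tr$G[, idx, drop = FALSE], tr$y, tr$i,
                  maf = maf_obs[idx], weights = wfun(maf_obs[idx]),
                  rho_grid = rho_grid)
    p_skat[r] <- fit$p_skat
    p_burden[r] <- fit$p_burden
    p_skato[r] <- fit$p_skato
    rho_min[r] <- fit$rho_min
    flags[r] <- fit$diagnostics$skato
  }
  data.frame(
    gene = regions$gene, chrom = regions$chrom,
    start = regions$start, stop = regions$stop,
    region_start = regions$region_start, region_end = regions$region_end,
    n_variants = n_var, p_skat = p_skat, p_burden = p_burden,
    p_skato = p_skato, rho_min = rho_min, flags = flags,
    stringsAsFactors = FALSE
  )
}

#' Run the GLS-SKAT pipeline from files
#'
#' File-based front end over [gls_skat()]: reads VCF genotypes, a
#' PED-style pedigree, a phenotype TSV and a gene table TSV, runs the
#' analysis, writes a results TSV, a residuals TSV for audit
#' (`<out>.residuals.tsv`) and a run-metadata sidecar (`<out>.meta.yaml`
#' when the yaml package is available, otherwise `.meta.txt`), and
#' returns the fit.
#'
#' @param vcf,ped,pheno,genes Input paths (`ped` may be NULL; the pedigree
#'   is informational for the analysis itself).
#' @param out Output TSV path.
#' @param genes_zero_based Is the gene table in BED coordinate dialect?
#' @param ... Passed to [gls_skat()].
#' @return The `gls_skat` object, invisibly.
#' @export
run_pipeline <- function(vcf, pheno, genes, ped = NULL, out,
                         genes_zero_based = FALSE, ...) {
  gm <- read_vcf_dosage(vcf)
  ph <- utils::read.table(pheno, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  gn <- read_gene_table(genes, zero_based_half_open = genes_zero_based)
  if (!is.null(ped)) read_ped_table(ped)   # structural validation only
  fit <- gls_skat(gm, ph, gn, ...)
  utils::write.table(fit$results, out, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(id = names(fit$residual_phenotype),
               residual = unname(fit$residual_phenotype)),
    paste0(out, ".residuals.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  meta <- list(
    package = "glsskat",
    version = as.character(utils::packageVersion("glsskat")),
    n_input = fit$n_input, n_analysis = fit$n_analysis,
    n_excluded_twins = length(fit$kinship$excluded),
    excluded = fit$kinship$excluded, n_unrelated = fit$n_unrelated,
    kinship = fit$kinship[c("method", "n_variants_used")],
    decorrelator = fit$decorrelator, settings = fit$settings
  )
  if (requireNamespace("yaml", quietly = TRUE)) {
    writeLines(yaml::as.yaml(meta), paste0(out, ".meta.yaml"))
  } else {
    utils::capture.output(utils::str(meta), file = paste0(out, ".meta.txt"))
  }
  invisible(fit)
}

#' @export
print.gls_skat <- function(x, ...) {
  cat("GLS-SKAT family-based gene-region association\n")
  cat(sprintf("  individuals: %d analysed (%d input, %d twin-excluded), %d unrelated for covariate fit\n",
              x$n_analysis, x$n_input, length(x$kinship$excluded), x$n_unrelated))
  cat(sprintf("  kinship: %s on %d variants; transform: %s (%s)%s\n",
              x$kinship$method, x$kinship$n_variants_used,
              x$decorrelator$source, x$decorrelator$decomposition,
              if (!is.null(x$decorrelator$h2))
                sprintf(", h2 = %.3f", x$decorrelator$h2) else ""))
  tested <- sum(!is.na(x$results$p_skato))
  cat(sprintf("  regions: %d (%d tested), Bonferroni alpha = %.2g\n",
              nrow(x$results), tested, x$bonferroni$rounded))
  top <- x$results[order(x$results$p_skato), ]
  top <- utils::head(top[!is.na(top$p_skato),
                         c("gene", "n_variants", "p_skat", "p_burden", "p_skato")], 5)
  cat("  top regions:\n")
  print(top, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
summary.gls_skat <- function(object, ...) {
  p <- object$results$p_skato
  p <- p[!is.na(p)]
  lam <- if (length(p)) qq_lambda(p)$lambda else NA_real_
  out <- list(
    n_regions = nrow(object$results), n_tested = length(p),
    lambda = lam,
    n_significant = sum(p <= object$bonferroni$raw),
    bonferroni = object$bonferroni,
    coefficients = stats::coef(object$covariate_model)
  )
  class(out) <- "summary.gls_skat"
  out
}

#' @export
print.summary.gls_skat <- function(x, ...) {
  cat(sprintf("Regions tested: %d / %d\n", x$n_tested, x$n_regions))
  cat(sprintf("Genomic-control lambda (SKAT-O): %.3f\n", x$lambda))
  cat(sprintf("Significant at Bonferroni %.2g: %d\n",
              x$bonferroni$rounded, x$n_significant))
  cat("Covariate model coefficients:\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' QQ plot of region p-values
#'
#' @param x A `gls_skat` fit.
#' @param which Which p-value column to plot.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.gls_skat <- function(x, which = c("p_skato", "p_skat", "p_burden"), ...) {
  which <- match.arg(which)
  p <- x$results[[which]]
  p <- p[!is.na(p)]
  qq <- qq_lambda(p)
  graphics::plot(qq$pairs$expected, qq$pairs$observed,
                 xlab = expression(Expected ~ -log[10](p)),
                 ylab = expression(Observed ~ -log[10](p)),
                 main = sprintf("%s QQ (lambda = %.3f)", which, qq$lambda), ...)
  graphics::abline(0, 1, col = "grey50")
  invisible(qq)
}

#' @export
residuals.gls_skat <- function(object, ...) {
  stats::residuals(object$covariate_model$fit)
}

#' @export
coef.gls_skat <- function(object, ...) stats::coef(object$covariate_model)
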