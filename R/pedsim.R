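## Pedigree templates. Each template is a data.frame of member slots with
## within-family parent indices (NA = absent / married-in from the
## population), sexes (1 = male, 2 = female) and a generation index.
ped_templates <- list(
  ## 3 generations, 10 members: a founder couple, their 4 children, and 4
  ## grandchildren each born to one of the children and an unlisted
  ## married-in parent (so the family has exactly 2 listed founders).
  g3 = data.frame(
    member = 1:10,
    father = c(NA, NA, 1, 1, 1, 1, 3, NA, 5, NA),
    mother = c(NA, NA, 2, 2, 2, 2, NA, 4, NA, 6),
    sex    = c(1, 2, 1, 2, 1, 2, 1, 2, 1, 2),
    generation = c(0, 0, 1, 1, 1, 1, 2, 2, 2, 2)
  )
)

#' Build a multi-family pedigree from a template
#'
#' Replicates a named family template `n_families` times, producing a
#' pedigree table with globally unique individual ids. The default template
#' `"g3"` is a 3-generation, 10-member family with 2 founders, 4 offspring
#' and 4 grandchildren (each grandchild has one listed parent; the other is
#' an unlisted married-in individual).
#'
#' @param n_families Number of families.
#' @param template Template name; see `names(glsskat:::ped_templates)`.
#' @return A `data.frame` with columns `id`, `family`, `father`, `mother`
#'   (NA when absent), `sex` (1/2) and `generation`, one row per individual.
#' @examples
#' ped <- build_pedigrees(2)
#' table(ped$generation)
#' @export
build_pedigrees <- function(n_families, template = "g3") {
  if (!is.character(template) || !template %in% names(ped_templates))
    stop("unknown pedigree template: ", template)
  stopifnot(n_families >= 1)
  tpl <- ped_templates[[template]]
  blocks <- lapply(seq_len(n_families), function(f) {
    id <- sprintf("F%03d_I%02d", f, tpl$member)
    data.frame(
      id = id,
      family = sprintf("F%03d", f),
      father = ifelse(is.na(tpl$father), NA_character_, id[tpl$father]),
      mother = ifelse(is.na(tpl$mother), NA_character_, id[tpl$mother]),
      sex = tpl$sex,
      generation = tpl$generation,
      stringsAsFactors = FALSE
    )
  })
  ped <- do.call(rbind, blocks)
  rownames(ped) <- NULL
  validate_pedigree(ped)
  ped
}

#' Validate pedigree structure
#'
#' Checks that parent ids refer to individuals of the same family with a
#' strictly lower generation index (which also guarantees acyclicity) and
#' that sexes are coded 1/2.
#'
#' @param ped Pedigree `data.frame` as returned by [build_pedigrees()].
#' @return The pedigree, invisibly; errors on violation.
#' @export
validate_pedigree <- function(ped) {
  req <- c("id", "family", "father", "mother", "sex", "generation")
  if (!all(req %in% names(ped))) stop("pedigree lacks columns: ",
                                      paste(setdiff(req, names(ped)), collapse = ", "))
  if (anyDuplicated(ped$id)) stop("duplicate individual ids in pedigree")
  if (!all(ped$sex %in% c(1, 2))) stop("sex must be coded 1 (male) / 2 (female)")
  for (side in c("father", "mother")) {
    p <- ped[[side]]
    has <- !is.na(p)
    j <- match(p[has], ped$id)
    if (anyNA(j)) stop(side, " ids missing from pedigree")
    if (any(ped$family[j] != ped$family[has]))
      stop(side, " assigned across families")
    if (any(ped$generation[j] >= ped$generation[has]))
      stop(side, " must belong to a strictly earlier generation")
  }
  invisible(ped)
}

#' Gene-drop genotypes through a pedigree
#'
#' Simulates biallelic autosomal dosages by Mendelian transmission: each
#' founder haplotype carries an alternate allele with probability equal to
#' the variant's founder MAF; every offspring receives one uniformly chosen
#' allele from each listed parent; where a parent is unlisted (married-in),
#' the transmitted allele is drawn from the founder MAF. Variants are
#' independent (no linkage disequilibrium).
#'
#' @param ped Pedigree table ([build_pedigrees()]).
#' @param founder_maf Vector of founder minor allele frequencies in
#'   (0, 0.5], one per variant.
#' @param seed Integer seed; the draw is reproducible given
#'   `(ped, founder_maf, seed)`.
#' @return Integer dosage matrix (individuals x variants, values 0/1/2)
#'   with individual ids as row names.
#' @export
gene_drop <- function(ped, founder_maf, seed = 1L) {
  validate_pedigree(ped)
  if (any(founder_maf <= 0) || any(founder_maf > 0.5))
    stop("founder MAFs must lie in (0, 0.5]")
  set.seed(seed)
  n <- nrow(ped)
  m <- length(founder_maf)
  ord <- order(ped$generation)
  fa <- match(ped$father, ped$id)
  mo <- match(ped$mother, ped$id)
  H1 <- matrix(0L, n, m)
  H2 <- matrix(0L, n, m)
  for (i in ord) {
    H1[i, ] <- transmit(fa[i], H1, H2, founder_maf, m)
    H2[i, ] <- transmit(mo[i], H1, H2, founder_maf, m)
  }
  G <- H1 + H2
  rownames(G) <- ped$id
  colnames(G) <- sprintf("v%d", seq_len(m))
  G
}

## One transmitted haplotype: Mendelian pick from a listed parent,
## population draw from the founder MAF otherwise.
transmit <- function(parent, H1, H2, maf, m) {
  if (is.na(parent)) return((stats::runif(m) < maf) + 0L)
  hap <- H2[parent, ]
  pick <- stats::runif(m) < 0.5
  hap[pick] <- H1[parent, pick]
  hap
}

#' Draw a founder MAF spectrum
#'
#' Sequence-like site-frequency mix: a fraction `prop_rare` of variants has
#' MAF uniform on `rare_range` (default (0.0005, 0.01)), the rest uniform
#' on `common_range` (default (0.01, 0.5)), so both the kinship MAF filter
#' and the rare-variant weighting are exercised downstream.
#'
#' @param m Number of variants.
#' @param prop_rare Fraction of rare variants.
#' @param rare_range,common_range MAF ranges.
#' @param seed Integer seed.
#' @return MAF vector of length `m`.
#' @export
draw_founder_mafs <- function(m, prop_rare = 0.8,
                              rare_range = c(5e-4, 0.01),
                              common_range = c(0.01, 0.5), seed = 1L) {
  set.seed(seed)
  rare <- stats::runif(m) < prop_rare
  maf <- numeric(m)
  maf[rare] <- stats::runif(sum(rare), rare_range[1], rare_range[2])
  maf[!rare] <- stats::runif(sum(!rare), common_range[1], common_range[2])
  maf
}

#' Simulate a quantitative trait over a pedigree
#'
#' Trait model: `y = intercept + X beta + G_causal beta_causal + g + e`
#' where `X` holds the five covariates (sex, age, age^2, medication,
#' smoking; age ~ U(20, 80), medication ~ Bern(0.3), smoking ~ Bern(0.25)),
#' `g` is a zero-mean polygenic component with covariance
#' `h2 * sigma2 * (2 * pedigree kinship)` and `e` is independent noise with
#' variance `(1 - h2) * sigma2`. Causal effects, when supplied, act
#' additively on the dosages.
#'
#' @param G Dosage matrix from [gene_drop()] (only needed when `causal` is
#'   given; may be NULL otherwise).
#' @param ped Pedigree table.
#' @param covariate_effects Named vector with entries `sex`, `age`, `age2`,
#'   `med`, `smoke` (any subset; missing entries are 0).
#' @param intercept Trait intercept.
#' @param h2 Narrow-sense heritability of the non-covariate trait variance,
#'   in `[0, 1)`.
#' @param sigma2 Total non-covariate trait variance (> 0).
#' @param causal Optional list with `index` (variant columns of `G`) and
#'   `beta` (same length) giving causal dosage effects.
#' @param seed Integer seed.
#' @return `data.frame` with columns `id`, `trait`, `sex`, `age`, `age2`,
#'   `med`, `smoke`, one row per pedigree member.
#' @export
simulate_phenotype <- function(G = NULL, ped, covariate_effects = NULL,
                               intercept = 110, h2 = 0.3, sigma2 = 225,
                               causal = NULL, seed = 1L) {
  validate_pedigree(ped)
  if (!is.finite(h2) || h2 < 0 || h2 >= 1) stop("h2 must lie in [0, 1)")
  if (!is.finite(sigma2) || sigma2 <= 0) stop("sigma2 must be positive")
  set.seed(seed)
  n <- nrow(ped)
  eff <- c(sex = 0, age = 0, age2 = 0, med = 0, smoke = 0)
  if (!is.null(covariate_effects)) {
    bad <- setdiff(names(covariate_effects), names(eff))
    if (length(bad)) stop("unknown covariates: ", paste(bad, collapse = ", "))
    eff[names(covariate_effects)] <- covariate_effects
  }
  covar <- data.frame(
    sex = ped$sex,
    age = stats::runif(n, 20, 80),
    med = stats::rbinom(n, 1, 0.3),
    smoke = stats::rbinom(n, 1, 0.25)
  )
  covar$age2 <- covar$age^2
  fixed <- intercept +
    as.matrix(covar[, c("sex", "age", "age2", "med", "smoke")]) %*%
    eff[c("sex", "age", "age2", "med", "smoke")]
  genetic <- 0
  if (!is.null(causal) && length(causal$index)) {
    if (is.null(G)) stop("causal effects require the dosage matrix G")
    if (length(causal$beta) != length(causal$index))
      stop("causal index/beta length mismatch")
    genetic <- as.vector(G[ped$id, causal$index, drop = FALSE] %*% causal$beta)
  }
  poly <- if (h2 > 0) polygenic_draw(ped, sqrt(h2 * sigma2)) else 0
  noise <- stats::rnorm(n, 0, sqrt((1 - h2) * sigma2))
  data.frame(
    id = ped$id,
    trait = as.vector(fixed) + genetic + poly + noise,
    sex = covar$sex, age = covar$age, age2 = covar$age2,
    med = covar$med, smoke = covar$smoke,
    stringsAsFactors = FALSE
  )
}

## Draw a polygenic vector with covariance sd^2 * (2 Phi), familywise
## (families are independent blocks).
polygenic_draw <- function(ped, sd) {
  out <- numeric(nrow(ped))
  for (fam in unique(ped$family)) {
    rows <- which(ped$family == fam)
    K2 <- pedigree_expected_kinship(ped[rows, , drop = FALSE])
    L <- chol(K2)
    out[rows] <- sd * as.vector(crossprod(L, stats::rnorm(length(rows))))
  }
  out
}
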