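#' Estimate an empirical kinship (genetic relationship) matrix
#'
#' Two estimators on the 2x-kinship (GRM) scale, computed from dense
#' dosage data after dropping monomorphic variants and variants with folded
#' MAF below `maf_min`:
#' \describe{
#'   \item{BN}{Balding-Nichols / centered-standardized cross-product,
#'     `K_ij = (1/M) sum_m (g_im - 2p_m)(g_jm - 2p_m) / (2 p_m (1 - p_m))`.}
#'   \item{IBS}{average identity-by-state sharing,
#'     `K_ij = (1/M) sum_m (2 - |g_im - g_jm|) / 2`, entries in [0, 1].}
#' }
#'
#' @param G Dosage matrix (individuals x variants, values 0/1/2, complete).
#' @param method `"BN"` (default; covariance-like, suited to GLS) or
#'   `"IBS"`.
#' @param maf_min Folded-MAF filter applied before estimation.
#' @param check_pd If TRUE (default for BN), verify the smallest eigenvalue
#'   exceeds `eig_floor` and fail with advice to review duplicates/twins.
#' @param eig_floor Positive-definiteness floor.
#' @return Object of class `kinship_matrix`: list with `K` (named
#'   symmetric matrix), `method`, `n_variants_used`, `excluded` (ids
#'   removed upstream, recorded by the pipeline) and `ids`.
#' @export
estimate_kinship <- function(G, method = c("BN", "IBS"), maf_min = 0.01,
                             check_pd = NULL, eig_floor = 1e-8) {
  method <- match.arg(method)
  G <- as.matrix(G)
  if (anyNA(G)) stop("missing genotypes are not supported; complete data required")
  if (nrow(G) < 2L) stop("need at least 2 individuals")
  p <- colMeans(G) / 2
  maf <- pmin(p, 1 - p)
  keep <- maf >= maf_min & p > 0 & p < 1
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message(sprintf("kinship: dropped %d variants (monomorphic or MAF < %g)",
                    n_drop, maf_min))
  if (!any(keep)) stop("no variants left after the MAF filter")
  Gk <- G[, keep, drop = FALSE]
  pk <- p[keep]
  M <- ncol(Gk)
  if (method == "BN") {
    Xs <- sweep(sweep(Gk, 2L, 2 * pk, `-`), 2L, sqrt(2 * pk * (1 - pk)), `/`)
    K <- tcrossprod(Xs) / M
  } else {
    D <- ibs_distance_sum(Gk)
    K <- 1 - D / (2 * M)
  }
  K <- (K + t(K)) / 2
  ids <- rownames(G)
  if (is.null(ids)) ids <- sprintf("ind%d", seq_len(nrow(G)))
  dimnames(K) <- list(ids, ids)
  md <- mean(diag(K))
  if (method == "BN" && (md < 0.5 || md > 2))
    warning(sprintf("BN kinship mean diagonal %.3f outside [0.5, 2]; check input", md))
  if (is.null(check_pd)) check_pd <- method == "BN"
  if (check_pd) {
    ## The sample-centered BN estimator always has the all-ones vector in
    ## its null space (rows sum to zero); deflate that structural direction
    ## by adding (1/n) 1 1' before certifying the remaining spectrum, so
    ## the check catches genuine extra degeneracy (twins, duplicates) only.
    n <- nrow(K)
    Kc <- if (method == "BN") K + matrix(1 / n, n, n) else K
    ok <- tryCatch({
      R <- chol(Kc - diag(eig_floor, n))
      min(diag(R))^2 > eig_floor
    }, error = function(e) FALSE)
    if (!ok)
      stop("kinship matrix is numerically singular (smallest non-structural ",
           "eigenvalue <= ", eig_floor,
           "); review identical twins / duplicated samples")
  }
  structure(list(K = K, method = method, n_variants_used = M,
                 excluded = character(), ids = ids),
            class = "kinship_matrix")
}

## sum_m |g_im - g_jm| for all pairs via dosage indicator cross-products.
ibs_distance_sum <- function(G) {
  I0 <- (G == 0) * 1
  I1 <- (G == 1) * 1
  I2 <- (G == 2) * 1
  C01 <- tcrossprod(I0, I1)
  C12 <- tcrossprod(I1, I2)
  C02 <- tcrossprod(I0, I2)
  (C01 + t(C01) + C12 + t(C12)) + 2 * (C02 + t(C02))
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat(sprintf("Empirical kinship matrix (%s), %d individuals, %d variants used\n",
              x$method, length(x$ids), x$n_variants_used))
  if (length(x$excluded))
    cat("Excluded individuals:", paste(x$excluded, collapse = ", "), "\n")
  cat(sprintf("Mean diagonal: %.4f\n", mean(diag(x$K))))
  invisible(x)
}

#' Detect and exclude identical twins / duplicated samples
#'
#' Pairs with genotype concordance at or above `concordance_min` are
#' treated as identical twins and the later member (in input order) of each
#' pair is removed, so the kinship matrix stays nonsingular. A known twin
#' list overrides detection. Concordance is evaluated on a deterministic
#' subsample of at most `max_variants` variants.
#'
#' @param G Dosage matrix (individuals x variants).
#' @param concordance_min Concordance threshold for flagging a pair.
#' @param twin_list Optional list/matrix of id pairs; overrides detection.
#' @param max_variants Subsample size for the concordance scan.
#' @return List with `G` (matrix after exclusions) and `excluded`
#'   (character vector of removed ids, possibly empty).
#' @export
detect_and_exclude_twins <- function(G, concordance_min = 0.99,
                                     twin_list = NULL, max_variants = 1000L) {
  G <- as.matrix(G)
  ids <- rownames(G)
  if (is.null(ids)) stop("genotype matrix must have individual ids as row names")
  if (!is.null(twin_list)) {
    pairs <- if (is.matrix(twin_list)) twin_list else do.call(rbind, twin_list)
    if (ncol(pairs) != 2L) stop("twin_list must contain id pairs")
    miss <- setdiff(as.vector(pairs), ids)
    if (length(miss)) stop("twin ids not in genotypes: ", paste(miss, collapse = ", "))
  } else {
    keep_v <- if (ncol(G) > max_variants)
      round(seq(1, ncol(G), length.out = max_variants)) else seq_len(ncol(G))
    Gs <- G[, keep_v, drop = FALSE]
    conc <- pair_concordance(Gs)
    hits <- which(conc >= concordance_min & upper.tri(conc), arr.ind = TRUE)
    pairs <- cbind(ids[hits[, 1]], ids[hits[, 2]])
  }
  excluded <- character()
  if (NROW(pairs) > 0) {
    for (k in seq_len(nrow(pairs))) {
      i <- match(pairs[k, 1], ids)
      j <- match(pairs[k, 2], ids)
      drop_id <- ids[max(i, j)]          # the later one in input order
      if (!(pairs[k, 1] %in% excluded || pairs[k, 2] %in% excluded))
        excluded <- c(excluded, drop_id)
    }
  }
  list(G = G[!ids %in% excluded, , drop = FALSE], excluded = excluded)
}

## Pairwise fraction of identical dosages, via indicator cross-products.
pair_concordance <- function(G) {
  m <- ncol(G)
  eq <- tcrossprod((G == 0) * 1) + tcrossprod((G == 1) * 1) +
    tcrossprod((G == 2) * 1)
  eq / m
}

#' Expected kinship from pedigree structure
#'
#' The standard recursive (tabular) kinship algorithm on the declared
#' pedigree, returned on the 2x-kinship scale so the diagonal of a
#' non-inbred individual is 1 and full sibs / parent-offspring pairs are
#' 0.5 — directly comparable to the BN estimate. Founders (and unlisted
#' married-in parents) are treated as unrelated and non-inbred.
#'
#' @param ped Pedigree table ([build_pedigrees()]).
#' @return Symmetric matrix (individuals x individuals) with id dimnames.
#' @export
pedigree_expected_kinship <- function(ped) {
  validate_pedigree(ped)
  n <- nrow(ped)
  fa <- match(ped$father, ped$id)
  mo <- match(ped$mother, ped$id)
  ord <- order(ped$generation)
  Phi <- matrix(0, n, n)
  done <- logical(n)
  for (i in ord) {
    prev <- which(done)
    phi_f <- if (!is.na(fa[i])) Phi[fa[i], prev] else numeric(length(prev))
    phi_m <- if (!is.na(mo[i])) Phi[mo[i], prev] else numeric(length(prev))
    if (length(prev)) {
      Phi[i, prev] <- 0.5 * (phi_f + phi_m)
      Phi[prev, i] <- Phi[i, prev]
    }
    inb <- if (!is.na(fa[i]) && !is.na(mo[i])) Phi[fa[i], mo[i]] else 0
    Phi[i, i] <- 0.5 * (1 + inb)
    done[i] <- TRUE
  }
  K2 <- 2 * Phi
  dimnames(K2) <- list(ped$id, ped$id)
  K2
}
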