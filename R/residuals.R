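#' Select a mutually unrelated subset of individuals
#'
#' If a curated list is supplied (as in studies where the organizers
#' distribute one) it is validated and returned verbatim. Otherwise a
#' greedy independent-set heuristic is applied to the relatedness graph
#' whose edges are kinship entries above `threshold`: repeatedly keep the
#' individual with the fewest remaining relatedness edges (ties broken by
#' input order) and drop its neighbours.
#'
#' @param kinship A `kinship_matrix` or plain symmetric matrix with id
#'   dimnames.
#' @param threshold Relatedness cut on the estimated-kinship (GRM) scale;
#'   0.10 separates third-degree relatives from estimation noise.
#' @param provided_list Optional character vector of ids, returned after
#'   membership validation.
#' @return Character vector of unrelated ids, in input order; no retained
#'   pair has a kinship entry above `threshold`.
#' @export
select_unrelated <- function(kinship, threshold = 0.10, provided_list = NULL) {
  K <- if (inherits(kinship, "kinship_matrix")) kinship$K else as.matrix(kinship)
  ids <- rownames(K)
  if (is.null(ids)) stop("kinship matrix must carry individual ids")
  if (!is.null(provided_list)) {
    miss <- setdiff(provided_list, ids)
    if (length(miss))
      stop("provided unrelated ids not in kinship: ", paste(miss, collapse = ", "))
    return(provided_list)
  }
  A <- K > threshold
  diag(A) <- FALSE
  active <- rep(TRUE, nrow(K))
  keep <- logical(nrow(K))
  while (any(active)) {
    deg <- rowSums(A[, active, drop = FALSE]) * active
    deg[!active] <- Inf
    i <- which.min(deg)                 # which.min takes the first tie
    keep[i] <- TRUE
    active[i] <- FALSE
    active[A[i, ]] <- FALSE
  }
  ids[keep]
}

#' Fit the covariate model on the unrelated subset
#'
#' Ordinary least squares of the trait on the five standard covariates
#' (sex, age, age^2, medication use, smoking), restricted to the unrelated
#' individuals so family correlation cannot bias the fit. No ancestry or
#' principal-component covariates are included: the downstream kinship
#' decorrelation absorbs population and family structure.
#'
#' @param phenotypes Phenotype table with columns `id`, `trait` and the
#'   covariates (`age2` is built from `age` when absent).
#' @param unrelated Character vector of ids to fit on.
#' @param covariates Covariate column names (default the five standard
#'   ones).
#' @return Object of class `covariate_model` wrapping the `lm` fit, with
#'   `coefficients`, `covariates` and `n_unrelated`.
#' @export
fit_covariate_model <- function(phenotypes,
                                unrelated,
                                covariates = c("sex", "age", "age2", "med", "smoke")) {
  phenotypes <- add_age2(phenotypes, covariates)
  miss <- setdiff(c("id", "trait", covariates), names(phenotypes))
  if (length(miss)) stop("phenotype table lacks columns: ", paste(miss, collapse = ", "))
  sub <- phenotypes[phenotypes$id %in% unrelated, , drop = FALSE]
  if (nrow(sub) < length(covariates) + 2L)
    stop("too few unrelated individuals (", nrow(sub), ") to fit ",
         length(covariates), " covariates")
  form <- stats::reformulate(covariates, response = "trait")
  X <- stats::model.matrix(form, sub)
  if (qr(X)$rank < ncol(X)) {
    ## name the offending columns for the user
    qx <- qr(X)
    bad <- colnames(X)[qx$pivot[seq(qx$rank + 1L, ncol(X))]]
    stop("covariate matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm(form, data = sub)
  structure(list(fit = fit, coefficients = stats::coef(fit),
                 covariates = covariates, n_unrelated = nrow(sub)),
            class = "covariate_model")
}

#' @export
print.covariate_model <- function(x, ...) {
  cat("Covariate model (OLS on", x$n_unrelated, "unrelated individuals)\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.covariate_model <- function(object, ...) object$coefficients

#' Project the covariate model to all individuals
#'
#' Residual = observed trait minus the prediction of the unrelated-subset
#' model, computed for every individual, related ones included. This is a
#' projection of fixed coefficients, not a re-fit.
#'
#' @param model A `covariate_model`.
#' @param phenotypes Phenotype table covering all analysis individuals.
#' @return Named numeric vector of residuals (names = ids, input order).
#' @export
project_residuals <- function(model, phenotypes) {
  stopifnot(inherits(model, "covariate_model"))
  phenotypes <- add_age2(phenotypes, model$covariates)
  need <- c("id", "trait", model$covariates)
  miss <- setdiff(need, names(phenotypes))
  if (length(miss)) stop("phenotype table lacks columns: ", paste(miss, collapse = ", "))
  cc <- stats::complete.cases(phenotypes[, need])
  if (!all(cc))
    stop("missing trait/covariates for individuals: ",
         paste(utils::head(phenotypes$id[!cc], 10), collapse = ", "))
  pred <- stats::predict(model$fit, newdata = phenotypes)
  res <- phenotypes$trait - as.vector(pred)
  names(res) <- phenotypes$id
  res
}

add_age2 <- function(phenotypes, covariates) {
  if ("age2" %in% covariates && !"age2" %in% names(phenotypes) &&
      "age" %in% names(phenotypes))
    phenotypes$age2 <- phenotypes$age^2
  phenotypes
}
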