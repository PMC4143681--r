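# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small except where a check's precision demands otherwise.

tiny_config <- function(...) {
  sim_config(n_families = 15, n_null_genes = 30, n_background_variants = 1500,
             seed = 101, ...)
}

# A small decorrelated dataset with iid-normal transformed phenotype,
# suitable for direct skat_o calls.
white_region <- function(n = 200, m = 12, seed = 1) {
  set.seed(seed)
  maf <- runif(m, 0.02, 0.4)
  G <- matrix(rbinom(n * m, 2, rep(maf, each = n)), n, m)
  keep <- colSums(G) > 0 & colSums(G) < 2 * n
  G <- G[, keep, drop = FALSE]
  p <- colMeans(G) / 2
  list(G = G, y = rnorm(n), i = rep(1, n), maf = pmin(p, 1 - p))
}

# Hand-built 5-member nuclear family pedigree (two founders, three sibs).
nuclear_ped <- function() {
  data.frame(
    id = c("dad", "mum", "s1", "s2", "s3"),
    family = "fam1",
    father = c(NA, NA, "dad", "dad", "dad"),
    mother = c(NA, NA, "mum", "mum", "mum"),
    sex = c(1, 2, 1, 2, 1),
    generation = c(0, 0, 1, 1, 1),
    stringsAsFactors = FALSE
  )
}
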