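test_that("the BN entry matches a hand evaluation", {
  ## two individuals, two variants, dosages (0,2) and (2,0): p = 0.5 each,
  ## standardized entries +/- sqrt(2), K = [[2, -2], [-2, 2]]
  G <- rbind(ind1 = c(0L, 2L), ind2 = c(2L, 0L))
  k <- estimate_kinship(G, method = "BN", check_pd = FALSE)
  expect_equal(unname(k$K), matrix(c(2, -2, -2, 2), 2), tolerance = 1e-12)
  expect_equal(k$n_variants_used, 2L)
})

test_that("duplicate individuals give identical kinship entries", {
  set.seed(5)
  G <- matrix(rbinom(40 * 60, 2, 0.3), 40, 60)
  G[2, ] <- G[1, ]
  rownames(G) <- sprintf("i%02d", 1:40)
  k <- estimate_kinship(G, check_pd = FALSE)
  expect_equal(k$K[1, 1], k$K[1, 2], tolerance = 1e-12)
  expect_equal(k$K[2, 2], k$K[1, 2], tolerance = 1e-12)
  ## and make the PD certification fail, as twins must
  expect_error(estimate_kinship(G, check_pd = TRUE), "singular")
})

test_that("variants below the MAF filter contribute nothing", {
  set.seed(6)
  n <- 200
  G <- cbind(
    common = rbinom(n, 2, 0.3),
    rare = c(rep(1L, 2), rep(0L, n - 2))   # sample MAF 0.005 < 0.01
  )
  rownames(G) <- sprintf("i%03d", seq_len(n))
  expect_message(k <- estimate_kinship(G, check_pd = FALSE), "dropped 1")
  expect_equal(k$n_variants_used, 1L)
  ## monomorphic variants are dropped too, not divided by zero
  G2 <- cbind(G, mono = rep(0L, n))
  expect_message(k2 <- estimate_kinship(G2, check_pd = FALSE), "dropped 2")
  expect_equal(k2$n_variants_used, 1L)
  expect_error(estimate_kinship(G[, 2, drop = FALSE], check_pd = FALSE),
               "no variants")
  G[3, 1] <- NA
  expect_error(estimate_kinship(G), "missing")
})

test_that("IBS entries are exact sharing fractions in [0, 1]", {
  G <- rbind(a = c(0L, 1L, 2L, 2L), b = c(2L, 1L, 2L, 0L),
             c = c(1L, 1L, 1L, 1L))
  k <- estimate_kinship(G, method = "IBS", maf_min = 0)
  expect_true(all(k$K >= 0 & k$K <= 1))
  expect_equal(unname(diag(k$K)), rep(1, 3))
  ## pair (a, b): |0-2|+|1-1|+|2-2|+|2-0| = 4 over 2M = 8
  expect_equal(k$K["a", "b"], 1 - 4 / 8)
  expect_equal(k$K["a", "c"], 1 - 3 / 8)
})

test_that("permuting individuals permutes the kinship consistently", {
  set.seed(8)
  G <- matrix(rbinom(30 * 80, 2, 0.25), 30, 80)
  rownames(G) <- sprintf("i%02d", 1:30)
  k1 <- estimate_kinship(G, check_pd = FALSE)
  perm <- sample(30)
  k2 <- estimate_kinship(G[perm, ], check_pd = FALSE)
  expect_equal(k2$K, k1$K[perm, perm], tolerance = 1e-12)
})

test_that("twin detection flags near-duplicates and keeps earlier members", {
  set.seed(9)
  G <- matrix(rbinom(30 * 400, 2, 0.3), 30, 400)
  rownames(G) <- sprintf("i%02d", 1:30)
  none <- detect_and_exclude_twins(G)
  expect_identical(none$G, G)
  expect_length(none$excluded, 0)
  ## inject two identical pairs: the later id of each pair goes
  G[5, ] <- G[2, ]
  G[20, ] <- G[11, ]
  two <- detect_and_exclude_twins(G)
  expect_setequal(two$excluded, c("i05", "i20"))
  expect_equal(nrow(two$G), 28)
  ## 95% concordance stays below a 0.99 threshold
  G2 <- G[1:10, ]
  G2[2, ] <- G2[1, ]
  flip <- seq(1, 400, by = 20)
  G2[2, flip] <- 2L - G2[2, flip]
  res <- detect_and_exclude_twins(G2, concordance_min = 0.99)
  expect_false("i02" %in% res$excluded)
  ## a provided twin list overrides detection
  lst <- detect_and_exclude_twins(G, twin_list = rbind(c("i03", "i07")))
  expect_identical(lst$excluded, "i07")
  expect_error(detect_and_exclude_twins(G, twin_list = rbind(c("i03", "zz"))),
               "not in genotypes")
})

test_that("pedigree-expected kinship reproduces textbook coefficients", {
  ped <- nuclear_ped()
  K2 <- pedigree_expected_kinship(ped)
  expect_equal(unname(diag(K2)), rep(1, 5))
  expect_equal(K2["dad", "mum"], 0)
  expect_equal(K2["dad", "s1"], 0.5)     # parent-offspring
  expect_equal(K2["s1", "s2"], 0.5)      # full sibs
  ## template family: grandchild-grandparent 0.25, grandchild via one
  ## listed parent only; cousins through sibs are 0.125
  tpl <- build_pedigrees(1)
  K2t <- pedigree_expected_kinship(tpl)
  expect_equal(unname(K2t["F001_I01", "F001_I07"]), 0.25)
  expect_equal(unname(K2t["F001_I07", "F001_I08"]), 0.125)
  ## an inbred child of full sibs has diagonal 1.25
  inb <- rbind(nuclear_ped(),
               data.frame(id = "k", family = "fam1", father = "s1",
                          mother = "s2", sex = 1, generation = 2))
  expect_equal(unname(pedigree_expected_kinship(inb)["k", "k"]), 1.25)
})
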