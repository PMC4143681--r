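test_that("the default template yields 10 members and 2 founders per family", {
  ped <- build_pedigrees(1)
  expect_equal(nrow(ped), 10)
  expect_equal(sum(is.na(ped$father) & is.na(ped$mother)), 2)
  expect_equal(sort(unique(ped$generation)), c(0, 1, 2))
  ped85 <- build_pedigrees(85)
  expect_equal(nrow(ped85), 850)
  expect_silent(validate_pedigree(ped85))
  expect_error(build_pedigrees(1, template = "nope"), "unknown")
})

test_that("pedigree invariants are enforced", {
  bad <- nuclear_ped()
  bad$father[3] <- "s2"                # parent from the same generation
  expect_error(validate_pedigree(bad), "earlier generation")
  bad2 <- nuclear_ped()
  bad2$father[3] <- "ghost"
  expect_error(validate_pedigree(bad2), "missing")
})

test_that("gene drop is Mendelian-consistent and reproducible", {
  ped <- nuclear_ped()
  maf <- c(0.5, 0.2, 0.05)
  G1 <- gene_drop(ped, maf, seed = 4)
  G2 <- gene_drop(ped, maf, seed = 4)
  expect_identical(G1, G2)
  expect_true(all(G1 %in% 0:2))
  ## exhaustive trio legality over many draws
  legal <- list("00" = 0, "01" = 0:1, "02" = 1, "11" = 0:2, "12" = 1:2,
                "22" = 2)
  for (seed in 1:25) {
    G <- gene_drop(ped, runif(20, 0.05, 0.5), seed = seed)
    for (child in c("s1", "s2", "s3")) {
      key <- paste0(pmin(G["dad", ], G["mum", ]), pmax(G["dad", ], G["mum", ]))
      ok <- vapply(seq_along(key), function(j)
        G[child, j] %in% legal[[key[j]]], TRUE)
      expect_true(all(ok))
    }
  }
  expect_error(gene_drop(ped, c(0.2, 0.7)), "0, 0.5")
  expect_error(gene_drop(ped, c(0.2, 0)), "0, 0.5")
})

test_that("homozygous parents force offspring dosage", {
  ped <- nuclear_ped()
  for (seed in 1:40) {
    G <- gene_drop(ped, rep(0.5, 8), seed = seed)
    both0 <- G["dad", ] == 0 & G["mum", ] == 0
    both2 <- G["dad", ] == 2 & G["mum", ] == 2
    for (child in c("s1", "s2", "s3")) {
      expect_true(all(G[child, both0] == 0))
      expect_true(all(G[child, both2] == 2))
    }
  }
})

test_that("founder allele frequency matches the binomial draw", {
  ## 10,000 founders: 5,000 template families contribute 2 founders each
  ped <- build_pedigrees(5000)
  founders <- ped$id[is.na(ped$father) & is.na(ped$mother)]
  G <- gene_drop(ped, 0.3, seed = 11)
  af <- mean(G[founders, 1]) / 2
  se <- sqrt(0.3 * 0.7 / (2 * length(founders)))
  expect_lt(abs(af - 0.3), 3 * se)
})

test_that("sib-pair trait correlation tracks h2 / 2", {
  ped <- build_pedigrees(350)          # 6 sib pairs per family
  sibs <- subset(ped, generation == 1)
  pairs <- do.call(rbind, lapply(split(sibs$id, sibs$family), function(ids)
    t(combn(ids, 2))))
  ## h2 = 0.6, no covariate effects: expected correlation 0.6 * 0.5 = 0.3
  ph <- simulate_phenotype(NULL, ped, covariate_effects = c(age = 0),
                           h2 = 0.6, sigma2 = 100, seed = 21)
  tr <- setNames(ph$trait, ph$id)
  r <- cor(tr[pairs[, 1]], tr[pairs[, 2]])
  expect_lt(abs(r - 0.3), 3 / sqrt(nrow(pairs)) + 0.02)
  ## h2 = 0: relatives uncorrelated
  ph0 <- simulate_phenotype(NULL, ped, covariate_effects = c(age = 0),
                            h2 = 0, sigma2 = 100, seed = 22)
  tr0 <- setNames(ph0$trait, ph0$id)
  r0 <- cor(tr0[pairs[, 1]], tr0[pairs[, 2]])
  expect_lt(abs(r0), 3 / sqrt(nrow(pairs)))
})

test_that("OLS on simulated unrelateds recovers a covariate effect", {
  ped <- build_pedigrees(500)          # h2 = 0 makes all traits independent
  ph <- simulate_phenotype(NULL, ped, covariate_effects = c(age = 0.5),
                           h2 = 0, sigma2 = 25, seed = 31)
  fit <- lm(trait ~ sex + age + age2 + med + smoke, data = ph)
  est <- coef(summary(fit))["age", ]
  expect_lt(abs(est["Estimate"] - 0.5), 3 * est["Std. Error"])
})

test_that("phenotype simulation validates its variance parameters", {
  ped <- nuclear_ped()
  expect_error(simulate_phenotype(NULL, ped, h2 = 1), "0, 1")
  expect_error(simulate_phenotype(NULL, ped, h2 = -0.1), "0, 1")
  expect_error(simulate_phenotype(NULL, ped, sigma2 = 0), "positive")
  expect_error(simulate_phenotype(NULL, ped,
                                  covariate_effects = c(height = 1)),
               "unknown covariates")
})

test_that("the founder MAF spectrum honours its ranges and proportions", {
  maf <- draw_founder_mafs(20000, seed = 3)
  expect_true(all(maf > 0 & maf <= 0.5))
  frac_rare <- mean(maf < 0.01)
  expect_lt(abs(frac_rare - 0.8), 0.02)
})
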