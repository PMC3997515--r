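test_that("effects and deviance are exact on crafted profiles", {
  # perfectly additive: control -1, A 0, B 0, both +1
  m <- make_matrix(rbind(c(-1, 0, 0, 1)))
  eff <- compute_effects(m, make_design())
  expect_equal(eff$e_A, 1)
  expect_equal(eff$e_B, 1)
  expect_equal(eff$e_AB, 2)
  expect_equal(eff$delta, 0)
  expect_equal(eff$deviance, 0)

  # pure interaction: only the combination responds
  m2 <- make_matrix(rbind(c(0, 0, 0, 2)))
  eff2 <- compute_effects(m2, make_design())
  expect_equal(eff2$delta, 2)
  expect_equal(eff2$deviance, 4)
  expect_equal(classify_direction(eff2), "positive")
})

test_that("delta equals the interaction contrast and is label-symmetric", {
  z <- rand_matrix(40, seed = 71)
  d <- make_design()
  eff <- compute_effects(z, d)
  tr <- d$treatment
  contrast <- rowMeans(z[, tr == "both"]) - rowMeans(z[, tr == "sigA"]) -
    rowMeans(z[, tr == "sigB"]) + rowMeans(z[, tr == "control"])
  expect_equal(eff$delta, unname(contrast), tolerance = 1e-12)

  # exchanging the two signals leaves the deviance unchanged
  d_swap <- d
  d_swap$treatment <- c(sigA = "sigB", sigB = "sigA", control = "control",
                        both = "both")[as.character(d$treatment)]
  eff_swap <- compute_effects(z, d_swap)
  expect_equal(eff_swap$deviance, eff$deviance, tolerance = 1e-12)
})

test_that("permutation p-values respect the add-one floor and tie convention", {
  z <- per_gene_standardize(rand_matrix(30, seed = 81))
  d <- make_design()
  p_pg <- permutation_pvalues(z, d, B = 99, mode = "per_gene", seed = 1)
  expect_true(all(p_pg >= 1 / 100 & p_pg <= 1))
  p_pool <- permutation_pvalues(z, d, B = 99, mode = "pooled", seed = 1)
  expect_true(all(p_pool >= 1 / (30 * 99 + 1) & p_pool <= 1))

  # a constant (all-equal) row has D = 0 and all D* = 0: p = 1 under ">="
  z2 <- rbind(z, g_const = 0)
  p2 <- permutation_pvalues(z2, d, B = 50, mode = "per_gene", seed = 2)
  expect_equal(unname(p2["g_const"]), 1)
})

test_that("permutation p-values are reproducible and seed-isolated", {
  z <- per_gene_standardize(rand_matrix(20, seed = 91))
  d <- make_design()
  p1 <- permutation_pvalues(z, d, B = 200, mode = "pooled", seed = 7)
  p2 <- permutation_pvalues(z, d, B = 200, mode = "pooled", seed = 7)
  expect_identical(as.vector(p1), as.vector(p2))
  p3 <- permutation_pvalues(z, d, B = 200, mode = "pooled", seed = 8)
  expect_false(identical(as.vector(p1), as.vector(p3)))
})

test_that("p-values are invariant to positive affine rescaling of raw rows", {
  m <- rand_matrix(15, seed = 95)
  d <- make_design()
  a <- runif(15, 0.2, 4)
  b <- rnorm(15, 0, 3)
  p1 <- permutation_pvalues(per_gene_standardize(m), d, B = 150,
                            mode = "per_gene", seed = 5)
  p2 <- permutation_pvalues(per_gene_standardize(a * m + b), d, B = 150,
                            mode = "per_gene", seed = 5)
  expect_equal(as.vector(p1), as.vector(p2), tolerance = 1e-12)
})

test_that("exact enumeration matches brute-force label permutation", {
  # 8 samples -> 8!/(2!)^4 = 2520 distinct assignments
  z <- per_gene_standardize(rand_matrix(4, seed = 101))
  d <- make_design()
  p_exact <- permutation_pvalues(z, d, mode = "exact_per_gene")
  expect_equal(attr(p_exact, "B_effective"), 2520)

  # independent oracle: enumerate all 8! = 40320 position permutations of
  # the weight vector (each distinct assignment appears (2!)^4 = 16 times)
  tr <- d$treatment
  w <- (tr == "both") / 2 - (tr == "sigA") / 2 - (tr == "sigB") / 2 +
    (tr == "control") / 2
  perms <- all_perms(seq_len(8))
  W <- t(vapply(perms, function(pp) w[pp], numeric(8)))
  for (g in seq_len(nrow(z))) {
    Dg <- sum(w * z[g, ])^2
    Dstar <- as.vector(W %*% z[g, ])^2
    oracle <- mean(Dstar >= Dg - 1e-9 * (1 + Dg))
    expect_equal(unname(p_exact[g]), oracle, tolerance = 1e-12)
  }

  # the identity assignment is always counted: p >= 1/2520, and the
  # {control, both} self-mapping tie class makes the true floor 72/2520
  expect_true(all(p_exact >= 72 / 2520 - 1e-12))
})

test_that("exact enumeration refuses designs with more than 12 samples", {
  z <- per_gene_standardize(rand_matrix(3, r = 4, seed = 1))
  expect_error(permutation_pvalues(z, make_design(4), mode = "exact_per_gene"),
               "refused")
})

test_that("Holm adjustment matches the hand-applied step-down oracle", {
  expect_equal(holm_adjust(c(0.001, 0.01, 0.04)), c(0.003, 0.02, 0.04))
  expect_equal(holm_adjust(rep(1, 4)), rep(1, 4))
  expect_equal(holm_adjust(0.3), 0.3)
  expect_error(holm_adjust(c(0.2, 1.5)), "\\[0, 1\\]")
})

test_that("Holm is at least as conservative as BH on random vectors", {
  set.seed(111)
  for (i in 1:20) {
    p <- runif(sample(2:50, 1))
    expect_true(all(holm_adjust(p) >= bh_fdr(p) - 1e-12))
  }
})

test_that("direction classification follows the sign of delta", {
  expect_equal(classify_direction(c(2, -0.5, 0)),
               c("positive", "negative", NA))
})

test_that("enrichment test boundaries and errors behave", {
  e0 <- enrichment_test(0, 10, 0.05)
  expect_equal(e0$estimate, 0)
  expect_equal(e0$ci_low, 0)
  en <- enrichment_test(10, 10, 0.05)
  expect_equal(en$ci_high, 1)
  expect_error(enrichment_test(11, 10, 0.05), "\\[0, n\\]")
  expect_error(enrichment_test(1, 10, 0), "p0")
  expect_error(enrichment_test(1, 10, 1), "p0")
})

test_that("enrichment test agrees with binom.test on a grid", {
  for (n in c(10, 50, 264)) {
    for (x in unique(pmin(n, c(0, 1, 3, round(n * 0.1), n)))) {
      mine_g <- enrichment_test(x, n, 0.05, alternative = "greater")
      ref_g <- binom.test(x, n, 0.05, alternative = "greater")
      expect_equal(mine_g$p_value, ref_g$p.value, tolerance = 1e-12)
      mine_2 <- enrichment_test(x, n, 0.05, alternative = "two.sided")
      ref_2 <- binom.test(x, n, 0.05, alternative = "two.sided")
      expect_equal(mine_2$p_value, ref_2$p.value, tolerance = 1e-12)
      # Clopper-Pearson interval (binom.test's two-sided CI)
      expect_equal(c(mine_g$ci_low, mine_g$ci_high),
                   ref_2$conf.int[1:2], tolerance = 1e-12)
    }
  }
})

test_that("null permutation p-values are approximately uniform (pooled)", {
  d <- generate_dataset(simulation_params(n_genes = 200, frac_regulated = 0,
                                          array_distortion = FALSE, seed = 121))
  z <- per_gene_standardize(d$expression)
  p <- permutation_pvalues(z, d$design, B = 500, mode = "pooled", seed = 3)
  frac <- mean(p < 0.05)
  # binomial 99.9% band around 0.05 for 200 genes (genes are not fully
  # independent of the pool, so the band is generous)
  expect_gt(frac, 0.005)
  expect_lt(frac, 0.13)
  expect_gt(ks.test(as.vector(p), "punif")$p.value, 0.001)
})

test_that("synergy_test warns when B cannot resolve the Holm threshold", {
  z <- per_gene_standardize(rand_matrix(50, seed = 131))
  d <- make_design()
  expect_warning(
    synergy_test(z, d, B = 100, mode = "per_gene", seed = 1),
    "resolution too coarse")
  expect_silent(
    res <- synergy_test(z, d, B = 100, mode = "pooled", seed = 1))
  expect_equal(nrow(res$table), 50L)
  expect_true(all(res$table$p_holm >= res$table$p_perm))
  expect_true(all(res$table$flagged == (res$table$p_holm < 0.05)))
  expect_equal(res$enrichment$x, sum(res$table$p_perm < 0.05))
})

test_that("stronger planted interactions earn smaller permutation p-values", {
  d <- make_design()
  tr <- d$treatment
  frac_small <- sapply(c(0, 3, 8), function(snr) {
    set.seed(200 + snr)
    G <- 120
    m <- rand_matrix(G, sd = 0.3, seed = 300 + snr)
    # detectable interaction geometry: singles repress, combination activates
    planted <- 1:40
    eff <- outer(rep(snr * 0.3, 40), as.numeric(tr == "both")) -
      outer(rep(snr * 0.15, 40), as.numeric(tr %in% c("sigA", "sigB")))
    m[planted, ] <- m[planted, ] + eff
    z <- per_gene_standardize(m)
    p <- permutation_pvalues(z, d, B = 400, mode = "pooled", seed = 17)
    mean(p[planted] < 0.05)
  })
  expect_true(all(diff(frac_small) >= 0))
  expect_lt(frac_small[1], 0.2)
  expect_gt(frac_small[3], 0.8)
})
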