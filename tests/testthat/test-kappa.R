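test_that("weighted kappa: agreement, independence and degenerate margins", {
  expect_equal(weighted_kappa(10, 0, 0, 10), 1)
  for (r in c(0, 0.25, 0.5, 1)) {
    expect_equal(weighted_kappa(5, 5, 5, 5, r = r), 0)
  }
  # degenerate margin: everyone split-positive
  expect_equal(weighted_kappa(3, 7, 0, 0), 0)
  expect_error(weighted_kappa(-1, 2, 3, 4), class = "pedsda_domain_error")
  expect_error(weighted_kappa(1, 1, 1, 1, r = 1.5), class = "pedsda_domain_error")
})

test_that("kappa(0.5) equals Cohen's kappa; kappa(1)/kappa(0) equal the quality indices", {
  expect_equal(weighted_kappa(20, 5, 10, 65), oracle_cohen_kappa(20, 5, 10, 65))
  withr::with_seed(101, {
    for (k in 1:200) {
      tab <- random_2x2()
      a <- tab[1]; b <- tab[2]; c <- tab[3]; d <- tab[4]
      n <- sum(tab)
      expect_equal(weighted_kappa(a, b, c, d, r = 0.5),
                   oracle_cohen_kappa(a, b, c, d), tolerance = 1e-12)
      P <- (a + c) / n; Q <- (a + b) / n
      if (a + c > 0 && Q < 1 && P > 0) {
        SE <- a / (a + c)
        expect_equal(weighted_kappa(a, b, c, d, r = 1), (SE - Q) / (1 - Q),
                     tolerance = 1e-12)
      }
      if (b + d > 0 && Q > 0 && P < 1) {
        SP <- d / (b + d)
        expect_equal(weighted_kappa(a, b, c, d, r = 0), (SP - (1 - Q)) / Q,
                     tolerance = 1e-12)
      }
      # sign follows the cross-product difference
      if (P > 0 && P < 1 && Q > 0 && Q < 1) {
        expect_equal(sign(weighted_kappa(a, b, c, d)), sign(a * d - b * c))
      }
    }
  })
})

test_that("kappa confidence interval: sign behaviour and bootstrap agreement", {
  expect_gt(kappa_confidence_interval(50, 0, 0, 50)[["lower"]], 0)
  ci0 <- kappa_confidence_interval(25, 25, 25, 25)
  expect_lt(ci0[["lower"]], 0)
  expect_gt(ci0[["upper"]], 0)
  expect_error(kappa_confidence_interval(1, 0, 0, 0), class = "pedsda_domain_error")

  # asymptotic interval at r = 0.5 vs a 10^4-resample bootstrap oracle
  ci <- kappa_confidence_interval(20, 5, 10, 65)
  boot <- withr::with_seed(2024, {
    draws <- rmultinom(1e4, 100, c(20, 5, 10, 65) / 100)
    ks <- apply(draws, 2, function(t) oracle_cohen_kappa(t[1], t[2], t[3], t[4]))
    quantile(ks, c(0.025, 0.975), names = FALSE)
  })
  expect_lt(abs(ci[["lower"]] - boot[1]), 0.02)
  expect_lt(abs(ci[["upper"]] - boot[2]), 0.02)

  # asymptotic se matches the independently coded variance formula
  withr::with_seed(5, {
    for (k in 1:50) {
      tab <- random_2x2()
      expect_equal(pedsda:::kappa_se_fce(tab[1], tab[2], tab[3], tab[4]),
                   sqrt(max(oracle_kappa_var(tab[1], tab[2], tab[3], tab[4]), 0)),
                   tolerance = 1e-12)
    }
  })
})

test_that("bootstrap interval for r != 0.5 is seeded, reproducible and clipped", {
  ci1 <- kappa_confidence_interval(20, 5, 10, 65, r = 0.8)
  ci2 <- kappa_confidence_interval(20, 5, 10, 65, r = 0.8)
  expect_identical(ci1, ci2)
  expect_gte(ci1[["lower"]], -1)
  expect_lte(ci1[["upper"]], 1)
  expect_true(ci1[["lower"]] <= weighted_kappa(20, 5, 10, 65, r = 0.8))
})

test_that("chi-square test: independence, strong association, and summation oracle", {
  ind <- chi_square_test(25, 25, 25, 25)
  expect_equal(ind$statistic, 0)
  expect_equal(ind$p_value, 1)
  # stratum-by-severity table: 75/229 vs 31/316 severe
  strong <- chi_square_test(75, 154, 31, 285)
  expect_lt(strong$p_value, 0.0001)
  expect_equal(chi_square_test(20, 5, 10, 65)$statistic,
               oracle_chi2(20, 5, 10, 65), tolerance = 1e-12)
  # zero-margin tables are defined, not errors
  z <- chi_square_test(0, 0, 5, 5)
  expect_equal(z$statistic, 0)
  expect_equal(z$p_value, 1)
  withr::with_seed(303, {
    for (k in 1:100) {
      tab <- random_2x2()
      got <- chi_square_test(tab[1], tab[2], tab[3], tab[4])
      expect_equal(got$statistic, oracle_chi2(tab[1], tab[2], tab[3], tab[4]),
                   tolerance = 1e-12)
      m <- matrix(tab, 2, byrow = TRUE)
      if (all(rowSums(m) > 0) && all(colSums(m) > 0)) {
        ref <- suppressWarnings(chisq.test(m, correct = FALSE))
        expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
        expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
      }
    }
  })
})
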