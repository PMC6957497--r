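test_that("haploid transitions: identity at d = 0, stationary at large d", {
  expect_equal(haploid_transition(0, 8, 0.8), diag(2), ignore_attr = TRUE)
  far <- haploid_transition(1e3, 8, 0.7)
  expect_equal(far[1, ], c(`0` = 0.3, `1` = 0.7))
  expect_equal(far[2, ], c(`0` = 0.3, `1` = 0.7))
})

test_that("haploid diagonal entry matches the closed form at d=0.02, tau=8", {
  h <- haploid_transition(0.02, 8, 0.8)
  expect_equal(h[2, 2], exp(-0.16) + 0.8 * (1 - exp(-0.16)), tolerance = 1e-12)
  expect_equal(h[2, 2], 0.970429, tolerance = 1e-6)
  expect_error(haploid_transition(-0.1, 8, 0.8), "nonnegative")
})

test_that("transition matrices are row-stochastic with the right stationaries", {
  for (d in c(0, 1e-4, 0.02, 0.3, 50)) {
    for (lamb in c(0.2, 0.5, 0.8)) {
      h <- haploid_transition(d, 8, lamb)
      m <- diploid_transition(d, 8, lamb)
      expect_equal(rowSums(h), c(`0` = 1, `1` = 1), tolerance = 1e-12)
      expect_equal(rowSums(m), c(`0` = 1, `1` = 1, `2` = 1), tolerance = 1e-12)
      expect_true(all(h >= 0) && all(m >= 0))
      expect_equal(as.numeric(c(1 - lamb, lamb) %*% h), c(1 - lamb, lamb),
                   tolerance = 1e-12)
      expect_equal(as.numeric(dbinom(0:2, 2, lamb) %*% m),
                   dbinom(0:2, 2, lamb), tolerance = 1e-10)
    }
  }
})

test_that("diploid 0->2 requires both haplotypes to switch", {
  d <- 0.05; tau <- 8; lamb <- 0.7
  m <- diploid_transition(d, tau, lamb)
  expect_equal(m[1, 3], ((1 - exp(-d * tau)) * lamb)^2, tolerance = 1e-12)
  expect_equal(diploid_transition(0, tau, lamb), diag(3), ignore_attr = TRUE)
})

test_that("diploid transitions equal brute-force ordered-pair composition", {
  d <- 0.013; tau <- 6; lamb <- 0.55
  h <- haploid_transition(d, tau, lamb)
  pairs <- list(c(0, 0), c(0, 1), c(1, 1))
  for (x in 0:2) {
    p <- pairs[[x + 1]]
    for (y in 0:2) {
      brute <- 0
      for (a in 0:1) for (b in 0:1) {
        if (a + b == y) brute <- brute + h[p[1] + 1, a + 1] * h[p[2] + 1, b + 1]
      }
      expect_equal(diploid_transition(d, tau, lamb)[x + 1, y + 1], brute,
                   tolerance = 1e-14)
    }
  }
})

test_that("inference probabilities follow the independent allele-flip model", {
  expect_equal(inference_matrix(0), diag(3), ignore_attr = TRUE)
  e <- 0.03
  m <- inference_matrix(e)
  expect_equal(rowSums(m), c(`0` = 1, `1` = 1, `2` = 1), tolerance = 1e-15)
  expect_equal(inference_prob(2, 0, e), e^2)
  expect_equal(inference_prob(1, 1, e), (1 - e)^2 + e^2)
  expect_equal(inference_prob(0, 1, e), e * (1 - e))
  # mirror symmetry between the two homozygous rows
  expect_equal(m[1, ], rev(m[3, ]), ignore_attr = TRUE)
  expect_error(inference_prob(3, 0, e), "dosages")
})

test_that("expected dosage error: printed form vs exact flip-model enumeration", {
  expect_equal(expected_dosage_error(0, 0.8, "literal"), 0)
  expect_equal(expected_dosage_error(0, 0.8, "flip_model"), 0)
  expect_equal(expected_dosage_error(0.01, 0.8, "literal"), 0.019868,
               tolerance = 1e-12)
  # exact 9-cell enumeration oracle
  for (e in c(0.01, 0.05)) {
    for (lamb in c(0.5, 0.8)) {
      brute <- 0
      for (x in 0:2) for (y in 0:2) {
        brute <- brute + dbinom(x, 2, lamb) * inference_prob(y, x, e) *
          abs(y - x)
      }
      expect_equal(expected_dosage_error(e, lamb, "flip_model"), brute,
                   tolerance = 1e-14)
      # the literal formula under-counts the quadratic term by eps^2*(l^2+(1-l)^2)
      expect_equal(expected_dosage_error(e, lamb, "flip_model") -
                     expected_dosage_error(e, lamb, "literal"),
                   e^2 * (lamb^2 + (1 - lamb)^2), tolerance = 1e-9)
    }
  }
})

test_that("two-parent Mendelian rate matches its single-child simplification", {
  for (lamb in c(0.3, 0.5, 0.8)) {
    for (e in c(0.005, 0.01, 0.05)) {
      ll <- lamb * (1 - lamb)
      simplified <- e * (2 - 2 * ll) + e^2 * (1 - 6 * ll + 2 * ll^2)
      expect_equal(expected_mendelian_rate("two_parent", 1, e, lamb),
                   simplified, tolerance = 1e-12)
    }
  }
  expect_equal(expected_mendelian_rate("two_parent", 1, 0.01, 0.5),
               0.0149625, tolerance = 1e-12)
  expect_equal(expected_mendelian_rate("two_parent", 3, 0, 0.7), 0)
  expect_equal(expected_mendelian_rate("one_parent", 2, 0, 0.7), 0)
  expect_error(expected_mendelian_rate("two_parent", 0, 0.01, 0.5),
               "positive integer")
})

test_that("one-parent rate tends to 2 eps^2 in the single-ancestry limit", {
  e <- 0.02
  expect_equal(expected_mendelian_rate("one_parent", 1, e, 1e-9), 2 * e^2,
               tolerance = 1e-6)
})

test_that("two-parent closed form equals exact mechanism enumeration", {
  for (m in 1:2) {
    for (lamb in c(0.5, 0.8)) {
      expect_equal(expected_mendelian_rate("two_parent", m, 0.02, lamb),
                   exact_mendelian_rate("two_parent", m, 0.02, lamb),
                   tolerance = 1e-12)
    }
  }
})

test_that("epsilon estimation inverts the forward formula exactly", {
  fams <- tibble::tibble(type = c("two_parent", "two_parent", "one_parent"),
                         m = c(1L, 3L, 2L))
  L <- 2000
  for (true_eps in c(0.001, 0.02, 0.1, 0.25)) {
    counts <- vapply(seq_len(nrow(fams)), function(f) {
      L * expected_mendelian_rate(fams$type[f], fams$m[f], true_eps, 0.8)
    }, 0)
    expect_equal(estimate_epsilon(counts, fams, L, 0.8), true_eps,
                 tolerance = 1e-10)
  }
  expect_equal(estimate_epsilon(c(0, 0, 0), fams, L, 0.8), 0)
})

test_that("an unachievable Mendelian-error rate is rejected informatively", {
  fams <- tibble::tibble(type = "two_parent", m = 1L)
  expect_error(estimate_epsilon(1900, fams, 2000, 0.5), "no allelic error rate")
})

test_that("double-crossover probability follows the truncated Poisson form", {
  expect_equal(double_crossover_prob(0, 8), 0)
  expect_equal(double_crossover_prob(0.02, 8), 1 - 1.16 * exp(-0.16),
               tolerance = 1e-12)
  expect_equal(double_crossover_prob(0.02, 8), 0.011513, tolerance = 1e-4)
  w <- seq(0, 0.2, by = 0.005)
  expect_true(all(diff(double_crossover_prob(w, 8)) > 0))
  expect_error(double_crossover_prob(-0.01, 8), "nonnegative")
})

test_that("per-family Mendelian counting agrees with the oracle rule", {
  ped <- ped_quad()
  map <- make_uniform_map(60, 0.1)
  set.seed(11)
  sim <- gene_drop(ped, map, 0.7, 8)
  obs <- inject_errors(sim, 0.08)
  b <- align_ancestry(obs, map, ped)
  fams <- count_mendelian_errors(b)
  expect_equal(nrow(fams), 1)
  dos <- b$dosage
  manual <- sum(!nf_ok_vec(dos[, "A"], dos[, "B"],
                           dos[, c("C", "D"), drop = FALSE]))
  expect_equal(fams$n_me, manual)
})
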