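params_default <- function(eps = 0.01) error_model_params(eps, 0.8, 8)

test_that("a consistent observation flanked by itself is left unchanged", {
  trio <- ped_trio()
  y <- c(0, 1, 1)
  out <- correct_locus(y, x_left = y, x_right = y,
                       d_left = 1e-5, d_right = 1e-5,
                       ped = trio, params = params_default())
  expect_equal(as.vector(out), y)
  expect_false(attr(out, "failed"))
})

test_that("a trio blip is pulled back to the flanking configuration", {
  trio <- ped_trio()
  truth <- c(0, 1, 1)
  y <- c(0, 1, 2)   # child call drifted; inconsistent with F = 0
  out <- correct_locus(y, truth, truth, 0.1 / 100, 0.1 / 100,
                       ped = trio, params = params_default())
  expect_equal(as.vector(out), truth)
  expect_gt(attr(out, "log_prob"), attr(out, "runner_up"))
})

test_that("boundary correction with a single flank matches the oracle", {
  trio <- ped_trio()
  y <- c(2, 0, 0)
  xr <- c(1, 0, 1)
  out <- correct_locus(y, x_left = NULL, x_right = xr, d_right = 0.001,
                       ped = trio, params = params_default(), max_diff = 3)
  want <- oracle_map(y, NULL, xr, NA, 0.001, trio, 0.01, 0.8, 8)
  expect_equal(as.vector(out), want$config)
  expect_equal(attr(out, "log_prob"), want$score, tolerance = 1e-9)
})

test_that("MAP correction equals the brute-force scorer on random instances", {
  peds <- small_peds()
  set.seed(2024)
  for (rep in 1:40) {
    ped <- peds[[sample(length(peds), 1)]]
    n <- nrow(ped)
    eps <- runif(1, 0.005, 0.05)
    lamb <- runif(1, 0.25, 0.85)
    tau <- sample(4:10, 1)
    dl <- runif(1, 1e-4, 0.05)
    dr <- runif(1, 1e-4, 0.05)
    y <- sample(0:2, n, replace = TRUE)
    xl <- random_consistent(ped)
    xr <- random_consistent(ped)
    out <- correct_locus(y, xl, xr, dl, dr, ped,
                         error_model_params(eps, lamb, tau), max_diff = n)
    want <- oracle_map(y, xl, xr, dl, dr, ped, eps, lamb, tau)
    expect_equal(as.vector(out), want$config)
    expect_equal(attr(out, "log_prob"), want$score, tolerance = 1e-9)
  }
})

test_that("correcting error-free data is a no-op", {
  ped <- ped_quad()
  map <- make_uniform_map(300, 0.05)
  sim <- simulate_ancestry(ped, map, epsilon = 0, seed = 5)
  # with no injected errors the data carry no Mendelian errors, the estimated
  # allelic error rate is zero, and MAP correction can never move off the data
  corr <- correct_all(sim$bundle, error_model_params(NA, 0.8, 8))
  expect_equal(glance(corr)$epsilon, 0)
  expect_equal(corr$corrected$dosage, sim$truth$dosage)
  expect_equal(glance(corr)$cells_changed, 0L)
  expect_equal(glance(corr)$mendelian_before, 0L)
})

test_that("correction reduces the dosage error and clears Mendelian errors", {
  ped <- ped_quad()
  map <- make_uniform_map(500, 0.03)
  wins <- 0
  for (seed in 1:3) {
    sim <- simulate_ancestry(ped, map, epsilon = 0.01, seed = seed)
    corr <- correct_all(sim$bundle, params_default())
    ev <- evaluate_correction(sim$truth, sim$observed, corr$corrected,
                              ped, map)
    if (ev$dosage_error_rate[2] < ev$dosage_error_rate[1]) wins <- wins + 1
    expect_equal(ev$mendelian_error_loci[2], 0L)
    expect_lte(glance(corr)$mendelian_after, glance(corr)$mendelian_before)
  }
  expect_gte(wins, 2)
})

test_that("marker and block modes agree on totals for clean block structure", {
  ped <- ped_trio()
  map <- make_uniform_map(200, 0.05)
  sim <- simulate_ancestry(ped, map, epsilon = 0.01, seed = 77)
  cm <- correct_all(sim$bundle, params_default(), mode = "marker")
  cb <- correct_all(sim$bundle, params_default(), mode = "block")
  expect_equal(glance(cb)$mendelian_after, 0L)
  expect_equal(glance(cm)$mendelian_after, 0L)
  # both reduce the error relative to the observation
  evm <- evaluate_correction(sim$truth, sim$observed, cm$corrected, ped, map)
  evb <- evaluate_correction(sim$truth, sim$observed, cb$corrected, ped, map)
  expect_lt(evm$dosage_error_rate[2], evm$dosage_error_rate[1])
  expect_lt(evb$dosage_error_rate[2], evb$dosage_error_rate[1])
})

test_that("epsilon is estimated from the data when requested", {
  ped <- example_pedigree("medium")
  map <- make_uniform_map(800, 0.03)
  sim <- simulate_ancestry(ped, map, epsilon = 0.02, seed = 31)
  corr <- correct_all(sim$bundle, error_model_params(NA, 0.8, 8))
  expect_gt(glance(corr)$epsilon, 0.005)
  expect_lt(glance(corr)$epsilon, 0.05)
})

test_that("low-quality cells trigger locus reconsideration", {
  ped <- ped_trio()
  map <- make_uniform_map(100, 0.05)
  sim <- simulate_ancestry(ped, map, epsilon = 0, seed = 13,
                           low_quality_cells = 5)
  fl <- flag_loci(sim$bundle)
  expect_equal(unique(fl$reason), "low_quality")
  corr <- correct_all(sim$bundle, params_default())
  # clean data: flagged loci are re-examined but nothing should change
  expect_equal(corr$corrected$dosage, sim$truth$dosage)
})

test_that("corrected loci are a subset of flagged loci", {
  ped <- example_pedigree("small")
  map <- make_uniform_map(400, 0.03)
  sim <- simulate_ancestry(ped, map, epsilon = 0.02, seed = 9)
  corr <- correct_all(sim$bundle, params_default(0.02))
  ch <- tidy(corr)
  expect_true(all(ch$locus[ch$n_changed > 0] %in% corr$flags$locus))
  # totals consistent with per-locus records
  expect_equal(glance(corr)$n_corrected_loci,
               length(unique(ch$locus[ch$n_changed > 0])))
})
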