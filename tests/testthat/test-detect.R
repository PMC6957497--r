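trio_ped_set <- function() {
  matrix(c(
    0, 0, 0,  0, 1, 0,  0, 1, 1,  0, 2, 1,
    1, 0, 0,  1, 0, 1,  1, 1, 0,  1, 1, 1,  1, 1, 2,  1, 2, 1,  1, 2, 2,
    2, 0, 1,  2, 1, 1,  2, 1, 2,  2, 2, 2
  ), ncol = 3, byrow = TRUE)
}

test_that("trio consistency matches the known configuration set", {
  trio <- ped_trio()
  expect_true(is_mendelian_consistent(c(0, 2, 1), trio))
  expect_true(is_mendelian_consistent(c(2, 0, 1), trio))
  expect_false(is_mendelian_consistent(c(0, 0, 1), trio))
  expect_false(is_mendelian_consistent(c(2, 0, 0), trio))
})

test_that("enumerate_ped on a trio returns exactly the 15 configurations", {
  got <- enumerate_ped(ped_trio())
  expect_equal(colnames(got), c("F", "M", "C"))
  want <- trio_ped_set()
  key <- function(m) sort(apply(m, 1, paste, collapse = ""))
  expect_equal(key(got), key(want))
})

test_that("single founders and parent-child pairs enumerate correctly", {
  single <- pedigree(data.frame(id = "X"))
  expect_equal(as.vector(enumerate_ped(single)), 0:2)
  pair <- enumerate_ped(ped_pair())
  expect_equal(nrow(pair), 7)  # all 9 minus (0,2) and (2,0)
  bad <- apply(pair, 1, function(r) all(r == c(0, 2)) || all(r == c(2, 0)))
  expect_false(any(bad))
})

test_that("enumeration refuses oversized pedigrees", {
  expect_error(enumerate_ped(example_pedigree("large")),
               "enumerate_candidates")
})

test_that("consistency agrees with the exhaustive allele-assignment oracle", {
  set.seed(42)
  for (ped in small_peds()) {
    n <- nrow(ped)
    configs <- matrix(sample(0:2, 60 * n, replace = TRUE), ncol = n)
    got <- is_mendelian_consistent(configs, ped)
    want <- apply(configs, 1, oracle_consistent, ped = ped)
    expect_equal(got, want)
  }
})

test_that("missing dosages relax the consistency constraints", {
  trio <- ped_trio()
  expect_true(is_mendelian_consistent(c(0, NA, 1), trio))
  expect_false(is_mendelian_consistent(c(0, NA, 2), trio))
  expect_true(is_mendelian_consistent(c(NA, NA, 2), trio))
})

test_that("candidate enumeration around an observation honours the radius", {
  trio <- ped_trio()
  y_ok <- c(0, 1, 1)
  expect_equal(enumerate_candidates(y_ok, trio, 0),
               matrix(c(0L, 1L, 1L), 1, dimnames = list(NULL, trio$id)))
  y_bad <- c(0, 0, 1)
  got <- enumerate_candidates(y_bad, trio, 1)
  key <- sort(apply(got, 1, paste, collapse = ""))
  expect_equal(key, c("000", "011", "021", "101", "201"))
  # counting bound over all radii
  for (k in 0:3) {
    got <- enumerate_candidates(y_bad, trio, k)
    expect_lte(nrow(got), sum(choose(3, 0:k) * 2^(0:k)))
  }
})

test_that("full-radius candidates equal the full consistent set", {
  for (ped in small_peds()) {
    n <- nrow(ped)
    set.seed(n)
    y <- sample(0:2, n, replace = TRUE)
    got <- enumerate_candidates(y, ped, n)
    want <- enumerate_ped(ped)
    key <- function(m) sort(apply(m, 1, paste, collapse = ""))
    expect_equal(key(got), key(want))
  }
})

make_track_bundle <- function(track, pos_cM, qual = NULL) {
  # single-founder "pedigree" so only the double-crossover detector fires
  ped <- pedigree(data.frame(id = "I1"))
  L <- length(track)
  dos <- matrix(as.integer(track), L, 1,
                dimnames = list(sprintf("m%03d", seq_len(L)), "I1"))
  map <- genetic_map(data.frame(marker = rownames(dos), chrom = "1",
                                pos_cM = pos_cM))
  am <- ancestry_matrix(dos, qual)
  align_ancestry(am, map, ped)
}

test_that("short reversion runs are flagged, long ones are not", {
  # 10 loci of 1, then a run of 2s, then 10 loci of 1; run span set by spacing
  for (case in list(list(span = 1.2, expect_flag = TRUE),
                    list(span = 1.9, expect_flag = TRUE),
                    list(span = 2.1, expect_flag = FALSE),
                    list(span = 5.0, expect_flag = FALSE))) {
    run_len <- 5
    pos <- c(seq(0, 9), # flank of 1s, 9 cM
             10 + seq(0, case$span, length.out = run_len),
             20 + case$span + seq(0, 9))
    track <- c(rep(1, 10), rep(2, run_len), rep(1, 10))
    fl <- flag_loci(make_track_bundle(track, pos))
    dc <- fl[fl$reason == "double_crossover", ]
    if (case$expect_flag) {
      expect_equal(dc$locus, 11:15)
      expect_equal(unique(dc$evidence), case$span, tolerance = 1e-9)
    } else {
      expect_equal(nrow(dc), 0)
    }
  }
})

test_that("an established run between two blips is not itself flagged", {
  pos <- seq(0, 2.2, length.out = 23)   # 0.1 cM spacing
  track <- rep(1, 23)
  track[c(5, 19)] <- 2                   # two isolated blips 1.4 cM apart
  fl <- flag_loci(make_track_bundle(track, pos))
  dc <- fl[fl$reason == "double_crossover", ]
  expect_setequal(dc$locus, c(5L, 19L))
})

test_that("Mendelian and low-quality flags carry their evidence", {
  trio <- ped_trio()
  L <- 10
  dos <- matrix(1L, L, 3, dimnames = list(sprintf("m%02d", 1:L), trio$id))
  dos[4, ] <- c(0L, 0L, 1L)     # impossible trio configuration
  qual <- matrix(0.99, L, 3, dimnames = dimnames(dos))
  qual[7, 2] <- 0.85
  map <- genetic_map(data.frame(marker = rownames(dos), chrom = "1",
                                pos_cM = seq(0, 45, by = 5)))
  b <- align_ancestry(ancestry_matrix(dos, qual), map, trio)
  fl <- flag_loci(b)
  expect_equal(fl$locus[fl$reason == "mendelian"], 4L)
  lq <- fl[fl$reason == "low_quality", ]
  expect_equal(lq$locus, 7L)
  expect_equal(lq$individual, "M")
  expect_equal(lq$evidence, 0.85)
  # threshold is strict: exactly 0.90 passes
  qual[7, 2] <- 0.90
  b2 <- align_ancestry(ancestry_matrix(dos, qual), map, trio)
  expect_equal(nrow(flag_loci(b2)[flag_loci(b2)$reason == "low_quality", ]), 0)
})
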