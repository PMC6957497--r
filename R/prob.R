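#' Haploid ancestry transition matrix
#'
#' Two-state Markov transition probabilities for a single ancestry allele
#' over a genetic distance `d` (Morgans): with probability `exp(-d * tau)`
#' no ancestry switch occurs; otherwise the state is redrawn from the
#' stationary admixture distribution `(1 - lamb, lamb)`. Rows index the
#' current state (0 = population B, 1 = population A), columns the next.
#'
#' @param d Genetic distance in Morgans, `>= 0`.
#' @param tau Generations since admixture.
#' @param lamb Population-A admixture proportion.
#' @return Row-stochastic 2x2 matrix with dimnames `0:1`.
#' @examples
#' haploid_transition(0.02, tau = 8, lamb = 0.8)
#' @export
haploid_transition <- function(d, tau, lamb) {
  if (length(d) != 1 || is.na(d) || d < 0) {
    stop("`d` must be a single nonnegative distance in Morgans",
         call. = FALSE)
  }
  e <- exp(-d * tau)
  pi1 <- lamb
  m <- matrix(c(
    e + (1 - pi1) * (1 - e), pi1 * (1 - e),
    (1 - pi1) * (1 - e),     e + pi1 * (1 - e)
  ), 2, 2, byrow = TRUE, dimnames = list(0:1, 0:1))
  m
}

#' Diploid ancestry dosage transition matrix
#'
#' Dosage-level (0/1/2) transition probabilities obtained by composing two
#' independent haploid chains and projecting ordered allele pairs onto
#' unordered dosages. Preserves the `Binomial(2, lamb)` stationary
#' distribution.
#'
#' @inheritParams haploid_transition
#' @return Row-stochastic 3x3 matrix with dimnames `0:2`.
#' @examples
#' diploid_transition(0.02, tau = 8, lamb = 0.8)
#' @export
diploid_transition <- function(d, tau, lamb) {
  h <- haploid_transition(d, tau, lamb)
  pairs <- list(`0` = c(1L, 1L), `1` = c(1L, 2L), `2` = c(2L, 2L))
  m <- matrix(0, 3, 3, dimnames = list(0:2, 0:2))
  for (x in 0:2) {
    p <- pairs[[x + 1]]
    for (a in 1:2) for (b in 1:2) {
      y <- (a - 1L) + (b - 1L)
      m[x + 1, y + 1] <- m[x + 1, y + 1] + h[p[1], a] * h[p[2], b]
    }
  }
  m
}

#' Inference probability matrix P(observed | true)
#'
#' Under the allelic error model each of the two ancestry alleles is flipped
#' independently with probability `epsilon`; the observed dosage is the sum
#' of the observed alleles. Rows index the true dosage, columns the observed.
#'
#' @param epsilon Allelic error rate in `[0, 0.5)`.
#' @return Row-stochastic 3x3 matrix with dimnames `0:2`.
#' @export
inference_matrix <- function(epsilon) {
  if (length(epsilon) != 1 || is.na(epsilon) || epsilon < 0 || epsilon >= 0.5) {
    stop("`epsilon` must lie in [0, 0.5)", call. = FALSE)
  }
  e <- epsilon
  matrix(c(
    (1 - e)^2,   2 * e * (1 - e),     e^2,
    e * (1 - e), (1 - e)^2 + e^2,     e * (1 - e),
    e^2,         2 * e * (1 - e),     (1 - e)^2
  ), 3, 3, byrow = TRUE, dimnames = list(0:2, 0:2))
}

#' Probability of observing dosage y given true dosage x
#'
#' @param y,x Observed and true dosages in `{0, 1, 2}` (vectorized).
#' @param epsilon Allelic error rate.
#' @return Numeric vector of probabilities.
#' @examples
#' inference_prob(2, 0, 0.01) # both alleles flipped: epsilon^2
#' @export
inference_prob <- function(y, x, epsilon) {
  if (any(!(y %in% 0:2)) || any(!(x %in% 0:2))) {
    stop("dosages must lie in {0, 1, 2}", call. = FALSE)
  }
  m <- inference_matrix(epsilon)
  m[cbind(x + 1, y + 1)]
}

#' Expected dosage error rate
#'
#' The expected mean absolute difference between observed and true dosages,
#' `E|Y - X|`, with the true dosage marginally `Binomial(2, lamb)`.
#' `variant = "flip_model"` (the default) computes it exactly from the
#' allelic flip model by enumeration; `variant = "literal"` evaluates the
#' commonly quoted closed form `2e(1-e) + e^2 [lamb^2 + (1-lamb)^2]`, whose
#' quadratic term is half that of the flip model (a difference of at most
#' `epsilon^2`, negligible at realistic error rates).
#'
#' @param epsilon Allelic error rate.
#' @param lamb Admixture proportion.
#' @param variant `"flip_model"` or `"literal"`.
#' @return Expected dosage error rate (scalar).
#' @export
expected_dosage_error <- function(epsilon, lamb,
                                  variant = c("flip_model", "literal")) {
  variant <- match.arg(variant)
  if (variant == "literal") {
    return(2 * epsilon * (1 - epsilon) +
             epsilon^2 * (lamb^2 + (1 - lamb)^2))
  }
  m <- inference_matrix(epsilon)
  px <- stats::dbinom(0:2, 2, lamb)
  sum(vapply(0:2, function(x) {
    px[x + 1] * sum(m[x + 1, ] * abs(0:2 - x))
  }, 0))
}

# linear and quadratic coefficients of the expected per-locus Mendelian-error
# rate as a polynomial a*eps + b*eps^2
mendelian_rate_coefficients <- function(family_type, m, lamb) {
  ll <- lamb * (1 - lamb)
  if (family_type == "two_parent") {
    a <- 2 * m + (8 - 6 * m - (1 / 2)^(m - 3)) * ll +
      (4 * m - 16 * (3 / 4)^m + (1 / 2)^(m - 4)) * ll^2
    b <- 2 - m + (4 * m - 12 + (1 / 2)^(m - 2)) * ll -
      (6 * m - 16 * (3 / 4)^m + (1 / 2)^(m - 3)) * ll^2
  } else {
    k1 <- ll * (2 - (1 - lamb / 2)^m - (1 / 2 + lamb / 2)^m + m / 2)
    k2 <- lamb * (1 + lamb - (1 - lamb)^m) +
      (1 - lamb)^2 * (2 - lamb + lamb^m)
    a <- 2 * k1
    b <- k2 - 2 * k1
  }
  c(a = a, b = b)
}

#' Expected Mendelian-error rate per locus in a nuclear family
#'
#' Closed-form expected number of Mendelian-inconsistent loci per marker in
#' a nuclear family, as a quadratic polynomial in the allelic error rate,
#' derived under the assumption that at most one family member carries an
#' ancestry inference error at a given locus. Distinct polynomials apply to
#' families with two parents and with a single recorded parent.
#'
#' @param family_type `"two_parent"` or `"one_parent"`.
#' @param m Number of children, `>= 1`.
#' @param epsilon Allelic error rate (vectorized).
#' @param lamb Admixture proportion.
#' @return Expected Mendelian errors per locus.
#' @export
expected_mendelian_rate <- function(family_type = c("two_parent", "one_parent"),
                                    m, epsilon, lamb) {
  family_type <- match.arg(family_type)
  if (length(m) != 1 || is.na(m) || m < 1 || m != round(m)) {
    stop("`m` must be a positive integer", call. = FALSE)
  }
  if (any(epsilon < 0) || any(epsilon >= 0.5)) {
    stop("`epsilon` must lie in [0, 0.5)", call. = FALSE)
  }
  co <- mendelian_rate_coefficients(family_type, m, lamb)
  co[["a"]] * epsilon + co[["b"]] * epsilon^2
}

#' Estimate the allelic error rate from observed Mendelian errors
#'
#' Solves for the allelic error rate `epsilon` that equates the total
#' expected number of Mendelian-inconsistent loci across a set of nuclear
#' families (each contributing `L * expected_mendelian_rate(...)`) with the
#' total observed count. The aggregate model is quadratic in `epsilon`; the
#' root in `[0, 0.5)` is returned (the smaller one if both qualify).
#'
#' @param observed_me Numeric vector of observed Mendelian-error locus
#'   counts, one per family.
#' @param families Data frame with columns `type` (`"two_parent"` /
#'   `"one_parent"`) and `m` (children per family), e.g. the output of
#'   [extract_nuclear_families()].
#' @param L Number of loci scanned per family.
#' @param lamb Admixture proportion.
#' @return Estimated `epsilon` (scalar).
#' @examples
#' fams <- data.frame(type = "two_parent", m = 2)
#' cnt <- 2000 * expected_mendelian_rate("two_parent", 2, 0.02, 0.8)
#' estimate_epsilon(cnt, fams, L = 2000, lamb = 0.8)
#' @export
estimate_epsilon <- function(observed_me, families, L, lamb) {
  stopifnot(L >= 1, nrow(families) >= 1,
            length(observed_me) == nrow(families))
  if (any(observed_me < 0)) stop("counts must be nonnegative", call. = FALSE)
  total <- sum(observed_me)
  if (total == 0) return(0)
  co <- vapply(seq_len(nrow(families)), function(f) {
    mendelian_rate_coefficients(families$type[f], families$m[f], lamb)
  }, c(a = 0, b = 0))
  A <- L * sum(co["a", ])
  B <- L * sum(co["b", ])
  # solve B e^2 + A e - total = 0 on [0, 0.5)
  roots <- if (abs(B) < 1e-300) total / A else {
    disc <- A^2 + 4 * B * total
    if (disc < 0) numeric(0) else {
      (-A + c(1, -1) * sqrt(disc)) / (2 * B)
    }
  }
  roots <- sort(roots[!is.na(roots) & roots >= 0 & roots < 0.5])
  if (!length(roots)) {
    grid <- seq(0, 0.4999, length.out = 512)
    mx <- max(A * grid + B * grid^2)
    stop("no allelic error rate in [0, 0.5) reproduces the observed ",
         "Mendelian-error rate (", signif(total / (L * nrow(families)), 4),
         " per family-locus); model maximum over the interval is ",
         signif(mx / (L * nrow(families)), 4), " per family-locus",
         call. = FALSE)
  }
  roots[1]
}

#' Probability of two or more crossovers in a window
#'
#' Crossover counts in a window of `window_M` Morgans are modelled as
#' Poisson with rate `window_M * tau`; this returns
#' `P(R >= 2) = 1 - exp(-x) - x exp(-x)`. Double-crossover reversions within
#' a window where this probability is small are treated as inference errors.
#'
#' @param window_M Window length in Morgans, `>= 0`.
#' @param tau Generations since admixture.
#' @return Probability of observing at least two crossovers (vectorized in
#'   `window_M`).
#' @examples
#' double_crossover_prob(0.02, tau = 8)
#' @export
double_crossover_prob <- function(window_M, tau) {
  if (any(is.na(window_M)) || any(window_M < 0)) {
    stop("`window_M` must be nonnegative", call. = FALSE)
  }
  x <- window_M * tau
  1 - exp(-x) - x * exp(-x)
}

#' Count Mendelian-inconsistent loci per nuclear family
#'
#' Applies the Mendelian consistency check to each nuclear family of a
#' bundle and counts inconsistent loci (0/1 per family-locus). Loci where a
#' member's call is missing enter the check with that member unconstrained.
#'
#' @param bundle An `ancestry_bundle` from [align_ancestry()].
#' @param families Optional nuclear-family table from
#'   [extract_nuclear_families()]; extracted from the bundle's pedigree when
#'   omitted.
#' @return `families` with an extra integer column `n_me`.
#' @export
count_mendelian_errors <- function(bundle, families = NULL) {
  stopifnot(inherits(bundle, "ancestry_bundle"))
  if (is.null(families)) families <- extract_nuclear_families(bundle$ped)
  n_me <- vapply(seq_len(nrow(families)), function(f) {
    par <- families$parents[[f]]
    ch <- families$children[[f]]
    ids <- c(par, ch)
    dos <- t(bundle$dosage[, ids, drop = FALSE])
    father <- c(rep(0L, length(par)),
                rep(if (length(par) >= 1) 1L else 0L, length(ch)))
    mother <- c(rep(0L, length(par)),
                rep(if (length(par) == 2) 2L else 0L, length(ch)))
    sum(!.consistent_loci_cpp(dos, father, mother))
  }, 0L)
  families$n_me <- n_me
  families
}
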