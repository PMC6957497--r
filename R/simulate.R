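#' Uniformly spaced synthetic genetic map
#'
#' A chromosome-22-like default: `L` markers at `spacing_cM` intervals
#' (2000 markers at 0.03 cM span 60 cM).
#'
#' @param L Number of markers.
#' @param spacing_cM Inter-marker spacing in centiMorgans (default 0.03).
#' @param chrom Chromosome label.
#' @return A [genetic_map()].
#' @export
make_uniform_map <- function(L, spacing_cM = 0.03, chrom = "22") {
  stopifnot(L >= 1, spacing_cM >= 0)
  genetic_map(tibble::tibble(
    marker = sprintf("mk%05d", seq_len(L)),
    chrom = chrom,
    pos_cM = (seq_len(L) - 1) * spacing_cM
  ))
}

#' Simulate a founder's haploid ancestry track
#'
#' The ancestry of a founder haplotype follows a two-state Markov chain
#' along the map: the first locus of each chromosome is population A with
#' probability `lamb`; over an interval of `d` Morgans a recombination
#' event occurs with probability `1 - exp(-d * tau)` (at most one per
#' interval), upon which the ancestry is redrawn as Bernoulli(`lamb`),
#' otherwise it is copied. Redraws that land on the current state are
#' invisible, so the marginal process matches the conditional transition
#' model of [haploid_transition()].
#'
#' @param map A [genetic_map()].
#' @param lamb Admixture proportion.
#' @param tau Generations since admixture (default 8).
#' @return Integer vector of 0/1 ancestries, one per marker.
#' @export
simulate_founder_track <- function(map, lamb, tau = 8) {
  d <- map_distances(map)
  L <- length(d)
  switch_p <- ifelse(is.na(d), 1, 1 - exp(-d * tau))
  sw <- runif(L) < switch_p
  vals <- rbinom(L, 1L, lamb)
  idx <- cummax(ifelse(sw, seq_len(L), 0L))
  vals[idx]
}

# transmit one haplotype from a parent's pair of tracks through one meiosis:
# the source haplotype starts uniform and switches with prob 1 - exp(-d)
meiosis <- function(track1, track2, d) {
  L <- length(track1)
  switch_p <- ifelse(is.na(d), 0.5, 1 - exp(-d))
  sw <- runif(L) < switch_p
  sw[1] <- TRUE
  src <- rbinom(L, 1L, 0.5)
  idx <- cummax(ifelse(sw, seq_len(L), 0L))
  src <- src[idx]
  ifelse(src == 0L, track1, track2)
}

#' Gene-drop ancestry tracks through a pedigree
#'
#' Simulates two haploid ancestry tracks for every founder with
#' [simulate_founder_track()] and transmits haplotypes to offspring in
#' generation order: each meiosis copies one of the parent's two tracks,
#' switching source track between adjacent markers with probability
#' `1 - exp(-d)` (single-generation crossover rate, `tau = 1`). A parent
#' missing from the pedigree contributes a fresh founder track. The true
#' dosage at each marker is the sum of the two allele tracks, and is
#' Mendelian-consistent at every locus by construction.
#'
#' @param ped A [pedigree()].
#' @param map A [genetic_map()].
#' @param lamb Admixture proportion (default 0.8).
#' @param tau Founder generations since admixture (default 8).
#' @return List with `tracks` (per individual, a 2-column 0/1 matrix) and
#'   `truth` (an [ancestry_matrix()], markers x individuals in `ped` order).
#' @export
gene_drop <- function(ped, map, lamb = 0.8, tau = 8) {
  stopifnot(inherits(ped, "pedigree"), inherits(map, "genetic_map"))
  d <- map_distances(map)
  topo <- ped_topology(ped)
  n <- nrow(ped)
  tracks <- vector("list", n)
  names(tracks) <- topo$ids
  for (i in seq_len(n)) {
    fa <- topo$father[i]
    mo <- topo$mother[i]
    pat <- if (fa == 0) simulate_founder_track(map, lamb, tau) else {
      meiosis(tracks[[fa]][, 1], tracks[[fa]][, 2], d)
    }
    mat <- if (mo == 0) simulate_founder_track(map, lamb, tau) else {
      meiosis(tracks[[mo]][, 1], tracks[[mo]][, 2], d)
    }
    tracks[[i]] <- cbind(paternal = pat, maternal = mat)
  }
  dosage <- vapply(tracks, function(tr) tr[, 1] + tr[, 2],
                   integer(nrow(map)))
  dosage <- matrix(as.integer(dosage), nrow = nrow(map),
                   dimnames = list(map$marker, topo$ids))
  tracks <- tracks[ped$id]
  list(tracks = tracks,
       truth = ancestry_matrix(dosage[, ped$id, drop = FALSE]))
}

#' Inject allelic inference errors into simulated tracks
#'
#' Flips every ancestry allele independently with probability `epsilon` and
#' rebuilds the observed dosage matrix, mimicking the error process of an
#' upstream local-ancestry caller. A constant-0.99 quality matrix is
#' attached so the low-quality detector has input; `low_quality_cells`
#' cells (chosen at random) can be demoted below any threshold.
#'
#' @param sim Output of [gene_drop()].
#' @param epsilon Allelic error rate in `[0, 0.5)`.
#' @param low_quality_cells Number of cells to mark low-quality (default 0).
#' @return An [ancestry_matrix()] of observed dosages with quality.
#' @export
inject_errors <- function(sim, epsilon, low_quality_cells = 0) {
  if (epsilon < 0 || epsilon >= 0.5) {
    stop("`epsilon` must lie in [0, 0.5)", call. = FALSE)
  }
  dos <- vapply(sim$tracks, function(tr) {
    flips <- matrix(runif(length(tr)) < epsilon, nrow(tr))
    obs <- ifelse(flips, 1L - tr, tr)
    as.integer(obs[, 1] + obs[, 2])
  }, integer(nrow(sim$truth$dosage)))
  dimnames(dos) <- dimnames(sim$truth$dosage)
  qual <- matrix(0.99, nrow(dos), ncol(dos), dimnames = dimnames(dos))
  if (low_quality_cells > 0) {
    pick <- sample(length(qual), min(low_quality_cells, length(qual)))
    qual[pick] <- 0.5
  }
  ancestry_matrix(dos, qual)
}

#' Simulate a complete ancestry data set for a pedigree
#'
#' Convenience wrapper: seeds the RNG, gene-drops truth, injects errors and
#' returns an aligned bundle ready for [flag_loci()] / [correct_all()]
#' together with the truth.
#'
#' @param ped A [pedigree()].
#' @param map A [genetic_map()] (default: 2000 markers at 0.03 cM).
#' @param lamb,tau Admixture proportion and founder generations.
#' @param epsilon Injected allelic error rate.
#' @param seed RNG seed (required, for reproducibility).
#' @param low_quality_cells Passed to [inject_errors()].
#' @return List of class `ancestry_sim` with elements `truth`, `observed`,
#'   `tracks`, `bundle`, `map`, `ped` and the simulation settings.
#' @examples
#' ped <- example_pedigree("small")
#' sim <- simulate_ancestry(ped, make_uniform_map(200), epsilon = 0.01,
#'                          seed = 1)
#' sim$bundle
#' @export
simulate_ancestry <- function(ped, map = make_uniform_map(2000), lamb = 0.8,
                              tau = 8, epsilon = 0.01, seed,
                              low_quality_cells = 0) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  set.seed(seed)
  sim <- gene_drop(ped, map, lamb, tau)
  observed <- inject_errors(sim, epsilon, low_quality_cells)
  structure(
    list(
      truth = sim$truth, observed = observed, tracks = sim$tracks,
      bundle = align_ancestry(observed, map, ped),
      map = map, ped = ped,
      settings = list(lamb = lamb, tau = tau, epsilon = epsilon,
                      seed = seed)
    ),
    class = "ancestry_sim"
  )
}

#' @export
print.ancestry_sim <- function(x, ...) {
  s <- x$settings
  cat("<ancestry_sim> family", ped_family(x$ped), "-",
      nrow(x$truth$dosage), "markers x", ncol(x$truth$dosage),
      "individuals\n  lambda =", s$lamb, " tau =", s$tau,
      " epsilon =", s$epsilon, " seed =", s$seed, "\n")
  invisible(x)
}

#' Evaluate inference accuracy before and after correction
#'
#' Computes, against the simulated truth, the dosage error rate (mean
#' absolute difference between called and true dosages over all individuals
#' and loci), the number of loci with at least one erroneous call, the
#' number of Mendelian-inconsistent loci, and the number of
#' double-crossover runs shorter than `window_cM`, for the observed matrix
#' and (optionally) the corrected one.
#'
#' @param truth,observed True and observed [ancestry_matrix()] objects.
#' @param corrected Optional corrected [ancestry_matrix()].
#' @param ped A [pedigree()].
#' @param map A [genetic_map()].
#' @param window_cM Double-crossover window (default 2).
#' @return A tibble of class `ancestry_metrics`, one row per step
#'   (`"observed"`, `"corrected"`), with an attribute `by_individual`.
#' @export
evaluate_correction <- function(truth, observed, corrected = NULL, ped, map,
                                window_cM = 2) {
  stopifnot(inherits(truth, "ancestry_matrix"),
            inherits(observed, "ancestry_matrix"))
  if (!identical(dim(truth$dosage), dim(observed$dosage))) {
    stop("truth and observed shapes differ", call. = FALSE)
  }
  steps <- list(observed = observed)
  if (!is.null(corrected)) {
    if (!identical(dim(truth$dosage), dim(corrected$dosage))) {
      stop("truth and corrected shapes differ", call. = FALSE)
    }
    steps$corrected <- corrected
  }
  rows <- lapply(names(steps), function(nm) {
    y <- steps[[nm]]$dosage
    x <- truth$dosage
    diffs <- abs(y - x)
    bundle <- align_ancestry(steps[[nm]], map, ped)
    fl <- flag_loci(bundle, window_cM = window_cM)
    dc <- fl[fl$reason == "double_crossover", , drop = FALSE]
    runs <- if (nrow(dc)) {
      # a run = maximal stretch of consecutive flagged loci per individual
      sum(vapply(split(dc$locus, dc$individual), function(l) {
        l <- sort(unique(l))
        sum(diff(c(-10L, l)) != 1L)
      }, 0L))
    } else 0L
    tibble::tibble(
      step = nm,
      dosage_error_rate = mean(diffs, na.rm = TRUE),
      loci_with_errors = sum(apply(diffs > 0, 1, any, na.rm = TRUE)),
      mendelian_error_loci = sum(!consistent_loci(
        bundle$dosage, bundle$ped)),
      double_crossover_runs = runs
    )
  })
  out <- dplyr::bind_rows(rows)
  by_ind <- lapply(names(steps), function(nm) {
    diffs <- abs(steps[[nm]]$dosage - truth$dosage)
    tibble::tibble(step = nm, id = colnames(diffs),
                   dosage_error_rate = colMeans(diffs, na.rm = TRUE),
                   loci_with_errors = colSums(diffs > 0, na.rm = TRUE))
  })
  attr(out, "by_individual") <- dplyr::bind_rows(by_ind)
  structure(out, class = c("ancestry_metrics", class(out)))
}

#' Representative example pedigrees
#'
#' Three fixture pedigrees used throughout the documentation and tests: a
#' large three-generation pedigree (n = 20), a medium three-generation
#' pedigree (n = 10), and a small two-generation pedigree (n = 4). They are
#' representative structures, not replicas of any particular study family.
#'
#' @param size `"large"`, `"medium"` or `"small"`.
#' @return A [pedigree()].
#' @examples
#' example_pedigree("small")
#' @export
example_pedigree <- function(size = c("large", "medium", "small")) {
  size <- match.arg(size)
  lines <- switch(size,
    small = c(
      "fam4 p1 0 0 1 -9",
      "fam4 p2 0 0 2 -9",
      "fam4 c1 p1 p2 1 -9",
      "fam4 c2 p1 p2 2 -9"
    ),
    medium = c(
      "fam10 g1 0 0 1 -9",
      "fam10 g2 0 0 2 -9",
      "fam10 p1 g1 g2 1 -9",
      "fam10 p2 g1 g2 2 -9",
      "fam10 p3 g1 g2 1 -9",
      "fam10 s1 0 0 2 -9",
      "fam10 s2 0 0 1 -9",
      "fam10 k1 p1 s1 1 -9",
      "fam10 k2 p1 s1 2 -9",
      "fam10 k3 s2 p2 1 -9"
    ),
    large = c(
      "fam20 g1 0 0 1 -9",
      "fam20 g2 0 0 2 -9",
      "fam20 p1 g1 g2 1 -9",
      "fam20 p2 g1 g2 2 -9",
      "fam20 p3 g1 g2 1 -9",
      "fam20 p4 g1 g2 2 -9",
      "fam20 s1 0 0 2 -9",
      "fam20 s2 0 0 1 -9",
      "fam20 s3 0 0 2 -9",
      "fam20 k1 p1 s1 1 -9",
      "fam20 k2 p1 s1 2 -9",
      "fam20 k3 p1 s1 1 -9",
      "fam20 k4 p1 s1 2 -9",
      "fam20 k5 s2 p2 1 -9",
      "fam20 k6 s2 p2 2 -9",
      "fam20 k7 s2 p2 1 -9",
      "fam20 k8 s2 p2 2 -9",
      "fam20 k9 p3 s3 1 -9",
      "fam20 k10 p3 s3 2 -9",
      "fam20 k11 p3 s3 1 -9"
    )
  )
  read_pedigree(text = lines)[[1]]
}
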