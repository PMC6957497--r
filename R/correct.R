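LOG_FLOOR <- log(1e-300)

# vectorized scorer: log P(Y|X) + log P(X_right|X) + log P(X|X_left) for each
# candidate row of `cands`; NA observations / flanks drop the matching factor
score_candidates <- function(cands, y, x_left, x_right, t_left, t_right,
                             epsilon) {
  K <- nrow(cands)
  n <- ncol(cands)
  score <- numeric(K)
  logE <- pmax(log(inference_matrix(epsilon)), LOG_FLOOR)
  cv <- as.vector(cands)
  obs <- rep(as.integer(y), each = K)
  ok <- !is.na(obs) & !is.na(cv)
  inf <- numeric(K * n)
  inf[ok] <- logE[cbind(cv[ok] + 1L, obs[ok] + 1L)]
  score <- rowSums(matrix(inf, K))
  if (!is.null(x_left)) {
    logT <- pmax(log(t_left), LOG_FLOOR)
    xl <- rep(as.integer(x_left), each = K)
    ok <- !is.na(xl) & !is.na(cv)
    tr <- numeric(K * n)
    tr[ok] <- logT[cbind(xl[ok] + 1L, cv[ok] + 1L)]
    score <- score + rowSums(matrix(tr, K))
  }
  if (!is.null(x_right)) {
    logT <- pmax(log(t_right), LOG_FLOOR)
    xr <- rep(as.integer(x_right), each = K)
    ok <- !is.na(xr) & !is.na(cv)
    tr <- numeric(K * n)
    tr[ok] <- logT[cbind(cv[ok] + 1L, xr[ok] + 1L)]
    score <- score + rowSums(matrix(tr, K))
  }
  score
}

#' Correct one locus by pedigree-constrained MAP selection
#'
#' Replaces an observed dosage configuration by the Mendelian-consistent
#' configuration maximizing the joint probability
#' `P(Y_t | X_t) P(X_right | X_t) P(X_t | X_left)`, where the inference term
#' factorizes over individuals under the allelic flip model and the
#' transition terms factorize over individuals under the diploid ancestry
#' switch model at the flanking genetic distances. The flanking
#' configurations are taken as correct. At a chromosome boundary pass `NULL`
#' for the absent flank and its factor is dropped.
#'
#' The search covers consistent configurations within Hamming distance
#' `max_diff` of `y`; if none exists, `max_diff + 1` is tried once, after
#' which the locus is returned unchanged with `attr(, "failed") = TRUE`.
#' Score ties (within 1e-12) are broken toward the fewest changes relative
#' to `y`, then lexicographically, so the result is deterministic.
#'
#' @param y Observed configuration (vector over `ped$id`).
#' @param x_left,x_right Flanking configurations or `NULL`.
#' @param d_left,d_right Genetic distances to the flanks in Morgans.
#' @param ped A [pedigree()].
#' @param params An [error_model_params()] with a concrete `epsilon`.
#' @param max_diff Hamming search radius (default 2).
#' @return Integer configuration with attributes `log_prob` (winner),
#'   `runner_up` (second-best log probability or `NA`), `escalated`,
#'   `failed`.
#' @export
correct_locus <- function(y, x_left = NULL, x_right = NULL,
                          d_left = NA, d_right = NA, ped, params,
                          max_diff = 2) {
  stopifnot(inherits(ped, "pedigree"), inherits(params, "error_model_params"))
  if (is.null(x_left) && is.null(x_right)) {
    stop("at least one flanking configuration is required", call. = FALSE)
  }
  t_left <- if (!is.null(x_left)) {
    diploid_transition(d_left, params$tau, params$lamb)
  }
  t_right <- if (!is.null(x_right)) {
    diploid_transition(d_right, params$tau, params$lamb)
  }
  map_correct(y, x_left, x_right, t_left, t_right, ped, params, max_diff)
}

# MAP selection with precomputed transition matrices (hot path of the sweeps)
map_correct <- function(y, x_left, x_right, t_left, t_right, ped, params,
                        max_diff) {
  escalated <- FALSE
  cands <- enumerate_candidates(y, ped, max_diff)
  if (nrow(cands) == 0) {
    escalated <- TRUE
    cands <- enumerate_candidates(y, ped, max_diff + 1)
  }
  if (nrow(cands) == 0) {
    out <- as.integer(y)
    names(out) <- ped$id
    attr(out, "log_prob") <- NA_real_
    attr(out, "runner_up") <- NA_real_
    attr(out, "escalated") <- TRUE
    attr(out, "failed") <- TRUE
    return(out)
  }
  score <- score_candidates(cands, y, x_left, x_right, t_left, t_right,
                            params$epsilon)
  best <- max(score)
  tied <- which(score >= best - 1e-12)
  if (length(tied) > 1) {
    ham <- rowSums(cands[tied, , drop = FALSE] !=
                     matrix(as.integer(y), length(tied), ncol(cands),
                            byrow = TRUE), na.rm = TRUE)
    tied <- tied[ham == min(ham)]
    if (length(tied) > 1) {
      o <- do.call(order, as.data.frame(cands[tied, , drop = FALSE]))
      tied <- tied[o[1]]
    }
  }
  pick <- tied[1]
  out <- as.integer(cands[pick, ])
  names(out) <- ped$id
  attr(out, "log_prob") <- score[pick]
  attr(out, "runner_up") <- if (nrow(cands) > 1) {
    max(score[-pick])
  } else NA_real_
  attr(out, "escalated") <- escalated
  attr(out, "failed") <- FALSE
  out
}

#' Detect and correct ancestry inference errors across a chromosome
#'
#' Runs the full pipeline on an aligned bundle: flag loci
#' ([flag_loci()]), then sweep left to right over the flagged loci (or
#' flagged blocks) correcting each by [correct_locus()]. The flanking
#' context on each side is the nearest locus that is either unflagged or
#' already corrected; corrected values are trusted as left context for the
#' remainder of the sweep. In `mode = "block"`, maximal runs of identical
#' configurations are treated as single loci, with the flanking blocks as
#' neighbours.
#'
#' @param bundle An `ancestry_bundle` from [align_ancestry()].
#' @param params An [error_model_params()]; if its `epsilon` is `NA` it is
#'   estimated from the bundle's Mendelian errors via [estimate_epsilon()].
#' @param window_cM,quality_threshold Passed to [flag_loci()].
#' @param max_diff Hamming search radius per locus (default 2).
#' @param mode `"marker"` (default) corrects flagged loci one by one;
#'   `"block"` corrects maximal identical runs as units.
#' @param sweeps Number of flag-and-correct passes (default 1).
#' @return An object of class `ancestry_correction`: list with `corrected`
#'   (an [ancestry_matrix()]), `original`, `flags`, `changes` (per-locus
#'   record tibble), `params`, and `summary` (see [glance()]).
#' @export
correct_all <- function(bundle, params, window_cM = 2,
                        quality_threshold = 0.90, max_diff = 2,
                        mode = c("marker", "block"), sweeps = 1) {
  stopifnot(inherits(bundle, "ancestry_bundle"),
            inherits(params, "error_model_params"))
  mode <- match.arg(mode)
  if (is.na(params$epsilon)) {
    fams <- count_mendelian_errors(bundle)
    if (nrow(fams) == 0) {
      stop("cannot estimate epsilon: no nuclear family in the pedigree",
           call. = FALSE)
    }
    eps <- estimate_epsilon(fams$n_me, fams, L = nrow(bundle$dosage),
                            lamb = params$lamb)
    params <- error_model_params(eps, params$lamb, params$tau)
  }
  W <- bundle$dosage
  ped <- bundle$ped
  map <- bundle$map
  mendelian_before <- sum(!consistent_loci(W, ped))
  flags0 <- NULL
  changes <- list()
  for (sweep in seq_len(sweeps)) {
    wb <- bundle
    wb$dosage <- W
    flags <- flag_loci(wb, params, window_cM = window_cM,
                       quality_threshold = quality_threshold)
    if (sweep == 1) flags0 <- flags
    if (nrow(flags) == 0) break
    flagged <- sort(unique(flags$locus))
    chrom_f <- factor(map$chrom, unique(map$chrom))
    for (ch in levels(chrom_f)) {
      sel <- which(chrom_f == ch)
      fl <- intersect(flagged, sel)
      if (!length(fl)) next
      res <- if (mode == "marker") {
        sweep_markers(W, fl, sel, map, ped, params, max_diff)
      } else {
        sweep_blocks(W, fl, sel, map, ped, params, max_diff)
      }
      W <- res$W
      if (nrow(res$changes)) {
        res$changes$sweep <- sweep
        changes[[length(changes) + 1]] <- res$changes
      }
    }
  }
  changes <- if (length(changes)) dplyr::bind_rows(changes) else {
    tibble::tibble(locus = integer(), marker = character(),
                   n_changed = integer(), individuals = list(),
                   log_prob = double(), runner_up = double(),
                   escalated = logical(), failed = logical(),
                   sweep = integer())
  }
  if (nrow(changes)) {
    reason_of <- split(flags0$reason, flags0$locus)
    changes$reasons <- vapply(changes$locus, function(l) {
      paste(sort(unique(reason_of[[as.character(l)]])), collapse = "+")
    }, "")
  } else {
    changes$reasons <- character(0)
  }
  cons_after <- consistent_loci(W, ped)
  by_indiv <- tibble::tibble(
    id = colnames(W),
    loci_changed = colSums(W != bundle$dosage, na.rm = TRUE)
  )
  summary <- tibble::tibble(
    n_loci = nrow(W),
    n_individuals = ncol(W),
    epsilon = params$epsilon,
    n_flagged_loci = length(unique(flags0$locus)),
    n_corrected_loci = length(unique(changes$locus[changes$n_changed > 0])),
    cells_changed = sum(W != bundle$dosage, na.rm = TRUE),
    mendelian_before = mendelian_before,
    mendelian_after = sum(!cons_after),
    unresolved = sum(changes$failed)
  )
  structure(
    list(
      corrected = ancestry_matrix(W, bundle$quality),
      original = ancestry_matrix(bundle$dosage, bundle$quality),
      flags = flags0, changes = changes, params = params,
      by_individual = by_indiv, summary = summary, map = map, ped = ped
    ),
    class = "ancestry_correction"
  )
}

# memoised diploid transition matrices keyed by distance: flagged loci in a
# sweep reuse a small set of inter-marker distances
transition_cache <- function(params) {
  env <- new.env(parent = emptyenv())
  function(d) {
    key <- sprintf("%.12g", d)
    m <- env[[key]]
    if (is.null(m)) {
      m <- diploid_transition(d, params$tau, params$lamb)
      env[[key]] <- m
    }
    m
  }
}

sweep_markers <- function(W, fl, sel, map, ped, params, max_diff) {
  done <- integer(0)
  recs <- list()
  pos <- map$pos_cM
  flset <- fl
  tcache <- transition_cache(params)
  for (t in fl) {
    left <- neighbour_left(t, sel, flset, done)
    right <- neighbour_right(t, sel, flset)
    xl <- if (!is.na(left)) W[left, ] else NULL
    xr <- if (!is.na(right)) W[right, ] else NULL
    if (is.null(xl) && is.null(xr)) next
    tl <- if (!is.na(left)) tcache((pos[t] - pos[left]) / 100)
    tr <- if (!is.na(right)) tcache((pos[right] - pos[t]) / 100)
    fix <- map_correct(W[t, ], xl, xr, tl, tr, ped, params, max_diff)
    ch <- which(!is.na(W[t, ]) & W[t, ] != fix)
    if (length(ch)) W[t, ] <- ifelse(is.na(W[t, ]), W[t, ], fix)
    done <- c(done, t)
    recs[[length(recs) + 1]] <- tibble::tibble(
      locus = t, marker = map$marker[t], n_changed = length(ch),
      individuals = list(colnames(W)[ch]),
      log_prob = attr(fix, "log_prob"), runner_up = attr(fix, "runner_up"),
      escalated = attr(fix, "escalated"), failed = attr(fix, "failed")
    )
  }
  list(W = W, changes = if (length(recs)) dplyr::bind_rows(recs) else {
    tibble::tibble(locus = integer(), marker = character(),
                   n_changed = integer(), individuals = list(),
                   log_prob = double(), runner_up = double(),
                   escalated = logical(), failed = logical())
  })
}

neighbour_left <- function(t, sel, flset, done) {
  cand <- sel[sel < t]
  cand <- cand[!(cand %in% setdiff(flset, done))]
  if (length(cand)) max(cand) else NA_integer_
}

neighbour_right <- function(t, sel, flset) {
  cand <- sel[sel > t]
  cand <- cand[!(cand %in% flset)]
  if (length(cand)) min(cand) else NA_integer_
}

sweep_blocks <- function(W, fl, sel, map, ped, params, max_diff) {
  pos <- map$pos_cM
  tcache <- transition_cache(params)
  key <- apply(W[sel, , drop = FALSE], 1, paste, collapse = ",")
  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nb <- length(r$lengths)
  block_of <- rep(seq_len(nb), r$lengths)
  flagged_block <- sort(unique(block_of[match(fl, sel)]))
  done <- integer(0)
  recs <- list()
  for (b in flagged_block) {
    lb <- rev(setdiff(seq_len(b - 1), setdiff(flagged_block, done)))
    rb <- setdiff(seq(b + 1, nb), flagged_block)
    rb <- rb[rb <= nb]
    lb <- if (length(lb)) lb[1] else NA
    rb <- if (length(rb)) rb[1] else NA
    if (b == 1) lb <- NA
    if (b == nb) rb <- NA
    t0 <- sel[starts[b]]
    t1 <- sel[ends[b]]
    xl <- if (!is.na(lb)) W[sel[ends[lb]], ] else NULL
    xr <- if (!is.na(rb)) W[sel[starts[rb]], ] else NULL
    if (is.null(xl) && is.null(xr)) next
    tl <- if (!is.na(lb)) tcache((pos[t0] - pos[sel[ends[lb]]]) / 100)
    tr <- if (!is.na(rb)) tcache((pos[sel[starts[rb]]] - pos[t1]) / 100)
    y <- W[t0, ]
    fix <- map_correct(y, xl, xr, tl, tr, ped, params, max_diff)
    ch <- which(!is.na(y) & y != fix)
    loci <- sel[starts[b]:ends[b]]
    if (length(ch)) {
      for (t in loci) W[t, ] <- ifelse(is.na(W[t, ]), W[t, ], fix)
    }
    done <- c(done, b)
    recs[[length(recs) + 1]] <- tibble::tibble(
      locus = loci, marker = map$marker[loci],
      n_changed = length(ch),
      individuals = rep(list(colnames(W)[ch]), length(loci)),
      log_prob = attr(fix, "log_prob"), runner_up = attr(fix, "runner_up"),
      escalated = attr(fix, "escalated"), failed = attr(fix, "failed")
    )
  }
  list(W = W, changes = if (length(recs)) dplyr::bind_rows(recs) else {
    tibble::tibble(locus = integer(), marker = character(),
                   n_changed = integer(), individuals = list(),
                   log_prob = double(), runner_up = double(),
                   escalated = logical(), failed = logical())
  })
}

#' @export
print.ancestry_correction <- function(x, ...) {
  s <- x$summary
  cat("<ancestry_correction> ", s$n_loci, " loci x ", s$n_individuals,
      " individuals (family ", ped_family(x$ped), ")\n", sep = "")
  cat("  epsilon used:       ", signif(s$epsilon, 4), "\n", sep = "")
  cat("  flagged loci:       ", s$n_flagged_loci, "\n", sep = "")
  cat("  corrected loci:     ", s$n_corrected_loci,
      " (", s$cells_changed, " calls changed)\n", sep = "")
  cat("  Mendelian errors:   ", s$mendelian_before, " -> ",
      s$mendelian_after, "\n", sep = "")
  if (s$unresolved > 0) cat("  unresolved loci:    ", s$unresolved, "\n")
  invisible(x)
}
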