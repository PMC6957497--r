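#' Mendelian consistency of dosage configurations
#'
#' A configuration (one dosage in `{0, 1, 2}` per pedigree member) is
#' Mendelian-consistent when some assignment of ordered ancestry-allele
#' pairs realizes every dosage with each non-founder receiving exactly one
#' allele from each recorded parent. Missing (`NA`) dosages leave the member
#' unconstrained. Decided by genotype elimination with depth-first search.
#'
#' @param config A vector of length `n` (ordered as `ped$id`), or a matrix
#'   with `n` columns, one configuration per row.
#' @param ped A [pedigree()].
#' @return Logical scalar or vector (one per row).
#' @examples
#' trio <- read_pedigree(text = c(
#'   "f F 0 0 1 -9", "f M 0 0 2 -9", "f C F M 1 -9"
#' ))[[1]]
#' is_mendelian_consistent(c(0, 2, 1), trio)
#' is_mendelian_consistent(c(0, 0, 1), trio)
#' @export
is_mendelian_consistent <- function(config, ped) {
  stopifnot(inherits(ped, "pedigree"))
  if (is.null(dim(config))) config <- matrix(config, nrow = 1)
  if (ncol(config) != nrow(ped)) {
    stop("configuration length must equal the number of individuals",
         call. = FALSE)
  }
  topo <- ped_topology(ped)
  dos <- t(config[, topo$order, drop = FALSE])
  storage.mode(dos) <- "integer"
  as.logical(.consistent_loci_cpp(dos, topo$father, topo$mother))
}

# consistency over the loci of a bundle's dosage matrix (L x n, ped order)
consistent_loci <- function(dosage, ped) {
  topo <- ped_topology(ped)
  dos <- t(dosage[, topo$order, drop = FALSE])
  storage.mode(dos) <- "integer"
  as.logical(.consistent_loci_cpp(dos, topo$father, topo$mother))
}

#' Enumerate all Mendelian-consistent configurations
#'
#' Materializes the full set of dosage configurations over the pedigree that
#' satisfy Mendelian inheritance (for a parent-offspring trio this is a
#' 15-member set). Exhaustive over `3^n`, so restricted to small pedigrees.
#'
#' @param ped A [pedigree()].
#' @param max_n Refuse enumeration above this size (default 12).
#' @return Integer matrix, one consistent configuration per row, columns
#'   named by individual id; rows in lexicographic order.
#' @export
enumerate_ped <- function(ped, max_n = 12) {
  stopifnot(inherits(ped, "pedigree"))
  n <- nrow(ped)
  if (n > max_n) {
    stop("pedigree has ", n, " > max_n = ", max_n, " members; use ",
         "enumerate_candidates() to search near an observed configuration",
         call. = FALSE)
  }
  grid <- as.matrix(expand.grid(rep(list(0:2), n)))
  grid <- grid[do.call(order, as.data.frame(grid)), , drop = FALSE]
  keep <- is_mendelian_consistent(grid, ped)
  out <- grid[keep, , drop = FALSE]
  dimnames(out) <- list(NULL, ped$id)
  out
}

#' Consistent configurations within Hamming distance of an observation
#'
#' Enumerates every Mendelian-consistent configuration differing from `y` in
#' at most `max_diff` coordinates (any replacement value in `{0, 1, 2}`),
#' including `y` itself when consistent. Under low per-individual error
#' rates, simultaneous errors in three or more members are improbable, so a
#' small `max_diff` retains the relevant candidates at a fraction of the
#' `3^n` cost.
#'
#' @param y Observed configuration (vector over `ped$id`; `NA` entries are
#'   not varied).
#' @param ped A [pedigree()].
#' @param max_diff Maximum Hamming distance (default 2).
#' @return Integer matrix of consistent candidates (possibly 0 rows), one
#'   per row, columns named by individual id.
#' @export
enumerate_candidates <- function(y, ped, max_diff = 2) {
  stopifnot(inherits(ped, "pedigree"), max_diff >= 0)
  n <- nrow(ped)
  if (length(y) != n) {
    stop("`y` must have one dosage per individual", call. = FALSE)
  }
  editable <- which(!is.na(y))
  blocks <- list(matrix(as.integer(y), nrow = 1))
  k_max <- min(max_diff, length(editable))
  alt_of <- lapply(0:2, function(v) setdiff(0:2, v)) # the two other values
  for (k in seq_len(k_max)) {
    sets <- if (length(editable) == 1 && k == 1) {
      matrix(editable, 1, 1)
    } else {
      t(combn(editable, k))
    }
    alt <- as.matrix(expand.grid(rep(list(1:2), k)))
    for (s in seq_len(nrow(sets))) {
      pos <- sets[s, ]
      block <- matrix(rep(as.integer(y), each = nrow(alt)),
                      nrow = nrow(alt))
      # replace each varied coordinate by one of its two alternative values
      for (j in seq_len(k)) {
        block[, pos[j]] <- alt_of[[y[pos[j]] + 1]][alt[, j]]
      }
      blocks[[length(blocks) + 1]] <- block
    }
  }
  cands <- do.call(rbind, blocks)
  keep <- is_mendelian_consistent(cands, ped)
  out <- cands[keep, , drop = FALSE]
  dimnames(out) <- list(NULL, ped$id)
  out
}

#' Flag loci carrying likely ancestry-inference errors
#'
#' Three detectors are applied to an aligned bundle:
#' \describe{
#'   \item{mendelian}{loci whose dosage configuration is
#'     Mendelian-inconsistent in the pedigree;}
#'   \item{double_crossover}{for each individual, interior runs of constant
#'     dosage that revert to the flanking state (equal dosage on both
#'     sides), span less than `window_cM`, and are no longer than either
#'     flanking run (the reversion must be the transient state, not the
#'     established one) — a double crossover within so short a window is
#'     improbable (see [double_crossover_prob()]) and is treated as an
#'     error;}
#'   \item{low_quality}{calls whose upstream posterior quality falls below
#'     `quality_threshold`.}
#' }
#'
#' @param bundle An `ancestry_bundle` from [align_ancestry()].
#' @param params Optional [error_model_params()] (not needed by the
#'   detectors themselves; accepted for pipeline symmetry).
#' @param window_cM Double-crossover window in centiMorgans (default 2).
#' @param quality_threshold Minimum acceptable call quality (default 0.90).
#' @return A tibble of class `ancestry_flags` with columns `locus` (row
#'   index in the bundle), `marker`, `chrom`, `reason`, `individual` (`NA`
#'   for pedigree-wide Mendelian flags) and `evidence` (run span in cM, or
#'   the offending quality).
#' @export
flag_loci <- function(bundle, params = NULL, window_cM = 2,
                      quality_threshold = 0.90) {
  stopifnot(inherits(bundle, "ancestry_bundle"))
  dos <- bundle$dosage
  map <- bundle$map
  flags <- list()

  cons <- consistent_loci(dos, bundle$ped)
  if (any(!cons)) {
    idx <- which(!cons)
    flags$mendelian <- tibble::tibble(
      locus = idx, marker = map$marker[idx], chrom = map$chrom[idx],
      reason = "mendelian", individual = NA_character_,
      evidence = NA_real_
    )
  }

  chrom_f <- factor(map$chrom, unique(map$chrom))
  dc <- list()
  for (ch in levels(chrom_f)) {
    sel <- which(chrom_f == ch)
    pos <- map$pos_cM[sel]
    for (j in seq_len(ncol(dos))) {
      track <- dos[sel, j]
      r <- rle(ifelse(is.na(track), -1L, track))
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      nr <- length(r$values)
      if (nr < 3) next
      spans <- pos[ends] - pos[starts]
      for (b in 2:(nr - 1)) {
        if (r$values[b] < 0) next
        if (r$values[b - 1] != r$values[b + 1]) next
        if (r$values[b - 1] < 0) next
        span <- spans[b]
        # the reverted run must be the transient state: no longer than the
        # established flanking runs, else the flanks are the deviation
        if (span > min(spans[b - 1], spans[b + 1])) next
        if (span < window_cM) {
          loci <- sel[starts[b]:ends[b]]
          dc[[length(dc) + 1]] <- tibble::tibble(
            locus = loci, marker = map$marker[loci],
            chrom = map$chrom[loci], reason = "double_crossover",
            individual = colnames(dos)[j], evidence = span
          )
        }
      }
    }
  }
  if (length(dc)) flags$double_crossover <- dplyr::bind_rows(dc)

  if (!is.null(bundle$quality)) {
    low <- which(!is.na(bundle$quality) &
                   bundle$quality < quality_threshold, arr.ind = TRUE)
    if (nrow(low)) {
      flags$low_quality <- tibble::tibble(
        locus = low[, 1], marker = map$marker[low[, 1]],
        chrom = map$chrom[low[, 1]], reason = "low_quality",
        individual = colnames(dos)[low[, 2]],
        evidence = bundle$quality[low]
      )
    }
  }

  out <- if (length(flags)) {
    dplyr::arrange(dplyr::bind_rows(flags), .data$locus, .data$reason)
  } else {
    tibble::tibble(locus = integer(), marker = character(),
                   chrom = character(), reason = character(),
                   individual = character(), evidence = double())
  }
  structure(out, class = c("ancestry_flags", class(out)),
            window_cM = window_cM, quality_threshold = quality_threshold)
}
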