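# Independent oracles: every routine here recomputes the quantity it checks
# from first principles (full enumeration or direct simulation), sharing no
# code path with the package implementation.

# Mendelian consistency by exhaustive enumeration of ordered allele pairs
oracle_consistent <- function(config, ped) {
  n <- nrow(ped)
  fa <- match(ped$father_id, ped$id)
  mo <- match(ped$mother_id, ped$id)
  pairs_of <- function(d) {
    if (is.na(d)) {
      list(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
    } else if (d == 0) {
      list(c(0, 0))
    } else if (d == 2) {
      list(c(1, 1))
    } else {
      list(c(0, 1), c(1, 0))
    }
  }
  cand <- lapply(config, pairs_of)
  idx <- expand.grid(lapply(cand, seq_along))
  for (r in seq_len(nrow(idx))) {
    asn <- lapply(seq_len(n), function(i) cand[[i]][[idx[r, i]]])
    ok <- TRUE
    for (i in seq_len(n)) {
      if (!is.na(fa[i]) && !(asn[[i]][1] %in% asn[[fa[i]]])) { ok <- FALSE; break }
      if (!is.na(mo[i]) && !(asn[[i]][2] %in% asn[[mo[i]]])) { ok <- FALSE; break }
    }
    if (ok) return(TRUE)
  }
  FALSE
}

# vectorized nuclear-family consistency from dosages (p2 = NULL: one parent)
nf_ok_vec <- function(p1, p2, kids) {
  f0 <- p1 <= 1; f1 <- p1 >= 1
  if (is.null(p2)) {
    m0 <- rep(TRUE, length(p1)); m1 <- m0
  } else {
    m0 <- p2 <= 1; m1 <- p2 >= 1
  }
  ok <- rep(TRUE, length(p1))
  for (j in seq_len(ncol(kids))) {
    cc <- kids[, j]
    ok <- ok & ((cc == 0 & f0 & m0) | (cc == 2 & f1 & m1) |
                  (cc == 1 & ((f0 & m1) | (f1 & m0))))
  }
  ok
}

# Monte-Carlo expected Mendelian-error rate per locus under the
# one-member-at-a-time allelic-flip mechanism
mc_mendelian_rate <- function(type, m, eps, lam, reps) {
  perturb <- function(a, b) {
    u <- runif(length(a))
    p1 <- eps * (1 - eps)
    ifelse(u < p1, (1 - a) + b,
           ifelse(u < 2 * p1, a + (1 - b),
                  ifelse(u < 2 * p1 + eps^2, (1 - a) + (1 - b), a + b)))
  }
  if (type == "two_parent") {
    fa1 <- rbinom(reps, 1, lam); fa2 <- rbinom(reps, 1, lam)
    ma1 <- rbinom(reps, 1, lam); ma2 <- rbinom(reps, 1, lam)
    kidp <- sapply(seq_len(m), function(k) {
      ifelse(rbinom(reps, 1, 0.5) == 0, fa1, fa2)
    })
    kidm <- sapply(seq_len(m), function(k) {
      ifelse(rbinom(reps, 1, 0.5) == 0, ma1, ma2)
    })
    alleles <- c(list(cbind(fa1, fa2), cbind(ma1, ma2)),
                 lapply(seq_len(m), function(k) cbind(kidp[, k], kidm[, k])))
    dos <- cbind(fa1 + fa2, ma1 + ma2, kidp + kidm)
    nme <- numeric(reps)
    for (j in seq_along(alleles)) {
      dd <- dos
      dd[, j] <- perturb(alleles[[j]][, 1], alleles[[j]][, 2])
      nme <- nme + !nf_ok_vec(dd[, 1], dd[, 2], dd[, -(1:2), drop = FALSE])
    }
  } else {
    pa1 <- rbinom(reps, 1, lam); pa2 <- rbinom(reps, 1, lam)
    kidp <- sapply(seq_len(m), function(k) {
      ifelse(rbinom(reps, 1, 0.5) == 0, pa1, pa2)
    })
    kidm <- sapply(seq_len(m), function(k) rbinom(reps, 1, lam))
    alleles <- c(list(cbind(pa1, pa2)),
                 lapply(seq_len(m), function(k) cbind(kidp[, k], kidm[, k])))
    dos <- cbind(pa1 + pa2, kidp + kidm)
    nme <- numeric(reps)
    for (j in seq_along(alleles)) {
      dd <- dos
      dd[, j] <- perturb(alleles[[j]][, 1], alleles[[j]][, 2])
      nme <- nme + !nf_ok_vec(dd[, 1], NULL, dd[, -1, drop = FALSE])
    }
  }
  list(mean = mean(nme), se = stats::sd(nme) / sqrt(reps))
}

# Exact expected Mendelian-error rate by full enumeration (same mechanism)
exact_mendelian_rate <- function(type, m, eps, lam) {
  w_founder <- function(a) ifelse(a == 1, lam, 1 - lam)
  tot <- 0
  flip_w <- c(eps * (1 - eps), eps * (1 - eps), eps^2)
  flips <- list(c(1, 0), c(0, 1), c(1, 1))
  if (type == "two_parent") {
    for (fa1 in 0:1) for (fa2 in 0:1) for (ma1 in 0:1) for (ma2 in 0:1) {
      pf <- prod(w_founder(c(fa1, fa2, ma1, ma2)))
      grids <- expand.grid(rep(list(1:2), 2 * m))
      for (g in seq_len(nrow(grids))) {
        sel <- as.integer(grids[g, ])
        kal <- lapply(seq_len(m), function(k) {
          c(c(fa1, fa2)[sel[2 * k - 1]], c(ma1, ma2)[sel[2 * k]])
        })
        pg <- pf * (1 / 4)^m
        dos <- c(fa1 + fa2, ma1 + ma2, vapply(kal, sum, 0))
        alleles <- c(list(c(fa1, fa2), c(ma1, ma2)), kal)
        for (j in seq_along(alleles)) {
          for (q in 1:3) {
            nal <- ifelse(flips[[q]] == 1, 1 - alleles[[j]], alleles[[j]])
            nd <- dos; nd[j] <- sum(nal)
            if (!nf_ok_vec(nd[1], nd[2],
                           matrix(nd[-(1:2)], 1))) {
              tot <- tot + pg * flip_w[q]
            }
          }
        }
      }
    }
  } else {
    for (pa1 in 0:1) for (pa2 in 0:1) {
      pf <- prod(w_founder(c(pa1, pa2)))
      grids <- expand.grid(c(rep(list(1:2), m), rep(list(0:1), m)))
      for (g in seq_len(nrow(grids))) {
        v <- as.integer(grids[g, ])
        sel <- v[seq_len(m)]; oth <- v[m + seq_len(m)]
        kal <- lapply(seq_len(m), function(k) {
          c(c(pa1, pa2)[sel[k]], oth[k])
        })
        pg <- pf * (1 / 2)^m * prod(w_founder(oth))
        dos <- c(pa1 + pa2, vapply(kal, sum, 0))
        alleles <- c(list(c(pa1, pa2)), kal)
        for (j in seq_along(alleles)) {
          for (q in 1:3) {
            nal <- ifelse(flips[[q]] == 1, 1 - alleles[[j]], alleles[[j]])
            nd <- dos; nd[j] <- sum(nal)
            if (!nf_ok_vec(nd[1], NULL, matrix(nd[-1], 1))) {
              tot <- tot + pg * flip_w[q]
            }
          }
        }
      }
    }
  }
  tot
}

# Brute-force MAP corrector over the full consistent set, with all
# probabilities recomputed from first principles
oracle_map <- function(y, xl, xr, dl, dr, ped, eps, lamb, tau) {
  n <- nrow(ped)
  grid <- as.matrix(expand.grid(rep(list(0:2), n)))
  cons <- apply(grid, 1, oracle_consistent, ped = ped)
  cfgs <- grid[cons, , drop = FALSE]
  pyx <- function(yv, xv) {
    a <- switch(xv + 1, c(0, 0), c(0, 1), c(1, 1))
    pr <- 0
    for (f1 in 0:1) for (f2 in 0:1) {
      o <- c(if (f1) 1 - a[1] else a[1], if (f2) 1 - a[2] else a[2])
      if (sum(o) == yv) {
        pr <- pr + eps^f1 * (1 - eps)^(1 - f1) * eps^f2 * (1 - eps)^(1 - f2)
      }
    }
    pr
  }
  hap <- function(d) {
    e <- exp(-d * tau)
    matrix(c(e + (1 - lamb) * (1 - e), lamb * (1 - e),
             (1 - lamb) * (1 - e), e + lamb * (1 - e)),
           2, 2, byrow = TRUE)
  }
  dip <- function(d) {
    h <- hap(d)
    out <- matrix(0, 3, 3)
    prs <- list(c(1, 1), c(1, 2), c(2, 2))
    for (x in 0:2) {
      p <- prs[[x + 1]]
      for (a in 1:2) for (b in 1:2) {
        yy <- (a - 1) + (b - 1)
        out[x + 1, yy + 1] <- out[x + 1, yy + 1] + h[p[1], a] * h[p[2], b]
      }
    }
    out
  }
  score <- apply(cfgs, 1, function(x) {
    s <- sum(log(pmax(mapply(pyx, y, x), 1e-300)))
    if (!is.null(xl)) {
      tm <- dip(dl)
      s <- s + sum(log(pmax(tm[cbind(xl + 1, x + 1)], 1e-300)))
    }
    if (!is.null(xr)) {
      tm <- dip(dr)
      s <- s + sum(log(pmax(tm[cbind(x + 1, xr + 1)], 1e-300)))
    }
    s
  })
  best <- max(score)
  tied <- which(score >= best - 1e-12)
  if (length(tied) > 1) {
    ham <- rowSums(cfgs[tied, , drop = FALSE] !=
                     matrix(y, length(tied), n, byrow = TRUE))
    tied <- tied[ham == min(ham)]
    if (length(tied) > 1) {
      tied <- tied[do.call(order, as.data.frame(cfgs[tied, , drop = FALSE]))[1]]
    }
  }
  list(config = unname(cfgs[tied[1], ]), score = best)
}

# random consistent configuration for a small pedigree
random_consistent <- function(ped) {
  grid <- as.matrix(expand.grid(rep(list(0:2), nrow(ped))))
  cons <- apply(grid, 1, oracle_consistent, ped = ped)
  cfgs <- grid[cons, , drop = FALSE]
  unname(cfgs[sample(nrow(cfgs), 1), ])
}
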