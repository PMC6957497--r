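#' Construct a pedigree
#'
#' A pedigree is a tibble with one row per individual and columns `id`,
#' `father_id`, `mother_id` (`NA` when the parent is not in the pedigree),
#' `sex` (`"male"`, `"female"` or `"unknown"`; parsed but unused by the
#' autosomal ancestry model) and `genotyped` (logical). Individuals may be
#' listed in any order; functions that need it compute a parents-first
#' ordering internally.
#'
#' @param df Data frame with at least an `id` column; missing columns are
#'   filled with defaults (`father_id`/`mother_id` = `NA`, `sex` = unknown,
#'   `genotyped` = `TRUE`).
#' @param name Family name attached to the pedigree.
#' @return A tibble of class `pedigree`.
#' @examples
#' pedigree(data.frame(
#'   id = c("F", "M", "C"),
#'   father_id = c(NA, NA, "F"),
#'   mother_id = c(NA, NA, "M")
#' ))
#' @export
pedigree <- function(df, name = "ped") {
  df <- tibble::as_tibble(df)
  if (!"id" %in% names(df)) stop("pedigree needs an `id` column", call. = FALSE)
  df$id <- as.character(df$id)
  if (!"father_id" %in% names(df)) df$father_id <- NA_character_
  if (!"mother_id" %in% names(df)) df$mother_id <- NA_character_
  if (!"sex" %in% names(df)) df$sex <- "unknown"
  if (!"genotyped" %in% names(df)) df$genotyped <- TRUE
  df$father_id <- as.character(df$father_id)
  df$mother_id <- as.character(df$mother_id)
  df <- df[, c("id", "father_id", "mother_id", "sex", "genotyped")]
  validate_pedigree(df, name)
  structure(df, class = c("pedigree", class(df)), family = name)
}

validate_pedigree <- function(df, name) {
  if (nrow(df) < 1) stop("pedigree `", name, "` is empty", call. = FALSE)
  if (any(!nzchar(df$id)) || anyNA(df$id)) {
    stop("pedigree `", name, "` has empty individual ids", call. = FALSE)
  }
  dup <- df$id[duplicated(df$id)]
  if (length(dup)) {
    stop("duplicate individual id(s) in family `", name, "`: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  refs <- stats::na.omit(c(df$father_id, df$mother_id))
  missing <- setdiff(refs, df$id)
  if (length(missing)) {
    stop("parent id(s) referenced but absent in family `", name, "`: ",
         paste(sort(unique(missing)), collapse = ", "), call. = FALSE)
  }
  # acyclicity via topological sort
  if (is.null(topo_order_or_null(df))) {
    stop("cyclic ancestry in family `", name, "`", call. = FALSE)
  }
  invisible(df)
}

topo_order_or_null <- function(df) {
  n <- nrow(df)
  fa <- match(df$father_id, df$id)
  mo <- match(df$mother_id, df$id)
  placed <- logical(n)
  ord <- integer(0)
  ok <- function(p) is.na(p) | placed[ifelse(is.na(p), 1L, p)]
  repeat {
    idx <- which(!placed & ok(fa) & ok(mo))
    if (!length(idx)) break
    ord <- c(ord, idx)
    placed[idx] <- TRUE
  }
  if (length(ord) < n) NULL else ord
}

#' @export
print.pedigree <- function(x, ...) {
  cat("<pedigree> family:", attr(x, "family"), "- n =", nrow(x),
      "(", sum(is.na(x$father_id) & is.na(x$mother_id)), "founders )\n")
  NextMethod()
}

ped_family <- function(ped) attr(ped, "family") %||% "ped"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Depth of each individual below the founders
#'
#' Founders have generation 0; every other individual is one more than the
#' deepest recorded parent.
#' @param ped A [pedigree()].
#' @return Integer vector aligned with `ped$id`.
#' @export
ped_generation <- function(ped) {
  ord <- topo_order_or_null(ped)
  fa <- match(ped$father_id, ped$id)
  mo <- match(ped$mother_id, ped$id)
  gen <- integer(nrow(ped))
  for (i in ord) {
    g <- -1L
    if (!is.na(fa[i])) g <- max(g, gen[fa[i]])
    if (!is.na(mo[i])) g <- max(g, gen[mo[i]])
    gen[i] <- g + 1L
  }
  gen
}

# parents-first view used by the C++ kernel: list(order, father, mother)
# father/mother are 1-based indices into the reordered individuals, 0 = absent
ped_topology <- function(ped) {
  ord <- topo_order_or_null(ped)
  ids <- ped$id[ord]
  fa <- match(ped$father_id[ord], ids)
  mo <- match(ped$mother_id[ord], ids)
  fa[is.na(fa)] <- 0L
  mo[is.na(mo)] <- 0L
  list(order = ord, ids = ids, father = as.integer(fa), mother = as.integer(mo))
}

#' Read pedigrees from a PLINK `.fam` / pre-makeped LINKAGE file
#'
#' Whitespace-delimited, six columns per line: family id, individual id,
#' father id, mother id, sex (1 = male, 2 = female, other = unknown) and
#' phenotype (ignored). `"0"` denotes a missing parent.
#'
#' @param file Path to the pedigree file.
#' @param text Optional character vector of lines, used instead of `file`.
#' @return A named list of [pedigree()] objects, one per family id, in order
#'   of first appearance.
#' @examples
#' read_pedigree(text = c("f1 F 0 0 1 -9", "f1 M 0 0 2 -9", "f1 C F M 1 -9"))
#' @export
read_pedigree <- function(file, text = NULL) {
  lines <- if (is.null(text)) readLines(file) else text
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("pedigree file is empty", call. = FALSE)
  fields <- strsplit(lines, "[ \t]+")
  bad <- which(lengths(fields) < 6)
  if (length(bad)) {
    stop("pedigree line ", bad[1], " has fewer than 6 fields", call. = FALSE)
  }
  rec <- tibble::tibble(
    family = vapply(fields, `[[`, "", 1),
    id = vapply(fields, `[[`, "", 2),
    father_id = vapply(fields, `[[`, "", 3),
    mother_id = vapply(fields, `[[`, "", 4),
    sex = vapply(fields, `[[`, "", 5)
  )
  rec$father_id[rec$father_id == "0"] <- NA_character_
  rec$mother_id[rec$mother_id == "0"] <- NA_character_
  rec$sex <- unname(c("1" = "male", "2" = "female")[rec$sex])
  rec$sex[is.na(rec$sex)] <- "unknown"
  fams <- unique(rec$family)
  out <- lapply(fams, function(f) {
    pedigree(rec[rec$family == f, -1], name = f)
  })
  stats::setNames(out, fams)
}

#' Write pedigrees back to `.fam` format
#'
#' @param peds A [pedigree()] or list of pedigrees.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_pedigree <- function(peds, file) {
  if (inherits(peds, "pedigree")) peds <- list(peds)
  lines <- unlist(lapply(peds, function(p) {
    fa <- ifelse(is.na(p$father_id), "0", p$father_id)
    mo <- ifelse(is.na(p$mother_id), "0", p$mother_id)
    sx <- c(male = "1", female = "2", unknown = "0")[p$sex]
    paste(ped_family(p), p$id, fa, mo, sx, "-9")
  }))
  writeLines(lines, file)
  invisible(file)
}

#' Drop ungenotyped founders and split a pedigree into connected parts
#'
#' Removes top-generation individuals (those with no recorded parents) that
#' are not in `genotyped_ids`, severs the corresponding parent links, and
#' partitions the remaining individuals into connected sub-pedigrees.
#' Individuals left without any relative (singleton components) are dropped.
#'
#' @param ped A [pedigree()].
#' @param genotyped_ids Character vector of individual ids with data;
#'   must be a subset of the pedigree ids.
#' @return A list of [pedigree()] objects (possibly empty, with a warning).
#' @export
split_on_missing_founders <- function(ped, genotyped_ids) {
  stopifnot(inherits(ped, "pedigree"))
  extra <- setdiff(genotyped_ids, ped$id)
  if (length(extra)) {
    stop("genotyped ids not in pedigree: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  founder <- is.na(ped$father_id) & is.na(ped$mother_id)
  drop <- founder & !(ped$id %in% genotyped_ids)
  keep <- ped[!drop, , drop = FALSE]
  if (nrow(keep) == 0) {
    warning("all individuals removed from family `", ped_family(ped), "`")
    return(list())
  }
  keep$father_id[!(keep$father_id %in% keep$id)] <- NA_character_
  keep$mother_id[!(keep$mother_id %in% keep$id)] <- NA_character_
  comp <- connected_components(keep)
  sizes <- tabulate(comp)
  parts <- sort(unique(comp[sizes[comp] > 1]))
  if (!length(parts)) {
    warning("family `", ped_family(ped),
            "` reduced to unrelated singletons; all removed")
    return(list())
  }
  out <- lapply(seq_along(parts), function(k) {
    sub <- keep[comp == parts[k], , drop = FALSE]
    nm <- if (length(parts) == 1) ped_family(ped) else {
      paste0(ped_family(ped), ".", k)
    }
    pedigree(sub, name = nm)
  })
  out
}

connected_components <- function(df) {
  n <- nrow(df)
  idx <- seq_len(n)
  fa <- match(df$father_id, df$id)
  mo <- match(df$mother_id, df$id)
  # union-find over parent-child edges
  parent <- idx
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[ri] <<- rj
  }
  for (i in idx) {
    if (!is.na(fa[i])) union(i, fa[i])
    if (!is.na(mo[i])) union(i, mo[i])
  }
  roots <- vapply(idx, find, 0L)
  match(roots, unique(roots))
}

#' Partition a pedigree into non-overlapping nuclear families
#'
#' Greedily selects parent(s)-plus-children units so that no individual is
#' used twice. Sibships are ranked by size (larger first), then by parental
#' generation (earlier first), then by order of appearance; at selection time
#' a sibship contributes only its still-unused children, and is skipped when
#' a structural parent is already used. Sibships whose second parent is not
#' recorded in the pedigree form `one_parent` families.
#'
#' @param ped A [pedigree()].
#' @return A tibble with columns `family` (integer), `type`
#'   (`"two_parent"`/`"one_parent"`), `parents` and `children` (list columns
#'   of ids), and `m` (number of children). Individuals not placed in any
#'   family are in `attr(, "leftovers")`.
#' @examples
#' trio <- read_pedigree(text = c(
#'   "f F 0 0 1 -9", "f M 0 0 2 -9", "f C F M 1 -9"
#' ))[[1]]
#' extract_nuclear_families(trio)
#' @export
extract_nuclear_families <- function(ped) {
  stopifnot(inherits(ped, "pedigree"))
  gen <- ped_generation(ped)
  names(gen) <- ped$id
  kids <- ped[!(is.na(ped$father_id) & is.na(ped$mother_id)), , drop = FALSE]
  if (nrow(kids) == 0) {
    out <- tibble::tibble(
      family = integer(), type = character(),
      parents = list(), children = list(), m = integer()
    )
    attr(out, "leftovers") <- ped$id
    return(out)
  }
  key <- paste(kids$father_id, kids$mother_id, sep = "\r")
  sib <- split(kids$id, key)
  pinfo <- lapply(sib, function(ids) {
    i <- match(ids[1], ped$id)
    c(ped$father_id[i], ped$mother_id[i])
  })
  m0 <- lengths(sib)
  pgen <- vapply(pinfo, function(p) {
    p <- p[!is.na(p)]
    min(gen[p])
  }, 0)
  ord <- order(-m0, pgen, vapply(sib, function(ids) {
    min(match(ids, ped$id))
  }, 0))
  used <- character(0)
  rows <- list()
  fam <- 0L
  for (s in ord) {
    par <- pinfo[[s]][!is.na(pinfo[[s]])]
    if (any(par %in% used)) next
    ch <- setdiff(sib[[s]], used)
    if (!length(ch)) next
    fam <- fam + 1L
    type <- if (length(par) == 2) "two_parent" else "one_parent"
    rows[[fam]] <- tibble::tibble(
      family = fam, type = type,
      parents = list(par), children = list(ch), m = length(ch)
    )
    used <- c(used, par, ch)
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble::tibble(family = integer(), type = character(),
                   parents = list(), children = list(), m = integer())
  }
  attr(out, "leftovers") <- setdiff(ped$id, used)
  out
}
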