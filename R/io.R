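#' Construct an ancestry dosage matrix
#'
#' Holds per-marker diploid local-ancestry dosages for a set of individuals:
#' the count (0, 1 or 2) of population-A ancestry alleles at each marker.
#' Rows are markers (in map order), columns individuals. An optional quality
#' matrix of the same shape carries the upstream caller's per-call posterior
#' confidence in `[0, 1]`.
#'
#' @param dosage Integer matrix, markers x individuals, entries in
#'   `{0, 1, 2}` or `NA`, with marker row names and individual column names.
#' @param quality Optional numeric matrix of the same shape, values in
#'   `[0, 1]`.
#' @return An object of class `ancestry_matrix`.
#' @export
ancestry_matrix <- function(dosage, quality = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(rownames(dosage)) || is.null(colnames(dosage))) {
    stop("dosage matrix needs marker row names and individual column names",
         call. = FALSE)
  }
  bad <- which(!is.na(dosage) & !(dosage %in% 0:2))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(dosage))
    stop("dosage value out of {0,1,2,NA} at marker `",
         rownames(dosage)[rc[1]], "`, individual `", colnames(dosage)[rc[2]],
         "`", call. = FALSE)
  }
  if (!is.null(quality)) {
    quality <- as.matrix(quality)
    storage.mode(quality) <- "double"
    if (!identical(dim(quality), dim(dosage))) {
      stop("quality matrix shape differs from dosage", call. = FALSE)
    }
    if (any(quality < 0 | quality > 1, na.rm = TRUE)) {
      stop("quality values must lie in [0, 1]", call. = FALSE)
    }
    dimnames(quality) <- dimnames(dosage)
  }
  structure(list(dosage = dosage, quality = quality),
            class = "ancestry_matrix")
}

#' @export
print.ancestry_matrix <- function(x, ...) {
  cat("<ancestry_matrix>", nrow(x$dosage), "markers x", ncol(x$dosage),
      "individuals;", if (is.null(x$quality)) "no" else "with",
      "quality\n")
  invisible(x)
}

#' @export
dim.ancestry_matrix <- function(x) dim(x$dosage)

#' Read an ancestry dosage matrix from TSV
#'
#' Expected layout: a header line `marker` followed by individual ids, then
#' one row per marker with values in `{0, 1, 2, NA}`.
#'
#' @param file Path to the dosage TSV.
#' @param quality_file Optional path to a quality TSV of identical layout
#'   with values in `[0, 1]`.
#' @return An [ancestry_matrix()].
#' @export
read_ancestry_matrix <- function(file, quality_file = NULL) {
  dosage <- read_marker_table(file)
  quality <- if (!is.null(quality_file)) read_marker_table(quality_file)
  if (!is.null(quality) && !identical(dimnames(quality), dimnames(dosage))) {
    stop("quality file markers/individuals do not match the dosage file",
         call. = FALSE)
  }
  ancestry_matrix(dosage, quality)
}

read_marker_table <- function(file) {
  tab <- readr::read_tsv(file, col_types = readr::cols(
    .default = readr::col_double(),
    marker = readr::col_character()
  ), na = c("NA", ""), progress = FALSE)
  probs <- readr::problems(tab)
  if (nrow(probs)) {
    stop("malformed table `", file, "`: row ", probs$row[1], ", ",
         probs$expected[1], " but got ", probs$actual[1], call. = FALSE)
  }
  if (names(tab)[1] != "marker") {
    stop("first column of `", file, "` must be `marker`", call. = FALSE)
  }
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$marker
  m
}

#' Write an ancestry matrix (and its quality) to TSV
#'
#' @param x An [ancestry_matrix()].
#' @param file Output path for the dosage TSV.
#' @param quality_file Optional output path for the quality TSV.
#' @return `file`, invisibly.
#' @export
write_ancestry_matrix <- function(x, file, quality_file = NULL) {
  stopifnot(inherits(x, "ancestry_matrix"))
  write_marker_table(x$dosage, file)
  if (!is.null(quality_file)) {
    if (is.null(x$quality)) stop("no quality matrix to write", call. = FALSE)
    write_marker_table(x$quality, quality_file)
  }
  invisible(file)
}

write_marker_table <- function(m, file) {
  df <- tibble::as_tibble(m, rownames = "marker")
  readr::write_tsv(df, file, na = "NA", progress = FALSE)
}

#' Construct a genetic map
#'
#' An ordered table of marker positions in centiMorgans, grouped by
#' chromosome. Positions must be non-decreasing within a chromosome;
#' co-located markers (equal positions) are allowed.
#'
#' @param df Data frame with columns `marker`, `chrom`, `pos_cM`.
#' @return A tibble of class `genetic_map`.
#' @export
genetic_map <- function(df) {
  df <- tibble::as_tibble(df)[, c("marker", "chrom", "pos_cM")]
  df$marker <- as.character(df$marker)
  df$chrom <- as.character(df$chrom)
  df$pos_cM <- as.numeric(df$pos_cM)
  if (anyNA(df$pos_cM) || any(df$pos_cM < 0)) {
    stop("map positions must be nonnegative numbers", call. = FALSE)
  }
  if (anyDuplicated(df$marker)) {
    stop("duplicate marker ids in map", call. = FALSE)
  }
  for (ch in unique(df$chrom)) {
    p <- df$pos_cM[df$chrom == ch]
    if (any(diff(p) < 0)) {
      stop("map positions decrease on chromosome ", ch, call. = FALSE)
    }
  }
  structure(df, class = c("genetic_map", class(df)))
}

#' Read a genetic map
#'
#' Accepts either a 3-column whitespace/tab-delimited table
#' (`marker`, `chromosome`, `cM`, with or without a header) or a 6-column
#' PLINK `.bim` file, whose third column is taken as the cM position.
#'
#' @param file Path to the map file.
#' @return A [genetic_map()].
#' @export
read_genetic_map <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (length(unique(nf)) != 1) stop("ragged map file", call. = FALSE)
  if (nf[1] == 6) {
    df <- tibble::tibble(
      marker = vapply(fields, `[[`, "", 2),
      chrom = vapply(fields, `[[`, "", 1),
      pos_cM = as.numeric(vapply(fields, `[[`, "", 3))
    )
  } else if (nf[1] == 3) {
    # drop a header line if the position field is not numeric
    if (is.na(suppressWarnings(as.numeric(fields[[1]][3])))) {
      fields <- fields[-1]
    }
    df <- tibble::tibble(
      marker = vapply(fields, `[[`, "", 1),
      chrom = vapply(fields, `[[`, "", 2),
      pos_cM = as.numeric(vapply(fields, `[[`, "", 3))
    )
  } else {
    stop("map file must have 3 columns or be a 6-column .bim", call. = FALSE)
  }
  genetic_map(df)
}

#' Write a genetic map as 3-column TSV
#' @param map A [genetic_map()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_genetic_map <- function(map, file) {
  readr::write_tsv(tibble::as_tibble(unclass(map))[, c("marker", "chrom", "pos_cM")],
                   file, col_names = FALSE, progress = FALSE)
  invisible(file)
}

#' Inter-marker distances in Morgans
#'
#' @param map A [genetic_map()].
#' @return Numeric vector of length `nrow(map)`: distance from the previous
#'   marker on the same chromosome, in Morgans; `NA` for the first marker of
#'   each chromosome.
#' @export
map_distances <- function(map) {
  stopifnot(inherits(map, "genetic_map"))
  unlist(lapply(split(map$pos_cM, factor(map$chrom, unique(map$chrom))),
                function(p) c(NA_real_, diff(p) / 100)),
         use.names = FALSE)
}

#' Align an ancestry matrix with a map and a pedigree
#'
#' Restricts the matrix to the individuals present in the pedigree and the
#' markers present in the map, reorders markers to map order, and reports
#' what was dropped.
#'
#' @param anc An [ancestry_matrix()].
#' @param map A [genetic_map()].
#' @param ped A [pedigree()].
#' @return An `ancestry_bundle`: list with elements `dosage`, `quality`,
#'   `map` (restricted), `ped`, and `dropped` (list of dropped individual and
#'   marker ids).
#' @export
align_ancestry <- function(anc, map, ped) {
  stopifnot(inherits(anc, "ancestry_matrix"), inherits(map, "genetic_map"),
            inherits(ped, "pedigree"))
  ids <- intersect(ped$id, colnames(anc$dosage))
  if (!length(ids)) {
    stop("no pedigree individual found in the ancestry matrix", call. = FALSE)
  }
  mk <- map$marker[map$marker %in% rownames(anc$dosage)]
  if (!length(mk)) {
    stop("no overlap between map and ancestry-matrix markers", call. = FALSE)
  }
  dropped <- list(
    individuals = setdiff(colnames(anc$dosage), ids),
    markers = setdiff(rownames(anc$dosage), mk),
    no_data = setdiff(ped$id, ids)
  )
  # one column per pedigree member; members without calls stay all-NA and
  # contribute only through the Mendelian constraints they impose on others
  dosage <- matrix(NA_integer_, length(mk), nrow(ped),
                   dimnames = list(mk, ped$id))
  dosage[, ids] <- anc$dosage[mk, ids]
  quality <- NULL
  if (!is.null(anc$quality)) {
    quality <- matrix(NA_real_, length(mk), nrow(ped),
                      dimnames = list(mk, ped$id))
    quality[, ids] <- anc$quality[mk, ids]
  }
  structure(
    list(
      dosage = dosage, quality = quality,
      map = genetic_map(map[map$marker %in% mk, ]),
      ped = ped, dropped = dropped
    ),
    class = "ancestry_bundle"
  )
}

#' @export
print.ancestry_bundle <- function(x, ...) {
  cat("<ancestry_bundle>", nrow(x$dosage), "markers x", ncol(x$dosage),
      "individuals; family:", ped_family(x$ped), "\n")
  nd <- lengths(x$dropped)
  if (any(nd > 0)) {
    cat("  dropped:", paste(names(nd)[nd > 0], nd[nd > 0], collapse = ", "),
        "\n")
  }
  invisible(x)
}
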