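#' Genotype matrix container
#'
#' Bundles an individuals-by-markers dosage matrix (counted-allele copies,
#' coded 0/1/2 with `NA` for missing calls) with a marker map and a
#' population label per individual.  All downstream machinery -- quality
#' control, LD statistics, the genomic relationship matrix and the
#' whole-genome regression models -- operates on this container.
#'
#' @param dosages numeric matrix, individuals x markers, entries in
#'   \{0, 1, 2, NA\}.  Row names are used as individual ids when `ids` is
#'   missing.
#' @param map data.frame with columns `chr` (autosome index), `pos`
#'   (base pairs, 1-based) and `name` (marker id), one row per marker,
#'   sorted by (chr, pos).
#' @param pop character/factor vector of population labels, one per
#'   individual; a single value is recycled.
#' @param ids character vector of unique individual ids.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `map`, `ids`, `pop`.
#' @export
genotype_matrix <- function(dosages, map, pop = "pop1", ids = rownames(dosages)) {
  dosages <- as.matrix(dosages)
  if (is.null(ids)) ids <- paste0("ind", seq_len(nrow(dosages)))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("duplicated individual ids: ",
                               paste(head(unique(ids[duplicated(ids)]), 3), collapse = ", "))
  if (length(ids) != nrow(dosages)) stop("ids length does not match dosage rows")
  map <- as.data.frame(map)
  stopifnot(all(c("chr", "pos", "name") %in% names(map)))
  if (nrow(map) != ncol(dosages)) stop("map rows do not match dosage columns")
  ## raw calls are 0/1/2/NA; mean-dosage imputation may insert fractional
  ## values, so the container enforces the [0, 2] range only
  if (length(dosages) > 0 && !all(is.na(dosages))) {
    rng <- range(dosages, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 2) stop("dosages must lie in [0, 2] (or be NA)")
  }
  o <- order(map$chr, map$pos)
  if (is.unsorted(o)) {
    map <- map[o, , drop = FALSE]
    dosages <- dosages[, o, drop = FALSE]
  }
  for (ch in unique(map$chr)) {
    p <- map$pos[map$chr == ch]
    if (any(diff(p) <= 0)) stop("marker positions must be strictly increasing within chromosome ", ch)
  }
  pop <- rep_len(as.character(pop), length(ids))
  rownames(dosages) <- ids
  colnames(dosages) <- map$name
  structure(list(dosages = dosages, map = map, ids = ids, pop = pop),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$ids), "individuals x", nrow(x$map), "markers\n")
  cat("  chromosomes:", length(unique(x$map$chr)),
      " populations:", paste(names(table(x$pop)), table(x$pop), sep = "=", collapse = ", "), "\n")
  miss <- mean(is.na(x$dosages))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Counted-allele frequencies from observed calls
#'
#' @param genos a [genotype_matrix]
#' @return numeric vector of per-marker frequencies of the counted allele,
#'   computed over non-missing calls.
#' @export
allele_freq <- function(genos) {
  colMeans(genos$dosages, na.rm = TRUE) / 2
}

#' Stack two genotype matrices sharing a marker map
#'
#' Used to build the joint (two-population) dataset for combined-reference
#' and multi-trait analyses.
#'
#' @param g1,g2 [genotype_matrix] objects with identical marker maps.
#' @return a [genotype_matrix] holding both sets of individuals.
#' @export
merge_genotypes <- function(g1, g2) {
  if (!identical(g1$map$name, g2$map$name))
    stop("marker maps differ; cannot merge")
  genotype_matrix(rbind(g1$dosages, g2$dosages), g1$map,
                  pop = c(g1$pop, g2$pop), ids = c(g1$ids, g2$ids))
}

#' Subset a genotype matrix
#'
#' @param genos a [genotype_matrix]
#' @param ids individual ids to keep (order preserved as given)
#' @param markers optional marker names or column indices to keep
#' @return a [genotype_matrix]
#' @export
subset_genotypes <- function(genos, ids = genos$ids, markers = NULL) {
  ri <- match(ids, genos$ids)
  if (anyNA(ri)) stop("unknown individual id(s): ", paste(head(ids[is.na(ri)], 3), collapse = ", "))
  ci <- seq_len(ncol(genos$dosages))
  if (!is.null(markers)) {
    ci <- if (is.character(markers)) match(markers, genos$map$name) else markers
    if (anyNA(ci)) stop("unknown marker(s)")
  }
  genotype_matrix(genos$dosages[ri, ci, drop = FALSE],
                  genos$map[ci, , drop = FALSE],
                  pop = genos$pop[ri], ids = genos$ids[ri])
}
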