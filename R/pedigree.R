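## Pedigree machinery: numerator relationship matrix (tabular method),
## inbreeding coefficients and the sparse A-inverse by Henderson's rules.

#' Build a validated pedigree
#'
#' Orders individuals topologically (parents before offspring), detects
#' cycles, and returns integer parent indices.  Unknown parents are coded
#' `"0"`, `NA` or `""` on input and `0L` internally.
#'
#' @param df data.frame with columns `id`, `sire`, `dam` (character or
#'   numeric); additional columns are carried through.
#' @return a `pedigree` object: list with `id` (ordered), `sire`, `dam`
#'   (integer indices into `id`, 0 = unknown) and `extra` (the reordered
#'   input rows).
#' @export
pedigree <- function(df) {
  df <- as.data.frame(df)
  stopifnot(all(c("id", "sire", "dam") %in% names(df)))
  id <- as.character(df$id)
  if (anyDuplicated(id)) stop("duplicated pedigree id: ",
                              id[anyDuplicated(id)])
  clean <- function(x) {
    x <- as.character(x)
    x[is.na(x) | x == "" | x == "0"] <- NA
    x
  }
  sire <- clean(df$sire); dam <- clean(df$dam)
  unknown <- unique(c(sire[!is.na(sire) & !(sire %in% id)],
                      dam[!is.na(dam) & !(dam %in% id)]))
  if (length(unknown) > 0)
    stop("parent(s) not in pedigree: ", paste(head(unknown, 3), collapse = ", "))
  n <- length(id)
  si <- match(sire, id); di <- match(dam, id)
  ## Kahn-style topological sort
  order_idx <- integer(0)
  placed <- logical(n)
  repeat {
    ready <- which(!placed & (is.na(si) | placed[si]) & (is.na(di) | placed[di]))
    if (length(ready) == 0) break
    order_idx <- c(order_idx, ready)
    placed[ready] <- TRUE
  }
  if (!all(placed))
    stop("pedigree cycle involving individual ", id[which(!placed)[1]])
  perm <- order_idx
  id2 <- id[perm]
  si2 <- match(id[si[perm]], id2); di2 <- match(id[di[perm]], id2)
  si2[is.na(si2)] <- 0L; di2[is.na(di2)] <- 0L
  structure(list(id = id2, sire = si2, dam = di2,
                 extra = df[perm, setdiff(names(df), c("id", "sire", "dam")),
                            drop = FALSE]),
            class = "pedigree")
}

#' @export
print.pedigree <- function(x, ...) {
  cat("pedigree:", length(x$id), "individuals,",
      sum(x$sire == 0 & x$dam == 0), "founders\n")
  invisible(x)
}

#' Numerator relationship matrix by the tabular method
#'
#' Dense construction; intended for moderate pedigrees and as the
#' independent check of the sparse inverse.
#'
#' @param ped a [pedigree]
#' @return dense numeric matrix A with dimnames = ids.
#' @export
a_matrix <- function(ped) {
  n <- length(ped$id)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- ped$sire[i]; d <- ped$dam[i]
    A[i, i] <- 1 + if (s > 0 && d > 0) 0.5 * A[s, d] else 0
    if (i > 1) {
      j <- seq_len(i - 1)
      aj <- 0.5 * ((if (s > 0) A[j, s] else 0) + (if (d > 0) A[j, d] else 0))
      A[i, j] <- aj
      A[j, i] <- aj
    }
  }
  A
}

#' Inbreeding coefficients
#'
#' Computed as `diag(A) - 1` from the tabular-method numerator
#' relationship matrix.
#'
#' @param ped a [pedigree]
#' @return named numeric vector of inbreeding coefficients F.
#' @export
inbreeding <- function(ped) {
  ## tabular method; O(n^2) but the package's pedigrees record three
  ## generations, so n stays moderate
  setNames(diag(a_matrix(ped)) - 1, ped$id)
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding accounted for (Mendelian sampling
#' variance `d_i = 0.5 - 0.25 (F_s + F_d)` for two known parents,
#' `0.75 - 0.25 F_p` for one, 1 for none).  Inbreeding can be switched off
#' to obtain the classical non-inbred rules.
#'
#' @param ped a [pedigree]
#' @param use_inbreeding logical; account for inbreeding (default TRUE)
#' @return list with `Ainv` (dgCMatrix, dimnames = ids), `logdet_A`
#'   (log-determinant of A, a REML constant) and `f` (inbreeding
#'   coefficients used).
#' @export
a_inverse <- function(ped, use_inbreeding = TRUE) {
  n <- length(ped$id)
  f <- if (use_inbreeding) inbreeding(ped) else rep(0, n)
  ii <- integer(9L * n); jj <- integer(9L * n); xx <- numeric(9L * n)
  k <- 0L
  add <- function(i, j, v) {
    k <<- k + 1L
    ii[k] <<- i; jj[k] <<- j; xx[k] <<- v
  }
  d <- numeric(n)
  for (i in seq_len(n)) {
    s <- ped$sire[i]; dm <- ped$dam[i]
    d[i] <- if (s > 0 && dm > 0) 0.5 - 0.25 * (f[s] + f[dm])
            else if (s > 0) 0.75 - 0.25 * f[s]
            else if (dm > 0) 0.75 - 0.25 * f[dm]
            else 1
    al <- 1 / d[i]
    add(i, i, al)
    for (p in c(s, dm)) if (p > 0) {
      add(i, p, -al / 2); add(p, i, -al / 2)
    }
    pars <- c(s, dm)[c(s, dm) > 0]
    if (length(pars) > 0)
      for (p1 in pars) for (p2 in pars) add(p1, p2, al / 4)
  }
  ii <- ii[seq_len(k)]; jj <- jj[seq_len(k)]; xx <- xx[seq_len(k)]
  Ainv <- sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                       dimnames = list(ped$id, ped$id))
  list(Ainv = Ainv, logdet_A = sum(log(d)), f = f)
}
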