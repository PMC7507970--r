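## Genotype file I/O: PLINK text (.ped/.map) and minimal VCF 4.2 (GT only).
## The PLINK dialect is the classic white-space one with alleles coded 1/2;
## dosage counts copies of allele "2".  The VCF writer emits GT-only records
## with REF=A, ALT=B so that dosage equals the ALT-allele count.

#' Write genotypes as PLINK text files
#'
#' Writes `<prefix>.ped` and `<prefix>.map`.  Alleles are coded 1/2 with the
#' counted allele written as "2"; missing calls become "0 0".
#'
#' @param genos a [genotype_matrix]
#' @param prefix output path prefix
#' @return invisibly, the two file paths.
#' @export
write_plink <- function(genos, prefix) {
  d <- genos$dosages
  codes <- c(`0` = "1 1", `1` = "1 2", `2` = "2 2")
  al <- matrix("0 0", nrow(d), ncol(d))
  ok <- !is.na(d)
  al[ok] <- codes[as.character(d[ok])]
  ped_lines <- paste(genos$pop, genos$ids, "0", "0", "0", "-9",
                     apply(al, 1, paste, collapse = " "))
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  writeLines(ped_lines, ped_path)
  map <- genos$map
  writeLines(paste(map$chr, map$name, 0, map$pos), map_path)
  invisible(c(ped_path, map_path))
}

#' Write genotypes as a minimal VCF 4.2 file
#'
#' GT-only records; REF/ALT are the placeholder alleles A/B and dosage is
#' the ALT count, so `1/1` corresponds to dosage 2 and `./.` to missing.
#'
#' @param genos a [genotype_matrix]
#' @param path output file path
#' @return invisibly, `path`.
#' @export
write_vcf <- function(genos, path) {
  d <- genos$dosages
  gt_codes <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix("./.", nrow(d), ncol(d))
  ok <- !is.na(d)
  gt[ok] <- gt_codes[as.character(d[ok])]
  hdr <- c("##fileformat=VCFv4.2",
           "##source=gxepred",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", genos$ids), collapse = "\t"))
  body <- paste(genos$map$chr, genos$map$pos, genos$map$name, "A", "B",
                ".", ".", ".", "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read genotypes from PLINK text or VCF files
#'
#' @param path for `format = "plink_text"` the path prefix (without
#'   extension) of the `.ped`/`.map` pair; for `format = "vcf"` the VCF
#'   file path.
#' @param format `"plink_text"` or `"vcf"`.
#' @return a [genotype_matrix].  Heterozygotes map to dosage 1 regardless
#'   of allele order; `0 0` (PLINK) and `./.` (VCF) map to missing.
#' @export
read_genotypes <- function(path, format = c("plink_text", "vcf")) {
  format <- match.arg(format)
  if (format == "plink_text") read_plink_text(path) else read_vcf_gt(path)
}

read_plink_text <- function(prefix) {
  map_path <- paste0(prefix, ".map")
  ped_path <- paste0(prefix, ".ped")
  map_raw <- fread(map_path, header = FALSE,
                   col.names = c("chr", "name", "cm", "pos"))
  ped <- fread(ped_path, header = FALSE, colClasses = "character")
  m <- nrow(map_raw)
  if (ncol(ped) != 6 + 2 * m)
    stop("malformed .ped: expected ", 6 + 2 * m, " fields, found ", ncol(ped),
         " (line 1)")
  ids <- ped[[2]]
  if (anyDuplicated(ids))
    stop("duplicated id in .ped: ", ids[anyDuplicated(ids)])
  a1 <- as.matrix(ped[, seq(7, 6 + 2 * m - 1, by = 2), with = FALSE])
  a2 <- as.matrix(ped[, seq(8, 6 + 2 * m, by = 2), with = FALSE])
  ok_codes <- c("0", "1", "2")
  bad <- which(!(a1 %in% ok_codes) | !(a2 %in% ok_codes))
  if (length(bad) > 0)
    stop("malformed .ped: unexpected allele code at line ",
         (bad[1] - 1) %% nrow(a1) + 1)
  d <- (a1 == "2") + (a2 == "2")
  d[a1 == "0" | a2 == "0"] <- NA
  storage.mode(d) <- "integer"
  genotype_matrix(d, data.frame(chr = map_raw$chr, pos = map_raw$pos,
                                name = map_raw$name),
                  pop = ped[[1]], ids = ids)
}

read_vcf_gt <- function(path) {
  lines <- readLines(path)
  hdr_i <- grep("^#CHROM", lines)
  if (length(hdr_i) != 1) stop("malformed VCF: no #CHROM header line")
  hdr <- strsplit(lines[hdr_i], "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 10) stop("malformed VCF: no sample columns")
  ids <- hdr[-(1:9)]
  if (anyDuplicated(ids)) stop("duplicated sample id in VCF")
  body <- lines[-seq_len(hdr_i)]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != length(hdr)))
    stop("malformed VCF: wrong field count at line ", hdr_i + which(nf != length(hdr))[1])
  m <- length(fields)
  d <- matrix(NA_integer_, length(ids), m)
  chr <- integer(m); pos <- integer(m); nm <- character(m)
  for (j in seq_len(m)) {
    f <- fields[[j]]
    chr[j] <- as.integer(f[1]); pos[j] <- as.integer(f[2]); nm[j] <- f[3]
    gt <- sub(":.*", "", f[-(1:9)])
    alleles1 <- substr(gt, 1, 1)
    alleles2 <- substr(gt, 3, 3)
    dj <- (alleles1 == "1") + (alleles2 == "1")
    dj[alleles1 == "." | alleles2 == "."] <- NA
    d[, j] <- dj
  }
  genotype_matrix(d, data.frame(chr = chr, pos = pos, name = nm),
                  pop = "pop1", ids = ids)
}
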