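#' Genotype matrix container
#'
#' The central data structure of the pipeline: a samples x variants matrix of
#' allele dosages together with the site table.  Diploid calls take values
#' 0/1/2 (count of the non-reference allele), haploid calls 0/1; missing calls
#' are `NA`.  Sites are biallelic SNVs identified by (chrom, pos, ref, alt).
#'
#' @param geno integer matrix, samples in rows (rownames = sample ids),
#'   variants in columns.  Values in `0:ploidy` or `NA`.
#' @param sites data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`; one row per column of `geno`.
#' @param ploidy 1 (haploid, e.g. chromosome Y) or 2 (autosomal diploid).
#' @param pop optional character vector of population labels per sample.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, sites, ploidy = 2L, pop = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  stopifnot(ploidy %in% c(1L, 2L))
  if (nrow(sites) != ncol(geno))
    stop("site table has ", nrow(sites), " rows but genotype matrix has ",
         ncol(geno), " columns")
  needed <- c("chrom", "pos", "ref", "alt")
  if (!all(needed %in% names(sites)))
    stop("site table must have columns: ", paste(needed, collapse = ", "))
  if (length(geno) && !all(is.na(geno))) {
    rng <- range(geno, na.rm = TRUE)
    if (rng[1] < 0L || rng[2] > ploidy)
      stop("genotype values must lie in 0..", ploidy, " or NA")
  }
  if (is.null(rownames(geno)))
    rownames(geno) <- sprintf("S%04d", seq_len(nrow(geno)))
  if (anyDuplicated(rownames(geno)))
    stop("duplicate sample ids")
  if (!is.null(pop)) {
    if (length(pop) != nrow(geno))
      stop("pop labels must match sample count")
    pop <- as.character(pop)
  }
  sites <- data.frame(chrom = as.character(sites$chrom),
                      pos = as.integer(sites$pos),
                      ref = as.character(sites$ref),
                      alt = as.character(sites$alt),
                      stringsAsFactors = FALSE)
  structure(list(geno = geno, sites = sites, ploidy = as.integer(ploidy),
                 pop = pop),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d sites, ploidy %d\n",
              nrow(x$geno), ncol(x$geno), x$ploidy))
  if (!is.null(x$pop)) {
    tab <- table(x$pop)
    cat("  populations:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

n_samples <- function(g) nrow(g$geno)
n_sites <- function(g) ncol(g$geno)

sample_ids <- function(g) rownames(g$geno)

#' Site identity keys ("chrom:pos:ref:alt")
#' @param g genotype_matrix
#' @return character vector, one key per site
#' @export
site_keys <- function(g) {
  with(g$sites, paste(chrom, pos, ref, alt, sep = ":"))
}

#' Subset a genotype matrix
#'
#' @param g genotype_matrix
#' @param samples sample index / logical / id vector (NULL = all)
#' @param sites site index or logical vector (NULL = all)
#' @return genotype_matrix
#' @export
subset_genotypes <- function(g, samples = NULL, sites = NULL) {
  if (is.null(samples)) samples <- seq_len(nrow(g$geno))
  if (is.character(samples)) samples <- match(samples, rownames(g$geno))
  if (is.null(sites)) sites <- seq_len(ncol(g$geno))
  genotype_matrix(g$geno[samples, sites, drop = FALSE],
                  g$sites[sites, , drop = FALSE],
                  ploidy = g$ploidy,
                  pop = if (!is.null(g$pop)) g$pop[samples])
}

#' Non-reference allele frequency per site
#'
#' Missing calls are excluded from both numerator and denominator.
#'
#' @param g genotype_matrix
#' @return numeric vector of length `n_sites(g)`; NaN where all calls missing
#' @export
allele_freq <- function(g) {
  ac <- colSums(g$geno, na.rm = TRUE)
  an <- colSums(!is.na(g$geno)) * g$ploidy
  ac / an
}

#' Non-reference allele count and sampled allele count per site
#' @param g genotype_matrix
#' @return list with integer vectors `ac` (allele count) and `an`
#'   (non-missing sampled alleles)
#' @export
allele_counts <- function(g) {
  list(ac = as.integer(colSums(g$geno, na.rm = TRUE)),
       an = as.integer(colSums(!is.na(g$geno)) * g$ploidy))
}

## ---- VCF I/O ---------------------------------------------------------------
## Minimal GT-only VCFv4.2 reader/writer.  The pipeline's VCFs carry a single
## GT FORMAT field over biallelic SNVs, which data.table parses directly; the
## writer emits the same dialect (diploid "0/0|0/1|1/1|./.", haploid "0|1|.").

#' Write a genotype matrix as VCFv4.2
#'
#' @param g genotype_matrix
#' @param path output file
#' @return `path`, invisibly
#' @export
write_vcf <- function(g, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=arabpop",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
             con)
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", rownames(g$geno)), collapse = "\t"),
             con)
  if (g$ploidy == 2L) {
    codes <- c("0/0", "0/1", "1/1")
    gt <- matrix(codes[g$geno + 1L], nrow = nrow(g$geno))
    gt[is.na(g$geno)] <- "./."
  } else {
    gt <- matrix(as.character(g$geno), nrow = nrow(g$geno))
    gt[is.na(g$geno)] <- "."
  }
  body <- cbind(g$sites$chrom, g$sites$pos, ".", g$sites$ref, g$sites$alt,
                ".", "PASS", ".", "GT", t(gt))
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read a GT-only VCF into a genotype matrix
#'
#' Accepts plain-text VCFv4.2 with biallelic SNVs and a GT field (first
#' FORMAT entry).  Ploidy is auto-detected from the genotype separator
#' unless given.
#'
#' @param path VCF file
#' @param ploidy 1, 2 or NULL (auto-detect)
#' @param pop optional population labels (recycled onto samples by id via a
#'   named vector, or given in sample order)
#' @return genotype_matrix
#' @export
read_vcf <- function(path, ploidy = NULL, pop = NULL) {
  hdr <- NULL
  con <- file(path, "r")
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) break
    if (startsWith(line, "#CHROM")) { hdr <- line; break }
  }
  close(con)
  if (is.null(hdr)) stop("no #CHROM header line in ", path)
  cols <- strsplit(sub("^#", "", hdr), "\t", fixed = TRUE)[[1]]
  dt <- data.table::fread(path, skip = hdr, header = TRUE, sep = "\t",
                          colClasses = list(character = 1L))
  data.table::setnames(dt, 1L, "CHROM")
  samples <- cols[-(1:9)]
  sites <- data.frame(chrom = dt$CHROM, pos = dt$POS, ref = dt$REF,
                      alt = dt$ALT, stringsAsFactors = FALSE)
  gt_raw <- as.matrix(dt[, -(1:9), with = FALSE])
  ## strip any trailing FORMAT fields (sub drops dim; restore it)
  gt_raw <- matrix(sub(":.*$", "", gt_raw), nrow = nrow(dt))
  if (is.null(ploidy))
    ploidy <- if (any(grepl("[/|]", gt_raw[1, ]))) 2L else 1L
  if (ploidy == 2L) {
    map <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L,
             "0|0" = 0L, "0|1" = 1L, "1|0" = 1L, "1|1" = 2L)
    geno <- matrix(map[gt_raw], nrow = nrow(gt_raw))
  } else {
    geno <- matrix(c("0" = 0L, "1" = 1L)[gt_raw], nrow = nrow(gt_raw))
  }
  geno <- t(geno)
  rownames(geno) <- samples
  if (!is.null(pop) && !is.null(names(pop))) pop <- unname(pop[samples])
  genotype_matrix(geno, sites, ploidy = ploidy, pop = pop)
}

#' Read a BED file of intervals (0-based, half-open)
#'
#' @param path BED file with at least chrom/start/end columns
#' @return data.frame(chrom, start, end) plus `name` when a 4th column exists
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 3L)
      stop("malformed BED line ", i, ": fewer than 3 fields")
    s <- suppressWarnings(as.numeric(p[2])); e <- suppressWarnings(as.numeric(p[3]))
    if (is.na(s) || is.na(e) || e < s)
      stop("malformed BED line ", i, ": bad interval [", p[2], ", ", p[3], ")")
  }
  out <- data.frame(chrom = vapply(parts, `[`, "", 1L),
                    start = as.numeric(vapply(parts, `[`, "", 2L)),
                    end = as.numeric(vapply(parts, `[`, "", 3L)),
                    stringsAsFactors = FALSE)
  if (all(lengths(parts) >= 4L))
    out$name <- vapply(parts, `[`, "", 4L)
  out
}

write_bed <- function(df, path) {
  cols <- c("chrom", "start", "end", intersect("name", names(df)))
  utils::write.table(format(df[cols], scientific = FALSE, trim = TRUE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

write_tsv <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

read_tsv <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
}
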