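#' Read an allele-count panel
#'
#' Reads the native counts format: a header row of population names, then
#' one row per SNP with, for each population, a pair
#' `"countAlleleA,countAlleleB"`. Whitespace-delimited, plain or gzipped
#' (detected from the `.gz` extension or transparently by the connection).
#'
#' @param path file path.
#' @param drop_incomplete drop SNPs where any population has total count 0
#'   (default TRUE). SNP order is preserved: blocks are genomic.
#' @return An `allele_panel`: list with `populations` (character),
#'   `countA`, `countB` (L x P integer matrices, SNPs in rows) and
#'   `snp_ids`.
#' @export
read_counts <- function(path, drop_incomplete = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1) stop("empty counts file")
  pops <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (anyDuplicated(pops)) {
    stop("parse error line 1: duplicate population name")
  }
  P <- length(pops)
  L <- length(lines) - 1
  countA <- matrix(0L, L, P)
  countB <- matrix(0L, L, P)
  for (l in seq_len(L)) {
    fields <- strsplit(trimws(lines[l + 1]), "\\s+")[[1]]
    if (length(fields) != P) {
      stop(sprintf("parse error line %d: expected %d pairs, found %d",
                   l + 1, P, length(fields)))
    }
    parts <- strsplit(fields, ",", fixed = TRUE)
    if (any(lengths(parts) != 2)) {
      stop(sprintf("parse error line %d: malformed count pair", l + 1))
    }
    num <- suppressWarnings(as.integer(unlist(parts)))
    if (anyNA(num) || any(num < 0)) {
      stop(sprintf("parse error line %d: malformed count pair", l + 1))
    }
    countA[l, ] <- num[c(TRUE, FALSE)]
    countB[l, ] <- num[c(FALSE, TRUE)]
  }
  panel <- allele_panel(pops, countA, countB)
  if (drop_incomplete) panel <- drop_incomplete_snps(panel)
  panel
}

#' Construct an allele-count panel in memory
#'
#' @param populations character vector of unique population names.
#' @param countA,countB L x P matrices of non-negative allele counts.
#' @param snp_ids optional SNP labels.
#' @return an `allele_panel`.
#' @export
allele_panel <- function(populations, countA, countB, snp_ids = NULL) {
  countA <- as.matrix(countA); countB <- as.matrix(countB)
  stopifnot(ncol(countA) == length(populations),
            all(dim(countA) == dim(countB)),
            all(countA >= 0), all(countB >= 0),
            !anyDuplicated(populations))
  colnames(countA) <- colnames(countB) <- populations
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(nrow(countA)))
  structure(list(populations = populations, countA = countA,
                 countB = countB, snp_ids = snp_ids),
            class = "allele_panel")
}

#' @export
print.allele_panel <- function(x, ...) {
  cat(sprintf("allele_panel: %d SNPs x %d populations\n",
              nrow(x$countA), length(x$populations)))
  invisible(x)
}

drop_incomplete_snps <- function(panel) {
  tot <- panel$countA + panel$countB
  keep <- apply(tot >= 1, 1, all)
  subset_panel(panel, keep)
}

subset_panel <- function(panel, keep) {
  allele_panel(panel$populations,
               panel$countA[keep, , drop = FALSE],
               panel$countB[keep, , drop = FALSE],
               panel$snp_ids[keep])
}

#' Write an allele-count panel in the native counts format
#'
#' @param panel an `allele_panel`.
#' @param path output path; gzipped when it ends in `.gz`.
#' @return `path`, invisibly.
#' @export
write_counts <- function(panel, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(paste(panel$populations, collapse = " "), con)
  body <- matrix(paste(panel$countA, panel$countB, sep = ","),
                 nrow = nrow(panel$countA))
  writeLines(apply(body, 1, paste, collapse = " "), con)
  invisible(path)
}

#' Sample allele frequencies and heterozygosity from a panel
#'
#' Computes per-SNP sample frequencies \eqn{\hat p = a/(a+b)}, chromosome
#' counts \eqn{n = a+b}, and the per-population mean unbiased
#' heterozygosity \eqn{\hat h_i = \mathrm{mean}_l\, 2\hat p(1-\hat p)
#' n/(n-1)} (over SNPs with \eqn{n \ge 2}).
#'
#' @param panel an `allele_panel` with every SNP complete (total count
#'   \eqn{\ge 1} in every population).
#' @return A `freq_matrix`: list with `freqs` and `sizes` (P x L matrices,
#'   populations in rows), `het` (per-population mean heterozygosity; `NA`
#'   where no SNP has \eqn{n \ge 2}) and `populations`.
#' @export
allele_frequencies <- function(panel) {
  if (nrow(panel$countA) == 0) stop("empty panel")
  a <- t(panel$countA)
  n <- a + t(panel$countB)
  if (any(n < 1)) stop("panel contains SNPs with total count 0; use drop_incomplete")
  p <- a / n
  hl <- 2 * p * (1 - p) * n / (n - 1)       # Inf/NaN where n == 1
  hl[n < 2] <- NA
  het <- rowMeans(hl, na.rm = TRUE)
  het[is.nan(het)] <- NA
  structure(list(freqs = p, sizes = n, het = het,
                 populations = panel$populations),
            class = "freq_matrix")
}
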