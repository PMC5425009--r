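#' Genotype matrix container
#'
#' Bundles a samples x sites matrix of alt-allele dosages with its site
#' table and sample identifiers. Dosage codes are 0 (homozygous reference),
#' 1 (heterozygous), 2 (homozygous alternate) and `NA` (missing call).
#'
#' @param codes Integer matrix, samples in rows, sites in columns. Values
#'   must be in `{0, 1, 2, NA}`.
#' @param sites Data frame with one row per site and columns `chrom`,
#'   `pos` (1-based, as in VCF), `id`, `ref`, `alt`, `vtype` (`"SNP"` or
#'   `"InDel"`). Missing optional columns are filled with defaults.
#' @param samples Character vector of sample identifiers, one per row of
#'   `codes`.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `codes`, `sites` and `samples`.
#' @export
genotype_matrix <- function(codes, sites, samples = rownames(codes)) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (is.null(samples)) {
    samples <- paste0("S", seq_len(nrow(codes)))
  }
  samples <- as.character(samples)
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  if (!all(c("chrom", "pos") %in% names(sites))) {
    stop("`sites` must have at least `chrom` and `pos` columns")
  }
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  if (is.null(sites$id)) sites$id <- "."
  if (is.null(sites$ref)) sites$ref <- "A"
  if (is.null(sites$alt)) sites$alt <- "T"
  if (is.null(sites$vtype)) {
    sites$vtype <- ifelse(nchar(sites$ref) == 1L & nchar(sites$alt) == 1L,
                          "SNP", "InDel")
  }
  if (nrow(sites) != ncol(codes)) {
    stop("number of sites (", nrow(sites), ") does not match code columns (",
         ncol(codes), ")")
  }
  if (length(samples) != nrow(codes)) {
    stop("number of samples does not match code rows")
  }
  if (any(sites$pos < 1L, na.rm = TRUE)) stop("positions must be >= 1")
  bad <- !(codes %in% c(0L, 1L, 2L, NA_integer_))
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or NA")
  rownames(codes) <- samples
  rownames(sites) <- NULL
  structure(list(codes = codes, sites = sites, samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$samples), "samples x",
      nrow(x$sites), "sites\n")
  cat("  chromosomes:", paste(unique(x$sites$chrom), collapse = ", "), "\n")
  nmiss <- sum(is.na(x$codes))
  cat("  missing calls:", nmiss,
      sprintf("(%.2f%%)", 100 * nmiss / length(x$codes)), "\n")
  invisible(x)
}

#' Subset a genotype matrix
#'
#' @param x A [genotype_matrix()].
#' @param i Sample index (logical, integer or sample names).
#' @param j Site index (logical or integer).
#' @param ... Ignored.
#' @return A `genotype_matrix` restricted to the selected samples and sites.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$samples)
  if (missing(j)) j <- seq_len(nrow(x$sites))
  if (is.character(i)) i <- match(i, x$samples)
  genotype_matrix(x$codes[i, j, drop = FALSE],
                  x$sites[j, , drop = FALSE],
                  x$samples[i])
}

#' @export
dim.genotype_matrix <- function(x) c(length(x$samples), nrow(x$sites))

#' Number of samples / sites in a genotype matrix
#'
#' @param x A [genotype_matrix()].
#' @return Integer count.
#' @export
n_samples <- function(x) length(x$samples)

#' @rdname n_samples
#' @export
n_sites <- function(x) nrow(x$sites)
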