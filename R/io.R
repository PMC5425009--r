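#' Read a VCF file into a genotype matrix
#'
#' Parses a VCF v4.2 file (via \pkg{vcfR}) and converts the GT field to
#' alt-allele dosages. Phase separators are ignored: `0/1` and `0|1` both
#' code 1. `./.` maps to missing.
#'
#' @param path Path to an uncompressed or gzipped VCF file.
#' @param multiallelic One of `"error"` (default, strict mode: a record
#'   with more than one ALT allele aborts with its position) or `"drop"`
#'   (such records are removed with a warning).
#' @return A [genotype_matrix()].
#' @export
read_vcf <- function(path, multiallelic = c("error", "drop")) {
  multiallelic <- match.arg(multiallelic)
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    where <- paste0(fix[multi, "CHROM"], ":", fix[multi, "POS"])
    if (multiallelic == "error") {
      stop("multiallelic record(s) at ", paste(utils::head(where, 5), collapse = ", "),
           "; rerun with multiallelic = \"drop\" to remove them")
    }
    warning("dropping ", sum(multi), " multiallelic record(s)")
    v <- v[!multi, ]
    fix <- vcfR::getFIX(v)
    if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  # gt is sites x samples of strings like "0/1", "0|1", ".", "./."
  dose <- gt_to_dosage(gt)
  sites <- data.frame(chrom = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]),
                      id = ifelse(is.na(fix[, "ID"]), ".", fix[, "ID"]),
                      ref = fix[, "REF"],
                      alt = fix[, "ALT"],
                      stringsAsFactors = FALSE)
  sites$vtype <- ifelse(nchar(sites$ref) == 1L & nchar(sites$alt) == 1L,
                        "SNP", "InDel")
  genotype_matrix(t(dose), sites, samples = colnames(gt))
}

# Convert a matrix of GT strings to integer dosages (same shape).
gt_to_dosage <- function(gt) {
  u <- unique(as.vector(gt))
  map <- vapply(u, function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_integer_)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_integer_)
    a <- suppressWarnings(as.integer(alleles))
    if (anyNA(a) || any(a > 1L)) {
      stop("unsupported GT value: ", g)
    }
    sum(a)
  }, integer(1))
  out <- map[match(as.vector(gt), u)]
  dim(out) <- dim(gt)
  dimnames(out) <- dimnames(gt)
  out
}

#' Write a genotype matrix as VCF v4.2
#'
#' Writes an uncompressed diploid VCF with a GT-only FORMAT column.
#' Positions are written 1-based as stored; missing calls become `./.`.
#'
#' @param x A [genotype_matrix()].
#' @param path Output file path.
#' @param chrom_lengths Optional named vector of chromosome lengths used to
#'   emit `##contig` header lines.
#' @return Invisibly, `path`.
#' @export
write_vcf <- function(x, path, chrom_lengths = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=polyloc",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (!is.null(chrom_lengths)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(chrom_lengths), as.integer(chrom_lengths)))
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", x$samples),
                      collapse = "\t"))
  gtmap <- c("0/0", "0/1", "1/1")
  gstr <- matrix("./.", nrow = nrow(x$codes), ncol = ncol(x$codes))
  ok <- !is.na(x$codes)
  gstr[ok] <- gtmap[x$codes[ok] + 1L]
  body <- paste(x$sites$chrom, x$sites$pos, x$sites$id, x$sites$ref,
                x$sites$alt, ".", "PASS", ".", "GT",
                apply(gstr, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a FAM-style sample file
#'
#' Six whitespace-separated columns: family, individual id, sire, dam, sex
#' (1 = male, 2 = female, 0 = unknown), phenotype (1 = control, 2 = case,
#' 0 or -9 = missing). `0` in the sire/dam columns means founder.
#'
#' @param path Path to the FAM file.
#' @return A data frame with columns `family`, `id`, `sire`, `dam`, `sex`
#'   and `phenotype` (factor with levels `control`, `case`; `NA` missing).
#' @export
read_samples <- function(path) {
  if (!file.exists(path)) stop("sample file not found: ", path)
  raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("family", "id", "sire", "dam",
                                         "sex", "phenotype"),
                           colClasses = c(rep("character", 4), "integer",
                                         "character"))
  if (nrow(raw) == 0) {
    warning("empty sample file: ", path)
  }
  known <- c("0", "1", "2", "-9")
  bad <- !(raw$phenotype %in% known)
  if (any(bad)) {
    stop("unknown phenotype code(s) on line(s) ",
         paste(which(bad), collapse = ", "), ": ",
         paste(unique(raw$phenotype[bad]), collapse = ", "))
  }
  raw$sire[raw$sire == "0"] <- NA_character_
  raw$dam[raw$dam == "0"] <- NA_character_
  ph <- rep(NA_character_, nrow(raw))
  ph[raw$phenotype == "1"] <- "control"
  ph[raw$phenotype == "2"] <- "case"
  raw$phenotype <- factor(ph, levels = c("control", "case"))
  raw
}

#' Write a pedigree as a 6-column FAM file
#'
#' @param pedigree Data frame with columns `family`, `id`, `sire`, `dam`,
#'   `sex` and `phenotype` (factor or character with values `control`/`case`,
#'   `NA` = missing).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_fam <- function(pedigree, path) {
  ph <- as.character(pedigree$phenotype)
  code <- ifelse(is.na(ph), 0L, ifelse(ph == "case", 2L, 1L))
  out <- data.frame(family = pedigree$family,
                    id = pedigree$id,
                    sire = ifelse(is.na(pedigree$sire), "0", pedigree$sire),
                    dam = ifelse(is.na(pedigree$dam), "0", pedigree$dam),
                    sex = pedigree$sex,
                    phenotype = code)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read gene intervals from a BED file
#'
#' BED4 input: chrom, start, end, name; 0-based half-open coordinates are
#' kept internally. A gene covers VCF (1-based) positions `start + 1` to
#' `end`.
#'
#' @param path Path to a BED file (no header).
#' @return A data frame with columns `chrom`, `start`, `end`, `name` and
#'   `strand` (`"*"` when the file has no strand column).
#' @export
read_genes <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  info <- file.info(path)
  if (info$size == 0) {
    warning("empty BED file: ", path)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 4) stop("BED file must have at least 4 columns")
  out <- data.frame(chrom = as.character(raw[[1]]),
                    start = as.integer(raw[[2]]),
                    end = as.integer(raw[[3]]),
                    name = as.character(raw[[4]]),
                    strand = if (ncol(raw) >= 6) as.character(raw[[6]]) else "*",
                    stringsAsFactors = FALSE)
  if (any(out$start >= out$end)) {
    stop("BED intervals must satisfy start < end (line ",
         which(out$start >= out$end)[1], ")")
  }
  out
}

#' Read a two-column chromosome-length table
#'
#' @param path Tab-separated file: chromosome name, length in bp.
#' @return Named integer vector of lengths.
#' @export
read_chrom_lengths <- function(path) {
  if (!file.exists(path)) stop("chromosome-length file not found: ", path)
  raw <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  len <- as.integer(raw[[2]])
  if (any(is.na(len)) || any(len <= 0)) stop("chromosome lengths must be positive integers")
  stats::setNames(len, as.character(raw[[1]]))
}

#' Write a simulation configuration sidecar
#'
#' Records every simulation parameter, including the seed, as JSON next to
#' the simulated data so a run can be reproduced exactly.
#'
#' @param config A [sim_config()].
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
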