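#' Construct a genotype matrix
#'
#' The central genotype container: an N x M numeric matrix of counted-allele
#' dosages (0, 1, 2; \code{NA} for missing) with sample and marker metadata.
#' Dosages count copies of \code{counted_allele}, so the container is
#' strand/label agnostic: flipping which allele is counted at a marker maps
#' dosage z to 2 - z without changing any downstream relationship estimate.
#'
#' @param dosages numeric N x M matrix with entries in \{0, 1, 2, NA\}.
#'   Mean-imputed matrices (real-valued entries in [0, 2]) are accepted when
#'   \code{validate_entries = FALSE}.
#' @param sample_ids character vector of N unique sample identifiers.
#' @param marker_ids character vector of M unique marker identifiers.
#' @param chromosome character/integer vector of M chromosome labels.
#' @param position integer vector of M 1-based physical positions,
#'   nondecreasing within a chromosome.
#' @param counted_allele,other_allele character vectors of M allele labels;
#'   dosage counts copies of \code{counted_allele}.
#' @param validate_entries if \code{TRUE} (default), require every
#'   non-missing dosage to be exactly 0, 1 or 2.
#' @return an object of class \code{genotype_matrix}.
#' @export
genotype_matrix <- function(dosages, sample_ids = rownames(dosages),
                            marker_ids = colnames(dosages),
                            chromosome = rep("1", ncol(dosages)),
                            position = seq_len(ncol(dosages)),
                            counted_allele = rep("A", ncol(dosages)),
                            other_allele = rep("B", ncol(dosages)),
                            validate_entries = TRUE) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  n <- nrow(dosages); m <- ncol(dosages)
  if (is.null(sample_ids)) sample_ids <- paste0("id", seq_len(n))
  if (is.null(marker_ids)) marker_ids <- paste0("snp", seq_len(m))
  sample_ids <- as.character(sample_ids)
  marker_ids <- as.character(marker_ids)
  if (length(sample_ids) != n) stop("sample_ids length != nrow(dosages)")
  if (length(marker_ids) != m) stop("marker_ids length != ncol(dosages)")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample_ids: ", sample_ids[duplicated(sample_ids)][1L])
  if (anyDuplicated(marker_ids))
    stop("duplicate marker_ids: ", marker_ids[duplicated(marker_ids)][1L])
  if (length(chromosome) != m || length(position) != m ||
      length(counted_allele) != m || length(other_allele) != m)
    stop("marker metadata must have one entry per marker")
  position <- as.integer(position)
  if (any(position < 1L, na.rm = TRUE)) stop("positions are 1-based (>= 1)")
  for (chr in unique(chromosome)) {
    pos_chr <- position[chromosome == chr]
    if (is.unsorted(pos_chr)) stop("positions not nondecreasing on chromosome ", chr)
  }
  if (validate_entries) {
    vals <- dosages[!is.na(dosages)]
    if (length(vals) && !all(vals %in% c(0, 1, 2)))
      stop("non-missing dosages must be 0, 1 or 2")
  }
  dimnames(dosages) <- list(sample_ids, marker_ids)
  structure(list(dosages = dosages, sample_ids = sample_ids,
                 marker_ids = marker_ids,
                 chromosome = as.character(chromosome), position = position,
                 counted_allele = as.character(counted_allele),
                 other_allele = as.character(other_allele)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  nmiss <- sum(is.na(x$dosages))
  cat(sprintf("genotype_matrix: %d samples x %d markers (%d missing calls, %.2f%%)\n",
              nrow(x$dosages), ncol(x$dosages), nmiss,
              100 * nmiss / length(x$dosages)))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

subset_markers <- function(geno, keep) {
  genotype_matrix(geno$dosages[, keep, drop = FALSE],
                  sample_ids = geno$sample_ids,
                  marker_ids = geno$marker_ids[keep],
                  chromosome = geno$chromosome[keep],
                  position = geno$position[keep],
                  counted_allele = geno$counted_allele[keep],
                  other_allele = geno$other_allele[keep],
                  validate_entries = FALSE)
}

subset_samples <- function(geno, keep) {
  genotype_matrix(geno$dosages[keep, , drop = FALSE],
                  sample_ids = geno$sample_ids[keep],
                  marker_ids = geno$marker_ids,
                  chromosome = geno$chromosome,
                  position = geno$position,
                  counted_allele = geno$counted_allele,
                  other_allele = geno$other_allele,
                  validate_entries = FALSE)
}

#' Construct a phenotype table
#'
#' One row per sample: trait values (missing allowed), the fixed-effect
#' factors gender, farm and year, and the slaughter-age covariate in days.
#'
#' @param df data.frame with a \code{sample_id} column, factor columns
#'   \code{gender}, \code{farm}, \code{year}, a numeric \code{slaughter_age}
#'   column, and one numeric column per trait.
#' @param traits character vector naming the trait columns; defaults to all
#'   columns other than id/factor/covariate columns.
#' @return an object of class \code{phenotype_table} (a data.frame).
#' @export
phenotype_table <- function(df, traits = NULL) {
  required <- c("sample_id", "gender", "farm", "year", "slaughter_age")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("phenotype table lacks column(s): ", paste(missing_cols, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample id: ", df$sample_id[duplicated(df$sample_id)][1L])
  for (fc in c("gender", "farm", "year")) df[[fc]] <- factor(df[[fc]])
  df$slaughter_age <- as.numeric(df$slaughter_age)
  if (is.null(traits)) traits <- setdiff(names(df), required)
  for (tr in traits) {
    v <- df[[tr]]
    if (!is.numeric(v)) {
      v2 <- suppressWarnings(as.numeric(as.character(v)))
      bad <- !is.na(v) & v != "" & v != "NA" & is.na(v2)
      if (any(bad)) stop("unparseable numeric in trait '", tr, "'")
      df[[tr]] <- v2
    }
  }
  structure(df, traits = traits, class = c("phenotype_table", "data.frame"))
}

#' @export
print.phenotype_table <- function(x, ...) {
  cat(sprintf("phenotype_table: %d samples, traits: %s\n", nrow(x),
              paste(attr(x, "traits"), collapse = ", ")))
  NextMethod()
}

#' Read genotypes from PLINK RAW or minimal VCF
#'
#' PLINK RAW is the additive-recode text dialect (header
#' \code{FID IID PAT MAT SEX PHENOTYPE SNP1_A ...}): the \code{_A} suffix
#' names the counted allele and body entries are dosages 0/1/2 or NA.
#' The VCF reader handles plain-text VCF 4.x with biallelic records and a GT
#' field; \code{0/0}, \code{0/1}, \code{1/1} and \code{./.} map to dosages
#' 0, 1, 2 and missing of the ALT allele (phased \code{|} separators
#' accepted).
#'
#' @param path file path.
#' @param format \code{"plink_raw"} or \code{"vcf"}.
#' @return a \code{\link{genotype_matrix}}.
#' @export
read_genotypes <- function(path, format = c("plink_raw", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format, plink_raw = read_plink_raw(path), vcf = read_vcf_geno(path))
}

read_plink_raw <- function(path) {
  header <- strsplit(readLines(path, n = 1L), "[ \t]+")[[1]]
  lead <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (length(header) < 6L || !identical(header[1:6], lead))
    stop("line 1: malformed PLINK RAW header (expected FID IID PAT MAT SEX PHENOTYPE ...)")
  snp_cols <- header[-(1:6)]
  m <- length(snp_cols)
  # counted allele is PLINK's SNP_A suffix
  counted <- sub(".*_", "", snp_cols)
  marker_ids <- sub("_[^_]*$", "", snp_cols)
  tab <- read.table(path, header = TRUE, check.names = FALSE,
                    colClasses = c(rep("character", 2), rep("numeric", 4 + m)),
                    na.strings = "NA")
  dos <- as.matrix(tab[, -(1:6), drop = FALSE])
  vals <- dos[!is.na(dos)]
  if (length(vals) && !all(vals %in% c(0, 1, 2))) {
    bad_row <- which(apply(dos, 1L, function(r) any(!is.na(r) & !(r %in% c(0, 1, 2)))))[1L]
    stop("line ", bad_row + 1L, ": dosage outside {0,1,2}")
  }
  genotype_matrix(dos, sample_ids = tab$IID, marker_ids = marker_ids,
                  counted_allele = counted,
                  other_allele = rep("N", m))
}

read_vcf_geno <- function(path) {
  lines <- readLines(path)
  hdr_i <- grep("^#CHROM", lines)
  if (length(hdr_i) != 1L) stop("malformed VCF: missing #CHROM header line")
  hdr <- strsplit(lines[hdr_i], "\t")[[1]]
  if (length(hdr) < 10L) stop("VCF has no sample columns")
  samples <- hdr[-(1:9)]
  body <- lines[-seq_len(hdr_i)]
  body <- body[nzchar(body)]
  m <- length(body)
  n <- length(samples)
  dos <- matrix(NA_real_, n, m)
  chrom <- pos <- id <- ref <- alt <- character(m)
  for (j in seq_len(m)) {
    f <- strsplit(body[j], "\t")[[1]]
    lineno <- hdr_i + j
    if (length(f) != 9L + n) stop("line ", lineno, ": wrong field count")
    if (grepl(",", f[5], fixed = TRUE))
      stop("line ", lineno, ": non-biallelic record (ALT = ", f[5], ")")
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    gt_i <- match("GT", fmt)
    if (is.na(gt_i)) stop("line ", lineno, ": no GT field")
    chrom[j] <- f[1]; pos[j] <- f[2]
    id[j] <- if (f[3] == ".") paste0(f[1], ":", f[2]) else f[3]
    ref[j] <- f[4]; alt[j] <- f[5]
    gts <- vapply(strsplit(f[-(1:9)], ":", fixed = TRUE), `[`, "", gt_i)
    alleles <- strsplit(gts, "[/|]")
    dos[, j] <- vapply(alleles, function(a) {
      if (any(a == ".")) return(NA_real_)
      a <- suppressWarnings(as.integer(a))
      if (anyNA(a) || any(a > 1L)) stop("line ", lineno, ": unparseable GT")
      sum(a)
    }, 0)
  }
  genotype_matrix(dos, sample_ids = samples, marker_ids = id,
                  chromosome = chrom, position = as.integer(pos),
                  counted_allele = alt, other_allele = ref)
}

#' Write genotypes in the PLINK RAW dialect
#'
#' @param geno a \code{\link{genotype_matrix}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_genotypes <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_matrix"))
  snp_cols <- paste0(geno$marker_ids, "_", geno$counted_allele)
  header <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE", snp_cols)
  n <- nrow(geno$dosages)
  lead <- data.frame(FID = geno$sample_ids, IID = geno$sample_ids,
                     PAT = 0L, MAT = 0L, SEX = 0L, PHENOTYPE = -9L)
  body <- cbind(lead, as.data.frame(geno$dosages, check.names = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = " "), con)
  write.table(body, con, sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a phenotype table from delimited text
#'
#' Expects a header naming \code{sample_id}, the fixed-effect columns
#' \code{gender}, \code{farm}, \code{year}, the \code{slaughter_age}
#' covariate and one column per trait. Blank or NA trait cells become
#' missing values.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return a \code{\link{phenotype_table}}.
#' @export
read_phenotypes <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                   na.strings = c("NA", ""), check.names = FALSE)
  phenotype_table(df)
}

#' Write a phenotype table as delimited text
#'
#' @param pheno a \code{\link{phenotype_table}}.
#' @param path output file path.
#' @param sep field separator (default tab).
#' @return \code{path}, invisibly.
#' @export
write_phenotypes <- function(pheno, path, sep = "\t") {
  write.table(as.data.frame(pheno), path, sep = sep, quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}

#' Restrict genotypes and phenotypes to their shared samples
#'
#' Both objects are subset to the intersection of their sample ids and put
#' in the genotype matrix's order, so rows align for modelling.
#'
#' @param geno a \code{\link{genotype_matrix}}.
#' @param pheno a \code{\link{phenotype_table}}.
#' @param quiet suppress the message reporting dropped counts.
#' @return list with elements \code{geno} and \code{pheno}.
#' @export
align_samples <- function(geno, pheno, quiet = FALSE) {
  shared <- intersect(geno$sample_ids, pheno$sample_id)
  if (!length(shared))
    stop("no shared sample ids between genotypes and phenotypes")
  shared <- geno$sample_ids[geno$sample_ids %in% shared]  # genotype order
  if (!quiet)
    message(sprintf("align_samples: kept %d; dropped %d genotyped, %d phenotyped",
                    length(shared), length(geno$sample_ids) - length(shared),
                    nrow(pheno) - length(shared)))
  g <- subset_samples(geno, match(shared, geno$sample_ids))
  p <- pheno[match(shared, pheno$sample_id), , drop = FALSE]
  rownames(p) <- NULL
  attr(p, "traits") <- attr(pheno, "traits")
  class(p) <- class(pheno)
  list(geno = g, pheno = p)
}
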