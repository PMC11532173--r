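#' @include AllClasses.R
NULL

#' Column-name dialect for summary-statistics files
#'
#' Maps the canonical field names used throughout the package to the column
#' headers of a particular file format. Only the mandatory fields
#' (snp, effect_allele, other_allele, beta, se, pval) must be present in a
#' file; the rest are filled with NA when absent.
#'
#' @param snp,effect_allele,other_allele,eaf,beta,se,pval,n_cases,n_total,chrom,pos
#'   Column header carrying each field.
#' @return Named character vector (canonical name -> file column).
#' @examples
#' gwasDialect()                     # package default headers
#' gwasDialect(snp = "rsid", pval = "p")
#' @export
gwasDialect <- function(snp = "SNP", effect_allele = "effect_allele",
                        other_allele = "other_allele", eaf = "eaf",
                        beta = "beta", se = "se", pval = "pval",
                        n_cases = "n_cases", n_total = "n_total",
                        chrom = "chrom", pos = "pos") {
  c(snp = snp, effect_allele = effect_allele, other_allele = other_allele,
    eaf = eaf, beta = beta, se = se, pval = pval, n_cases = n_cases,
    n_total = n_total, chrom = chrom, pos = pos)
}

.MANDATORY_FIELDS <- c("snp", "effect_allele", "other_allele",
                       "beta", "se", "pval")

#' Construct a GwasTable from a data.frame
#'
#' Rows violating the per-record invariants (positive finite SE, p-value in
#' (0,1], valid distinct alleles, allele frequency strictly inside (0,1)
#' when present) are dropped with a warning reporting the count.
#'
#' @param records data.frame with at least the mandatory canonical columns
#'   \code{snp}, \code{effect_allele}, \code{other_allele}, \code{beta},
#'   \code{se}, \code{pval}; optional \code{eaf}, \code{n_cases},
#'   \code{n_total}, \code{chrom}, \code{pos}.
#' @param traitLabel Trait name stored on the table.
#' @return A validated [GwasTable-class].
#' @export
gwasTable <- function(records, traitLabel = "trait") {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing <- setdiff(.MANDATORY_FIELDS, names(records))
  if (length(missing))
    .stopf("missing mandatory column(s): %s", paste(missing, collapse = ", "))
  for (col in setdiff(.GWAS_COLUMNS, names(records)))
    records[[col]] <- NA
  records <- records[.GWAS_COLUMNS]
  records$snp <- as.character(records$snp)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  for (col in c("eaf", "beta", "se", "pval", "pos"))
    records[[col]] <- as.numeric(records[[col]])

  ok <- !is.na(records$snp) &
    records$effect_allele %in% .VALID_ALLELES &
    records$other_allele %in% .VALID_ALLELES &
    records$effect_allele != records$other_allele &
    is.finite(records$beta) &
    is.finite(records$se) & records$se > 0 &
    is.finite(records$pval) & records$pval > 0 & records$pval <= 1 &
    (is.na(records$eaf) | (records$eaf > 0 & records$eaf < 1))
  if (any(!ok)) {
    .warnf("dropped %d row(s) violating record invariants in '%s'",
           sum(!ok), traitLabel)
    records <- records[ok, , drop = FALSE]
  }
  if (anyDuplicated(records$snp)) {
    .warnf("dropped %d duplicated snp id(s) in '%s'",
           sum(duplicated(records$snp)), traitLabel)
    records <- records[!duplicated(records$snp), , drop = FALSE]
  }
  rownames(records) <- NULL
  methods::new("GwasTable", traitLabel = traitLabel, records = records)
}

#' Read GWAS summary statistics from a delimited file
#'
#' Reads a header-named TSV or CSV file (delimiter auto-detected from the
#' header line) and maps its columns through a [gwasDialect()]. Rows
#' violating the record invariants are dropped with a warning.
#'
#' @param path File path.
#' @param dialect Column mapping from [gwasDialect()].
#' @param traitLabel Trait name; defaults to the file name without
#'   extension.
#' @return A [GwasTable-class].
#' @seealso [writeGwas()] for the inverse.
#' @export
readGwas <- function(path, dialect = gwasDialect(), traitLabel = NULL) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  header <- readLines(path, n = 1L)
  if (!length(header) || !nzchar(header))
    .stopf("empty input file: %s", path)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           comment.char = "")
  if (!nrow(raw)) .stopf("file has a header but no data rows: %s", path)
  missing <- setdiff(dialect[.MANDATORY_FIELDS], names(raw))
  if (length(missing))
    .stopf("file lacks mandatory column(s): %s", paste(missing, collapse = ", "))
  records <- data.frame(row.names = seq_len(nrow(raw)))
  for (field in names(dialect)) {
    col <- dialect[[field]]
    records[[field]] <- if (col %in% names(raw)) raw[[col]] else NA
  }
  if (is.null(traitLabel))
    traitLabel <- sub("\\.[^.]*$", "", basename(path))
  gwasTable(records, traitLabel = traitLabel)
}

#' Write a GwasTable to a tab-delimited file
#'
#' Writes the canonical columns under the dialect's headers. Reading the
#' file back with the same dialect round-trips all retained fields.
#'
#' @param x A [GwasTable-class].
#' @param path Output file path.
#' @param dialect Column mapping from [gwasDialect()].
#' @return Invisibly, \code{path}.
#' @export
writeGwas <- function(x, path, dialect = gwasDialect()) {
  stopifnot(methods::is(x, "GwasTable"))
  out <- x@records
  names(out) <- unname(dialect[names(out)])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a square LD matrix from a TSV with snp-id header
#'
#' The file must be a square numeric table whose header row names the SNP
#' ids; values are pairwise r-squared.
#'
#' @param path File path.
#' @return Symmetric matrix with unit diagonal, dimnames = snp ids.
#' @export
readLDMatrix <- function(path) {
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   check.names = FALSE))
  rownames(m) <- colnames(m)
  ldMatrix(m)
}

#' Validate an LD (r-squared) matrix
#'
#' @param m Square numeric matrix, symmetric, unit diagonal, values in
#'   \[0, 1\], with snp ids as dimnames.
#' @return The validated matrix (invisibly unchanged).
#' @export
ldMatrix <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    .stopf("LD matrix must be square")
  if (is.null(colnames(m))) .stopf("LD matrix needs snp ids as dimnames")
  if (is.null(rownames(m))) rownames(m) <- colnames(m)
  if (any(m < -1e-9 | m > 1 + 1e-9, na.rm = TRUE))
    .stopf("LD r-squared values must lie in [0, 1]")
  if (max(abs(m - t(m))) > 1e-8) .stopf("LD matrix must be symmetric")
  if (max(abs(diag(m) - 1)) > 1e-8) .stopf("LD matrix diagonal must be 1")
  m
}
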