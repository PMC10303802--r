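#' Validate a methylation beta matrix
#'
#' A beta matrix is a numeric probes x samples matrix with unique probe ids
#' as rownames, unique sample ids as colnames, and values in \[0,1\] (or `NA`
#' for missing).
#'
#' @param beta Matrix to validate.
#' @return The matrix, invisibly unchanged, for piping into callers.
#' @keywords internal
validate_beta_matrix <- function(beta) {
  if (!is.matrix(beta) || !is.numeric(beta)) {
    stop("'beta' must be a numeric matrix (probes x samples)")
  }
  if (is.null(rownames(beta)) || is.null(colnames(beta))) {
    stop("'beta' must have probe rownames and sample colnames")
  }
  if (anyDuplicated(rownames(beta))) stop("duplicate probe ids in 'beta'")
  if (anyDuplicated(colnames(beta))) stop("duplicate sample ids in 'beta'")
  rng <- range(beta, na.rm = TRUE)
  if (rng[1L] < 0 || rng[2L] > 1) {
    stop("beta values must lie in [0,1]; observed range [",
         format(rng[1L]), ", ", format(rng[2L]), "]")
  }
  beta
}

# Shared reader for "first column = row id, header = sample ids" tables.
read_id_matrix <- function(path, sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                           check.names = FALSE, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  as.matrix(tab)
}

#' Read a beta matrix from TSV/CSV
#'
#' First column holds probe ids, the header row holds sample ids, values are
#' decimals in \[0,1\]; empty cells are read as missing. The separator is
#' inferred from the file extension (`.csv` means comma, otherwise tab).
#'
#' @param path Path to the table.
#' @param sep Field separator; default inferred from the extension.
#' @return Validated numeric matrix, probes x samples.
#' @export
read_beta_matrix <- function(path, sep = NULL) {
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  validate_beta_matrix(read_id_matrix(path, sep))
}

#' Write a beta matrix as TSV
#'
#' Values are written with 17 significant digits so write/read round trips
#' are exact.
#'
#' @param beta Validated beta matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(beta, path) {
  validate_beta_matrix(beta)
  write_numeric_matrix(beta, path, id_col = "probe_id")
  invisible(path)
}

# Full-precision numeric matrix writer (TSV, row ids in first column).
write_numeric_matrix <- function(x, path, id_col = "id") {
  body <- matrix(sprintf("%.17g", x), nrow = nrow(x))
  body[is.na(x)] <- ""
  lines <- c(paste(c(id_col, colnames(x)), collapse = "\t"),
             paste(rownames(x), apply(body, 1L, paste, collapse = "\t"),
                   sep = "\t"))
  # An empty matrix still gets its header.
  if (nrow(x) == 0L) lines <- lines[1L]
  writeLines(lines, path)
}
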