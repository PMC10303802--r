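#' Linear DNAm-age clock model
#'
#' A clock is a linear predictor over CpG probes together with an invertible
#' age transform: predicted DNAm age is
#' `inverse_age_transform(intercept + sum(w_i * beta_i))`. Horvath-style
#' clocks use the piecewise log/linear transform; PhenoAge-style clocks use
#' the identity transform (their linear predictor is already in years).
#'
#' @param name Non-empty clock name.
#' @param intercept Intercept of the linear predictor (transformed-age scale).
#' @param coefficients Named numeric vector of per-probe weights; names are
#'   probe ids, which must be unique. At least one coefficient.
#' @param transform A [transform_spec()]. Default: identity.
#' @return An object of class `"clock_model"`.
#' @seealso [predict.clock_model()], [read_clock()]
#' @examples
#' cl <- clock_model("toy", 30, c(cg01 = 10), transform_spec("identity"))
#' beta <- matrix(0.5, 1, 1, dimnames = list("cg01", "s1"))
#' predict(cl, beta) # 30 + 10 * 0.5 = 35
#' @export
clock_model <- function(name, intercept, coefficients,
                        transform = transform_spec("identity")) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("'name' must be a non-empty string")
  }
  if (!is.numeric(intercept) || length(intercept) != 1L ||
      !is.finite(intercept)) {
    stop("'intercept' must be a single finite number")
  }
  if (!is.numeric(coefficients) || length(coefficients) < 1L) {
    stop("'coefficients' must be a numeric vector with at least one entry")
  }
  ids <- names(coefficients)
  if (is.null(ids) || any(!nzchar(ids))) {
    stop("'coefficients' must be named by probe id")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate probe ids in clock coefficients: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(!is.finite(coefficients))) stop("non-finite clock coefficient")
  stopifnot(inherits(transform, "transform_spec"))
  structure(list(name = name, intercept = as.numeric(intercept),
                 coefficients = coefficients, transform = transform),
            class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf("DNAm-age clock '%s': %d CpG probes, intercept %.4g\n",
              x$name, length(x$coefficients), x$intercept))
  print(x$transform)
  invisible(x)
}

#' @export
coef.clock_model <- function(object, ...) object$coefficients

#' @export
length.clock_model <- function(x) length(x$coefficients)

#' Predict DNAm age from a beta matrix
#'
#' Applies the clock's linear predictor to each sample column and maps the
#' result through the inverse age transform. Clock probes absent from the
#' matrix, or with missing beta values in a sample, are resolved by
#' `missing_policy`:
#' \describe{
#'   \item{`impute_cohort_mean`}{missing cells take the probe's mean across
#'     samples with data; probes absent from the matrix entirely fall back to
#'     beta 0.5 (with a warning). The default: real 450K exports often lack
#'     a few clock probes.}
#'   \item{`impute_half`}{every missing value is set to beta 0.5.}
#'   \item{`error`}{any missing clock probe aborts, listing the absent ids.}
#' }
#'
#' @param object A [clock_model()].
#' @param beta Numeric matrix, probes x samples, with probe ids as rownames
#'   and sample ids as colnames; values in \[0,1\] or `NA` for missing.
#' @param missing_policy How to resolve missing clock probes (see above).
#' @param ... Unused.
#' @return A data frame with one row per sample: `sample_id`, `clock`,
#'   `dnam_age` (years) and `n_missing_probes`.
#' @export
predict.clock_model <- function(object, beta,
                                missing_policy = c("impute_cohort_mean",
                                                   "impute_half", "error"),
                                ...) {
  missing_policy <- match.arg(missing_policy)
  beta <- validate_beta_matrix(beta)
  ids <- names(object$coefficients)
  present <- ids[ids %in% rownames(beta)]
  absent <- setdiff(ids, present)
  if (length(present) == 0L) {
    stop("no clock probe of '", object$name, "' present in the beta matrix")
  }

  sub <- matrix(NA_real_, nrow = length(ids), ncol = ncol(beta),
                dimnames = list(ids, colnames(beta)))
  sub[present, ] <- beta[present, , drop = FALSE]
  n_missing <- colSums(is.na(sub))

  if (missing_policy == "error") {
    if (length(absent) > 0L) {
      stop("missing clock probes (policy 'error'): ",
           paste(utils::head(absent, 10L), collapse = ", "),
           if (length(absent) > 10L) sprintf(" ... (%d total)", length(absent)))
    }
    if (any(n_missing > 0L)) {
      stop("missing beta values for clock probes in ",
           sum(n_missing > 0L), " sample(s) (policy 'error')")
    }
  } else if (missing_policy == "impute_cohort_mean") {
    row_mean <- rowMeans(sub, na.rm = TRUE)
    orphan <- !is.finite(row_mean)
    if (any(orphan)) {
      warning(sum(orphan), " clock probe(s) absent from the cohort; ",
              "imputed at beta 0.5")
      row_mean[orphan] <- 0.5
    }
    idx <- which(is.na(sub), arr.ind = TRUE)
    if (nrow(idx) > 0L) sub[idx] <- row_mean[idx[, 1L]]
  } else { # impute_half
    sub[is.na(sub)] <- 0.5
  }

  score <- object$intercept +
    as.numeric(crossprod(object$coefficients, sub))
  data.frame(sample_id = colnames(beta),
             clock = object$name,
             dnam_age = inverse_age_transform(score, object$transform),
             n_missing_probes = as.integer(n_missing),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Reserved probe-id of the intercept row in coefficient CSV files.
.intercept_id <- "(Intercept)"

#' Read a clock coefficient file
#'
#' Coefficient files are headerless two-column CSV (probe id, weight) with
#' exactly one row whose id is `"(Intercept)"`, matching the layout of
#' published clock coefficient supplements.
#'
#' @param path Path to the CSV file.
#' @param name Clock name; defaults to the file name without extension.
#' @param transform A [transform_spec()] attached to the loaded clock.
#' @return A [clock_model()].
#' @export
read_clock <- function(path, name = NULL,
                       transform = transform_spec("identity")) {
  if (is.null(name)) name <- tools::file_path_sans_ext(basename(path))
  tab <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE,
                         colClasses = c("character", "numeric"))
  if (ncol(tab) != 2L) stop("clock file must have two columns (id, weight)")
  ids <- tab[[1L]]
  is_int <- ids == .intercept_id
  if (sum(is_int) != 1L) {
    stop("clock file must contain exactly one '", .intercept_id, "' row")
  }
  probe_ids <- ids[!is_int]
  if (anyDuplicated(probe_ids)) {
    stop("duplicate probe row(s) in clock file: ",
         paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "))
  }
  w <- tab[[2L]][!is_int]
  names(w) <- probe_ids
  clock_model(name, tab[[2L]][is_int], w, transform)
}

#' Write a clock coefficient file
#'
#' Inverse of [read_clock()]: values are written with 17 significant digits
#' so a write/read round trip reproduces every coefficient exactly.
#'
#' @param clock A [clock_model()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_clock <- function(clock, path) {
  stopifnot(inherits(clock, "clock_model"))
  ids <- c(.intercept_id, names(clock$coefficients))
  vals <- c(clock$intercept, unname(clock$coefficients))
  writeLines(paste(ids, sprintf("%.17g", vals), sep = ","), path)
  invisible(path)
}
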