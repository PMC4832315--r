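#' Read a summary-statistics table
#'
#' Reads a tab- or comma-delimited text table with a header row and one
#' row per variant.  Required columns (case-insensitive; accepted synonyms
#' in parentheses): `variant` (`snp`, `rsid`, `id`), `beta_exposure`
#' (`beta_x`, `bx`, `b_exposure`), `se_exposure` (`se_x`, `stderr_exposure`),
#' `beta_outcome` (`beta_y`, `by`, `b_outcome`), `se_outcome` (`se_y`,
#' `stderr_outcome`).  Optional columns: `eaf`, `weight`, `n_exposure`,
#' `n_outcome`.  The delimiter is detected from the header line unless
#' given explicitly.
#'
#' @param path path to the table.
#' @param sep field delimiter; `NULL` (default) detects tab vs comma.
#' @param orient orient variants to their risk-increasing alleles after
#'   reading (default `TRUE`).
#' @return A validated [summary_set()].
#' @export
read_summary_table <- function(path, sep = NULL, orient = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  syn <- list(
    variant = c("variant", "snp", "rsid", "id"),
    beta_exposure = c("beta_exposure", "beta_x", "bx", "b_exposure", "beta.exposure"),
    se_exposure = c("se_exposure", "se_x", "stderr_exposure", "se.exposure"),
    beta_outcome = c("beta_outcome", "beta_y", "by", "b_outcome", "beta.outcome"),
    se_outcome = c("se_outcome", "se_y", "stderr_outcome", "se.outcome"),
    eaf = c("eaf", "freq", "effect_allele_freq"),
    weight = c("weight", "weights", "w"),
    n_exposure = c("n_exposure", "n_x"),
    n_outcome = c("n_outcome", "n_y"))
  lownames <- tolower(names(df))
  pick <- function(key) {
    hit <- which(lownames %in% syn[[key]])
    if (length(hit)) df[[hit[1]]] else NULL
  }
  required <- c("variant", "beta_exposure", "se_exposure",
                "beta_outcome", "se_outcome")
  missing <- required[vapply(required, function(k) is.null(pick(k)), logical(1))]
  if (length(missing))
    stop("missing required column(s) ", paste(missing, collapse = ", "),
         "; found headers: ", paste(names(df), collapse = ", "))
  for (key in c("beta_exposure", "se_exposure", "beta_outcome", "se_outcome",
                "eaf", "weight")) {
    v <- pick(key)
    if (!is.null(v) && !is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))[1]
      stop(sprintf("non-numeric value in column '%s' at data row %d", key, bad))
    }
  }
  s <- summary_set(variant = pick("variant"),
                   beta_x = pick("beta_exposure"), se_x = pick("se_exposure"),
                   beta_y = pick("beta_outcome"), se_y = pick("se_outcome"),
                   eaf = pick("eaf"), weights = pick("weight"),
                   n_x = pick("n_exposure")[1], n_y = pick("n_outcome")[1])
  if (orient) s <- orient_to_risk_increasing(s)
  s
}

#' Read a variant correlation (LD) matrix
#'
#' Reads a delimited square numeric matrix, optionally with a header row
#' (and/or first column) of variant identifiers.  When identifiers are
#' present they must be a permutation of `variant_ids`, and the matrix is
#' reordered to match; without identifiers the file order is assumed to
#' match.  The matrix is symmetrized within a `1e-8` tolerance and the
#' unit diagonal is enforced.
#'
#' @param path path to the matrix file.
#' @param variant_ids optional character vector giving the required
#'   row/column order.
#' @param sep field delimiter; `NULL` detects tab vs comma.
#' @return A K x K correlation matrix.
#' @export
read_ld_matrix <- function(path, variant_ids = NULL, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (is.null(sep)) sep <- if (grepl("\t", lines[1])) "\t" else ","
  first <- strsplit(lines[1], sep, fixed = TRUE)[[1]]
  has_header <- anyNA(suppressWarnings(as.numeric(first)))
  dat <- utils::read.table(text = lines, header = has_header, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.numeric(dat[[1]])) {
    rownames(dat) <- dat[[1]]
    dat <- dat[, -1, drop = FALSE]
  }
  m <- as.matrix(dat)
  if (nrow(m) != ncol(m))
    stop(sprintf("LD matrix must be square; got %d x %d", nrow(m), ncol(m)))
  if (!is.numeric(m)) stop("LD matrix contains non-numeric entries")
  if (any(abs(m) > 1 + 1e-8))
    stop("LD matrix entries must lie in [-1, 1]; largest magnitude ",
         format(max(abs(m))))
  if (!is.null(variant_ids)) {
    if (nrow(m) != length(variant_ids))
      stop(sprintf("LD matrix is %d x %d but %d variants were supplied",
                   nrow(m), ncol(m), length(variant_ids)))
    if (has_header) {
      ids <- colnames(m)
      if (!setequal(ids, variant_ids))
        stop("LD matrix header is not a permutation of the variant ids")
      ord <- match(variant_ids, ids)
      m <- m[ord, ord]
    }
    dimnames(m) <- list(variant_ids, variant_ids)
  }
  if (max(abs(m - t(m))) > 1e-8)
    stop("LD matrix is not symmetric (tolerance 1e-8)")
  m <- (m + t(m)) / 2
  diag(m) <- 1
  m
}

#' Write causal estimates to delimited text or JSON
#'
#' @param estimates a [causal_estimate()] or list of them.
#' @param path output path.
#' @param format `"tsv"`, `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_estimates <- function(estimates, path, format = c("tsv", "csv", "json")) {
  format <- match.arg(format)
  if (inherits(estimates, "causal_estimate")) estimates <- list(estimates)
  df <- do.call(rbind, lapply(estimates, as.data.frame))
  if (format == "json") {
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    utils::write.table(df, path, sep = if (format == "tsv") "\t" else ",",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
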