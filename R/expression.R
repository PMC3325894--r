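# Gene-expression profiles and Pearson correlation between interacting
# proteins. An expression matrix is a plain numeric matrix: one row per
# protein (rownames = protein identifiers), one column per sample.

#' Read a gene-expression matrix
#'
#' Expects a tab-separated file with a header row of sample labels; the first
#' column holds the protein/gene identifier and all remaining cells are
#' numeric expression levels.
#'
#' @param path Path to the expression TSV.
#' @return A numeric matrix, rows named by protein, with `ncol >= 2` samples.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          colClasses = "character", fill = FALSE,
                          stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty expression file: ", path)
  if (ncol(df) < 3L) stop("expression data needs at least two sample columns")
  ids <- df[[1L]]
  if (anyDuplicated(ids)) {
    stop("duplicate protein identifier in expression file: ",
         ids[duplicated(ids)][1L])
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric expression value '%s' at row %s, column %s",
                 vals[bad[1L, 1L], bad[1L, 2L]], ids[bad[1L, 1L]],
                 colnames(vals)[bad[1L, 2L]]))
  }
  if (any(!is.finite(num))) stop("expression values must be finite")
  dimnames(num) <- list(ids, colnames(vals))
  num
}

#' Write a gene-expression matrix
#'
#' Writes the TSV dialect read by [read_expression()], at full double
#' precision so a round trip is lossless to the printed digits.
#'
#' @param expr Numeric matrix with protein rownames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  cols <- colnames(expr)
  if (is.null(cols)) cols <- sprintf("S%02d", seq_len(ncol(expr)))
  header <- paste(c("protein", cols), collapse = "\t")
  body <- vapply(seq_len(nrow(expr)), function(i) {
    paste(c(rownames(expr)[i], format(expr[i, ], digits = 15, trim = TRUE,
                                      scientific = FALSE)),
          collapse = "\t")
  }, character(1L))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Pearson correlation of two expression profiles
#'
#' Sample Pearson correlation with the s-1 denominator:
#' \deqn{PCC(X,Y) = \frac{1}{s-1} \sum_{i=1}^{s}
#'   \frac{g(X,i)-\bar g(X)}{\sigma(X)} \cdot
#'   \frac{g(Y,i)-\bar g(Y)}{\sigma(Y)}}
#' The result is clipped to \eqn{[-1, 1]} against floating-point overshoot.
#' A constant profile has no defined correlation: the function signals a
#' condition of class `"pecnet_degenerate_profile"`, which edge-level callers
#' translate to a contribution of 0 (see [edge_pcc()]).
#'
#' @param x,y Numeric vectors of equal length `s >= 2`.
#' @return The correlation, a single value in \eqn{[-1, 1]}.
#' @export
#' @examples
#' pcc(c(1, 2, 3), c(1, 2, 4))
pcc <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) != length(y)) stop("profiles differ in length")
  s <- length(x)
  if (s < 2L) stop("at least two samples are required")
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("expression profiles must be finite")
  }
  sx <- stats::sd(x)
  sy <- stats::sd(y)
  if (sx == 0 || sy == 0) {
    stop(errorCondition(
      "degenerate profile: zero standard deviation, correlation undefined",
      class = "pecnet_degenerate_profile"
    ))
  }
  r <- sum(((x - mean(x)) / sx) * ((y - mean(y)) / sy)) / (s - 1)
  min(1, max(-1, r))
}

# Standardize profiles once: (x - mean) / sd per row; rows with zero variance
# or any NA are dropped so that downstream dot products skip them.
.standardized_profiles <- function(expr) {
  stopifnot(is.matrix(expr), is.numeric(expr))
  if (ncol(expr) < 2L) stop("at least two samples are required")
  mu <- rowMeans(expr)
  sdv <- apply(expr, 1L, stats::sd)
  ok <- is.finite(sdv) & sdv > 0
  z <- (expr[ok, , drop = FALSE] - mu[ok]) / sdv[ok]
  z
}

#' Pearson correlation for every network edge
#'
#' For each interaction (u, v) returns the correlation of the two expression
#' profiles. An edge whose endpoint is missing from the expression matrix, or
#' whose profile is constant (degenerate), contributes 0 rather than an
#' error: a zero term leaves every downstream sum defined without inventing
#' data.
#'
#' @param net An `igraph` network.
#' @param expr Numeric expression matrix with protein rownames.
#' @return A `data.frame` with columns `u`, `v` (canonical unordered edge
#'   key as in [ppi_edges()]) and `pcc` in \eqn{[-1, 1]}.
#' @export
edge_pcc <- function(net, expr) {
  ed <- ppi_edges(net)
  ed$pcc <- 0
  if (nrow(ed) == 0L) return(ed)
  z <- .standardized_profiles(expr)
  ok <- ed$u %in% rownames(z) & ed$v %in% rownames(z)
  if (any(ok)) {
    r <- rowSums(z[ed$u[ok], , drop = FALSE] * z[ed$v[ok], , drop = FALSE]) /
      (ncol(z) - 1L)
    ed$pcc[ok] <- pmin(1, pmax(-1, r))
  }
  ed
}
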