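# Shared internal helpers: validation, correlation p-values, matrix views.

#' Two-sided P value for a Pearson correlation
#'
#' Converts a correlation coefficient and sample size into the usual
#' t-statistic P value, `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2`
#' degrees of freedom. Vectorised over `r`.
#'
#' @param r Pearson correlation coefficient(s) in `[-1, 1]`.
#' @param n Number of paired observations (must be > 2).
#' @return Two-sided P value(s) in `(0, 1]`; `|r| = 1` maps to 0.
#' @export
#' @examples
#' pearson_p(0.5, 20)
pearson_p <- function(r, n) {
  stopifnot(n > 2)
  r <- pmin(1, pmax(-1, r))
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  out <- 2 * pt(-abs(tt), df = n - 2)
  out[abs(r) >= 1] <- 0
  out
}

# Row-wise Pearson correlation of matrix rows against one vector.
# Rows with zero variance return NA.
row_cor <- function(mat, y) {
  yc <- y - mean(y)
  sy <- sqrt(sum(yc^2))
  mc <- mat - rowMeans(mat)
  sx <- sqrt(rowSums(mc^2))
  num <- as.vector(mc %*% yc)
  r <- num / (sx * sy)
  r[sx == 0] <- NA_real_
  r
}

# Convert a tibble with id columns + one column per sample into a plain
# numeric matrix (rows = features, cols = samples).
tbl_to_matrix <- function(tbl, id_cols) {
  samp <- setdiff(names(tbl), id_cols)
  m <- as.matrix(tbl[, samp, drop = FALSE])
  storage.mode(m) <- "double"
  m
}

sample_cols <- function(tbl, id_cols) setdiff(names(tbl), id_cols)

abort_fmt <- function(...) rlang::abort(sprintf(...))

# Checks that cohort is a valid cohort table; returns it invisibly.
validate_cohort <- function(cohort) {
  req <- c("sample_id", "age", "sex")
  missing <- setdiff(req, names(cohort))
  if (length(missing) > 0) {
    abort_fmt("cohort table is missing column(s): %s", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(cohort$sample_id)) abort_fmt("cohort sample_id values must be unique")
  if (any(is.na(cohort$age)) || any(is.na(cohort$sex))) {
    abort_fmt("cohort age and sex must not contain missing values")
  }
  if (any(cohort$age <= 0 | cohort$age >= 120)) {
    abort_fmt("cohort ages must lie in (0, 120)")
  }
  if (!all(cohort$sex %in% c("male", "female"))) {
    abort_fmt("cohort sex must be 'male' or 'female'")
  }
  invisible(cohort)
}

new_result <- function(tbl, class) {
  structure(tbl, class = c(class, class(tbl)))
}
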