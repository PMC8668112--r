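#' Developmental stages used throughout the package
#'
#' Ordered factor levels for the six human early-embryo stages the design
#' tables refer to.
#'
#' @return Character vector of stage names in developmental order.
#' @export
embryo_stages <- function() {
  c("oocyte", "zygote", "2cell", "4cell", "8cell", "morula")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate that a table carries required columns
#'
#' Errors with a message naming every missing column, so schema problems in
#' hand-edited TSVs surface immediately.
#'
#' @param x data.frame-like object.
#' @param required character vector of column names.
#' @param what label used in the error message.
#' @return Invisibly `TRUE`.
#' @export
check_columns <- function(x, required, what = "table") {
  missing <- setdiff(required, names(x))
  if (length(missing)) {
    stop(sprintf("%s is missing required column(s): %s", what,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

#' Odds ratio of a 2x2 contingency table
#'
#' Computes (a*d)/(b*c) for the table `rbind(c(a, b), c(c, d))`. When any
#' cell is zero the Haldane-Anscombe correction adds 0.5 to every cell so
#' the estimate stays finite and positive.
#'
#' @param tab 2x2 numeric matrix.
#' @param haldane add 0.5 to all cells when any cell is zero (default TRUE).
#' @return List with `or`, `log_or`, `se_log_or`, and the Woolf 95 percent
#'   confidence limits `ci_lo`, `ci_hi`.
#' @export
odds_ratio <- function(tab, haldane = TRUE) {
  stopifnot(is.matrix(tab), all(dim(tab) == c(2L, 2L)), all(tab >= 0))
  t2 <- tab
  if (haldane && any(tab == 0)) t2 <- tab + 0.5
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  se <- sqrt(sum(1 / t2))
  list(or = or, log_or = log(or), se_log_or = se,
       ci_lo = exp(log(or) - 1.959964 * se),
       ci_hi = exp(log(or) + 1.959964 * se))
}

#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie chance-corrected agreement between two labelings of the
#' same objects. Used to score trajectory-cluster recovery against planted
#' truth.
#'
#' @param a,b vectors of cluster labels (any type, equal length).
#' @return Numeric scalar in [-1, 1]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (n < 2) return(1)
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_i <- sum(comb2(rowSums(tab)))
  sum_j <- sum(comb2(colSums(tab)))
  expected <- sum_i * sum_j / comb2(n)
  max_index <- (sum_i + sum_j) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Two-sided Fisher exact test p-value for a 2x2 table
#'
#' Thin wrapper around [stats::fisher.test()] that returns `NA` when a row
#' or column margin is zero (the test is undefined there), matching how the
#' bias filters treat degenerate tables.
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @return p-value, or `NA_real_` on a zero margin.
#' @export
fisher2x2 <- function(tab) {
  stopifnot(all(dim(tab) == c(2L, 2L)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(NA_real_)
  stats::fisher.test(tab)$p.value
}

# clamp a numeric vector into [lo, hi]
clamp <- function(x, lo = 0, hi = 1) pmin(hi, pmax(lo, x))

# stable site identifier
site_key <- function(chrom, pos) paste0(chrom, ":", pos)

# sample() without the scalar-x surprise
resample <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}
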