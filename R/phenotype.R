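#' Reconstruct an integer count from a printed percentage
#'
#' Published phenotype tables print category percentages and a total
#' \code{n}; the underlying count is recovered as
#' \code{round(percent * n / 100)} (half away from zero) and then verified:
#' the reconstructed count must reproduce the printed percentage at the
#' printed precision, otherwise the function errors rather than guessing.
#'
#' @param percent Printed percentage(s), 0-100.
#' @param n Total scored (>= 1), scalar or vector matching \code{percent}.
#' @param digits Decimal places of the printed percentage (default 1).
#' @param label Optional cell label(s) used in error messages.
#' @return Integer count(s).
#' @examples
#' counts_from_percentages(88.1, 42)   # 37
#' counts_from_percentages(100.0, 79)  # 79
#' @export
counts_from_percentages <- function(percent, n, digits = 1L, label = NULL) {
  stopifnot(all(percent >= 0), all(percent <= 100), all(n >= 1))
  cnt <- floor(percent * n / 100 + 0.5)  # half away from zero (inputs >= 0)
  back <- round(100 * cnt / n, digits)
  bad <- abs(back - round(percent, digits)) > 1e-8
  if (any(bad)) {
    lab <- if (is.null(label)) sprintf("%.*f%% of n=%d", digits,
                                       percent[bad], as.integer(n)[bad])
           else label[bad]
    stop("no integer count reproduces the printed percentage for cell(s): ",
         paste(lab, collapse = ", "))
  }
  as.integer(cnt)
}

log_hyper <- function(k, row1, row2, col1) {
  lchoose(row1, k) + lchoose(row2, col1 - k) - lchoose(row1 + row2, col1)
}

#' Two-tailed Fisher's exact test for a 2x2 table
#'
#' Point-probability method: the two-sided p-value sums the hypergeometric
#' probabilities of every table with the observed margins whose probability
#' does not exceed that of the observed table (with the conventional 1e-7
#' relative tolerance for floating-point ties). Evaluated in log space from
#' binomial coefficients, accurate to well over 10 significant digits at
#' desk-scale counts.
#'
#' @param a,b,c,d Non-negative integer cell counts, rows (a, b) and (c, d);
#'   both margins must be positive.
#' @return \code{fisher_result}: list with the \code{table} and
#'   \code{p_two_tailed}. Invariant under transposition of the table.
#' @examples
#' fisher_exact_two_tailed(79, 0, 37, 5)$p_two_tailed  # 0.00428 (prints 0.0043)
#' @export
fisher_exact_two_tailed <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  row1 <- a + b; row2 <- c + d; col1 <- a + c; col2 <- b + d
  if (row1 == 0 || row2 == 0 || col1 == 0 || col2 == 0) {
    stop("empty margin: Fisher's exact test undefined")
  }
  support <- max(0, col1 - row2):min(col1, row1)
  lp <- log_hyper(support, row1, row2, col1)
  lp_obs <- log_hyper(a, row1, row2, col1)
  p <- sum(exp(lp[lp <= lp_obs + log(1 + 1e-7)]))
  structure(list(table = matrix(counts, 2, 2, byrow = TRUE,
                                dimnames = list(NULL, NULL)),
                 p_two_tailed = min(p, 1)),
            class = "fisher_result")
}

#' @export
print.fisher_result <- function(x, ...) {
  cat("2x2 table:\n"); print(x$table)
  cat(sprintf("two-tailed Fisher exact p = %.6g\n", x$p_two_tailed))
  invisible(x)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' Score-test inversion without continuity correction:
#' \code{(p + z^2/2n +/- z * sqrt(p(1-p)/n + z^2/4n^2)) / (1 + z^2/n)}.
#'
#' @param x Successes (0 <= x <= n).
#' @param n Trials (>= 1).
#' @param confidence Confidence level, default 0.95.
#' @return \code{wilson_interval}: list with \code{x}, \code{n},
#'   \code{estimate}, \code{confidence}, \code{lower}, \code{upper}.
#'   \code{x = 0} gives \code{lower = 0}; \code{x = n} gives
#'   \code{upper = 1}.
#' @export
wilson_ci <- function(x, n, confidence = 0.95) {
  stopifnot(length(x) == 1L, length(n) == 1L)
  if (n < 1) stop("n must be >= 1")
  stopifnot(x >= 0, x <= n, confidence > 0, confidence < 1)
  z <- stats::qnorm((1 + confidence) / 2)
  p <- x / n
  centre <- p + z^2 / (2 * n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2))
  denom <- 1 + z^2 / n
  lower <- max(0, (centre - half) / denom)
  upper <- min(1, (centre + half) / denom)
  if (x == 0) lower <- 0
  if (x == n) upper <- 1
  structure(list(x = x, n = n, estimate = p, confidence = confidence,
                 lower = lower, upper = upper),
            class = "wilson_interval")
}

#' @export
print.wilson_interval <- function(x, ...) {
  cat(sprintf("%d/%d = %.4f, %d%% Wilson CI [%.4f, %.4f]\n", x$x, x$n,
              x$estimate, round(100 * x$confidence), x$lower, x$upper))
  invisible(x)
}

#' Build a phenotype count table from printed percentages
#'
#' @param df data.frame with a \code{genotype} column, one percentage column
#'   per category, and an \code{n} column of totals.
#' @param categories Character vector naming the category columns, in their
#'   severity order.
#' @param digits Printed precision of the percentages.
#' @return \code{phenotype_table}: data.frame with \code{genotype}, integer
#'   category count columns and \code{n}; counts per row sum to \code{n}
#'   (verified).
#' @export
phenotype_from_percentages <- function(df, categories, digits = 1L) {
  stopifnot(all(c("genotype", "n", categories) %in% names(df)))
  out <- data.frame(genotype = df$genotype, stringsAsFactors = FALSE)
  for (cat_ in categories) {
    out[[cat_]] <- counts_from_percentages(
      df[[cat_]], df$n, digits = digits,
      label = sprintf("%s[%s]", df$genotype, cat_))
  }
  out$n <- as.integer(df$n)
  sums <- rowSums(out[, categories, drop = FALSE])
  if (any(sums != out$n)) {
    stop("reconstructed counts do not sum to n for genotype(s): ",
         paste(out$genotype[sums != out$n], collapse = ", "))
  }
  attr(out, "categories") <- categories
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' Phenotype table from raw counts
#'
#' @param df data.frame with \code{genotype} and integer category columns.
#' @param categories Category column names in severity order.
#' @return \code{phenotype_table} with \code{n} computed as the row sum.
#' @export
phenotype_from_counts <- function(df, categories) {
  stopifnot(all(c("genotype", categories) %in% names(df)))
  out <- df[, c("genotype", categories), drop = FALSE]
  if (any(unlist(out[categories]) < 0)) stop("counts must be non-negative")
  out$n <- as.integer(rowSums(out[, categories, drop = FALSE]))
  attr(out, "categories") <- categories
  class(out) <- c("phenotype_table", "data.frame")
  out
}

#' Fisher tests and Wilson intervals against a control genotype
#'
#' Dichotomizes each genotype's category counts into the success category
#' versus all other categories pooled, tests each non-control genotype
#' against the control with the two-tailed Fisher exact test, and attaches
#' the Wilson interval of each genotype's success proportion.
#'
#' @param table A \code{phenotype_table}.
#' @param control_label Genotype to test against (must be present).
#' @param success_category One of the table's categories (default
#'   \code{"normal"}).
#' @param confidence Wilson interval confidence level.
#' @return data.frame, one row per genotype: \code{genotype}, \code{x}
#'   (successes), \code{n}, \code{proportion}, \code{lower}, \code{upper},
#'   \code{p_two_tailed} (NA for the control row).
#' @export
compare_genotypes <- function(table, control_label,
                              success_category = "normal",
                              confidence = 0.95) {
  stopifnot(inherits(table, "phenotype_table"))
  categories <- attr(table, "categories")
  if (!(success_category %in% categories)) {
    stop("unknown success category '", success_category, "'")
  }
  if (!(control_label %in% table$genotype)) {
    stop("control genotype '", control_label, "' not in table")
  }
  x <- table[[success_category]]
  fail <- table$n - x
  ctl <- match(control_label, table$genotype)
  res <- lapply(seq_len(nrow(table)), function(i) {
    ci <- wilson_ci(x[i], table$n[i], confidence)
    p <- if (i == ctl) NA_real_ else
      fisher_exact_two_tailed(x[ctl], fail[ctl], x[i], fail[i])$p_two_tailed
    data.frame(genotype = table$genotype[i], x = x[i], n = table$n[i],
               proportion = x[i] / table$n[i], lower = ci$lower,
               upper = ci$upper, p_two_tailed = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "success_category") <- success_category
  attr(out, "control") <- control_label
  out
}
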