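# OTU fractions, major-OTU selection, and profile-likelihood (binomial LRT)
# confidence intervals.

#' Profile-likelihood (LRT) confidence interval for a binomial proportion
#'
#' The interval is the set of proportions `p` for which the binomial
#' log-likelihood-ratio statistic \eqn{2[\ell(\hat p) - \ell(p)]} does not
#' exceed the chi-square(1) quantile at `level`; endpoints are found by
#' bracketed root-finding and clamped to `[0, 1]`. `k = 0` gives a lower
#' bound of exactly 0 and `k = n` an upper bound of exactly 1.
#'
#' @param k observed count, `0 <= k <= n`.
#' @param n number of trials, `n >= 1`.
#' @param level confidence level (default 0.95).
#' @return numeric `c(lower, upper)` on the proportion scale.
#' @examples
#' binomial_lrt_ci(50, 100)
#' binomial_lrt_ci(0, 10)
#' @export
binomial_lrt_ci <- function(k, n, level = 0.95) {
  fail_if(n < 1, "n must be >= 1")
  fail_if(k < 0 || k > n, "k must satisfy 0 <= k <= n")
  fail_if(level <= 0 || level >= 1, "level must be in (0, 1)")
  crit <- qchisq(level, df = 1)
  ll <- function(p) {
    (if (k > 0) k * log(p) else 0) + (if (k < n) (n - k) * log1p(-p) else 0)
  }
  phat <- k / n
  llmax <- ll(min(max(phat, 1e-15), 1 - 1e-15))
  f <- function(p) 2 * (llmax - ll(p)) - crit
  lower <- if (k == 0) 0 else
    uniroot(f, c(1e-15, phat), tol = 1e-12)$root
  upper <- if (k == n) 1 else
    uniroot(f, c(phat, 1 - 1e-15), tol = 1e-12)$root
  c(lower = max(0, lower), upper = min(1, upper))
}

#' Per-sample OTU fractions with confidence intervals
#'
#' Computes, for every sample `i` and OTU `j`, the fraction
#' \eqn{f_{i,j} = 100 \; C_{i,j} / \sum_j C_{i,j}} (percent) and the mean
#' fraction \eqn{\bar f_j = \sum_i f_{i,j} / N} over the `N` samples, plus a
#' per-point profile-likelihood confidence interval treating each OTU's count
#' against the sample total as binomial (see [binomial_lrt_ci()]). Samples
#' whose row sum is zero are dropped with a warning.
#'
#' @param x an [otu_count_table()] or an integer matrix (samples x OTUs).
#' @param days optional named numeric vector of sampling days; defaults to
#'   the table's `days` or, failing that, days parsed from sample ids of the
#'   form `d<number>`.
#' @param level confidence level for the intervals (default 0.95).
#' @param ci compute confidence intervals (default TRUE).
#' @return object of class `fraction_series`: list with `sample_id`, `day`,
#'   `fractions`, `lower`, `upper` (samples x OTUs matrices, percent),
#'   `mean_fraction` (named, percent), `n_samples`, `level`.
#' @export
compute_fractions <- function(x, days = NULL, level = 0.95, ci = TRUE) {
  if (inherits(x, "otu_count_table")) {
    counts <- x$counts
    if (is.null(days)) days <- x$days
  } else {
    counts <- as.matrix(x)
  }
  fail_if(ncol(counts) == 0 || nrow(counts) == 0, "empty count table")
  tot <- rowSums(counts)
  if (any(tot == 0)) {
    warning("dropping ", sum(tot == 0), " sample(s) with zero reads: ",
            paste(rownames(counts)[tot == 0], collapse = ", "))
    counts <- counts[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  fail_if(nrow(counts) == 0, "no samples with positive read totals")
  if (is.null(days)) {
    guess <- suppressWarnings(as.numeric(sub("^d", "", rownames(counts))))
    if (!any(is.na(guess))) days <- setNames(guess, rownames(counts))
  }
  if (!is.null(days)) days <- unname(days[rownames(counts)])
  frac <- 100 * counts / tot
  lower <- upper <- NULL
  if (ci) {
    lower <- upper <- matrix(NA_real_, nrow(counts), ncol(counts),
                             dimnames = dimnames(counts))
    for (i in seq_len(nrow(counts))) {
      for (j in seq_len(ncol(counts))) {
        b <- binomial_lrt_ci(counts[i, j], tot[i], level)
        lower[i, j] <- 100 * b[1]
        upper[i, j] <- 100 * b[2]
      }
    }
  }
  structure(list(sample_id = rownames(counts), day = days,
                 fractions = frac, lower = lower, upper = upper,
                 mean_fraction = colMeans(frac),
                 n_samples = nrow(counts), level = level),
            class = "fraction_series")
}

#' @export
print.fraction_series <- function(x, ...) {
  cat("Fraction series: ", x$n_samples, " samples x ", ncol(x$fractions),
      " OTUs (CI level ", x$level, ")\n", sep = "")
  top <- head(sort(x$mean_fraction, decreasing = TRUE), 5)
  cat("  top mean fractions:",
      paste(sprintf("%s=%.2f%%", names(top), top), collapse = ", "), "\n")
  invisible(x)
}

#' Long-format view of a fraction series
#'
#' @param x a `fraction_series`.
#' @param ... unused.
#' @return data.frame with columns `sample_id`, `day`, `otu`, `fraction`,
#'   `lower`, `upper` (percent).
#' @method as.data.frame fraction_series
#' @export
as.data.frame.fraction_series <- function(x, ...) {
  ns <- nrow(x$fractions); no <- ncol(x$fractions)
  out <- data.frame(
    sample_id = rep(x$sample_id, times = no),
    day = if (is.null(x$day)) NA_real_ else rep(x$day, times = no),
    otu = rep(colnames(x$fractions), each = ns),
    fraction = as.vector(x$fractions),
    lower = if (is.null(x$lower)) NA_real_ else as.vector(x$lower),
    upper = if (is.null(x$upper)) NA_real_ else as.vector(x$upper),
    stringsAsFactors = FALSE
  )
  out[order(out$otu, out$day, out$sample_id), ]
}

#' Write / read a fraction series as tab-delimited long format
#'
#' @param x a `fraction_series`.
#' @param path file path.
#' @return `path` (write) or a `fraction_series` (read).
#' @export
write_fraction_series <- function(x, path) {
  stopifnot(inherits(x, "fraction_series"))
  df <- as.data.frame(x)
  attr <- sprintf("# level=%s", x$level)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(attr, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fraction_series
#' @export
read_fraction_series <- function(path) {
  first <- readLines(path, n = 1L)
  level <- if (grepl("^# level=", first)) as.numeric(sub("^# level=", "", first)) else 0.95
  df <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  samples <- unique(df$sample_id)
  otus <- unique(df$otu)
  shape <- function(col) {
    m <- matrix(NA_real_, length(samples), length(otus),
                dimnames = list(samples, otus))
    m[cbind(match(df$sample_id, samples), match(df$otu, otus))] <- df[[col]]
    m
  }
  frac <- shape("fraction")
  days <- df$day[match(samples, df$sample_id)]
  structure(list(sample_id = samples, day = days, fractions = frac,
                 lower = shape("lower"), upper = shape("upper"),
                 mean_fraction = colMeans(frac), n_samples = length(samples),
                 level = level),
            class = "fraction_series")
}

#' Select major OTUs by mean fraction
#'
#' Returns the OTUs whose mean fraction \eqn{\bar f_j} is strictly greater
#' than `threshold_percent`, sorted by decreasing mean fraction.
#'
#' @param series a `fraction_series`.
#' @param threshold_percent threshold in percent (default 0.5).
#' @return character vector of OTU ids.
#' @export
select_major_otus <- function(series, threshold_percent = 0.5) {
  stopifnot(inherits(series, "fraction_series"))
  mf <- sort(series$mean_fraction, decreasing = TRUE)
  names(mf)[mf > threshold_percent]
}
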