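#' Bin a record into fixed geologic-time periods
#'
#' Right-open bins `[k*width, (k+1)*width)` anchored at 0 Ma. Each bin
#' reports the sample count, arithmetic mean and sample standard deviation
#' (+/- 1 sigma); empty bins are omitted. With `by_mineral = TRUE`,
#' per-mineral sub-bins are appended.
#'
#' @param values Data frame with columns `age` (Ma) and `value`, and
#'   optionally `mineral`.
#' @param width Bin width in Myr (default 100).
#' @param by_mineral Also compute per-mineral sub-bins.
#' @return Data frame `bin_lo`, `bin_hi`, `mineral` (`"all"` for pooled
#'   rows), `n`, `mean`, `sd`.
#' @export
bin_record <- function(values, width = 100, by_mineral = FALSE) {
  .assert(width > 0, "width must be positive", "feoc_domain_error")
  .assert(all(c("age", "value") %in% names(values)),
          "values needs age and value columns", "feoc_data_error")
  one <- function(df, label) {
    b <- floor(df$age / width)
    parts <- split(df$value, b)
    data.frame(bin_lo = as.numeric(names(parts)) * width,
               bin_hi = (as.numeric(names(parts)) + 1) * width,
               mineral = label,
               n = lengths(parts),
               mean = vapply(parts, mean, 0),
               sd = vapply(parts, function(v)
                 if (length(v) > 1) sd(v) else 0, 0),
               stringsAsFactors = FALSE)
  }
  out <- one(values, "all")
  if (by_mineral && "mineral" %in% names(values)) {
    subs <- lapply(split(values, values$mineral), function(df)
      one(df, df$mineral[1]))
    out <- rbind(out, do.call(rbind, subs))
  }
  out <- out[order(out$mineral != "all", out$mineral, out$bin_lo), ]
  rownames(out) <- NULL
  out
}

#' Two-group comparison by Welch's t-test
#'
#' Two-tailed unequal-variance t-test; the safer default when group sizes
#' and variances differ, as they do between mineralogies in the record.
#'
#' @param a,b Numeric vectors, each with at least 2 values.
#' @return List with `t`, `p` (two-tailed), `df`, and the group means.
#' @export
compare_groups <- function(a, b) {
  .assert(length(a) >= 2 && length(b) >= 2,
          "each group needs at least 2 values", "feoc_data_error")
  ht <- t.test(a, b, var.equal = FALSE, alternative = "two.sided")
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter),
       mean_a = mean(a), mean_b = mean(b))
}

#' Centred running average of an age series
#'
#' Moving average over a `+/- window/2` age interval, evaluated on a
#' regular age grid; grid points whose window contains no observations are
#' reported as missing.
#'
#' @param series Data frame with columns `age` (Ma) and `value`.
#' @param window Full window width, Myr (default 100).
#' @param grid Evaluation grid; defaults to a 10 Myr grid spanning the
#'   data.
#' @return Data frame `age`, `value` (`NA` in gaps), `n` per grid point.
#' @export
running_average <- function(series, window = 100, grid = NULL) {
  .assert(window > 0, "window must be positive", "feoc_domain_error")
  .assert(all(c("age", "value") %in% names(series)),
          "series needs age and value columns", "feoc_data_error")
  if (is.null(grid)) {
    grid <- seq(floor(min(series$age) / 10) * 10,
                ceiling(max(series$age) / 10) * 10, by = 10)
  }
  half <- window / 2
  res <- vapply(grid, function(g) {
    i <- abs(series$age - g) <= half
    c(if (any(i)) mean(series$value[i]) else NA_real_, sum(i))
  }, numeric(2))
  data.frame(age = grid, value = res[1, ], n = res[2, ])
}
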