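# internal helpers shared across modules

#' @importFrom stats median quantile rnorm sd lm coef optimize optim approx
#'   predict t.test setNames
#' @importFrom utils read.csv write.csv
NULL

.assert <- function(cond, msg, class = "feoc_error") {
  if (!isTRUE(cond)) {
    stop(structure(class = c(class, "error", "condition"),
                   list(message = msg, call = sys.call(-1))))
  }
  invisible(TRUE)
}

.is_num <- function(x, n = NULL) {
  ok <- is.numeric(x) && all(is.finite(x))
  if (!is.null(n)) ok <- ok && length(x) == n
  ok
}

# trapezoidal integral of y over x (x ascending)
.trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

# multivariate normal draws via (jittered) Cholesky; mu length p, Sigma p x p.
# Returns p x n matrix. Zero covariance yields replicated mu.
.rmvnorm <- function(n, mu, Sigma) {
  p <- length(mu)
  if (all(Sigma == 0)) return(matrix(mu, nrow = p, ncol = n))
  R <- tryCatch(chol(Sigma), error = function(e) {
    chol(Sigma + diag(1e-12 * max(diag(Sigma), 1e-300), p))
  })
  mu + t(R) %*% matrix(rnorm(p * n), p, n)
}

# evaluate a polynomial with coefficients in increasing order at x
.polyval <- function(coeffs, x) {
  y <- numeric(length(x))
  for (i in seq_along(coeffs)) y <- y + coeffs[i] * x^(i - 1)
  y
}

.feoc_minerals <- c("goethite", "haematite")
.feoc_endmembers <- c("M-DOC", "C-DOC", "FA")

.pair_key <- function(mineral, endmember) paste(mineral, endmember, sep = "|")
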