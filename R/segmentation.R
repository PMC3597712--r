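#' Divide a series into half-overlapping windows
#'
#' @param x Numeric sample vector (one channel of one epoch).
#' @param window_len Window length in samples.
#' @param overlap_fraction Fraction of overlap between consecutive windows;
#'   the default 0.5 gives the half-overlapping grid used throughout.
#' @return An object of class `segment_grid`: `window_len`, `step`,
#'   `starts` (0-based window start samples; windows are half-open
#'   `[start, start + window_len)`), and `n_windows`. Trailing samples not
#'   covered by a full window are dropped.
#' @examples
#' segment_series(rnorm(1000), 200)$starts  # 0 100 ... 800
#' @export
segment_series <- function(x, window_len, overlap_fraction = 0.5) {
  n <- length(x)
  stopifnot(window_len >= 3, overlap_fraction >= 0, overlap_fraction < 1)
  if (n < window_len)
    stop("epoch of ", n, " samples is shorter than one window (",
         window_len, " samples)")
  step <- max(1L, as.integer(round(window_len * (1 - overlap_fraction))))
  n_windows <- (n - window_len) %/% step + 1L
  structure(list(window_len = as.integer(window_len), step = step,
                 starts = (seq_len(n_windows) - 1L) * step,
                 n_windows = n_windows),
            class = "segment_grid")
}

window_samples <- function(x, grid, i) {
  s <- grid$starts[i]
  x[(s + 1L):(s + grid$window_len)]
}

#' Design matrix of the polynomial map model
#'
#' Builds the regression problem for a one-step map predicting `x[t+1]` from
#' all monomials of total degree `<= p` in the `m` most recent values
#' `x[t], ..., x[t-m+1]`, including the constant term.
#'
#' @param segment Numeric sample vector.
#' @param m Embedding dimension (number of lags).
#' @param p Polynomial order.
#' @return List with `X` (one row per predictable time point, one column per
#'   monomial in [monomial_exponents()] order), `y` (next-sample targets) and
#'   `exponents`.
#' @export
design_matrix <- function(segment, m, p) {
  n <- length(segment)
  if (n <= m + 1) stop("segment must be longer than m + 1 samples")
  ex <- monomial_exponents(m, p)
  lags <- vapply(seq_len(m), function(k) segment[(m - k + 1L):(n - k)],
                 numeric(n - m))
  X <- vapply(seq_len(nrow(ex)), function(i) {
    v <- rep(1, nrow(lags))
    for (j in seq_len(m)) if (ex[i, j] > 0L) v <- v * lags[, j]^ex[i, j]
    v
  }, numeric(nrow(lags)))
  list(X = X, y = segment[(m + 1L):n], exponents = ex)
}

#' Fit the polynomial map to one window
#'
#' Ridge-stabilised least squares for the one-step map coefficients. A
#' zero-variance window cannot identify any dynamics; it is flagged
#' degenerate and receives the constant-only solution.
#'
#' @inheritParams design_matrix
#' @param ridge Ridge penalty added to the normal equations; the default is
#'   numerically invisible on well-posed fits.
#' @return List with `coefs`, `residual_var` (mean squared one-step
#'   prediction error) and `degenerate` flag.
#' @export
fit_poly_map <- function(segment, m, p, ridge = 1e-8) {
  ex <- monomial_exponents(m, p)
  n_coef <- nrow(ex)
  if (length(segment) < 2L * n_coef)
    stop("segment of ", length(segment), " samples cannot identify ",
         n_coef, " coefficients (need >= ", 2L * n_coef, ")")
  if (stats::sd(segment) == 0) {
    coefs <- c(segment[1], rep(0, n_coef - 1L))
    return(list(coefs = coefs, residual_var = 0, degenerate = TRUE))
  }
  d <- design_matrix(segment, m, p)
  a <- solve(crossprod(d$X) + ridge * diag(n_coef), crossprod(d$X, d$y))
  r <- d$y - d$X %*% a
  list(coefs = drop(a), residual_var = mean(r^2), degenerate = FALSE)
}

#' Fit the map model on every window of a grid
#'
#' @param x Sample vector the grid was built on.
#' @param grid A [segment_series()] grid.
#' @inheritParams fit_poly_map
#' @param normalize Z-score each window before fitting (default `FALSE`:
#'   only the epoch mean is assumed removed; amplitude information is kept
#'   because it carries discriminative signal through noise attenuation).
#' @return Object of class `segment_models`: coefficient matrix `coefs`
#'   (window by monomial), `residual_var`, `degenerate` flags, and the fit
#'   settings.
#' @export
fit_segment_models <- function(x, grid, m = 3, p = 1, ridge = 1e-8,
                               normalize = FALSE) {
  stopifnot(inherits(grid, "segment_grid"))
  fits <- lapply(seq_len(grid$n_windows), function(i) {
    seg <- window_samples(x, grid, i)
    if (normalize && stats::sd(seg) > 0) seg <- (seg - mean(seg)) / stats::sd(seg)
    fit_poly_map(seg, m, p, ridge)
  })
  structure(list(coefs = do.call(rbind, lapply(fits, `[[`, "coefs")),
                 residual_var = vapply(fits, `[[`, numeric(1), "residual_var"),
                 degenerate = vapply(fits, `[[`, logical(1), "degenerate"),
                 m = m, p = p, ridge = ridge, normalize = normalize,
                 grid = grid),
            class = "segment_models")
}

#' Euclidean distance between two coefficient vectors
#'
#' @param a,b Coefficient vectors of equal length.
#' @return `sqrt(sum((a - b)^2))`.
#' @export
coef_distance <- function(a, b) {
  if (length(a) != length(b))
    stop("coefficient vectors differ in length (", length(a), " vs ",
         length(b), ")")
  sqrt(sum((a - b)^2))
}

#' Pairwise coefficient-distance matrix
#'
#' @param models A [fit_segment_models()] result with at least 2 windows.
#' @return Symmetric zero-diagonal matrix of Euclidean distances between the
#'   windows' coefficient vectors; indices of degenerate-flagged windows are
#'   attached as attribute `"degenerate"`.
#' @export
distance_matrix <- function(models) {
  stopifnot(inherits(models, "segment_models"))
  if (nrow(models$coefs) < 2L) stop("need at least 2 windows")
  d <- as.matrix(stats::dist(models$coefs))
  dimnames(d) <- NULL
  attr(d, "degenerate") <- which(models$degenerate)
  d
}
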