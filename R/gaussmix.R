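#' Fit a two-component univariate Gaussian mixture by EM
#'
#' Deterministic initialization by one-dimensional 2-means on the sorted data
#' (so the fit is invariant to data order and affine-equivariant); EM iterates
#' until the relative log-likelihood change is below \code{tol} or
#' \code{max_iter} iterations. The log-likelihood is non-decreasing at every
#' iteration; components are returned ordered so that \code{muHi >= muLo}.
#'
#' @param x numeric data (at least 10 distinct values).
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations.
#' @param min_sd lower bound on component SDs, as a fraction of \code{sd(x)},
#'   guarding against variance collapse.
#' @return list with weightHi, muLo, muHi, sdLo, sdHi, logLik (trace),
#'   responsibilityHi (per observation), separated (FALSE when the fit is
#'   effectively single-component).
#' @examples
#' fitDoubleGaussian(c(rnorm(200), rnorm(200, 4)))
#' @export
fitDoubleGaussian <- function(x, tol = 1e-8, max_iter = 500L,
                              min_sd = 1e-3) {
  x <- as.numeric(x)
  if (length(unique(x)) < 10)
    stop("need at least 10 distinct values to fit a double Gaussian")
  sdx <- stats::sd(x)
  if (sdx == 0) stop("degenerate data: all values equal")
  floorSD <- min_sd * sdx

  # deterministic 1-D 2-means: start from lower/upper quartile centers
  c1 <- stats::quantile(x, 0.25, names = FALSE)
  c2 <- stats::quantile(x, 0.75, names = FALSE)
  for (it in 1:100) {
    z <- abs(x - c1) <= abs(x - c2)
    n1 <- sum(z)
    if (n1 == 0 || n1 == length(x)) break
    c1n <- mean(x[z]); c2n <- mean(x[!z])
    if (c1n == c1 && c2n == c2) break
    c1 <- c1n; c2 <- c2n
  }
  z <- abs(x - c1) <= abs(x - c2)
  w <- max(min(mean(!z), 0.95), 0.05)
  mu <- c(mean(x[z]), if (any(!z)) mean(x[!z]) else mean(x) + sdx)
  s <- pmax(c(if (sum(z) > 1) stats::sd(x[z]) else sdx,
              if (sum(!z) > 1) stats::sd(x[!z]) else sdx),
            floorSD, na.rm = TRUE)

  ll <- -Inf; trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    d1 <- (1 - w) * stats::dnorm(x, mu[1], s[1])
    d2 <- w * stats::dnorm(x, mu[2], s[2])
    tot <- d1 + d2
    tot[tot == 0] <- .Machine$double.xmin
    newll <- sum(log(tot))
    trace <- c(trace, newll)
    if (is.finite(ll) && abs(newll - ll) <= tol * (abs(ll) + 1e-12)) break
    ll <- newll
    r2 <- d2 / tot                      # responsibility of component 2
    n2 <- sum(r2); n1 <- length(x) - n2
    w <- n2 / length(x)
    mu[1] <- sum((1 - r2) * x) / max(n1, 1e-12)
    mu[2] <- sum(r2 * x) / max(n2, 1e-12)
    s[1] <- sqrt(sum((1 - r2) * (x - mu[1])^2) / max(n1, 1e-12))
    s[2] <- sqrt(sum(r2 * (x - mu[2])^2) / max(n2, 1e-12))
    s <- pmax(s, floorSD)
  }
  # order components by mean
  if (mu[1] > mu[2]) {
    mu <- rev(mu); s <- rev(s); w <- 1 - w
    r2 <- 1 - r2
  }
  # Ashman's D > 2 indicates a genuinely bimodal fit
  D <- sqrt(2) * (mu[2] - mu[1]) / sqrt(s[1]^2 + s[2]^2)
  sep <- D > 2 && w > 1e-3 && w < 1 - 1e-3
  list(weightHi = w, muLo = mu[1], muHi = mu[2], sdLo = s[1], sdHi = s[2],
       logLik = trace, responsibilityHi = r2, separated = sep)
}
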