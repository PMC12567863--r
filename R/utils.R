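#' @importFrom rlang %||% abort warn .data
#' @importFrom stats rnorm runif rpois rgamma rbinom sd quantile aov prcomp
#'   kmeans dist var median fft lm coef predict setNames complete.cases
#' @importFrom utils head tail
NULL

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Cosine similarity between rows of two matrices
#'
#' Zero-length or all-zero rows get similarity 0 (with a warning) rather than
#' NaN, so degenerate profiles never crash a recommendation.
#'
#' @param x,y Numeric vectors of equal length, or matrices with the same
#'   number of columns (similarity is computed between all row pairs).
#' @return For vectors, a scalar in `[-1, 1]`; for matrices, an
#'   `nrow(x) x nrow(y)` matrix.
#' @examples
#' cosine_sim(c(1, 2, 3), c(3, 2, 1))
#' @export
cosine_sim <- function(x, y) {
  if (is.vector(x) && is.vector(y)) {
    if (length(x) != length(y)) abort("cosine_sim: vectors must have equal length")
    nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
    if (nx == 0 || ny == 0) {
      warn("cosine_sim: zero vector; similarity defined as 0")
      return(0)
    }
    return(sum(x * y) / (nx * ny))
  }
  x <- as.matrix(x); y <- as.matrix(y)
  if (ncol(x) != ncol(y)) abort("cosine_sim: column counts differ")
  nx <- sqrt(rowSums(x^2)); ny <- sqrt(rowSums(y^2))
  zx <- nx == 0; zy <- ny == 0
  if (any(zx) || any(zy)) warn("cosine_sim: zero vector(s); similarity defined as 0")
  nx[zx] <- 1; ny[zy] <- 1
  s <- (x %*% t(y)) / outer(nx, ny)
  s[zx, ] <- 0; s[, zy] <- 0
  s
}

# trailing rolling mean/sd over a window of w points ending at each position
roll_stat <- function(x, w, fun) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    seg <- x[max(1L, i - w + 1L):i]
    fun(seg)
  }, numeric(1))
}

roll_mean <- function(x, w) roll_stat(x, w, mean)
roll_sd <- function(x, w) roll_stat(x, w, function(s) if (length(s) < 2) 0 else sd(s))

# slope of least-squares line over trailing window (0 when < 2 points)
roll_slope <- function(x, w) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    seg <- x[max(1L, i - w + 1L):i]
    m <- length(seg)
    if (m < 2) return(0)
    t <- seq_len(m)
    sum((t - mean(t)) * (seg - mean(seg))) / sum((t - mean(t))^2)
  }, numeric(1))
}
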