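#' @importFrom methods new validObject is slot slotNames setValidity show
#' @importFrom stats kmeans median quantile rnorm runif sd shapiro.test
#'   wilcox.test predict approx uniroot rlnorm var
#' @importFrom utils head tail write.csv read.csv
NULL

## Centered moving average with shrinking windows at the edges.
## k is the (odd) window length in samples; k <= 1 is the identity.
.movingAverage <- function(x, k) {
  n <- length(x)
  if (k <= 1L || n == 0L) return(x)
  h <- (k - 1L) %/% 2L
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

## Bilinear interpolation of matrix `img` at (possibly fractional)
## row/col positions. Out-of-bounds positions return `fill`.
.bilinearSample <- function(img, r, c, fill = NA_real_) {
  H <- nrow(img); W <- ncol(img)
  out <- rep(fill, length(r))
  ok <- r >= 1 & r <= H & c >= 1 & c <= W & is.finite(r) & is.finite(c)
  if (!any(ok)) return(out)
  r <- r[ok]; c <- c[ok]
  r0 <- pmin(floor(r), H - 1L); c0 <- pmin(floor(c), W - 1L)
  fr <- r - r0; fc <- c - c0
  i00 <- (c0 - 1) * H + r0
  v <- img[i00] * (1 - fr) * (1 - fc) +
    img[i00 + 1L] * fr * (1 - fc) +
    img[i00 + H] * (1 - fr) * fc +
    img[i00 + H + 1L] * fr * fc
  out[ok] <- v
  out
}

## FNV-1a 32-bit string hash, kept in double arithmetic (R has no
## native unsigned 32-bit integer). Deterministic across platforms.
.fnv1a <- function(s) {
  vapply(s, function(one) {
    bytes <- utf8ToInt(enc2utf8(one))
    h <- 2166136261
    for (b in bytes) {
      h <- .bitXor32(h, b)
      h <- (h * 16777619) %% 4294967296
    }
    h
  }, numeric(1), USE.NAMES = FALSE)
}

.bitXor32 <- function(a, b) {
  ## xor of two doubles holding 32-bit unsigned values
  r <- 0; p <- 1
  for (i in 1:32) {
    ra <- a %% 2; rb <- b %% 2
    if (ra != rb) r <- r + p
    a <- (a - ra) / 2; b <- (b - rb) / 2
    p <- p * 2
    if (a == 0 && b == 0) break
  }
  r
}

## Derive a bounded child seed from a user seed and a character salt,
## so that independent stages of a simulation consume distinct streams.
.deriveSeed <- function(seed, salt) {
  as.integer((as.numeric(seed) + .fnv1a(salt)) %% 2147483647)
}

## Evaluate `expr` under a fixed seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(expr)
}

## Mean-one log-normal deviates with coefficient of variation `cv`.
.rlnormMean1 <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

## Clip to [0,255] and quantize to 8-bit integers (round half up like
## typical camera pipelines; base round() half-even is fine here).
.quantize8 <- function(x) {
  x <- round(x)
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
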