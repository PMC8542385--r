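# Internal separable filtering with reflective boundaries.
#
# 1-D convolutions are applied as dense operator matrices (G %*% X %*% t(G))
# so that boundary handling is exact whole-sample reflection and results are
# bit-reproducible across platforms.  Operators are memoised per
# (length, kernel) since fields in one run share dimensions.

.op_cache <- new.env(parent = emptyenv())

# reflect an out-of-range 1-based index into 1..n (whole-sample symmetric)
.reflect_idx <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  i <- i - 1L
  p <- 2L * (n - 1L)
  i <- i %% p
  i <- ifelse(i >= n, p - i, i)
  i + 1L
}

# dense n x n operator applying a symmetric-origin 1-D kernel with
# reflect boundary; kernel has odd length, centre at (length+1)/2
.conv_operator <- function(n, kernel) {
  key <- paste0(n, ":", paste(signif(kernel, 15), collapse = ","))
  hit <- .op_cache[[key]]
  if (!is.null(hit)) return(hit)
  r <- (length(kernel) - 1L) %/% 2L
  A <- matrix(0, n, n)
  for (o in -r:r) {
    j <- .reflect_idx(seq_len(n) + o, n)
    idx <- cbind(seq_len(n), j)
    A[idx] <- A[idx] + kernel[o + r + 1L]
  }
  .op_cache[[key]] <- A
  A
}

.gauss_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Gaussian blur of a matrix, reflect boundary; sigma = 0 is the identity
gaussian_blur <- function(m, sigma) {
  stopifnot(is.matrix(m), sigma >= 0)
  if (sigma == 0) return(m)
  k <- .gauss_kernel(sigma)
  R <- .conv_operator(nrow(m), k)
  C <- .conv_operator(ncol(m), k)
  R %*% m %*% t(C)
}

# Sobel gradient magnitude, reflect boundary
sobel_magnitude <- function(m) {
  stopifnot(is.matrix(m))
  s <- c(1, 2, 1)
  d <- c(1, 0, -1)  # derivative kernel (correlation sense is symmetric here up to sign)
  Sr <- .conv_operator(nrow(m), s)
  Sc <- .conv_operator(ncol(m), s)
  Dr <- .conv_operator(nrow(m), d)
  Dc <- .conv_operator(ncol(m), d)
  gx <- Sr %*% m %*% t(Dc)
  gy <- Dr %*% m %*% t(Sc)
  sqrt(gx^2 + gy^2)
}

# 8- (default) or 4-connected components of a logical mask
label_components <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask))
  cpp_label_components(mask != 0, as.integer(connectivity))
}

# Otsu threshold of intensities in [0, 1] (256 levels)
otsu_threshold <- function(m) {
  EBImage::otsu(m, range = c(0, 1), levels = 256)
}
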