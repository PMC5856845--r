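# Internal Gaussian filtering and Hessian helpers. Convolution is delegated
# to EBImage::filter2 (FFT, replicate borders); kernels are sampled Gaussian
# derivatives truncated at ~3.5 sigma.

gauss1d <- function(sigma, order = 0L) {
  r <- max(1L, ceiling(3.5 * sigma))
  x <- seq(-r, r)
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  switch(as.character(order),
         "0" = g,
         "1" = -x / sigma^2 * g,
         "2" = (x^2 - sigma^2) / sigma^4 * g,
         stop("order must be 0, 1 or 2"))
}

conv2 <- function(img, kernel) {
  out <- EBImage::filter2(img, kernel, boundary = "replicate")
  if (!is.matrix(out)) out <- EBImage::imageData(out)
  out
}

edt <- function(mask) {
  out <- EBImage::distmap(mask * 1L)
  if (!is.matrix(out)) out <- EBImage::imageData(out)
  out
}

cc_label <- function(mask) {
  out <- EBImage::bwlabel(mask * 1L)
  if (!is.matrix(out)) out <- EBImage::imageData(out)
  out
}

# Gaussian blur; x a matrix, returns matrix of same shape.
gblur2 <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- outer(gauss1d(sigma), gauss1d(sigma))
  conv2(img, k)
}

# Scale-normalized Hessian (second Gaussian derivatives times sigma^2).
# Rows of the image matrix index y (image row), columns index x.
hessian_at_scale <- function(img, sigma) {
  g0 <- gauss1d(sigma, 0L)
  g2 <- gauss1d(sigma, 2L)
  s2 <- sigma^2
  list(
    # outer(row_kernel, col_kernel): first argument varies along rows (y)
    yy = s2 * conv2(img, outer(g2, g0)),
    xx = s2 * conv2(img, outer(g0, g2)),
    xy = s2 * conv2(img, outer(gauss1d(sigma, 1L), gauss1d(sigma, 1L)))
  )
}

# Frangi-type vesselness for bright ridges on dark background at one scale.
# beta controls blobness selectivity; c defaults to half the maximum
# Frobenius norm of the Hessian over the image.
frangi_at_scale <- function(img, sigma, beta = 0.5) {
  H <- hessian_at_scale(img, sigma)
  half_trace <- (H$xx + H$yy) / 2
  root <- sqrt(((H$xx - H$yy) / 2)^2 + H$xy^2)
  mu1 <- half_trace + root
  mu2 <- half_trace - root
  swap <- abs(mu1) > abs(mu2)          # order |lambda1| <= |lambda2|
  l1 <- ifelse(swap, mu2, mu1)
  l2 <- ifelse(swap, mu1, mu2)
  S <- sqrt(l1^2 + l2^2)
  cc <- max(S) / 2
  if (cc <= 0) return(matrix(0, nrow(img), ncol(img)))
  Rb <- ifelse(l2 != 0, l1 / l2, 0)
  v <- exp(-Rb^2 / (2 * beta^2)) * (1 - exp(-S^2 / (2 * cc^2)))
  v[l2 >= 0] <- 0                      # bright ridges need lambda2 < 0
  v
}
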