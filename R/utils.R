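## Small numeric helpers shared across stages. All spatial operators use
## symmetric (mirror, edge-inclusive) boundary handling so that constants are
## preserved and no artificial frame response is created.

clip01 <- function(x) pmin(pmax(x, 0), 1)

## index vector implementing symmetric reflection of 1..n for out-of-range i
reflectIndex <- function(i, n) {
  i <- (i - 1L) %% (2L * n)
  ifelse(i >= n, 2L * n - 1L - i, i) + 1L
}

## shift a matrix by (dr, dc) with mirror boundaries:
## out[i, j] = m[reflect(i + dr), reflect(j + dc)]
shiftMirror <- function(m, dr, dc) {
  m[reflectIndex(seq_len(nrow(m)) + dr, nrow(m)),
    reflectIndex(seq_len(ncol(m)) + dc, ncol(m)), drop = FALSE]
}

## 2-D correlation with an (odd x odd) kernel under mirror boundaries;
## kernels here are small (<= 7x7), so shift-and-add is fast and exact
conv2Mirror <- function(m, kernel) {
  kr <- nrow(kernel); kc <- ncol(kernel)
  cr <- (kr + 1L) %/% 2L; cc <- (kc + 1L) %/% 2L
  out <- matrix(0, nrow(m), ncol(m))
  for (a in seq_len(kr)) {
    for (b in seq_len(kc)) {
      k <- kernel[a, b]
      if (k != 0) out <- out + k * shiftMirror(m, a - cr, b - cc)
    }
  }
  out
}

gaussianKernel1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

## separable Gaussian blur with mirror boundaries; sigma = 0 is the identity
gaussianBlur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- gaussianKernel1d(sigma)
  r <- (length(k) - 1L) %/% 2L
  out <- matrix(0, nrow(m), ncol(m))
  for (s in seq_along(k)) out <- out + k[s] * shiftMirror(m, s - r - 1L, 0L)
  out2 <- matrix(0, nrow(m), ncol(m))
  for (s in seq_along(k)) out2 <- out2 + k[s] * shiftMirror(out, 0L, s - r - 1L)
  out2
}

## rotate a matrix 90 degrees counter-clockwise
rot90ccw <- function(m) t(m)[ncol(m):1, , drop = FALSE]

## 0-based ellipse membership mask on a size x size raster;
## e = (centerRow, centerCol, semiAxisRow, semiAxisCol, rotationDeg)
ellipseMask <- function(size, e) {
  rows <- matrix(0:(size - 1L), size, size)
  cols <- matrix(0:(size - 1L), size, size, byrow = TRUE)
  th <- e[5] * pi / 180
  dr <- rows - e[1]; dc <- cols - e[2]
  rr <- dr * cos(th) + dc * sin(th)
  cc <- -dr * sin(th) + dc * cos(th)
  (rr / e[3])^2 + (cc / e[4])^2 <= 1
}
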