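# Separable binary morphology with a box (Chebyshev) structuring element.
# Dilation/erosion by `w` adds/removes w whole voxel layers, which is the
# reading of an "N-voxel width" strip used throughout the hydro module.

shift3 <- function(x, axis, by, fill = FALSE) {
  if (by == 0L) return(x)
  d <- dim(x)
  out <- array(fill, d)
  n <- d[axis]
  if (abs(by) >= n) return(out)
  src <- dst <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  if (by > 0) {
    dst[[axis]] <- (by + 1L):n
    src[[axis]] <- 1L:(n - by)
  } else {
    dst[[axis]] <- 1L:(n + by)
    src[[axis]] <- (1L - by):n
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
  out
}

dilate_box <- function(x, width) {
  stopifnot(width >= 1L)
  x <- x != 0
  for (axis in 1:3) {
    acc <- x
    for (b in seq_len(width)) {
      acc <- acc | shift3(x, axis, b) | shift3(x, axis, -b)
    }
    x <- acc
  }
  x
}

erode_box <- function(x, width) {
  stopifnot(width >= 1L)
  x <- x != 0
  for (axis in 1:3) {
    acc <- x
    for (b in seq_len(width)) {
      # outside the grid counts as background, so border voxels erode away
      acc <- acc & shift3(x, axis, b, fill = FALSE) &
        shift3(x, axis, -b, fill = FALSE)
    }
    x <- acc
  }
  x
}
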