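# Mask-aware separable Gaussian smoothing.

gauss_kernel1d <- function(sd) {
  if (sd <= 0) return(1)
  r <- max(1L, ceiling(3 * sd))
  k <- exp(-((-r):r)^2 / (2 * sd^2))
  k / sum(k)
}

shift_arr <- function(arr, axis, by, fill = 0) {
  dims <- dim(arr)
  if (by == 0) return(arr)
  out <- array(fill, dims)
  idx_src <- idx_dst <- lapply(dims, seq_len)
  if (by > 0) { idx_dst[[axis]] <- (1 + by):dims[axis]
                idx_src[[axis]] <- 1:(dims[axis] - by) }
  else { idx_dst[[axis]] <- 1:(dims[axis] + by)
         idx_src[[axis]] <- (1 - by):dims[axis] }
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    arr[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

conv1d_axis <- function(arr, kernel, axis) {
  r <- (length(kernel) - 1) / 2
  out <- array(0, dim(arr))
  for (t in seq_along(kernel))
    out <- out + kernel[t] * shift_arr(arr, axis, t - 1 - r)
  out
}

# Smooth `arr` inside `mask` with an isotropic Gaussian of `sd_vox` voxels.
# Normalizing by the smoothed mask keeps edge voxels unbiased (no background
# zeros leak into the mean). Values outside the mask are returned as 0.
gauss_smooth3d <- function(arr, sd_vox, mask = NULL) {
  if (sd_vox <= 0) return(arr)
  k <- gauss_kernel1d(sd_vox)
  if (is.null(mask)) mask <- array(TRUE, dim(arr))
  num <- arr * mask
  den <- mask * 1
  for (ax in 1:3) {
    num <- conv1d_axis(num, k, ax)
    den <- conv1d_axis(den, k, ax)
  }
  out <- array(0, dim(arr))
  ok <- mask & den > 0
  out[ok] <- num[ok] / den[ok]
  out
}
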