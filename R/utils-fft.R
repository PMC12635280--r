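## Spectral helpers shared by the forward field model, the unwrapping step,
## V-SHARP and both dipole inversions. All operators assume periodic
## boundaries with the zero-frequency component at index 1 and arrays
## ordered (x, y, z), z being the B0 axis.

#' Discrete Fourier frequencies
#'
#' Frequencies (cycles per unit length) for an n-point DFT with sample
#' spacing `d`, ordered to match [stats::fft()] output.
#'
#' @param n Number of samples.
#' @param d Sample spacing (default 1).
#' @return Numeric vector of length `n`.
#' @keywords internal
fft_freq <- function(n, d = 1) {
  stopifnot(n >= 1, d > 0)
  k <- c(seq.int(0L, floor((n - 1) / 2)), seq.int(-floor(n / 2), -1L))
  k / (n * d)
}

fft3 <- function(x) fft(x)
ifft3 <- function(x) fft(x, inverse = TRUE) / length(x)

## Real part of the inverse transform; the imaginary residue of a
## real-valued operation is numerical noise and is dropped.
ifft3_re <- function(x) Re(ifft3(x))

#' k-space dipole kernel
#'
#' Unit-susceptibility field response in Fourier space,
#' `D(k) = 1/3 - kz^2 / |k|^2`, with the `D(0) := 0` convention so a
#' uniform susceptibility produces no field offset. `kz` is the component
#' along the main-field (third array) axis.
#'
#' @param dim Integer vector of length 3, grid size.
#' @param voxel_size_mm Numeric length-3 voxel spacing in mm.
#' @return A `dim`-shaped numeric array.
#' @export
dipole_kernel <- function(dim, voxel_size_mm = c(1, 1, 1)) {
  stopifnot(length(dim) == 3, length(voxel_size_mm) == 3)
  kx <- fft_freq(dim[1], voxel_size_mm[1])
  ky <- fft_freq(dim[2], voxel_size_mm[2])
  kz <- fft_freq(dim[3], voxel_size_mm[3])
  k2 <- outer(outer(kx^2, ky^2, `+`), kz^2, `+`)
  kz2 <- outer(array(0, dim[1:2]) + 0, kz^2, `+`)
  dim(kz2) <- dim
  d <- 1 / 3 - kz2 / k2
  d[k2 == 0] <- 0
  d
}

## Eigenvalues of the (negative) periodic discrete Laplacian,
## sum_a (2 sin(pi f_a h_a? ))^2 in physical units 1/mm^2 when spacing given.
laplace_eigenvalues <- function(dim, voxel_size_mm = c(1, 1, 1)) {
  ev1 <- function(n, d) (2 * sin(pi * fft_freq(n, 1)))^2 / d^2
  ex <- ev1(dim[1], voxel_size_mm[1])
  ey <- ev1(dim[2], voxel_size_mm[2])
  ez <- ev1(dim[3], voxel_size_mm[3])
  out <- outer(outer(ex, ey, `+`), ez, `+`)
  dim(out) <- dim
  out
}

## Circular convolution with a kernel given already centred at index (1,1,1)
## (i.e. wrap-around layout). Both inputs real.
fft_convolve <- function(x, kernel_hat) {
  ifft3_re(fft3(x) * kernel_hat)
}

#' Spherical mean-value kernel in k-space
#'
#' Normalised ball indicator of the given radius, laid out with its centre
#' wrapped to index (1,1,1), returned as its (real) Fourier transform.
#' Used by the SMV filter in V-SHARP and by ball erosion.
#'
#' @keywords internal
sphere_kernel_ft <- function(dim, voxel_size_mm, radius_mm, normalize = TRUE) {
  dx <- voxel_size_mm
  cx <- ((seq_len(dim[1]) - 1 + floor(dim[1] / 2)) %% dim[1] - floor(dim[1] / 2)) * dx[1]
  cy <- ((seq_len(dim[2]) - 1 + floor(dim[2] / 2)) %% dim[2] - floor(dim[2] / 2)) * dx[2]
  cz <- ((seq_len(dim[3]) - 1 + floor(dim[3] / 2)) %% dim[3] - floor(dim[3] / 2)) * dx[3]
  r2 <- outer(outer(cx^2, cy^2, `+`), cz^2, `+`)
  dim(r2) <- dim
  ball <- (r2 <= radius_mm^2) * 1
  n_in <- sum(ball)
  if (normalize) ball <- ball / n_in
  structure(fft3(ball), n_voxels = n_in)
}

## Anti-aliased sphere kernel: voxels within one voxel width of the
## surface get fractional weight, reducing discretisation error of the
## spherical mean relative to a hard indicator.
aa_sphere_kernel_ft <- function(dim, voxel_size_mm, radius_mm) {
  dx <- voxel_size_mm
  cx <- ((seq_len(dim[1]) - 1 + floor(dim[1] / 2)) %% dim[1] - floor(dim[1] / 2)) * dx[1]
  cy <- ((seq_len(dim[2]) - 1 + floor(dim[2] / 2)) %% dim[2] - floor(dim[2] / 2)) * dx[2]
  cz <- ((seq_len(dim[3]) - 1 + floor(dim[3] / 2)) %% dim[3] - floor(dim[3] / 2)) * dx[3]
  r <- sqrt(outer(outer(cx^2, cy^2, `+`), cz^2, `+`))
  dim(r) <- dim
  h <- max(dx)
  w <- pmin(pmax((radius_mm - r) / h + 0.5, 0), 1)
  fft3(w / sum(w))
}

#' Binary erosion by a ball
#'
#' Morphological erosion of a logical volume with a spherical structuring
#' element of physical radius `radius_mm`, computed by FFT convolution.
#'
#' @param mask Logical 3D array.
#' @param radius_mm Ball radius in mm; 0 returns the mask unchanged.
#' @param voxel_size_mm Voxel spacing in mm.
#' @return Logical array of the same shape.
#' @export
erode_ball <- function(mask, radius_mm, voxel_size_mm = c(1, 1, 1)) {
  stopifnot(is.array(mask), length(dim(mask)) == 3)
  if (radius_mm < 0) stop("erosion radius must be >= 0")
  if (radius_mm == 0) return(mask != 0)
  kh <- sphere_kernel_ft(dim(mask), voxel_size_mm, radius_mm)
  frac <- fft_convolve(mask * 1, kh)
  ## a voxel survives only if the whole ball lies inside the mask;
  ## 0.5/n guards against FFT round-off
  frac >= 1 - 0.5 / attr(kh, "n_voxels")
}

#' Reflect a volume across the mid-sagittal index plane
#'
#' Flips the first (left-right) array axis, mapping slice i to N+1-i.
#' On a grid built symmetrically about that plane this realises the
#' contralateral-mirror construction used for healthy-reference masks.
#'
#' @param x 3D array (any type).
#' @return Array of the same shape and type.
#' @export
mirror_lr <- function(x) {
  stopifnot(length(dim(x)) == 3)
  x[dim(x)[1]:1, , , drop = FALSE]
}

#' Dice-Sorensen overlap coefficient
#'
#' `2|A and B| / (|A| + |B|)` for two binary masks on the same grid.
#' Two empty masks are in perfect (vacuous) agreement and return 1.
#'
#' @param mask_a,mask_b Logical arrays of identical shape.
#' @return Scalar in \[0, 1\].
#' @export
dice <- function(mask_a, mask_b) {
  stopifnot(identical(dim(mask_a), dim(mask_b)))
  a <- mask_a != 0
  b <- mask_b != 0
  denom <- sum(a) + sum(b)
  if (denom == 0) {
    message("dice: both masks empty; returning 1 by convention")
    return(1)
  }
  2 * sum(a & b) / denom
}

## Reduced gyromagnetic ratio of the proton, MHz/T.
GAMMA_BAR_MHZ_PER_T <- 42.577

#' Static-dephasing conversion constant
#'
#' kappa maps a susceptibility source magnitude (ppm) to the reversible
#' transverse relaxation rate R2' (1/s) it generates in the
#' static-dephasing sphere regime: `kappa = (2*pi/(9*sqrt(3))) *
#' gamma_bar * B0 * 1e-6` per ppm. At 3 T this is about 51.5 s^-1/ppm.
#'
#' @param b0_tesla Main field strength in tesla.
#' @return Scalar, s^-1 per ppm.
#' @export
static_dephasing_kappa <- function(b0_tesla = 3) {
  (2 * pi / (9 * sqrt(3))) * GAMMA_BAR_MHZ_PER_T * 1e6 * b0_tesla * 1e-6
}
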