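#' Confocal image stack
#'
#' Container for a single-channel 3D fluorescence volume: a `(z, y, x)`
#' array of non-negative intensities plus the voxel spacing in um.
#'
#' @param voxels 3D numeric array ordered `(z, y, x)`.
#' @param spacing numeric length-3 `(z, y, x)` in um/voxel.
#' @return object of class `image_stack`.
#' @export
image_stack <- function(voxels, spacing) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L) stop("voxels must be a 3D array (z, y, x)")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("spacing must be 3 positive numbers (z, y, x)")
  structure(list(voxels = voxels, spacing = spacing), class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack: %d x %d x %d (z,y,x), spacing %.3g/%.3g/%.3g um>\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Binary segmentation volume
#'
#' @param mask 3D logical array `(z, y, x)`.
#' @param spacing voxel spacing `(z, y, x)` in um.
#' @param warning_flag optional character note attached by the segmenter
#'   (e.g. when a constant image produced an empty mask).
#' @return object of class `binary_volume`.
#' @export
binary_volume <- function(mask, spacing, warning_flag = NULL) {
  structure(list(mask = mask, spacing = as.numeric(spacing),
                 warning_flag = warning_flag), class = "binary_volume")
}

#' Read a multi-page TIFF as an image stack
#'
#' @param path path to a single-channel multi-page TIFF (8 or 16 bit).
#' @param spacing voxel spacing `(z, y, x)` in um.
#' @param channel channel to extract if pages carry more than one; an error
#'   is raised for multi-channel files when `channel` is `NULL`.
#' @return an [image_stack] with voxels ordered `(z, y, x)` and raw
#'   integer intensities preserved.
#' @export
read_stack <- function(path, spacing = c(0.24, 0.05, 0.05), channel = NULL) {
  if (!file.exists(path)) stop("cannot read stack: no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (length(pages) == 0L) stop("empty TIFF: ", path)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) {
      if (is.null(channel))
        stop("multi-channel TIFF: pass `channel` to select one")
      p[, , channel]
    } else p
  })
  d <- dim(pages[[1]])
  vox <- array(0, c(length(pages), d[1], d[2]))
  for (i in seq_along(pages)) vox[i, , ] <- pages[[i]]
  image_stack(vox, spacing)
}

#' Write an image stack to a multi-page TIFF
#'
#' @param stack an [image_stack]; intensities must fit the requested depth.
#' @param path output path.
#' @param bits 8 or 16 bits per sample.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits = 16L) {
  maxv <- 2^bits - 1
  if (max(stack$voxels) > maxv) stop("intensities exceed ", bits, "-bit range")
  pages <- lapply(seq_len(dim(stack$voxels)[1]), function(i)
    stack$voxels[i, , ] / maxv)
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  invisible(path)
}

#' Repair single-black-pixel artifacts
#'
#' Post-segmentation confocal slices can contain isolated zero-valued
#' pixels. Per 2D slice, every pixel with value 0 whose eight in-plane
#' neighbors all have values greater than 0 is replaced by the mean of
#' those eight neighbors. The rule is applied in a single pass over the
#' original values, so replacements do not cascade, and pixels with any
#' zero-valued or missing neighbor are left unchanged.
#'
#' @param stack an [image_stack].
#' @return an [image_stack] with repaired slices.
#' @export
fix_black_pixels <- function(stack) {
  vox <- stack$voxels
  d <- dim(vox)
  if (d[2] < 3L || d[3] < 3L) return(stack)
  for (i in seq_len(d[1])) {
    sl <- vox[i, , ]
    core <- sl[2:(d[2] - 1L), 2:(d[3] - 1L)]
    nb <- list(sl[1:(d[2] - 2L), 1:(d[3] - 2L)], sl[1:(d[2] - 2L), 2:(d[3] - 1L)],
               sl[1:(d[2] - 2L), 3:d[3]],        sl[2:(d[2] - 1L), 1:(d[3] - 2L)],
               sl[2:(d[2] - 1L), 3:d[3]],        sl[3:d[2], 1:(d[3] - 2L)],
               sl[3:d[2], 2:(d[3] - 1L)],        sl[3:d[2], 3:d[3]])
    allpos <- Reduce(`&`, lapply(nb, function(m) m > 0))
    fix <- core == 0 & allpos
    if (any(fix)) {
      nbsum <- Reduce(`+`, nb)
      core[fix] <- nbsum[fix] / 8
      sl[2:(d[2] - 1L), 2:(d[3] - 1L)] <- core
      vox[i, , ] <- sl
    }
  }
  image_stack(vox, stack$spacing)
}

#' Segmentation configuration
#'
#' Defaults are the study settings for granule-cell spine stacks:
#' smoothing weight `mu_smooth = 1`, intensity weights `lambda1 = 1` and
#' `lambda2 = 9` (background is weighted heavily because spines are sparse
#' bright objects), 100 iterations, Otsu initialization.
#'
#' @param mu_smooth number of morphological smoothing passes per iteration.
#' @param lambda1 weight of the inside-intensity term.
#' @param lambda2 weight of the outside-intensity term.
#' @param iterations fixed iteration count.
#' @param init `"otsu"` or `"checkerboard"`.
#' @return list of class `segmentation_config`.
#' @export
segmentation_config <- function(mu_smooth = 1L, lambda1 = 1, lambda2 = 9,
                                iterations = 100L,
                                init = c("otsu", "checkerboard")) {
  init <- match.arg(init)
  stopifnot(iterations >= 1L, lambda1 > 0, lambda2 > 0, mu_smooth >= 0)
  structure(list(mu_smooth = as.integer(mu_smooth), lambda1 = lambda1,
                 lambda2 = lambda2, iterations = as.integer(iterations),
                 init = init), class = "segmentation_config")
}

#' Morphological active contours without edges (ACWE)
#'
#' Region-based Chan-Vese segmentation in its morphological formulation:
#' at each iteration the level set is attracted toward the region whose
#' mean intensity it matches best (balloon-free data term weighted by
#' `lambda1`/`lambda2`), then regularized by `mu_smooth` passes of the
#' curvature morphological operator (alternating sup-of-erosions and
#' inf-of-dilations over nine planar structuring elements in 3D).
#'
#' @param stack an [image_stack] (pre-deconvolved).
#' @param config a [segmentation_config]; the default reproduces the study
#'   parameters (mu = 1, lambda1 = 1, lambda2 = 9, 100 iterations).
#' @return a [binary_volume]; for a constant image with Otsu initialization
#'   an empty mask is returned with `warning_flag` set instead of an error.
#' @export
segment_acwe <- function(stack, config = segmentation_config()) {
  img <- stack$voxels
  if (diff(range(img)) == 0) {
    return(binary_volume(array(FALSE, dim(img)), stack$spacing,
                         warning_flag = "constant image: empty mask"))
  }
  u <- switch(config$init,
              otsu = init_otsu(img),
              checkerboard = init_checkerboard(dim(img)))
  if (!any(u) || all(u)) {
    return(binary_volume(array(FALSE, dim(img)), stack$spacing,
                         warning_flag = "degenerate initialization: empty mask"))
  }
  storage.mode(u) <- "logical"
  for (it in seq_len(config$iterations)) {
    c1 <- mean(img[u]); c0 <- mean(img[!u])
    g <- gradient_magnitude_l1(u)
    aux <- g * (config$lambda1 * (img - c1)^2 - config$lambda2 * (img - c0)^2)
    u[aux < 0] <- TRUE
    u[aux > 0] <- FALSE
    if (config$mu_smooth > 0) {
      for (s in seq_len(config$mu_smooth)) {
        u <- if ((it + s) %% 2L == 0L) sup_inf(inf_sup(u)) else inf_sup(sup_inf(u))
      }
    }
  }
  binary_volume(u, stack$spacing)
}

init_otsu <- function(img) {
  # slice-wise min-max normalization: dim z-planes still contribute
  # foreground, and the initialization is invariant to global affine
  # intensity rescaling
  d <- dim(img)
  norm <- img
  for (i in seq_len(d[1])) {
    sl <- img[i, , ]
    rg <- range(sl)
    norm[i, , ] <- if (diff(rg) > 0) (sl - rg[1]) / diff(rg) else sl * 0
  }
  thr <- otsu_threshold(as.vector(norm))
  norm > thr
}

# classic 256-bin Otsu on values scaled to [0, 1]
otsu_threshold <- function(x) {
  x <- x[is.finite(x)]
  r <- range(x)
  if (diff(r) == 0) return(r[1])
  h <- tabulate(pmin(255L, as.integer((x - r[1]) / diff(r) * 256)) + 1L, 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(256L) - 1L))
  mu_t <- mu[256L]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  k <- which.max(sigma_b)
  r[1] + (k - 0.5) / 256 * diff(r)
}

init_checkerboard <- function(d, square = 5L) {
  iz <- (seq_len(d[1]) - 1L) %/% square
  iy <- (seq_len(d[2]) - 1L) %/% square
  ix <- (seq_len(d[3]) - 1L) %/% square
  parity <- outer(outer(iz, iy, `+`), ix, `+`) %% 2L
  parity == 0L
}

# shift a 3D array by (dz, dy, dx) with edge replication
shift3 <- function(a, dz, dy, dx) {
  d <- dim(a)
  iz <- pmin(pmax(seq_len(d[1]) - dz, 1L), d[1])
  iy <- pmin(pmax(seq_len(d[2]) - dy, 1L), d[2])
  ix <- pmin(pmax(seq_len(d[3]) - dx, 1L), d[3])
  a[iz, iy, ix, drop = FALSE]
}

gradient_magnitude_l1 <- function(u) {
  ud <- array(as.numeric(u), dim(u))
  g <- array(0, dim(u))
  for (ax in 1:3) {
    dl <- c(0L, 0L, 0L); dl[ax] <- 1L
    fw <- shift3(ud, -dl[1], -dl[2], -dl[3])
    bw <- shift3(ud, dl[1], dl[2], dl[3])
    g <- g + abs(fw - bw) / 2
  }
  g
}

# the nine planar structuring elements of the 3D curvature operator,
# each as a 9 x 3 matrix of (dz, dy, dx) offsets
curv_se3 <- function() {
  t3 <- -1:1
  grid2 <- expand.grid(a = t3, b = t3)
  list(
    cbind(grid2$a, grid2$b, 0L),            # z-y plane
    cbind(grid2$a, 0L, grid2$b),            # z-x plane
    cbind(0L, grid2$a, grid2$b),            # y-x plane
    cbind(grid2$a, grid2$b, grid2$b),       # diagonal planes
    cbind(grid2$a, grid2$b, -grid2$b),
    cbind(grid2$b, grid2$a, grid2$b),
    cbind(grid2$b, grid2$a, -grid2$b),
    cbind(grid2$b, grid2$b, grid2$a),
    cbind(grid2$b, -grid2$b, grid2$a)
  )
}

se_erode <- function(u, se) {
  out <- u
  for (r in seq_len(nrow(se))) {
    if (all(se[r, ] == 0L)) next
    out <- out & shift3(u, se[r, 1], se[r, 2], se[r, 3])
  }
  out
}

se_dilate <- function(u, se) {
  out <- u
  for (r in seq_len(nrow(se))) {
    if (all(se[r, ] == 0L)) next
    out <- out | shift3(u, se[r, 1], se[r, 2], se[r, 3])
  }
  out
}

sup_inf <- function(u) {
  ses <- curv_se3()
  out <- se_erode(u, ses[[1]])
  for (i in 2:length(ses)) out <- out | se_erode(u, ses[[i]])
  out
}

inf_sup <- function(u) {
  ses <- curv_se3()
  out <- se_dilate(u, ses[[1]])
  for (i in 2:length(ses)) out <- out & se_dilate(u, ses[[i]])
  out
}

#' Dice overlap of two binary volumes
#'
#' @param a,b `binary_volume`s or logical arrays of identical shape.
#' @return Dice coefficient in `[0, 1]` (1 when both are empty).
#' @export
dice_coefficient <- function(a, b) {
  if (inherits(a, "binary_volume")) a <- a$mask
  if (inherits(b, "binary_volume")) b <- b$mask
  stopifnot(identical(dim(a), dim(b)))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}
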