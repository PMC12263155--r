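#' Count filaments in a field-of-view image
#'
#' Nucleation activity can be read out by diluting a polymerization reaction,
#' stabilizing with labeled phalloidin, and counting filaments per TIRF field
#' of view. The image is Otsu-thresholded, the binary mask is skeletonized
#' (Zhang-Suen thinning), and connected skeletons with arc length of at least
#' `min_length_um` are counted. Deterministic for fixed input.
#'
#' @param image 2-D numeric intensity matrix.
#' @param min_length_um Minimum filament arc length to count (um).
#' @param pixel_size_um Pixel size (um).
#' @return Integer filament count.
#' @export
count_filaments <- function(image, min_length_um = 1, pixel_size_um = 0.254) {
  if (!is.matrix(image)) abort_input("image must be a 2-D matrix")
  if (length(image) == 0L) return(0L)
  rng <- range(image)
  if (rng[1L] == rng[2L]) return(0L)  # blank field
  norm <- (image - rng[1L]) / (rng[2L] - rng[1L])
  thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  mask <- norm > thr
  if (!any(mask)) return(0L)
  skel <- thin_mask(mask)
  # bwlabel is 4-connected; label a dilated skeleton so diagonal runs stay
  # one component, then measure arc length along the skeleton, counting
  # diagonal neighbor steps as sqrt(2) pixels
  dil <- EBImage::dilate(EBImage::Image(skel), EBImage::makeBrush(3, "box"))
  labels <- as.matrix(EBImage::imageData(EBImage::bwlabel(dil)))
  labs <- labels * skel
  n_lab <- max(labs)
  if (n_lab == 0) return(0L)
  arc <- numeric(n_lab)
  nr <- nrow(labs); nc <- ncol(labs)
  add_pairs <- function(a, b, w) {
    same <- a > 0 & a == b
    if (any(same)) {
      tab <- tabulate(a[same], nbins = n_lab)
      arc <<- arc + w * tab
    }
  }
  add_pairs(labs[-nr, ], labs[-1L, ], 1)                 # vertical
  add_pairs(labs[, -nc], labs[, -1L], 1)                 # horizontal
  add_pairs(labs[-nr, -nc], labs[-1L, -1L], sqrt(2))     # diagonal
  add_pairs(labs[-nr, -1L], labs[-1L, -nc], sqrt(2))     # anti-diagonal
  sum(arc * pixel_size_um >= min_length_um)
}

# Zhang-Suen binary thinning, vectorized over the whole mask per iteration.
thin_mask <- function(mask) {
  m <- mask * 1L
  pad <- function(x) {
    out <- matrix(0L, nrow(x) + 2L, ncol(x) + 2L)
    out[2:(nrow(x) + 1L), 2:(ncol(x) + 1L)] <- x
    out
  }
  repeat {
    changed <- FALSE
    for (step in 1:2) {
      p <- pad(m)
      nr <- nrow(m); nc <- ncol(m)
      ri <- 2:(nr + 1L); ci <- 2:(nc + 1L)
      p2 <- p[ri - 1L, ci];      p3 <- p[ri - 1L, ci + 1L]
      p4 <- p[ri, ci + 1L];      p5 <- p[ri + 1L, ci + 1L]
      p6 <- p[ri + 1L, ci];      p7 <- p[ri + 1L, ci - 1L]
      p8 <- p[ri, ci - 1L];      p9 <- p[ri - 1L, ci - 1L]
      bsum <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      # number of 0->1 transitions around the 8-neighborhood
      a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
        (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
        (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      cond <- m == 1L & bsum >= 2 & bsum <= 6 & a == 1
      if (step == 1L) {
        cond <- cond & (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        cond <- cond & (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) {
        m[cond] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m
}

#' Simulate a field of view with planted filaments
#'
#' Draws straight filaments of given lengths at random non-overlapping
#' positions and orientations on a dark background, with Gaussian blur and
#' noise, for validating [count_filaments()].
#'
#' @param lengths_um Filament lengths (um), one filament each.
#' @param image_px Field size in pixels (square).
#' @param pixel_size_um Pixel size (um).
#' @param intensity Filament intensity above background.
#' @param background Background level.
#' @param noise_sd Additive Gaussian noise.
#' @param psf_sigma_px Gaussian blur sigma (pixels); 0 disables.
#' @param seed RNG seed.
#' @param max_tries Placement attempts per filament before giving up.
#' @return Intensity matrix with the planted count in attribute `"n_planted"`.
#' @export
simulate_filament_fov <- function(lengths_um, image_px = 256,
                                  pixel_size_um = 0.254, intensity = 1000,
                                  background = 100, noise_sd = 0,
                                  psf_sigma_px = 0, seed = 0,
                                  max_tries = 200) {
  img <- matrix(0, image_px, image_px)
  margin <- 3L
  with_seed(seed, {
    for (L in lengths_um) {
      len_px <- L / pixel_size_um
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        theta <- stats::runif(1L, 0, pi)
        x0 <- stats::runif(1L, margin, image_px - margin)
        y0 <- stats::runif(1L, margin, image_px - margin)
        x1 <- x0 + len_px * cos(theta)
        y1 <- y0 + len_px * sin(theta)
        if (x1 < margin || x1 > image_px - margin ||
            y1 < margin || y1 > image_px - margin) next
        # Bresenham-style stepping gives a single-pixel-wide line
        npts <- max(2L, abs(round(x1 - x0)), abs(round(y1 - y0))) + 1L
        xs <- round(seq(x0, x1, length.out = npts))
        ys <- round(seq(y0, y1, length.out = npts))
        idx <- unique(cbind(xs, ys))
        # keep a clear halo so filaments stay separable
        halo <- 0L
        for (dx in -2:2) for (dy in -2:2) {
          halo <- halo + sum(img[cbind(pmin(pmax(idx[, 1L] + dx, 1L), image_px),
                                       pmin(pmax(idx[, 2L] + dy, 1L), image_px))])
        }
        if (halo > 0) next
        img[idx] <- intensity
        placed <- TRUE
        break
      }
      if (!placed) warning("could not place a filament without overlap",
                           call. = FALSE)
    }
    if (psf_sigma_px > 0) {
      img <- EBImage::gblur(img, sigma = psf_sigma_px)
    }
    img <- img + background
    if (noise_sd > 0) {
      img <- img + matrix(stats::rnorm(length(img), 0, noise_sd),
                          nrow(img), ncol(img))
    }
  })
  attr(img, "n_planted") <- length(lengths_um)
  img
}
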