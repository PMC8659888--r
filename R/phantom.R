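# Synthetic T1-like tumor phantoms: smooth anatomical background plus a
# small, bright, irregular (possibly multi-lobed) foreground region whose
# area fraction varies over almost two orders of magnitude -- the scale
# variation the multi-level architecture is designed for.

#' Phantom dataset configuration
#'
#' @param image_size pixels per side (default 256).
#' @param n_pairs number of image/mask pairs.
#' @param tumor_area_range `(min_frac, max_frac)` of the slice area covered
#'   by tumor; areas are drawn log-uniformly so small scales are as common
#'   as large ones.  Default `c(0.001, 0.08)`.
#' @param n_lobes_range integer range of tumor lobes (connected bumps).
#' @param foreground_intensity `c(mean, sd)` of the per-pixel tumor
#'   intensity (bright on T1, default mean 0.75, sd 0.08).
#' @param background_scale upper bound of the background intensity after
#'   min-max scaling (default 0.55, leaving a clear but noisy contrast).
#' @param background_cells cells per side of the coarse Gaussian field that
#'   is smoothly interpolated to make the anatomy-like background.
#' @param background_noise_sd per-pixel Gaussian noise added on top of the
#'   smooth field (on the pre-scaling intensity scale).
#' @param seed master seed; pair `i` derives its own stream from it, so a
#'   dataset is reproducible pair by pair.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(image_size = 256L, n_pairs = 100L,
                           tumor_area_range = c(0.001, 0.08),
                           n_lobes_range = c(1L, 3L),
                           foreground_intensity = c(mean = 0.75, sd = 0.08),
                           background_scale = 0.55,
                           background_cells = 6L,
                           background_noise_sd = 0.3,
                           seed = 1L) {
  if (length(tumor_area_range) != 2L ||
      !(tumor_area_range[1] > 0 && tumor_area_range[1] <= tumor_area_range[2] &&
        tumor_area_range[2] < 0.5))
    stop("tumor_area_range must satisfy 0 < min <= max < 0.5")
  if (any(n_lobes_range < 1L)) stop("n_lobes_range must be >= 1")
  structure(list(image_size = as.integer(image_size),
                 n_pairs = as.integer(n_pairs),
                 tumor_area_range = as.numeric(tumor_area_range),
                 n_lobes_range = as.integer(round(n_lobes_range)),
                 foreground_intensity = foreground_intensity,
                 background_scale = background_scale,
                 background_cells = as.integer(background_cells),
                 background_noise_sd = background_noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

# Run `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Rasterize one irregular lobe: an ellipse (axes a, b, rotation phi) whose
# radius is modulated by a low-order cosine series in polar angle.
lobe_mask <- function(size, cx, cy, a, b, phi, amp, pha) {
  xs <- matrix(rep(seq_len(size) - 1, size), size, size)
  ys <- t(xs)
  dx <- xs - cx
  dy <- ys - cy
  u <- cos(phi) * dx + sin(phi) * dy
  v <- -sin(phi) * dx + cos(phi) * dy
  r <- sqrt((u / a)^2 + (v / b)^2)
  theta <- atan2(v / b, u / a)
  mod <- 1
  for (j in seq_along(amp)) mod <- mod + amp[j] * cos((j + 1) * theta + pha[j])
  r <= mod
}

# Draw lobe geometry for a target pixel area, rasterize, and rescale the
# radii until the realized area is within 3% of the target (the boundary
# discretization limit for very small tumors).
draw_mask <- function(size, target_px, n_lobes) {
  for (attempt in 1:25) {
    r0 <- sqrt(target_px / pi)
    margin <- min(0.35 * size, 3 * r0 + 2)
    cx <- runif(1, margin, size - 1 - margin)
    cy <- runif(1, margin, size - 1 - margin)
    lobes <- vector("list", n_lobes)
    share <- if (n_lobes == 1L) 1 else {
      s <- c(0.7, rep(0.3 / (n_lobes - 1), n_lobes - 1))
      s / sum(s)
    }
    for (l in seq_len(n_lobes)) {
      rl <- sqrt(share[l] * target_px / pi)
      asp <- runif(1, 0.6, 1)
      off <- if (l == 1L) c(0, 0) else {
        ang <- runif(1, 0, 2 * pi)
        d <- r0 * runif(1, 0.5, 1.0)
        c(d * cos(ang), d * sin(ang))
      }
      lobes[[l]] <- list(cx = cx + off[1], cy = cy + off[2],
                         a = rl / sqrt(asp), b = rl * sqrt(asp),
                         phi = runif(1, 0, pi),
                         amp = runif(3, 0, 0.12),
                         pha = runif(3, 0, 2 * pi))
    }
    scale <- 1
    for (iter in 1:12) {
      m <- matrix(FALSE, size, size)
      for (lb in lobes)
        m <- m | lobe_mask(size, lb$cx, lb$cy, scale * lb$a, scale * lb$b,
                           lb$phi, lb$amp, lb$pha)
      got <- sum(m)
      if (got > 0 && abs(got - target_px) <= max(0.03 * target_px, 1))
        return(m)
      scale <- scale * sqrt(target_px / max(got, 1))
    }
  }
  stop("could not realize the requested tumor area; ",
       "the area range is degenerate for this image size")
}

#' Generate one phantom image/mask pair
#'
#' Deterministic in `(config$seed, index)`: the same pair is produced
#' regardless of generation order.  The image is the sum of a smooth
#' low-frequency Gaussian field and white noise, min-max scaled to
#' `[0, background_scale]`, with per-pixel foreground intensities drawn
#' from the configured Gaussian inside the mask (clamped to \[0, 1\]).
#'
#' @param config a [phantom_config()].
#' @param index pair index, `1 <= index <= n_pairs`.
#' @return a list of class `slice_pair` with `image` (matrix in \[0, 1\]),
#'   `mask` (binary integer matrix), and `fg_fraction`.
#' @export
generate_pair <- function(config, index) {
  stopifnot(inherits(config, "phantom_config"))
  if (index < 1L || index > config$n_pairs)
    stop("index must be in [1, n_pairs]")
  size <- config$image_size
  with_seed(config$seed + 1009L * as.integer(index), {
    lo <- config$tumor_area_range[1]
    hi <- config$tumor_area_range[2]
    # sample the interior so convergence tolerance and pixel rounding
    # cannot leave the range
    lo2 <- lo * 1.1
    hi2 <- hi * 0.9
    frac <- if (lo2 >= hi2) sqrt(lo * hi)
            else exp(runif(1, log(lo2), log(hi2)))
    target_px <- max(round(frac * size^2), 3)
    if (lo2 < hi2) {
      # keep the realized fraction inside the range despite rounding and
      # the rasterizer's +-1 px tolerance
      target_px <- min(max(target_px, ceiling(lo * size^2) + 1L, 3),
                       max(floor(hi * size^2) - 1L, 3))
    }
    n_lobes <- if (config$n_lobes_range[1] == config$n_lobes_range[2])
      config$n_lobes_range[1]
    else sample(config$n_lobes_range[1]:config$n_lobes_range[2], 1)
    mask <- draw_mask(size, target_px, n_lobes)
    # background: coarse Gaussian field, smoothly upsampled, plus noise
    g <- config$background_cells
    coarse <- matrix(stats::rnorm(g * g), g, g)
    field <- as_array(cpp_bilinear_fwd(array(coarse, c(g, g, 1, 1)),
                                       size, size))[, , 1, 1]
    field <- field + stats::rnorm(size^2, sd = config$background_noise_sd)
    rng <- range(field)
    bg <- if (rng[2] > rng[1]) (field - rng[1]) / (rng[2] - rng[1]) else field * 0
    img <- bg * config$background_scale
    fg <- stats::rnorm(sum(mask), mean = config$foreground_intensity[["mean"]],
                       sd = config$foreground_intensity[["sd"]])
    img[mask] <- fg
    img[img < 0] <- 0
    img[img > 1] <- 1
    structure(list(image = img, mask = matrix(as.integer(mask), size, size),
                   fg_fraction = mean(mask)),
              class = "slice_pair")
  })
}

#' Generate a phantom dataset on disk
#'
#' Writes `n_pairs` image/mask PNG pairs (`image_%04d.png` as 8-bit gray,
#' `mask_%04d.png` strictly \{0, 255\}) plus `manifest.csv` with columns
#' `file_image`, `file_mask`, `seed` and `fg_fraction`.
#'
#' @param config a [phantom_config()].
#' @param out_dir output directory (created if missing).
#' @return the manifest as a data frame (invisibly also written to disk).
#' @export
generate_dataset <- function(config, out_dir) {
  stopifnot(inherits(config, "phantom_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0) stop("out_dir is not writable: ", out_dir)
  n <- config$n_pairs
  manifest <- data.frame(file_image = sprintf("image_%04d.png", seq_len(n)),
                         file_mask = sprintf("mask_%04d.png", seq_len(n)),
                         seed = config$seed + 1009L * seq_len(n),
                         fg_fraction = numeric(n))
  for (i in seq_len(n)) {
    p <- generate_pair(config, i)
    fi <- file.path(out_dir, manifest$file_image[i])
    fm <- file.path(out_dir, manifest$file_mask[i])
    ok <- tryCatch({
      png::writePNG(p$image, fi)
      png::writePNG(p$mask + 0, fm)  # 0/1 doubles -> 8-bit {0, 255}
      TRUE
    }, error = function(e) e)
    if (!isTRUE(ok))
      stop("failed writing ", fi, ": ", conditionMessage(ok))
    manifest$fg_fraction[i] <- p$fg_fraction
  }
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  manifest
}

#' Generate a phantom dataset in memory
#'
#' Convenience wrapper used by the training examples and tests: returns a
#' list of `slice_pair`s without touching the file system.
#'
#' @param config a [phantom_config()].
#' @param indices which pairs to generate (default all).
#' @return list of `slice_pair` objects.
#' @export
generate_pairs <- function(config, indices = seq_len(config$n_pairs)) {
  lapply(indices, function(i) generate_pair(config, i))
}
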