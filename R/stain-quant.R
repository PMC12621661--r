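# Simplified digital DAB burden scoring: optical-density transform, stain
# colour deconvolution onto an H-DAB basis, and grid-superpixel
# aggregation. A regular tile grid stands in for the original superpixel
# segmentation; the mean-intensity contract is unchanged.

#' Stain quantification configuration
#'
#' Bundles the stain basis and tiling parameters. The default stain vectors
#' are the standard haematoxylin / DAB optical-density unit vectors of
#' Ruifrok-Johnston colour deconvolution; vectors are re-normalised to unit
#' length and must not be collinear.
#'
#' @param dab_vector,hematoxylin_vector Length-3 stain vectors in OD space.
#' @param tile_size Pixels per (square) superpixel side, `>= 4`.
#' @param tissue_od_threshold Minimum tile-mean total OD (sum over channels)
#'   for a tile to count as tissue; lighter tiles are background.
#' @param background_intensity White level of the scanner (default 255).
#' @return List of class `stain_config`.
#' @export
stain_config <- function(dab_vector = c(0.268, 0.570, 0.776),
                         hematoxylin_vector = c(0.650, 0.704, 0.286),
                         tile_size = 32,
                         tissue_od_threshold = 0.05,
                         background_intensity = 255) {
  unitize <- function(v) {
    v <- as.numeric(v)
    if (length(v) != 3 || any(!is.finite(v)) || sum(v^2) == 0) {
      abort("stain vectors must be finite length-3 and non-zero")
    }
    v / sqrt(sum(v^2))
  }
  dab <- unitize(dab_vector)
  hem <- unitize(hematoxylin_vector)
  if (abs(sum(dab * hem)) > 1 - 1e-8) abort("stain vectors are collinear")
  if (tile_size < 4) abort("tile_size must be >= 4")
  structure(
    list(dab_vector = dab, hematoxylin_vector = hem,
         tile_size = as.integer(tile_size),
         tissue_od_threshold = tissue_od_threshold,
         background_intensity = background_intensity),
    class = "stain_config"
  )
}

check_rgb <- function(image) {
  if (length(dim(image)) != 3 || dim(image)[3] != 3) {
    abort("expected an RGB array with dim (height, width, 3)")
  }
  image
}

#' RGB to optical density transform
#'
#' `OD = -log10(max(I, 1) / background)` per channel; a white pixel maps to
#' OD 0, and intensities are floored at 1 to keep the transform finite.
#'
#' @param image RGB array (height x width x 3) with values in
#'   `[0, background_intensity]`.
#' @param background_intensity White level (default 255).
#' @return OD array of the same shape.
#' @export
rgb_to_od <- function(image, background_intensity = 255) {
  check_rgb(image)
  if (any(image < 0 | image > background_intensity)) {
    abort("intensities must lie in [0, background_intensity]")
  }
  -log10(pmax(image, 1) / background_intensity)
}

#' Optical density back to RGB intensities
#'
#' Inverse of [rgb_to_od()] up to the 1-intensity floor.
#'
#' @param od OD array.
#' @param background_intensity White level.
#' @return Intensity array.
#' @export
od_to_rgb <- function(od, background_intensity = 255) {
  background_intensity * 10^(-od)
}

#' Deconvolve the DAB channel from an OD image
#'
#' Least-squares projection of each OD pixel onto the two-stain basis
#' (haematoxylin, DAB); the DAB coefficient is returned with negative
#' concentrations clamped to zero.
#'
#' @param od_image OD array (height x width x 3), e.g. from [rgb_to_od()].
#' @param config A [stain_config()].
#' @return Matrix (height x width) of DAB concentrations.
#' @export
deconvolve_dab <- function(od_image, config = stain_config()) {
  check_rgb(od_image)
  S <- cbind(config$hematoxylin_vector, config$dab_vector)
  proj <- solve(crossprod(S), t(S))  # 2 x 3 least-squares operator
  d <- dim(od_image)
  px <- matrix(od_image, ncol = 3)   # pixels x channels
  conc <- px %*% t(proj)             # pixels x (hem, dab)
  matrix(pmax(conc[, 2], 0), nrow = d[1], ncol = d[2])
}

#' Grid-superpixel DAB burden score
#'
#' Tiles the image on a regular `tile_size` grid (partial edge tiles are
#' kept), discards tiles whose mean total OD falls below the tissue
#' threshold, and scores the slide as the mean over tissue tiles of the
#' tile-mean DAB concentration. With no tissue tiles the score is missing.
#'
#' @param image RGB array (height x width x 3).
#' @param config A [stain_config()].
#' @return One-row tibble: `mean_dab_od`, `n_tiles_tissue`, `n_tiles_total`.
#' @export
superpixel_burden <- function(image, config = stain_config()) {
  check_rgb(image)
  ts <- config$tile_size
  d <- dim(image)
  if (d[1] < ts || d[2] < ts) abort("image smaller than one tile")
  od <- rgb_to_od(image, config$background_intensity)
  dab <- deconvolve_dab(od, config)
  total_od <- od[, , 1] + od[, , 2] + od[, , 3]
  row_bins <- ceiling(seq_len(d[1]) / ts)
  col_bins <- ceiling(seq_len(d[2]) / ts)
  tile_of <- interaction(row_bins[row(dab)], col_bins[col(dab)], drop = FALSE)
  tile_total <- tapply(as.vector(total_od), tile_of, mean)
  tile_dab <- tapply(as.vector(dab), tile_of, mean)
  keep <- !is.na(tile_total) & tile_total >= config$tissue_od_threshold
  n_total <- sum(!is.na(tile_total))
  n_tissue <- sum(keep)
  tibble(
    mean_dab_od = if (n_tissue > 0) mean(tile_dab[keep]) else NA_real_,
    n_tiles_tissue = n_tissue, n_tiles_total = n_total
  )
}

#' Read an RGB image file for stain quantification
#'
#' Reads a PNG tile into the 0..background intensity scale expected by
#' [superpixel_burden()]. Grayscale images are replicated across channels
#' and any alpha channel is dropped.
#'
#' @param path PNG file path.
#' @param background_intensity Target white level.
#' @return RGB array (height x width x 3).
#' @export
read_rgb_image <- function(path, background_intensity = 255) {
  if (!requireNamespace("png", quietly = TRUE)) {
    abort("reading PNG tiles requires the 'png' package")
  }
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  img * background_intensity
}

#' Render a synthetic stained tile with known composition
#'
#' Builds an RGB tile from per-pixel haematoxylin and DAB concentration
#' maps through the stain model `I = background * 10^(-(c_h H + c_d D))`.
#' Used to construct ground-truth fixtures for the burden scorer.
#'
#' @param hematoxylin,dab Concentration matrices of equal dimension.
#' @param config A [stain_config()].
#' @return RGB array (height x width x 3).
#' @export
simulate_stain_tile <- function(hematoxylin, dab, config = stain_config()) {
  if (!all(dim(hematoxylin) == dim(dab))) {
    abort("concentration maps must have equal dimensions")
  }
  od <- outer(as.matrix(hematoxylin), config$hematoxylin_vector) +
    outer(as.matrix(dab), config$dab_vector)
  od_to_rgb(od, config$background_intensity)
}
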