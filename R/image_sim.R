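#' Image simulation configuration
#'
#' Parameters of the synthetic RNA-FISH cell generator: per cell a
#' three-channel (DAPI / SON / FISH) 2-D image containing one elliptical
#' nucleus with bright speckle foci. In "Speckle" cells the FISH mean
#' inside speckles is `fish_enrichment` times the nucleoplasm mean; in
#' "Diffused" cells the FISH signal is uniform across the nucleus.
#'
#' @param n_cells Number of cells (one image stack per cell).
#' @param img_size Image side in pixels (default 128).
#' @param nucleus_radius_px Nucleus semi-major axis (default 32; the
#'   minor axis is 0.8 of it).
#' @param speckles_per_nucleus Speckle foci per nucleus (default 6).
#' @param speckle_radius_px Speckle radius (default 4); speckles lie
#'   fully inside the nucleus, so this must be smaller than the minor
#'   axis.
#' @param fish_enrichment Speckle-to-nucleoplasm FISH mean ratio for
#'   Speckle cells (>= 0, default 3).
#' @param fraction_diffuse Fraction of cells with diffuse FISH
#'   (default 0).
#' @param noise_sd Gaussian noise SD added to every channel (default 2
#'   intensity units).
#' @param nucleoplasm_level Mean nucleoplasmic FISH intensity
#'   (default 100).
#' @param positivity_floor Background FISH intensity outside nuclei
#'   (default 10).
#' @param seed Integer seed.
#' @return An object of class `image_sim_config`.
#' @export
image_sim_config <- function(n_cells = 50L, img_size = 128L,
                             nucleus_radius_px = 32, speckles_per_nucleus = 6L,
                             speckle_radius_px = 4, fish_enrichment = 3,
                             fraction_diffuse = 0, noise_sd = 2,
                             nucleoplasm_level = 100, positivity_floor = 10,
                             seed = 1L) {
  cfg <- list(n_cells = as.integer(n_cells), img_size = as.integer(img_size),
              nucleus_radius_px = nucleus_radius_px,
              speckles_per_nucleus = as.integer(speckles_per_nucleus),
              speckle_radius_px = speckle_radius_px,
              fish_enrichment = fish_enrichment,
              fraction_diffuse = fraction_diffuse, noise_sd = noise_sd,
              nucleoplasm_level = nucleoplasm_level,
              positivity_floor = positivity_floor, seed = as.integer(seed))
  stopifnot(cfg$n_cells >= 1, cfg$img_size >= 16,
            cfg$fish_enrichment >= 0,
            cfg$fraction_diffuse >= 0, cfg$fraction_diffuse <= 1,
            cfg$noise_sd >= 0, cfg$positivity_floor >= 0)
  minor <- 0.8 * cfg$nucleus_radius_px
  if (cfg$speckle_radius_px >= minor) {
    stop("speckle_radius_px must be smaller than the nucleus minor axis (",
         minor, " px)")
  }
  structure(cfg, class = "image_sim_config")
}

.disk_mask <- function(size, cx, cy, r) {
  x <- matrix(seq_len(size), size, size)
  y <- matrix(seq_len(size), size, size, byrow = TRUE)
  (x - cx)^2 + (y - cy)^2 <= r^2
}

.ellipse_mask <- function(size, cx, cy, a, b) {
  x <- matrix(seq_len(size), size, size)
  y <- matrix(seq_len(size), size, size, byrow = TRUE)
  ((x - cx) / a)^2 + ((y - cy) / b)^2 <= 1
}

# Fixed channel baselines (intensity units). DAPI marks the nucleus, SON
# is bright only in speckle foci; FISH levels come from the config.
IMG_DAPI_BG <- 10
IMG_DAPI_NUCLEUS <- 200
IMG_SON_BG <- 5
IMG_SON_NUCLEOPLASM <- 20
IMG_SON_SPECKLE <- 250

#' Simulate an RNA-FISH cell cohort with ground truth
#'
#' @param config An [image_sim_config()].
#' @return List of class `cell_cohort`: `cells` (each with matrices
#'   `dapi`, `son`, `fish` and a `truth` list holding `nucleus_mask`,
#'   `speckle_mask`, `pattern`) and the `config`. The per-cell true
#'   pattern is `"Speckle"` or `"Diffused"`.
#' @export
simulate_cells <- function(config) {
  stopifnot(inherits(config, "image_sim_config"))
  set.seed(config$seed)
  size <- config$img_size
  a <- config$nucleus_radius_px
  b <- 0.8 * a
  sr <- config$speckle_radius_px
  n_diffuse <- round(config$fraction_diffuse * config$n_cells)
  pattern <- sample(c(rep("Diffused", n_diffuse),
                      rep("Speckle", config$n_cells - n_diffuse)))
  cells <- lapply(seq_len(config$n_cells), function(i) {
    cx <- size / 2 + stats::runif(1, -0.05, 0.05) * size
    cy <- size / 2 + stats::runif(1, -0.05, 0.05) * size
    nucleus <- .ellipse_mask(size, cx, cy, a, b)
    speckle <- matrix(FALSE, size, size)
    for (s in seq_len(config$speckles_per_nucleus)) {
      repeat {  # rejection-sample a center whose whole disk fits
        sx <- cx + stats::runif(1, -1, 1) * (a - sr)
        sy <- cy + stats::runif(1, -1, 1) * (b - sr)
        if (((sx - cx) / (a - sr))^2 + ((sy - cy) / (b - sr))^2 <= 1) break
      }
      speckle <- speckle | .disk_mask(size, sx, sy, sr)
    }
    speckle <- speckle & nucleus

    dapi <- matrix(IMG_DAPI_BG, size, size)
    dapi[nucleus] <- IMG_DAPI_NUCLEUS
    son <- matrix(IMG_SON_BG, size, size)
    son[nucleus] <- IMG_SON_NUCLEOPLASM
    son[speckle] <- IMG_SON_SPECKLE
    fish <- matrix(config$positivity_floor, size, size)
    fish[nucleus] <- config$nucleoplasm_level
    if (pattern[i] == "Speckle") {
      fish[speckle] <- config$fish_enrichment * config$nucleoplasm_level
    }
    if (config$noise_sd > 0) {
      np <- size * size
      dapi <- pmax(dapi + rnorm(np, sd = config$noise_sd), 0)
      son <- pmax(son + rnorm(np, sd = config$noise_sd), 0)
      fish <- pmax(fish + rnorm(np, sd = config$noise_sd), 0)
    }
    list(dapi = dapi, son = son, fish = fish,
         truth = list(nucleus_mask = nucleus, speckle_mask = speckle,
                      pattern = pattern[i]))
  })
  structure(list(cells = cells, config = config), class = "cell_cohort")
}

# TIFF intensities are stored as 16-bit fractions of this full scale.
IMG_TIFF_SCALE <- 65535

#' Write / read one cell as a multi-page TIFF
#'
#' Pages are in channel order DAPI, SON, FISH (16-bit).
#'
#' @param cell One element of a `cell_cohort`'s `cells`.
#' @param path TIFF path.
#' @return `read_cell_tiff` returns a list of matrices `dapi`, `son`,
#'   `fish` on the original intensity scale.
#' @export
write_cell_tiff <- function(cell, path) {
  pages <- lapply(cell[c("dapi", "son", "fish")], function(m) {
    pmin(m / IMG_TIFF_SCALE, 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_cell_tiff
#' @export
read_cell_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != 3L) stop("expected 3 pages (DAPI, SON, FISH)")
  stats::setNames(lapply(pages, function(m) m * IMG_TIFF_SCALE),
                  c("dapi", "son", "fish"))
}
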