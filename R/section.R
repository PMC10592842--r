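#' A histological section with physical-scale metadata
#'
#' Bundles one digitized RGB section with the metadata every downstream
#' stage needs: the in-plane resolution (micrometres per pixel, isotropic),
#' the position of the section in its serial stack, and the physical
#' spacing between consecutive sections. Intensities use 0-255 semantics
#' (stored as doubles); dark-field material has a near-black background
#' with bright labeled fibers.
#'
#' Coordinates throughout the package are 0-based `(row, col)` pairs and
#' pixel ranges are half-open, so a 256-pixel patch at `top_left = c(0, 0)`
#' covers rows and columns 0..255.
#'
#' @param image numeric array, `H x W x 3` (or `H x W`, replicated to three
#'   identical channels), values in 0-255.
#' @param um_per_px positive scalar, micrometres per pixel.
#' @param section_index integer position of the section in its stack.
#' @param spacing_mm physical distance (mm) between consecutive sections.
#' @param tissue_mask optional `H x W` logical matrix (tissue vs slide).
#' @return An object of class `ft_section`.
#' @export
ft_section <- function(image, um_per_px, section_index = 1L,
                       spacing_mm = 1.2, tissue_mask = NULL) {
  if (length(dim(image)) == 2) {
    image <- array(rep(image, 3L), c(dim(image), 3L))
  }
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3) {
    abort("image must be H x W x 3 (or H x W grayscale)",
          class = "ft_validation_error")
  }
  if (d[1] < 64 || d[2] < 64) {
    abort("section images must be at least 64 x 64 pixels",
          class = "ft_validation_error")
  }
  if (!is.numeric(um_per_px) || length(um_per_px) != 1 || um_per_px <= 0) {
    abort("um_per_px must be a positive scalar",
          class = "ft_validation_error")
  }
  if (!is.numeric(spacing_mm) || spacing_mm <= 0) {
    abort("spacing_mm must be positive", class = "ft_validation_error")
  }
  if (!is.null(tissue_mask)) {
    if (!identical(dim(tissue_mask), d[1:2])) {
      abort("tissue_mask must match the image grid",
            class = "ft_validation_error")
    }
    tissue_mask <- tissue_mask > 0
  }
  structure(
    list(image = image, um_per_px = um_per_px,
         section_index = as.integer(section_index),
         spacing_mm = spacing_mm, tissue_mask = tissue_mask),
    class = "ft_section")
}

#' @export
print.ft_section <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf(
    "<ft_section> %d x %d px @ %.3g um/px (%.2f x %.2f mm), index %d\n",
    d[1], d[2], x$um_per_px, d[1] * x$um_per_px / 1000,
    d[2] * x$um_per_px / 1000, x$section_index))
  invisible(x)
}

#' @export
dim.ft_section <- function(x) dim(x$image)[1:2]

#' Read a section image from disk
#'
#' Reads an 8-bit PNG or TIFF (grayscale images are replicated to three
#' channels) and attaches physical metadata. Pixel values are preserved
#' bit-exactly for 8-bit inputs (stored on the 0-255 scale).
#'
#' @inheritParams ft_section
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @return An `ft_section`.
#' @export
load_section <- function(path, um_per_px = 1.76, section_index = 1L,
                         spacing_mm = 1.2) {
  if (!file.exists(path)) {
    abort(paste0("cannot read section image: ", path), class = "ft_io_error")
  }
  img <- read_image_file(path)
  ft_section(round(img * 255), um_per_px, section_index, spacing_mm)
}

read_image_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    abort(paste0("unsupported image format: .", ext), class = "ft_io_error"))
  if (length(dim(img)) == 3 && dim(img)[3] == 4) img <- img[, , 1:3]  # drop alpha
  if (length(dim(img)) == 3 && dim(img)[3] == 2) img <- img[, , 1]    # gray+alpha
  img
}

#' Write a section image to disk
#'
#' @param section an `ft_section`.
#' @param path output path; format chosen by extension (`.png`, `.tif`).
#' @return `path`, invisibly.
#' @export
save_section <- function(section, path) {
  img <- section$image / 255
  img[img < 0] <- 0
  img[img > 1] <- 1
  write_image_file(img, path)
  invisible(path)
}

write_image_file <- function(img, path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
    abort(paste0("unsupported image format: .", ext), class = "ft_io_error"))
  invisible(path)
}

#' Read / write a label mask
#'
#' Label maps (0 = background, k > 0 = region id, up to 255 ids) travel as
#' single-channel 8-bit PNG/TIFF with the id stored in the pixel value.
#'
#' @param path mask file path.
#' @return Integer matrix of region ids.
#' @export
load_mask <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("cannot read mask: ", path), class = "ft_io_error")
  }
  img <- read_image_file(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  matrix(as.integer(round(img * 255)), nrow(img), ncol(img))
}

#' @rdname load_mask
#' @param mask integer matrix of region ids (0-255).
#' @export
save_mask <- function(mask, path) {
  if (max(mask) > 255) abort("label ids above 255 cannot be stored in 8-bit masks",
                             class = "ft_validation_error")
  write_image_file(matrix(mask / 255, nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Estimate the tissue mask of a section
#'
#' Dark-field slides have a near-black background, so tissue is taken as
#' the largest 8-connected component of pixels whose mean channel
#' intensity exceeds `intensity_floor`, with interior holes filled. The
#' result feeds the brain-outline false-positive filter and white-matter
#' constrained patch sampling.
#'
#' @param section an `ft_section`.
#' @param intensity_floor intensity threshold on the 0-255 scale.
#' @return Logical `H x W` matrix.
#' @export
compute_tissue_mask <- function(section, intensity_floor = 10) {
  mm <- rowMeans(section$image, dims = 2)
  fg <- mm > intensity_floor
  if (!any(fg)) {
    abort("blank section: no pixels above the intensity floor",
          class = "ft_blank_section")
  }
  lab <- label_components(fg, connectivity = 8L)
  sizes <- tabulate(lab[lab > 0])
  keep <- lab == which.max(sizes)
  keep <- EBImage::fillHull(keep) > 0
  matrix(as.logical(keep), nrow(keep), ncol(keep))
}

#' Connected-component labeling
#'
#' Labels connected sets of `TRUE` pixels under 4- or 8-connectivity.
#' Label ids are assigned in raster-scan order of each component's first
#' pixel, starting at 1.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8.
#' @return Integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask, connectivity = 8L) {
  label_components_cpp(mask > 0, as.integer(connectivity))
}

#' Extract a patch from a section
#'
#' @param section an `ft_section`.
#' @param top_left 0-based `(row, col)` of the patch's top-left pixel.
#' @param size patch side length in pixels.
#' @param pad if `TRUE`, patches extending past the section border are
#'   completed by mirror reflection; otherwise out-of-bounds requests error.
#' @param target optional label/binary matrix on the section grid from
#'   which the patch's segmentation target is cropped.
#' @return An `ft_patch` (fields `pixels`, `origin`, `target`,
#'   `class_label`).
#' @export
extract_patch <- function(section, top_left, size = 256L, pad = FALSE,
                          target = NULL) {
  d <- dim(section$image)
  r0 <- top_left[1]; c0 <- top_left[2]
  if (r0 < 0 || c0 < 0 || (!pad && (r0 + size > d[1] || c0 + size > d[2]))) {
    if (!pad) {
      abort("patch does not fit inside the section (enable pad for border tiles)",
            class = "ft_range_error")
    }
  }
  rows <- reflect_index(seq.int(r0 + 1, r0 + size), d[1])
  cols <- reflect_index(seq.int(c0 + 1, c0 + size), d[2])
  px <- section$image[rows, cols, , drop = FALSE]
  tg <- if (!is.null(target)) target[rows, cols] else NULL
  structure(list(pixels = px, origin = c(row = r0, col = c0),
                 target = tg, class_label = NULL),
            class = "ft_patch")
}

# mirror-reflect 1-based indices into 1..n (boundary not repeated)
reflect_index <- function(idx, n) {
  if (n == 1) return(rep(1L, length(idx)))
  period <- 2L * (n - 1L)
  k <- (idx - 1L) %% period
  ifelse(k < n, k + 1L, period - k + 1L)
}

# re-insert a patch (used by round-trip invariants and tile stitching)
insert_patch <- function(section, patch) {
  sz <- dim(patch$pixels)[1]
  r0 <- patch$origin[["row"]]; c0 <- patch$origin[["col"]]
  section$image[(r0 + 1):(r0 + sz), (c0 + 1):(c0 + sz), ] <- patch$pixels
  section
}

#' Convert between physical area and pixel count
#'
#' `area_px = area_mm2 * 1e6 / um_per_px^2`. The two functions are exact
#' inverses (up to float tolerance); all mm-denominated detection filters
#' convert at run time through these helpers.
#'
#' @param area_mm2,area_px areas in mm^2 / pixels.
#' @param um_per_px micrometres per pixel.
#' @return Numeric scalar (or vector).
#' @export
mm2_to_px <- function(area_mm2, um_per_px) {
  stopifnot(all(area_mm2 >= 0), um_per_px > 0)
  area_mm2 * 1e6 / um_per_px^2
}

#' @rdname mm2_to_px
#' @export
px_to_mm2 <- function(area_px, um_per_px) {
  stopifnot(all(area_px >= 0), um_per_px > 0)
  area_px * um_per_px^2 / 1e6
}

#' Convert millimetres to pixels
#' @param mm length in millimetres.
#' @param um_per_px micrometres per pixel.
#' @return Length in pixels.
#' @export
mm_to_px <- function(mm, um_per_px) mm * 1000 / um_per_px

#' Read and write stack manifests
#'
#' A stack manifest is a YAML file listing the ordered section image paths
#' of one serial stack together with `um_per_px`, `spacing_mm` and optional
#' per-section annotation masks and per-stack pathway ROI masks. Paths are
#' resolved relative to the manifest's directory.
#'
#' @param path manifest path.
#' @return A list with elements `sections` (tibble: path, mask, index),
#'   `um_per_px`, `spacing_mm`, `pathways` (named list of mask paths).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("manifest not found: ", path), class = "ft_io_error")
  }
  m <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  secs <- purrr::map_dfr(seq_along(m$sections), function(i) {
    s <- m$sections[[i]]
    tibble(index = i,
           path = file.path(base, s$path),
           mask = if (!is.null(s$mask)) file.path(base, s$mask) else NA_character_)
  })
  pw <- NULL
  if (!is.null(m$pathways)) {
    pw <- lapply(m$pathways, function(p) file.path(base, p))
  }
  list(sections = secs, um_per_px = m$um_per_px, spacing_mm = m$spacing_mm,
       pathways = pw)
}

#' @rdname read_manifest
#' @param manifest list as returned by [read_manifest()] but with paths
#'   relative to the manifest directory.
#' @export
write_manifest <- function(manifest, path) {
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' Load a full stack through its manifest
#'
#' @param path manifest path.
#' @return List with `sections` (list of `ft_section`), `annotations`
#'   (list of label matrices or NULL), `pathways` (named list of logical
#'   masks or NULL).
#' @export
load_stack <- function(path) {
  m <- read_manifest(path)
  sections <- purrr::pmap(m$sections, function(index, path, mask) {
    load_section(path, um_per_px = m$um_per_px, section_index = index,
                 spacing_mm = m$spacing_mm)
  })
  annotations <- purrr::map(m$sections$mask, function(p) {
    if (is.na(p)) NULL else load_mask(p)
  })
  pathways <- if (!is.null(m$pathways)) {
    lapply(m$pathways, function(p) load_mask(p) > 0)
  }
  list(sections = sections, annotations = annotations, pathways = pathways)
}
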