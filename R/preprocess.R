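#' Multispectral palmprint samples
#'
#' Bundles up to four co-registered grayscale region-of-interest (ROI)
#' images of one palm acquisition, keyed by illumination band: near-infrared
#' (`nir`), `red`, `green`, `blue`. Missing bands are allowed (the quaternion
#' construction zero-fills them) but at least one band must be present, and
#' all present bands must share one size. Pixel values are held on the unit
#' interval; 8-bit inputs are rescaled by 1/255.
#'
#' @param bands named list of numeric matrices; names from
#'   `c("nir", "red", "green", "blue")`
#' @param label subject (palm) identifier
#' @param instance acquisition index within the subject
#' @return an object of class `palm_sample`
#' @export
palm_sample <- function(bands, label, instance = 1L) {
  if (!is.list(bands) || length(bands) == 0L)
    stop("at least one band must be available")
  bad <- setdiff(names(bands), band_names())
  if (length(bad)) stop("unknown band name(s): ", paste(bad, collapse = ", "))
  bands <- lapply(bands, function(m) {
    if (!is.matrix(m)) stop("each band must be a matrix")
    storage.mode(m) <- "double"
    if (max(m, 1) > 1) m <- m / 255
    if (min(m) < 0 || max(m) > 1) stop("pixel values must lie in [0, 1] (or 0..255)")
    m
  })
  dims <- unique(lapply(bands, dim))
  if (length(dims) != 1L) stop("all present bands must share one size")
  structure(list(bands = bands, label = label, instance = instance),
            class = "palm_sample")
}

band_names <- function() c("nir", "red", "green", "blue")

#' @export
print.palm_sample <- function(x, ...) {
  dm <- dim(x$bands[[1L]])
  cat("<palm_sample> subject ", x$label, ", instance ", x$instance,
      ", ", dm[1L], "x", dm[2L], ", bands: ",
      paste(names(x$bands), collapse = "+"), "\n", sep = "")
  invisible(x)
}

#' Histogram equalization
#'
#' Standard 256-bin cumulative-histogram equalization, applied per band to
#' remove global intensity differences between acquisitions. Values are
#' quantized to 256 levels, mapped through the empirical CDF, and returned
#' on the unit interval. A constant image is returned unchanged (the CDF is
#' degenerate and there is no contrast to spread).
#' @param img numeric matrix in `[0, 1]` (or 8-bit 0..255)
#' @return matrix of the same size with values in `[0, 1]`
#' @export
hist_equalize <- function(img) {
  if (length(img) == 0L) stop("empty image")
  if (max(img) > 1) img <- img / 255
  lev <- as.integer(round(img * 255))
  if (min(lev) == max(lev)) return(img)  # degenerate histogram guard
  counts <- tabulate(lev + 1L, nbins = 256L)
  cdf <- cumsum(counts) / length(img)
  out <- matrix(cdf[lev + 1L], nrow(img), ncol(img))
  out
}

#' Block-mean downsampling
#'
#' Decimates an image by an integer factor using the mean over each
#' `factor` x `factor` block (anti-aliased, unlike naive subsampling); a
#' 128 x 128 ROI with factor 2 becomes 64 x 64. Constant images stay
#' constant.
#' @param img numeric matrix whose dimensions are divisible by `factor`
#' @param factor integer decimation factor
#' @return matrix of size `dim(img) / factor`
#' @export
downsample <- function(img, factor = 2L) {
  factor <- as.integer(factor)
  h <- nrow(img); w <- ncol(img)
  if (h %% factor || w %% factor)
    stop("image dimensions must be divisible by the downsampling factor")
  if (factor == 1L) return(img)
  # average factor x factor blocks via two reshapes
  m <- matrix(img, nrow = factor)
  m <- colMeans(m)                      # collapses rows within blocks
  m <- matrix(m, nrow = h %/% factor)   # (h/f) x w
  m <- matrix(t(m), nrow = factor)
  m <- colMeans(m)
  t(matrix(m, nrow = w %/% factor))
}

#' Center crop
#'
#' Utility for inputs larger than the nominal ROI; takes the central
#' `size` x `size` window.
#' @param img numeric matrix at least `size` in both dimensions
#' @param size output side length
#' @export
center_crop <- function(img, size) {
  h <- nrow(img); w <- ncol(img)
  if (h < size || w < size) stop("image smaller than the requested crop")
  r0 <- (h - size) %/% 2L
  c0 <- (w - size) %/% 2L
  img[(r0 + 1L):(r0 + size), (c0 + 1L):(c0 + size), drop = FALSE]
}

#' Build the quaternion image of a multispectral sample
#'
#' Encodes the four bands as one quaternion-valued image
#' \eqn{Q = I + R\,i + G\,j + B\,k} with the channel assignment
#' (a, b, c, d) = (NIR, red, green, blue). Unavailable bands contribute a
#' zero channel, so the representation degrades gracefully when fewer than
#' four illuminations were captured.
#' @param sample a [palm_sample], bands already preprocessed to a common size
#' @return an H x W `qarr`
#' @export
build_quaternion_image <- function(sample) {
  bands <- sample$bands
  if (length(bands) == 0L) stop("no bands available")
  dm <- dim(bands[[1L]])
  z <- matrix(0, dm[1L], dm[2L])
  pick <- function(nm) if (!is.null(bands[[nm]])) bands[[nm]] else z
  qarr(pick("nir"), pick("red"), pick("green"), pick("blue"))
}

#' Row-major vectorization of a quaternion image
#'
#' Flattens an H x W quaternion image to a length H*W quaternion vector
#' recorded by row: pixel (x, y) (0-based, origin top-left) maps to index
#' x*W + y. `reshape_qimage` is the inverse.
#' @param Q a 2-D `qarr`
#' @return a 1-D `qarr` of length `prod(dim(Q))`
#' @export
vectorize_qimage <- function(Q) {
  Q <- as_qarr(Q)
  qarr(as.vector(t(Q$a)), as.vector(t(Q$b)), as.vector(t(Q$c)), as.vector(t(Q$d)))
}

#' @rdname vectorize_qimage
#' @param v a 1-D `qarr` of length `nrow * ncol`
#' @param nrow,ncol target image size
#' @export
reshape_qimage <- function(v, nrow, ncol) {
  v <- as_qarr(v)
  if (length(v) != nrow * ncol) stop("length does not match the target shape")
  rm <- function(x) t(matrix(x, ncol, nrow))  # inverse of row-major flatten
  qarr(rm(v$a), rm(v$b), rm(v$c), rm(v$d))
}

#' Preprocess a sample into a quaternion image
#'
#' Fixed order: (pre-cropped ROI) -> per-band histogram equalization ->
#' block-mean downsampling -> quaternion construction. With the defaults a
#' 128 x 128 ROI becomes the 64 x 64 quaternion image consumed by both the
#' global (QPCA) and local (QDWT) feature extractors.
#' @param sample a [palm_sample]
#' @param equalize apply histogram equalization (default TRUE)
#' @param downsample_factor integer block-mean factor (default 2)
#' @param crop optional side length for a preliminary center crop
#' @return an H x W `qarr`
#' @export
preprocess_sample <- function(sample, equalize = TRUE, downsample_factor = 2L,
                              crop = NULL) {
  bands <- sample$bands
  bands <- lapply(bands, function(m) {
    if (!is.null(crop)) m <- center_crop(m, crop)
    if (equalize) m <- hist_equalize(m)
    if (downsample_factor > 1L) m <- downsample(m, downsample_factor)
    m
  })
  out <- sample
  out$bands <- bands
  build_quaternion_image(out)
}

#' Read a multispectral dataset from disk
#'
#' Accepts either a directory laid out as
#' `<root>/<subject>/<instance>_<band>.png` with band in
#' nir/red/green/blue, or a manifest CSV with columns
#' `subject, instance, band, path`. PNG is read with the png package;
#' `.tif`/`.tiff` files are read with the tiff package when it is installed.
#' @param root dataset directory (ignored when `manifest` is given)
#' @param manifest optional manifest CSV path
#' @return list of [palm_sample] objects, ordered by subject then instance
#' @export
read_dataset <- function(root = NULL, manifest = NULL) {
  if (is.null(root) && is.null(manifest)) stop("give a dataset root or a manifest")
  if (!is.null(manifest)) {
    tab <- utils::read.csv(manifest, stringsAsFactors = FALSE)
    need <- c("subject", "instance", "band", "path")
    if (!all(need %in% names(tab))) stop("manifest must have columns subject, instance, band, path")
    base <- dirname(manifest)
    tab$path <- ifelse(file.exists(tab$path), tab$path, file.path(base, tab$path))
  } else {
    if (!dir.exists(root)) stop("dataset root does not exist: ", root)
    subjects <- list.dirs(root, recursive = FALSE)
    rows <- list()
    for (sd in subjects) {
      files <- list.files(sd, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE)
      for (f in files) {
        stem <- sub("\\.[^.]+$", "", f)
        parts <- strsplit(stem, "_", fixed = TRUE)[[1L]]
        if (length(parts) != 2L || !(parts[2L] %in% band_names())) next
        rows[[length(rows) + 1L]] <- data.frame(
          subject = basename(sd), instance = parts[1L], band = parts[2L],
          path = file.path(sd, f), stringsAsFactors = FALSE)
      }
    }
    if (!length(rows)) stop("no band images found under ", root)
    tab <- do.call(rbind, rows)
  }
  key <- paste(tab$subject, tab$instance, sep = "\r")
  out <- lapply(split(seq_len(nrow(tab)), key), function(idx) {
    sub <- tab[idx, , drop = FALSE]
    bands <- stats::setNames(lapply(sub$path, read_gray_image), sub$band)
    palm_sample(bands, label = sub$subject[1L], instance = sub$instance[1L])
  })
  ord <- order(vapply(out, function(s) paste(s$label, s$instance), ""))
  unname(out[ord])
}

read_gray_image <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF requires the tiff package")
    tiff::readTIFF(path)
  } else stop("unsupported image format: ", ext)
  if (length(dim(img)) == 3L) img <- img[, , 1L]  # gray stored with channels
  img
}
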