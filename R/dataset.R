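#' Binary pattern dataset
#'
#' Container for {0,1} pattern matrices with optional class labels and an
#' optional 2-D grid layout for image-like data. This is the input type for
#' every model in the package: rows are samples, columns are visible units.
#'
#' @param patterns numeric matrix with entries in {0,1}; rows = samples.
#' @param labels optional integer vector of class indices (1-based),
#'   one per row of `patterns`.
#' @param layout optional integer vector `c(rows, cols)` with
#'   `rows * cols == ncol(patterns)`.
#' @param meta optional list of provenance metadata (generator spec, seed,
#'   binarization method, ...), carried along untouched.
#' @return an object of class `binary_dataset`.
#' @export
binary_dataset <- function(patterns, labels = NULL, layout = NULL, meta = list()) {
  patterns <- as.matrix(patterns)
  stop_if_not_binary(patterns)
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != nrow(patterns)) {
      stop("labels must have one entry per sample", call. = FALSE)
    }
  }
  if (!is.null(layout)) {
    layout <- as.integer(layout)
    if (length(layout) != 2 || prod(layout) != ncol(patterns)) {
      stop("layout rows*cols must equal the number of units", call. = FALSE)
    }
  }
  structure(
    list(patterns = patterns, labels = labels, layout = layout, meta = meta),
    class = "binary_dataset"
  )
}

#' @export
print.binary_dataset <- function(x, ...) {
  cat(sprintf(
    "<binary_dataset> %d samples x %d units%s%s\n",
    nrow(x$patterns), ncol(x$patterns),
    if (!is.null(x$labels)) sprintf(", %d classes", length(unique(x$labels))) else "",
    if (!is.null(x$layout)) sprintf(", layout %dx%d", x$layout[1], x$layout[2]) else ""
  ))
  invisible(x)
}

#' Sample a binary prototype mixture
#'
#' Draws each sample by picking a prototype according to `class_weights` and
#' flipping every bit independently with probability `flip_prob`. This is the
#' package's stand-in for datasets of binarized natural-image patches: a small
#' number of latent causes observed through bit-flip noise.
#'
#' @param prototypes {0,1} matrix, one prototype per row.
#' @param n_samples number of samples to draw.
#' @param class_weights probability vector over prototypes (default uniform);
#'   must sum to 1 within 1e-12.
#' @param flip_prob per-bit flip probability in \[0, 0.5\].
#' @param seed integer seed; the draw is bit-reproducible given the seed.
#' @param layout optional grid layout passed to [binary_dataset()].
#' @return a [binary_dataset()] whose labels record the source prototype.
#' @export
generate_mixture <- function(prototypes, n_samples,
                             class_weights = NULL, flip_prob = 0.1,
                             seed = NULL, layout = NULL) {
  prototypes <- as.matrix(prototypes)
  stop_if_not_binary(prototypes, "prototypes")
  k <- nrow(prototypes)
  if (is.null(class_weights)) class_weights <- rep(1 / k, k)
  if (length(class_weights) != k || any(class_weights < 0) ||
      abs(sum(class_weights) - 1) > 1e-12) {
    stop("class_weights must be a length-K probability vector summing to 1",
         call. = FALSE)
  }
  if (flip_prob < 0 || flip_prob > 0.5) {
    stop("flip_prob must lie in [0, 0.5]", call. = FALSE)
  }
  with_seed(seed, {
    labels <- sample.int(k, n_samples, replace = TRUE, prob = class_weights)
    base <- prototypes[labels, , drop = FALSE]
    flips <- matrix(stats::runif(length(base)) < flip_prob,
                    nrow(base), ncol(base))
    patterns <- (base + flips) %% 2
    binary_dataset(patterns, labels = labels, layout = layout,
                   meta = list(generator = "mixture", flip_prob = flip_prob,
                               n_prototypes = k, seed = seed))
  })
}

#' Binarize real-valued images by a population threshold
#'
#' Thresholds intensities at the median (default) or mean of the full input
#' population: an entry becomes 1 iff it strictly exceeds the threshold.
#' Optionally the threshold is computed per image (row) instead.
#'
#' @param images numeric matrix (rows = images) or vector; must be finite.
#' @param method `"median"` or `"mean"`.
#' @param per_image compute one threshold per row instead of one global one.
#' @param layout,labels forwarded to [binary_dataset()].
#' @return a [binary_dataset()]; the threshold strategy is recorded in `meta`.
#' @export
binarize <- function(images, method = c("median", "mean"),
                     per_image = FALSE, layout = NULL, labels = NULL) {
  method <- match.arg(method)
  if (is.vector(images)) images <- matrix(images, nrow = 1)
  images <- as.matrix(images)
  if (length(images) == 0) stop("empty input", call. = FALSE)
  if (!all(is.finite(images))) stop("images must be finite", call. = FALSE)
  thr_fun <- if (method == "median") stats::median else mean
  if (per_image) {
    thr <- apply(images, 1, thr_fun)
    patterns <- (images > thr) * 1
  } else {
    thr <- thr_fun(images)
    patterns <- (images > thr) * 1
  }
  binary_dataset(patterns, labels = labels, layout = layout,
                 meta = list(binarize = method, per_image = per_image,
                             threshold = thr))
}

#' Integer offsets of a discrete disk
#'
#' All integer offsets `(dx, dy)` with `dx^2 + dy^2 <= radius^2`, used to
#' slice circular patches out of images. The radius-2 disk has 13 pixels,
#' which is the visible-layer size used throughout the single-layer
#' experiments.
#'
#' @param radius non-negative integer radius.
#' @return data.frame with columns `dx`, `dy`; `nrow()` is the patch size.
#' @export
circular_mask <- function(radius) {
  if (radius < 0) stop("radius must be >= 0", call. = FALSE)
  r <- floor(radius)
  g <- expand.grid(dx = -r:r, dy = -r:r)
  g <- g[g$dx^2 + g$dy^2 <= radius^2, , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Extract circular patches from a gray-scale image
#'
#' Samples `n_patches` disk-shaped patches of the given radius at uniformly
#' random valid centers. Pixel values are returned raw; pass the result to
#' [binarize()] to obtain a [binary_dataset()].
#'
#' @param image numeric matrix (an image).
#' @param radius disk radius; the patch has `nrow(circular_mask(radius))` pixels.
#' @param n_patches number of patches.
#' @param seed integer seed.
#' @return numeric matrix, one patch per row (disk pixels in mask order).
#' @export
circular_patches <- function(image, radius, n_patches, seed = NULL) {
  image <- as.matrix(image)
  off <- circular_mask(radius)
  r <- max(abs(c(off$dx, off$dy)), 0)
  rows_ok <- (1 + r):(nrow(image) - r)
  cols_ok <- (1 + r):(ncol(image) - r)
  if (length(rows_ok) < 1 || length(cols_ok) < 1) {
    stop("image too small for this radius", call. = FALSE)
  }
  with_seed(seed, {
    ci <- sample(rows_ok, n_patches, replace = TRUE)
    cj <- sample(cols_ok, n_patches, replace = TRUE)
    out <- matrix(0, n_patches, nrow(off))
    for (p in seq_len(n_patches)) {
      out[p, ] <- image[cbind(ci[p] + off$dx, cj[p] + off$dy)]
    }
    out
  })
}

#' Local receptive-field connectivity mask
#'
#' Builds the {0,1} connectivity matrix between a `rows x cols` pixel grid
#' and one post-synaptic unit per grid position (stride 1 gives a 1:1 layer
#' correspondence). Each post unit connects to the pre units inside a
#' `field x field` window centred on its position, clipped at the borders
#' (no zero padding). A 20x20 grid with 5x5 windows and stride 1 yields
#' 8,836 connections instead of the 160,000 of full connectivity.
#'
#' @param rows,cols grid dimensions of the pre-synaptic layer.
#' @param field odd window width.
#' @param stride step between post-unit centres (>= 1).
#' @return {0,1} matrix of shape `(rows*cols, n_post)`, row-major pixel order,
#'   with attribute `post_layout` giving the post grid shape.
#' @export
receptive_field_mask <- function(rows, cols, field = 5, stride = 1) {
  if (field %% 2 != 1) stop("field must be odd", call. = FALSE)
  if (stride < 1) stop("stride must be >= 1", call. = FALSE)
  if (field > rows || field > cols) {
    stop("field larger than the grid", call. = FALSE)
  }
  half <- (field - 1) / 2
  centers_r <- seq(1, rows, by = stride)
  centers_c <- seq(1, cols, by = stride)
  n_pre <- rows * cols
  n_post <- length(centers_r) * length(centers_c)
  mask <- matrix(0, n_pre, n_post)
  # pixel (r, c) -> row-major index (r-1)*cols + c
  post <- 0L
  for (pr in centers_r) {
    for (pc in centers_c) {
      post <- post + 1L
      rr <- max(1, pr - half):min(rows, pr + half)
      cc <- max(1, pc - half):min(cols, pc + half)
      idx <- as.vector(outer((rr - 1) * cols, cc, `+`))
      mask[idx, post] <- 1
    }
  }
  attr(mask, "post_layout") <- c(length(centers_r), length(centers_c))
  mask
}

#' Default prototypes on the radius-2 disk
#'
#' Four deterministic geometric prototypes (left half, right half, centre
#' cross, outer ring) over the 13 pixels of the radius-2 discrete disk.
#' These define the latent causes of the default single-layer study fixture.
#'
#' @return a 4 x 13 {0,1} matrix.
#' @export
default_patch_prototypes <- function() {
  off <- circular_mask(2)
  p <- rbind(
    left   = as.numeric(off$dx < 0),
    right  = as.numeric(off$dx > 0),
    center = as.numeric(abs(off$dx) + abs(off$dy) <= 1),
    ring   = as.numeric(off$dx^2 + off$dy^2 >= 2)
  )
  rownames(p) <- NULL
  p
}

## Seven-segment style glyph for digit d (0..9) on an n x n grid.
segment_glyph <- function(d, n = 10) {
  segs <- list(
    `0` = c("t", "b", "lu", "ll", "ru", "rl"),
    `1` = c("ru", "rl"),
    `2` = c("t", "ru", "m", "ll", "b"),
    `3` = c("t", "ru", "m", "rl", "b"),
    `4` = c("lu", "m", "ru", "rl"),
    `5` = c("t", "lu", "m", "rl", "b"),
    `6` = c("t", "lu", "m", "ll", "rl", "b"),
    `7` = c("t", "ru", "rl"),
    `8` = c("t", "b", "m", "lu", "ll", "ru", "rl"),
    `9` = c("t", "lu", "ru", "m", "rl", "b")
  )[[as.character(d)]]
  g <- matrix(0, n, n)
  mid <- ceiling(n / 2)
  for (s in segs) {
    switch(s,
      t  = g[1, ] <- 1,
      m  = g[mid, ] <- 1,
      b  = g[n, ] <- 1,
      lu = g[1:mid, 1] <- 1,
      ll = g[mid:n, 1] <- 1,
      ru = g[1:mid, n] <- 1,
      rl = g[mid:n, n] <- 1
    )
  }
  g
}

#' Labeled toy digit dataset with uninformative borders
#'
#' Ten seven-segment-style digit glyphs drawn on the 10x10 interior of a
#' 12x12 grid whose 1-pixel border is always zero, mimicking the
#' uninformative margins of handwritten-digit images. Samples are drawn as a
#' prototype mixture with bit-flip noise applied to interior pixels only, so
#' border pixels are structurally silent and should be disconnected by an
#' importance-guided pruner.
#'
#' @param n_samples number of samples.
#' @param n_classes number of digit classes to use (2..10; default 10).
#' @param flip_prob interior bit-flip probability.
#' @param seed integer seed.
#' @return a labeled [binary_dataset()] with `layout = c(12, 12)`; label `k`
#'   corresponds to digit `k - 1`.
#' @export
toy_digits <- function(n_samples, n_classes = 10, flip_prob = 0.05, seed = NULL) {
  stopifnot(n_classes >= 2, n_classes <= 10)
  side <- 12L
  protos <- matrix(0, n_classes, side * side)
  interior <- as.vector(outer((1:10) * side, 2:11, `+`))  # rows 2..11, cols 2..11
  for (d in seq_len(n_classes)) {
    g <- segment_glyph(d - 1, 10)
    full <- matrix(0, side, side)
    full[2:11, 2:11] <- g
    protos[d, ] <- as.vector(t(full))  # row-major
  }
  with_seed(seed, {
    labels <- sample.int(n_classes, n_samples, replace = TRUE)
    patterns <- protos[labels, , drop = FALSE]
    flips <- matrix(stats::runif(n_samples * length(interior)) < flip_prob,
                    n_samples, length(interior))
    patterns[, interior] <- (patterns[, interior] + flips) %% 2
    binary_dataset(patterns, labels = labels, layout = c(side, side),
                   meta = list(generator = "toy_digits", flip_prob = flip_prob,
                               n_classes = n_classes, seed = seed))
  })
}

#' Read an IDX-format array file
#'
#' Parses the simple big-endian IDX container used to distribute image and
#' label arrays. Supports unsigned byte and 32-bit integer payloads.
#'
#' @param path file path.
#' @return an array with the dimensions declared in the header (images come
#'   back as `n x rows x cols`).
#' @export
read_idx <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "integer", n = 4, size = 1, signed = FALSE)
  if (magic[1] != 0 || magic[2] != 0) stop("not an IDX file", call. = FALSE)
  ndim <- magic[4]
  dims <- readBin(con, "integer", n = ndim, size = 4, endian = "big")
  n <- prod(dims)
  data <- switch(as.character(magic[3]),
    "8" = readBin(con, "integer", n = n, size = 1, signed = FALSE),
    "12" = readBin(con, "integer", n = n, size = 4, endian = "big"),
    stop("unsupported IDX data type", call. = FALSE)
  )
  if (ndim == 1) return(data)
  aperm(array(data, dim = rev(dims)), ndim:1)
}

#' Read a directory of PNG images as gray-scale rows
#'
#' @param dir directory containing `.png` files.
#' @return numeric matrix, one flattened (row-major) gray-scale image per row.
#' @export
read_png_dir <- function(dir) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required to read PNG files", call. = FALSE)
  }
  files <- sort(list.files(dir, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) stop("no PNG files found", call. = FALSE)
  rows <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 3) img <- apply(img[, , 1:min(3, dim(img)[3]), drop = FALSE], c(1, 2), mean)
    as.vector(t(img))
  })
  do.call(rbind, rows)
}

#' Write a binary dataset to a JSON archive
#'
#' Stores patterns (as compact 0/1 strings), labels, layout and generation
#' metadata so a dataset's provenance travels with it. [read_binary_dataset()]
#' restores it exactly.
#'
#' @param x a [binary_dataset()].
#' @param path output file path.
#' @export
write_binary_dataset <- function(x, path) {
  stopifnot(inherits(x, "binary_dataset"))
  obj <- list(
    format = "prunebm-dataset-v1",
    n_units = ncol(x$patterns),
    patterns = apply(x$patterns, 1, paste0, collapse = ""),
    labels = x$labels,
    layout = x$layout,
    meta = x$meta
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_binary_dataset
#' @export
read_binary_dataset <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  patterns <- do.call(rbind, lapply(strsplit(obj$patterns, ""), as.numeric))
  binary_dataset(patterns,
                 labels = obj$labels,
                 layout = obj$layout,
                 meta = as.list(obj$meta))
}
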