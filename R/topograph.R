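# Spectral topographs: multitaper band power per channel, scalp
# interpolation onto a 64 x 64 grid, 0-255 encoding, hemisphere split.

the_cache <- new.env(parent = emptyenv())

#' Discrete prolate spheroidal sequence (DPSS) tapers
#'
#' Computed from the standard symmetric tridiagonal eigenproblem whose
#' eigenvectors are the Slepian sequences; results are cached per
#' `(n, nw, k)`.
#'
#' @param n Sequence length.
#' @param nw Time half-bandwidth product (default 2.5).
#' @param k Number of tapers (default `floor(2 * nw) - 1`).
#' @return `n x k` matrix of unit-energy tapers, best-concentrated first.
#' @export
dpss_tapers <- function(n, nw = 2.5, k = floor(2 * nw) - 1) {
  stopifnot(n >= 2, nw > 0, k >= 1, k < n)
  key <- sprintf("dpss_%d_%g_%d", n, nw, k)
  if (!is.null(the_cache[[key]])) return(the_cache[[key]])
  w <- nw / n
  i <- seq_len(n) - 1
  diag_main <- ((n - 1 - 2 * i) / 2)^2 * cos(2 * pi * w)
  off <- (i[-1] * (n - i[-1])) / 2
  A <- matrix(0, n, n)
  diag(A) <- diag_main
  A[cbind(2:n, 1:(n - 1))] <- off
  A[cbind(1:(n - 1), 2:n)] <- off
  e <- eigen(A, symmetric = TRUE)
  tap <- e$vectors[, seq_len(k), drop = FALSE]
  # sign convention: symmetric tapers positive mean, antisymmetric tapers
  # positive initial slope
  for (j in seq_len(k)) {
    s <- sum(tap[, j])
    if (abs(s) > 1e-8) {
      if (s < 0) tap[, j] <- -tap[, j]
    } else if (tap[2, j] - tap[1, j] < 0) {
      tap[, j] <- -tap[, j]
    }
  }
  tap <- sweep(tap, 2, sqrt(colSums(tap^2)), "/")
  the_cache[[key]] <- tap
  tap
}

#' Multitaper band power of a segment
#'
#' Power spectral density is estimated per channel by averaging DPSS-tapered
#' periodograms, then summarized as the mean PSD over each frequency band.
#'
#' @param seg An `eeg_segment` (or anything with `data` and `fs`).
#' @param band_edges List of `c(lo, hi)` pairs in Hz; defaults to alpha
#'   (8-13), beta (13-30), gamma (30-50).
#' @param nw Time half-bandwidth product for the tapers.
#' @return Channels x bands matrix of nonnegative band powers.
#' @export
band_power <- function(seg, band_edges = list(c(8, 13), c(13, 30), c(30, 50)),
                       nw = 2.5) {
  x <- seg$data
  fs <- seg$fs
  n <- ncol(x)
  if (n < 4) stop("segment too short")
  hi <- vapply(band_edges, function(b) b[2], 0)
  if (any(hi > fs / 2 + 1e-9))
    stop("band edge above Nyquist frequency (", fs / 2, " Hz)")
  tap <- dpss_tapers(n, nw)
  k <- ncol(tap)
  freqs <- (seq_len(n) - 1) * fs / n
  half <- which(freqs <= fs / 2)
  psd <- matrix(0, nrow(x), length(half))
  for (j in seq_len(k)) {
    tx <- x * matrix(tap[, j], nrow(x), n, byrow = TRUE)
    sp <- Mod(t(stats::mvfft(t(tx))))^2 / fs
    psd <- psd + sp[, half, drop = FALSE]
  }
  psd <- psd / k
  out <- matrix(0, nrow(x), length(band_edges))
  f <- freqs[half]
  for (b in seq_along(band_edges)) {
    sel <- f >= band_edges[[b]][1] & f < band_edges[[b]][2]
    if (!any(sel)) stop("band ", b, " contains no frequency bins")
    out[, b] <- rowMeans(psd[, sel, drop = FALSE])
  }
  rownames(out) <- if (!is.null(seg$channel_names)) seg$channel_names else NULL
  out
}

#' Interpolate per-channel values over the scalp disc
#'
#' Thin-plate spline interpolation (exact at the electrodes, reproduces
#' affine fields) with an inverse-distance fallback for fewer than three
#' electrodes. Pixels outside the unit head disc are set to 0.
#'
#' @param values Named numeric vector, channel -> scalar.
#' @param montage A [montage()] with positions for every named channel.
#' @param size Grid size (default 64).
#' @return `size x size` matrix; row 1 is anterior, column 1 the left edge.
#' @export
interpolate_scalp <- function(values, montage, size = 64) {
  pos <- montage_positions(montage, names(values))
  px <- pos$x; py <- pos$y
  v <- as.numeric(values)
  m <- length(v)
  g <- (seq_len(size) - 0.5) / size * 2 - 1
  gx <- matrix(g, size, size, byrow = TRUE)       # columns left -> right
  gy <- matrix(rev(g), size, size)                # rows anterior -> posterior
  inside <- gx^2 + gy^2 <= 1
  field <- matrix(0, size, size)

  tps_ok <- m >= 3
  if (tps_ok) {
    # check non-collinearity for the polynomial part
    X <- cbind(1, px, py)
    tps_ok <- qr(X)$rank == 3
  }
  if (tps_ok) {
    rk <- function(d2) ifelse(d2 <= 0, 0, 0.5 * d2 * log(d2))  # r^2 log r
    D2 <- outer(px, px, "-")^2 + outer(py, py, "-")^2
    K <- rk(D2)
    A <- rbind(cbind(K + diag(1e-10, m), cbind(1, px, py)),
               cbind(t(cbind(1, px, py)), matrix(0, 3, 3)))
    sol <- solve(A, c(v, 0, 0, 0))
    w <- sol[seq_len(m)]; a <- sol[m + 1:3]
    qx <- gx[inside]; qy <- gy[inside]
    G2 <- outer(qx, px, "-")^2 + outer(qy, py, "-")^2
    field[inside] <- rk(G2) %*% w + a[1] + a[2] * qx + a[3] * qy
  } else {
    qx <- gx[inside]; qy <- gy[inside]
    D2 <- outer(qx, px, "-")^2 + outer(qy, py, "-")^2
    W <- 1 / pmax(D2, 1e-12)
    field[inside] <- (W %*% v) / rowSums(W)
  }
  field
}

#' Encode per-band fields as a 0-255 topograph image
#'
#' Each band is min-max scaled independently (min -> 0, max -> 255, rounded
#' to the nearest integer with ties away from zero); a constant band maps to
#' all zeros.
#'
#' @param fields 3 x size x size numeric array, or list of 3 matrices, in
#'   band order alpha, beta, gamma.
#' @param meta Optional named list of metadata carried on the result
#'   (`subject_id`, `trial_id`, `label`, `start_time`).
#' @param band_edges Band definitions stored alongside the image.
#' @return A `band_topograph`: integer array `3 x size x size` in `[0, 255]`.
#' @export
encode_image <- function(fields, meta = list(),
                         band_edges = list(c(8, 13), c(13, 30), c(30, 50))) {
  if (is.list(fields)) {
    size <- nrow(fields[[1]])
    arr <- array(0, c(length(fields), size, size))
    for (b in seq_along(fields)) arr[b, , ] <- fields[[b]]
    fields <- arr
  }
  if (!all(is.finite(fields))) stop("non-finite field values")
  img <- array(0L, dim(fields))
  for (b in seq_len(dim(fields)[1])) {
    f <- fields[b, , ]
    lo <- min(f); hi <- max(f)
    if (hi > lo) {
      scaled <- (f - lo) / (hi - lo) * 255
      img[b, , ] <- as.integer(floor(scaled + 0.5))  # ties away from zero
    }
  }
  structure(
    list(image = img,
         subject_id = meta$subject_id %||% NA_character_,
         trial_id = meta$trial_id %||% NA_character_,
         label = meta$label %||% NA_character_,
         start_time = meta$start_time %||% NA_real_,
         band_edges = band_edges),
    class = "band_topograph")
}

#' @export
print.band_topograph <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("<band_topograph> %d x %d x %d, subject=%s label=%s\n",
              d[1], d[2], d[3], x$subject_id, x$label))
  invisible(x)
}

#' Split a topograph into hemispheres
#'
#' Left = columns 1..width/2, right = the remainder; concatenating the halves
#' restores the original image exactly.
#'
#' @param t A `band_topograph`.
#' @return List with integer arrays `left` and `right` (class `hemi_pair`).
#' @export
split_hemispheres <- function(t) {
  img <- if (inherits(t, "band_topograph")) t$image else t
  wd <- dim(img)[3]
  if (wd %% 2 != 0) stop("image width must be even")
  half <- wd %/% 2
  structure(list(left = img[, , seq_len(half), drop = FALSE],
                 right = img[, , (half + 1):wd, drop = FALSE]),
            class = "hemi_pair")
}

#' Convert an EEG segment to a band topograph
#'
#' Runs the full feature path: multitaper band power, scalp interpolation per
#' band, 0-255 encoding.
#'
#' @param seg An `eeg_segment` with `channel_names`.
#' @param montage A [montage()] covering the segment's channels.
#' @param band_edges Frequency bands (alpha, beta, gamma by default).
#' @param size Image size (default 64).
#' @param channel_names Channel names (defaults to `seg$channel_names`).
#' @return A `band_topograph`.
#' @export
segment_topograph <- function(seg, montage,
                              band_edges = list(c(8, 13), c(13, 30), c(30, 50)),
                              size = 64, channel_names = NULL) {
  ch <- channel_names %||% seg$channel_names
  if (is.null(ch)) stop("segment has no channel names")
  bp <- band_power(seg, band_edges)
  fields <- lapply(seq_along(band_edges), function(b) {
    v <- bp[, b]
    names(v) <- ch
    interpolate_scalp(v, montage, size)
  })
  encode_image(fields,
               meta = list(subject_id = seg$subject_id, trial_id = seg$trial_id,
                           label = seg$label, start_time = seg$start_time),
               band_edges = band_edges)
}

# ---------------------------------------------------------------------------
# Topograph dataset container: N x 3 x H x W integer array + metadata table.

#' Bundle topographs into a dataset
#'
#' @param topographs List of `band_topograph` objects.
#' @return A `topograph_dataset`: `images` (N x 3 x H x W integer array) and
#'   `meta` (data frame with subject_id, trial_id, label, start_time).
#' @export
topograph_dataset <- function(topographs) {
  stopifnot(length(topographs) > 0)
  d <- dim(topographs[[1]]$image)
  images <- array(0L, c(length(topographs), d))
  meta <- data.frame(
    subject_id = vapply(topographs, function(t) t$subject_id, ""),
    trial_id = vapply(topographs, function(t) t$trial_id, ""),
    label = vapply(topographs, function(t) t$label, ""),
    start_time = vapply(topographs, function(t) as.numeric(t$start_time), 0),
    stringsAsFactors = FALSE)
  for (i in seq_along(topographs)) images[i, , , ] <- topographs[[i]]$image
  structure(list(images = images, meta = meta,
                 band_edges = topographs[[1]]$band_edges),
            class = "topograph_dataset")
}

#' @export
print.topograph_dataset <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf("<topograph_dataset> %d images %dx%dx%d, %d subjects, %d classes\n",
              d[1], d[2], d[3], d[4],
              length(unique(x$meta$subject_id)), length(unique(x$meta$label))))
  invisible(x)
}

#' Save / load a topograph dataset
#'
#' Images are stored as a flat uint8 binary file with a JSON shape descriptor
#' and a CSV metadata table.
#'
#' @param ds A `topograph_dataset`.
#' @param dir Output directory (created if missing).
#' @return `dir` (save) or the dataset (load).
#' @export
save_topographs <- function(ds, dir) {
  stopifnot(inherits(ds, "topograph_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  con <- file(file.path(dir, "images.u8"), "wb")
  writeBin(as.raw(as.integer(ds$images)), con)
  close(con)
  jsonlite::write_json(
    list(dim = dim(ds$images), band_edges = ds$band_edges),
    file.path(dir, "shape.json"), auto_unbox = FALSE, digits = NA)
  utils::write.csv(ds$meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  invisible(dir)
}

#' @rdname save_topographs
#' @export
load_topographs <- function(dir) {
  shape <- jsonlite::read_json(file.path(dir, "shape.json"),
                               simplifyVector = TRUE)
  d <- as.integer(shape$dim)
  con <- file(file.path(dir, "images.u8"), "rb")
  raw <- readBin(con, "raw", n = prod(d))
  close(con)
  images <- array(as.integer(raw), d)
  meta <- utils::read.csv(file.path(dir, "metadata.csv"),
                          stringsAsFactors = FALSE,
                          colClasses = c(subject_id = "character",
                                         trial_id = "character",
                                         label = "character"))
  be <- shape$band_edges
  if (is.matrix(be)) be <- lapply(seq_len(nrow(be)), function(i) be[i, ])
  structure(list(images = images, meta = meta, band_edges = be),
            class = "topograph_dataset")
}

#' Export a topograph as PNG
#'
#' The three bands are written as RGB channels for visual inspection.
#' Requires the `png` package.
#'
#' @param t A `band_topograph`.
#' @param path Output `.png` path.
#' @return `path`, invisibly.
#' @export
topograph_png <- function(t, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the png package is required for PNG export")
  img <- aperm(t$image, c(2, 3, 1)) / 255
  png::writePNG(img, path)
  invisible(path)
}
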