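# Electrode geometry.  Scalp positions are kept on a unit head disc obtained
# by azimuthal-equidistant projection of idealized 10-10 spherical angles:
# radius is proportional to the inclination from the vertex (Cz), azimuth 0
# points to the nose, and negative x is the left hemisphere.

# inclination theta (degrees from Cz) and azimuth phi (degrees clockwise from
# anterior midline; negative = left) for the standard positions used here
STANDARD_1020 <- local({
  tab <- rbind(
    c("Cz",    0,    0), c("Fz",   45,    0), c("Pz",  45,  180),
    c("Fpz",  90,    0), c("Oz",  90,  180),
    c("Fp1",  90,  -18), c("Fp2", 90,   18),
    c("AF3",  77,  -21), c("AF4", 77,   21),
    c("F7",   90,  -54), c("F8",  90,   54),
    c("F3",   62,  -40), c("F4",  62,   40),
    c("FC5",  72,  -69), c("FC6", 72,   69),
    c("FC1",  34,  -45), c("FC2", 34,   45),
    c("T7",   90,  -90), c("T8",  90,   90),
    c("C3",   45,  -90), c("C4",  45,   90),
    c("CP5",  72, -111), c("CP6", 72,  111),
    c("CP1",  34, -135), c("CP2", 34,  135),
    c("P7",   90, -126), c("P8",  90,  126),
    c("P3",   62, -140), c("P4",  62,  140),
    c("PO3",  77, -159), c("PO4", 77,  159),
    c("O1",   90, -162), c("O2",  90,  162))
  data.frame(channel = tab[, 1], theta = as.numeric(tab[, 2]),
             phi = as.numeric(tab[, 3]), stringsAsFactors = FALSE)
})

#' Electrode montage
#'
#' @param positions Data frame with columns `channel`, `x`, `y`; coordinates
#'   must lie inside the unit head disc (left = negative x, anterior =
#'   positive y).
#' @return An object of class `montage`.
#' @export
montage <- function(positions) {
  stopifnot(is.data.frame(positions),
            all(c("channel", "x", "y") %in% names(positions)))
  if (anyDuplicated(positions$channel)) stop("duplicated channel in montage")
  r <- sqrt(positions$x^2 + positions$y^2)
  if (any(r > 1 + 1e-9)) stop("montage positions must lie in the unit disc")
  if (nrow(positions) >= 3) {
    # at least 3 non-collinear positions
    xy <- cbind(positions$x, positions$y)
    ok <- FALSE
    for (i in 3:nrow(xy)) {
      a <- xy[2, ] - xy[1, ]; b <- xy[i, ] - xy[1, ]
      if (abs(a[1] * b[2] - a[2] * b[1]) > 1e-9) { ok <- TRUE; break }
    }
    if (!ok) stop("montage positions are collinear")
  }
  structure(list(positions = positions), class = "montage")
}

#' Standard 10-10 montage positions
#'
#' Azimuthal-equidistant projection of idealized spherical 10-10 angles onto
#' the unit head disc. Electrodes on the outer 10-20 ring (inclination 90
#' degrees) land at radius 0.9.
#'
#' @param channels Channel names to include; defaults to all 33 built-in
#'   positions. Alternatively give `n` to take the first `n` built-ins.
#' @param n Optional count (used when `channels` is `NULL`).
#' @return A [montage()].
#' @export
standard_montage <- function(channels = NULL, n = NULL) {
  tab <- STANDARD_1020
  if (is.null(channels)) {
    if (!is.null(n)) {
      if (n > nrow(tab)) stop("only ", nrow(tab), " built-in positions available")
      tab <- tab[seq_len(n), ]
    }
  } else {
    miss <- setdiff(channels, tab$channel)
    if (length(miss)) stop("no built-in position for: ", paste(miss, collapse = ", "))
    tab <- tab[match(channels, tab$channel), ]
  }
  r <- tab$theta / 100          # 90 degree ring -> radius 0.9
  phi <- tab$phi * pi / 180
  montage(data.frame(channel = tab$channel,
                     x = r * sin(phi), y = r * cos(phi),
                     stringsAsFactors = FALSE))
}

montage_positions <- function(m, channels) {
  stopifnot(inherits(m, "montage"))
  idx <- match(channels, m$positions$channel)
  if (anyNA(idx))
    stop("channel without montage position: ",
         paste(channels[is.na(idx)], collapse = ", "))
  m$positions[idx, , drop = FALSE]
}
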