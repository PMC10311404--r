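# Sliding SNP windows and their grayscale image encoding.
#
# A window covers W consecutive segregating sites; the window image is the
# N x W block of the state matrix with states mapped to gray levels
# 0 (ancestral), 127 (derived), 254 (other). Windows are placed on SNPs, not
# on physical coordinates, so SNP-dense regions get proportionally more
# windows.

#' Enumerate sliding SNP windows
#'
#' Windows of `width` SNPs advance by `step` SNPs: starting columns are
#' 1, 1+S, 1+2S, ... for a total of `floor((T - W)/S) + 1` windows, with
#' consecutive windows overlapping by `W - S` columns when `S < W`.
#'
#' @param m a [snp_matrix()].
#' @param width window width W in SNPs (default 50).
#' @param step window step S in SNPs (default 1).
#' @return a data frame of class `snp_windows` with columns `window_index`,
#'   `start_col`, `end_col`, `first_snp_bp`, `last_snp_bp`, `center_bp`
#'   (midpoint of the window's genomic span). Zero rows, with a warning, if
#'   the matrix has fewer than `width` SNPs.
#' @export
make_windows <- function(m, width = 50, step = 1) {
  stopifnot(inherits(m, "snp_matrix"), width >= 1, step >= 1)
  T <- ncol(m$states)
  if (T < width) {
    warning(sprintf("insufficient SNPs: %d sites for window width %d",
                    T, width))
    starts <- integer(0)
  } else {
    starts <- seq.int(1L, T - width + 1L, by = step)
  }
  ends <- starts + width - 1L
  out <- data.frame(window_index = seq_along(starts),
                    start_col = starts, end_col = ends,
                    first_snp_bp = m$positions_bp[starts],
                    last_snp_bp = m$positions_bp[ends])
  out$center_bp <- (out$first_snp_bp + out$last_snp_bp) / 2
  class(out) <- c("snp_windows", "data.frame")
  attr(out, "width") <- as.integer(width)
  attr(out, "step") <- as.integer(step)
  attr(out, "region_len") <- m$region_len
  out
}

GRAY_FACTOR <- 127L

#' Render SNP windows as grayscale images
#'
#' Each state is multiplied by 127: ancestral (0) becomes a black pixel (0),
#' derived (1) gray (127), and any other state (2) near-white (254). Rows are
#' samples, columns are SNPs in genomic order; no row sorting is applied.
#'
#' @param m a [snp_matrix()].
#' @param windows a `snp_windows` frame from [make_windows()]; defaults to
#'   all windows at the stored width/step.
#' @param width,step used when `windows` is not supplied.
#' @return a `window_images` object: an `N x W x L` integer array of gray
#'   levels with the window table in attribute `windows`.
#' @export
encode_windows <- function(m, windows = NULL, width = 50, step = 1) {
  stopifnot(inherits(m, "snp_matrix"))
  if (is.null(windows)) windows <- make_windows(m, width, step)
  W <- attr(windows, "width")
  if (is.null(W) && nrow(windows))
    W <- windows$end_col[1] - windows$start_col[1] + 1L
  n <- nrow(m$states)
  L <- nrow(windows)
  px <- array(0L, dim = c(n, W, L))
  for (j in seq_len(L)) {
    px[, , j] <- m$states[, windows$start_col[j]:windows$end_col[j],
                          drop = FALSE] * GRAY_FACTOR
  }
  structure(px, windows = windows, class = "window_images")
}

#' @export
print.window_images <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("window images: %d windows of %d samples x %d SNPs\n",
              d[3], d[1], d[2]))
  invisible(x)
}

# stack several window_images objects along the window axis
bind_images <- function(lst) {
  lst <- lst[vapply(lst, function(x) dim(x)[3] > 0, logical(1))]
  if (!length(lst)) stop("no windows to bind")
  d <- dim(lst[[1]])[1:2]
  arr <- array(unlist(lst, use.names = FALSE),
               dim = c(d[1], d[2], sum(vapply(lst, function(x) dim(x)[3],
                                              numeric(1)))))
  structure(arr, class = "window_images")
}

#' Dump window images as PNG files for inspection
#'
#' @param images a `window_images` array.
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix.
#' @return the file paths, invisibly.
#' @export
write_window_png <- function(images, dir, prefix = "window") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  L <- dim(images)[3]
  paths <- character(L)
  for (j in seq_len(L)) {
    paths[j] <- file.path(dir, sprintf("%s_%04d.png", prefix, j))
    grDevices::png(paths[j], width = dim(images)[2], height = dim(images)[1])
    graphics::par(mar = c(0, 0, 0, 0))
    graphics::image(t(images[nrow(images):1, , j]) / 254, col = gray.colors(
      3, start = 0, end = 1), axes = FALSE, useRaster = TRUE)
    grDevices::dev.off()
  }
  invisible(paths)
}
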