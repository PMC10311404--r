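# Selection profiles: averaging the per-window "selection" posteriors into a
# 1D probability track along the genome, then calling the sweep location and
# extent from the track.

#' Build a selection profile from window posteriors
#'
#' Averages the "selection"-class probabilities of nearby windows into one
#' probability per genomic position. Three averaging configurations are
#' supported:
#' \describe{
#'   \item{`"snp"`}{moving average of `k` consecutive windows on the
#'     probability array; the entry is placed at the midpoint of the genomic
#'     span covered by the `k` windows. SNP-dense regions get proportionally
#'     more entries.}
#'   \item{`"pos"`}{per window, the average over all windows whose center
#'     lies within `span/2` bp of its center.}
#'   \item{`"grid"`}{`grid` evenly spaced positions across the region; each
#'     averages the windows whose center falls within `span/2` bp. Grid
#'     points covering no window get `NA` (a no-data marker, not 0).}
#' }
#'
#' @param R a `prob_matrix` from [predict.sweep_cnn()] / [classify_windows()]
#'   (classes x windows), or a numeric vector of per-window selection
#'   probabilities.
#' @param windows the window table (taken from `R`'s attribute when present).
#' @param mode averaging configuration, see above.
#' @param k number of windows averaged in `"snp"` mode.
#' @param span averaging span in bp for `"pos"` and `"grid"` modes.
#' @param grid number of grid positions in `"grid"` mode.
#' @param class name of the selection class row of `R`.
#' @return a data frame of class `selection_profile` with columns
#'   `position_bp`, `prob`, `n_windows`.
#' @export
make_profile <- function(R, windows = NULL, mode = c("snp", "pos", "grid"),
                         k = 10, span = 5000, grid = NULL,
                         class = "selection") {
  mode <- match.arg(mode)
  if (is.null(windows)) windows <- attr(R, "windows")
  if (is.matrix(R)) {
    if (!class %in% rownames(R))
      stop(sprintf("class '%s' not found in probability matrix", class))
    p <- R[class, ]
  } else {
    p <- as.numeric(R)
  }
  if (is.null(windows) || nrow(windows) != length(p))
    stop("window table must align with the probability columns")
  L <- length(p)
  if (!L) stop("empty probability array")

  if (mode == "snp") {
    if (k < 1 || k > L)
      stop(sprintf("k = %d outside 1..%d available windows", k, L))
    if (k == 1) {
      probs <- p
    } else {
      cs <- c(0, cumsum(p))
      probs <- (cs[(k + 1):(L + 1)] - cs[1:(L - k + 1)]) / k
    }
    pos <- (windows$first_snp_bp[1:(L - k + 1)] +
            windows$last_snp_bp[k:L]) / 2
    out <- data.frame(position_bp = pos, prob = probs, n_windows = k)
    params <- list(k = k)
  } else if (mode == "pos") {
    ctr <- windows$center_bp
    probs <- vapply(ctr, function(cc) {
      mean(p[abs(ctr - cc) <= span / 2])
    }, numeric(1))
    nw <- vapply(ctr, function(cc) sum(abs(ctr - cc) <= span / 2), numeric(1))
    out <- data.frame(position_bp = ctr, prob = probs, n_windows = nw)
    params <- list(span = span)
  } else {
    region_len <- attr(windows, "region_len")
    if (is.null(region_len)) region_len <- max(windows$last_snp_bp)
    if (is.null(grid) || grid < 1) stop("grid mode needs a positive grid size")
    gp <- seq(1, region_len, length.out = grid)
    ctr <- windows$center_bp
    probs <- vapply(gp, function(cc) {
      sel <- abs(ctr - cc) <= span / 2
      if (!any(sel)) NA_real_ else mean(p[sel])
    }, numeric(1))
    nw <- vapply(gp, function(cc) sum(abs(ctr - cc) <= span / 2), numeric(1))
    out <- data.frame(position_bp = gp, prob = probs, n_windows = nw)
    params <- list(grid = grid, span = span)
  }
  class(out) <- c("selection_profile", "data.frame")
  attr(out, "mode") <- mode
  attr(out, "params") <- params
  out
}

#' @export
print.selection_profile <- function(x, ...) {
  cat(sprintf(
    "selection profile: %d positions (%s mode), prob %.3f - %.3f\n",
    nrow(x), attr(x, "mode"), suppressWarnings(min(x$prob, na.rm = TRUE)),
    suppressWarnings(max(x$prob, na.rm = TRUE))))
  invisible(x)
}

#' @export
plot.selection_profile <- function(x, ...) {
  graphics::plot(x$position_bp / 1e3, x$prob, type = "l",
                 xlab = "position (kb)", ylab = "P(selection)",
                 ylim = c(0, 1), ...)
  invisible(x)
}

#' Localize a sweep from a selection profile
#'
#' The reported location is the position of the profile maximum (ties:
#' leftmost, flagged); the extent is the maximal contiguous run of profile
#' positions around the peak whose probability stays at or above
#' `extent_threshold`.
#'
#' @param profile a `selection_profile`.
#' @param extent_threshold probability cut-off defining the extent
#'   (default 0.5).
#' @return an object of class `sweep_call`: `location_bp`, `extent`
#'   (start/end bp), `peak_prob`, `tie` flag.
#' @export
call_sweep <- function(profile, extent_threshold = 0.5) {
  ok <- !is.na(profile$prob)
  if (!any(ok)) stop("profile has no data")
  p <- profile$prob
  peak <- max(p[ok])
  # tolerance absorbs the rounding noise of running-sum averaging
  at_peak <- ok & abs(p - peak) < 1e-9
  i <- which(at_peak)[1]
  tie <- sum(at_peak) > 1
  lo <- i
  while (lo > 1 && ok[lo - 1] && p[lo - 1] >= extent_threshold) lo <- lo - 1
  hi <- i
  n <- length(p)
  while (hi < n && ok[hi + 1] && p[hi + 1] >= extent_threshold) hi <- hi + 1
  if (p[i] < extent_threshold) { lo <- i; hi <- i }
  structure(list(location_bp = profile$position_bp[i],
                 extent = c(start_bp = profile$position_bp[lo],
                            end_bp = profile$position_bp[hi]),
                 peak_prob = peak, tie = tie,
                 threshold = extent_threshold),
            class = "sweep_call")
}

#' @export
print.sweep_call <- function(x, ...) {
  cat(sprintf(
    "sweep call: %.0f bp (peak P = %.3f%s), extent %.0f - %.0f bp\n",
    x$location_bp, x$peak_prob, if (x$tie) ", tied peak" else "",
    x$extent["start_bp"], x$extent["end_bp"]))
  invisible(x)
}

#' Scan one SNP matrix with a trained model
#'
#' Encodes the windows, classifies them and builds the selection profile in
#' one call.
#'
#' @param object a fitted `sweep_cnn`.
#' @param m a [snp_matrix()].
#' @param step window step in SNPs.
#' @param ... passed to [make_profile()] (e.g. `mode`, `k`, `span`, `grid`).
#' @return a `selection_profile`, or NULL when the matrix has fewer SNPs
#'   than the window width.
#' @export
scan_replicate <- function(object, m, step = 1, ...) {
  R <- classify_windows(object, m, step = step)
  if (is.null(R)) return(NULL)
  make_profile(R, ...)
}

#' Write a profile as TSV (and optionally the extent as BED)
#'
#' @param profile a `selection_profile`.
#' @param file TSV output path.
#' @param bed optional BED output path for the extent of [call_sweep()].
#' @param chrom chromosome name used in the BED line.
#' @return `file`, invisibly.
#' @export
write_profile <- function(profile, file, bed = NULL, chrom = "region") {
  utils::write.table(as.data.frame(profile), file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(bed)) {
    cl <- call_sweep(profile)
    writeLines(sprintf("%s\t%d\t%d\tsweep_extent\t%.4f", chrom,
                       as.integer(cl$extent["start_bp"]) - 1L,
                       as.integer(cl$extent["end_bp"]), cl$peak_prob), bed)
  }
  invisible(file)
}
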