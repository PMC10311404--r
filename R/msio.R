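# SNP matrices and the Hudson ms text dialect.
#
# State coding used throughout the package:
#   0 = ancestral, 1 = derived, 2 = other (missing / gap / ambiguous)

STATE_ANCESTRAL <- 0L
STATE_DERIVED <- 1L
STATE_OTHER <- 2L

#' Construct a SNP matrix
#'
#' The internal container for polymorphism data: an `n x T` integer matrix of
#' per-site states (0 = ancestral, 1 = derived, 2 = other) with 1-based bp
#' positions.
#'
#' @param states integer matrix, haplotypes in rows, sites in columns.
#' @param positions_bp strictly increasing 1-based positions, one per column.
#' @param region_len length of the underlying region in bp.
#' @param sample_ids optional row labels.
#' @return an object of class `snp_matrix`.
#' @export
snp_matrix <- function(states, positions_bp, region_len,
                       sample_ids = NULL) {
  states <- as.matrix(states)
  storage.mode(states) <- "integer"
  if (ncol(states) != length(positions_bp))
    stop("positions_bp must have one entry per column of states")
  if (length(positions_bp) > 1 && any(diff(positions_bp) <= 0))
    stop("positions must be strictly increasing")
  if (length(states) && !all(states %in% 0:2))
    stop("states must be coded 0 (ancestral), 1 (derived), 2 (other)")
  if (is.null(sample_ids)) sample_ids <- paste0("hap", seq_len(nrow(states)))
  structure(list(states = states,
                 positions_bp = as.numeric(positions_bp),
                 region_len = region_len,
                 sample_ids = sample_ids),
            class = "snp_matrix")
}

#' @export
print.snp_matrix <- function(x, ...) {
  cat(sprintf("SNP matrix: %d haplotypes x %d sites over %g bp\n",
              nrow(x$states), ncol(x$states), x$region_len))
  invisible(x)
}

#' @export
dim.snp_matrix <- function(x) dim(x$states)

#' Write replicates in Hudson ms format
#'
#' Emits the classic dialect: a command line, a seed line, then one block per
#' replicate introduced by `//` with `segsites:` and `positions:` lines
#' followed by the 0/1 haplotype rows. Positions are printed with six decimal
#' places. A replicate with zero segregating sites gets `segsites: 0` and no
#' positions line.
#'
#' @param reps list of `ms_rep` replicates (as returned by [simulate_ms()]).
#' @param file file path or connection; `""` returns the text invisibly.
#' @param command command line for the header (defaults to the one recorded
#'   by [simulate_ms()]).
#' @return the lines written, invisibly.
#' @export
write_ms <- function(reps, file = "", command = NULL) {
  if (length(reps) == 0) stop("no replicates to write")
  if (inherits(reps, "ms_rep")) reps <- list(reps)
  n <- unique(vapply(reps, function(r) nrow(r$haplotypes), integer(1)))
  if (length(n) != 1) stop("replicates must share the same sample size")
  if (is.null(command)) command <- attr(reps, "command")
  if (is.null(command))
    command <- paste("sweepcnn-sim", n, length(reps))
  lines <- c(command, "0 0 0")
  for (r in reps) {
    T <- length(r$positions)
    lines <- c(lines, "", "//", paste0("segsites: ", T))
    if (T > 0) {
      lines <- c(lines,
                 paste("positions:",
                       paste(sprintf("%.6f", r$positions), collapse = " ")),
                 apply(r$haplotypes, 1, paste, collapse = ""))
    }
  }
  if (!identical(file, "")) writeLines(lines, file)
  invisible(lines)
}

#' Parse Hudson ms format into SNP matrices
#'
#' Reads the ms dialect (`//` replicate separators, `segsites:`,
#' `positions:`, binary haplotype rows). The 0/1 states map to
#' ancestral/derived, and relative positions are scaled to 1-based bp
#' positions by `ceiling(pos * region_len)`; ties at the printed precision
#' are resolved upward so positions stay strictly increasing.
#'
#' @param x file path, connection, or character vector of lines.
#' @param region_len bp length used to scale the relative positions.
#' @return a list of [snp_matrix()] objects, one per replicate.
#' @examples
#' txt <- c("ms 2 1", "1 2 3", "", "//", "segsites: 2",
#'          "positions: 0.10 0.50", "01", "10")
#' parse_ms(txt, region_len = 1e5)
#' @export
parse_ms <- function(x, region_len = 1e5) {
  lines <- if (is.character(x) && length(x) > 1) x
           else if (is.character(x) && !file.exists(x)) strsplit(x, "\n")[[1]]
           else readLines(x)
  starts <- which(trimws(lines) == "//")
  out <- vector("list", length(starts))
  bounds <- c(starts, length(lines) + 1L)
  for (k in seq_along(starts)) {
    block <- lines[(bounds[k] + 1L):(bounds[k + 1L] - 1L)]
    block <- block[nzchar(trimws(block))]
    seg_line <- grep("^segsites:", block, value = TRUE)
    if (length(seg_line) != 1)
      stop(sprintf("replicate %d: missing segsites line", k))
    T <- as.integer(sub("^segsites:\\s*", "", seg_line))
    if (T == 0) {
      out[[k]] <- snp_matrix(matrix(integer(0), nrow = 0, ncol = 0),
                             numeric(0), region_len)
      next
    }
    pos_line <- grep("^positions:", block, value = TRUE)
    if (length(pos_line) != 1)
      stop(sprintf("replicate %d: missing positions line", k))
    rel <- as.numeric(strsplit(sub("^positions:\\s*", "", pos_line),
                               "\\s+")[[1]])
    if (length(rel) != T)
      stop(sprintf("replicate %d: %d positions for segsites %d",
                   k, length(rel), T))
    haps <- block[grepl("^[012]+$", block)]
    if (length(haps) == 0)
      stop(sprintf("replicate %d: no haplotype rows", k))
    if (any(nchar(haps) != T))
      stop(sprintf("replicate %d: haplotype row length differs from segsites",
                   k))
    states <- matrix(as.integer(unlist(strsplit(haps, ""), use.names = FALSE)),
                     nrow = length(haps), byrow = TRUE)
    m <- snp_matrix(states, rel_to_bp(rel, region_len), region_len)
    attr(m, "rel_positions") <- rel
    out[[k]] <- m
  }
  out
}

# relative [0,1] positions -> strictly increasing 1-based bp
rel_to_bp <- function(rel, region_len) {
  bp <- ceiling(rel * region_len)
  bp[bp < 1] <- 1
  if (length(bp) > 1)
    for (i in 2:length(bp)) if (bp[i] <= bp[i - 1]) bp[i] <- bp[i - 1] + 1
  bp
}

#' Convert a simulated replicate to a SNP matrix
#'
#' @param x an `ms_rep` from [simulate_ms()].
#' @param region_len optional override of the replicate's region length.
#' @return a [snp_matrix()].
#' @export
as_snp_matrix <- function(x, region_len = NULL) {
  stopifnot(inherits(x, "ms_rep"))
  L <- if (is.null(region_len)) x$region_len else region_len
  snp_matrix(x$haplotypes, rel_to_bp(x$positions, L), L)
}
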