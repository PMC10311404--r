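# Parsers for real data: VCF (phased haplotypes) and FASTA alignments, plus
# the site filters applied before windowing. Both parsers polarize alleles
# into ancestral/derived; everything unresolvable (missing genotypes, gaps,
# ambiguity codes) becomes the OTHER state.

#' Parse a VCF of phased haplotypes into a SNP matrix
#'
#' Diploid samples are expanded into two haplotype rows. The ancestral
#' allele is taken from the `AA` INFO tag when `ancestral = "aa"` and the
#' tag is present (sites whose AA matches neither REF nor ALT are coded
#' OTHER); otherwise REF is treated as ancestral. Missing alleles (`.`)
#' become OTHER; alleles beyond the first ALT are kept as OTHER and the
#' site is then removed by [filter_sites()] as an infinite-sites violation.
#'
#' @param file VCF path (plain or gzipped).
#' @param sample_subset optional character vector of sample names.
#' @param ancestral `"aa"` (use the AA INFO tag, falling back to REF) or
#'   `"ref"`.
#' @param unphased `"error"` (default) to refuse unphased genotypes, or
#'   `"haplotype"` to treat each allele as a haplotype with a warning.
#' @param region_len region length; defaults to the maximum position.
#' @return a [snp_matrix()].
#' @export
parse_vcf <- function(file, sample_subset = NULL,
                      ancestral = c("aa", "ref"),
                      unphased = c("error", "haplotype"),
                      region_len = NULL) {
  ancestral <- match.arg(ancestral)
  unphased <- match.arg(unphased)
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("parse_vcf requires the vcfR package")
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  fix <- vcfR::getFIX(v, getINFO = TRUE)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  nsite <- nrow(gt)
  if (is.null(nsite) || nsite == 0) {  # zero-site VCF
    return(snp_matrix(matrix(integer(0), 0, 0), numeric(0),
                      if (is.null(region_len)) 0 else region_len))
  }
  if (!is.null(sample_subset)) {
    missing <- setdiff(sample_subset, colnames(gt))
    if (length(missing))
      stop("samples not in VCF: ", paste(missing, collapse = ", "))
    gt <- gt[, sample_subset, drop = FALSE]
  }
  pos <- as.numeric(fix[, "POS"])
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  aa <- rep(NA_character_, nsite)
  if (ancestral == "aa") {
    info <- fix[, "INFO"]
    has <- grepl("(^|;)AA=", info)
    aa[has] <- toupper(sub(";.*$", "",
                           sub("^.*?AA=", "", info[has])))
  }

  phased <- grepl("|", gt, fixed = TRUE) | !grepl("/", gt, fixed = TRUE)
  if (!all(phased | is.na(gt))) {
    if (unphased == "error")
      stop("unphased genotypes found; rerun with unphased = 'haplotype'")
    warning("unphased genotypes treated as haplotypes")
  }

  n_hap_per_sample <- max(lengths(strsplit(gt[!is.na(gt)], "[|/]")), 1)
  states <- matrix(STATE_OTHER, nrow = ncol(gt) * n_hap_per_sample,
                   ncol = nsite)
  ids <- character(nrow(states))
  for (s in seq_len(ncol(gt))) {
    al <- strsplit(ifelse(is.na(gt[, s]), ".", gt[, s]), "[|/]")
    for (h in seq_len(n_hap_per_sample)) {
      row <- (s - 1) * n_hap_per_sample + h
      ids[row] <- paste0(colnames(gt)[s], "_", h)
      a <- vapply(al, function(x) if (length(x) >= h) x[h] else ".",
                  character(1))
      st <- rep(STATE_OTHER, nsite)
      # polarize: which VCF allele index is ancestral?
      anc_idx <- rep(0L, nsite)   # default: REF ancestral
      if (ancestral == "aa") {
        alt1 <- toupper(vapply(strsplit(alt, ","), `[`, character(1), 1))
        anc_idx[!is.na(aa) & aa == alt1] <- 1L
        anc_idx[!is.na(aa) & aa != alt1 & aa != toupper(ref)] <- NA_integer_
      }
      ai <- suppressWarnings(as.integer(a))
      known <- !is.na(ai) & ai <= 1 & !is.na(anc_idx)
      st[known & ai == anc_idx] <- STATE_ANCESTRAL
      st[known & ai == (1L - anc_idx)] <- STATE_DERIVED
      states[row, ] <- st
    }
  }
  ord <- order(pos)
  pos <- pos[ord]
  states <- states[, ord, drop = FALSE]
  multi <- grepl(",", alt, fixed = TRUE)[ord]
  keep <- !duplicated(pos)
  out <- snp_matrix(states[, keep, drop = FALSE], pos[keep],
                    if (is.null(region_len)) max(pos, 1) else region_len,
                    sample_ids = ids)
  attr(out, "multiallelic") <- multi[keep]
  out
}

#' Parse an aligned FASTA into a SNP matrix
#'
#' Polymorphic columns of the alignment are extracted; gaps (`-`) and
#' ambiguity codes map to the OTHER state. The ancestral allele at each
#' column comes from a named outgroup sequence (excluded from the sample
#' rows) or, without an outgroup, from the majority allele.
#'
#' @param file FASTA path of equal-length aligned sequences.
#' @param outgroup optional name of the outgroup sequence.
#' @param region_len region length; defaults to the alignment length.
#' @return a [snp_matrix()].
#' @export
parse_fasta <- function(file, outgroup = NULL, region_len = NULL) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("parse_fasta requires the Biostrings package")
  seqs <- Biostrings::readBStringSet(file)
  if (length(unique(Biostrings::width(seqs))) != 1)
    stop("ragged alignment: sequences differ in length")
  chars <- toupper(as.matrix(seqs))
  valid <- c("A", "C", "G", "T")
  out_row <- NULL
  if (!is.null(outgroup)) {
    i <- match(outgroup, names(seqs))
    if (is.na(i)) stop("outgroup '", outgroup, "' not found")
    out_row <- chars[i, ]
    chars <- chars[-i, , drop = FALSE]
  }
  aln_len <- ncol(chars)
  poly <- which(vapply(seq_len(aln_len), function(j) {
    a <- chars[, j]
    length(unique(a[a %in% valid])) >= 2
  }, logical(1)))
  states <- matrix(STATE_OTHER, nrow = nrow(chars), ncol = length(poly))
  for (k in seq_along(poly)) {
    j <- poly[k]
    a <- chars[, j]
    anc <- if (!is.null(out_row) && out_row[j] %in% valid) {
      out_row[j]
    } else {
      tab <- sort(table(a[a %in% valid]), decreasing = TRUE)
      names(tab)[1]
    }
    states[a == anc, k] <- STATE_ANCESTRAL
    states[a %in% valid & a != anc, k] <- STATE_DERIVED
  }
  snp_matrix(states, poly,
             if (is.null(region_len)) aln_len else region_len,
             sample_ids = rownames(chars))
}

#' Filter sites to bi-allelic segregating SNPs
#'
#' Drops monomorphic columns (fewer than two distinct ancestral/derived
#' states among called alleles) and columns violating the infinite-sites
#' model (more than two alleles in the source record, i.e. both states
#' present together with additional called alleles recorded as OTHER while
#' the source was multi-allelic). The filter is idempotent and reports
#' counts per removal reason in attribute `filter_report`.
#'
#' @param m a [snp_matrix()].
#' @param multiallelic optional logical vector marking source-multi-allelic
#'   columns (e.g. from a VCF with >1 ALT allele); when missing, columns
#'   where both states and OTHER calls coexist are treated as violations
#'   only if flagged.
#' @return the filtered [snp_matrix()] with a `filter_report` attribute
#'   (`n_input`, `n_monomorphic`, `n_multiallelic`, `n_kept`).
#' @export
filter_sites <- function(m, multiallelic = NULL) {
  stopifnot(inherits(m, "snp_matrix"))
  T <- ncol(m$states)
  if (is.null(multiallelic)) multiallelic <- attr(m, "multiallelic")
  if (is.null(multiallelic)) multiallelic <- rep(FALSE, T)
  seg <- vapply(seq_len(T), function(j) {
    a <- m$states[, j]
    any(a == STATE_ANCESTRAL) && any(a == STATE_DERIVED)
  }, logical(1))
  drop_multi <- multiallelic & seg
  keep <- seg & !drop_multi
  out <- snp_matrix(m$states[, keep, drop = FALSE],
                    m$positions_bp[keep], m$region_len, m$sample_ids)
  attr(out, "multiallelic") <- multiallelic[keep]
  attr(out, "filter_report") <- list(
    n_input = T,
    n_monomorphic = sum(!seg),
    n_multiallelic = sum(drop_multi),
    n_kept = sum(keep))
  out
}

#' Write a site-filter report as TSV
#'
#' @param m a filtered [snp_matrix()] carrying a `filter_report` attribute.
#' @param file output path.
#' @export
write_filter_report <- function(m, file) {
  rep <- attr(m, "filter_report")
  if (is.null(rep)) stop("no filter report attached; run filter_sites first")
  utils::write.table(as.data.frame(rep), file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
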