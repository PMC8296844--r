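#' Windowed GC, gap and parsimony-substitution tracks over an alignment
#'
#' Non-overlapping windows of `width` columns are laid out in alignment
#' coordinates (the last window may be short). GC content is pooled across
#' all taxa per window, with gaps and `N` excluded from numerator and
#' denominator; the gap fraction is gap characters over rows times window
#' width; the substitution count is the sum of per-column Fitch parsimony
#' steps on the fixed tree topology.
#'
#' @param alignment A [gene_alignment()], named character vector, or
#'   `supermatrix` (its concatenated alignment is used).
#' @param tree `phylo` tree whose leaves match the alignment rows.
#' @param width Window width in columns (default 100).
#' @return A tibble: `window_index` (1-based), `start`, `end` (0-based
#'   half-open columns), `gc`, `gap_fraction`, `substitution_count`.
#' @export
window_stats <- function(alignment, tree, width = 100) {
  if (width <= 0) stop("width must be >= 1", call. = FALSE)
  if (inherits(alignment, "supermatrix")) alignment <- alignment$alignment
  mat <- if (is.matrix(alignment)) alignment else aln_matrix(alignment)
  mat <- toupper(mat)
  ncols <- ncol(mat)
  steps <- fitch_steps_matrix(tree, mat)
  starts <- seq.int(0L, ncols - 1L, by = width)
  ends <- pmin(starts + width, ncols)
  gc_col <- colSums(mat == "G" | mat == "C")
  acgt_col <- colSums(mat == "A" | mat == "C" | mat == "G" | mat == "T")
  gap_col <- colSums(mat == "-")
  nrows <- nrow(mat)
  purrr::map2_dfr(starts, ends, function(s, e) {
    cols <- (s + 1L):e
    denom <- sum(acgt_col[cols])
    tibble::tibble(
      window_index = s %/% width + 1L,
      start = s, end = e,
      gc = if (denom > 0) sum(gc_col[cols]) / denom else NA_real_,
      gap_fraction = sum(gap_col[cols]) / (nrows * (e - s)),
      substitution_count = sum(steps[cols]))
  })
}

#' Per-gene GC content over a supermatrix partition
#'
#' @param sm A `supermatrix` from [concatenate()].
#' @return A tibble: `gene`, `gc` (pooled across taxa over the gene's
#'   columns, gaps and `N` excluded).
#' @export
gene_gc <- function(sm) {
  stopifnot(inherits(sm, "supermatrix"))
  mat <- toupper(aln_matrix(gene_alignment(sm$alignment)))
  purrr::pmap_dfr(sm$partition, function(gene, start, end) {
    cols <- (start + 1L):end
    sub <- mat[, cols, drop = FALSE]
    denom <- sum(sub %in% c("A", "C", "G", "T"))
    tibble::tibble(gene = gene,
                   gc = if (denom > 0) sum(sub %in% c("G", "C")) / denom
                        else NA_real_)
  })
}
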