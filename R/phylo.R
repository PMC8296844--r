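## Tree algorithms: Fitch parsimony on nucleotide columns, Felsenstein
## pruning under JC69, reference branch-length estimation on the masked
## concatenate, and per-gene maximum-likelihood rate scalers.

NT_MASK <- c(A = 1L, C = 2L, G = 4L, T = 8L, N = 15L, `-` = 15L, `?` = 15L)

char_mask <- function(x) {
  m <- NT_MASK[x]
  m[is.na(m)] <- 15L
  unname(m)
}

tree_postorder <- function(tree) {
  tr <- ape::reorder.phylo(tree, "postorder")
  list(tree = tr, edge = tr$edge, ntip = length(tr$tip.label),
       nnode = tr$Nnode, root = length(tr$tip.label) + 1L,
       lengths = tr$edge.length)
}

#' Fitch parsimony steps for one alignment column
#'
#' Minimum number of state changes on a fixed tree topology under Fitch's
#' algorithm; missing states (`-`, `N`) contribute the universal state set.
#'
#' @param tree A `phylo` tree.
#' @param column_states Named character vector (leaf -> one of
#'   A/C/G/T/N/-).
#' @return Non-negative integer count.
#' @export
fitch_steps <- function(tree, column_states) {
  mat <- matrix(toupper(column_states), ncol = 1,
                dimnames = list(names(column_states), NULL))
  as.integer(fitch_steps_matrix(tree, mat))
}

#' Fitch parsimony steps for every column of a character matrix
#'
#' @param tree A `phylo` tree.
#' @param mat Character matrix, rows named by leaves, one column per site.
#' @return Integer vector of per-column step counts.
#' @export
fitch_steps_matrix <- function(tree, mat) {
  missing_leaves <- setdiff(tree$tip.label, rownames(mat))
  if (length(missing_leaves)) {
    stop("leaf absent from alignment: ", paste(missing_leaves,
                                               collapse = ", "),
         call. = FALSE)
  }
  po <- tree_postorder(tree)
  nsite <- ncol(mat)
  sets <- matrix(0L, nrow = po$ntip + po$nnode, ncol = nsite)
  for (i in seq_len(po$ntip)) {
    sets[i, ] <- char_mask(mat[po$tree$tip.label[i], ])
  }
  steps <- integer(nsite)
  seen <- logical(po$ntip + po$nnode)
  for (e in seq_len(nrow(po$edge))) {
    parent <- po$edge[e, 1]
    child <- po$edge[e, 2]
    cs <- sets[child, ]
    if (!seen[parent]) {
      sets[parent, ] <- cs
      seen[parent] <- TRUE
    } else {
      inter <- bitwAnd(sets[parent, ], cs)
      clash <- inter == 0L
      steps <- steps + clash
      sets[parent, ] <- ifelse(clash, bitwOr(sets[parent, ], cs), inter)
    }
  }
  steps
}

## ---- JC69 pruning ----------------------------------------------------------

jc69_pmat <- function(t) {
  e <- exp(-4 * t / 3)
  same <- 0.25 + 0.75 * e
  diff <- 0.25 - 0.25 * e
  m <- matrix(diff, 4, 4)
  diag(m) <- same
  m
}

tip_partial <- function(chars) {
  ## 4 x S one-hot (ones for missing)
  S <- length(chars)
  out <- matrix(0, 4, S)
  idx <- match(chars, c("A", "C", "G", "T"))
  known <- !is.na(idx)
  out[cbind(idx[known], which(known))] <- 1
  out[, !known] <- 1
  out
}

compress_patterns <- function(mat) {
  keys <- apply(mat, 2, paste, collapse = "")
  tab <- table(factor(keys, levels = unique(keys)))
  first <- match(names(tab), keys)
  list(mat = mat[, first, drop = FALSE], weights = as.numeric(tab))
}

#' Log-likelihood of an alignment under JC69 by Felsenstein pruning
#'
#' Gaps and `N` are treated as missing data (partial likelihood 1 for all
#' states). Site patterns are compressed before pruning.
#'
#' @param tree A `phylo` tree with non-negative branch lengths.
#' @param alignment A [gene_alignment()], named character vector, or
#'   character matrix with rows named by the tree's leaves.
#' @return The log-likelihood (numeric scalar).
#' @export
jc69_loglik <- function(tree, alignment) {
  if (is.null(tree$edge.length)) stop("tree has no branch lengths",
                                      call. = FALSE)
  if (any(tree$edge.length < 0)) stop("negative branch length",
                                      call. = FALSE)
  mat <- if (is.matrix(alignment)) alignment else aln_matrix(alignment)
  cp <- compress_patterns(mat)
  jc69_loglik_patterns(tree, cp$mat, cp$weights)
}

jc69_loglik_patterns <- function(tree, mat, weights) {
  po <- tree_postorder(tree)
  missing_leaves <- setdiff(po$tree$tip.label, rownames(mat))
  if (length(missing_leaves)) {
    stop("leaf absent from alignment: ",
         paste(missing_leaves, collapse = ", "), call. = FALSE)
  }
  S <- ncol(mat)
  partials <- vector("list", po$ntip + po$nnode)
  for (i in seq_len(po$ntip)) {
    partials[[i]] <- tip_partial(toupper(mat[po$tree$tip.label[i], ]))
  }
  logscale <- 0
  seen <- logical(po$ntip + po$nnode)
  for (e in seq_len(nrow(po$edge))) {
    parent <- po$edge[e, 1]
    child <- po$edge[e, 2]
    msg <- jc69_pmat(po$lengths[e]) %*% partials[[child]]
    if (!seen[parent]) {
      partials[[parent]] <- msg
      seen[parent] <- TRUE
    } else {
      partials[[parent]] <- partials[[parent]] * msg
    }
    ## rescale to avoid underflow
    mx <- apply(partials[[parent]], 2, max)
    mx[mx == 0] <- 1
    partials[[parent]] <- sweep(partials[[parent]], 2, mx, "/")
    logscale <- logscale + sum(weights * log(mx))
  }
  site_l <- colSums(partials[[po$root]] * 0.25)
  sum(weights * log(site_l)) + logscale
}

#' Estimate reference branch lengths under JC69
#'
#' Coordinate-wise optimization (one Brent pass per edge, repeated until
#' the log-likelihood improvement falls below `tol`) on a fixed topology.
#' The topology is never re-estimated.
#'
#' @param tree A `phylo` tree (branch lengths, if present, are the starting
#'   point; otherwise 0.1 per edge).
#' @param alignment Alignment covering the tree's leaves (e.g. the masked
#'   concatenate).
#' @param tol Stop when a full pass improves the log-likelihood by less.
#' @param max_pass Maximum number of passes over the edges.
#' @param upper Upper bound per branch length.
#' @return The tree with optimized `edge.length`.
#' @export
optimize_branch_lengths <- function(tree, alignment, tol = 1e-4,
                                    max_pass = 20, upper = 10) {
  mat <- if (is.matrix(alignment)) alignment else aln_matrix(alignment)
  cp <- compress_patterns(mat)
  tr <- tree
  if (is.null(tr$edge.length)) tr$edge.length <- rep(0.1, nrow(tr$edge))
  cur <- jc69_loglik_patterns(tr, cp$mat, cp$weights)
  for (pass in seq_len(max_pass)) {
    prev <- cur
    for (e in seq_len(nrow(tr$edge))) {
      f <- function(x) {
        tr$edge.length[e] <- x
        jc69_loglik_patterns(tr, cp$mat, cp$weights)
      }
      opt <- stats::optimize(f, c(0, upper), maximum = TRUE, tol = 1e-6)
      if (opt$objective > cur) {
        tr$edge.length[e] <- opt$maximum
        cur <- opt$objective
      }
    }
    if (cur - prev < tol) break
  }
  attr(tr, "loglik") <- cur
  tr
}

#' Per-gene ML rate scaler relative to reference branch lengths
#'
#' Maximizes the JC69 likelihood of one gene alignment with all reference
#' branch lengths multiplied by a single scalar `c_g` (1-D bounded
#' optimization, tolerance 1e-6).
#'
#' @param tree Reference tree with branch lengths (from the masked
#'   concatenate).
#' @param gene_alignment The gene's alignment.
#' @param gene Gene name for the result row.
#' @param lower,upper Scaler bounds.
#' @return One-row tibble: `gene`, `rate_scaler`, `loglik`, `n_columns`,
#'   `parsimony_rate` (Fitch steps per column with at least two resolved
#'   states), `no_signal`.
#' @export
fit_gene_rate <- function(tree, gene_alignment, gene = NULL,
                          lower = 1e-3, upper = 100) {
  aln <- as_gene_alignment(gene_alignment)
  gene <- gene %||% aln$gene
  mat <- aln_matrix(aln)
  mat <- mat[tree$tip.label, , drop = FALSE]
  informative <- colSums(matrix(mat %in% c("A", "C", "G", "T"),
                                nrow = nrow(mat))) >= 2L
  if (!any(informative)) {
    return(tibble::tibble(gene = gene, rate_scaler = NA_real_,
                          loglik = NA_real_, n_columns = ncol(mat),
                          parsimony_rate = NA_real_, no_signal = TRUE))
  }
  cp <- compress_patterns(mat)
  f <- function(c_g) {
    tr <- tree
    tr$edge.length <- tree$edge.length * c_g
    jc69_loglik_patterns(tr, cp$mat, cp$weights)
  }
  opt <- stats::optimize(f, c(lower, upper), maximum = TRUE, tol = 1e-6)
  steps <- fitch_steps_matrix(tree, mat[, informative, drop = FALSE])
  tibble::tibble(gene = gene, rate_scaler = opt$maximum,
                 loglik = opt$objective, n_columns = ncol(mat),
                 parsimony_rate = sum(steps) / sum(informative),
                 no_signal = opt$maximum <= lower * 1.01)
}

#' Fit rate scalers for a set of gene alignments
#'
#' @param tree Reference tree with branch lengths.
#' @param gene_alignments Named list of [gene_alignment()] objects.
#' @param ... Passed to [fit_gene_rate()].
#' @return An object of class `gene_rate_fit`: use [generics::tidy()] for
#'   the per-gene table (with `relative_rate` normalized to mean 1) and
#'   [generics::glance()] for the fit summary.
#' @export
fit_gene_rates <- function(tree, gene_alignments, ...) {
  rows <- dplyr::bind_rows(lapply(names(gene_alignments), function(g) {
    fit_gene_rate(tree, gene_alignments[[g]], gene = g, ...)
  }))
  rows$relative_rate <- rows$rate_scaler /
    mean(rows$rate_scaler, na.rm = TRUE)
  structure(list(rates = rows, tree = tree), class = "gene_rate_fit")
}

#' @export
print.gene_rate_fit <- function(x, ...) {
  cat("<gene_rate_fit> ", nrow(x$rates), " genes\n", sep = "")
  print(x$rates, ...)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.gene_rate_fit <- function(x, ...) x$rates

#' @export
glance.gene_rate_fit <- function(x, ...) {
  tibble::tibble(n_genes = nrow(x$rates),
                 n_estimated = sum(!is.na(x$rates$rate_scaler)),
                 mean_scaler = mean(x$rates$rate_scaler, na.rm = TRUE),
                 total_loglik = sum(x$rates$loglik, na.rm = TRUE))
}

#' Concatenate masked gene alignments into a supermatrix
#'
#' @param gene_alignments Named list of [gene_alignment()] objects.
#' @param gene_order Order of genes in the concatenate (default: list
#'   order).
#' @param pad If `TRUE`, taxa missing from a gene are padded as all-gap
#'   rows; if `FALSE`, conflicting taxon sets raise an error.
#' @return An object of class `supermatrix`: list with `alignment` (named
#'   character vector) and `partition`, a tibble with `gene`, `start`,
#'   `end` (0-based half-open column intervals).
#' @export
concatenate <- function(gene_alignments, gene_order = NULL, pad = TRUE) {
  if (length(gene_alignments) == 0L) stop("empty gene list", call. = FALSE)
  gene_order <- gene_order %||% names(gene_alignments)
  taxa <- sort(unique(unlist(lapply(gene_alignments,
                                    function(a) names(a$seqs)))))
  pieces <- matrix("", nrow = length(taxa), ncol = length(gene_order),
                   dimnames = list(taxa, gene_order))
  offsets <- integer(length(gene_order))
  widths <- integer(length(gene_order))
  pos <- 0L
  for (gi in seq_along(gene_order)) {
    g <- gene_order[gi]
    aln <- gene_alignments[[g]]
    if (is.null(aln)) stop("gene not found: ", g, call. = FALSE)
    width <- nchar(aln$seqs[1])
    missing_taxa <- setdiff(taxa, names(aln$seqs))
    if (length(missing_taxa) && !pad) {
      stop("gene ", g, " missing taxa (set pad = TRUE): ",
           paste(missing_taxa, collapse = ", "), call. = FALSE)
    }
    for (tx in taxa) {
      pieces[tx, gi] <- if (tx %in% names(aln$seqs)) aln$seqs[[tx]] else
        strrep("-", width)
    }
    offsets[gi] <- pos
    widths[gi] <- width
    pos <- pos + width
  }
  alignment <- stats::setNames(apply(pieces, 1, paste, collapse = ""), taxa)
  partition <- tibble::tibble(gene = gene_order, start = offsets,
                              end = offsets + widths)
  structure(list(alignment = alignment, partition = partition),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat("<supermatrix> ", length(x$alignment), " taxa x ",
      nchar(x$alignment[1]), " columns, ", nrow(x$partition), " genes\n",
      sep = "")
  invisible(x)
}

#' Split a supermatrix back into per-gene alignments
#'
#' @param sm A `supermatrix`.
#' @return Named list of [gene_alignment()] objects.
#' @export
split_supermatrix <- function(sm) {
  out <- lapply(seq_len(nrow(sm$partition)), function(i) {
    p <- sm$partition[i, ]
    gene_alignment(substr(sm$alignment, p$start + 1L, p$end),
                   gene = p$gene)
  })
  stats::setNames(out, sm$partition$gene)
}
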