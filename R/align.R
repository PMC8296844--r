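#' Translate a coding sequence under translation table 11
#'
#' Stops are rendered as `*`; codons containing `N` or `-` as `X`.
#'
#' @param cds Nucleotide string.
#' @param allow_trailing If `TRUE`, a trailing 1-2 nt partial codon is
#'   dropped instead of raising a frame error.
#' @return Amino-acid string.
#' @export
#' @examples
#' translate_cds("ATGAAATAA")  # "MK*"
translate_cds <- function(cds, allow_trailing = FALSE) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n %% 3L != 0L) {
    if (!allow_trailing) {
      stop("frame error: length ", n, " not divisible by 3", call. = FALSE)
    }
    cds <- substr(cds, 1L, n - n %% 3L)
  }
  if (nchar(cds) == 0L) return("")
  codons <- split_codons(cds)
  ct <- codon_table()
  aa <- ct$aa[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

## A record is a usable frame anchor / AA-alignable sequence when its length
## is a codon multiple and it translates with no internal stop.
is_translatable <- function(seq) {
  n <- nchar(seq)
  if (n == 0L || n %% 3L != 0L) return(FALSE)
  if (grepl("-", seq, fixed = TRUE)) return(FALSE)
  aa <- translate_cds(seq)
  body <- substr(aa, 1L, nchar(aa) - 1L)
  !grepl("*", body, fixed = TRUE)
}

default_nt_scores <- c(match = 2, mismatch = -3, gap_open = -5,
                       gap_extend = -2)

#' Global pairwise nucleotide alignment with affine gaps
#'
#' A thin wrapper over [Biostrings::pairwiseAlignment()] with the package's
#' default scoring (match 2, mismatch -3, gap open -5, gap extend -2).
#'
#' @param ref,query Non-empty nucleotide strings.
#' @param scores Named numeric vector with `match`, `mismatch`, `gap_open`,
#'   `gap_extend` (gap penalties negative).
#' @return A list with `ref`, `query` (aligned strings of equal length) and
#'   `score`.
#' @export
pairwise_align_nt <- function(ref, query, scores = default_nt_scores) {
  if (nchar(ref) == 0L || nchar(query) == 0L) {
    stop("empty input to pairwise alignment", call. = FALSE)
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scores[["match"]], mismatch = scores[["mismatch"]],
    baseOnly = FALSE, type = "DNA")
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(query),
    subject = Biostrings::DNAString(ref),
    type = "global", substitutionMatrix = mat,
    gapOpening = -scores[["gap_open"]],
    gapExtension = -scores[["gap_extend"]])
  list(ref = as.character(Biostrings::alignedSubject(aln)),
       query = as.character(Biostrings::alignedPattern(aln)),
       score = Biostrings::score(aln))
}

pairwise_align_aa <- function(ref, query) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(query),
    subject = Biostrings::AAString(ref),
    type = "global", substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 1)
  list(ref = as.character(Biostrings::alignedSubject(aln)),
       query = as.character(Biostrings::alignedPattern(aln)))
}

#' A gene alignment container
#'
#' @param seqs Named character vector of equal-length gapped sequences.
#' @param gene Gene name.
#' @param anchor Id of the frame-anchor row (ungapped length a codon
#'   multiple).
#' @return An object of class `gene_alignment`.
#' @export
gene_alignment <- function(seqs, gene = NA_character_,
                           anchor = NA_character_) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  if (length(unique(nchar(seqs))) > 1L) {
    stop("alignment rows have unequal lengths", call. = FALSE)
  }
  structure(list(gene = gene, seqs = seqs, anchor = anchor),
            class = "gene_alignment")
}

#' @export
print.gene_alignment <- function(x, ...) {
  cat("<gene_alignment>", if (!is.na(x$gene)) x$gene else "",
      ": ", length(x$seqs), " rows x ", nchar(x$seqs[1]), " columns\n",
      sep = "")
  invisible(x)
}

#' Coerce to a gene alignment
#' @param x A `gene_alignment`, named character vector, or sequence tibble
#'   of equal-length gapped sequences.
#' @param gene Optional gene name.
#' @return A `gene_alignment`.
#' @export
as_gene_alignment <- function(x, gene = NA_character_) {
  if (inherits(x, "gene_alignment")) return(x)
  gene_alignment(seq_named(x), gene = gene)
}

aln_matrix <- function(aln) {
  aln <- as_gene_alignment(aln)
  m <- do.call(rbind, strsplit(unname(aln$seqs), ""))
  rownames(m) <- names(aln$seqs)
  m
}

#' Translation-guided codon alignment of one gene across taxa
#'
#' The first record that translates full-length without internal stops is
#' the frame anchor. Every other translatable record is aligned to the
#' anchor at amino-acid level (Needleman-Wunsch, BLOSUM62) and the pairwise
#' alignments are merged in anchor coordinates (star alignment), then
#' back-translated so every amino-acid gap becomes a 3-nt gap. Records that
#' fail translation (candidate pseudogenes) are added by global nucleotide
#' alignment to the anchor, which can introduce non-triplet
#' (frameshift-revealing) gaps. Empty records are dropped with a warning.
#'
#' @param records Sequence tibble or named character vector of unaligned
#'   CDS.
#' @param gene Optional gene name carried into the result.
#' @return A [gene_alignment()].
#' @export
align_codon <- function(records, gene = NA_character_) {
  seqs <- seq_named(records)
  empty <- nchar(seqs) == 0L
  if (any(empty)) {
    warning("dropping ", sum(empty), " empty record(s) from alignment",
            call. = FALSE)
    seqs <- seqs[!empty]
  }
  if (length(seqs) < 2L) stop("need at least 2 non-empty records",
                              call. = FALSE)
  translatable <- vapply(seqs, is_translatable, logical(1))
  if (!any(translatable)) {
    stop("no translatable record to serve as frame anchor; ",
         "supply an external reference", call. = FALSE)
  }
  anchor_id <- names(seqs)[which(translatable)[1]]
  anchor_nt <- seqs[[anchor_id]]
  anchor_aa <- translate_cds(anchor_nt)
  anchor_codons <- split_codons(anchor_nt)
  La <- nchar(anchor_aa)

  aa_ids <- setdiff(names(seqs)[translatable], anchor_id)
  ## ins[[id]][i]: residues of `id` inserted before anchor AA position i
  ## (i in 1..La+1); aligned_aa maps of each row
  ins_counts <- matrix(0L, nrow = length(aa_ids), ncol = La + 1L,
                       dimnames = list(aa_ids, NULL))
  pair_rows <- list()
  for (id in aa_ids) {
    qa <- translate_cds(seqs[[id]])
    pw <- pairwise_align_aa(anchor_aa, qa)
    ra <- strsplit(pw$ref, "")[[1]]
    qq <- strsplit(pw$query, "")[[1]]
    apos <- 1L
    ins_here <- integer(La + 1L)
    qcells <- vector("list", La)       # query AA aligned to each anchor pos
    ins_cells <- vector("list", La + 1L)
    for (k in seq_along(ra)) {
      if (ra[k] == "-") {
        ins_here[apos] <- ins_here[apos] + 1L
        ins_cells[[apos]] <- c(ins_cells[[apos]], qq[k])
      } else {
        qcells[[apos]] <- if (qq[k] == "-") "-" else qq[k]
        apos <- apos + 1L
      }
    }
    ins_counts[id, ] <- ins_here
    pair_rows[[id]] <- list(qcells = qcells, ins_cells = ins_cells)
  }
  max_ins <- if (length(aa_ids)) apply(ins_counts, 2, max) else
    integer(La + 1L)

  ## build AA-level star alignment, then back-translate row by row
  build_row_nt <- function(id) {
    codons <- split_codons(seqs[[id]])
    ci <- 0L  # consumed codons of this record
    take <- function(aa_char) {
      if (aa_char == "-") return("---")
      ci <<- ci + 1L
      codons[ci]
    }
    parts <- character(0)
    pr <- pair_rows[[id]]
    for (i in seq_len(La + 1L)) {
      cells <- if (i <= La + 1L) pr$ins_cells[[i]] else NULL
      n_ins <- length(cells)
      pad <- max_ins[i] - n_ins
      parts <- c(parts, vapply(cells, take, character(1), USE.NAMES = FALSE),
                 rep("---", pad))
      if (i <= La) parts <- c(parts, take(pr$qcells[[i]] %||% "-"))
    }
    paste(parts, collapse = "")
  }
  anchor_row <- {
    parts <- character(0)
    for (i in seq_len(La + 1L)) {
      parts <- c(parts, rep("---", max_ins[i]))
      if (i <= La) parts <- c(parts, anchor_codons[i])
    }
    paste(parts, collapse = "")
  }
  rows <- stats::setNames(c(anchor_row,
                            vapply(aa_ids, build_row_nt, character(1))),
                          c(anchor_id, aa_ids))

  ## nucleotide-level addition of untranslatable records
  nt_ids <- names(seqs)[!translatable]
  ## column map: alignment column of each anchor ungapped nt
  for (id in nt_ids) {
    pw <- pairwise_align_nt(anchor_nt, seqs[[id]])
    rows <- insert_nt_row(rows, anchor_id, id, pw)
  }
  gene_alignment(rows[names(seqs)], gene = gene, anchor = anchor_id)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Project a pairwise (anchor vs query) nt alignment into an existing
## multiple alignment keyed by the anchor row, inserting new all-gap
## columns for query insertions.
insert_nt_row <- function(rows, anchor_id, id, pw) {
  anchor_aln <- strsplit(rows[[anchor_id]], "")[[1]]
  anchor_cols <- which(anchor_aln != "-")       # column of anchor nt k
  ra <- strsplit(pw$ref, "")[[1]]
  qa <- strsplit(pw$query, "")[[1]]
  width <- length(anchor_aln)
  new_row <- rep("-", width)
  ## insertions (query char over ref gap) grouped by anchor nt position
  ins_after <- vector("list", length(anchor_cols) + 1L)  # before nt k
  k <- 1L  # next anchor nt index
  for (j in seq_along(ra)) {
    if (ra[j] == "-") {
      ins_after[[k]] <- c(ins_after[[k]], qa[j])
    } else {
      new_row[anchor_cols[k]] <- qa[j]
      k <- k + 1L
    }
  }
  n_new <- sum(lengths(ins_after))
  if (n_new == 0L) {
    rows[[id]] <- paste(new_row, collapse = "")
    return(rows)
  }
  ## rebuild all rows with inserted columns
  old_mat <- do.call(rbind, strsplit(unname(rows), ""))
  rownames(old_mat) <- names(rows)
  all_ids <- c(rownames(old_mat), id)
  segs <- list()
  prev <- 0L
  for (k in seq_along(ins_after)) {
    cells <- ins_after[[k]]
    upto <- if (k <= length(anchor_cols)) anchor_cols[k] - 1L else width
    ## columns prev+1 .. upto (before the insertion point), then inserted
    if (upto >= prev + 1L) {
      seg_old <- old_mat[, (prev + 1L):upto, drop = FALSE]
      seg_new <- new_row[(prev + 1L):upto]
      segs[[length(segs) + 1L]] <- rbind(seg_old, seg_new)
    }
    if (length(cells)) {
      ins_block <- matrix("-", nrow = nrow(old_mat), ncol = length(cells))
      segs[[length(segs) + 1L]] <- rbind(ins_block, cells)
    }
    if (k <= length(anchor_cols)) {
      col <- anchor_cols[k]
      segs[[length(segs) + 1L]] <- rbind(old_mat[, col, drop = FALSE],
                                         new_row[col])
      prev <- col
    }
  }
  full <- do.call(cbind, segs)
  rownames(full) <- all_ids
  stats::setNames(apply(full, 1, paste, collapse = ""), all_ids)
}

#' Remove gaps from a sequence
#' @param x Gapped sequence string(s).
#' @return Ungapped string(s).
#' @export
degap <- function(x) gsub("-", "", x, fixed = TRUE)
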