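## Pseudogene lesion calling.
##
## A query CDS is aligned globally to an intact reference CDS and walked in
## the reference frame; the first of (a) a persistent frameshift, (b) an
## in-frame premature stop codon, (c) a terminal truncating deletion is the
## lesion. Compensated frameshifts (net indel length returning to 0 mod 3
## within the persistence window) are treated as evidence of function, not
## lesions.

STOP_CODONS <- c("TAA", "TAG", "TGA")

## Alignment used by the scanner: the query aligns globally to a local
## stretch of the reference (free reference end gaps), so terminal
## truncating deletions come out as clean terminal runs instead of being
## scattered into interior gaps; the unaligned reference ends are padded
## back as explicit deletion columns.
scan_alignment <- function(ref, query, scores = default_nt_scores) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scores[["match"]], mismatch = scores[["mismatch"]],
    baseOnly = FALSE, type = "DNA")
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(query),
    subject = Biostrings::DNAString(ref),
    type = "global-local", substitutionMatrix = mat,
    gapOpening = -scores[["gap_open"]],
    gapExtension = -scores[["gap_extend"]])
  s_start <- Biostrings::start(Biostrings::subject(aln))
  s_end <- Biostrings::end(Biostrings::subject(aln))
  lead_ref <- substr(ref, 1, s_start - 1)
  trail_ref <- substr(ref, s_end + 1, nchar(ref))
  list(ref = paste0(lead_ref,
                    as.character(Biostrings::alignedSubject(aln)),
                    trail_ref),
       query = paste0(strrep("-", nchar(lead_ref)),
                      as.character(Biostrings::alignedPattern(aln)),
                      strrep("-", nchar(trail_ref))),
       score = Biostrings::score(aln))
}

#' Scan one query sequence against an intact reference CDS
#'
#' @param ref_cds Reference CDS; must translate full-length without internal
#'   stops.
#' @param query_seq Query nucleotide string; may be empty (absent gene).
#' @param gene,taxon Labels carried into the result.
#' @param frameshift_window Persistence window F in codons: an out-of-frame
#'   stretch restored by a compensating indel within fewer than F codons is
#'   not a lesion.
#' @param truncation_fraction Minimum fraction T of reference codons a
#'   terminal deletion must cover to count as a truncation.
#' @param terminal_stop_tolerance A premature stop within this final
#'   fraction of codons yields status `intact` with a warning.
#' @param scores Alignment scores passed to [pairwise_align_nt()].
#' @return A one-row tibble: `gene`, `taxon`, `status` (`intact`,
#'   `pseudogene`, `absent`), `lesion_kind` (`frameshift`,
#'   `premature_stop`, `truncation`, `none`), `first_lesion_codon`
#'   (1-based or `NA`), `intact_fraction`.
#' @export
scan_gene <- function(ref_cds, query_seq, gene = NA_character_,
                      taxon = NA_character_, frameshift_window = 10,
                      truncation_fraction = 0.05,
                      terminal_stop_tolerance = 0.05,
                      scores = default_nt_scores) {
  if (!is_translatable(ref_cds)) {
    stop("reference CDS is not translatable full-length", call. = FALSE)
  }
  call_row <- function(status, kind, codon, fraction) {
    tibble::tibble(gene = gene, taxon = taxon, status = status,
                   lesion_kind = kind, first_lesion_codon = codon,
                   intact_fraction = fraction)
  }
  if (is.na(query_seq) || nchar(degap(query_seq)) == 0L) {
    return(call_row("absent", "none", NA_integer_, 0))
  }
  query_seq <- degap(query_seq)
  n_codons <- nchar(ref_cds) %/% 3L

  pw <- scan_alignment(ref_cds, query_seq, scores = scores)
  ra <- strsplit(pw$ref, "")[[1]]
  qa <- strsplit(pw$query, "")[[1]]
  ncol_aln <- length(ra)
  ref_pos <- cumsum(ra != "-")            # 0 before first ref nt
  codon_of <- function(p) (as.integer(p) - 1L) %/% 3L + 1L

  events <- list()
  add_event <- function(kind, codon, priority) {
    events[[length(events) + 1L]] <<- list(kind = kind, codon = codon,
                                           priority = priority)
  }

  ## terminal deletion runs (query gap against reference)
  del <- qa == "-" & ra != "-"
  lead_len <- 0L
  for (j in seq_len(ncol_aln)) {
    if (qa[j] != "-") break
    if (del[j]) lead_len <- lead_len + 1L
  }
  trail_start <- ncol_aln + 1L
  for (j in rev(seq_len(ncol_aln))) {
    if (qa[j] != "-") break
    trail_start <- j
  }
  walk_from <- 1L
  walk_to <- ncol_aln
  if (lead_len > 0L) {
    covered <- codon_of(ref_pos[lead_len])     # codons 1..covered touched
    if (covered / n_codons >= truncation_fraction) {
      add_event("truncation", 1L, 3)
      walk_from <- lead_len + 1L
    }
    ## shorter leading deletions stay in the frameshift walk: a 1-2 bp
    ## 5' deletion shifts the whole downstream frame
  }
  if (trail_start <= ncol_aln) {
    p0 <- ref_pos[trail_start]
    if (ra[trail_start] == "-") p0 <- p0 + 1L  # first deleted ref nt
    if (p0 <= nchar(ref_cds)) {
      c0 <- codon_of(p0)
      covered <- n_codons - c0 + 1L
      if (covered / n_codons >= truncation_fraction) {
        add_event("truncation", c0, 3)
      }
    }
    walk_to <- trail_start - 1L
  }

  ## frameshift: cumulative net indel length in the walked interior
  net <- 0L
  fs_open_codon <- NA_integer_
  fs_open <- FALSE
  for (j in seq.int(walk_from, length.out = max(0L, walk_to - walk_from + 1L))) {
    if (ra[j] == "-" && qa[j] != "-") net <- net + 1L
    if (ra[j] != "-" && qa[j] == "-") net <- net - 1L
    if (!fs_open && net %% 3L != 0L) {
      fs_open <- TRUE
      fs_open_codon <- codon_of(max(1L, ref_pos[j]))
      if (ra[j] == "-") fs_open_codon <- codon_of(ref_pos[j] + 1L)
    } else if (fs_open && net %% 3L == 0L) {
      close_codon <- codon_of(max(1L, ref_pos[j]))
      if (close_codon - fs_open_codon >= frameshift_window) {
        add_event("frameshift", fs_open_codon, 1)
      }
      fs_open <- FALSE
    }
  }
  if (fs_open) add_event("frameshift", fs_open_codon, 1)

  ## premature stops, read in the current reading frame of the query:
  ## only checked at reference codons whose start is frame-balanced
  net_before <- integer(ncol_aln + 1L)     # net indels before column j
  net <- 0L
  for (j in seq_len(ncol_aln)) {
    net_before[j] <- net
    if (ra[j] == "-" && qa[j] != "-") net <- net + 1L
    if (ra[j] != "-" && qa[j] == "-") net <- net - 1L
  }
  net_before[ncol_aln + 1L] <- net
  ref_cols <- which(ra != "-")             # column of ref nt p
  for (cd in seq_len(n_codons - 1L)) {     # terminal codon never a lesion
    p1 <- (cd - 1L) * 3L + 1L
    cols <- ref_cols[p1:(p1 + 2L)]
    if (net_before[cols[1]] %% 3L != 0L) next
    qcod <- qa[cols]
    if (any(qcod == "-")) next
    if (paste(qcod, collapse = "") %in% STOP_CODONS) {
      if (cd > (1 - terminal_stop_tolerance) * n_codons) {
        warning("stop codon in final ", terminal_stop_tolerance * 100,
                "% of ", gene, "/", taxon, " tolerated", call. = FALSE)
      } else {
        add_event("premature_stop", cd, 2)
      }
    }
  }

  if (length(events) == 0L) {
    return(call_row("intact", "none", NA_integer_, 1))
  }
  ev <- dplyr::bind_rows(lapply(events, tibble::as_tibble))
  ev <- ev[order(ev$codon, ev$priority), ]
  first <- ev[1, ]
  call_row("pseudogene", first$kind, as.integer(first$codon),
           (first$codon - 1) / n_codons)
}

#' Scan all (gene, taxon) pairs of a gene set
#'
#' @param gene_seqs Tibble with columns `gene`, `taxon`, `residues`
#'   (unaligned CDS; empty string = absent).
#' @param ref_taxon Taxon id whose sequences serve as references. When
#'   `NULL`, the first taxon with a translatable copy of each gene is used.
#' @param ... Passed to [scan_gene()].
#' @return A tibble of calls, one row per (gene, taxon), reference rows
#'   included as `intact`.
#' @export
scan_gene_set <- function(gene_seqs, ref_taxon = NULL, ...) {
  stopifnot(all(c("gene", "taxon", "residues") %in% names(gene_seqs)))
  out <- list()
  for (g in unique(gene_seqs$gene)) {
    sub <- gene_seqs[gene_seqs$gene == g, ]
    ref_id <- ref_taxon
    if (is.null(ref_id)) {
      ok <- vapply(sub$residues, is_translatable, logical(1))
      if (!any(ok)) {
        warning("gene ", g, ": no translatable reference; all rows absent",
                call. = FALSE)
        out[[g]] <- tibble::tibble(gene = g, taxon = sub$taxon,
                                   status = "absent", lesion_kind = "none",
                                   first_lesion_codon = NA_integer_,
                                   intact_fraction = 0)
        next
      }
      ref_id <- sub$taxon[which(ok)[1]]
    }
    ref_cds <- sub$residues[sub$taxon == ref_id]
    if (length(ref_cds) != 1L) {
      stop("reference taxon ", ref_id, " not present once for gene ", g,
           call. = FALSE)
    }
    out[[g]] <- dplyr::bind_rows(lapply(seq_len(nrow(sub)), function(i) {
      scan_gene(ref_cds, sub$residues[i], gene = g, taxon = sub$taxon[i],
                ...)
    }))
  }
  dplyr::bind_rows(out)
}

#' Categorize calls into the gene-by-taxon status matrix
#'
#' Categories mirror the heatmap shading convention: `absent` (darkest),
#' `pseudo_severe` (intact fraction < 0.25), `pseudo_moderate`
#' (0.25-0.75), `pseudo_mild` (> 0.75), `intact`.
#'
#' @param calls Tibble of calls from [scan_gene_set()].
#' @param wide If `TRUE` (default) return a wide tibble (gene rows, one
#'   column per taxon); otherwise long with a `category` column.
#' @return A tibble; missing (gene, taxon) cells are `absent`.
#' @export
build_status_matrix <- function(calls, wide = TRUE) {
  if (anyDuplicated(calls[, c("gene", "taxon")])) {
    stop("duplicate (gene, taxon) call", call. = FALSE)
  }
  long <- calls |>
    dplyr::mutate(category = status_category(.data$status,
                                             .data$intact_fraction)) |>
    dplyr::select("gene", "taxon", "category") |>
    tidyr::complete(gene = unique(calls$gene), taxon = unique(calls$taxon),
                    fill = list(category = "absent"))
  if (!wide) return(long)
  tidyr::pivot_wider(long, names_from = "taxon", values_from = "category")
}

status_category <- function(status, intact_fraction) {
  dplyr::case_when(
    status == "absent" ~ "absent",
    status == "intact" ~ "intact",
    intact_fraction < 0.25 ~ "pseudo_severe",
    intact_fraction <= 0.75 ~ "pseudo_moderate",
    TRUE ~ "pseudo_mild"
  )
}

#' Mask non-intact rows of gene alignments with gaps
#'
#' Rows whose call status is not `intact` are replaced by all-gap rows of
#' the same length, so pseudogenized copies contribute no signal to
#' downstream rate and selection analyses.
#'
#' @param gene_alignments A named list of [gene_alignment()] objects (names
#'   = genes), or a single `gene_alignment`.
#' @param calls Tibble of calls with `gene`, `taxon`, `status` covering
#'   every alignment row.
#' @return Masked alignments of the same shape as the input.
#' @export
mask_pseudogenes <- function(gene_alignments, calls) {
  single <- inherits(gene_alignments, "gene_alignment")
  alns <- if (single) {
    stats::setNames(list(gene_alignments), gene_alignments$gene)
  } else {
    gene_alignments
  }
  out <- lapply(names(alns), function(g) {
    aln <- alns[[g]]
    sub <- calls[calls$gene == g, ]
    st <- stats::setNames(sub$status, sub$taxon)
    missing <- setdiff(names(aln$seqs), names(st))
    if (length(missing)) {
      stop("no call for ", g, " / ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    width <- nchar(aln$seqs[1])
    gap_row <- strrep("-", width)
    seqs <- aln$seqs
    bad <- names(seqs)[st[names(seqs)] != "intact"]
    seqs[bad] <- gap_row
    gene_alignment(seqs, gene = aln$gene, anchor = aln$anchor)
  })
  names(out) <- names(alns)
  if (single) out[[1]] else out
}
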