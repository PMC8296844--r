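#' Read a FASTA file into a sequence tibble
#'
#' Residues are upper-cased, `U` is mapped to `T`, and ambiguity codes other
#' than `N` are mapped to `N` with a warning. Gap characters (`-`) are kept,
#' so aligned FASTA round-trips.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `description`, `residues`, one row
#'   per record in input order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) {
    stop("FASTA parse error at line 1: empty file ", path, call. = FALSE)
  }
  if (!startsWith(trimws(lines[nonempty[1]]), ">")) {
    stop("FASTA parse error at line ", nonempty[1],
         ": expected '>' header in ", path, call. = FALSE)
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  if (any(!nzchar(id))) {
    stop("FASTA parse error: empty record id in ", path, call. = FALSE)
  }
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  residues <- unname(normalize_residues(as.character(set)))
  tibble::tibble(id = id, description = description, residues = residues)
}

normalize_residues <- function(x) {
  x <- toupper(x)
  x <- gsub("U", "T", x, fixed = TRUE)
  bad <- grepl("[^ACGTN-]", x)
  if (any(bad)) {
    warning("ambiguity codes other than N mapped to N in ",
            sum(bad), " sequence(s)", call. = FALSE)
    x[bad] <- gsub("[^ACGTN-]", "N", x[bad])
  }
  x
}

#' Write a sequence tibble to FASTA
#'
#' @param seqs A tibble with columns `id` and `residues` (optionally
#'   `description`), or a named character vector.
#' @param path Output path.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  seqs <- as_seq_tbl(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(seqs))) {
    hdr <- seqs$id[i]
    if (!is.null(seqs$description) && nzchar(seqs$description[i])) {
      hdr <- paste(hdr, seqs$description[i])
    }
    writeLines(paste0(">", hdr), con)
    s <- seqs$residues[i]
    if (nchar(s) == 0L) next
    starts <- seq.int(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Coerce to the canonical sequence tibble
#'
#' @param x A tibble with `id`/`residues`, a named character vector, or a
#'   `Biostrings::XStringSet`.
#' @return A tibble with columns `id`, `description`, `residues`.
#' @export
as_seq_tbl <- function(x) {
  if (inherits(x, "XStringSet")) {
    x <- stats::setNames(as.character(x), names(x))
  }
  if (is.character(x)) {
    if (is.null(names(x))) stop("sequences must be named", call. = FALSE)
    return(tibble::tibble(id = names(x), description = "",
                          residues = normalize_residues(unname(x))))
  }
  if (is.data.frame(x)) {
    stopifnot(all(c("id", "residues") %in% names(x)))
    out <- tibble::as_tibble(x)
    if (is.null(out$description)) out$description <- ""
    return(out[, c("id", "description", "residues"),
               drop = FALSE] |> tibble::as_tibble())
  }
  stop("cannot coerce to sequence tibble", call. = FALSE)
}

seq_named <- function(seqs) {
  seqs <- as_seq_tbl(seqs)
  stats::setNames(seqs$residues, seqs$id)
}

#' Parse a Newick string into an `ape::phylo` tree
#'
#' @param text A Newick string.
#' @return A `phylo` object; leaf labels must be unique and branch lengths,
#'   when present, non-negative.
#' @export
parse_newick <- function(text) {
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop("Newick parse error: ", substr(text, 1, 60), call. = FALSE)
  }
  if (anyDuplicated(tr$tip.label)) {
    stop("Newick parse error: duplicate leaf labels", call. = FALSE)
  }
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0)) {
    stop("negative branch length in tree", call. = FALSE)
  }
  tr
}

#' Read a Newick tree file
#' @param path Path to a Newick file.
#' @return A `phylo` object.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  parse_newick(paste(readLines(path, warn = FALSE), collapse = ""))
}

#' Write a tree in Newick format
#' @param tree A `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

## ---- GenBank flat files ----------------------------------------------------
## Minimal LOCUS/FEATURES/ORIGIN parser, sufficient for CDS extraction.
## GenBank feature coordinates are 1-based inclusive; they are kept 1-based
## inclusive internally (the R substring convention) and reported 1-based.

#' Parse a GenBank flat file (CDS subset)
#'
#' Reads the LOCUS name, the ORIGIN sequence, and all CDS features with
#' their location (including `complement()` and `join()` forms) and
#' `/gene` and `/pseudo` qualifiers.
#'
#' @param path Path to a GenBank flat file.
#' @return A list with `accession`, `sequence` (upper-cased string) and
#'   `features`, a tibble with one row per CDS segment: `gene`, `start`,
#'   `end` (1-based inclusive), `strand` (`+`/`-`), `segment` (order within
#'   the feature), `pseudo` (logical), `feature_id`.
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  locus_line <- grep("^LOCUS", lines, value = TRUE)
  accession <- if (length(locus_line)) {
    strsplit(trimws(locus_line[1]), "\\s+")[[1]][2]
  } else {
    basename(path)
  }

  ## ORIGIN sequence
  o <- grep("^ORIGIN", lines)
  if (length(o) == 0L) stop("GenBank parse error: no ORIGIN in ", path,
                            call. = FALSE)
  seq_lines <- lines[(o[1] + 1):length(lines)]
  stop_at <- grep("^//", seq_lines)
  if (length(stop_at)) seq_lines <- seq_lines[seq_len(stop_at[1] - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  sequence <- normalize_residues(sequence)

  ## FEATURES table
  f <- grep("^FEATURES", lines)
  feats <- list()
  if (length(f)) {
    body <- lines[(f[1] + 1):(o[1] - 1L)]
    key_idx <- grep("^ {5}\\S", body)
    for (k in seq_along(key_idx)) {
      i0 <- key_idx[k]
      i1 <- if (k < length(key_idx)) key_idx[k + 1] - 1L else length(body)
      block <- body[i0:i1]
      key <- strsplit(trimws(block[1]), "\\s+")[[1]][1]
      if (key != "CDS") next
      ## location may continue over lines until the first qualifier
      qual_start <- grep("^ {21}/", block)
      loc_end <- if (length(qual_start)) qual_start[1] - 1L else length(block)
      loc <- paste(trimws(sub("^ {5}\\S+\\s*", "", block[1])),
                   paste(trimws(block[seq_len(loc_end)[-1]]), collapse = ""),
                   sep = "")
      loc <- gsub("\\s", "", loc)
      quals <- trimws(block[seq_along(block) > loc_end])
      gene <- NA_character_
      gm <- grep("^/gene=", quals, value = TRUE)
      if (length(gm)) gene <- gsub("\"", "", sub("^/gene=", "", gm[1]))
      pseudo <- any(grepl("^/pseudo\\b", quals))
      feats[[length(feats) + 1L]] <- list(gene = gene, loc = loc,
                                          pseudo = pseudo)
    }
  }
  seg_rows <- list()
  for (fi in seq_along(feats)) {
    segs <- tryCatch(parse_location(feats[[fi]]$loc),
                     error = function(e) {
                       warning("skipping unparseable CDS location: ",
                               feats[[fi]]$loc, call. = FALSE)
                       NULL
                     })
    if (is.null(segs)) next
    segs$gene <- feats[[fi]]$gene
    segs$pseudo <- feats[[fi]]$pseudo
    segs$feature_id <- fi
    seg_rows[[length(seg_rows) + 1L]] <- segs
  }
  features <- if (length(seg_rows)) {
    dplyr::bind_rows(seg_rows)[, c("gene", "start", "end", "strand",
                                   "segment", "pseudo", "feature_id")]
  } else {
    tibble::tibble(gene = character(), start = integer(), end = integer(),
                   strand = character(), segment = integer(),
                   pseudo = logical(), feature_id = integer())
  }
  list(accession = accession, sequence = sequence, features = features)
}

## Parse a GenBank location string into segments in feature order.
## Supports n..m, complement(...), join(...), nested combinations, and
## partial markers (< >, stripped). Multi-locus joins are not supported.
parse_location <- function(loc, complement = FALSE) {
  loc <- gsub("[<>]", "", loc)
  if (grepl("^complement\\(", loc)) {
    inner <- sub("^complement\\((.*)\\)$", "\\1", loc)
    return(parse_location(inner, complement = !complement))
  }
  if (grepl("^join\\(", loc) || grepl("^order\\(", loc)) {
    inner <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
    parts <- split_toplevel(inner)
    segs <- dplyr::bind_rows(lapply(parts, parse_location,
                                    complement = complement))
    ## complement(join(a,b)) means reverse-complement of the whole join:
    ## splice order is reversed
    if (complement) segs <- segs[rev(seq_len(nrow(segs))), ]
    segs$segment <- seq_len(nrow(segs))
    return(segs)
  }
  m <- regmatches(loc, regexec("^([0-9]+)(\\.\\.([0-9]+))?$", loc))[[1]]
  if (length(m) == 0L || !nzchar(m[2])) {
    stop("unsupported location: ", loc, call. = FALSE)
  }
  start <- as.integer(m[2])
  end <- if (nzchar(m[4])) as.integer(m[4]) else start
  if (start > end) stop("coordinate error: start > end in ", loc,
                        call. = FALSE)
  tibble::tibble(start = start, end = end,
                 strand = if (complement) "-" else "+", segment = 1L)
}

split_toplevel <- function(x) {
  depth <- 0L
  parts <- character(0)
  cur <- ""
  for (ch in strsplit(x, "")[[1]]) {
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") depth <- depth - 1L
    if (ch == "," && depth == 0L) {
      parts <- c(parts, cur)
      cur <- ""
    } else {
      cur <- paste0(cur, ch)
    }
  }
  c(parts, cur)
}

#' Extract spliced CDS sequences from a GenBank flat file
#'
#' Segments are spliced in feature order and minus-strand features
#' reverse-complemented. Duplicate features for a gene (inverted-repeat
#' copies) are resolved by taking the first in file order, with a message.
#' The trans-spliced `rps12` gene is skipped (multi-locus joins are not
#' supported). Genes with no feature are returned as explicit absent
#' placeholders (empty residues).
#'
#' @param flatfile Path to a GenBank flat file, or the result of
#'   [read_genbank()].
#' @param wanted_genes Character vector of gene names to extract.
#' @return A tibble with columns `taxon`, `gene`, `residues`, `pseudo_flag`,
#'   `present`.
#' @export
extract_cds <- function(flatfile, wanted_genes) {
  gb <- if (is.character(flatfile)) read_genbank(flatfile) else flatfile
  seqlen <- nchar(gb$sequence)
  out <- vector("list", length(wanted_genes))
  for (gi in seq_along(wanted_genes)) {
    g <- wanted_genes[gi]
    if (identical(g, "rps12")) {
      message("skipping trans-spliced gene rps12 (unsupported)")
      out[[gi]] <- tibble::tibble(taxon = gb$accession, gene = g,
                                  residues = "", pseudo_flag = FALSE,
                                  present = FALSE)
      next
    }
    feat <- gb$features[!is.na(gb$features$gene) & gb$features$gene == g, ]
    if (nrow(feat) == 0L) {
      out[[gi]] <- tibble::tibble(taxon = gb$accession, gene = g,
                                  residues = "", pseudo_flag = FALSE,
                                  present = FALSE)
      next
    }
    ids <- unique(feat$feature_id)
    if (length(ids) > 1L) {
      message("gene ", g, ": ", length(ids),
              " features found, using the first (IR duplicate?)")
    }
    feat <- feat[feat$feature_id == ids[1], ]
    feat <- feat[order(feat$segment), ]
    if (any(feat$end > seqlen)) {
      stop("coordinate error: segment of gene ", g,
           " exceeds sequence length", call. = FALSE)
    }
    pieces <- character(nrow(feat))
    for (si in seq_len(nrow(feat))) {
      piece <- substr(gb$sequence, feat$start[si], feat$end[si])
      if (feat$strand[si] == "-") piece <- revcomp(piece)
      pieces[si] <- piece
    }
    out[[gi]] <- tibble::tibble(taxon = gb$accession, gene = g,
                                residues = paste(pieces, collapse = ""),
                                pseudo_flag = feat$pseudo[1], present = TRUE)
  }
  dplyr::bind_rows(out)
}

#' Reverse-complement a nucleotide string
#'
#' Gap and N characters are preserved.
#' @param x A nucleotide string.
#' @return The reverse complement.
#' @export
revcomp <- function(x) {
  if (nchar(x) == 0L) return(x)
  chartr("ACGTN-", "TGCAN-",
         paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

#' Write a tibble as TSV
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_file <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV with a header row
#' @param path Input path.
#' @return A tibble.
#' @export
read_tsv_file <- function(path) {
  tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                      stringsAsFactors = FALSE,
                                      check.names = FALSE))
}
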