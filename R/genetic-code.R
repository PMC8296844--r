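## Plastid protein-coding genes use the bacterial/plastid genetic code
## (translation table 11). All codon-level machinery below is built on it.

.pl_cache <- new.env(parent = emptyenv())

NUCS <- c("A", "C", "G", "T")

#' Codon table under the bacterial/plastid genetic code
#'
#' Returns the 64 codons in lexicographic (A < C < G < T) order, their
#' amino-acid translation under translation table 11, and the index set of
#' the 61 sense codons. Cached after first call.
#'
#' @return A list with elements `codons` (character, length 64), `aa`
#'   (named character, `*` for stops), `sense` (integer indices into
#'   `codons`), `sense_codons` (character, length 61).
#' @export
codon_table <- function() {
  if (!is.null(.pl_cache$codon_table)) return(.pl_cache$codon_table)
  grid <- expand.grid(p3 = NUCS, p2 = NUCS, p1 = NUCS,
                      stringsAsFactors = FALSE)
  codons <- sort(paste0(grid$p1, grid$p2, grid$p3))
  gc11 <- Biostrings::getGeneticCode("11")
  aa <- unname(gc11[codons])
  names(aa) <- codons
  sense <- which(aa != "*")
  out <- list(codons = codons, aa = aa, sense = sense,
              sense_codons = codons[sense])
  .pl_cache$codon_table <- out
  out
}

codon_index <- function(codon) {
  ct <- codon_table()
  match(codon, ct$codons)
}

#' Split a nucleotide string into codons
#'
#' @param seq A nucleotide string; length must be divisible by 3.
#' @return Character vector of codons.
#' @keywords internal
split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3", call. = FALSE)
  if (n == 0L) return(character(0))
  starts <- seq.int(1L, n, by = 3L)
  substring(seq, starts, starts + 2L)
}

is_transition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
}

#' Nei-Gojobori synonymous/nonsynonymous site counts for one codon
#'
#' For each of the three codon positions the three single-base mutants are
#' enumerated; mutants creating a stop codon are discarded (not
#' renormalized, so S + N < 3 for codons with stop neighbours). The
#' synonymous fraction at a position is the number of synonymous non-stop
#' mutants divided by 3.
#'
#' @param codon A 3-letter codon over A/C/G/T.
#' @return A named numeric vector `c(S = ..., N = ...)`, or `c(S = NA, N =
#'   NA)` for stop or ambiguous codons.
#' @export
#' @examples
#' ng_site_counts("TTT")  # S = 1/3, N = 8/3
ng_site_counts <- function(codon) {
  ct <- codon_table()
  codon <- toupper(codon)
  if (!codon %in% ct$sense_codons) return(c(S = NA_real_, N = NA_real_))
  aa0 <- ct$aa[[codon]]
  chars <- strsplit(codon, "")[[1]]
  S <- 0; N <- 0
  for (pos in 1:3) {
    for (nt in setdiff(NUCS, chars[pos])) {
      mut <- chars
      mut[pos] <- nt
      mcod <- paste(mut, collapse = "")
      maa <- ct$aa[[mcod]]
      if (maa == "*") next
      if (maa == aa0) S <- S + 1 / 3 else N <- N + 1 / 3
    }
  }
  c(S = S, N = N)
}

## Pathway-averaged per-pair synonymous/nonsynonymous difference tables over
## the 61 sense codons. For codon pairs differing at k positions, all k!
## orderings of single-base steps are enumerated; orderings passing through a
## stop intermediate are dropped (equal weights over the stop-free ones).
## In the rare case that every ordering hits a stop, all orderings are used.
ng_tables <- function() {
  if (!is.null(.pl_cache$ng_tables)) return(.pl_cache$ng_tables)
  ct <- codon_table()
  n <- length(ct$sense_codons)
  SD <- matrix(0, n, n, dimnames = list(ct$sense_codons, ct$sense_codons))
  ND <- SD
  TS <- SD  # transition steps (for kappa estimation), pathway-averaged
  chars <- strsplit(ct$sense_codons, "")
  aa <- ct$aa
  for (i in seq_len(n)) {
    ci <- chars[[i]]
    for (j in seq_len(n)) {
      if (i == j) next
      cj <- chars[[j]]
      diff_pos <- which(ci != cj)
      k <- length(diff_pos)
      if (k == 0L) next
      perms <- all_perms(diff_pos)
      path_sd <- numeric(0); path_nd <- numeric(0); path_ts <- numeric(0)
      ok_sd <- numeric(0); ok_nd <- numeric(0); ok_ts <- numeric(0)
      for (p in perms) {
        cur <- ci
        sd <- 0; nd <- 0; ts <- 0; blocked <- FALSE
        for (pos in p) {
          nxt <- cur
          nxt[pos] <- cj[pos]
          a1 <- aa[[paste(cur, collapse = "")]]
          a2 <- aa[[paste(nxt, collapse = "")]]
          if (is_transition(cur[pos], nxt[pos])) ts <- ts + 1
          if (a2 == "*") blocked <- TRUE
          if (a1 == a2) sd <- sd + 1 else nd <- nd + 1
          cur <- nxt
        }
        path_sd <- c(path_sd, sd); path_nd <- c(path_nd, nd)
        path_ts <- c(path_ts, ts)
        if (!blocked) {
          ok_sd <- c(ok_sd, sd); ok_nd <- c(ok_nd, nd); ok_ts <- c(ok_ts, ts)
        }
      }
      if (length(ok_sd) > 0) {
        SD[i, j] <- mean(ok_sd); ND[i, j] <- mean(ok_nd)
        TS[i, j] <- mean(ok_ts)
      } else {
        SD[i, j] <- mean(path_sd); ND[i, j] <- mean(path_nd)
        TS[i, j] <- mean(path_ts)
      }
    }
  }
  sn <- vapply(ct$sense_codons, ng_site_counts, numeric(2))
  out <- list(SD = SD, ND = ND, TS = TS,
              S_site = sn["S", ], N_site = sn["N", ])
  .pl_cache$ng_tables <- out
  out
}

all_perms <- function(x) {
  if (length(x) == 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in all_perms(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}
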