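test_that("translation follows table 11 and renders stops/ambiguity", {
  expect_equal(translate_cds("ATGAAATAA"), "MK*")
  expect_equal(translate_cds("ATGTAAAAA"), "M*K")
  expect_equal(translate_cds("ATGNNNAAA"), "MXK")
  expect_error(translate_cds("ATGAA"), "frame error")
  expect_equal(translate_cds("ATGAA", allow_trailing = TRUE), "M")
})

test_that("pairwise alignment is optimal against brute-force enumeration", {
  scores <- c(match = 2, mismatch = -3, gap_open = -5, gap_extend = -2)
  score_pair <- function(a, b) {
    ## score an explicit gapped pair under affine costs
    av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
    s <- 0; in_gap_a <- FALSE; in_gap_b <- FALSE
    for (i in seq_along(av)) {
      if (av[i] == "-") {
        s <- s + scores["gap_extend"] + if (!in_gap_a) scores["gap_open"] else 0
        in_gap_a <- TRUE; in_gap_b <- FALSE
      } else if (bv[i] == "-") {
        s <- s + scores["gap_extend"] + if (!in_gap_b) scores["gap_open"] else 0
        in_gap_b <- TRUE; in_gap_a <- FALSE
      } else {
        s <- s + if (av[i] == bv[i]) scores["match"] else scores["mismatch"]
        in_gap_a <- FALSE; in_gap_b <- FALSE
      }
    }
    unname(s)
  }
  ## enumerate all global alignments of two short strings recursively
  best_score <- function(a, b) {
    rec <- function(i, j, arow, brow) {
      if (i > nchar(a) && j > nchar(b)) return(score_pair(arow, brow))
      out <- -Inf
      if (i <= nchar(a)) {
        out <- max(out, rec(i + 1, j, paste0(arow, substr(a, i, i)),
                            paste0(brow, "-")))
      }
      if (j <= nchar(b)) {
        out <- max(out, rec(i, j + 1, paste0(arow, "-"),
                            paste0(brow, substr(b, j, j))))
      }
      if (i <= nchar(a) && j <= nchar(b)) {
        out <- max(out, rec(i + 1, j + 1, paste0(arow, substr(a, i, i)),
                            paste0(brow, substr(b, j, j))))
      }
      out
    }
    rec(1, 1, "", "")
  }
  cases <- list(c("ACGT", "ACGT"), c("ACGT", "AGT"), c("AAA", "TTT"),
                c("ACGTA", "ACTA"), c("GATTA", "GCAT"))
  for (cs in cases) {
    pw <- pairwise_align_nt(cs[1], cs[2], scores)
    expect_equal(pw$score, best_score(cs[1], cs[2]),
                 info = paste(cs, collapse = " vs "))
    ## aligned strings reproduce the reported score
    expect_equal(score_pair(pw$ref, pw$query), pw$score)
  }
  expect_equal(pairwise_align_nt("ACGT", "ACGT")$score, 8)
  expect_error(pairwise_align_nt("", "ACGT"), "empty")
  ## score is symmetric in the input order
  expect_equal(pairwise_align_nt("GATTA", "GCAT")$score,
               pairwise_align_nt("GCAT", "GATTA")$score)
})

test_that("codon alignment back-translates cleanly and keeps frame", {
  ref <- "ATGAAATTTCCCGGGTAA"
  ident <- align_codon(c(a = ref, b = ref), gene = "g")
  expect_equal(unname(ident$seqs["a"]), ref)
  expect_equal(unname(ident$seqs["b"]), ref)

  ## clean 3-bp deletion -> one 3-nt gap at a codon boundary
  del3 <- paste0(substr(ref, 1, 6), substr(ref, 10, 18))
  aln <- align_codon(c(a = ref, b = del3))
  expect_equal(nchar(aln$seqs[["a"]]), 18)
  expect_match(unname(aln$seqs["b"]), "^[ACGT]{6}---[ACGT]{9}$")

  ## 1-bp deletion -> non-triplet gap, input residues preserved
  del1 <- paste0(substr(ref, 1, 7), substr(ref, 9, 18))
  aln2 <- align_codon(c(a = ref, b = del1))
  gaps <- gregexpr("-+", aln2$seqs["b"])[[1]]
  expect_true(any(attr(gaps, "match.length") %% 3 != 0))
  expect_equal(degap(unname(aln2$seqs["b"])), del1)
  expect_equal(degap(unname(aln2$seqs["a"])), ref)
})

test_that("alignment requires a translatable anchor and >= 2 records", {
  expect_error(align_codon(c(a = "ATGAA")), "at least 2")
  expect_error(align_codon(c(a = "ATGTAGAAATAA", b = "ATGTAGAAATAA")),
               "anchor")
})

test_that("degapping any aligned row recovers the input sequence", {
  tr <- rand_tree(6, L = 1.5, seed = 11)
  sa <- sim_alignment(tr, 40, seed = 5)
  inputs <- degap(sa$aln$seqs)
  ## perturb one row with a 2-bp deletion to force nt-level alignment
  inputs["t03"] <- paste0(substr(inputs["t03"], 1, 10),
                          substr(inputs["t03"], 13, nchar(inputs["t03"])))
  aln <- suppressWarnings(align_codon(inputs))
  for (id in names(inputs)) {
    expect_equal(degap(unname(aln$seqs[id])), unname(inputs[id]))
  }
  expect_equal(length(unique(nchar(aln$seqs))), 1L)
})
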