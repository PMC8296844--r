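ref12 <- "ATGAAATTTTAA"  # MKF*

test_that("scanner classifies the canonical toy cases", {
  expect_equal(scan_gene(ref12, ref12)$status, "intact")
  expect_equal(scan_gene(ref12, ref12)$intact_fraction, 1)

  stop2 <- scan_gene(ref12, "ATGTAATTTTAA")
  expect_equal(stop2$status, "pseudogene")
  expect_equal(stop2$lesion_kind, "premature_stop")
  expect_equal(stop2$first_lesion_codon, 2L)

  absent <- scan_gene(ref12, "")
  expect_equal(absent$status, "absent")
  expect_equal(absent$intact_fraction, 0)

  fs <- scan_gene(ref12, "ATGAATTTTAA")  # one A of codon 2 deleted
  expect_equal(fs$lesion_kind, "frameshift")
  expect_equal(fs$first_lesion_codon, 2L)
})

test_that("compensated frameshifts within the persistence window are intact", {
  ## 30-codon reference; +1 bp inserted in codon 5, -1 bp in codon 7
  ref <- paste0("ATG", strrep("GAAGCTTTC", 9), "CTT", "TAA")
  expect_true(is_translatable_ref <- nchar(ref) %% 3 == 0)
  q <- paste0(substr(ref, 1, 13), "T", substr(ref, 14, nchar(ref)))  # +1
  q <- paste0(substr(q, 1, 20), substr(q, 22, nchar(q)))             # -1
  call <- scan_gene(ref, q)
  expect_equal(call$status, "intact")

  ## the same insertion left uncompensated is a frameshift
  q2 <- paste0(substr(ref, 1, 13), "T", substr(ref, 14, nchar(ref)))
  call2 <- scan_gene(ref, q2)
  expect_equal(call2$lesion_kind, "frameshift")
  expect_equal(call2$first_lesion_codon, 5L)
})

test_that("terminal deletions are truncations; short ones are tolerated", {
  ref <- paste0("ATG", strrep("GAAGCTTTC", 20), "TAA")  # 62 codons
  n_codons <- nchar(ref) / 3
  ## remove the last 30 codons
  q <- substr(ref, 1, nchar(ref) - 90)
  call <- scan_gene(ref, q)
  expect_equal(call$lesion_kind, "truncation")
  expect_equal(call$first_lesion_codon, as.integer(n_codons - 30 + 1))
  expect_lt(abs(call$intact_fraction - (n_codons - 30) / n_codons), 1e-9)

  ## deleting only the last codon (< 5% of the gene) is tolerated
  q2 <- substr(ref, 1, nchar(ref) - 3)
  expect_equal(scan_gene(ref, q2)$status, "intact")

  ## a missing start region is a truncation at codon 1
  q3 <- substr(ref, 31, nchar(ref))
  call3 <- scan_gene(ref, q3)
  expect_equal(call3$lesion_kind, "truncation")
  expect_equal(call3$first_lesion_codon, 1L)
})

test_that("a stop in the final 5% of codons is tolerated with a warning", {
  ref <- paste0("ATG", strrep("GAAGCTTTC", 20), "TAA")  # 62 codons
  ## plant a stop at codon 61 (> 95% of 62)
  q <- ref
  substr(q, 181, 183) <- "TAA"
  expect_warning(call <- scan_gene(ref, q), "tolerated")
  expect_equal(call$status, "intact")
})

test_that("status matrix categories follow the intact-fraction thresholds", {
  calls <- tibble::tibble(
    gene = "g1", taxon = c("t1", "t2", "t3", "t4", "t5"),
    status = c("intact", "pseudogene", "pseudogene", "pseudogene",
               "absent"),
    lesion_kind = c("none", "premature_stop", "premature_stop",
                    "premature_stop", "none"),
    first_lesion_codon = c(NA, 2L, 50L, 90L, NA),
    intact_fraction = c(1, 0.1, 0.5, 0.9, 0))
  long <- build_status_matrix(calls, wide = FALSE)
  got <- stats::setNames(long$category, long$taxon)
  expect_equal(unname(got[c("t1", "t2", "t3", "t4", "t5")]),
               c("intact", "pseudo_severe", "pseudo_moderate",
                 "pseudo_mild", "absent"))
  wide <- build_status_matrix(calls)
  expect_equal(ncol(wide), 6L)  # gene + 5 taxa
  expect_error(build_status_matrix(dplyr::bind_rows(calls, calls[1, ])),
               "duplicate")
})

test_that("missing cells in the grid become absent", {
  calls <- tibble::tibble(gene = c("g1", "g1", "g2"),
                          taxon = c("t1", "t2", "t1"),
                          status = "intact", lesion_kind = "none",
                          first_lesion_codon = NA_integer_,
                          intact_fraction = 1)
  long <- build_status_matrix(calls, wide = FALSE)
  expect_equal(long$category[long$gene == "g2" & long$taxon == "t2"],
               "absent")
})

test_that("masking replaces non-intact rows by all-gap rows", {
  aln <- gene_alignment(c(t1 = "ATGAAA", t2 = "ATGAAA", t3 = "ATGCCC",
                          t4 = "ATGAAA"), gene = "g1", anchor = "t1")
  calls <- tibble::tibble(gene = "g1", taxon = paste0("t", 1:4),
                          status = c("intact", "intact", "pseudogene",
                                     "intact"))
  masked <- mask_pseudogenes(aln, calls)
  expect_equal(unname(masked$seqs["t3"]), "------")
  expect_equal(masked$seqs[c("t1", "t2", "t4")],
               aln$seqs[c("t1", "t2", "t4")])

  all_intact <- calls
  all_intact$status <- "intact"
  expect_equal(mask_pseudogenes(aln, all_intact)$seqs, aln$seqs)
  expect_error(mask_pseudogenes(aln, calls[-1, ]), "no call")
})

test_that("masked rows contribute zero parsimony substitutions", {
  tr <- tree4()
  aln <- gene_alignment(c(A = "ATGAAA", B = "ATGAAA", C = "ATGCCC",
                          D = "ATGAAA"), gene = "g1", anchor = "A")
  calls <- tibble::tibble(gene = "g1", taxon = c("A", "B", "C", "D"),
                          status = c("intact", "intact", "pseudogene",
                                     "intact"))
  masked <- mask_pseudogenes(aln, calls)
  before <- sum(fitch_steps_matrix(tr, aln_matrix(aln)))
  after <- sum(fitch_steps_matrix(tr, aln_matrix(masked)))
  expect_gt(before, 0)
  expect_equal(after, 0)
})

test_that("scan_gene_set picks a translatable reference automatically", {
  tr <- rand_tree(6, L = 1, seed = 3)
  sa <- sim_alignment(tr, 50, seed = 9)
  seqs <- degap(sa$aln$seqs)
  gene_seqs <- tibble::tibble(gene = "gX", taxon = names(seqs),
                              residues = unname(seqs))
  ## break taxon t02 with a premature stop at codon 10
  i <- which(gene_seqs$taxon == "t02")
  s <- gene_seqs$residues[i]
  substr(s, 28, 30) <- "TGA"
  gene_seqs$residues[i] <- s
  calls <- scan_gene_set(gene_seqs)
  expect_equal(nrow(calls), 6L)
  expect_equal(calls$status[calls$taxon == "t02"], "pseudogene")
  expect_equal(calls$first_lesion_codon[calls$taxon == "t02"], 10L)
  expect_true(all(calls$status[calls$taxon != "t02"] == "intact"))
})
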