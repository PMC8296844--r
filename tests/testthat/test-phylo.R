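test_that("Fitch steps match hand cases and handle missing data", {
  tr <- parse_newick("((A,B),(C,D));")
  expect_equal(fitch_steps(tr, c(A = "A", B = "C", C = "A", D = "A")), 1L)
  expect_equal(fitch_steps(tr, c(A = "G", B = "G", C = "G", D = "G")), 0L)
  expect_equal(fitch_steps(tr, c(A = "-", B = "-", C = "-", D = "-")), 0L)
  expect_equal(fitch_steps(tr, c(A = "A", B = "C", C = "G", D = "T")), 3L)
  expect_error(fitch_steps(tr, c(A = "A", B = "C", C = "G")), "absent")
})

test_that("Fitch equals brute-force minimization on random small trees", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(5:6, 1)
    tr <- ape::rtree(n, rooted = TRUE)
    tr$tip.label <- paste0("t", seq_len(n))
    states <- sample(c("A", "C", "G", "T", "-"), n, replace = TRUE,
                     prob = c(0.23, 0.23, 0.23, 0.23, 0.08))
    names(states) <- tr$tip.label
    expect_equal(fitch_steps(tr, states), brute_force_parsimony(tr, states),
                 info = paste("rep", rep))
  }
})

test_that("Fitch agrees with phangorn on random alignments", {
  skip_if_not_installed("phangorn")
  set.seed(7)
  tr <- ape::rtree(8, rooted = TRUE)
  tr$tip.label <- paste0("t", 1:8)
  mat <- matrix(sample(c("a", "c", "g", "t"), 8 * 60, replace = TRUE),
                nrow = 8, dimnames = list(tr$tip.label, NULL))
  pd <- phangorn::phyDat(mat, type = "DNA")
  expect_equal(sum(fitch_steps_matrix(tr, toupper(mat))),
               phangorn::fitch(tr, pd))
})

test_that("JC69 pruning matches the two-taxon closed form", {
  for (t in c(0.01, 0.1, 0.5, 2)) {
    tr <- parse_newick(sprintf("(A:%f,B:%f);", t / 2, t / 2))
    same <- jc69_loglik(tr, c(A = "A", B = "A"))
    diff <- jc69_loglik(tr, c(A = "A", B = "G"))
    expect_equal(same, log(0.25) + log(0.25 + 0.75 * exp(-4 * t / 3)),
                 tolerance = 1e-12)
    expect_equal(diff, log(0.25) + log(0.25 - 0.25 * exp(-4 * t / 3)),
                 tolerance = 1e-12)
  }
  ## missing data contributes nothing
  tr <- parse_newick("(A:0.1,B:0.1);")
  expect_equal(jc69_loglik(tr, c(A = "A", B = "-")), log(0.25))
})

test_that("JC69 likelihood is invariant under re-rooting", {
  tr <- rand_tree(6, L = 1.2, seed = 2)
  sa <- sim_alignment(tr, 40, seed = 3)
  mat <- aln_mat <- plastomics:::aln_matrix(sa$aln)
  ll0 <- jc69_loglik(tr, mat)
  for (node in c(2, 4)) {
    rerooted <- ape::root(tr, outgroup = tr$tip.label[node],
                          resolve.root = TRUE)
    expect_equal(jc69_loglik(rerooted, mat), ll0, tolerance = 1e-8)
  }
})

test_that("JC69 agrees with phangorn::pml", {
  skip_if_not_installed("phangorn")
  tr <- rand_tree(5, L = 1, seed = 8)
  sa <- sim_alignment(tr, 30, seed = 4)
  mat <- plastomics:::aln_matrix(sa$aln)
  pd <- phangorn::phyDat(mat, type = "DNA")
  fit <- phangorn::pml(ape::unroot(tr), pd)
  expect_equal(jc69_loglik(tr, mat), as.numeric(fit$logLik),
               tolerance = 1e-6)
})

test_that("branch-length optimization improves the likelihood", {
  tr <- rand_tree(6, L = 1.5, seed = 5)
  sa <- sim_alignment(tr, 80, seed = 6)
  mat <- plastomics:::aln_matrix(sa$aln)
  noisy <- tr
  set.seed(1)
  noisy$edge.length <- pmax(1e-4, tr$edge.length *
                              exp(stats::rnorm(length(tr$edge.length),
                                               0, 0.5)))
  opt <- optimize_branch_lengths(noisy, mat)
  expect_gt(attr(opt, "loglik"), jc69_loglik(noisy, mat))
  ## adding noise to optimized lengths lowers the likelihood
  jig <- opt
  set.seed(2)
  jig$edge.length <- pmax(1e-4, opt$edge.length *
                            exp(stats::rnorm(length(opt$edge.length),
                                             0, 0.6)))
  expect_lt(jc69_loglik(jig, mat), attr(opt, "loglik"))
})

test_that("gene rate scalers recover simulated multipliers", {
  tr <- rand_tree(8, L = 2, seed = 10)
  a1 <- sim_alignment(tr, 150, seed = 21, rate_multiplier = 0.5)
  a2 <- sim_alignment(tr, 150, seed = 22, rate_multiplier = 2)
  fit <- fit_gene_rates(tr, list(g1 = a1$aln, g2 = a2$aln))
  rates <- tidy(fit)
  ratio <- rates$rate_scaler[2] / rates$rate_scaler[1]
  expect_gt(ratio, 2)        # true ratio is 4; allow generous sampling CI
  expect_lt(ratio, 8)
  expect_equal(mean(rates$relative_rate), 1, tolerance = 1e-9)
  expect_equal(nrow(glance(fit)), 1L)
})

test_that("degenerate gene alignments are flagged", {
  tr <- tree4()
  allgap <- gene_alignment(c(A = "---", B = "---", C = "---", D = "---"),
                           gene = "g")
  row <- fit_gene_rate(tr, allgap)
  expect_true(is.na(row$rate_scaler))
  ident <- gene_alignment(c(A = "ATGATG", B = "ATGATG", C = "ATGATG",
                            D = "ATGATG"), gene = "g")
  row2 <- fit_gene_rate(tr, ident)
  expect_true(row2$no_signal)
})

test_that("concatenation tiles partitions and round-trips per-gene rows", {
  g1 <- gene_alignment(c(A = strrep("ATG", 100), B = strrep("ATG", 100)),
                       gene = "g1")
  g2 <- gene_alignment(c(A = strrep("GCT", 50), B = strrep("GCA", 50)),
                       gene = "g2")
  sm <- concatenate(list(g1 = g1, g2 = g2))
  expect_equal(nchar(sm$alignment[["A"]]), 450)
  expect_equal(sm$partition$start, c(0, 300))
  expect_equal(sm$partition$end, c(300, 450))
  back <- split_supermatrix(sm)
  expect_equal(back$g1$seqs, g1$seqs)
  expect_equal(back$g2$seqs, g2$seqs)
  expect_error(concatenate(list()), "empty")

  ## absent taxa are padded as all-gap rows only when pad = TRUE
  g3 <- gene_alignment(c(A = "ATG"), gene = "g3")
  expect_error(concatenate(list(g1 = g1, g3 = g3), pad = FALSE),
               "missing taxa")
  sm2 <- concatenate(list(g1 = g1, g3 = g3), pad = TRUE)
  expect_equal(substr(sm2$alignment[["B"]], 301, 303), "---")
})
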