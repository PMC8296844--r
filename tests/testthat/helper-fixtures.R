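## Shared fixtures: all built in code at test time.

## a fixed 4-taxon tree with branch lengths
tree4 <- function() parse_newick("((A:0.1,B:0.2):0.05,(C:0.15,D:0.1):0.05);")

## random binary tree with n tips labelled t01..tnn, total length L
rand_tree <- function(n, L = 2, seed = 1) {
  tr <- plastomics:::with_seed(seed, ape::rtree(n, rooted = TRUE))
  tr$tip.label <- sprintf("t%02d", seq_len(n))
  tr$edge.length <- tr$edge.length / sum(tr$edge.length) * L
  tr
}

## named character alignment -> gene_alignment with anchor = first row
sim_alignment <- function(tree, n_codons, omega_classes =
                            tibble::tibble(omega = 1, prop = 1),
                          seed = 1, rate_multiplier = 1, kappa = 2) {
  sim <- simulate_gene(tree, n_codons, omega_classes = omega_classes,
                       rate_multiplier = rate_multiplier, kappa = kappa,
                       seed = seed)
  aln <- gene_alignment(stats::setNames(paste0(sim$seqs, "TAA"),
                                        names(sim$seqs)),
                        gene = "simgene", anchor = names(sim$seqs)[1])
  list(aln = aln, sim = sim)
}

## write a small GenBank flat file; segments given as location string
write_toy_genbank <- function(path, sequence, cds_list, name = "TOY0001") {
  lines <- c(sprintf("LOCUS       %s %d bp    DNA     circular PLN",
                     name, nchar(sequence)),
             "DEFINITION  toy plastome record, synthetic.",
             "FEATURES             Location/Qualifiers")
  for (cds in cds_list) {
    lines <- c(lines,
               sprintf("     CDS             %s", cds$location),
               sprintf("                     /gene=\"%s\"", cds$gene))
    if (isTRUE(cds$pseudo)) {
      lines <- c(lines, "                     /pseudo")
    }
  }
  lines <- c(lines, "ORIGIN")
  pos <- 1L
  while (pos <= nchar(sequence)) {
    chunk <- substr(sequence, pos, min(pos + 59L, nchar(sequence)))
    groups <- gsub("(.{10})", "\\1 ", chunk)
    lines <- c(lines, sprintf("%9d %s", pos, trimws(groups)))
    pos <- pos + 60L
  }
  lines <- c(lines, "//")
  writeLines(lines, path)
  path
}

## brute-force parsimony: minimize changes over all internal labelings
## (vectorized over the full labeling grid; missing leaves can take any
## state, so edges into them never cost anything)
brute_force_parsimony <- function(tree, column_states) {
  states <- c("A", "C", "G", "T")
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  grid <- as.matrix(expand.grid(rep(list(states), nint),
                                stringsAsFactors = FALSE))
  leaf <- toupper(column_states[tree$tip.label])
  cost <- integer(nrow(grid))
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    pstate <- grid[, p - ntip]
    if (ch <= ntip) {
      cstate <- leaf[ch]
      if (!(cstate %in% states)) next
      cost <- cost + (pstate != cstate)
    } else {
      cost <- cost + (pstate != grid[, ch - ntip])
    }
  }
  min(cost)
}

## enumerate the nine single-base mutants of a codon (NG86 oracle)
ng_oracle <- function(codon) {
  gc11 <- Biostrings::getGeneticCode("11")
  aa0 <- gc11[[codon]]
  chars <- strsplit(codon, "")[[1]]
  S <- 0; N <- 0
  for (pos in 1:3) {
    for (nt in setdiff(c("A", "C", "G", "T"), chars[pos])) {
      mut <- chars; mut[pos] <- nt
      maa <- gc11[[paste(mut, collapse = "")]]
      if (maa == "*") next
      if (maa == aa0) S <- S + 1 / 3 else N <- N + 1 / 3
    }
  }
  c(S = S, N = N)
}
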