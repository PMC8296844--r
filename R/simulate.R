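## MG94-style codon model machinery and the ground-truth dataset generator.
##
## The evolutionary process runs over the 61 sense codons of translation
## table 11 (stop states are disallowed; stops appear only via lesion
## injection). Rates: single-nucleotide neighbours only, target-codon
## frequency times kappa for transitions, times omega (beta/alpha) for
## nonsynonymous changes. The generator at omega = alpha = beta = 1 is
## scaled to one expected substitution per codon per unit branch length;
## supplied tree branch lengths (substitutions per nucleotide site) are
## multiplied by 3 to convert to codon units.

mg94_parts <- function(kappa = 2, codon_freqs = NULL) {
  key <- paste0("mg94_", kappa, "_",
                if (is.null(codon_freqs)) "uniform" else
                  paste(signif(codon_freqs, 6), collapse = ","))
  if (!is.null(.pl_cache[[key]])) return(.pl_cache[[key]])
  ct <- codon_table()
  n <- length(ct$sense_codons)
  pi_c <- if (is.null(codon_freqs)) rep(1 / n, n) else codon_freqs / sum(codon_freqs)
  chars <- strsplit(ct$sense_codons, "")
  aa <- ct$aa[ct$sense_codons]
  Qs <- matrix(0, n, n)
  Qn <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      d <- which(chars[[i]] != chars[[j]])
      if (length(d) != 1L) next
      r <- pi_c[j]
      if (is_transition(chars[[i]][d], chars[[j]][d])) r <- r * kappa
      if (aa[i] == aa[j]) Qs[i, j] <- r else Qn[i, j] <- r
    }
  }
  q1 <- Qs + Qn
  diag(q1) <- -rowSums(q1)
  nu <- -sum(pi_c * diag(q1))   # expected rate per codon at omega = 1
  out <- list(Qs = Qs / nu, Qn = Qn / nu, pi = pi_c, n = n)
  .pl_cache[[key]] <- out
  out
}

## Eigendecomposition of Q = alpha*Qs + beta*Qn via pi-symmetrization;
## returns a closure computing P(t) with rows clipped/renormalized.
mg94_eigen <- function(alpha, beta, parts) {
  Q <- alpha * parts$Qs + beta * parts$Qn
  diag(Q) <- -rowSums(Q)
  s <- sqrt(parts$pi)
  B <- diag(s) %*% Q %*% diag(1 / s)
  B <- (B + t(B)) / 2
  ev <- eigen(B, symmetric = TRUE)
  V <- diag(1 / s) %*% ev$vectors
  W <- t(ev$vectors) %*% diag(s)
  list(values = ev$values, V = V, W = W)
}

mg94_pmat <- function(eg, t) {
  P <- eg$V %*% (exp(eg$values * t) * eg$W)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Simulation configuration for the synthetic dataset generator
#'
#' Defaults encode the study conditions the generator emulates: a few
#' dozen plastid protein-coding genes across a few dozen taxa evolved on a
#' shared tree under a codon model with per-gene rate multipliers, a small
#' minority of sites under positive selection, and pseudogene lesions
#' planted on chosen (gene, taxon) pairs.
#'
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the config.
#' @param n_taxa,n_genes Numbers of taxa and genes.
#' @param gene_length_codons Range (min, max) of gene lengths in codons
#'   (terminal stop codon added on top).
#' @param tree Optional `phylo` or Newick string; when `NULL` a Yule tree
#'   is simulated and rescaled to `tree_length`.
#' @param tree_length Total tree length (expected substitutions per
#'   nucleotide site summed over branches) for simulated trees.
#' @param rate_multipliers Per-gene positive rate multipliers (mean 1);
#'   when `NULL`, drawn log-uniformly on [0.25, 4] and normalized to mean
#'   1.
#' @param omega_classes Tibble with columns `omega`, `prop` (proportions
#'   sum to 1).
#' @param kappa Transition/transversion rate ratio.
#' @param codon_freqs Optional frequency vector over the 61 sense codons
#'   (default uniform).
#' @param lesion_plan Tibble with columns `gene` (index or name), `taxon`
#'   (index or name), `kind` (`premature_stop`, `frameshift`,
#'   `truncation`, `deletion`), `position_fraction` in (0, 1), and
#'   optional `indel_len` (1 or 2, frameshifts only).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1, n_taxa = 20, n_genes = 40,
                       gene_length_codons = c(80, 300), tree = NULL,
                       tree_length = 2, rate_multipliers = NULL,
                       omega_classes = NULL, kappa = 2,
                       codon_freqs = NULL, lesion_plan = NULL) {
  omega_classes <- omega_classes %||%
    tibble::tibble(omega = c(0.1, 1, 5), prop = c(0.7, 0.25, 0.05))
  if (abs(sum(omega_classes$prop) - 1) > 1e-8) {
    stop("omega class proportions must sum to 1", call. = FALSE)
  }
  if (!is.null(rate_multipliers) && any(rate_multipliers <= 0)) {
    stop("rate multipliers must be positive", call. = FALSE)
  }
  lesion_plan <- lesion_plan %||%
    tibble::tibble(gene = integer(), taxon = integer(), kind = character(),
                   position_fraction = numeric())
  structure(list(seed = as.integer(seed), n_taxa = n_taxa,
                 n_genes = n_genes,
                 gene_length_codons = gene_length_codons, tree = tree,
                 tree_length = tree_length,
                 rate_multipliers = rate_multipliers,
                 omega_classes = omega_classes, kappa = kappa,
                 codon_freqs = codon_freqs, lesion_plan = lesion_plan),
            class = "sim_config")
}

## deterministic per-gene seed stream (adding genes never perturbs earlier
## genes); kept below 2^31
gene_seed <- function(seed, gene_index) {
  as.integer((as.numeric(seed) * 1009 + gene_index * 7919) %% 2147483629)
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Simulate one gene's codon alignment on a tree
#'
#' Root codons are drawn from the codon frequencies; each branch applies
#' the exact CTMC transition matrix (matrix exponential of the MG94-style
#' generator) for its length times 3 (codon units) times the gene rate
#' multiplier. Per-site omega classes are drawn i.i.d. from
#' `omega_classes`.
#'
#' @param tree `phylo` tree with branch lengths.
#' @param n_codons Number of (sense) codons to simulate.
#' @param omega_classes Tibble `omega`, `prop`.
#' @param rate_multiplier Gene-level branch-length multiplier.
#' @param kappa Transition/transversion ratio.
#' @param codon_freqs Optional sense-codon frequencies.
#' @param seed Integer seed.
#' @return List with `seqs` (named character vector of CDS, no terminal
#'   stop), `site_omega` (numeric vector of true omega per codon site),
#'   and `codon_idx` (taxa x sites integer matrix of sense-codon indices).
#' @export
simulate_gene <- function(tree, n_codons, omega_classes =
                            tibble::tibble(omega = 1, prop = 1),
                          rate_multiplier = 1, kappa = 2,
                          codon_freqs = NULL, seed = 1) {
  parts <- mg94_parts(kappa, codon_freqs)
  with_seed(seed, {
    classes <- sample.int(nrow(omega_classes), n_codons, replace = TRUE,
                          prob = omega_classes$prop)
    po <- tree_postorder(tree)
    n_nodes <- po$ntip + po$nnode
    ## precompute per-class transition matrices per branch
    class_eg <- lapply(omega_classes$omega,
                       function(w) mg94_eigen(1, w, parts))
    states <- matrix(0L, nrow = n_nodes, ncol = n_codons)
    states[po$root, ] <- sample.int(parts$n, n_codons, replace = TRUE,
                                    prob = parts$pi)
    ## preorder = reverse postorder edge sweep
    for (e in rev(seq_len(nrow(po$edge)))) {
      parent <- po$edge[e, 1]
      child <- po$edge[e, 2]
      t_codon <- po$lengths[e] * 3 * rate_multiplier
      child_state <- integer(n_codons)
      for (k in seq_len(nrow(omega_classes))) {
        sel <- which(classes == k)
        if (!length(sel)) next
        P <- mg94_pmat(class_eg[[k]], t_codon)
        par_states <- states[parent, sel]
        for (cp in unique(par_states)) {
          idx <- sel[par_states == cp]
          child_state[idx] <- sample.int(parts$n, length(idx),
                                         replace = TRUE, prob = P[cp, ])
        }
      }
      states[child, ] <- child_state
    }
    ct <- codon_table()
    tip_idx <- states[seq_len(po$ntip), , drop = FALSE]
    rownames(tip_idx) <- po$tree$tip.label
    seqs <- apply(tip_idx, 1, function(ix)
      paste(ct$sense_codons[ix], collapse = ""))
    list(seqs = seqs, site_omega = omega_classes$omega[classes],
         codon_idx = tip_idx)
  })
}

apply_lesion <- function(seq, kind, position_fraction, n_codons,
                         indel_len = 1L) {
  pos_codon <- max(2L, min(n_codons - 1L,
                           as.integer(ceiling(position_fraction *
                                                n_codons))))
  nt_pos <- (pos_codon - 1L) * 3L + 1L
  switch(kind,
    premature_stop = {
      substr(seq, nt_pos, nt_pos + 2L) <- "TAA"
      seq
    },
    frameshift = {
      paste0(substr(seq, 1L, nt_pos - 1L),
             substr(seq, nt_pos + indel_len, nchar(seq)))
    },
    truncation = substr(seq, 1L, nt_pos - 1L),
    deletion = "",
    stop("unknown lesion kind: ", kind, call. = FALSE)
  )
}

#' Simulate a full ground-truth dataset
#'
#' Writes `tree.nwk`, `genes/<gene>.fasta` (unaligned CDS per taxon, with
#' a terminal stop codon; lesions applied), `ontology.tsv` (gene,
#' ontology; seven functional groups assigned cyclically) and
#' `truth.json`. The same config and seed produce byte-identical output.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created).
#' @return Invisibly, a list with `tree`, `genes` (tibble of gene, taxon,
#'   residues), `truth` (list), `dir`.
#' @export
simulate_dataset <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "genes"), showWarnings = FALSE)

  tree <- with_seed(config$seed, {
    if (!is.null(config$tree)) {
      tr <- if (inherits(config$tree, "phylo")) config$tree else
        parse_newick(config$tree)
      tr
    } else {
      tr <- ape::rphylo(config$n_taxa, birth = 1, death = 0)
      tr$tip.label <- sprintf("taxon%02d", seq_len(config$n_taxa))
      tr$edge.length <- tr$edge.length / sum(tr$edge.length) *
        config$tree_length
      tr
    }
  })
  taxa <- tree$tip.label

  gene_names <- sprintf("gene%03d", seq_len(config$n_genes))
  ## multipliers and lengths are drawn from per-gene streams so that
  ## adding genes never perturbs earlier genes; default multipliers are
  ## log-uniform on [0.25, 4] (mean ~1 by symmetry on the log scale)
  multipliers <- config$rate_multipliers %||% vapply(
    seq_len(config$n_genes), function(gi) {
      with_seed(gene_seed(config$seed + 1000003L, gi),
                exp(stats::runif(1, log(0.25), log(4))))
    }, numeric(1))
  if (length(multipliers) != config$n_genes) {
    stop("need one rate multiplier per gene", call. = FALSE)
  }
  len_range <- seq(config$gene_length_codons[1],
                   config$gene_length_codons[2])
  lengths_codons <- vapply(seq_len(config$n_genes), function(gi) {
    with_seed(gene_seed(config$seed + 2000003L, gi),
              len_range[sample.int(length(len_range), 1)])
  }, numeric(1))

  ## resolve lesion plan to names and validate
  plan <- config$lesion_plan
  if (nrow(plan)) {
    plan$gene <- if (is.numeric(plan$gene)) gene_names[plan$gene] else
      plan$gene
    plan$taxon <- if (is.numeric(plan$taxon)) taxa[plan$taxon] else
      plan$taxon
    if (!"indel_len" %in% names(plan)) plan$indel_len <- 1L
    if (any(plan$position_fraction <= 0 | plan$position_fraction >= 1)) {
      stop("config error: lesion position outside gene", call. = FALSE)
    }
  }

  gene_rows <- list()
  truth_status <- list()
  truth_sites <- list()
  ct <- codon_table()
  for (gi in seq_len(config$n_genes)) {
    g <- gene_names[gi]
    sim <- simulate_gene(tree, lengths_codons[gi],
                         omega_classes = config$omega_classes,
                         rate_multiplier = multipliers[gi],
                         kappa = config$kappa,
                         codon_freqs = config$codon_freqs,
                         seed = gene_seed(config$seed, gi))
    seqs <- paste0(sim$seqs, "TAA")  # terminal stop codon
    names(seqs) <- names(sim$seqs)
    n_codons <- lengths_codons[gi] + 1L
    status <- tibble::tibble(gene = g, taxon = taxa, status = "intact",
                             lesion_kind = "none",
                             lesion_codon = NA_integer_)
    gplan <- if (nrow(plan)) plan[plan$gene == g, ] else plan
    for (li in seq_len(nrow(gplan))) {
      tx <- gplan$taxon[li]
      kind <- gplan$kind[li]
      seqs[[tx]] <- apply_lesion(seqs[[tx]], kind,
                                 gplan$position_fraction[li], n_codons,
                                 gplan$indel_len[li])
      row <- which(status$taxon == tx)
      status$status[row] <- if (kind == "deletion") "absent" else
        "pseudogene"
      status$lesion_kind[row] <- if (kind == "deletion") "none" else kind
      status$lesion_codon[row] <- if (kind == "deletion") NA_integer_ else
        max(2L, min(n_codons - 1L,
                    as.integer(ceiling(gplan$position_fraction[li] *
                                         n_codons))))
    }
    gene_rows[[gi]] <- tibble::tibble(gene = g, taxon = taxa,
                                      residues = unname(seqs[taxa]))
    truth_status[[gi]] <- status
    truth_sites[[gi]] <- tibble::tibble(gene = g,
                                        site = seq_along(sim$site_omega),
                                        omega = sim$site_omega)
    present <- seqs[taxa][nchar(seqs[taxa]) > 0]
    write_fasta(tibble::tibble(id = names(present), description = "",
                               residues = unname(present)),
                file.path(dir, "genes", paste0(g, ".fasta")))
  }

  ontologies <- c("atp_synthesis", "cytochrome_electron_transport",
                  "ndh", "photosynthesis", "translation", "transcription",
                  "other")
  ontology <- tibble::tibble(gene = gene_names,
                             ontology = ontologies[
                               (seq_len(config$n_genes) - 1L) %%
                                 length(ontologies) + 1L])

  write_tree(tree, file.path(dir, "tree.nwk"))
  write_tsv_file(ontology, file.path(dir, "ontology.tsv"))
  truth <- list(
    seed = config$seed,
    genes = stats::setNames(as.list(multipliers), gene_names),
    gene_length_codons = stats::setNames(as.list(lengths_codons),
                                         gene_names),
    status = dplyr::bind_rows(truth_status),
    site_omega = dplyr::bind_rows(truth_sites)
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(tree = tree, genes = dplyr::bind_rows(gene_rows),
                 truth = truth, ontology = ontology, dir = dir))
}
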