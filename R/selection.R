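## Selection analyses on codon-aware gene alignments: gene-wide Kn/Ks by
## Nei-Gojobori counting with Jukes-Cantor correction, a per-site counting
## test on Fitch-reconstructed ancestral codons ("method A"), a per-site
## empirical-Bayes grid over synonymous/nonsynonymous rates ("method B"),
## the two-method consensus rule, per-branch Kn/Ks screening, and
## ontology-level enrichment of consensus sites.

## Map an alignment to a taxa x codon-sites matrix of sense-codon indices.
## Codon sites are defined in the frame of the anchor row (all columns
## where the anchor is ungapped, grouped in threes); with no anchor the
## alignment width must be a codon multiple and all columns are used.
## Cells that are not a clean sense codon (gap, N, stop) are NA.
codon_site_matrix <- function(aln, max_gap_fraction = 0.5) {
  aln <- as_gene_alignment(aln)
  mat <- aln_matrix(aln)
  if (!is.na(aln$anchor) && aln$anchor %in% rownames(mat)) {
    cols <- which(mat[aln$anchor, ] != "-")
  } else {
    cols <- seq_len(ncol(mat))
  }
  if (length(cols) %% 3L != 0L) {
    stop("frame error: ", length(cols), " frame columns not a codon ",
         "multiple", call. = FALSE)
  }
  n_sites <- length(cols) %/% 3L
  ct <- codon_table()
  n_taxa <- nrow(mat)
  idx <- matrix(NA_integer_, n_taxa, n_sites,
                dimnames = list(rownames(mat), NULL))
  gapfrac <- numeric(n_sites)
  for (s in seq_len(n_sites)) {
    cc <- cols[(3L * s - 2L):(3L * s)]
    sub <- mat[, cc, drop = FALSE]
    codons <- paste0(sub[, 1], sub[, 2], sub[, 3])
    idx[, s] <- match(codons, ct$sense_codons)
    gapfrac[s] <- mean(rowSums(sub == "-") > 0)
  }
  list(idx = idx, n_sites = n_sites, keep = gapfrac <= max_gap_fraction)
}

#' Gene-wide Kn/Ks by the Nei-Gojobori counting method
#'
#' Synonymous/nonsynonymous differences are counted over all unordered
#' sequence pairs with pathway averaging for multi-hit codons (equal
#' weights over stop-free orderings), site totals per the NG86 convention,
#' and Jukes-Cantor correction of the proportions. The gene ratio is the
#' ratio of the pair-averaged Kn to the pair-averaged Ks.
#'
#' @param gene_alignment Codon-aware alignment (rows failing codon
#'   structure contribute nothing).
#' @param gene Gene label for the result row.
#' @return One-row tibble: `gene`, `kn`, `ks`, `kn_ks` (`NA` when Ks = 0),
#'   `n_codon_columns`, `n_pairs`, `n_pairs_ks0`.
#' @export
gene_kn_ks <- function(gene_alignment, gene = NULL) {
  aln <- as_gene_alignment(gene_alignment)
  gene <- gene %||% aln$gene
  csm <- codon_site_matrix(aln, max_gap_fraction = 1)
  idx <- csm$idx
  usable_rows <- rowSums(!is.na(idx)) > 0L
  idx <- idx[usable_rows, , drop = FALSE]
  null_row <- tibble::tibble(gene = gene, kn = NA_real_, ks = NA_real_,
                             kn_ks = NA_real_,
                             n_codon_columns = csm$n_sites,
                             n_pairs = 0L, n_pairs_ks0 = 0L)
  if (nrow(idx) < 2L) return(null_row)
  ng <- ng_tables()
  n <- nrow(idx)
  kn_v <- numeric(0); ks_v <- numeric(0)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- idx[i, ]; b <- idx[j, ]
      ok <- !is.na(a) & !is.na(b)
      if (!any(ok)) next
      a <- a[ok]; b <- b[ok]
      sd <- sum(ng$SD[cbind(a, b)])
      nd <- sum(ng$ND[cbind(a, b)])
      S <- (sum(ng$S_site[a]) + sum(ng$S_site[b])) / 2
      N <- (sum(ng$N_site[a]) + sum(ng$N_site[b])) / 2
      if (S <= 0 || N <= 0) next
      pS <- sd / S; pN <- nd / N
      ks <- jc_correct(pS); kn <- jc_correct(pN)
      if (is.na(ks) || is.na(kn)) next
      ks_v <- c(ks_v, ks); kn_v <- c(kn_v, kn)
    }
  }
  if (!length(ks_v)) return(null_row)
  Kn <- mean(kn_v); Ks <- mean(ks_v)
  tibble::tibble(gene = gene, kn = Kn, ks = Ks,
                 kn_ks = if (Ks > 0) Kn / Ks else NA_real_,
                 n_codon_columns = csm$n_sites,
                 n_pairs = length(ks_v),
                 n_pairs_ks0 = sum(ks_v == 0))
}

jc_correct <- function(p) {
  if (is.na(p) || p >= 0.75) return(NA_real_)
  -0.75 * log(1 - 4 * p / 3)
}

## ---- Fitch ancestral reconstruction over 61 codon states -------------------
## Bottom-up Fitch sets, then a top-down refinement: keep the parent state
## when allowed; otherwise choose the set member with minimal
## nonsynonymous pathway count to the parent, ties broken lexicographically
## (sense codons are stored in lexicographic order).
fitch_codon_reconstruct <- function(tree, site_idx) {
  po <- tree_postorder(tree)
  n_states <- length(codon_table()$sense_codons)
  n_nodes <- po$ntip + po$nnode
  sets <- matrix(FALSE, n_nodes, n_states)
  for (i in seq_len(po$ntip)) {
    v <- site_idx[po$tree$tip.label[i]]
    if (is.na(v)) sets[i, ] <- TRUE else sets[i, v] <- TRUE
  }
  seen <- logical(n_nodes)
  for (e in seq_len(nrow(po$edge))) {
    parent <- po$edge[e, 1]; child <- po$edge[e, 2]
    if (!seen[parent]) {
      sets[parent, ] <- sets[child, ]
      seen[parent] <- TRUE
    } else {
      inter <- sets[parent, ] & sets[child, ]
      if (any(inter)) sets[parent, ] <- inter
      else sets[parent, ] <- sets[parent, ] | sets[child, ]
    }
  }
  ng <- ng_tables()
  state <- integer(n_nodes)
  state[po$root] <- which(sets[po$root, ])[1]
  for (e in rev(seq_len(nrow(po$edge)))) {
    parent <- po$edge[e, 1]; child <- po$edge[e, 2]
    ps <- state[parent]
    if (sets[child, ps]) {
      state[child] <- ps
    } else {
      cand <- which(sets[child, ])
      state[child] <- cand[which.min(ng$ND[ps, cand])]
    }
  }
  list(state = state, po = po)
}

## Reconstruct every kept site of a gene and classify per-branch changes.
## Returns per-site and per-edge syn/nonsyn pathway-averaged counts plus
## transition/transversion step counts for kappa estimation.
codon_changes <- function(tree, csm) {
  po <- tree_postorder(tree)
  n_edges <- nrow(po$edge)
  n_sites <- csm$n_sites
  ng <- ng_tables()
  sd_es <- matrix(0, n_edges, n_sites)
  nd_es <- matrix(0, n_edges, n_sites)
  ts_total <- 0; steps_total <- 0
  for (s in which(csm$keep)) {
    col <- csm$idx[, s]
    if (sum(!is.na(col)) < 2L) next
    rec <- fitch_codon_reconstruct(tree, col)
    anc <- rec$state
    for (e in seq_len(n_edges)) {
      p <- anc[po$edge[e, 1]]; c <- anc[po$edge[e, 2]]
      if (p != c) {
        sd_es[e, s] <- ng$SD[p, c]
        nd_es[e, s] <- ng$ND[p, c]
        ts_total <- ts_total + ng$TS[p, c]
        steps_total <- steps_total + ng$SD[p, c] + ng$ND[p, c]
      }
    }
  }
  list(sd_es = sd_es, nd_es = nd_es, po = po,
       ts_total = ts_total, tv_total = steps_total - ts_total)
}

site_f <- function(csm) {
  ng <- ng_tables()
  vapply(seq_len(csm$n_sites), function(s) {
    col <- csm$idx[, s]
    col <- col[!is.na(col)]
    if (!length(col)) return(NA_real_)
    S <- mean(ng$S_site[col]); N <- mean(ng$N_site[col])
    N / (N + S)
  }, numeric(1))
}

## Continuous binomial tails via the regularized incomplete beta function;
## for integer counts they coincide with the exact binomial tails.
binom_tail_upper <- function(n, s, f) {
  if (n <= 0) return(1)
  stats::pbeta(f, n, s + 1)
}
binom_tail_lower <- function(n, s, f) {
  if (s <= 0) return(1)
  stats::pbeta(1 - f, s, n + 1)
}

#' Per-site counting test for selection (method A)
#'
#' Ancestral codons are reconstructed by 61-state Fitch parsimony (ties
#' resolved toward minimal nonsynonymous change, then lexicographically);
#' per-branch changes are classified synonymous/nonsynonymous with pathway
#' averaging and summed per site. The one-sided tail probabilities compare
#' the observed nonsynonymous count to a binomial with success probability
#' equal to the site's expected nonsynonymous fraction.
#'
#' @param gene_alignment Codon-aware alignment.
#' @param tree `phylo` topology covering the alignment rows.
#' @param alpha Flagging threshold on `p_pos`.
#' @param max_gap_fraction Sites with gaps in more than this fraction of
#'   taxa are excluded (NA results, no flag).
#' @param gene Gene label.
#' @return Tibble per codon site: `gene`, `site`, `s`, `n`, `f`, `p_pos`,
#'   `p_neg`, `method_A`, `excluded`.
#' @export
site_test_counting <- function(gene_alignment, tree, alpha = 0.05,
                               max_gap_fraction = 0.5, gene = NULL) {
  aln <- as_gene_alignment(gene_alignment)
  gene <- gene %||% aln$gene
  csm <- codon_site_matrix(aln, max_gap_fraction)
  ch <- codon_changes(tree, csm)
  s_site <- colSums(ch$sd_es)
  n_site <- colSums(ch$nd_es)
  f <- site_f(csm)
  p_pos <- vapply(seq_len(csm$n_sites), function(i) {
    if (!csm$keep[i] || is.na(f[i])) return(NA_real_)
    binom_tail_upper(n_site[i], s_site[i], f[i])
  }, numeric(1))
  p_neg <- vapply(seq_len(csm$n_sites), function(i) {
    if (!csm$keep[i] || is.na(f[i])) return(NA_real_)
    binom_tail_lower(n_site[i], s_site[i], f[i])
  }, numeric(1))
  tibble::tibble(gene = gene, site = seq_len(csm$n_sites),
                 s = ifelse(csm$keep, s_site, NA_real_),
                 n = ifelse(csm$keep, n_site, NA_real_),
                 f = f, p_pos = p_pos, p_neg = p_neg,
                 method_A = !is.na(p_pos) & p_pos <= alpha &
                   (s_site + n_site) >= 1,
                 excluded = !csm$keep)
}

#' Per-site empirical-Bayes grid test for selection (method B)
#'
#' Site likelihoods are computed by Felsenstein pruning under the
#' MG94-style codon model on a 20 x 20 grid of synonymous/nonsynonymous
#' rates (alpha, beta) over [0, 5], with branch lengths fixed (times 3,
#' codon units) and a gene-level kappa estimated from reconstructed
#' changes. Grid weights are fitted by EM to maximize the summed log
#' marginal likelihood; the reported posterior is the weight-posterior
#' mass where beta > alpha.
#'
#' @param gene_alignment Codon-aware alignment.
#' @param tree `phylo` tree with branch lengths.
#' @param grid_points Points per grid axis.
#' @param grid_max Upper bound of the rate grid.
#' @param threshold Posterior probability threshold for the `method_B`
#'   flag.
#' @param kappa Transition/transversion ratio; `NULL` = estimate from the
#'   data (2 x transition/transversion step ratio, clamped to [0.5, 20]).
#' @param max_gap_fraction Site exclusion rule as in
#'   [site_test_counting()].
#' @param gene Gene label.
#' @return Tibble per codon site: `gene`, `site`, `alpha`, `beta`
#'   (posterior means), `posterior_prob_pos`, `posterior_prob_neg`,
#'   `method_B`, `excluded`; attribute `em_objective` holds the EM trace.
#' @export
site_test_ebgrid <- function(gene_alignment, tree, grid_points = 20,
                             grid_max = 5, threshold = 0.9, kappa = NULL,
                             max_gap_fraction = 0.5, gene = NULL) {
  aln <- as_gene_alignment(gene_alignment)
  gene <- gene %||% aln$gene
  if (length(aln$seqs) < 2L) stop("degenerate alignment: need >= 2 taxa",
                                  call. = FALSE)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths",
                                      call. = FALSE)
  csm <- codon_site_matrix(aln, max_gap_fraction)
  if (is.null(kappa)) {
    ch <- codon_changes(tree, csm)
    kappa <- if (ch$tv_total > 0) {
      min(20, max(0.5, 2 * ch$ts_total / ch$tv_total))
    } else 2
  }
  parts <- mg94_parts(kappa, NULL)
  grid_vals <- seq(0, grid_max, length.out = grid_points)
  grid <- expand.grid(alpha = grid_vals, beta = grid_vals)
  keep_sites <- which(csm$keep)
  S <- length(keep_sites)
  logl <- matrix(-Inf, nrow = S, ncol = nrow(grid))
  po <- tree_postorder(tree)
  tip_states <- csm$idx[po$tree$tip.label, keep_sites, drop = FALSE]
  for (k in seq_len(nrow(grid))) {
    eg <- mg94_eigen(grid$alpha[k], grid$beta[k], parts)
    logl[, k] <- codon_pruning_loglik(po, tip_states, eg, parts$pi)
  }
  em <- em_grid_weights(logl)
  post <- em$posterior
  pos_mask <- grid$beta > grid$alpha
  neg_mask <- grid$beta < grid$alpha
  out <- tibble::tibble(gene = gene, site = seq_len(csm$n_sites),
                        alpha = NA_real_, beta = NA_real_,
                        posterior_prob_pos = NA_real_,
                        posterior_prob_neg = NA_real_,
                        method_B = FALSE, excluded = !csm$keep)
  out$alpha[keep_sites] <- as.numeric(post %*% grid$alpha)
  out$beta[keep_sites] <- as.numeric(post %*% grid$beta)
  out$posterior_prob_pos[keep_sites] <- as.numeric(post %*% pos_mask)
  out$posterior_prob_neg[keep_sites] <- as.numeric(post %*% neg_mask)
  out$method_B <- !is.na(out$posterior_prob_pos) &
    out$posterior_prob_pos >= threshold
  attr(out, "em_objective") <- em$objective
  attr(out, "kappa") <- kappa
  out
}

## Pruning over the 61 codon states for all sites at once under one
## (alpha, beta) grid point; returns per-site log-likelihoods.
codon_pruning_loglik <- function(po, tip_states, eg, pi_c) {
  n_states <- length(pi_c)
  S <- ncol(tip_states)
  partials <- vector("list", po$ntip + po$nnode)
  for (i in seq_len(po$ntip)) {
    m <- matrix(0, n_states, S)
    v <- tip_states[i, ]
    known <- !is.na(v)
    m[cbind(v[known], which(known))] <- 1
    m[, !known] <- 1
    partials[[i]] <- m
  }
  pmats <- lapply(seq_len(nrow(po$edge)), function(e)
    mg94_pmat(eg, po$lengths[e] * 3))
  logscale <- numeric(S)
  seen <- logical(po$ntip + po$nnode)
  for (e in seq_len(nrow(po$edge))) {
    parent <- po$edge[e, 1]; child <- po$edge[e, 2]
    msg <- pmats[[e]] %*% partials[[child]]
    if (!seen[parent]) {
      partials[[parent]] <- msg
      seen[parent] <- TRUE
    } else {
      partials[[parent]] <- partials[[parent]] * msg
    }
    mx <- apply(partials[[parent]], 2, max)
    mx[mx <= 0] <- 1
    partials[[parent]] <- sweep(partials[[parent]], 2, mx, "/")
    logscale <- logscale + log(mx)
  }
  log(colSums(partials[[po$root]] * pi_c)) + logscale
}

## EM over grid weights for a sites x grid log-likelihood matrix. The
## objective (summed log marginal likelihood) is checked to be
## non-decreasing at every iteration.
em_grid_weights <- function(logl, max_iter = 500, tol = 1e-8) {
  K <- ncol(logl)
  w <- rep(1 / K, K)
  shift <- apply(logl, 1, max)
  L <- exp(logl - shift)          # sites x K, scaled
  objective <- numeric(0)
  for (it in seq_len(max_iter)) {
    marg <- as.numeric(L %*% w)
    obj <- sum(log(marg) + shift)
    if (length(objective) && obj < objective[length(objective)] - 1e-6) {
      stop("EM objective decreased; numerical failure", call. = FALSE)
    }
    objective <- c(objective, obj)
    post <- sweep(L, 2, w, "*") / marg
    w_new <- colMeans(post)
    if (length(objective) > 1 &&
        abs(obj - objective[length(objective) - 1]) < tol) break
    w <- w_new
  }
  marg <- as.numeric(L %*% w)
  post <- sweep(L, 2, w, "*") / marg
  list(weights = w, posterior = post, objective = objective)
}

#' Consensus of the two site-level selection methods
#'
#' A site is consensus-flagged only when flagged by both the counting test
#' and the empirical-Bayes grid.
#'
#' @param methodA_results Output of [site_test_counting()].
#' @param methodB_results Output of [site_test_ebgrid()] for the same
#'   gene/site grid.
#' @return The joined per-site tibble with a `consensus` column.
#' @export
consensus_sites <- function(methodA_results, methodB_results) {
  a <- methodA_results[, c("gene", "site", "s", "n", "p_pos", "p_neg",
                           "method_A", "excluded")]
  b <- methodB_results[, c("gene", "site", "alpha", "beta",
                           "posterior_prob_pos", "posterior_prob_neg",
                           "method_B")]
  if (nrow(a) != nrow(b) || !all(a$gene == b$gene) ||
      !all(a$site == b$site)) {
    stop("method A/B site index mismatch", call. = FALSE)
  }
  out <- dplyr::bind_cols(a, b[, setdiff(names(b), c("gene", "site"))])
  out$consensus <- out$method_A & out$method_B
  out
}

#' Per-gene selection summary table
#'
#' One row per gene: sites analyzed, counting-test sites, EB-grid
#' positive/negative sites, and the consensus-confirmed positions.
#'
#' @param site_results Consensus tibble from [consensus_sites()] (possibly
#'   several genes bound together).
#' @return A tibble with `gene`, `n_sites`, `methodA_sites`,
#'   `methodB_pos`, `methodB_neg`, `confirmed_n`, `confirmed_positions`.
#' @export
summarize_selection <- function(site_results) {
  site_results |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      n_sites = dplyr::n(),
      methodA_sites = sum(.data$method_A, na.rm = TRUE),
      methodB_pos = sum(.data$method_B, na.rm = TRUE),
      methodB_neg = sum(!is.na(.data$posterior_prob_neg) &
                          .data$posterior_prob_neg >= 0.9),
      confirmed_n = sum(.data$consensus, na.rm = TRUE),
      confirmed_positions = paste(.data$site[.data$consensus],
                                  collapse = ","),
      .groups = "drop")
}

#' Per-branch Kn/Ks screening
#'
#' Synonymous/nonsynonymous substitution counts from the Fitch
#' reconstruction are aggregated per branch over all sites and normalized
#' by the gene's synonymous/nonsynonymous site totals. Branches are
#' flagged when the ratio exceeds 1 with at least `min_subs` total
#' substitutions — a descriptive screen, not a likelihood-ratio test.
#'
#' @param gene_alignment Codon-aware alignment.
#' @param tree `phylo` topology.
#' @param min_subs Minimum substitutions on a branch for flagging.
#' @param max_gap_fraction Site exclusion rule.
#' @param gene Gene label.
#' @return Tibble per branch: `gene`, `branch` (child label), `sd`, `nd`,
#'   `kn`, `ks`, `kn_ks` (`Inf` when Ks = 0 and Kn > 0), `n_subs`,
#'   `flagged`.
#' @export
branch_kn_ks <- function(gene_alignment, tree, min_subs = 3,
                         max_gap_fraction = 0.5, gene = NULL) {
  aln <- as_gene_alignment(gene_alignment)
  gene <- gene %||% aln$gene
  csm <- codon_site_matrix(aln, max_gap_fraction)
  ch <- codon_changes(tree, csm)
  po <- ch$po
  ng <- ng_tables()
  keep <- csm$keep
  S_tot <- 0; N_tot <- 0
  for (s in which(keep)) {
    col <- csm$idx[, s]; col <- col[!is.na(col)]
    if (!length(col)) next
    S_tot <- S_tot + mean(ng$S_site[col])
    N_tot <- N_tot + mean(ng$N_site[col])
  }
  sd_b <- rowSums(ch$sd_es)
  nd_b <- rowSums(ch$nd_es)
  ks <- if (S_tot > 0) sd_b / S_tot else rep(NA_real_, length(sd_b))
  kn <- if (N_tot > 0) nd_b / N_tot else rep(NA_real_, length(nd_b))
  ratio <- ifelse(ks > 0, kn / ks, ifelse(kn > 0, Inf, NA_real_))
  child <- po$edge[, 2]
  lab <- ifelse(child <= po$ntip, po$tree$tip.label[child],
                paste0("node", child))
  tibble::tibble(gene = gene, branch = lab, sd = sd_b, nd = nd_b,
                 kn = kn, ks = ks, kn_ks = ratio,
                 n_subs = sd_b + nd_b,
                 flagged = !is.na(ratio) & ratio > 1 &
                   (sd_b + nd_b) >= min_subs)
}

#' Ontology-level enrichment of consensus-selected sites
#'
#' Selected vs non-selected site totals are accumulated per ontology; all
#' pairwise 2 x 2 Fisher exact tests (two-sided) are run across ontologies
#' plus each ontology against the rest, with Holm step-down adjustment
#' within each comparison family.
#'
#' @param site_results Consensus tibble from [consensus_sites()] over all
#'   genes.
#' @param ontology_map Tibble with `gene`, `ontology` covering all
#'   analyzed genes.
#' @return Tibble per comparison: `comparison` (`pairwise`/`vs_rest`),
#'   `group1`, `group2`, `selected1`, `nonselected1`, `selected2`,
#'   `nonselected2`, `odds_ratio`, `fisher_p`, `holm_p`.
#' @export
ontology_enrichment <- function(site_results, ontology_map) {
  missing <- setdiff(unique(site_results$gene), ontology_map$gene)
  if (length(missing)) {
    stop("ontology map missing genes: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tab <- site_results |>
    dplyr::filter(!.data$excluded) |>
    dplyr::left_join(ontology_map, by = "gene") |>
    dplyr::group_by(.data$ontology) |>
    dplyr::summarise(selected = sum(.data$consensus, na.rm = TRUE),
                     nonselected = sum(!.data$consensus, na.rm = TRUE),
                     .groups = "drop")
  empty <- tab$selected + tab$nonselected == 0
  if (any(empty)) {
    message("excluding ontology with zero sites: ",
            paste(tab$ontology[empty], collapse = ", "))
    tab <- tab[!empty, ]
  }
  onts <- tab$ontology
  rows <- list()
  if (length(onts) >= 2) {
    combs <- utils::combn(seq_along(onts), 2)
    for (k in seq_len(ncol(combs))) {
      i <- combs[1, k]; j <- combs[2, k]
      rows[[length(rows) + 1L]] <- fisher_row("pairwise", onts[i], onts[j],
        tab$selected[i], tab$nonselected[i],
        tab$selected[j], tab$nonselected[j])
    }
  }
  for (i in seq_along(onts)) {
    rows[[length(rows) + 1L]] <- fisher_row("vs_rest", onts[i], "rest",
      tab$selected[i], tab$nonselected[i],
      sum(tab$selected[-i]), sum(tab$nonselected[-i]))
  }
  out <- dplyr::bind_rows(rows)
  out$holm_p <- NA_real_
  for (cmp in unique(out$comparison)) {
    sel <- out$comparison == cmp
    out$holm_p[sel] <- stats::p.adjust(out$fisher_p[sel], method = "holm")
  }
  out
}

fisher_row <- function(comparison, g1, g2, s1, ns1, s2, ns2) {
  m <- matrix(c(s1, ns1, s2, ns2), nrow = 2, byrow = TRUE)
  ft <- stats::fisher.test(m)
  tibble::tibble(comparison = comparison, group1 = g1, group2 = g2,
                 selected1 = s1, nonselected1 = ns1,
                 selected2 = s2, nonselected2 = ns2,
                 odds_ratio = unname(ft$estimate), fisher_p = ft$p.value)
}
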