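#' Pipeline run configuration
#'
#' @param mode Input mode: `synthetic` (simulate with `sim`), `genes_dir`
#'   (directory of per-gene FASTA files) or `genbank_dir` (directory of
#'   GenBank flat files, requires `genes`).
#' @param out_dir Output directory.
#' @param sim A [sim_config()] (synthetic mode).
#' @param genes_dir,genbank_dir Input directories for the respective
#'   modes.
#' @param tree_path Newick tree (required for non-synthetic modes; the
#'   synthetic tree is written by the generator).
#' @param ontology_path Gene-to-ontology TSV (columns `gene`,
#'   `ontology`).
#' @param genes Gene names to extract in `genbank_dir` mode.
#' @param ref_taxon Reference taxon for the pseudogene scan (default:
#'   auto-pick per gene).
#' @param window_width Window width for the alignment tracks.
#' @param frameshift_window,truncation_fraction Scanner thresholds, see
#'   [scan_gene()].
#' @param alpha,posterior_threshold Selection thresholds for methods A
#'   and B.
#' @param grid_points EB grid resolution per axis.
#' @param seed Seed (synthetic mode).
#' @return A `run_config` list.
#' @export
run_config <- function(mode = c("synthetic", "genes_dir", "genbank_dir"),
                       out_dir, sim = NULL, genes_dir = NULL,
                       genbank_dir = NULL, tree_path = NULL,
                       ontology_path = NULL, genes = NULL,
                       ref_taxon = NULL, window_width = 100,
                       frameshift_window = 10, truncation_fraction = 0.05,
                       alpha = 0.05, posterior_threshold = 0.9,
                       grid_points = 20, seed = 1) {
  mode <- match.arg(mode)
  cfg <- list(mode = mode, out_dir = out_dir, sim = sim,
              genes_dir = genes_dir, genbank_dir = genbank_dir,
              tree_path = tree_path, ontology_path = ontology_path,
              genes = genes, ref_taxon = ref_taxon,
              window_width = window_width,
              frameshift_window = frameshift_window,
              truncation_fraction = truncation_fraction, alpha = alpha,
              posterior_threshold = posterior_threshold,
              grid_points = grid_points, seed = as.integer(seed))
  class(cfg) <- "run_config"
  validate_run_config(cfg)
  cfg
}

validate_run_config <- function(cfg) {
  if (cfg$mode == "synthetic") {
    if (is.null(cfg$sim)) cfg$sim <- sim_config(seed = cfg$seed)
  } else if (cfg$mode == "genes_dir") {
    if (is.null(cfg$genes_dir) || !dir.exists(cfg$genes_dir)) {
      stop("validation error: genes_dir not found", call. = FALSE)
    }
    if (is.null(cfg$tree_path) || !file.exists(cfg$tree_path)) {
      stop("validation error: tree file not found", call. = FALSE)
    }
  } else {
    if (is.null(cfg$genbank_dir) || !dir.exists(cfg$genbank_dir)) {
      stop("validation error: genbank_dir not found", call. = FALSE)
    }
    if (is.null(cfg$tree_path) || !file.exists(cfg$tree_path)) {
      stop("validation error: tree file not found", call. = FALSE)
    }
    if (is.null(cfg$genes)) {
      stop("validation error: genbank mode needs a gene list",
           call. = FALSE)
    }
  }
  if (!is.null(cfg$ontology_path) && !file.exists(cfg$ontology_path)) {
    stop("validation error: ontology file not found", call. = FALSE)
  }
  invisible(cfg)
}

log_line <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " ", ...)
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the full pipeline
#'
#' Stage order: load/simulate inputs, codon alignment, pseudogene scan,
#' masking, concatenation, reference branch lengths, window tracks, gene
#' rates, gene Kn/Ks, site selection (both methods), consensus, branch
#' screening, ontology enrichment. All tables are written as TSV under
#' `config$out_dir` together with `report.json`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list of the in-memory results.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  config <- validate_run_config(config)
  if (config$mode == "synthetic" && is.null(config$sim)) {
    config$sim <- sim_config(seed = config$seed)
  }
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logcon <- file(file.path(out_dir, "run.log"), "w")
  on.exit(close(logcon))

  ## stage 1: inputs
  log_line(logcon, "stage load: mode=", config$mode)
  if (config$mode == "synthetic") {
    ds <- simulate_dataset(config$sim, file.path(out_dir, "input"))
    gene_seqs <- ds$genes
    tree <- ds$tree
    ontology <- ds$ontology
  } else if (config$mode == "genes_dir") {
    files <- sort(list.files(config$genes_dir, pattern = "\\.fa(sta)?$",
                             full.names = TRUE))
    if (!length(files)) stop("stage load: no FASTA files in ",
                             config$genes_dir, call. = FALSE)
    gene_seqs <- dplyr::bind_rows(lapply(files, function(f) {
      recs <- read_fasta(f)
      tibble::tibble(gene = sub("\\.fa(sta)?$", "", basename(f)),
                     taxon = recs$id, residues = degap(recs$residues))
    }))
    tree <- read_tree(config$tree_path)
    ontology <- if (!is.null(config$ontology_path)) {
      read_tsv_file(config$ontology_path)
    } else NULL
  } else {
    files <- sort(list.files(config$genbank_dir,
                             pattern = "\\.(gb|gbk|genbank)$",
                             full.names = TRUE))
    if (!length(files)) stop("stage load: no GenBank files in ",
                             config$genbank_dir, call. = FALSE)
    gene_seqs <- dplyr::bind_rows(lapply(files, extract_cds,
                                         wanted_genes = config$genes))
    gene_seqs <- gene_seqs[, c("gene", "taxon", "residues")]
    tree <- read_tree(config$tree_path)
    ontology <- if (!is.null(config$ontology_path)) {
      read_tsv_file(config$ontology_path)
    } else NULL
  }
  genes <- unique(gene_seqs$gene)
  taxa <- unique(gene_seqs$taxon)
  ## taxa present in the tree only
  gene_seqs <- gene_seqs[gene_seqs$taxon %in% tree$tip.label, ]

  ## stage 2: pseudogene scan (on unaligned CDS)
  log_line(logcon, "stage pseudo-scan: ", length(genes), " genes x ",
           length(taxa), " taxa")
  calls <- scan_gene_set(gene_seqs, ref_taxon = config$ref_taxon,
                         frameshift_window = config$frameshift_window,
                         truncation_fraction = config$truncation_fraction)
  write_tsv_file(calls, file.path(out_dir, "calls.tsv"))
  write_tsv_file(build_status_matrix(calls),
                 file.path(out_dir, "status_matrix.tsv"))

  ## stage 3: codon alignment per gene
  log_line(logcon, "stage align")
  alignments <- list()
  for (g in genes) {
    sub <- gene_seqs[gene_seqs$gene == g & nchar(gene_seqs$residues) > 0, ]
    if (nrow(sub) < 2L) {
      log_line(logcon, "WARN gene ", g, " skipped: <2 sequences")
      next
    }
    aln <- tryCatch(
      suppressWarnings(align_codon(stats::setNames(sub$residues,
                                                   sub$taxon), gene = g)),
      error = function(e) {
        log_line(logcon, "WARN gene ", g, " alignment failed: ",
                 conditionMessage(e))
        NULL
      })
    if (!is.null(aln)) alignments[[g]] <- aln
  }

  ## stage 4: masking + concatenation
  log_line(logcon, "stage mask+concatenate: ", length(alignments),
           " aligned genes")
  ## pad missing (absent) taxa as all-gap rows before masking
  alignments <- lapply(alignments, function(aln) {
    width <- nchar(aln$seqs[1])
    missing <- setdiff(tree$tip.label, names(aln$seqs))
    if (length(missing)) {
      aln$seqs <- c(aln$seqs,
                    stats::setNames(rep(strrep("-", width),
                                        length(missing)), missing))
    }
    aln
  })
  masked <- mask_pseudogenes(alignments, calls)
  sm <- concatenate(masked)
  write_tsv_file(sm$partition, file.path(out_dir, "partition.tsv"))

  ## stage 5: reference branch lengths on the masked concatenate
  log_line(logcon, "stage branch-lengths")
  ref_tree <- optimize_branch_lengths(tree, sm$alignment)

  ## stage 6: window tracks
  log_line(logcon, "stage windows: width=", config$window_width)
  windows <- window_stats(sm, tree, width = config$window_width)
  write_tsv_file(windows, file.path(out_dir, "windows.tsv"))
  ggc <- gene_gc(sm)
  write_tsv_file(ggc, file.path(out_dir, "gene_gc.tsv"))

  ## stage 7: per-gene rates
  log_line(logcon, "stage gene-rates")
  rate_fit <- fit_gene_rates(ref_tree, masked)
  write_tsv_file(tidy(rate_fit), file.path(out_dir, "gene_rates.tsv"))

  ## stage 8: selection
  log_line(logcon, "stage selection")
  knks <- dplyr::bind_rows(lapply(names(masked), function(g)
    gene_kn_ks(masked[[g]], gene = g)))
  write_tsv_file(knks, file.path(out_dir, "gene_knks.tsv"))
  site_rows <- list()
  branch_rows <- list()
  for (g in names(masked)) {
    aln <- masked[[g]]
    non_gap <- sum(nchar(degap(aln$seqs)) > 0)
    if (non_gap < 3L) next
    a <- site_test_counting(aln, tree, alpha = config$alpha, gene = g)
    b <- site_test_ebgrid(aln, ref_tree,
                          grid_points = config$grid_points,
                          threshold = config$posterior_threshold,
                          gene = g)
    site_rows[[g]] <- consensus_sites(a, b)
    branch_rows[[g]] <- branch_kn_ks(aln, tree, gene = g)
  }
  site_results <- dplyr::bind_rows(site_rows)
  write_tsv_file(site_results, file.path(out_dir, "site_selection.tsv"))
  gene_summary <- summarize_selection(site_results)
  write_tsv_file(gene_summary, file.path(out_dir, "gene_summary.tsv"))
  branch_screen <- dplyr::bind_rows(branch_rows)
  write_tsv_file(branch_screen, file.path(out_dir, "branch_screen.tsv"))

  ## stage 9: enrichment
  enrichment <- NULL
  if (!is.null(ontology) && nrow(site_results)) {
    log_line(logcon, "stage enrichment")
    enrichment <- ontology_enrichment(site_results, ontology)
    write_tsv_file(enrichment, file.path(out_dir, "enrichment.tsv"))
  }

  report <- list(
    package_version = as.character(utils::packageVersion("plastomics")),
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    mode = config$mode,
    n_genes = length(genes), n_taxa = length(taxa),
    n_aligned_genes = length(alignments),
    n_pseudogene_calls = sum(calls$status == "pseudogene"),
    n_absent_calls = sum(calls$status == "absent"),
    n_windows = nrow(windows),
    n_site_rows = nrow(site_results),
    n_consensus_sites = sum(site_results$consensus, na.rm = TRUE))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log_line(logcon, "done")
  invisible(list(calls = calls, alignments = alignments, masked = masked,
                 supermatrix = sm, ref_tree = ref_tree, windows = windows,
                 gene_gc = ggc, rate_fit = rate_fit, knks = knks,
                 site_results = site_results, gene_summary = gene_summary,
                 branch_screen = branch_screen, enrichment = enrichment,
                 report = report))
}

## ---- command-line interface ------------------------------------------------

cli_usage <- function() {
  paste(
    "usage: plastomics <subcommand> [flags]",
    "subcommands:",
    "  simulate  --seed S --out DIR [--taxa N] [--genes N]",
    "  pseudo    --genes DIR --out FILE [--ref TAXON]",
    "  windows   --aln FASTA --tree NWK --out FILE [--width W]",
    "  all       --config FILE [--seed S] [--out DIR]",
    "flags uniform across subcommands: --seed, --config, --out",
    sep = "\n")
}

parse_flags <- function(argv) {
  flags <- list()
  i <- 1L
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--")) stop("unknown argument: ", a, call. = FALSE)
    key <- substring(a, 3)
    if (i == length(argv) || startsWith(argv[i + 1L], "--")) {
      stop("flag --", key, " needs a value", call. = FALSE)
    }
    flags[[key]] <- argv[i + 1L]
    i <- i + 2L
  }
  flags
}

#' Read a flat key-value config file
#'
#' One `key: value` (or `key=value`) pair per line; `#` comments allowed.
#' Keys mirror the arguments of [run_config()].
#'
#' @param path Config file path.
#' @return Named list of values (numbers coerced).
#' @export
read_config_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z_]+)\\s*[:=]\\s*(.*)$", ln))[[1]]
    if (length(m) < 3) stop("config parse error: ", ln, call. = FALSE)
    val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    out[[m[2]]] <- if (!is.na(num)) num else val
  }
  out
}

#' Command-line entry point
#'
#' @param argv Character vector of command-line arguments (subcommand
#'   first).
#' @return Integer exit code (0 = success).
#' @export
cli_main <- function(argv) {
  if (length(argv) == 0L) {
    message(cli_usage())
    return(2L)
  }
  sub <- argv[1]
  flags <- tryCatch(parse_flags(argv[-1]), error = function(e) {
    message(conditionMessage(e))
    message(cli_usage())
    NULL
  })
  if (is.null(flags)) return(2L)
  ok <- tryCatch({
    switch(sub,
      simulate = {
        cfg <- sim_config(seed = as.integer(flags$seed %||% 1),
                          n_taxa = as.integer(flags$taxa %||% 20),
                          n_genes = as.integer(flags$genes %||% 40))
        simulate_dataset(cfg, flags$out %||% "sim_out")
        TRUE
      },
      pseudo = {
        files <- sort(list.files(flags$genes, pattern = "\\.fa(sta)?$",
                                 full.names = TRUE))
        gene_seqs <- dplyr::bind_rows(lapply(files, function(f) {
          recs <- read_fasta(f)
          tibble::tibble(gene = sub("\\.fa(sta)?$", "", basename(f)),
                         taxon = recs$id, residues = degap(recs$residues))
        }))
        calls <- scan_gene_set(gene_seqs, ref_taxon = flags$ref)
        write_tsv_file(calls, flags$out %||% "calls.tsv")
        TRUE
      },
      windows = {
        aln <- read_fasta(flags$aln)
        tree <- read_tree(flags$tree)
        w <- window_stats(stats::setNames(aln$residues, aln$id), tree,
                          width = as.integer(flags$width %||% 100))
        write_tsv_file(w, flags$out %||% "windows.tsv")
        TRUE
      },
      all = {
        vals <- if (!is.null(flags$config)) read_config_file(flags$config)
                else list()
        for (k in intersect(names(flags), c("seed", "out"))) {
          vals[[if (k == "out") "out_dir" else k]] <- flags[[k]]
        }
        mode <- vals$mode %||% "synthetic"
        cfg_args <- vals[intersect(names(vals),
                                   names(formals(run_config)))]
        cfg_args$mode <- mode
        if (is.null(cfg_args$out_dir)) cfg_args$out_dir <- "plastomics_out"
        if (mode == "synthetic") {
          cfg_args$sim <- sim_config(
            seed = as.integer(vals$seed %||% 1),
            n_taxa = as.integer(vals$n_taxa %||% 20),
            n_genes = as.integer(vals$n_genes %||% 40))
        }
        run_all(do.call(run_config, cfg_args))
        TRUE
      },
      {
        message("unknown subcommand: ", sub)
        message(cli_usage())
        FALSE
      })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    FALSE
  })
  if (isTRUE(ok)) 0L else 2L
}
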