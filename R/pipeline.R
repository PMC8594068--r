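#' Read a run configuration file
#'
#' Plain `key = value` text with optional `[section]` headers (ignored) and
#' `#` comments.  Values that parse as numbers become numeric; `true` /
#' `false` become logical.
#'
#' @param path configuration file.
#' @return named list.
#' @export
read_run_config <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  # full-line comments only: "#" can legitimately appear in values (the
  # codeml-style foreground token "#1")
  lines <- lines[nzchar(lines) & !grepl("^[#\\[]", lines)]
  out <- list()
  for (l in lines) {
    kv <- strsplit(l, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", l)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) {
      num
    } else if (tolower(val) %in% c("true", "false")) {
      tolower(val) == "true"
    } else val
  }
  out
}

.config_defaults <- function(config) {
  defs <- list(alpha = 0.05, use_fdr = TRUE, beb_threshold = 0.95,
               n_starts = 3, foreground_token = "#1", basal_up = 5000,
               basal_down = 1000, max_extension = 1e6, seed = 1,
               grid_points = 10)
  for (k in names(defs)) if (is.null(config[[k]])) config[[k]] <- defs[[k]]
  if (config$alpha <= 0 || config$alpha >= 1) stop("alpha must be in (0,1)")
  if (config$beb_threshold <= 0 || config$beb_threshold >= 1) {
    stop("beb_threshold must be in (0,1)")
  }
  config
}

.write_manifest <- function(config, out_dir, extra = list()) {
  cfgfile <- tempfile()
  saveRDS(config[order(names(config))], cfgfile)
  manifest <- c(list(
    package = "hearsel",
    version = as.character(utils::packageVersion("hearsel")),
    config = config,
    config_hash = unname(tools::md5sum(cfgfile))), extra)
  unlink(cfgfile)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Run the coding positive-selection scan
#'
#' Orchestrates the screening over a directory of per-gene codon
#' alignments: per-gene two-step branch-site test (M0 branch lengths, then
#' Model A null/alternative), chi-square LRT, Benjamini-Hochberg FDR
#' across genes, consensus across alignment methods when several alignment
#' directories are supplied, and BEB site posteriors for the significant
#' genes.  Per-gene failures are logged and recorded, not fatal.
#'
#' @param config named list (or path to a `key = value` file, see
#'   [read_run_config()]).  Keys: `alignments` (directory of
#'   `<gene>.fasta` / `.phy` files; subdirectories are treated as
#'   alignment methods), `tree` (Newick with foreground marks), `out_dir`,
#'   and optional `alpha` (0.05), `use_fdr` (TRUE), `beb_threshold`
#'   (0.95), `n_starts` (3), `grid_points` (10), `reference_taxon`,
#'   `foreground_token` (`#1`).
#' @return list with `genes` (per-gene, per-method result table including
#'   q-values), `significant` (consensus gene ids), `sites` (per-site BEB
#'   table for significant genes), `failures`; TSVs and a JSON run
#'   manifest are written to `out_dir`.
#' @export
run_selection_scan <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  config <- .config_defaults(config)
  if (is.null(config$alignments) || is.null(config$tree) ||
      is.null(config$out_dir)) {
    stop("config needs 'alignments', 'tree' and 'out_dir'")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  ltree <- read_labeled_tree(config$tree, token = config$foreground_token)
  if (!length(ltree$foreground)) {
    stop("the input tree has no foreground branch")
  }

  subdirs <- list.dirs(config$alignments, recursive = FALSE)
  methods <- if (length(subdirs)) {
    setNames(subdirs, basename(subdirs))
  } else {
    setNames(config$alignments, "default")
  }

  all_results <- list()
  failures <- data.frame(gene_id = character(0), method = character(0),
                         error = character(0), stringsAsFactors = FALSE)
  tests_by_method <- list()
  for (m in names(methods)) {
    files <- sort(list.files(methods[[m]],
                             pattern = "\\.(fa|fasta|phy|phylip)$",
                             full.names = TRUE))
    tests <- list()
    for (f in files) {
      gene <- tools::file_path_sans_ext(basename(f))
      res <- tryCatch({
        aln <- read_codon_alignment(f)
        branch_site_test(aln, ltree, gene_id = gene,
                         n_starts = config$n_starts)
      }, error = function(e) conditionMessage(e))
      if (is.character(res)) {
        failures <- rbind(failures, data.frame(
          gene_id = gene, method = m, error = res,
          stringsAsFactors = FALSE))
      } else {
        tests[[gene]] <- res
      }
    }
    tests_by_method[[m]] <- tests
    if (length(tests)) {
      tab <- gene_test_table(tests)
      tab$q <- bh_fdr(tab$p)
      tab$alignment_method <- m
      all_results[[m]] <- tab
    } else {
      all_results[[m]] <- data.frame()
    }
  }

  field <- if (isTRUE(config$use_fdr)) "q" else "p"
  nonempty <- all_results[vapply(all_results, nrow, 0L) > 0]
  significant <- if (length(nonempty)) {
    consensus(nonempty, alpha = config$alpha, field = field)
  } else character(0)

  sites <- data.frame()
  first_m <- names(methods)[1]
  for (g in significant) {
    bst <- tests_by_method[[first_m]][[g]]
    if (is.null(bst)) next
    sp <- beb_posteriors(
      read_codon_alignment(sort(list.files(
        methods[[first_m]], pattern = paste0("^", g, "\\."),
        full.names = TRUE))[1]),
      bst$m0$tree, bst$fit_alt$params,
      grid_points = config$grid_points,
      threshold = config$beb_threshold,
      reference_taxon = config$reference_taxon)
    sp <- cbind(gene_id = g, sp, stringsAsFactors = FALSE)
    sites <- if (nrow(sites)) rbind(sites, sp) else sp
  }

  genes_tab <- if (length(nonempty)) {
    do.call(rbind, c(nonempty, list(make.row.names = FALSE)))
  } else {
    data.frame()
  }
  if (nrow(genes_tab)) {
    write_tsv(genes_tab, file.path(config$out_dir, "gene_results.tsv"))
  } else {
    writeLines(paste("gene_id", "lnL_null", "lnL_alt", "lrt_stat", "p",
                     "q", sep = "\t"),
               file.path(config$out_dir, "gene_results.tsv"))
  }
  if (nrow(sites)) {
    write_tsv(sites, file.path(config$out_dir, "pss_sites.tsv"))
  }
  if (nrow(failures)) {
    write_tsv(failures, file.path(config$out_dir, "failures.tsv"))
  }
  .write_manifest(config, config$out_dir,
                  list(n_genes = nrow(genes_tab),
                       n_significant = length(significant)))
  list(genes = genes_tab, significant = significant, sites = sites,
       failures = failures)
}

#' Run the accelerated-region annotation workflow
#'
#' Classifies accelerated regions as coding/noncoding against the exon set
#' and assigns them to genes by gene body, GREAT-style regulatory domain,
#' and (when TADs are supplied) TAD co-membership, then summarises counts.
#'
#' @param config named list or config-file path.  Keys: `regions` (BED),
#'   `genes` (TSV with gene_id, chrom, start, end, strand), `exons` (BED
#'   with gene id in column 4), `out_dir`; optional `tads` (BED),
#'   `lineage` label, `basal_up`, `basal_down`, `max_extension`.
#' @return list with `regions` (classified), `assignments`, `summary`;
#'   TSVs and a manifest are written to `out_dir`.
#' @export
run_region_annotation <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  config <- .config_defaults(config)
  if (is.null(config$regions) || is.null(config$genes) ||
      is.null(config$exons) || is.null(config$out_dir)) {
    stop("config needs 'regions', 'genes', 'exons' and 'out_dir'")
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  regions <- read_bed(config$regions)
  if (!is.null(config$lineage)) regions$lineage <- config$lineage
  units <- utils::read.table(config$genes, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE)
  exons <- read_bed(config$exons)
  exons$gene_id <- exons$id

  miss <- setdiff(unique(regions$chrom), unique(units$chrom))
  if (length(miss)) {
    warning(sum(regions$chrom %in% miss), " region(s) on chromosome(s) ",
            paste(miss, collapse = ","), " absent from the annotation")
  }

  regions <- classify_coding(regions, exons)
  asg <- assign_gene_body(regions, units, exons = exons,
                          noncoding_only = TRUE)
  domains <- build_regulatory_domains(units, config$basal_up,
                                      config$basal_down,
                                      config$max_extension)
  asg <- rbind(asg, assign_reg_domain(regions, domains))
  if (!is.null(config$tads)) {
    tads <- read_bed(config$tads)
    asg <- rbind(asg, assign_tad(regions, units, tads))
  }
  smry <- summarize_assignments(regions, asg)
  write_tsv(regions, file.path(config$out_dir, "regions_classified.tsv"))
  write_tsv(asg, file.path(config$out_dir, "assignments.tsv"))
  write_tsv(smry$by_mode, file.path(config$out_dir, "summary_by_mode.tsv"))
  write_tsv(smry$gene_ranking,
            file.path(config$out_dir, "gene_ranking.tsv"))
  write_tsv(smry$coding_split,
            file.path(config$out_dir, "coding_split.tsv"))
  .write_manifest(config, config$out_dir,
                  list(n_regions = nrow(regions),
                       n_assignments = nrow(asg)))
  list(regions = regions, assignments = asg, summary = smry)
}
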