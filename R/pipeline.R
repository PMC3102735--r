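# End-to-end orchestration: YAML/list config -> promoter extraction or
# FASTA pass-through -> scanning -> clusters -> enrichment report, and the
# expression path (calls -> composition -> overlap -> set enrichment).
# Every output file starts with comment lines carrying the config hash and
# seed, so identical configs give identical files.

#' Load and validate a pipeline configuration
#'
#' Configuration is a YAML file (or an R list) whose recognised fields are:
#' `genome`, `annotations`, `fasta`, `motifs` (list of `NAME: PATTERN`),
#' `window_bp`, `at_fraction` (number or `"estimate"`), `mode`,
#' `strands`, `cluster_gap`, `theta`, `pseudocount`, `expression`,
#' `categories`, `gene_sets`, `n_permutations`, `seed`, `out_prefix`.
#'
#' @param config path to a YAML file or a named list.
#' @return validated config list of class `pipeline_config`.
#' @export
load_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config not found: ", config,
                                   call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or YAML path",
                             call. = FALSE)
  defaults <- list(window_bp = 4000, at_fraction = 0.574,
                   mode = "total_bp", strands = "forward",
                   cluster_gap = 500, theta = 1.5, pseudocount = 1,
                   n_permutations = 1000, seed = 1, out_prefix = "zga")
  for (k in names(defaults))
    if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  known <- c(names(defaults), "genome", "annotations", "fasta", "motifs",
             "expression", "categories", "gene_sets")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (f in c("genome", "annotations", "fasta", "expression",
              "categories"))
    if (!is.null(config[[f]]) && !file.exists(config[[f]]))
      stop("config path for '", f, "' does not exist: ", config[[f]],
           call. = FALSE)
  if (!config$mode %in% c("total_bp", "exact_positions"))
    stop("mode must be total_bp or exact_positions", call. = FALSE)
  if (!config$strands %in% c("forward", "both"))
    stop("strands must be forward or both", call. = FALSE)
  if (config$theta <= 1) stop("theta must be > 1", call. = FALSE)
  structure(config, class = c("pipeline_config", "list"))
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[order(names(config))]), tmp)
  unname(tools::md5sum(tmp))
}

config_header <- function(config) {
  c(paste0("config_md5=", config_hash(unclass(config))),
    paste0("seed=", config$seed),
    paste0("zgatools_version=",
           as.character(utils::packageVersion("zgatools"))))
}

parse_motif_list <- function(motifs) {
  if (is.null(motifs) || length(motifs) == 0)
    stop("config must list at least one motif", call. = FALSE)
  lapply(names(motifs), function(nm) parse_motif(nm, motifs[[nm]]))
}

#' Run the sequence-enrichment pipeline
#'
#' Extracts promoter windows (when `genome` + `annotations` are given) or
#' takes a FASTA sequence set as-is (`fasta`), scans every configured
#' motif, calls site clusters, and tests counts against the compositional
#' binomial background. Writes `<prefix>_promoters.fa` (when extracted),
#' `<prefix>_<motif>_hits.bed`, `<prefix>_<motif>_clusters.bed`, and
#' `<prefix>_enrichment.tsv`.
#'
#' @param config config path or list (see [load_config()]).
#' @param quiet suppress progress messages.
#' @return list of `enrichment_result` (invisibly: paths in attribute
#'   `"files"`).
#' @export
run_enrichment_pipeline <- function(config, quiet = FALSE) {
  config <- load_config(config)
  say <- function(...) if (!quiet) message("[enrich] ", ...)
  hdr <- config_header(config)
  files <- character(0)
  if (!is.null(config$fasta)) {
    say("reading sequence set ", config$fasta)
    seqs <- read_fasta(config$fasta)
  } else if (!is.null(config$genome) && !is.null(config$annotations)) {
    say("extracting ", config$window_bp, " bp promoter windows")
    genome <- read_fasta(config$genome)
    ann <- read_annotations(config$annotations)
    prom <- extract_promoters(genome, ann, config$window_bp)
    seqs <- prom$records
    fa <- paste0(config$out_prefix, "_promoters.fa")
    write_fasta(seqs, fa)
    files <- c(files, fa)
  } else {
    stop("config needs either 'fasta' or 'genome' + 'annotations'",
         call. = FALSE)
  }
  bg <- if (identical(config$at_fraction, "estimate")) {
    say("estimating base composition from the sequence set")
    background_model(base_composition(seqs))
  } else background_model(config$at_fraction)
  motifs <- parse_motif_list(config$motifs)
  say("scanning ", length(motifs), " motif(s) over ", length(seqs),
      " sequences (", config$mode, " mode)")
  results <- set_enrichment_report(seqs, motifs, bg, mode = config$mode,
                                   strands = config$strands,
                                   cluster_gap = config$cluster_gap,
                                   set_name = basename(config$out_prefix))
  for (i in seq_along(results)) {
    m <- motifs[[i]]
    hb <- paste0(config$out_prefix, "_", m$name, "_hits.bed")
    cb <- paste0(config$out_prefix, "_", m$name, "_clusters.bed")
    write_hits_bed(attr(results[[i]], "hits"), m, hb, hdr)
    write_clusters_bed(attr(results[[i]], "clusters"), m, cb, hdr)
    files <- c(files, hb, cb)
  }
  tsv <- paste0(config$out_prefix, "_enrichment.tsv")
  write_enrichment_tsv(results, tsv, hdr)
  files <- c(files, tsv)
  say("wrote ", paste(basename(files), collapse = ", "))
  attr(results, "files") <- files
  invisible(results)
}

#' Run the expression pipeline
#'
#' Computes fold changes and threshold regulation calls, the gene-category
#' composition of the down- and up-regulated sets, and a permutation
#' gene-set enrichment for each configured gene set over the log2
#' fold-change ranking. Writes `<prefix>_calls.tsv`,
#' `<prefix>_composition.json` and `<prefix>_gsea.json`.
#'
#' @param config config path or list; must provide `expression` (TSV) and
#'   optionally `categories` (TSV) and `gene_sets` (named lists of gene
#'   ids, or the name of a category to use as a set).
#' @param quiet suppress progress messages.
#' @return list with `calls`, `composition`, `gsea` (invisibly; file paths
#'   in attribute `"files"`).
#' @export
run_expression_pipeline <- function(config, quiet = FALSE) {
  config <- load_config(config)
  say <- function(...) if (!quiet) message("[expression] ", ...)
  if (is.null(config$expression))
    stop("config needs an 'expression' table", call. = FALSE)
  hdr <- config_header(config)
  table <- read_expression(config$expression)
  categories <- if (!is.null(config$categories))
    read_categories(config$categories) else NULL
  if (is.null(categories))
    warning("no category table given; all genes treated as 'other'",
            call. = FALSE)
  fc <- fold_changes(table, config$pseudocount)
  calls <- call_regulation(fc, config$theta)
  say(sprintf("%d down / %d up / %d unchanged at %.2g-fold",
              attr(calls, "counts")[["down"]],
              attr(calls, "counts")[["up"]],
              attr(calls, "counts")[["unchanged"]], config$theta))
  composition <- lapply(c(down = "down", up = "up"), function(dir) {
    if (length(regulated_genes(calls, dir)) == 0) return(NULL)
    as.list(category_composition(calls, categories, dir))
  })
  gene_sets <- config$gene_sets
  if (is.null(gene_sets) && !is.null(categories)) {
    # default: every category with >= 2 genes present in the table
    gene_sets <- lapply(
      split(names(categories), categories)[
        intersect(GENE_CATEGORIES, unique(categories))],
      intersect, table$gene_id)
    gene_sets <- gene_sets[lengths(gene_sets) >= 2 &
                           lengths(gene_sets) < nrow(table)]
  }
  scores <- log2(fc)
  gsea <- lapply(names(gene_sets), function(nm) {
    gene_set_enrichment(scores, gene_sets[[nm]],
                        n_permutations = config$n_permutations,
                        seed = config$seed, set_name = nm)
  })
  names(gsea) <- names(gene_sets)

  calls_path <- paste0(config$out_prefix, "_calls.tsv")
  con <- file(calls_path, "w")
  writeLines(paste0("# ", hdr), con)
  utils::write.table(as.data.frame(calls), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  comp_path <- paste0(config$out_prefix, "_composition.json")
  jsonlite::write_json(
    list(header = as.list(hdr), counts = as.list(attr(calls, "counts")),
         composition = composition),
    comp_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  gsea_path <- paste0(config$out_prefix, "_gsea.json")
  jsonlite::write_json(
    list(header = as.list(hdr),
         results = lapply(gsea, function(g) as.list(
           as.data.frame(g)))),
    gsea_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(calls_path, comp_path, gsea_path)
  say("wrote ", paste(basename(files), collapse = ", "))
  out <- list(calls = calls, composition = composition, gsea = gsea)
  attr(out, "files") <- files
  invisible(out)
}
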