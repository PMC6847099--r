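# End-to-end orchestration: run every analysis stage in dependency order,
# write the per-stage TSV reports and a JSON run manifest with exclusion
# accounting.  All stage logic lives in the per-module functions; this file
# only wires them together.

#' Build a run configuration
#'
#' Inputs may be file paths (read with the package readers) or the
#' corresponding in-memory objects.  Every tunable of the downstream stages
#' is exposed here so a run is fully described by its resolved config.
#'
#' @param genome FASTA path or [Biostrings::DNAStringSet].
#' @param annotations GFF3 path or annotation data.frame.
#' @param rna_counts,ribo_counts counts TSV paths or `counts_table`s.
#' @param tss optional TSS TSV path or data.frame (promoter stage skipped
#'   when absent).
#' @param out_dir output directory.
#' @param fraction representative-set fraction.
#' @param n_groups number of ARD groups (8 = octiles).
#' @param positions TIR offsets for composition profiles/contrasts.
#' @param alpha family-wise error rate for all Bonferroni corrections.
#' @param fold run the secondary-structure stage.
#' @param fold_window half-width of the folding window in nt.
#' @param fold_max_genes cap on genes folded per contrasted group (keeps
#'   runtime proportionate; the positional tests lose little power beyond
#'   this).
#' @param contrast_base nucleotide for the octile contrast.
#' @param feature_type,id_attribute GFF options for [read_annotations()].
#' @return object of class `run_config`.
#' @export
run_config <- function(genome, annotations, rna_counts, ribo_counts,
                       tss = NULL, out_dir = tempfile("tirscope_run_"),
                       fraction = 1 / 3, n_groups = 8, positions = -30:30,
                       alpha = 0.05, fold = TRUE, fold_window = 100,
                       fold_max_genes = 50, contrast_base = "A",
                       feature_type = "CDS", id_attribute = "locus_tag") {
  structure(as.list(environment()), class = "run_config")
}

.resolve_input <- function(x, reader, what) {
  if (is.character(x)) {
    if (!file.exists(x)) stop("missing ", what, " file: ", x)
    reader(x)
  } else x
}

#' Run the full pipeline
#'
#' Stages, in dependency order: input resolution, expression profiling,
#' TIR composition + octile contrast, local secondary structure (optional),
#' promoter analysis (when a TSS table is supplied) and trinucleotide
#' ratios.  Each stage's tables are written to `config$out_dir` together
#' with `manifest.json` recording the resolved configuration and the genes
#' excluded at every filter.  Deterministic stages are bit-reproducible on
#' identical inputs and config.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with the stage results: `expression`,
#'   `profile_all`, `contrast`, `structure`, `promoters`, `trinuc`,
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "tirscope",
                   version = as.character(utils::packageVersion("tirscope")),
                   config = config[!vapply(config, is.object, logical(1))])

  genome <- .resolve_input(config$genome, read_genome, "genome")
  genes <- .resolve_input(config$annotations, function(p) {
    read_annotations(p, config$feature_type, config$id_attribute)
  }, "annotation")
  rna <- .resolve_input(config$rna_counts,
                        function(p) read_counts_table(p, "rna"), "RNA counts")
  ribo <- .resolve_input(config$ribo_counts,
                         function(p) read_counts_table(p, "ribo"),
                         "ribo counts")
  tss <- if (is.null(config$tss)) NULL else
    .resolve_input(config$tss, read_tss, "TSS")

  message("stage: expression")
  prof <- suppressMessages(
    expression_profile(rna, ribo, genes, config$fraction, config$n_groups))
  write_tsv_report(prof$table, file.path(config$out_dir, "expression.tsv"))
  manifest$expression <- list(
    n_genes = nrow(prof$table),
    n_representative = length(prof$representative),
    group_size = length(prof$representative) %/% config$n_groups,
    excluded = prof$excluded)

  message("stage: tir composition")
  hi_genes <- genes[genes$gene_id %in% octile_genes(prof, 1L), ]
  lo_genes <- genes[genes$gene_id %in% octile_genes(prof, config$n_groups), ]
  up <- -min(config$positions); dn <- max(config$positions)
  all_w <- tir_windows(genome,
                       genes[genes$gene_id %in% prof$representative, ],
                       upstream = up, downstream = dn)
  freq_all <- positional_frequencies(all_w, config$positions)
  write_tsv_report(as.data.frame(freq_all),
                   file.path(config$out_dir, "tir_frequencies.tsv"))
  hi_w <- all_w[hi_genes$gene_id]
  lo_w <- all_w[lo_genes$gene_id]
  ctr <- octile_contrast(hi_w, lo_w, config$positions,
                         base = config$contrast_base, alpha = config$alpha)
  write_tsv_report(ctr, file.path(config$out_dir, "tir_contrast.tsv"))
  manifest$composition <- list(
    positions_tested = attr(ctr, "m"),
    bonferroni_threshold = attr(ctr, "threshold"),
    n_significant = sum(ctr$significant))

  structure_res <- NULL
  if (isTRUE(config$fold)) {
    message("stage: secondary structure")
    pick <- function(g) utils::head(g, config$fold_max_genes)
    hi_p <- suppressMessages(
      fold_tir_set(genome, pick(hi_genes), upstream = config$fold_window,
                   downstream = config$fold_window))
    lo_p <- suppressMessages(
      fold_tir_set(genome, pick(lo_genes), upstream = config$fold_window,
                   downstream = config$fold_window))
    structure_res <- average_pairing_by_set(
      list(octile_high = hi_p, octile_low = lo_p), alpha = config$alpha)
    if (!is.null(structure_res$contrast)) {
      write_tsv_report(structure_res$contrast,
                       file.path(config$out_dir, "pairing_contrast.tsv"))
    }
    manifest$structure <- list(
      n_high = length(hi_p), n_low = length(lo_p),
      n_skipped = nrow(pick(hi_genes)) + nrow(pick(lo_genes)) -
        length(hi_p) - length(lo_p))
  }

  promoter_res <- NULL
  if (!is.null(tss)) {
    message("stage: promoters")
    tss_rep <- tss[tss$gene_id %in% prof$representative, , drop = FALSE]
    ups <- vapply(seq_len(nrow(tss_rep)), function(i) {
      extract_upstream_of_tss(genome, tss_rep[i, ], 50)
    }, character(1))
    names(ups) <- tss_rep$gene_id
    hits <- find_candidate_elements(ups)
    hist <- spacing_histogram(hits)
    probable <- filter_probable_promoters(hits)
    model <- if (nrow(probable) >= 2) {
      build_promoter_model(probable, ups, flank = 10)
    } else NULL
    leaders <- leader_lengths(tss_rep, genes)
    write_tsv_report(hits, file.path(config$out_dir, "promoter_hits.tsv"))
    write_tsv_report(
      data.frame(spacing = as.integer(names(hist)),
                 proportion = unname(hist)),
      file.path(config$out_dir, "promoter_spacing.tsv"))
    if (!is.null(model)) {
      write_tsv_report(
        data.frame(position = rep(model$positions, each = 4),
                   base = rep(BASES_DNA, length(model$positions)),
                   frequency = as.vector(model$frequencies),
                   n = rep(model$n, each = 4)),
        file.path(config$out_dir, "promoter_frequencies.tsv"))
    }
    write_tsv_report(
      data.frame(gene_id = names(leaders$lengths),
                 leader = unname(leaders$lengths)),
      file.path(config$out_dir, "leader_lengths.tsv"))
    promoter_res <- list(hits = hits, histogram = hist,
                         probable = probable, model = model,
                         leaders = leaders)
    manifest$promoters <- list(
      n_tss = nrow(tss_rep), n_candidates = nrow(hits),
      n_probable = nrow(probable),
      consensus = if (!is.null(model)) model$consensus else NA,
      leader_mean = leaders$mean, leader_frac_over = leaders$frac_over)
  }

  message("stage: trinucleotide ratios")
  trinuc <- genome_ratios(genome, genes, gene_ids = prof$representative,
                          genome_id = "run")
  write_tsv_report(
    data.frame(window = rownames(trinuc$ratios),
               round(as.data.frame(trinuc$ratios), 6),
               n_genes = unname(trinuc$n_genes), check.names = FALSE),
    file.path(config$out_dir, "trinucleotide_ratios.tsv"))
  manifest$trinuc <- list(n_total = trinuc$n_total,
                          n_genes = as.list(trinuc$n_genes))

  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  invisible(list(expression = prof, profile_all = freq_all, contrast = ctr,
                 structure = structure_res, promoters = promoter_res,
                 trinuc = trinuc, manifest = manifest))
}
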