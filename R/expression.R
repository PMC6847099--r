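# Expression profiling: representative-set construction, CPM normalisation,
# average ribosome density (ARD), octile assignment, synthesis rates and
# replicate QC.
#
# ARD is the per-gene ratio of CPM-normalised ribo-seq footprint counts to
# CPM-normalised RNA-seq fragment counts, a quantity that largely reflects
# translation initiation rate (often called translation efficiency, TE).

#' Per-gene counts for one assay
#'
#' @param counts non-negative integer matrix, genes x replicates.  Row names
#'   (or `gene_ids`) identify genes, column names (or `sample_ids`)
#'   replicates.
#' @param assay `"rna"` or `"ribo"`.
#' @param gene_ids,sample_ids optional explicit identifiers.
#' @return object of class `counts_table`.
#' @export
counts_table <- function(counts, assay = c("rna", "ribo"),
                         gene_ids = rownames(counts),
                         sample_ids = colnames(counts)) {
  assay <- match.arg(assay)
  counts <- as.matrix(counts)
  if (is.null(gene_ids)) stop("counts_table: gene ids required")
  if (is.null(sample_ids)) {
    sample_ids <- paste0(assay, "_rep", seq_len(ncol(counts)))
  }
  if (ncol(counts) < 1L) stop("counts_table: need at least one replicate")
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts_table: counts must be non-negative integers")
  }
  if (anyDuplicated(gene_ids)) stop("counts_table: duplicate gene ids")
  dimnames(counts) <- list(gene_ids, sample_ids)
  structure(list(assay = assay, genes = gene_ids, samples = sample_ids,
                 counts = counts),
            class = "counts_table")
}

#' @export
print.counts_table <- function(x, ...) {
  cat(sprintf("counts_table (%s): %d genes x %d replicate(s), %d total counts\n",
              x$assay, length(x$genes), length(x$samples), sum(x$counts)))
  invisible(x)
}

#' Read / write a counts table (TSV, first column gene_id)
#'
#' @param path TSV path; remaining columns are replicate counts.
#' @param assay `"rna"` or `"ribo"`.
#' @return a `counts_table`.
#' @export
read_counts_table <- function(path, assay) {
  df <- read_tsv_report(path)
  if (names(df)[1] != "gene_id") stop("first column must be gene_id: ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  counts_table(m, assay = assay)
}

#' @rdname read_counts_table
#' @param x a `counts_table`.
#' @export
write_counts_table <- function(x, path) {
  df <- data.frame(gene_id = x$genes, x$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_report(df, path)
}

#' Combine replicates by summing per-gene counts
#'
#' @param tables a single `counts_table` (replicates as columns) or a list of
#'   `counts_table`s of the same assay over the same gene universe.
#' @return a single-column `counts_table` of per-gene sums.
#' @export
combine_replicates <- function(tables) {
  if (inherits(tables, "counts_table")) tables <- list(tables)
  if (!length(tables)) stop("combine_replicates: no tables given")
  assays <- unique(vapply(tables, `[[`, character(1), "assay"))
  if (length(assays) != 1L) stop("combine_replicates: assay mismatch")
  ref <- tables[[1]]$genes
  for (t in tables) {
    if (!identical(sort(t$genes), sort(ref))) {
      stop("combine_replicates: gene set mismatch between replicates")
    }
  }
  total <- Reduce(`+`, lapply(tables, function(t) {
    rowSums(t$counts)[ref]
  }))
  counts_table(matrix(total, ncol = 1,
                      dimnames = list(ref, "combined")),
               assay = assays)
}

# per-gene totals of a counts table (replicate-summed)
.gene_totals <- function(x) rowSums(x$counts)

#' Select the representative (highly transcribed) gene set
#'
#' Genes are rank-ordered, highest to lowest, by RNA-seq fragments per gene
#' length (replicate-summed), and the top `floor(fraction * n)` are kept,
#' where `n` is the full annotated gene count.  Ties are broken by gene id
#' (lexicographically smaller kept first).  Genes with zero RNA density are
#' never selected.
#'
#' @param rna an RNA-seq `counts_table`.
#' @param genes annotation data.frame supplying `gene_id` and `length`.
#' @param fraction fraction of genes to keep, in (0, 1\].
#' @return character vector of selected gene ids (ranked).
#' @export
select_representative_set <- function(rna, genes, fraction = 1 / 3) {
  stopifnot(fraction > 0, fraction <= 1)
  total <- .gene_totals(rna)
  len <- stats::setNames(genes$length, genes$gene_id)[names(total)]
  if (anyNA(len)) {
    stop("select_representative_set: genes without annotated length: ",
         paste(utils::head(names(total)[is.na(len)]), collapse = ", "))
  }
  density <- total / len
  ord <- order(-density, names(density))
  k <- floor(fraction * length(density))
  sel <- names(density)[ord][seq_len(k)]
  nonzero <- density[sel] > 0
  if (!all(nonzero)) {
    message("select_representative_set: dropped ", sum(!nonzero),
            " zero-density gene(s) from the selection")
    sel <- sel[nonzero]
  }
  sel
}

#' Counts-per-million normalisation against a representative set
#'
#' The scale factor is computed from the representative genes only
#' (`1e6 / sum(counts over representative)`) and applied to every gene.
#'
#' @param table a `counts_table` (replicates are summed first).
#' @param representative character vector of representative gene ids.
#' @return named numeric vector of CPM values for every gene in `table`.
#' @export
normalize_cpm <- function(table, representative) {
  if (!length(representative)) stop("normalize_cpm: empty representative set")
  total <- .gene_totals(table)
  missing <- setdiff(representative, names(total))
  if (length(missing)) {
    stop("normalize_cpm: representative gene(s) absent from table: ",
         paste(utils::head(missing), collapse = ", "))
  }
  denom <- sum(total[representative])
  if (denom <= 0) stop("normalize_cpm: representative set has zero total")
  total * 1e6 / denom
}

#' Average ribosome density per gene
#'
#' `ard = ribo_cpm / rna_cpm`; genes with zero RNA CPM get `NA` (undefined)
#' and are excluded from octile assignment downstream.
#'
#' @param rna_cpm,ribo_cpm named numeric vectors over the same genes.
#' @return data.frame with `gene_id`, `rna_cpm`, `ribo_cpm`, `ard`.
#' @export
compute_ard <- function(rna_cpm, ribo_cpm) {
  if (!identical(sort(names(rna_cpm)), sort(names(ribo_cpm)))) {
    stop("compute_ard: gene sets differ between assays")
  }
  ribo_cpm <- ribo_cpm[names(rna_cpm)]
  ard <- ifelse(rna_cpm > 0, ribo_cpm / rna_cpm, NA_real_)
  n_undef <- sum(is.na(ard))
  if (n_undef > 0) {
    message("compute_ard: ", n_undef, " gene(s) with zero RNA CPM (ARD undefined)")
  }
  data.frame(gene_id = names(rna_cpm), rna_cpm = unname(rna_cpm),
             ribo_cpm = unname(ribo_cpm), ard = unname(ard),
             stringsAsFactors = FALSE)
}

#' Assign expression octiles by ARD rank
#'
#' Representative genes are sorted by ARD, highest first, and divided into
#' `n_groups` equal groups of `floor(n / n_groups)` genes; group 1 holds the
#' highest-ARD genes.  Remainder genes (the lowest-ARD tail) are left
#' unassigned (`NA`).
#'
#' @param ard named numeric ARD vector (or data.frame from [compute_ard()]).
#' @param representative gene ids to bin; all must have a defined ARD.
#' @param n_groups number of groups (default 8, i.e. octiles).
#' @return named integer vector over `representative` (NA = unassigned).
#' @export
assign_octiles <- function(ard, representative, n_groups = 8) {
  if (is.data.frame(ard)) ard <- stats::setNames(ard$ard, ard$gene_id)
  a <- ard[representative]
  if (anyNA(a)) {
    stop("assign_octiles: undefined ARD for representative gene(s): ",
         paste(utils::head(representative[is.na(a)]), collapse = ", "))
  }
  n <- length(a)
  if (n < n_groups) stop("assign_octiles: fewer genes than groups")
  size <- n %/% n_groups
  ord <- order(-a, names(a))
  oct <- rep(NA_integer_, n)
  oct[ord[seq_len(size * n_groups)]] <-
    rep(seq_len(n_groups), each = size)
  n_drop <- n - size * n_groups
  if (n_drop > 0) {
    message("assign_octiles: ", n_drop,
            " lowest-ARD gene(s) left unassigned (remainder)")
  }
  stats::setNames(oct, names(a))
}

#' Relative protein synthesis rates
#'
#' Ribo-seq coverage per gene length, scaled so the rates sum to 1e6 across
#' all genes (relative units); a proxy for relative protein production.
#'
#' @param ribo a ribo-seq `counts_table`.
#' @param genes annotation data.frame supplying lengths.
#' @return named numeric vector of relative rates.
#' @export
synthesis_rates <- function(ribo, genes) {
  total <- .gene_totals(ribo)
  len <- stats::setNames(genes$length, genes$gene_id)[names(total)]
  if (anyNA(len) || any(len <= 0)) {
    stop("synthesis_rates: missing or non-positive gene length")
  }
  rate <- total / len
  s <- sum(rate)
  if (s <= 0) stop("synthesis_rates: all rates are zero")
  rate * 1e6 / s
}

#' Pairwise Spearman correlations between replicates
#'
#' Replicate-to-replicate reproducibility over per-gene counts.
#'
#' @param table a `counts_table` with >= 2 replicates.
#' @return symmetric matrix of Spearman correlation coefficients.
#' @export
replicate_spearman <- function(table) {
  if (length(table$samples) < 2L) {
    stop("replicate_spearman: need at least 2 replicates")
  }
  stats::cor(table$counts, method = "spearman")
}

#' Build a full per-gene expression profile
#'
#' Runs the whole expression stage: replicate combination, representative-set
#' selection, CPM normalisation, ARD, octile assignment and synthesis rates.
#'
#' @param rna,ribo `counts_table`s (multi-replicate).
#' @param genes annotation data.frame.
#' @param fraction representative-set fraction (default top third).
#' @param n_groups number of ARD groups (default 8, octiles).
#' @return object of class `expression_profile`: list with `table` (per-gene
#'   data.frame: `gene_id`, `rna_count`, `ribo_count`, `rna_cpm`, `ribo_cpm`,
#'   `ard`, `synthesis_rate`, `octile`), `representative`, `n_groups` and an
#'   `excluded` accounting list.
#' @export
expression_profile <- function(rna, ribo, genes, fraction = 1 / 3,
                               n_groups = 8) {
  stopifnot(inherits(rna, "counts_table"), inherits(ribo, "counts_table"))
  if (rna$assay != "rna" || ribo$assay != "ribo") {
    stop("expression_profile: pass the RNA table first, ribo second")
  }
  if (!identical(sort(rna$genes), sort(ribo$genes))) {
    stop("expression_profile: assays cover different gene sets")
  }
  rna_c <- combine_replicates(rna)
  ribo_c <- combine_replicates(ribo)
  rep_set <- select_representative_set(rna_c, genes, fraction)
  rna_cpm <- normalize_cpm(rna_c, rep_set)
  ribo_cpm <- normalize_cpm(ribo_c, rep_set)[names(rna_cpm)]
  ard <- suppressMessages(compute_ard(rna_cpm, ribo_cpm))
  oct <- assign_octiles(ard, rep_set, n_groups)
  rates <- synthesis_rates(ribo_c, genes)
  tab <- data.frame(
    gene_id = ard$gene_id,
    rna_count = unname(.gene_totals(rna_c)[ard$gene_id]),
    ribo_count = unname(.gene_totals(ribo_c)[ard$gene_id]),
    rna_cpm = ard$rna_cpm,
    ribo_cpm = ard$ribo_cpm,
    ard = ard$ard,
    synthesis_rate = unname(rates[ard$gene_id]),
    octile = unname(oct[ard$gene_id]),
    stringsAsFactors = FALSE)
  structure(list(table = tab,
                 representative = rep_set,
                 n_groups = n_groups,
                 excluded = list(
                   zero_rna = sum(is.na(tab$ard)),
                   octile_remainder = length(rep_set) %% n_groups)),
            class = "expression_profile")
}

#' @export
print.expression_profile <- function(x, ...) {
  n <- nrow(x$table)
  size <- length(x$representative) %/% x$n_groups
  cat("expression_profile\n")
  cat(sprintf("  %d genes; representative set: %d; %d groups of %d\n",
              n, length(x$representative), x$n_groups, size))
  cat(sprintf("  genes with undefined ARD (zero RNA): %d\n",
              x$excluded$zero_rna))
  invisible(x)
}

#' @export
summary.expression_profile <- function(object, ...) {
  tab <- object$table[!is.na(object$table$octile), ]
  rng <- do.call(rbind, lapply(split(tab$ard, tab$octile), range))
  out <- data.frame(octile = as.integer(rownames(rng)),
                    n = as.integer(table(tab$octile)),
                    ard_min = rng[, 1], ard_max = rng[, 2])
  cat("ARD range by octile (1 = highest ARD):\n")
  print(out, row.names = FALSE)
  invisible(out)
}

#' Gene ids belonging to one octile
#'
#' @param profile an `expression_profile`.
#' @param octile group number (1 = highest ARD).
#' @return character vector of gene ids.
#' @export
octile_genes <- function(profile, octile) {
  tab <- profile$table
  tab$gene_id[!is.na(tab$octile) & tab$octile == octile]
}
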