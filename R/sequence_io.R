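# Sequence and annotation input/output plus strand-aware window extraction.
#
# Internal coordinates are 0-based half-open throughout; file interfaces use
# each format's native convention (GFF3 is 1-based inclusive).  "Offset 0" of
# a TIR window is the first nucleotide of the start codon; offset -1 is the
# base immediately 5' of it on the mRNA.

#' Read a genome from FASTA
#'
#' Sequences are uppercased and U is converted to T on input, so RNA FASTA is
#' accepted.  Characters outside `{A,C,G,T,N}`, duplicate contig ids and
#' empty records are rejected.
#'
#' @param path path to a FASTA file.
#' @return a named [Biostrings::DNAStringSet], one entry per contig.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(raw))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate contig id(s) in ", path, ": ", paste(dup, collapse = ", "))
  }
  seqs <- chartr("U", "T", toupper(as.character(raw)))
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence for record(s): ",
         paste(ids[nchar(seqs) == 0L], collapse = ", "))
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("illegal characters in record(s): ", paste(ids[bad], collapse = ", "))
  }
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- ids
  genome
}

#' Read gene annotations from GFF3
#'
#' Keeps records of one feature type and converts the GFF3 1-based inclusive
#' coordinates to the internal 0-based half-open convention.  The gene
#' identifier is taken from a configurable attribute key because NCBI GFF
#' dialects differ.
#'
#' @param path path to a GFF3 file.
#' @param feature_type feature type to keep (column 3; default `"CDS"`).
#' @param id_attribute attribute key holding the gene id (default
#'   `"locus_tag"`).
#' @return data.frame with columns `gene_id`, `contig`, `start` (0-based,
#'   inclusive), `end` (0-based, exclusive), `strand`, `length`.
#' @export
read_annotations <- function(path, feature_type = "CDS",
                             id_attribute = "locus_tag") {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == feature_type]
  if (length(gr) == 0L) {
    stop("no '", feature_type, "' features found in ", path)
  }
  strands <- as.character(GenomicRanges::strand(gr))
  if (any(strands == "*")) {
    stop("feature(s) without a strand ('.') at record(s) ",
         paste(which(strands == "*"), collapse = ", "), " of ", path)
  }
  ids <- S4Vectors::mcols(gr)[[id_attribute]]
  if (is.null(ids)) {
    stop("attribute '", id_attribute, "' absent from ", feature_type,
         " records in ", path)
  }
  ids <- as.character(ids)
  if (anyNA(ids)) {
    stop("missing '", id_attribute, "' for record(s) ",
         paste(which(is.na(ids)), collapse = ", "), " of ", path)
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate gene id(s) in ", path, ": ", paste(dup, collapse = ", "))
  }
  data.frame(gene_id = ids,
             contig = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = strands,
             length = GenomicRanges::width(gr),
             stringsAsFactors = FALSE)
}

#' Write gene annotations to GFF3
#'
#' Inverse of [read_annotations()]: internal 0-based half-open coordinates
#' are written back as GFF3 1-based inclusive values.
#'
#' @param genes annotation data.frame as returned by [read_annotations()].
#' @param path output path.
#' @param feature_type feature type for column 3.
#' @param id_attribute attribute key to store the gene id under.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(genes, path, feature_type = "CDS",
                              id_attribute = "locus_tag") {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand)
  S4Vectors::mcols(gr)[["source"]] <- "tirscope"
  S4Vectors::mcols(gr)[["type"]] <- feature_type
  if (feature_type == "CDS") S4Vectors::mcols(gr)[["phase"]] <- 0L
  S4Vectors::mcols(gr)[[id_attribute]] <- genes$gene_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a transcriptional start site (TSS) table
#'
#' TSV with columns `gene_id`, `contig`, `position` (0-based, on the gene's
#' strand), `strand`.  TSS prediction itself is out of scope; this table is
#' consumed as produced by an external predictor.
#'
#' @param path file to read.
#' @return data.frame of TSS records.
#' @export
read_tss <- function(path) {
  df <- read_tsv_report(path)
  need <- c("gene_id", "contig", "position", "strand")
  if (!all(need %in% names(df))) {
    stop("TSS table must have columns ", paste(need, collapse = ", "))
  }
  df$position <- as.integer(df$position)
  df[need]
}

#' @rdname read_tss
#' @param tss TSS data.frame.
#' @export
write_tss <- function(tss, path) {
  write_tsv_report(tss[, c("gene_id", "contig", "position", "strand")], path)
}

#' Extract a strand-aware TIR window around a start codon
#'
#' Returns the mRNA-sense RNA sequence covering offsets
#' `[-upstream, +downstream]`, where offset 0 is the first nucleotide of the
#' annotated start codon.  Reverse-strand genes yield the reverse complement,
#' transcribed T to U.  Windows crossing a contig edge are shortened (never
#' padded) and flagged `complete = FALSE`; offsets are preserved.
#'
#' @param genome named [Biostrings::DNAStringSet] from [read_genome()].
#' @param gene one annotation row (list or single-row data.frame) with fields
#'   `gene_id`, `contig`, `start`, `end`, `strand`.
#' @param upstream,downstream non-negative window extents in nt.
#' @return an object of class `tir_window`: list with `gene_id`, `offsets`
#'   (integer vector), `sequence` (RNA string) and `complete`.
#' @export
extract_tir_window <- function(genome, gene, upstream, downstream) {
  stopifnot(upstream >= 0, downstream >= 0)
  gene <- as.list(gene)
  if (!gene$contig %in% names(genome)) {
    stop("contig not present in genome: ", gene$contig)
  }
  contig <- genome[[gene$contig]]
  L <- length(contig)
  if (gene$strand == "+") {
    anchor <- gene$start
    g0 <- max(0L, anchor - as.integer(upstream))
    g1 <- min(L, anchor + as.integer(downstream) + 1L)
    seq_dna <- as.character(Biostrings::subseq(contig, g0 + 1L, g1))
    offsets <- seq.int(g0 - anchor, g1 - 1L - anchor)
  } else {
    anchor <- gene$end - 1L
    g0 <- max(0L, anchor - as.integer(downstream))
    g1 <- min(L, anchor + as.integer(upstream) + 1L)
    seq_dna <- as.character(Biostrings::reverseComplement(
      Biostrings::subseq(contig, g0 + 1L, g1)))
    offsets <- seq.int(anchor - (g1 - 1L), anchor - g0)
  }
  structure(list(gene_id = gene$gene_id,
                 offsets = offsets,
                 sequence = dna_to_rna(seq_dna),
                 complete = length(offsets) == upstream + downstream + 1L),
            class = "tir_window")
}

#' @export
print.tir_window <- function(x, ...) {
  cat("TIR window for", x$gene_id, "\n")
  cat("  offsets:", min(x$offsets), "..", max(x$offsets),
      if (!x$complete) "(truncated)" else "", "\n")
  cat("  sequence:", x$sequence, "\n")
  invisible(x)
}

#' Base at a given offset of a TIR window
#'
#' @param window a `tir_window`.
#' @param offset integer offset (0 = first base of the start codon).
#' @return single RNA character, or `NA` if the offset lies outside the
#'   window.
#' @export
window_base <- function(window, offset) {
  i <- match(offset, window$offsets)
  if (is.na(i)) return(NA_character_)
  substr(window$sequence, i, i)
}

#' Contiguous sub-sequence of a TIR window by offset range
#'
#' @param window a `tir_window`.
#' @param from,to inclusive offset range.
#' @param require_complete if `TRUE` (default) return `NA` unless every
#'   offset in the range is present and no base is `N`.
#' @return RNA string or `NA`.
#' @export
window_subseq <- function(window, from, to, require_complete = TRUE) {
  i0 <- match(from, window$offsets)
  i1 <- match(to, window$offsets)
  if (is.na(i0) || is.na(i1)) {
    if (require_complete) return(NA_character_)
    present <- window$offsets >= from & window$offsets <= to
    if (!any(present)) return(NA_character_)
    i0 <- min(which(present)); i1 <- max(which(present))
  }
  s <- substr(window$sequence, i0, i1)
  if (require_complete && grepl("N", s, fixed = TRUE)) return(NA_character_)
  s
}

#' Extract TIR windows for a set of genes
#'
#' @inheritParams extract_tir_window
#' @param genes annotation data.frame.
#' @return named list of `tir_window` objects (names = gene ids).
#' @export
tir_windows <- function(genome, genes, upstream = 30, downstream = 30) {
  out <- lapply(seq_len(nrow(genes)), function(i) {
    extract_tir_window(genome, genes[i, ], upstream, downstream)
  })
  names(out) <- genes$gene_id
  out
}

#' Sequence immediately upstream of a TSS
#'
#' Returns the `n` nucleotides 5' of (not including) the TSS on the gene's
#' strand, as an RNA-alphabet string; shorter if a contig edge intervenes.
#'
#' @param genome named [Biostrings::DNAStringSet].
#' @param tss one TSS record (list/row with `contig`, `position`, `strand`).
#' @param n number of nucleotides requested (>= 1).
#' @return RNA string (possibly shorter than `n`, possibly empty).
#' @export
extract_upstream_of_tss <- function(genome, tss, n) {
  stopifnot(n >= 1)
  tss <- as.list(tss)
  if (!tss$contig %in% names(genome)) {
    stop("contig not present in genome: ", tss$contig)
  }
  contig <- genome[[tss$contig]]
  L <- length(contig)
  pos <- as.integer(tss$position)
  if (tss$strand == "+") {
    g0 <- max(0L, pos - as.integer(n)); g1 <- pos
    if (g1 <= g0) return("")
    s <- as.character(Biostrings::subseq(contig, g0 + 1L, g1))
  } else {
    g0 <- pos + 1L; g1 <- min(L, pos + 1L + as.integer(n))
    if (g1 <= g0) return("")
    s <- as.character(Biostrings::reverseComplement(
      Biostrings::subseq(contig, g0 + 1L, g1)))
  }
  dna_to_rna(s)
}

#' Full mRNA-sense coding sequence of a gene
#'
#' @param genome named [Biostrings::DNAStringSet].
#' @param gene one annotation row.
#' @return RNA string of length `end - start`.
#' @export
gene_mrna <- function(genome, gene) {
  gene <- as.list(gene)
  if (!gene$contig %in% names(genome)) {
    stop("contig not present in genome: ", gene$contig)
  }
  s <- Biostrings::subseq(genome[[gene$contig]], gene$start + 1L, gene$end)
  if (gene$strand == "-") s <- Biostrings::reverseComplement(s)
  dna_to_rna(as.character(s))
}
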