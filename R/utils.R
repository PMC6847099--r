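# Internal helpers shared across modules.

BASES_DNA <- c("A", "C", "G", "T")
BASES_RNA <- c("A", "C", "G", "U")

dna_to_rna <- function(x) chartr("Tt", "Uu", x)
rna_to_dna <- function(x) chartr("Uu", "Tt", x)

# reverse complement of a DNA character scalar/vector (keeps N)
revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# reverse complement of a character *vector* of single bases
revcomp_vec <- function(v) {
  rev(c(A = "T", C = "G", G = "C", T = "A", N = "N")[v])
}

#' Write a tab-separated report with a commented header line
#'
#' All tirscope writers emit UTF-8 TSV whose first line is the column header
#' prefixed with `#`, so downstream tools that skip comment lines still see a
#' clean table.
#'
#' @param df data.frame to write.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(df, path) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  if (nrow(df) > 0) {
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a tab-separated report written by [write_tsv_report()]
#'
#' Accepts either a `#`-commented or a plain header line.
#'
#' @param path file to read.
#' @return data.frame.
#' @export
read_tsv_report <- function(path) {
  first <- readLines(path, n = 1L)
  if (startsWith(first, "#")) {
    hdr <- strsplit(sub("^#", "", first), "\t", fixed = TRUE)[[1]]
    utils::read.table(path, sep = "\t", skip = 1L, col.names = hdr,
                      stringsAsFactors = FALSE, quote = "", comment.char = "")
  } else {
    utils::read.table(path, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, quote = "", comment.char = "#")
  }
}

# minimal IUPAC code covering a set of DNA bases (sorted subset of A,C,G,T)
iupac_code <- function(bases) {
  codes <- c(A = "A", C = "C", G = "G", T = "T",
             AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
             ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N")
  key <- paste(sort(unique(bases)), collapse = "")
  if (!key %in% names(codes)) stop("not a DNA base set: ", key)
  unname(codes[key])
}
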