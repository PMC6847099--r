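# Bacteroidetes -7 promoter element analysis: candidate discovery in
# TSS-upstream sequences, spacing histogram, probable-promoter filtering,
# positional frequency model, IUPAC consensus derivation and leader-length
# statistics.
#
# Spacing convention: the number of nucleotides strictly between the
# element's 3' base and the TSS, so "4 or 5 nt spacing" means 4-5
# intervening bases.  Element coordinate labels follow the -7 element
# nomenclature (element = positions -12..-5 for spacing 4, i.e. T-12 A-11
# .. T-6 G-5).

PROMOTER_SEED <- "TANNTTTG"

# normalise sequences to uppercase DNA
.as_dna_upper <- function(x) chartr("U", "T", toupper(x))

#' Find candidate -7 promoter elements upstream of TSSs
#'
#' Two discovery modes over the sequences immediately upstream of predicted
#' TSSs (conventionally the 50 nt 5' of each TSS):
#'
#' * `consensus_scan` (default): best-scoring match per sequence to a
#'   degenerate seed pattern (default `TANNTTTG`); the score is the number
#'   of agreeing non-N pattern positions, and a hit is reported when the
#'   score reaches `min_score` (default 6, i.e. all defined positions).
#' * `gibbs`: a width-8 Gibbs motif sampler ([gibbs_motif_sampler()]); one
#'   hit per sequence with its log-odds score.
#'
#' At most one hit per gene is returned (best score; ties broken in favour
#' of the most TSS-proximal site).
#'
#' @param upstream_seqs named character vector, one upstream sequence per
#'   gene (RNA or DNA; the 3' end must abut the TSS).
#' @param mode `"consensus_scan"` or `"gibbs"`.
#' @param pattern seed pattern for the scan (IUPAC N = unconstrained).
#' @param min_score minimum scan score for a hit.
#' @param iterations,restarts,pseudocount,seed Gibbs sampler settings;
#'   `seed` is required in `gibbs` mode.
#' @return data.frame with `gene_id`, `element` (8-mer, DNA alphabet),
#'   `spacing` (nt strictly between element and TSS) and `score`.
#' @export
find_candidate_elements <- function(upstream_seqs,
                                    mode = c("consensus_scan", "gibbs"),
                                    pattern = PROMOTER_SEED, min_score = 6,
                                    iterations = 2000, restarts = 20,
                                    pseudocount = 0.5, seed = NULL) {
  mode <- match.arg(mode)
  if (!length(upstream_seqs)) stop("find_candidate_elements: empty input")
  seqs <- .as_dna_upper(upstream_seqs)
  short <- nchar(seqs) < 8L
  if (any(short)) {
    warning("dropping ", sum(short), " upstream sequence(s) shorter than 8 nt")
    seqs <- seqs[!short]
  }
  if (!length(seqs)) stop("find_candidate_elements: no usable sequences")

  if (mode == "consensus_scan") {
    pat <- strsplit(pattern, "", fixed = TRUE)[[1]]
    if (length(pat) != 8L) stop("pattern must be 8 nt")
    defined <- which(pat != "N")
    rows <- lapply(names(seqs), function(g) {
      s <- seqs[[g]]
      L <- nchar(s)
      starts <- seq_len(L - 7L)
      score <- integer(length(starts))
      for (dp in defined) {
        score <- score + (substring(s, starts + dp - 1L,
                                    starts + dp - 1L) == pat[dp])
      }
      best <- max(score)
      if (best < min_score) return(NULL)
      start <- max(starts[score == best])  # most TSS-proximal on ties
      data.frame(gene_id = g,
                 element = substring(s, start, start + 7L),
                 spacing = L - (start + 7L),
                 score = best, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    if (is.null(out)) {
      out <- data.frame(gene_id = character(0), element = character(0),
                        spacing = integer(0), score = numeric(0))
    }
    return(out)
  }

  # gibbs mode
  if (is.null(seed)) stop("gibbs mode requires an explicit seed")
  fit <- gibbs_motif_sampler(seqs, width = 8, iterations = iterations,
                             restarts = restarts,
                             pseudocount = pseudocount, seed = seed)
  data.frame(gene_id = names(seqs),
             element = substring(seqs, fit$starts, fit$starts + 7L),
             spacing = nchar(seqs) - (fit$starts + 7L),
             score = fit$site_scores, stringsAsFactors = FALSE)
}

#' Gibbs motif sampler
#'
#' Site-sampler variant: one motif occurrence per sequence.  In each
#' iteration one sequence is held out, a position weight matrix with
#' pseudocounts is built from the remaining sites against the pooled
#' background composition, and a new site for the held-out sequence is drawn
#' proportional to its likelihood ratio.  Every `shift_every` iterations a
#' phase-shift move proposes sliding all sites one position left or right
#' and keeps the shift when it raises the total log-odds — the standard cure
#' for the sampler locking onto a register offset by one.  The best-scoring
#' state across restarts is returned.  Fully deterministic given `seed`.
#'
#' @param seqs named character vector of DNA sequences (all longer than
#'   `width`).
#' @param width motif width.
#' @param iterations number of single-sequence updates per restart.
#' @param restarts independent restarts.
#' @param pseudocount Dirichlet pseudocount added per base.
#' @param shift_every iterations between phase-shift proposals.
#' @param seed RNG seed (required).
#' @return list with `starts` (named integer vector of 1-based site starts),
#'   `pwm` (4 x width frequency matrix, rows A/C/G/T), `site_scores`
#'   (per-sequence log-odds) and `score` (total log-odds).
#' @export
gibbs_motif_sampler <- function(seqs, width = 8, iterations = 2000,
                                restarts = 20, pseudocount = 0.5,
                                shift_every = 50, seed) {
  if (missing(seed) || is.null(seed)) {
    stop("gibbs_motif_sampler: seed is required")
  }
  set.seed(seed)
  seqs <- .as_dna_upper(seqs)
  stopifnot(all(nchar(seqs) >= width))
  N <- length(seqs)
  enc <- lapply(seqs, function(s) {
    match(strsplit(s, "", fixed = TRUE)[[1]], BASES_DNA)
  })
  bg <- tabulate(unlist(enc), 4)
  bg <- bg / sum(bg)
  # per-sequence window matrices: n_windows x width of base codes
  win <- lapply(enc, function(e) {
    nw <- length(e) - width + 1L
    outer(seq_len(nw), seq_len(width) - 1L,
          function(i, j) e[i + j])
  })
  colshift <- 4L * (seq_len(width) - 1L)

  state_score <- function(starts) {
    cnt <- matrix(pseudocount, 4, width)
    for (s in seq_len(N)) {
      w <- win[[s]][starts[s], ]
      cnt[cbind(w, seq_len(width))] <- cnt[cbind(w, seq_len(width))] + 1
    }
    pwm <- sweep(cnt, 2, colSums(cnt), "/")
    lo <- log(pwm / bg)
    per_site <- vapply(seq_len(N), function(s) {
      sum(lo[cbind(win[[s]][starts[s], ], seq_len(width))])
    }, numeric(1))
    list(pwm = pwm, lo = lo, per_site = per_site, total = sum(per_site))
  }

  best <- NULL
  for (r in seq_len(restarts)) {
    starts <- vapply(win, function(W) sample.int(nrow(W), 1L), integer(1))
    cnt <- matrix(pseudocount, 4, width)
    for (s in seq_len(N)) {
      w <- win[[s]][starts[s], ]
      cnt[cbind(w, seq_len(width))] <- cnt[cbind(w, seq_len(width))] + 1
    }
    for (it in seq_len(iterations)) {
      s <- ((it - 1L) %% N) + 1L
      w_old <- win[[s]][starts[s], ]
      cnt[cbind(w_old, seq_len(width))] <-
        cnt[cbind(w_old, seq_len(width))] - 1
      pwm <- sweep(cnt, 2, colSums(cnt), "/")
      lo_flat <- as.vector(log(pwm / bg))        # column-major: base + 4*(col-1)
      IDX <- win[[s]] + rep(colshift, each = nrow(win[[s]]))
      sc <- rowSums(matrix(lo_flat[IDX], nrow(win[[s]]), width))
      pr <- exp(sc - max(sc))
      starts[s] <- sample.int(length(pr), 1L, prob = pr)
      w_new <- win[[s]][starts[s], ]
      cnt[cbind(w_new, seq_len(width))] <-
        cnt[cbind(w_new, seq_len(width))] + 1
      if (it %% shift_every == 0L) {
        cur <- state_score(starts)$total
        for (d in c(-1L, 1L)) {
          cand <- starts + d
          if (all(cand >= 1L) &&
              all(cand <= vapply(win, nrow, integer(1)))) {
            if (state_score(cand)$total > cur) {
              starts <- cand
              cnt <- matrix(pseudocount, 4, width)
              for (s2 in seq_len(N)) {
                w2 <- win[[s2]][starts[s2], ]
                cnt[cbind(w2, seq_len(width))] <-
                  cnt[cbind(w2, seq_len(width))] + 1
              }
              break
            }
          }
        }
      }
    }
    st <- state_score(starts)
    if (is.null(best) || st$total > best$score) {
      best <- list(starts = stats::setNames(starts, names(seqs)),
                   pwm = st$pwm, site_scores = st$per_site,
                   score = st$total)
    }
  }
  rownames(best$pwm) <- BASES_DNA
  best
}

#' Histogram of element-to-TSS spacings
#'
#' @param hits hit data.frame from [find_candidate_elements()].
#' @return named numeric vector mapping spacing to proportion (sums to 1).
#' @export
spacing_histogram <- function(hits) {
  if (!nrow(hits)) stop("spacing_histogram: no hits")
  tab <- table(hits$spacing)
  props <- as.numeric(tab) / nrow(hits)
  stats::setNames(props, names(tab))
}

#' Keep probable promoters by spacing
#'
#' Candidates whose element sits 4 or 5 nt upstream of the TSS are deemed
#' probable promoters; everything else is discarded.
#'
#' @param hits hit data.frame.
#' @param spacings accepted spacings (default `c(4, 5)`).
#' @return filtered hit data.frame (subset of the input; idempotent).
#' @export
filter_probable_promoters <- function(hits, spacings = c(4L, 5L)) {
  hits[hits$spacing %in% spacings, , drop = FALSE]
}

#' Build a positional frequency model from aligned promoter elements
#'
#' Hits are aligned on the element; counts and frequencies are tallied over
#' the element and `flank` nt on each side.  Columns are labelled on the
#' promoter coordinate system (element = -12..-5, the -7 element naming).
#' Flank positions falling outside a source sequence reduce that column's
#' `n` without error.
#'
#' @param hits (filtered) hit data.frame.
#' @param upstream_seqs the same named sequences the hits were found in.
#' @param flank nt of aligned flank on each side of the element.
#' @return object of class `promoter_model`: list with `width`, `positions`
#'   (column labels), `counts` (4 x P), `frequencies` (4 x P), `n` (per
#'   column) and `consensus` (IUPAC string over the element, from
#'   [derive_consensus()] defaults).
#' @export
build_promoter_model <- function(hits, upstream_seqs, flank = 0) {
  if (nrow(hits) < 2L) stop("build_promoter_model: need at least 2 hits")
  seqs <- .as_dna_upper(upstream_seqs)
  width <- 8L
  P <- width + 2L * flank
  counts <- matrix(0L, 4, P, dimnames = list(BASES_DNA, NULL))
  n <- integer(P)
  for (h in seq_len(nrow(hits))) {
    s <- seqs[[hits$gene_id[h]]]
    L <- nchar(s)
    start <- L - 7L - hits$spacing[h]      # 1-based element start
    for (col in seq_len(P)) {
      pos <- start - flank + col - 1L
      if (pos < 1L || pos > L) next
      b <- substr(s, pos, pos)
      if (!b %in% BASES_DNA) next
      counts[b, col] <- counts[b, col] + 1L
      n[col] <- n[col] + 1L
    }
  }
  freq <- sweep(counts, 2, pmax(n, 1L), "/")
  labels <- seq(-12L - flank, by = 1L, length.out = P)
  colnames(counts) <- colnames(freq) <- labels
  model <- structure(list(width = width, positions = labels,
                          counts = counts, frequencies = freq, n = n,
                          flank = flank, n_hits = nrow(hits)),
                     class = "promoter_model")
  model$consensus <- derive_consensus(model)
  model
}

#' @export
print.promoter_model <- function(x, ...) {
  cat(sprintf("promoter_model from %d aligned elements (flank %d)\n",
              x$n_hits, x$flank))
  cat("  consensus:", x$consensus, "\n")
  invisible(x)
}

#' Derive an IUPAC consensus from a frequency model
#'
#' Per column: the plain base if its frequency reaches
#' `invariant_threshold`; otherwise the minimal IUPAC code covering every
#' base whose frequency exceeds `absent_threshold` (so a column where only G
#' is effectively absent yields `H`).
#'
#' @param model a `promoter_model`, or a 4 x w frequency matrix with rows
#'   A/C/G/T (U accepted).
#' @param invariant_threshold frequency above which a column is called
#'   invariant (> 0.5; default 0.9).
#' @param absent_threshold frequency at or below which a base is treated as
#'   absent (default 0.05).
#' @return IUPAC consensus string over the element columns.
#' @export
derive_consensus <- function(model, invariant_threshold = 0.9,
                             absent_threshold = 0.05) {
  stopifnot(invariant_threshold > 0.5, invariant_threshold < 1,
            absent_threshold > 0, absent_threshold < 1)
  if (inherits(model, "promoter_model")) {
    freq <- model$frequencies[, as.character(seq(-12L, -5L)), drop = FALSE]
  } else {
    freq <- as.matrix(model)
  }
  rn <- chartr("U", "T", rownames(freq))
  if (!setequal(rn, BASES_DNA)) {
    stop("frequency matrix rows must be the four bases")
  }
  rownames(freq) <- rn
  freq <- freq[BASES_DNA, , drop = FALSE]
  cons <- vapply(seq_len(ncol(freq)), function(j) {
    col <- freq[, j]
    if (max(col) >= invariant_threshold) return(names(which.max(col)))
    present <- names(col)[col > absent_threshold]
    if (!length(present)) present <- BASES_DNA
    iupac_code(present)
  }, character(1))
  paste(cons, collapse = "")
}

#' Leader lengths from TSS records
#'
#' The leader is the number of nucleotides strictly between the TSS and the
#' first base of the start codon (TSS at the start codon itself gives
#' leader 0, a leaderless transcript).
#'
#' @param tss TSS data.frame (`gene_id`, `contig`, `position`, `strand`).
#' @param genes annotation data.frame.
#' @param threshold leaders strictly longer than this count towards
#'   `frac_over` (default 10 nt).
#' @return list with `lengths` (named integer vector), `mean`, `frac_over`
#'   and `threshold`.
#' @export
leader_lengths <- function(tss, genes, threshold = 10) {
  m <- merge(tss, genes, by = "gene_id", suffixes = c(".tss", ""))
  if (!nrow(m)) stop("leader_lengths: no TSS records match the annotation")
  if (any(m$strand.tss != m$strand)) {
    stop("leader_lengths: TSS strand disagrees with gene strand for: ",
         paste(utils::head(m$gene_id[m$strand.tss != m$strand]),
               collapse = ", "))
  }
  leader <- ifelse(m$strand == "+", m$start - m$position,
                   m$position - (m$end - 1L))
  if (any(leader < 0)) {
    stop("leader_lengths: TSS downstream of the start codon for: ",
         paste(utils::head(m$gene_id[leader < 0]), collapse = ", "))
  }
  lengths <- stats::setNames(as.integer(leader), m$gene_id)
  list(lengths = lengths, mean = mean(lengths),
       frac_over = mean(lengths > threshold), threshold = threshold)
}
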