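# Independent oracle for the partition function: exhaustive enumeration of
# every nested structure (feasible for n <= ~14).  Deliberately shares no
# code with the dynamic programme it checks.

enum_structures <- function(ch, i, j, minh, wt) {
  if (j - i < minh + 1) return(list(list(w = 1, paired = integer(0))))
  out <- enum_structures(ch, i, j - 1, minh, wt)   # j unpaired
  for (k in i:(j - minh - 1)) {
    w <- wt(ch[k], ch[j])
    if (w > 0) {
      left <- enum_structures(ch, i, k - 1, minh, wt)
      inner <- enum_structures(ch, k + 1, j - 1, minh, wt)
      for (a in left) for (b in inner) {
        out[[length(out) + 1L]] <- list(w = a$w * w * b$w,
                                        paired = c(a$paired, b$paired, k, j))
      }
    }
  }
  out
}

enum_pf <- function(seq, minh = 3, gc = exp(3), au = exp(2), gu = exp(1)) {
  ch <- strsplit(toupper(seq), "")[[1]]
  n <- length(ch)
  wt <- function(a, b) {
    switch(paste(sort(c(a, b)), collapse = ""),
           CG = gc, AU = au, GU = gu, 0)
  }
  ss <- enum_structures(ch, 1L, n, minh, wt)
  Z <- sum(vapply(ss, `[[`, numeric(1), "w"))
  p <- numeric(n)
  for (s in ss) for (i in unique(s$paired)) p[i] <- p[i] + s$w
  list(Z = Z, p_paired = p / Z, n_structures = length(ss))
}
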