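# Independent brute-force oracle: a plain-R three-state (Gotoh) global
# affine-gap aligner with the documented deterministic tie-breaks, plus an
# oracle read classifier built on it.  Shares no code with the package's
# C++ aligner; used to cross-check scores, alignments and read classes.

ORACLE_NEG <- -1e9

oracle_align <- function(read, ref, match = 5, mismatch = -4,
                         go = -20, ge = -2) {
  rd <- strsplit(read, "")[[1L]]
  rf <- strsplit(ref, "")[[1L]]
  n <- length(rd)
  m <- length(rf)
  sub <- function(a, b) {
    if (a == "N" || b == "N") mismatch else if (a == b) match else mismatch
  }
  M <- matrix(ORACLE_NEG, n + 1L, m + 1L)
  X <- matrix(ORACLE_NEG, n + 1L, m + 1L) # gap in ref (read base consumed)
  Y <- matrix(ORACLE_NEG, n + 1L, m + 1L) # gap in read (ref base consumed)
  M[1L, 1L] <- 0
  if (n > 0L) X[2L:(n + 1L), 1L] <- go + ge * seq_len(n)
  if (m > 0L) Y[1L, 2L:(m + 1L)] <- go + ge * seq_len(m)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- sub(rd[i], rf[j])
      M[i + 1L, j + 1L] <- max(M[i, j], Y[i, j], X[i, j]) + s
      X[i + 1L, j + 1L] <- max(X[i, j + 1L] + ge, M[i, j + 1L] + go + ge,
                               Y[i, j + 1L] + go + ge)
      Y[i + 1L, j + 1L] <- max(Y[i + 1L, j] + ge, M[i + 1L, j] + go + ge,
                               X[i + 1L, j] + go + ge)
    }
  }
  # traceback; end state and predecessors tested in the documented order
  i <- n; j <- m
  vals <- c(M = M[i + 1L, j + 1L], Y = Y[i + 1L, j + 1L],
            X = X[i + 1L, j + 1L])
  st <- names(vals)[which.max(vals)] # which.max keeps the first (M > Y > X)
  score <- unname(max(vals))
  pat <- character(0)
  subj <- character(0)
  while (i > 0L || j > 0L) {
    if (st == "M") {
      s <- sub(rd[i], rf[j])
      want <- M[i + 1L, j + 1L] - s
      pat <- c(rd[i], pat); subj <- c(rf[j], subj)
      st <- if (M[i, j] == want) "M" else if (Y[i, j] == want) "Y" else "X"
      i <- i - 1L; j <- j - 1L
    } else if (st == "X") {
      here <- X[i + 1L, j + 1L]
      pat <- c(rd[i], pat); subj <- c("-", subj)
      st <- if (X[i, j + 1L] + ge == here) "X"
            else if (M[i, j + 1L] + go + ge == here) "M" else "Y"
      i <- i - 1L
    } else {
      here <- Y[i + 1L, j + 1L]
      pat <- c("-", pat); subj <- c(rf[j], subj)
      st <- if (Y[i + 1L, j] + ge == here) "Y"
            else if (M[i + 1L, j] + go + ge == here) "M" else "X"
      j <- j - 1L
    }
  }
  list(score = score, pattern = paste(pat, collapse = ""),
       subject = paste(subj, collapse = ""))
}

oracle_identity <- function(aln) {
  p <- strsplit(aln$pattern, "")[[1L]]
  s <- strsplit(aln$subject, "")[[1L]]
  sum(p == s & p != "-" & p != "N") / length(p)
}

# does any gap of the alignment touch the half-open window [ws, we)?
oracle_window_indel <- function(aln, ws, we) {
  p <- strsplit(aln$pattern, "")[[1L]]
  s <- strsplit(aln$subject, "")[[1L]]
  ref_pos <- 0L
  k <- 1L
  n <- length(p)
  while (k <= n) {
    if (s[k] == "-") {
      anchor <- ref_pos - 1L
      if (anchor >= ws && anchor < we) return(TRUE)
      while (k <= n && s[k] == "-") k <- k + 1L
    } else if (p[k] == "-") {
      a <- ref_pos
      while (k <= n && p[k] == "-" && s[k] != "-") {
        ref_pos <- ref_pos + 1L; k <- k + 1L
      }
      if (a < we && ref_pos > ws) return(TRUE)
    } else {
      ref_pos <- ref_pos + 1L; k <- k + 1L
    }
  }
  FALSE
}

# full oracle classifier: align to both alleles, assign by score (ties to
# the reference), apply the identity floor, score window indels
oracle_classify <- function(read, ref_seq, hdr_seq, win_ref, win_hdr,
                            min_identity = 0.6) {
  ar <- oracle_align(read, ref_seq)
  ah <- oracle_align(read, hdr_seq)
  to_hdr <- ah$score > ar$score
  best <- if (to_hdr) ah else ar
  if (oracle_identity(best) < min_identity) return("UNALIGNED")
  win <- if (to_hdr) win_hdr else win_ref
  ind <- oracle_window_indel(best, win$start, win$end)
  if (to_hdr) {
    if (ind) "HDR_INDEL" else "HDR_CLEAN"
  } else {
    if (ind) "REF_INDEL" else "REF_CLEAN"
  }
}
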