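# shared helpers: classed conditions, seeded RNG scope, small DNA utilities

pq_stop <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(paste0("pq_", class), "pegquant_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

#' Evaluate an expression under a local RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` (Mersenne-Twister) and
#' restores the caller's RNG state afterwards, so seeded generators leave no
#' global side effects.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_local_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    pq_stop("'seed' must be a single integer", "bad_seed")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

#' Reverse complement of a DNA string
#'
#' @param x Character scalar over the DNA alphabet (IUPAC codes allowed).
#' @return Character scalar, the reverse complement.
#' @examples
#' revcomp("ACGTN")
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# uppercase, RNA U -> T
normalize_dna <- function(x, rna_ok = FALSE) {
  x <- toupper(x)
  if (rna_ok) x <- chartr("U", "T", x)
  x
}

assert_dna <- function(x, what, allow_n = TRUE, allow_empty = FALSE) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    pq_stop(sprintf("'%s' must be a single string", what), "bad_input")
  if (!allow_empty && nchar(x) == 0L)
    pq_stop(sprintf("'%s' must be non-empty", what), "bad_input")
  alpha <- if (allow_n) "ACGTN" else "ACGT"
  if (nchar(x) > 0L && grepl(sprintf("[^%s]", alpha), x))
    pq_stop(sprintf("'%s' contains characters outside {%s}", what,
                    paste(strsplit(alpha, "")[[1]], collapse = ",")),
            "bad_alphabet")
  invisible(x)
}

# does base 'b' (A/C/G/T/N) satisfy IUPAC code 'p'?
iupac_matches <- function(p, b) {
  allowed <- Biostrings::IUPAC_CODE_MAP[[p]]
  if (is.null(allowed)) pq_stop(sprintf("invalid IUPAC code '%s'", p), "bad_input")
  b %in% strsplit(allowed, "")[[1]]
}

# vectorised IUPAC match of a pattern against a same-length DNA substring
iupac_match_str <- function(pattern, s) {
  if (nchar(pattern) != nchar(s)) return(FALSE)
  pc <- strsplit(pattern, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  all(vapply(seq_along(pc), function(i) iupac_matches(pc[i], sc[i]), logical(1)))
}
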