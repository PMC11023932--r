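# shared fixtures: a deterministic target locus and small random builders

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# deterministic 100-bp amplicon with a + strand protospacer at [20,40),
# TGG PAM at [40,43), nick at 37, and GG at +7 (indices 43-44) so the
# canonical GG-to-CA substitution edit applies
fix_spacer <- function() "GACGTTACCGGATTACGCTA"

fix_amplicon <- function() {
  left <- "TTACGAATCCGTTGCAGCAT"
  right <- paste0("GG", "ATCGTTGCAACGTGGCTAGTCAAGCTGATCCGATTACGGCATCAATGCAGGTACA")
  amplicon_reference("amp1", paste0(left, fix_spacer(), "TGG", right))
}

fix_design <- function(edit = edit_spec("substitution", 7, "GG", "CA")) {
  pegrna_design(fix_spacer(), pbs_len = 13, rt_template = "UGCAUCGUACGCA",
                intended_edit = edit)
}

# the same biological locus stored on the opposite strand
fix_amplicon_rc <- function() {
  amplicon_reference("amp1_rc", revcomp(fix_amplicon()$sequence))
}

# reads data.frame from bare sequences at constant quality
reads_df <- function(seqs, quality = 37L) {
  data.frame(id = sprintf("r%04d", seq_along(seqs)), seq = seqs,
             qual = vapply(nchar(seqs), function(L)
               strrep(rawToChar(as.raw(quality + 33L)), L), character(1)),
             stringsAsFactors = FALSE)
}

# apply k random point events (substitution, or indel of <= 3 nt) to a
# sequence; returns the mutated sequence (uses the current RNG)
mutate_seq <- function(seqstr, k) {
  for (i in seq_len(k)) {
    L <- nchar(seqstr)
    type <- sample(c("sub", "ins", "del"), 1L)
    if (type == "sub") {
      p <- sample.int(L, 1L)
      base <- sample(setdiff(c("A", "C", "G", "T"),
                             substr(seqstr, p, p)), 1L)
      substr(seqstr, p, p) <- base
    } else if (type == "ins") {
      p <- sample.int(L + 1L, 1L) - 1L
      ins <- rand_dna(sample.int(3L, 1L))
      seqstr <- paste0(substr(seqstr, 1L, p), ins,
                       substr(seqstr, p + 1L, L))
    } else {
      len <- sample.int(min(3L, L - 10L), 1L)
      p <- sample.int(L - len, 1L)
      seqstr <- paste0(substr(seqstr, 1L, p - 1L),
                       substr(seqstr, p + len, L))
    }
  }
  seqstr
}
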