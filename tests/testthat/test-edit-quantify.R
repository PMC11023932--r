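# protospacer location, nick arithmetic, edited-allele construction,
# quality filtering, alignment assignment and outcome tallies

test_that("protospacer location reports + strand coordinates and PAM", {
  amp <- fix_amplicon()
  des <- fix_design()
  hit <- locate_protospacer(amp, des)
  expect_equal(hit$start, 20L)
  expect_equal(hit$end, 40L)
  expect_equal(hit$strand, "+")
  expect_equal(hit$pam_start, 40L)
  expect_equal(hit$pam_end, 43L)
})

test_that("reverse-complement storage flips the reported strand", {
  amp_rc <- fix_amplicon_rc()
  des <- fix_design()
  hit <- locate_protospacer(amp_rc, des)
  expect_equal(hit$strand, "-")
  # mirrored coordinates: protospacer [60,80), PAM [57,60) on a 100-mer
  expect_equal(hit$start, amp_rc$length - 40L)
  expect_equal(hit$end, amp_rc$length - 20L)
  expect_equal(hit$pam_end, amp_rc$length - 40L)
})

test_that("absent or ambiguous spacers raise classed errors", {
  set.seed(8)
  des <- fix_design()
  none <- amplicon_reference("none", rand_dna(80))
  expect_false(grepl(fix_spacer(), none$sequence, fixed = TRUE))
  expect_error(locate_protospacer(none, des), class = "pq_not_found")
  twice <- amplicon_reference("twice", paste0(
    fix_spacer(), "TGGAAAA", fix_spacer(), "TGGAAAA"))
  expect_error(locate_protospacer(twice, des), class = "pq_ambiguous")
})

test_that("nick position is 3 nt 5' of the PAM on the nicked strand", {
  hit_plus <- structure(list(start = 20L, end = 40L, strand = "+",
                             pam_start = 40L, pam_end = 43L,
                             spacer_length = 20L),
                        class = "protospacer_hit")
  expect_equal(nick_position(hit_plus), 37L)
  hit_minus <- structure(list(start = 10L, end = 30L, strand = "-",
                              pam_start = 7L, pam_end = 10L,
                              spacer_length = 20L),
                         class = "protospacer_hit")
  expect_equal(nick_position(hit_minus), 13L)
  w <- quant_window(37, 10)
  expect_equal(c(w$start, w$end), c(27L, 47L))
})

test_that("edited alleles place the edit relative to the nick", {
  amp <- fix_amplicon()
  ref <- amp$sequence
  # substitution at +7 changes exactly indices 43-44 (0-based)
  hdr <- build_edited_allele(amp, 37L, "+",
                             edit_spec("substitution", 7, "GG", "CA"))
  d <- which(strsplit(ref, "")[[1]] != strsplit(hdr, "")[[1]]) - 1L
  expect_equal(d, c(43L, 44L))
  # +5 single-base substitution changes index 41 (= cut + 5 - 1)
  b41 <- substr(ref, 42, 42)
  alt <- setdiff(c("A", "C", "G", "T"), b41)[1]
  hdr5 <- build_edited_allele(amp, 37L, "+",
                              edit_spec("substitution", 5, b41, alt))
  expect_equal(which(strsplit(ref, "")[[1]] != strsplit(hdr5, "")[[1]]) - 1L,
               41L)
  # insertion at +1 inserts at index 37; deletion shortens by its length
  ins <- build_edited_allele(amp, 37L, "+", edit_spec("insertion", 1, "", "CAT"))
  expect_equal(nchar(ins), nchar(ref) + 3L)
  expect_equal(substr(ins, 38, 40), "CAT")
  expect_equal(substr(ins, 1, 37), substr(ref, 1, 37))
  del15 <- substr(ref, 38, 52)
  del <- build_edited_allele(amp, 37L, "+",
                             edit_spec("deletion", 1, del15, ""))
  expect_equal(nchar(del), nchar(ref) - 15L)
})

test_that("edited alleles are strand-coherent", {
  amp <- fix_amplicon()
  amp_rc <- fix_amplicon_rc()
  des <- fix_design()
  edit <- des$intended_edit
  hdr_plus <- build_edited_allele(amp, 37L, "+", edit)
  cut_rc <- nick_position(locate_protospacer(amp_rc, des))
  hdr_minus <- build_edited_allele(amp_rc, cut_rc, "-", edit)
  expect_equal(revcomp(hdr_minus), hdr_plus)
})

test_that("ref-allele mismatches and out-of-bounds edits are rejected", {
  amp <- fix_amplicon()
  expect_error(build_edited_allele(amp, 37L, "+",
                                   edit_spec("substitution", 7, "AA", "CC")),
               class = "pq_ref_mismatch")
  expect_error(build_edited_allele(amp, 37L, "+",
                                   edit_spec("deletion", 60,
                                             strrep("A", 10), "")),
               class = "pq_out_of_bounds")
})

test_that("mean-quality filter uses a strict >= threshold", {
  expect_true(passes_quality(rep(30, 50), 30))
  q <- rep(30, 50); q[1] <- 25 # mean 29.9
  expect_false(passes_quality(q, 30))
  expect_true(passes_quality(q, 29))
  expect_error(passes_quality(numeric(0)), class = "pq_empty_read")
})

test_that("reads identical to an allele are assigned to it cleanly", {
  amp <- fix_amplicon()
  hdr <- build_edited_allele(amp, 37L, "+", fix_design()$intended_edit)
  w <- quant_window(37L, 10L, amp$length)
  a_hdr <- align_and_assign(hdr, amp$sequence, hdr)
  expect_equal(a_hdr$assigned, "HDR")
  expect_equal(a_hdr$identity, 1.0)
  expect_equal(classify_read(a_hdr, w), "HDR_CLEAN")
  a_ref <- align_and_assign(amp$sequence, amp$sequence, hdr)
  expect_equal(a_ref$assigned, "REF")
  expect_equal(classify_read(a_ref, w), "REF_CLEAN")
})

test_that("unrelated reads fall below the identity floor", {
  amp <- fix_amplicon()
  hdr <- build_edited_allele(amp, 37L, "+", fix_design()$intended_edit)
  set.seed(421)
  junk <- rand_dna(50)
  # brute-force check that the best identity really is below the floor
  id_ref <- oracle_identity(oracle_align(junk, amp$sequence))
  id_hdr <- oracle_identity(oracle_align(junk, hdr))
  expect_lt(max(id_ref, id_hdr), 0.6)
  a <- align_and_assign(junk, amp$sequence, hdr)
  expect_equal(a$assigned, "NONE")
  expect_equal(classify_read(a, quant_window(37L, 10L, amp$length)),
               "UNALIGNED")
})

test_that("window scoping separates indel-containing from clean reads", {
  amp <- fix_amplicon()
  ref <- amp$sequence
  hdr <- build_edited_allele(amp, 37L, "+", fix_design()$intended_edit)
  w <- quant_window(37L, 10L, amp$length)
  # 2-bp deletion inside the window -> REF_INDEL
  del_in <- paste0(substr(ref, 1, 38), substr(ref, 41, nchar(ref)))
  expect_equal(classify_read(align_and_assign(del_in, ref, hdr), w),
               "REF_INDEL")
  # 1-bp insertion ~30 nt 3' of the window -> REF_CLEAN
  ins_out <- paste0(substr(ref, 1, 85), "A", substr(ref, 86, nchar(ref)))
  expect_equal(classify_read(align_and_assign(ins_out, ref, hdr), w),
               "REF_CLEAN")
  # substitutions alone never make a read indel-containing
  sub_in <- ref
  substr(sub_in, 38, 38) <- if (substr(ref, 38, 38) == "A") "C" else "A"
  expect_equal(classify_read(align_and_assign(sub_in, ref, hdr), w),
               "REF_CLEAN")
  # edited read with an extra window insertion -> HDR_INDEL
  hdr_ins <- paste0(substr(hdr, 1, 30), "TT", substr(hdr, 31, nchar(hdr)))
  expect_equal(classify_read(align_and_assign(hdr_ins, ref, hdr), w),
               "HDR_INDEL")
})

test_that("insertion window membership follows the left-anchor rule", {
  ind <- alignment_indels("ACGTTA", "ACG-TA")
  expect_equal(ind$type, "insertion")
  expect_equal(ind$anchor, 2L)
  ind2 <- alignment_indels("AC--TA", "ACGGTA")
  expect_equal(ind2$type, "deletion")
  expect_equal(c(ind2$ref_start, ind2$ref_end), c(2L, 4L))
})

test_that("tally arithmetic reproduces the worked example and identities", {
  classes <- c(rep("HDR_CLEAN", 25), rep("HDR_INDEL", 5),
               rep("REF_INDEL", 10), rep("REF_CLEAN", 60))
  t <- tally_outcomes(classes)
  f <- t$frequencies
  expect_equal(unname(f["f_intended_wo_indel"]), 0.25)
  expect_equal(unname(f["f_total_intended"]), 0.30)
  expect_equal(unname(f["f_total_indels"]), 0.15)
  expect_equal(unname(f["f_indels_wo_intended"]), 0.10)
  # all-reference input gives all-zero frequencies
  f0 <- tally_outcomes(rep("REF_CLEAN", 10))$frequencies
  expect_true(all(f0[c("f_intended_wo_indel", "f_intended_w_indel",
                       "f_total_intended", "f_total_indels",
                       "f_indels_wo_intended")] == 0))
  expect_error(tally_outcomes(rep("UNALIGNED", 5)), class = "pq_zero_aligned")
})

test_that("tallies partition reads and are order-invariant", {
  set.seed(11)
  for (rep in 1:20) {
    classes <- sample(READ_CLASSES, 200, replace = TRUE)
    t <- tally_outcomes(classes)
    expect_equal(sum(t$counts), length(classes))
    f <- t$frequencies
    expect_equal(unname(f["f_total_intended"]),
                 unname(f["f_intended_wo_indel"] + f["f_intended_w_indel"]))
    expect_equal(unname(f["f_total_indels"]),
                 unname(f["f_intended_w_indel"] + f["f_indels_wo_intended"]))
    expect_true(all(f >= 0 & f <= 1))
    t2 <- tally_outcomes(sample(classes))
    expect_identical(t2$counts, t$counts)
  }
})

test_that("window auto-expands to contain the intended-edit footprint", {
  amp <- fix_amplicon()
  des <- fix_design(edit_spec("substitution", 15,
                              substr(amp$sequence, 52, 52),
                              if (substr(amp$sequence, 52, 52) == "A") "C"
                              else "A"))
  res <- quantify_amplicon(amp, des, reads_df(amp$sequence))
  # +15 edit at index 51 lies outside the default [27,47) window
  expect_gte(res$window_ref$end, 52L)
  expect_equal(res$tally$counts[["REF_CLEAN"]], 1L)
})

test_that("batch and single-read classification agree", {
  amp <- fix_amplicon()
  des <- fix_design()
  hdr <- build_edited_allele(amp, 37L, "+", des$intended_edit)
  w_ref <- quant_window(37L, 10L, amp$length)
  w_hdr <- quant_window(37L, 10L, nchar(hdr))
  set.seed(5150)
  seqs <- vapply(1:60, function(i) {
    base <- if (i %% 2) amp$sequence else hdr
    mutate_seq(base, sample(0:2, 1L))
  }, character(1))
  batch <- classify_reads(seqs, NULL, amp$sequence, hdr, w_ref, w_hdr)
  single <- vapply(seqs, function(s) {
    a <- align_and_assign(s, amp$sequence, hdr)
    if (a$assigned == "NONE") "UNALIGNED"
    else classify_read(a, if (a$assigned == "HDR") w_hdr else w_ref)
  }, character(1), USE.NAMES = FALSE)
  expect_equal(batch, single)
})

test_that("quality-discarded reads are excluded before alignment", {
  amp <- fix_amplicon()
  des <- fix_design()
  reads <- reads_df(c(amp$sequence, amp$sequence))
  reads$qual[2] <- strrep(rawToChar(as.raw(20 + 33)), nchar(amp$sequence))
  res <- quantify_amplicon(amp, des, reads)
  expect_equal(res$tally$counts[["DISCARDED_QUALITY"]], 1L)
  expect_equal(res$tally$n_aligned, 1L)
})
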