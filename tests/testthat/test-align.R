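test_that("a read equal to a reference substring aligns gap-free", {
  ref <- "TTTACGTACGTTTTGCA"
  aln <- align_semi_global("ACGTACGT", ref)
  expect_equal(aln$score, 8)
  expect_equal(nrow(aln$ops), 1L)
  expect_equal(aln$ops$op, "match")
  expect_equal(aln$ref_start, 3L)
  expect_equal(aln$ref_end, 11L)
})

test_that("a single inserted base yields one leftmost 1-nt insertion", {
  ref <- "GATTACAGATTACAGG"
  read <- "GATTACAGGATTACAGG"  # extra G inserted in the GG run
  aln <- align_semi_global(read, ref)
  ind <- peartools:::alignment_indels(aln)
  expect_equal(nrow(ind), 1L)
  expect_equal(ind$kind, "ins")
  expect_equal(ind$length, 1L)
  # leftmost placement: the inserted G left-normalises to the start of
  # the G run at reference position 7
  expect_equal(ind$ref_pos, 7L)
  expect_equal(aln$score, 16 - 5)
})

test_that("empty sequences are rejected", {
  expect_error(align_semi_global("", "ACGT"), "empty sequence")
  expect_error(align_semi_global("ACGT", ""), "empty sequence")
})

test_that("alignment matches exhaustive enumeration on tiny instances", {
  set.seed(202)
  for (k in 1:40) {
    read <- rand_dna(sample(2:5, 1))
    ref <- rand_dna(sample(3:7, 1))
    en <- enum_align(read, ref)
    aln <- align_semi_global(read, ref)
    expect_equal(aln$score, en$score)
    expect_true(validate_alignment(aln))
    ms <- aln_multiset(aln)
    expect_true(any(vapply(en$multisets, identical, logical(1), ms)),
                label = paste("multiset optimal for", read, "vs", ref))
  }
})

test_that("alignment score equals the memoised-recursion oracle on 25-nt pairs", {
  set.seed(203)
  for (k in 1:60) {
    read <- rand_dna(sample(5:25, 1))
    ref <- rand_dna(sample(5:25, 1))
    aln <- align_semi_global(read, ref)
    o <- oracle_align(read, ref)
    expect_equal(aln$score, o$score)
    expect_true(validate_alignment(aln))
  }
})

test_that("anchor identity thresholds at 75% of the first 20 reference bases", {
  spec <- toy_amplicon()
  mutate_at <- function(seq, positions) {
    chars <- strsplit(seq, "")[[1]]
    for (p in positions) {
      chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1]
    }
    paste(chars, collapse = "")
  }
  # 5 anchor mismatches: 15/20 = 75% passes
  read15 <- mutate_at(spec$ref_seq, c(2, 5, 9, 13, 17))
  expect_equal(anchor_identity(align_semi_global(read15, spec$ref_seq)), 0.75)
  expect_equal(classify_read(read15, spec)$label, "unedited")
  # 6 anchor mismatches: 14/20 fails
  read14 <- mutate_at(spec$ref_seq, c(2, 5, 9, 13, 17, 19))
  expect_equal(anchor_identity(align_semi_global(read14, spec$ref_seq)), 0.70)
  expect_equal(classify_read(read14, spec)$label, "filtered")
})

test_that("reads not covering the anchor are filtered", {
  spec <- toy_amplicon()
  short <- substr(spec$ref_seq, 1, 10)          # covers half the anchor
  expect_equal(classify_read(short, spec)$label, "filtered")
  inner <- substr(spec$ref_seq, 30, 70)         # starts past the anchor
  expect_equal(classify_read(inner, spec)$label, "filtered")
})

test_that("cut-site indel window is inclusive at 2 bp and excludes 3 bp", {
  spec <- toy_amplicon()
  cut <- spec$cut_site
  read_with <- function(ed) apply_edit(spec$ref_seq, ed)

  # 1-nt insertion exactly at the cut: distance 0
  ins0 <- edit_spec("insertion", cut, "", "T")
  aln <- align_semi_global(read_with(ins0), spec$ref_seq)
  call <- detect_cutsite_indel(aln, cut)
  expect_equal(call$kind, "ins")
  expect_equal(call$distance_to_cut, 0L)

  # deletion with 5' boundary 2 nt from the cut: called (boundary inclusive)
  del2 <- cut_deletion(spec, len = 1L, offset = 2L)
  aln2 <- align_semi_global(read_with(del2), spec$ref_seq)
  expect_false(is.null(detect_cutsite_indel(aln2, cut)))

  # deletion 3 nt away: outside the window
  del3 <- cut_deletion(spec, len = 1L, offset = 3L)
  aln3 <- align_semi_global(read_with(del3), spec$ref_seq)
  expect_null(detect_cutsite_indel(aln3, cut))

  # long deletion counted by its nearest boundary: 10-nt deletion whose 5'
  # boundary is 2 nt 3' of the cut
  del10 <- cut_deletion(spec, len = 10L, offset = 2L)
  aln10 <- align_semi_global(read_with(del10), spec$ref_seq)
  call10 <- detect_cutsite_indel(aln10, cut)
  expect_false(is.null(call10))
  expect_equal(call10$length, 10L)

  # deletion 5 nt 3' of the cut: none
  del5 <- cut_deletion(spec, len = 3L, offset = 5L)
  aln5 <- align_semi_global(read_with(del5), spec$ref_seq)
  expect_null(detect_cutsite_indel(aln5, cut))
})

test_that("classification follows the intended/byproduct/unedited rules", {
  spec <- toy_amplicon()  # substitution edit

  expect_equal(classify_read(spec$ref_seq, spec)$label, "unedited")
  expect_equal(classify_read(spec$edited_seq, spec)$label, "intended")

  # intended substitution plus a cut-site deletion: NOT intended
  # ("with the intended modification, without indels")
  with_both <- apply_edit(spec$edited_seq, cut_deletion(spec))
  expect_equal(classify_read(with_both, spec)$label, "indel_byproduct")

  # a lone cut-site deletion is a byproduct
  byp <- apply_edit(spec$ref_seq, cut_deletion(spec))
  expect_equal(classify_read(byp, spec)$label, "indel_byproduct")
})

test_that("intended insertion and deletion edits are recognised exactly", {
  for (kind in c("insertion", "deletion")) {
    spec <- toy_amplicon(kind)
    expect_equal(classify_read(spec$edited_seq, spec)$label, "intended")
    expect_equal(classify_read(spec$ref_seq, spec)$label, "unedited")
    # a different indel near the cut is a byproduct, not intended
    byp <- apply_edit(spec$ref_seq, cut_deletion(spec))
    expect_equal(classify_read(byp, spec)$label, "indel_byproduct")
  }
})

test_that("error-free simulated reads are classified exactly as their truth", {
  for (kind in c("substitution", "insertion", "deletion")) {
    spec <- toy_amplicon(kind)
    byp <- list(list(edit = cut_deletion(spec), prop = 0.1))
    sim <- simulate_reads(spec, 400, 0.3, byp, per_base_error = 0, seed = 21)
    cls <- classify_reads(sim$reads$seq, spec)
    expect_identical(cls$label, sim$reads$truth)
  }
})

test_that("the four labels partition every read set", {
  spec <- toy_amplicon()
  byp <- list(list(edit = cut_deletion(spec), prop = 0.1))
  sim <- simulate_reads(spec, 300, 0.3, byp, per_base_error = 0.05, seed = 22)
  cls <- classify_reads(sim$reads$seq, spec)
  counts <- table(factor(cls$label, levels = c("filtered", "intended",
                                               "indel_byproduct", "unedited")))
  expect_equal(sum(counts), 300)
  expect_true(all(cls$label %in% c("filtered", "intended",
                                   "indel_byproduct", "unedited")))
})

test_that("classification ignores reference sequence beyond the read span", {
  set.seed(77)
  spec <- toy_amplicon()
  longer <- amplicon_spec(spec$name, paste0(spec$ref_seq, rand_dna(40)),
                          spec$spacer, spec$edit)
  reads <- c(spec$ref_seq, spec$edited_seq,
             apply_edit(spec$ref_seq, cut_deletion(spec)))
  expect_identical(classify_reads(reads, spec)$label,
                   classify_reads(reads, longer)$label)
})

test_that("both-strand mode classifies reverse-complemented reads", {
  spec <- toy_amplicon()
  rc <- revcomp(spec$edited_seq)
  # in given orientation the read cannot be recognised as the intended edit
  expect_false(classify_read(rc, spec)$label == "intended")
  expect_equal(classify_read(rc, spec, both_strands = TRUE)$label, "intended")
})
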