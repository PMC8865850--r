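test_that("splice-donor activity is a registry lookup", {
  expect_equal(splice_state("GGTAAGT"), "active")    # canonical G-GT-AAGT
  expect_equal(splice_state("GACAAGT"), "inactive")  # disabled G-AC-AAGT
  expect_equal(splice_state("GCTAAGT"), "inactive")  # GT -> CT disruption

  # registering a variant changes only that context
  active <- active_donor_contexts(extra = "GGTAAGA")
  expect_equal(splice_state("GGTAAGA", active), "active")
  expect_equal(splice_state("GACAAGT", active), "inactive")
  expect_equal(splice_state("GGTAAGT", active), "active")

  # config file route
  cfg <- tempfile(fileext = ".json")
  jsonlite::write_json(c("GGTGAGT"), cfg)
  expect_equal(splice_state("GGTGAGT", active_donor_contexts(config = cfg)),
               "active")

  expect_error(splice_state("GGTAAG"), "invalid donor context")
  expect_error(splice_state("GGTAANT"), "invalid donor context")
})

test_that("the PBS is the reverse complement of the 5'-of-nick segment", {
  # protospacer-strand reference with positions [13..17] = TGCAT | nick
  anchor13 <- "ACGTTGCAACGTG"             # fills [0..12]
  spacer <- paste0("CAT", "GCAGGACTTACCAATCC")  # protospacer [15..34]
  # layout: [13..14] = TG, protospacer starts at 15 so that [13..17]="TGCAT"
  ref <- paste0(anchor13, "TG", "CAT", "GCAGGACTTACCAATCC", "TGG",
                "GACAAGTCGATCGATCGTACGTAGCTAGGACGT")
  # nick = protospacer_start + 17 = 15 + 17 = 32... use actual spec to check
  ed <- edit_spec("substitution", 39, "AC", "GT")
  spec <- amplicon_spec("pbs_toy", ref, spacer, ed)
  pg <- design_pegrna(spec, pbs_len = 5, rt_len = 16)
  expected_pbs <- chartr("T", "U",
                         revcomp(substr(ref, spec$cut_site - 4, spec$cut_site)))
  expect_equal(pg$pbs, expected_pbs)
  expect_equal(nchar(pg$pbs), 5L)
})

test_that("pegRNA design satisfies the reverse-complement identities on the grid", {
  set.seed(61)
  for (strand in c("+", "-")) {
    spec <- random_amplicon(strand = strand)
    cspec <- peartools:::canonicalize_spec(spec)
    cut <- cspec$cut_site
    grid <- pegrna_grid(spec)  # PBS {10,13,16} x RT {16,24,33}
    expect_equal(nrow(grid), 9L)
    for (k in seq_len(nrow(grid))) {
      expect_equal(nchar(grid$pbs[k]), grid$pbs_len[k])
      expect_equal(nchar(grid$rt_template[k]), grid$rt_len[k])
      # PBS: reverse complement of the pbs_len bases 5' of the nick
      expect_equal(revcomp(chartr("U", "T", grid$pbs[k])),
                   substr(cspec$ref_seq, cut - grid$pbs_len[k] + 1, cut))
      # RT: reverse complement of the first rt_len EDITED bases 3' of the nick
      expect_equal(revcomp(chartr("U", "T", grid$rt_template[k])),
                   substr(cspec$edited_seq, cut + 1, cut + grid$rt_len[k]))
      expect_equal(grid$extension[k], paste0(grid$rt_template[k], grid$pbs[k]))
    }
  }
})

test_that("design errors when the RT cannot encode the edit", {
  spec <- toy_amplicon()  # edit ends 12 nt 3' of the nick
  expect_error(design_pegrna(spec, 10, 5), "RT too short")
  expect_error(design_pegrna(spec, 200, 24), "amplicon too short")
  expect_error(design_pegrna(spec, 10, 200), "amplicon too short")
})

test_that("the edit encoded by the RT template reproduces the edited amplicon", {
  set.seed(62)
  for (kind in c("substitution", "insertion", "deletion")) {
    for (strand in c("+", "-")) {
      spec <- random_amplicon(kind, strand)
      pg <- design_pegrna(spec, 10, 24)
      expect_equal(pegrna_apply(pg, spec), spec$edited_seq)
    }
  }
})

test_that("reads from the RT-encoded template are classified as intended", {
  set.seed(63)
  spec <- random_amplicon("substitution", "+")
  pg <- design_pegrna(spec, 10, 24)
  template <- pegrna_apply(pg, spec)
  reads <- rep(template, 20)
  q <- quantify_sample(classify_reads(reads, spec))
  expect_equal(q$editing_pct, 100)
})

test_that("complementary-strand nicking sites are reported with signed offsets", {
  spec <- toy_amplicon()
  cspec <- peartools:::canonicalize_spec(spec)
  ref <- cspec$ref_seq
  primary <- cspec$cut_site

  # complementary-strand protospacer whose nick falls 17 nt 3' of the
  # primary nick: engineer a CC PAM at p with implied nick p+6 = primary+17
  p <- primary + 11L
  chars <- strsplit(ref, "")[[1]]
  chars[p + 1] <- "C"; chars[p + 2] <- "C"; chars[p + 3] <- "T"
  ref2 <- paste(chars, collapse = "")
  spec2 <- amplicon_spec("nicked", ref2, spec$spacer,
                         edit_spec(spec$edit$kind, spec$edit$position,
                                   substr(ref2, spec$edit$position + 1,
                                          spec$edit$position + 2), "GT"))
  nicks <- enumerate_nicks(spec2, search_range = 30)
  expect_true(17L %in% nicks$offset)
  hit <- nicks[nicks$offset == 17L, ]
  # the reported spacer is the complementary-strand protospacer
  expect_equal(hit$spacer, revcomp(substr(ref2, p + 4, p + 23)))

  # a window too small to reach it returns no such site
  near <- enumerate_nicks(spec2, search_range = 10)
  expect_false(17L %in% near$offset)
})

test_that("enumerated nick offsets agree with an independent CC-PAM scan", {
  spec <- toy_amplicon()
  cspec <- peartools:::canonicalize_spec(spec)
  ref <- cspec$ref_seq
  primary <- cspec$cut_site
  # independent scan: every CC dinucleotide at p with room for a 20-nt
  # protospacer implies a complementary-strand nick at p + 6
  expected <- integer(0)
  for (p in 0:(nchar(ref) - 23L)) {
    if (substr(ref, p + 1L, p + 2L) == "CC") {
      expected <- c(expected, p + 6L - primary)
    }
  }
  expected <- sort(expected[abs(expected) <= 30L])
  nicks <- enumerate_nicks(spec, search_range = 30)
  expect_equal(sort(nicks$offset), expected)
  # the toy amplicon's spacer contains CC runs 5' of the nick, so negative
  # offsets must be present
  expect_true(any(nicks$offset < 0))
})

test_that("an amplicon without complementary PAMs in range yields no nicks", {
  spec <- toy_amplicon()
  # search range so small that no CC lands within it
  nicks_all <- enumerate_nicks(spec, search_range = 30)
  min_abs <- min(abs(nicks_all$offset))
  if (min_abs > 1L) {
    expect_equal(nrow(enumerate_nicks(spec, search_range = min_abs - 1L)), 0L)
  }
  expect_error(enumerate_nicks(spec, search_range = 0), "positive")
})
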