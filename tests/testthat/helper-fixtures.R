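# Fixture builders: synthetic amplicons with a protospacer + NGG PAM and a
# splice-donor context downstream of the nick, mirroring the reporter
# layout (anchor filler | protospacer | PAM | spacer-to-donor filler |
# donor | tail).

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# Deterministic toy amplicon used across tests.
# Layout (0-based): anchor [0,20) | protospacer [20,40) | PAM TGG [40,43) |
# GAC [43,46) | donor GACAAGT [46,53) | tail [53,83).
# Nick at 37; intended substitution at 47 (AC -> GT), i.e. 10 nt 3' of it.
toy_amplicon <- function(edit_kind = "substitution", strand = "+") {
  anchor <- "ACGTTGCAACGTGCTAGCTA"
  spacer <- "GTCACCTCCAATGACTAGGG"
  mid <- "GAC"
  donor <- "GACAAGT"
  tail <- "CGATCGATCGTACGTAGCTAGGACGTAGTCGATG"
  ref <- paste0(anchor, spacer, "TGG", mid, donor, tail)
  donor_start <- nchar(anchor) + 20L + 3L + nchar(mid)  # 46
  edit <- switch(edit_kind,
    substitution = edit_spec("substitution", donor_start + 1L, "AC", "GT"),
    insertion    = edit_spec("insertion", donor_start + 1L, "", "GT"),
    deletion     = edit_spec("deletion", donor_start + 1L, "AC", "")
  )
  if (strand == "-") {
    L <- nchar(ref)
    nr <- nchar(edit$ref_allele)
    edit <- edit_spec(edit$kind, L - edit$position - nr,
                      ref_allele = if (nr) revcomp(edit$ref_allele) else "",
                      alt_allele = if (nchar(edit$alt_allele)) revcomp(edit$alt_allele) else "")
    ref <- revcomp(ref)
  }
  amplicon_spec(paste0("toy_", edit_kind, strand), ref, spacer, edit)
}

# Random amplicon with the toy layout but random filler/spacer; retries
# until the protospacer is unique in the amplicon.
random_amplicon <- function(edit_kind = "substitution", strand = "+") {
  repeat {
    anchor <- rand_dna(20L)
    spacer <- rand_dna(20L)
    mid <- rand_dna(3L)
    tail <- rand_dna(34L)
    ref <- paste0(anchor, spacer, "TGG", mid, "GACAAGT", tail)
    donor_start <- 46L
    edit <- switch(edit_kind,
      substitution = edit_spec("substitution", donor_start + 1L, "AC", "GT"),
      insertion    = edit_spec("insertion", donor_start + 1L, "", "GT"),
      deletion     = edit_spec("deletion", donor_start + 1L, "AC", "")
    )
    if (strand == "-") {
      L <- nchar(ref)
      nr <- nchar(edit$ref_allele)
      edit <- edit_spec(edit$kind, L - edit$position - nr,
                        ref_allele = if (nr) revcomp(edit$ref_allele) else "",
                        alt_allele = if (nchar(edit$alt_allele)) revcomp(edit$alt_allele) else "")
      ref <- revcomp(ref)
    }
    spec <- tryCatch(amplicon_spec("rand", ref, spacer, edit),
                     error = function(e) NULL)
    if (!is.null(spec)) return(spec)
  }
}

# A 1-nt deletion byproduct at the cut site of a spec.
cut_deletion <- function(spec, len = 1L, offset = 0L) {
  pos <- spec$cut_site + offset
  edit_spec("deletion", pos,
            ref_allele = substr(spec$ref_seq, pos + 1L, pos + len),
            alt_allele = "")
}
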