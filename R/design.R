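#' Canonical splice donor context
#'
#' The 7-nt donor context spanning the last exonic base and the first six
#' intronic bases, 5'-G-GT-AAGT-3', with the GT dinucleotide opening the
#' intron obligatory for splicing.
#'
#' @format character scalar.
#' @export
CANONICAL_DONOR <- "GGTAAGT"

#' Active splice-donor context registry
#'
#' The donor activity model is a lookup: a 7-nt context is active iff it is
#' registered as active. The registry seeds with the canonical donor; known
#' additional active variants (e.g. from reporter characterisation
#' experiments) are supplied as extra entries or via a JSON config file
#' holding an array of 7-nt contexts, keeping the activity model
#' data-driven and auditable.
#'
#' @param extra character vector of additional active 7-nt contexts.
#' @param config optional path to a JSON array of active contexts.
#' @return character vector of active donor contexts.
#' @export
active_donor_contexts <- function(extra = character(0), config = NULL) {
  if (!is.null(config)) {
    extra <- c(extra, unlist(jsonlite::read_json(config, simplifyVector = TRUE)))
  }
  if (length(extra) > 0L) {
    assert_dna(extra, "active donor contexts")
    if (any(nchar(extra) != 7L)) {
      stop("invalid donor context", call. = FALSE)
    }
  }
  unique(c(CANONICAL_DONOR, toupper(extra)))
}

#' Splice-donor activity state of a 7-nt context
#'
#' @param context 7-nt DNA string (last exonic base + first 6 intronic).
#' @param active character vector of active contexts
#'   (default [active_donor_contexts()]).
#' @return `"active"` or `"inactive"`.
#' @export
splice_state <- function(context, active = active_donor_contexts()) {
  if (!is.character(context) || length(context) != 1L ||
      nchar(context) != 7L || grepl("[^ACGT]", context)) {
    stop("invalid donor context", call. = FALSE)
  }
  if (context %in% active) "active" else "inactive"
}

#' Design a pegRNA for an amplicon target
#'
#' Constructs the 3' extension of a prime-editing guide: the primer binding
#' site (PBS) is the reverse complement, as RNA, of the `pbs_len` reference
#' bases immediately 5' of the nick on the protospacer strand; the reverse
#' transcriptase template (RT) is the reverse complement, as RNA, of the
#' first `rt_len` bases of the *edited* sequence immediately 3' of the
#' nick on the protospacer strand. The full extension is RT then PBS read
#' 5'->3'. The intended edit must lie within the RT span.
#'
#' @param spec an [amplicon_spec()] (either strand; design arithmetic is
#'   done on the protospacer strand).
#' @param pbs_len PBS length in nt.
#' @param rt_len RT template length in nt.
#' @return object of class `pegrna`: `spacer` (RNA), `pbs`, `rt_template`,
#'   `extension`, plus `pbs_len`, `rt_len`.
#' @export
design_pegrna <- function(spec, pbs_len, rt_len) {
  stopifnot(inherits(spec, "amplicon_spec"))
  if (pbs_len < 1L || rt_len < 1L) {
    stop("pbs_len and rt_len must be >= 1", call. = FALSE)
  }
  cspec <- canonicalize_spec(spec)
  cut <- cspec$cut_site
  ed <- cspec$edit

  if (ed$position < cut) {
    stop("edit lies 5' of the nick on the protospacer strand; prime editing ",
         "writes 3' of the nick", call. = FALSE)
  }
  # end of the edit in edited-sequence coordinates (5' segment up to the
  # nick is unchanged, so edited coordinates equal reference coordinates
  # through the edit start); deletions must be bridged by >= 1 base of 3'
  # flank beyond the junction
  edit_end <- ed$position + max(nchar(ed$alt_allele), 1L)
  if (cut + rt_len < edit_end) {
    stop("RT too short to encode edit", call. = FALSE)
  }
  if (cut - pbs_len < 0L) stop("amplicon too short", call. = FALSE)
  if (cut + rt_len > nchar(cspec$edited_seq)) {
    stop("amplicon too short", call. = FALSE)
  }

  pbs_dna <- substr(cspec$ref_seq, cut - pbs_len + 1L, cut)
  rt_dna <- substr(cspec$edited_seq, cut + 1L, cut + rt_len)
  pbs <- dna_to_rna(revcomp(pbs_dna))
  rt <- dna_to_rna(revcomp(rt_dna))
  structure(
    list(spacer = dna_to_rna(spec$spacer), pbs = pbs, rt_template = rt,
         extension = paste0(rt, pbs), pbs_len = pbs_len, rt_len = rt_len),
    class = "pegrna"
  )
}

#' Reconstruct the edited amplicon encoded by a pegRNA
#'
#' Decodes the RT template back to DNA and splices it onto the reference at
#' the nick, continuing with reference sequence beyond the RT span (shifted
#' by the edit's length change). For a correctly designed pegRNA the result
#' equals `apply_edit(ref_seq, edit)`. The sequence is returned in the
#' spec's original forward-strand frame.
#'
#' @param pegrna a [design_pegrna()] result.
#' @param spec the [amplicon_spec()] it was designed for.
#' @return edited amplicon DNA string.
#' @export
pegrna_apply <- function(pegrna, spec) {
  stopifnot(inherits(pegrna, "pegrna"), inherits(spec, "amplicon_spec"))
  cspec <- canonicalize_spec(spec)
  cut <- cspec$cut_site
  rt_dna <- revcomp(chartr("U", "T", pegrna$rt_template))
  delta <- nchar(cspec$edit$alt_allele) - nchar(cspec$edit$ref_allele)
  tail_start <- cut + nchar(rt_dna) - delta
  out <- paste0(substr(cspec$ref_seq, 1L, cut), rt_dna,
                substr(cspec$ref_seq, tail_start + 1L, nchar(cspec$ref_seq)))
  if (spec$strand == "-") revcomp(out) else out
}

#' Enumerate candidate pegRNAs over a PBS x RT grid
#'
#' @param spec an [amplicon_spec()].
#' @param pbs_lens,rt_lens vectors of lengths to combine (defaults are the
#'   commonly screened PBS 10/13/16 by RT 16/24/33 grid).
#' @return data.frame with one row per (PBS, RT) combination and the
#'   designed sequences.
#' @export
pegrna_grid <- function(spec, pbs_lens = c(10L, 13L, 16L),
                        rt_lens = c(16L, 24L, 33L)) {
  combos <- expand.grid(pbs_len = pbs_lens, rt_len = rt_lens)
  rows <- lapply(seq_len(nrow(combos)), function(k) {
    pg <- design_pegrna(spec, combos$pbs_len[k], combos$rt_len[k])
    data.frame(pbs_len = pg$pbs_len, rt_len = pg$rt_len, spacer = pg$spacer,
               pbs = pg$pbs, rt_template = pg$rt_template,
               extension = pg$extension, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Enumerate complementary-strand nicking sites
#'
#' Finds every protospacer with an NGG PAM on the strand opposite the
#' primary protospacer whose implied nick falls within `search_range` nt of
#' the primary nick. Offsets are nick-to-nick and signed: positive offsets
#' lie 3' of the primary nick on the protospacer (edited) strand, negative
#' offsets 5'.
#'
#' @param spec an [amplicon_spec()].
#' @param search_range maximum absolute nick offset in nt.
#' @return data.frame with `offset`, `spacer` (complementary-strand
#'   protospacer), `nick_pos` (inter-base, protospacer-strand frame);
#'   empty when no site exists.
#' @export
enumerate_nicks <- function(spec, search_range) {
  stopifnot(inherits(spec, "amplicon_spec"))
  if (search_range <= 0) stop("search_range must be positive", call. = FALSE)
  cspec <- canonicalize_spec(spec)
  seq <- cspec$ref_seq
  L <- nchar(seq)
  primary <- cspec$cut_site

  out <- data.frame(offset = integer(0), spacer = character(0),
                    nick_pos = integer(0), stringsAsFactors = FALSE)
  # complementary-strand protospacer+PAM appears on this strand as
  # CCN + revcomp(protospacer): PAM at [p, p+3), protospacer at [p+3, p+23)
  for (p in 0:(L - 23L)) {
    if (substr(seq, p + 1L, p + 2L) != "CC") next
    nick <- p + 6L  # between protospacer positions 17/18 on the other strand
    offset <- nick - primary
    if (abs(offset) > search_range) next
    spacer <- revcomp(substr(seq, p + 4L, p + 23L))
    out <- rbind(out, data.frame(offset = offset, spacer = spacer,
                                 nick_pos = nick, stringsAsFactors = FALSE))
  }
  out[order(abs(out$offset)), , drop = FALSE]
}
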