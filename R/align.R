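OP_LEVELS <- c("match", "mismatch", "ins", "del")

#' Semi-global alignment of a read against a reference amplicon
#'
#' Aligns the read globally (every read base is placed) against the
#' reference with free end gaps in the reference, using affine gap costs:
#' match +1, mismatch -1, and a gap of length L costing
#' `gap_open + L * gap_extend` (defaults -4 - L). Tie-breaking is
#' deterministic (diagonal moves preferred over gaps); indel runs are
#' subsequently left-normalised so their reported positions are leftmost.
#'
#' @param read,ref non-empty DNA strings.
#' @param match,mismatch,gap_open,gap_extend scoring parameters.
#' @return an object of class `pe_alignment`: `score`, `ops` (data.frame
#'   with columns `op`, `length`, `ref_pos`, `read_pos`; `ref_pos` is the
#'   0-based start on the reference, for insertions the inter-base point),
#'   `ref_start`/`ref_end` (aligned reference span), plus the input
#'   sequences.
#' @export
align_semi_global <- function(read, ref, match = 1, mismatch = -1,
                              gap_open = -4, gap_extend = -1) {
  if (!nzchar(read) || !nzchar(ref)) stop("empty sequence", call. = FALSE)
  assert_dna(read, "read")
  assert_dna(ref, "ref")
  res <- .gotoh_semiglobal(read, ref, match, mismatch, gap_open, gap_extend)
  runs <- res$runs
  ops <- data.frame(
    op = OP_LEVELS[runs[, "op"]],
    length = runs[, "length"],
    ref_pos = runs[, "ref_pos"],
    read_pos = runs[, "read_pos"],
    stringsAsFactors = FALSE
  )
  structure(
    list(score = res$score, ops = ops,
         ref_start = res$ref_start, ref_end = res$ref_end,
         read = read, ref = ref),
    class = "pe_alignment"
  )
}

#' Anchor identity of an alignment
#'
#' Fraction of the first `anchor_len` reference bases (positions 0 ..
#' `anchor_len - 1`) that are matched by the read. Reference bases outside
#' the aligned span, deleted, or mismatched count as non-matches; gaps count
#' as non-matches.
#'
#' @param aln a `pe_alignment`.
#' @param anchor_len anchor length in nt (default 20, the first 20 bp of the
#'   reference amplicon).
#' @return fraction in \[0, 1\].
#' @export
anchor_identity <- function(aln, anchor_len = 20L) {
  stopifnot(inherits(aln, "pe_alignment"))
  matched <- 0L
  for (k in seq_len(nrow(aln$ops))) {
    if (aln$ops$op[k] != "match") next
    s <- aln$ops$ref_pos[k]
    e <- s + aln$ops$length[k]              # half-open on reference
    ov <- min(e, anchor_len) - max(s, 0L)
    if (ov > 0L) matched <- matched + ov
  }
  matched / anchor_len
}

# Extract indel runs from an alignment as clean gap calls, left-normalised:
# a deletion of ref [s, s+L) shifts left while ref[s-1] == ref[s+L-1]; an
# insertion at inter-base p with inserted bases q rotates left while
# ref[p-1] equals the last inserted base.
alignment_indels <- function(aln) {
  stopifnot(inherits(aln, "pe_alignment"))
  ops <- aln$ops
  idx <- which(ops$op %in% c("ins", "del"))
  if (length(idx) == 0L) {
    return(data.frame(kind = character(0), ref_pos = integer(0),
                      length = integer(0), seq = character(0),
                      stringsAsFactors = FALSE))
  }
  ref <- aln$ref
  out <- lapply(idx, function(k) {
    len <- ops$length[k]
    if (ops$op[k] == "del") {
      s <- ops$ref_pos[k]
      while (s > 0L &&
             substr(ref, s, s) == substr(ref, s + len, s + len)) {
        s <- s - 1L
      }
      data.frame(kind = "del", ref_pos = s, length = len,
                 seq = substr(ref, s + 1L, s + len), stringsAsFactors = FALSE)
    } else {
      p <- ops$ref_pos[k]
      q <- substr(aln$read, ops$read_pos[k] + 1L, ops$read_pos[k] + len)
      while (p > 0L && substr(ref, p, p) == substr(q, len, len)) {
        q <- paste0(substr(q, len, len), substr(q, 1L, len - 1L))
        p <- p - 1L
      }
      data.frame(kind = "ins", ref_pos = p, length = len, seq = q,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}

#' Call an indel near the cut site
#'
#' Scans the alignment's indels for one whose reference anchor point lies
#' within `window` nt of the cut site: for insertions the insertion point,
#' for deletions the nearer of the two deletion boundaries (inclusive).
#' Indels of any length qualify. Returns `NULL` when no indel is in the
#' window; with several, the one nearest the cut is returned.
#'
#' @param aln a `pe_alignment`.
#' @param cut inter-base cut position on the reference.
#' @param window window half-width in nt (default 2, i.e. cut +/- 2 bp).
#' @return list with `kind`, `length`, `ref_pos`, `seq`,
#'   `distance_to_cut`, or `NULL`.
#' @export
detect_cutsite_indel <- function(aln, cut, window = 2L) {
  ind <- alignment_indels(aln)
  if (nrow(ind) == 0L) return(NULL)
  dist <- vapply(seq_len(nrow(ind)), function(k) {
    if (ind$kind[k] == "ins") {
      ind$ref_pos[k] - cut
    } else {
      d1 <- ind$ref_pos[k] - cut
      d2 <- ind$ref_pos[k] + ind$length[k] - cut
      if (abs(d1) <= abs(d2)) d1 else d2
    }
  }, numeric(1))
  hit <- which(abs(dist) <= window)
  if (length(hit) == 0L) return(NULL)
  best <- hit[which.min(abs(dist[hit]))]
  list(kind = ind$kind[best], length = ind$length[best],
       ref_pos = ind$ref_pos[best], seq = ind$seq[best],
       distance_to_cut = as.integer(dist[best]))
}

# Left-normalised representation of the intended edit, for comparison with
# alignment indel calls (which are left-normalised too).
normalized_intended_indel <- function(spec) {
  ed <- spec$edit
  if (ed$kind == "substitution") return(NULL)
  ref <- spec$ref_seq
  if (ed$kind == "deletion") {
    s <- ed$position
    len <- nchar(ed$ref_allele)
    while (s > 0L && substr(ref, s, s) == substr(ref, s + len, s + len)) {
      s <- s - 1L
    }
    list(kind = "del", ref_pos = s, length = len,
         seq = substr(ref, s + 1L, s + len))
  } else {
    p <- ed$position
    q <- ed$alt_allele
    len <- nchar(q)
    while (p > 0L && substr(ref, p, p) == substr(q, len, len)) {
      q <- paste0(substr(q, len, len), substr(q, 1L, len - 1L))
      p <- p - 1L
    }
    list(kind = "ins", ref_pos = p, length = len, seq = q)
  }
}

# Read bases aligned to reference interval [from, to); NA when any position
# in the interval is deleted or unaligned.
read_bases_at <- function(aln, from, to) {
  if (from < aln$ref_start || to > aln$ref_end) return(NA_character_)
  out <- character(0)
  for (k in seq_len(nrow(aln$ops))) {
    op <- aln$ops$op[k]
    if (op == "ins") next
    s <- aln$ops$ref_pos[k]
    e <- s + aln$ops$length[k]
    ov_s <- max(s, from); ov_e <- min(e, to)
    if (ov_s >= ov_e) next
    if (op == "del") return(NA_character_)
    off <- aln$ops$read_pos[k] + (ov_s - s)
    out <- c(out, substr(aln$read, off + 1L, off + (ov_e - ov_s)))
  }
  paste0(out, collapse = "")
}

#' Classify a read against an amplicon target
#'
#' Applies, in order: (1) the anchor filter — reads matching fewer than
#' `anchor_min` of the first 20 reference bases are `filtered` (reads whose
#' alignment does not cover the anchor are filtered too); (2) intended-edit
#' detection — for substitution edits the read must carry the alternate
#' allele at the edit position and contain no indel anywhere; for intended
#' insertions/deletions the alignment must contain an indel matching the
#' intended edit exactly (left-normalised position, length and inserted
#' bases); (3) otherwise a cut-site indel (within `window` bp) different
#' from the intended edit makes the read an `indel_byproduct`; (4) else the
#' read is `unedited`.
#'
#' @param read DNA string.
#' @param spec an [amplicon_spec()].
#' @param anchor_min minimum anchor identity (default 0.75, i.e. at least
#'   75% of the first 20 bp).
#' @param window cut-site indel window half-width in bp (default 2).
#' @param both_strands if `TRUE`, also try the reverse complement of the
#'   read and keep the orientation with the better anchor identity.
#' @return list with `label` (one of `filtered`, `intended`,
#'   `indel_byproduct`, `unedited`) and `indel` (cut-site indel call or
#'   `NULL`).
#' @export
classify_read <- function(read, spec, anchor_min = 0.75, window = 2L,
                          both_strands = FALSE) {
  stopifnot(inherits(spec, "amplicon_spec"))
  if (!nzchar(read)) stop("empty sequence", call. = FALSE)
  aln <- align_semi_global(read, spec$ref_seq)
  if (both_strands) {
    aln_rc <- align_semi_global(revcomp(read), spec$ref_seq)
    if (anchor_identity(aln_rc) > anchor_identity(aln)) aln <- aln_rc
  }
  if (anchor_identity(aln) < anchor_min) {
    return(list(label = "filtered", indel = NULL))
  }

  ed <- spec$edit
  indels <- alignment_indels(aln)
  cut_call <- detect_cutsite_indel(aln, spec$cut_site, window = window)

  if (ed$kind == "substitution") {
    at_edit <- read_bases_at(aln, ed$position,
                             ed$position + nchar(ed$ref_allele))
    if (!is.na(at_edit) && at_edit == ed$alt_allele && nrow(indels) == 0L) {
      return(list(label = "intended", indel = NULL))
    }
  } else {
    want <- normalized_intended_indel(spec)
    hit <- nrow(indels) > 0L & any(
      indels$kind == want$kind & indels$ref_pos == want$ref_pos &
        indels$length == want$length & indels$seq == want$seq
    )
    if (hit) {
      return(list(label = "intended",
                  indel = list(kind = want$kind, length = want$length,
                               ref_pos = want$ref_pos, seq = want$seq,
                               distance_to_cut = NA_integer_)))
    }
  }

  intended_is_cut_call <- FALSE
  if (!is.null(cut_call) && ed$kind != "substitution") {
    want <- normalized_intended_indel(spec)
    intended_is_cut_call <- cut_call$kind == want$kind &&
      cut_call$ref_pos == want$ref_pos && cut_call$length == want$length &&
      cut_call$seq == want$seq
  }
  if (!is.null(cut_call) && !intended_is_cut_call) {
    return(list(label = "indel_byproduct", indel = cut_call))
  }
  list(label = "unedited", indel = NULL)
}

#' Classify a set of reads
#'
#' @param reads character vector of read sequences (names used as read ids
#'   when present).
#' @param spec an [amplicon_spec()].
#' @inheritParams classify_read
#' @return data.frame with columns `id`, `label`, `indel_kind`,
#'   `indel_length`, `indel_ref_pos`.
#' @export
classify_reads <- function(reads, spec, anchor_min = 0.75, window = 2L,
                           both_strands = FALSE) {
  ids <- names(reads)
  if (is.null(ids)) ids <- paste0("read", seq_along(reads))
  # classification is a pure function of the read sequence: classify each
  # distinct sequence once (amplicon reads are heavily duplicated)
  uniq <- unique(reads)
  res_uniq <- lapply(uniq, classify_read, spec = spec,
                     anchor_min = anchor_min, window = window,
                     both_strands = both_strands)
  res <- res_uniq[match(reads, uniq)]
  data.frame(
    id = ids,
    label = vapply(res, `[[`, character(1), "label"),
    indel_kind = vapply(res, function(r)
      if (is.null(r$indel)) NA_character_ else r$indel$kind, character(1)),
    indel_length = vapply(res, function(r)
      if (is.null(r$indel)) NA_integer_ else as.integer(r$indel$length),
      integer(1)),
    indel_ref_pos = vapply(res, function(r)
      if (is.null(r$indel)) NA_integer_ else as.integer(r$indel$ref_pos),
      integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
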