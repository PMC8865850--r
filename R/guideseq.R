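#' GUIDE-seq double-stranded oligodeoxynucleotide (dsODN) tag
#'
#' The standard 34-nt blunt dsODN captured at double-strand breaks, and the
#' 15-nt centre fragment used for tag counting.
#'
#' @format character scalars.
#' @export
GUIDESEQ_DSODN <- "GTTTAATTGAGTTGTCATATGTTAATAACGGTAT"

#' @rdname GUIDESEQ_DSODN
#' @export
GUIDESEQ_DSODN_CENTER <- "GTTGTCATATGTTAA"

#' Count dsODN tag integrations in a read set
#'
#' A read counts for the centre (respectively full) category when it
#' contains the exact centre fragment (respectively the entire dsODN) in
#' either orientation; matching is exact (no mismatches tolerated in the
#' tag) and each read is counted at most once per category. The centre
#' fragment is a subsequence of the full tag, so `n_center_tag >=
#' n_full_tag` always.
#'
#' @param reads character vector of read sequences.
#' @param dsodn full dsODN sequence (default [GUIDESEQ_DSODN]).
#' @param center 15-nt centre fragment (default [GUIDESEQ_DSODN_CENTER]);
#'   must be a substring of `dsodn` or of its reverse complement.
#' @return list of class `tag_count`: `n_reads`, `n_full_tag`,
#'   `n_center_tag`.
#' @export
count_tags <- function(reads, dsodn = GUIDESEQ_DSODN,
                       center = GUIDESEQ_DSODN_CENTER) {
  assert_dna(dsodn, "dsodn")
  assert_dna(center, "center")
  if (!grepl(center, dsodn, fixed = TRUE) &&
      !grepl(center, revcomp(dsodn), fixed = TRUE)) {
    stop("inconsistent tag definition: center fragment is not a substring ",
         "of the dsODN (either orientation)", call. = FALSE)
  }
  if (length(reads) > 0L) assert_dna(reads, "reads")
  has_either <- function(frag) {
    grepl(frag, reads, fixed = TRUE) | grepl(revcomp(frag), reads, fixed = TRUE)
  }
  structure(
    list(n_reads = length(reads),
         n_full_tag = sum(has_either(dsodn)),
         n_center_tag = sum(has_either(center))),
    class = "tag_count"
  )
}

#' Tag-integration percentage of modified reads
#'
#' Expresses the centre-fragment tag count as a percentage of the modified
#' read population (reads carrying an indel or a tag), the denominator used
#' when reporting tag integration frequency of modified cells; pass
#' `n_modified = tag$n_reads` to report against all reads instead.
#'
#' @param tag a `tag_count` from [count_tags()].
#' @param n_modified number of modified reads (indel- or tag-carrying).
#' @return percentage on \[0, 100\].
#' @export
tag_pct_of_modified <- function(tag, n_modified) {
  stopifnot(inherits(tag, "tag_count"))
  if (n_modified <= 0) return(0)
  100 * tag$n_center_tag / n_modified
}

#' Filter candidate off-target sites
#'
#' Computes position-wise (Hamming) mismatches of each candidate site
#' against the 20-nt target spacer — the PAM is excluded from the count —
#' and retains sites with at most `max_mismatches` mismatches that are
#' absent from the background controls. The result is sorted by mismatch
#' count, then by descending read support when an `n_reads` column is
#' present.
#'
#' @param candidates data.frame with columns `site_seq` (20-nt protospacer,
#'   optionally followed by a 3-nt PAM that is ignored), `in_background`
#'   (logical), and optionally `n_reads`.
#' @param target_spacer 20-nt spacer sequence.
#' @param max_mismatches retention threshold (default 7).
#' @return the input data.frame with added `mismatches` and `retained`
#'   columns, restricted to retained sites and sorted.
#' @export
filter_offtargets <- function(candidates, target_spacer, max_mismatches = 7L) {
  assert_dna(target_spacer, "target_spacer")
  stopifnot(is.data.frame(candidates),
            all(c("site_seq", "in_background") %in% names(candidates)))
  k <- nchar(target_spacer)
  sites <- toupper(candidates$site_seq)
  if (any(!nchar(sites) %in% c(k, k + 3L))) {
    stop("site/spacer length mismatch", call. = FALSE)
  }
  proto <- substr(sites, 1L, k)
  spl <- strsplit(proto, "", fixed = TRUE)
  tgt <- strsplit(target_spacer, "", fixed = TRUE)[[1]]
  mm <- vapply(spl, function(s) sum(s != tgt), integer(1))
  out <- candidates
  out$mismatches <- mm
  out$retained <- mm <= max_mismatches & !candidates$in_background
  out <- out[out$retained, , drop = FALSE]
  ord <- if ("n_reads" %in% names(out)) {
    order(out$mismatches, -out$n_reads)
  } else {
    order(out$mismatches)
  }
  out[ord, , drop = FALSE]
}
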