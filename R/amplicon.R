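#' Specify an intended edit on a reference amplicon
#'
#' An edit is described on the forward strand of the reference amplicon with
#' 0-based coordinates. Substitutions replace `ref_allele` by an `alt_allele`
#' of equal length; insertions have an empty `ref_allele` (the new bases are
#' placed immediately before `position`); deletions have an empty
#' `alt_allele`.
#'
#' @param kind one of `"substitution"`, `"insertion"`, `"deletion"`.
#' @param position 0-based forward-strand offset of the edit.
#' @param ref_allele reference bases replaced (empty string for insertions).
#' @param alt_allele replacement bases (empty string for deletions).
#' @return an object of class `edit_spec`.
#' @export
edit_spec <- function(kind, position, ref_allele = "", alt_allele = "") {
  kind <- match.arg(kind, c("substitution", "insertion", "deletion"))
  if (!is.numeric(position) || length(position) != 1L || position < 0 ||
      position != floor(position)) {
    stop("position must be a non-negative integer offset", call. = FALSE)
  }
  if (nzchar(ref_allele)) assert_dna(ref_allele, "ref_allele")
  if (nzchar(alt_allele)) assert_dna(alt_allele, "alt_allele")
  nr <- nchar(ref_allele)
  na <- nchar(alt_allele)
  ok <- switch(kind,
    substitution = nr == na && nr >= 1L,
    insertion    = nr == 0L && na >= 1L,
    deletion     = na == 0L && nr >= 1L
  )
  if (!ok) {
    stop("allele lengths inconsistent with edit kind '", kind, "'",
         call. = FALSE)
  }
  structure(
    list(kind = kind, position = as.integer(position),
         ref_allele = ref_allele, alt_allele = alt_allele),
    class = "edit_spec"
  )
}

#' Apply an edit to a sequence
#'
#' @param seq DNA string (forward strand).
#' @param edit an [edit_spec()].
#' @return the edited sequence; its length changes by
#'   `nchar(alt_allele) - nchar(ref_allele)`.
#' @export
apply_edit <- function(seq, edit) {
  assert_dna(seq)
  stopifnot(inherits(edit, "edit_spec"))
  pos <- edit$position
  nr <- nchar(edit$ref_allele)
  if (pos + nr > nchar(seq)) {
    stop("edit inconsistent with reference: edit extends past sequence end",
         call. = FALSE)
  }
  if (nr > 0L && substr(seq, pos + 1L, pos + nr) != edit$ref_allele) {
    stop("edit inconsistent with reference: ref_allele does not match",
         call. = FALSE)
  }
  paste0(substr(seq, 1L, pos), edit$alt_allele,
         substr(seq, pos + nr + 1L, nchar(seq)))
}

#' Invert an edit
#'
#' Returns the edit that, applied to the edited sequence, restores the
#' original: substitutions swap alleles, insertions become deletions of the
#' inserted bases and vice versa.
#'
#' @param edit an [edit_spec()].
#' @return an [edit_spec()] acting on the edited sequence.
#' @export
invert_edit <- function(edit) {
  stopifnot(inherits(edit, "edit_spec"))
  kind <- switch(edit$kind,
    substitution = "substitution",
    insertion = "deletion",
    deletion = "insertion"
  )
  edit_spec(kind, edit$position,
            ref_allele = edit$alt_allele, alt_allele = edit$ref_allele)
}

#' Locate a protospacer (spacer + NGG PAM) in an amplicon
#'
#' Searches both strands for the unique occurrence of the 20-nt spacer
#' followed immediately by an NGG PAM on the same strand. Coordinates are
#' reported on the forward strand, 0-based: `start` is the offset of the
#' first base of the protospacer's forward-strand footprint (the 20-nt
#' interval `[start, start + 20)`).
#'
#' @param ref_seq amplicon sequence (forward strand).
#' @param spacer 20-nt protospacer-strand sequence.
#' @return list with `strand` (`"+"` or `"-"`), `start` and `pam_ok = TRUE`.
#' @export
find_protospacer <- function(ref_seq, spacer) {
  assert_dna(ref_seq, "ref_seq")
  assert_dna(spacer, "spacer")
  if (nchar(spacer) != 20L) stop("spacer length must be exactly 20", call. = FALSE)
  if (nchar(ref_seq) < 23L) stop("ref_seq must be at least 23 nt", call. = FALSE)

  hits_on <- function(seq) {
    # all spacer occurrences followed by NGG
    starts <- integer(0)
    from <- 1L
    repeat {
      hit <- regexpr(spacer, substr(seq, from, nchar(seq)), fixed = TRUE)
      if (hit == -1L) break
      s <- from + as.integer(hit) - 1L  # 1-based
      pam <- substr(seq, s + 20L, s + 22L)
      if (nchar(pam) == 3L && substr(pam, 2L, 3L) == "GG") {
        starts <- c(starts, s - 1L)     # 0-based
      }
      from <- s + 1L
    }
    starts
  }

  fwd <- hits_on(ref_seq)
  rev <- hits_on(revcomp(ref_seq))
  n_hits <- length(fwd) + length(rev)
  if (n_hits == 0L) stop("target not found", call. = FALSE)
  if (n_hits > 1L) stop("ambiguous target", call. = FALSE)

  if (length(fwd) == 1L) {
    list(strand = "+", start = fwd, pam_ok = TRUE)
  } else {
    # map reverse-strand 0-based start back to forward coordinates
    L <- nchar(ref_seq)
    list(strand = "-", start = L - rev - 20L, pam_ok = TRUE)
  }
}

#' Nick position implied by a protospacer match
#'
#' SpCas9 nicks between protospacer positions 17 and 18 (3 nt 5' of the
#' PAM on the protospacer strand). The cut site is returned as an
#' inter-base integer `k` on the forward strand, meaning the nick falls
#' between forward offsets `k - 1` and `k`.
#'
#' @param match a protospacer match from [find_protospacer()].
#' @return inter-base cut position (integer).
#' @export
cut_site <- function(match) {
  stopifnot(is.list(match), !is.null(match$strand), !is.null(match$start))
  if (match$strand == "+") match$start + 17L else match$start + 3L
}

#' Build an amplicon target specification
#'
#' Bundles the reference amplicon, its protospacer location, the implied
#' nick, and the intended edit (checked for downstream placement is left to
#' design functions). The edited sequence is derived with [apply_edit()].
#'
#' @param name identifier.
#' @param ref_seq reference amplicon (forward strand, uppercase A/C/G/T).
#' @param spacer 20-nt protospacer sequence (protospacer-strand convention).
#' @param edit an [edit_spec()] in forward-strand coordinates.
#' @return an object of class `amplicon_spec` with fields `name`, `ref_seq`,
#'   `spacer`, `protospacer_start`, `strand`, `cut_site`, `edit`,
#'   `edited_seq`.
#' @export
amplicon_spec <- function(name, ref_seq, spacer, edit) {
  assert_dna(ref_seq, "ref_seq")
  stopifnot(inherits(edit, "edit_spec"))
  m <- find_protospacer(ref_seq, spacer)
  cut <- cut_site(m)
  if (cut <= 0L || cut >= nchar(ref_seq)) {
    stop("cut site falls outside the amplicon", call. = FALSE)
  }
  structure(
    list(name = name, ref_seq = ref_seq, spacer = spacer,
         protospacer_start = m$start, strand = m$strand,
         cut_site = cut, edit = edit,
         edited_seq = apply_edit(ref_seq, edit)),
    class = "amplicon_spec"
  )
}

#' @export
print.amplicon_spec <- function(x, ...) {
  cat("amplicon_spec '", x$name, "': ", nchar(x$ref_seq), " nt, protospacer ",
      x$strand, "[", x$protospacer_start, ",", x$protospacer_start + 20L,
      "), nick at ", x$cut_site, ", edit ", x$edit$kind, "@", x$edit$position,
      " ", x$edit$ref_allele, ">", x$edit$alt_allele, "\n", sep = "")
  invisible(x)
}

#' Read a target specification from FASTA + JSON
#'
#' The JSON file mirrors the amplicon specification: fields `name`,
#' `spacer`, and `edit` (`kind`, `position`, `ref_allele`, `alt_allele`).
#' The reference amplicon is taken from the FASTA record whose name matches
#' `name` (or the single record if the file holds one sequence).
#'
#' @param json_path path to the JSON target specification.
#' @param fasta_path path to the reference amplicon FASTA.
#' @return an [amplicon_spec()].
#' @export
read_target_spec <- function(json_path, fasta_path) {
  js <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  nm <- if (!is.null(js$name)) js$name else names(seqs)[1L]
  idx <- if (length(seqs) == 1L) 1L else match(nm, names(seqs))
  if (is.na(idx)) stop("amplicon '", nm, "' not found in FASTA", call. = FALSE)
  ed <- edit_spec(js$edit$kind, js$edit$position,
                  ref_allele = if (is.null(js$edit$ref_allele)) "" else js$edit$ref_allele,
                  alt_allele = if (is.null(js$edit$alt_allele)) "" else js$edit$alt_allele)
  amplicon_spec(nm, toupper(as.character(seqs[[idx]])), js$spacer, ed)
}

# Canonicalise a spec so that the protospacer strand is the forward strand.
# Design arithmetic (PBS/RT extraction, nick offsets) is done in this frame.
canonicalize_spec <- function(spec) {
  stopifnot(inherits(spec, "amplicon_spec"))
  if (spec$strand == "+") return(spec)
  L <- nchar(spec$ref_seq)
  ed <- spec$edit
  nr <- nchar(ed$ref_allele)
  flipped <- edit_spec(
    ed$kind,
    L - ed$position - nr,
    ref_allele = if (nr > 0L) revcomp(ed$ref_allele) else "",
    alt_allele = if (nchar(ed$alt_allele) > 0L) revcomp(ed$alt_allele) else ""
  )
  amplicon_spec(spec$name, revcomp(spec$ref_seq), spec$spacer, flipped)
}
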