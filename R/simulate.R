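#' Simulate amplicon sequencing reads with a known editing mixture
#'
#' Draws each read from the intended-edit template, one of the byproduct
#' indel templates, or the unedited reference, with the given mixture
#' proportions; truncates to `read_len` from the amplicon 5' end; and adds
#' i.i.d. substitution sequencing errors at `per_base_error` per base
#' (errors are substitutions only, so the indel structure of a read is
#' never perturbed). Quality strings are constant high quality ("I") since
#' downstream classification applies no quality filtering. Deterministic
#' for a fixed seed.
#'
#' @param spec an [amplicon_spec()].
#' @param n_reads number of reads.
#' @param frac_intended proportion of reads carrying the intended edit.
#' @param byproducts list of byproduct components, each a list with `edit`
#'   (an insertion/deletion [edit_spec()] applied to the reference) and
#'   `prop` (proportion). `frac_intended + sum(prop)` must be <= 1; the
#'   remainder is unedited.
#' @param per_base_error substitution error probability per base.
#' @param read_len read length in nt (defaults to the reference length; the
#'   shorter of `read_len` and each template's length is emitted).
#' @param seed integer seed.
#' @return list with `reads` — data.frame(`id`, `seq`, `qual`, `truth`) —
#'   and the templates used.
#' @export
simulate_reads <- function(spec, n_reads, frac_intended, byproducts = list(),
                           per_base_error = 0, read_len = NULL, seed = 1L) {
  stopifnot(inherits(spec, "amplicon_spec"))
  assert_probability(frac_intended, "frac_intended")
  assert_probability(per_base_error, "per_base_error")
  props <- vapply(byproducts, function(b) b$prop, numeric(1))
  if (frac_intended + sum(props) > 1 + 1e-12) {
    stop("frac_intended plus byproduct proportions exceed 1", call. = FALSE)
  }
  if (is.null(read_len)) read_len <- nchar(spec$ref_seq)

  ed <- spec$edit
  edit_end <- ed$position + max(nchar(ed$alt_allele), 1L)
  if (read_len < max(20L, edit_end)) {
    stop("read too short for classification", call. = FALSE)
  }

  templates <- c(
    list(intended = spec$edited_seq),
    stats::setNames(
      lapply(byproducts, function(b) apply_edit(spec$ref_seq, b$edit)),
      if (length(byproducts)) paste0("byproduct", seq_along(byproducts)) else NULL
    ),
    list(unedited = spec$ref_seq)
  )
  truth_labels <- c("intended",
                    rep("indel_byproduct", length(byproducts)),
                    "unedited")
  probs <- c(frac_intended, props, 1 - frac_intended - sum(props))

  with_seed(seed, {
    comp <- sample.int(length(templates), n_reads, replace = TRUE, prob = probs)
    seqs <- vapply(comp, function(k) {
      tpl <- templates[[k]]
      substr(tpl, 1L, min(read_len, nchar(tpl)))
    }, character(1))
    if (per_base_error > 0) {
      seqs <- vapply(seqs, function(s) {
        L <- nchar(s)
        hit <- which(stats::runif(L) < per_base_error)
        if (length(hit) == 0L) return(s)
        chars <- strsplit(s, "", fixed = TRUE)[[1]]
        for (p in hit) {
          chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
        }
        paste0(chars, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    list(
      reads = data.frame(
        id = sprintf("read%06d", seq_len(n_reads)),
        seq = seqs,
        qual = vapply(nchar(seqs), function(L) strrep("I", L), character(1)),
        truth = truth_labels[comp],
        stringsAsFactors = FALSE
      ),
      templates = templates
    )
  })
}

#' Write simulated reads as FASTQ
#'
#' @param reads data.frame with `id`, `seq`, `qual` (from
#'   [simulate_reads()]).
#' @param path output FASTQ path.
#' @export
write_fastq <- function(reads, path) {
  lines <- character(4L * nrow(reads))
  lines[seq(1L, length(lines), by = 4L)] <- paste0("@", reads$id)
  lines[seq(2L, length(lines), by = 4L)] <- reads$seq
  lines[seq(3L, length(lines), by = 4L)] <- "+"
  lines[seq(4L, length(lines), by = 4L)] <- reads$qual
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file into a data.frame
#'
#' @param path FASTQ path.
#' @return data.frame with `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(
    id = names(x),
    seq = as.character(x),
    qual = as.character(S4Vectors::mcols(x)$qualities),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Simulate a cell population with correlated plasmid and genomic editing
#'
#' Hierarchical Bernoulli model per cell: transfection (probability
#' `p_transfect`); for transfected cells, plasmid (reporter) editing with
#' probability `p_plasmid_edit_given_transfect`; genomic editing with
#' probability `p_genomic_given_plasmid_edit` when the plasmid was edited,
#' `p_genomic_given_transfect_only` when transfected without plasmid
#' editing, and `p_genomic_given_untransfect` otherwise.
#' `p_genomic_given_plasmid_edit >= p_genomic_given_transfect_only` encodes
#' the surrogate-enrichment hypothesis that cells editing the reporter are
#' more likely to edit the genome. Observed fluorescence flags (`bfp` for
#' transfection, `gfp` for plasmid editing; `reporter_signal` mirrors
#' `gfp`) are the latent states flipped with false-positive/false-negative
#' rates `fp_rate`/`fn_rate`.
#'
#' @param n_cells number of cells.
#' @param p_transfect,p_plasmid_edit_given_transfect,p_genomic_given_plasmid_edit,p_genomic_given_transfect_only,p_genomic_given_untransfect
#'   model probabilities.
#' @param fp_rate,fn_rate fluorescence detection error probabilities.
#' @param seed integer seed.
#' @return data.frame with logical columns `transfected`, `plasmid_edited`,
#'   `genomic_edited`, `bfp`, `gfp`, `reporter_signal`.
#' @export
simulate_population <- function(n_cells,
                                p_transfect,
                                p_plasmid_edit_given_transfect,
                                p_genomic_given_plasmid_edit,
                                p_genomic_given_transfect_only,
                                p_genomic_given_untransfect = 0,
                                fp_rate = 0, fn_rate = 0, seed = 1L) {
  for (nm in c("p_transfect", "p_plasmid_edit_given_transfect",
               "p_genomic_given_plasmid_edit", "p_genomic_given_transfect_only",
               "p_genomic_given_untransfect", "fp_rate", "fn_rate")) {
    assert_probability(get(nm), nm)
  }
  if (p_genomic_given_plasmid_edit < p_genomic_given_transfect_only) {
    warning("p_genomic_given_plasmid_edit < p_genomic_given_transfect_only: ",
            "population contradicts the surrogate-enrichment hypothesis",
            call. = FALSE)
  }
  with_seed(seed, {
    transfected <- stats::runif(n_cells) < p_transfect
    plasmid_edited <- transfected &
      (stats::runif(n_cells) < p_plasmid_edit_given_transfect)
    p_gen <- ifelse(plasmid_edited, p_genomic_given_plasmid_edit,
             ifelse(transfected, p_genomic_given_transfect_only,
                    p_genomic_given_untransfect))
    genomic_edited <- stats::runif(n_cells) < p_gen
    flip <- function(truth) {
      u <- stats::runif(n_cells)
      ifelse(truth, u >= fn_rate, u < fp_rate)
    }
    bfp <- flip(transfected)
    gfp <- flip(plasmid_edited)
    data.frame(transfected = transfected, plasmid_edited = plasmid_edited,
               genomic_edited = genomic_edited,
               bfp = bfp, gfp = gfp, reporter_signal = gfp)
  })
}
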