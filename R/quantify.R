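#' Specificity of editing (intended% over byproduct indel%)
#'
#' Specificity is the intended-editing percentage divided by the byproduct
#' indel percentage. Indel percentages at or below the NGS detection floor
#' are replaced by the floor (default 0.05%) so that near-zero indel rates
#' do not produce spuriously high specificity values.
#'
#' @param editing_pct intended editing percentage(s), on \[0, 100\].
#' @param indel_pct byproduct indel percentage(s), on \[0, 100\].
#' @param floor detection floor applied to the denominator, in percent.
#' @return specificity ratio(s).
#' @export
specificity <- function(editing_pct, indel_pct, floor = 0.05) {
  if (any(editing_pct < 0) || any(indel_pct < 0)) {
    stop("percentages must be non-negative", call. = FALSE)
  }
  editing_pct / pmax(indel_pct, floor)
}

#' Summarise read classifications into per-sample editing statistics
#'
#' Computes read counts per class and the sample-level editing percentage,
#' byproduct indel percentage, and specificity. All reads — including
#' anchor-filtered ones — stay in the denominator by default, matching the
#' convention that frequencies are per total sequenced read; set
#' `denominator = "passing"` to exclude filtered reads.
#'
#' @param labels character vector of per-read labels (`filtered`,
#'   `intended`, `indel_byproduct`, `unedited`), or a data.frame from
#'   [classify_reads()] with a `label` column.
#' @param floor specificity detection floor in percent (default 0.05).
#' @param denominator `"all"` (default) or `"passing"`.
#' @return one-row data.frame with `n_total`, `n_intended`, `n_indel`,
#'   `n_unedited`, `n_filtered`, `editing_pct`, `indel_pct`, `specificity`.
#' @export
quantify_sample <- function(labels, floor = 0.05, denominator = c("all", "passing")) {
  denominator <- match.arg(denominator)
  if (is.data.frame(labels)) labels <- labels$label
  if (length(labels) == 0L) stop("no reads", call. = FALSE)
  bad <- setdiff(unique(labels),
                 c("filtered", "intended", "indel_byproduct", "unedited"))
  if (length(bad) > 0L) {
    stop("unknown read labels: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  n_total <- length(labels)
  n_intended <- sum(labels == "intended")
  n_indel <- sum(labels == "indel_byproduct")
  n_unedited <- sum(labels == "unedited")
  n_filtered <- sum(labels == "filtered")
  if (n_filtered == n_total) warning("all reads filtered", call. = FALSE)
  denom <- if (denominator == "all") n_total else n_total - n_filtered
  if (denom == 0L) {
    editing_pct <- 0
    indel_pct <- 0
  } else {
    editing_pct <- 100 * n_intended / denom
    indel_pct <- 100 * n_indel / denom
  }
  data.frame(
    n_total = n_total, n_intended = n_intended, n_indel = n_indel,
    n_unedited = n_unedited, n_filtered = n_filtered,
    editing_pct = editing_pct, indel_pct = indel_pct,
    specificity = specificity(editing_pct, indel_pct, floor = floor)
  )
}

#' Write a per-sample quantification table
#'
#' Percentages are rounded to two decimals in the TSV; the returned and
#' in-memory values keep full precision.
#'
#' @param quant data.frame of [quantify_sample()] rows.
#' @param path output TSV path.
#' @export
write_quant_tsv <- function(quant, path) {
  out <- quant
  for (col in c("editing_pct", "indel_pct", "specificity")) {
    out[[col]] <- round(out[[col]], 2)
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
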