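#' Genomic editing rates under the three enrichment gates
#'
#' Computes the genomic editing percentage in three sorting gates over a
#' cell population: `none` (all cells, no enrichment), `transfection`
#' (BFP-positive cells, regardless of GFP), and `pear` (GFP-positive
#' reporter-edited cells, regardless of BFP). Gating uses the observed
#' fluorescence flags — what a sorter can see — not the latent states.
#' Fold changes are relative to the unenriched gate.
#'
#' @param cells data.frame from [simulate_population()] (or any table with
#'   logical `bfp`, `gfp`, `genomic_edited` columns).
#' @return data.frame with one row per gate: `gate`, `n_cells`,
#'   `editing_pct`, `fold_vs_none`.
#' @export
gated_editing_rates <- function(cells) {
  stopifnot(is.data.frame(cells),
            all(c("bfp", "gfp", "genomic_edited") %in% names(cells)))
  if (nrow(cells) == 0L) stop("empty population", call. = FALSE)
  gates <- list(
    none = rep(TRUE, nrow(cells)),
    transfection = cells$bfp,
    pear = cells$gfp
  )
  rate <- function(sel) {
    n <- sum(sel)
    if (n == 0L) {
      warning("empty gate: editing undefined", call. = FALSE)
      return(c(n = 0, pct = NA_real_))
    }
    c(n = n, pct = 100 * mean(cells$genomic_edited[sel]))
  }
  res <- vapply(gates, rate, numeric(2))
  base_pct <- res["pct", "none"]
  data.frame(
    gate = names(gates),
    n_cells = as.integer(res["n", ]),
    editing_pct = res["pct", ],
    fold_vs_none = if (!is.na(base_pct) && base_pct > 0) {
      res["pct", ] / base_pct
    } else {
      rep(NA_real_, 3L)
    },
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Pearson product-moment correlation
#'
#' Standard Pearson correlation with explicit validation, used to compare
#' matched condition means (e.g. editing efficiency of the same pegRNA/nick
#' combinations on a plasmid reporter versus a chromosomal copy).
#'
#' @param x,y numeric vectors of equal length >= 3 with nonzero variance.
#' @return correlation coefficient in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("undefined correlation: zero variance", call. = FALSE)
  }
  stats::cor(x, y, method = "pearson")
}

#' Read matched plasmid/cell-line condition means
#'
#' Loads a two-column TSV of per-condition mean editing efficiencies
#' measured on the plasmid reporter and on the matched chromosomal target
#' (36 PBS x RT x nick conditions per target in the reference screens), as
#' exported from the screen's source-data tables.
#'
#' @param path TSV with numeric columns `plasmid` and `cell_line`.
#' @return data.frame with columns `plasmid`, `cell_line`.
#' @export
read_condition_means <- function(path) {
  if (!file.exists(path)) {
    stop("condition-means table not found: ", path, call. = FALSE)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("plasmid", "cell_line") %in% names(df))) {
    stop("expected columns 'plasmid' and 'cell_line'", call. = FALSE)
  }
  df
}
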