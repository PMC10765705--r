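# Variant filtering front end: routine class / frequency / deleteriousness
# filters producing the patient candidate gene set under a stated inheritance
# mode.

.effect_classes <- c("nonsense", "frameshift", "nonsynonymous", "splice_site",
                     "synonymous", "intronic", "UTR", "ncRNA", "other")
.zygosities <- c("hom", "het", "hemi")

#' Construct a variant table
#'
#' Validates and normalizes an annotated variant data frame. Required
#' columns: `gene`, `effect_class`, `zygosity`. Optional numeric columns (all
#' in `[0, 1]`, `NA` = annotation missing): `freq_gnomad`, `freq_popmax`,
#' `freq_inhouse`, `dbscsnv_rf`, `dbscsnv_ada`, `spliceai`,
#' `polyphen2_hdiv`, `revel`, `sift`. Missing optional columns are added as
#' all-`NA`.
#'
#' @param df A data frame of annotated variants.
#' @param column_map Optional named character vector mapping this package's
#'   column names to the input's column names (e.g.
#'   `c(gene = "Gene.refGene", freq_gnomad = "gnomAD_exome_ALL")`).
#' @return A validated data frame of class `variant_table`.
#' @export
variant_table <- function(df, column_map = NULL) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (ours in names(column_map)) {
      theirs <- column_map[[ours]]
      if (!theirs %in% names(df)) stop("column-map source column not found: ", theirs)
      df[[ours]] <- df[[theirs]]
    }
  }
  req <- c("gene", "effect_class", "zygosity")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("missing required column(s): ", paste(miss, collapse = ", "))
  if (any(!nzchar(df$gene) | is.na(df$gene))) stop("empty gene identifiers")
  df$effect_class <- as.character(df$effect_class)
  bad <- setdiff(unique(df$effect_class), .effect_classes)
  if (length(bad)) stop("unknown effect class(es): ", paste(bad, collapse = ", "))
  df$zygosity <- as.character(df$zygosity)
  bad <- setdiff(unique(df$zygosity), .zygosities)
  if (length(bad)) stop("unknown zygosity value(s): ", paste(bad, collapse = ", "))
  score_cols <- c("freq_gnomad", "freq_popmax", "freq_inhouse", "dbscsnv_rf",
                  "dbscsnv_ada", "spliceai", "polyphen2_hdiv", "revel", "sift")
  for (sc in score_cols) {
    if (!sc %in% names(df)) df[[sc]] <- rep(NA_real_, nrow(df))
    df[[sc]] <- suppressWarnings(as.numeric(df[[sc]]))
    v <- df[[sc]]
    if (any(v < 0 | v > 1, na.rm = TRUE)) stop("scores in column ", sc, " outside [0, 1]")
  }
  df <- df[c(req, score_cols, setdiff(names(df), c(req, score_cols)))]
  class(df) <- c("variant_table", "data.frame")
  df
}

#' Read an annotated variant TSV
#'
#' @param path Tab-separated file with a header row.
#' @inheritParams variant_table
#' @return A `variant_table`.
#' @export
read_variants <- function(path, column_map = NULL) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = c("NA", ".", ""))
  variant_table(df, column_map = column_map)
}

.any_splicing_hit <- function(v, cutoff = 0.5) {
  s <- cbind(v$dbscsnv_rf, v$dbscsnv_ada, v$spliceai)
  apply(s >= cutoff, 1, function(r) isTRUE(any(r)))
}

#' Variant-class filter
#'
#' Keeps nonsense, frameshift, nonsynonymous and splice-site variants;
#' intronic, UTR and ncRNA variants are excluded. Synonymous variants are
#' rescued only when a splicing predictor (dbscSNV RF/ADA or SpliceAI) calls
#' them splice-affecting at >= 0.5.
#'
#' @param v A `variant_table`.
#' @return Logical vector, one value per variant row.
#' @export
passes_class_filter <- function(v) {
  stopifnot(inherits(v, "variant_table"))
  keep_class <- v$effect_class %in% c("nonsense", "frameshift", "nonsynonymous", "splice_site")
  keep_class | (v$effect_class == "synonymous" & .any_splicing_hit(v))
}

#' Population-frequency filter
#'
#' Recessive mode keeps variants with all present frequency annotations
#' (gnomAD, AF_popmax, in-house) `<= 0.02`; dominant mode requires `< 0.001`.
#' A missing frequency passes (novel variant).
#'
#' @param v A `variant_table`.
#' @param mode `"recessive"` or `"dominant"`.
#' @return Logical vector per row.
#' @export
passes_frequency <- function(v, mode = c("recessive", "dominant")) {
  stopifnot(inherits(v, "variant_table"))
  mode <- match.arg(mode)
  f <- cbind(v$freq_gnomad, v$freq_popmax, v$freq_inhouse)
  ok <- if (mode == "recessive") f <= 0.02 else f < 0.001
  apply(ok, 1, function(r) all(r, na.rm = TRUE))
}

#' Deleteriousness filter
#'
#' Truncating variants (nonsense, frameshift) pass unconditionally.
#' Splice-site and synonymous variants pass when any splicing predictor is
#' >= 0.5. Nonsynonymous variants pass when `polyphen2_hdiv >= 0.5` or
#' `revel >= 0.5` or `sift <= sift_cutoff`; with all three predictors missing
#' the variant passes (it cannot be affirmatively predicted benign).
#'
#' @param v A `variant_table`.
#' @param sift_cutoff SIFT "deleterious at or below" cutoff; default 0.5 as
#'   in the routine filter table (the conventional 0.05 can be supplied
#'   instead).
#' @return Logical vector per row.
#' @export
passes_deleteriousness <- function(v, sift_cutoff = 0.5) {
  stopifnot(inherits(v, "variant_table"))
  out <- logical(nrow(v))
  trunc <- v$effect_class %in% c("nonsense", "frameshift")
  out[trunc] <- TRUE
  spl <- v$effect_class %in% c("splice_site", "synonymous")
  out[spl] <- .any_splicing_hit(v)[spl]
  nsyn <- v$effect_class == "nonsynonymous"
  pp <- v$polyphen2_hdiv >= 0.5
  rv <- v$revel >= 0.5
  sf <- v$sift <= sift_cutoff
  pred <- cbind(pp, rv, sf)
  hit <- apply(pred, 1, function(r) isTRUE(any(r)))
  none_scored <- apply(pred, 1, function(r) all(is.na(r)))
  out[nsyn] <- (hit | none_scored)[nsyn]
  out
}

#' Filter a variant table into the patient candidate gene set
#'
#' Applies the class, frequency and deleteriousness filters, then collects
#' genes compatible with the inheritance mode: under the recessive mode a
#' gene qualifies via a passing homozygous/hemizygous variant or via at least
#' two distinct passing heterozygous variants (unphased compound-het proxy);
#' under the dominant mode any passing variant qualifies.
#'
#' @param v A `variant_table`.
#' @param mode `"recessive"` or `"dominant"`.
#' @param sift_cutoff Passed to [passes_deleteriousness()].
#' @return An object of class `candidate_gene_set`: list with `mode`, `genes`
#'   (sorted character vector), `supporting` (named list gene -> passing
#'   variant rows), and `report` (row counts after each filter stage).
#' @export
filter_variants <- function(v, mode = c("recessive", "dominant"), sift_cutoff = 0.5) {
  stopifnot(inherits(v, "variant_table"))
  mode <- match.arg(mode)
  if (!nrow(v)) {
    warning("empty variant table; no candidate genes")
    return(structure(list(mode = mode, genes = character(0),
                          supporting = list(),
                          report = c(input = 0L, class = 0L, frequency = 0L,
                                     deleteriousness = 0L, genes = 0L)),
                     class = "candidate_gene_set"))
  }
  p1 <- passes_class_filter(v)
  p2 <- p1 & passes_frequency(v, mode)
  p3 <- p2 & passes_deleteriousness(v, sift_cutoff)
  kept <- v[p3, , drop = FALSE]
  genes <- character(0)
  if (nrow(kept)) {
    if (mode == "recessive") {
      by_gene <- split(kept$zygosity, kept$gene)
      ok <- vapply(by_gene, function(z) any(z %in% c("hom", "hemi")) || sum(z == "het") >= 2, TRUE)
      genes <- names(by_gene)[ok]
    } else {
      genes <- unique(kept$gene)
    }
  }
  genes <- sort(genes)
  supporting <- lapply(stats::setNames(genes, genes),
                       function(g) kept[kept$gene == g, , drop = FALSE])
  structure(list(mode = mode, genes = genes, supporting = supporting,
                 report = c(input = nrow(v), class = sum(p1), frequency = sum(p2),
                            deleteriousness = sum(p3), genes = length(genes))),
            class = "candidate_gene_set")
}

#' @export
print.candidate_gene_set <- function(x, ...) {
  cat("<candidate_gene_set> mode ", x$mode, ": ", length(x$genes),
      " gene(s) from ", x$report[["input"]], " variants\n", sep = "")
  invisible(x)
}
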