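# Normalized phylogenetic profiling (NPP): conservation matrices, clade maps,
# and per-clade retrieval of co-evolved genes.

#' Construct a bitscore table
#'
#' Holds raw best-BLAST-hit bitscores of every gene against every species,
#' together with each query protein's self-alignment bitscore. This is the raw
#' input from which a normalized conservation matrix is built.
#'
#' @param best_hit Numeric matrix, genes x species, of best-hit bitscores.
#'   `NA` encodes "no hit found in that species". Must have row and column
#'   names (gene and species identifiers).
#' @param self_hit Named numeric vector of per-gene self-hit bitscores; names
#'   must match `rownames(best_hit)`.
#' @return An object of class `bitscore_table`.
#' @export
bitscore_table <- function(best_hit, self_hit) {
  if (!is.matrix(best_hit) || !is.numeric(best_hit))
    stop("`best_hit` must be a numeric matrix")
  if (is.null(rownames(best_hit)) || is.null(colnames(best_hit)))
    stop("`best_hit` must have gene rownames and species colnames")
  if (anyDuplicated(rownames(best_hit)) || anyDuplicated(colnames(best_hit)))
    stop("duplicated gene or species identifiers")
  if (is.null(names(self_hit))) stop("`self_hit` must be a named vector")
  missing_self <- setdiff(rownames(best_hit), names(self_hit))
  if (length(missing_self))
    stop("self-hit bitscores missing for: ", paste(missing_self, collapse = ", "))
  self_hit <- self_hit[rownames(best_hit)]
  if (any(!is.finite(self_hit)) || any(self_hit <= 0))
    stop("all self-hit bitscores must be positive and finite")
  if (any(best_hit < 0, na.rm = TRUE))
    stop("best-hit bitscores must be non-negative")
  structure(
    list(genes = rownames(best_hit), species = colnames(best_hit),
         best_hit = best_hit, self_hit = self_hit),
    class = "bitscore_table")
}

#' @export
print.bitscore_table <- function(x, ...) {
  cat("<bitscore_table> ", length(x$genes), " genes x ", length(x$species),
      " species; ", sum(is.na(x$best_hit)), " missing hits\n", sep = "")
  invisible(x)
}

#' Normalize a bitscore table into a conservation matrix
#'
#' Each observed best-hit bitscore is divided by the query's self-hit bitscore
#' (a ratio in (0, 1], clipped at 1 when a cross-species hit outscores the
#' self-hit), log2-transformed, and finally z-scored within each species
#' column so that lineage-specific bitscore scales do not dominate the
#' correlation structure. Missing hits (no ortholog detected) are imputed on
#' the log2 scale *before* z-scoring.
#'
#' @param raw A [bitscore_table()].
#' @param missing_policy How to impute a gene absent from a species, on the
#'   log2-ratio scale: `"floor_epsilon"` (default) uses the column minimum
#'   minus 1, keeping absent genes strictly least-conserved; `"column_min"`
#'   uses the column minimum itself.
#' @return An object of class `conservation_matrix` with elements `values`
#'   (genes x species z-score matrix), `presence` (logical matrix, TRUE where
#'   a best hit was observed), `genes`, `species`, and `meta` (normalization
#'   provenance: policy, sd convention, number of clipped ratios).
#' @details Z-scoring uses the sample standard deviation (n - 1 denominator),
#'   recorded in `meta$sd`. A species column that is constant after imputation
#'   has no usable signal and raises an error naming the column.
#' @export
normalize_bitscores <- function(raw, missing_policy = c("floor_epsilon", "column_min")) {
  stopifnot(inherits(raw, "bitscore_table"))
  missing_policy <- match.arg(missing_policy)
  ratio <- raw$best_hit / raw$self_hit
  n_clipped <- sum(ratio > 1, na.rm = TRUE)
  ratio[ratio > 1] <- 1
  if (any(ratio <= 0, na.rm = TRUE))
    stop("zero bitscores cannot be log-transformed; encode absent hits as NA")
  v <- log2(ratio)
  presence <- !is.na(v)
  if (any(colSums(presence) == 0))
    stop("species with no observed hits at all: ",
         paste(colnames(v)[colSums(presence) == 0], collapse = ", "))
  col_min <- apply(v, 2, min, na.rm = TRUE)
  fill <- if (missing_policy == "floor_epsilon") col_min - 1 else col_min
  idx <- which(!presence, arr.ind = TRUE)
  if (nrow(idx)) v[idx] <- fill[idx[, 2]]
  mu <- colMeans(v)
  sdev <- apply(v, 2, stats::sd)
  degenerate <- sdev == 0 | !is.finite(sdev)
  if (any(degenerate))
    stop("species column(s) with zero variance after imputation: ",
         paste(colnames(v)[degenerate], collapse = ", "))
  z <- sweep(sweep(v, 2, mu, "-"), 2, sdev, "/")
  structure(
    list(values = z, presence = presence, genes = raw$genes, species = raw$species,
         meta = list(missing_policy = missing_policy, sd = "sample (n-1)",
                     n_clipped = n_clipped)),
    class = "conservation_matrix")
}

#' Wrap an already-normalized matrix as a conservation matrix
#'
#' For workflows starting from a pre-normalized profile matrix rather than raw
#' bitscores. Presence defaults to "everywhere observed" unless given.
#'
#' @param values Numeric genes x species matrix of normalized scores.
#' @param presence Optional logical matrix of the same shape.
#' @return A `conservation_matrix`.
#' @export
conservation_matrix <- function(values, presence = NULL) {
  if (!is.matrix(values) || is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must be a matrix with gene rownames and species colnames")
  if (is.null(presence)) {
    presence <- !is.na(values)
  } else {
    stopifnot(is.logical(presence), all(dim(presence) == dim(values)))
  }
  structure(
    list(values = values, presence = presence, genes = rownames(values),
         species = colnames(values),
         meta = list(missing_policy = "pre-normalized", sd = "unknown",
                     n_clipped = NA_integer_)),
    class = "conservation_matrix")
}

#' @export
print.conservation_matrix <- function(x, ...) {
  cat("<conservation_matrix> ", length(x$genes), " genes x ", length(x$species),
      " species (", x$meta$missing_policy, " imputation)\n", sep = "")
  invisible(x)
}

#' Construct a clade map
#'
#' Groups species into named clades. The special clade `"Eukaryota"` covers
#' every species and is added automatically (as the union of all listed
#' species) when absent. Clades may be nested; every clade must be a subset of
#' Eukaryota.
#'
#' @param clades Named list mapping clade name -> character vector of species.
#' @return An object of class `clade_map`.
#' @export
clade_map <- function(clades) {
  if (!is.list(clades) || is.null(names(clades)) || any(names(clades) == ""))
    stop("`clades` must be a named list of species vectors")
  clades <- lapply(clades, function(x) unique(as.character(x)))
  all_species <- unique(unlist(clades, use.names = FALSE))
  if (!"Eukaryota" %in% names(clades)) {
    clades <- c(clades, list(Eukaryota = all_species))
  } else {
    extra <- setdiff(all_species, clades$Eukaryota)
    if (length(extra))
      stop("species outside Eukaryota: ", paste(utils::head(extra, 5), collapse = ", "))
  }
  structure(list(clades = clades, species = clades$Eukaryota), class = "clade_map")
}

#' The 16 published clade names
#'
#' Reference clade names spanning the eukaryotic tree used for clade-wise
#' profiling; supplied for convenience when building custom clade maps.
#' @return Character vector of 16 clade names (Eukaryota not included).
#' @export
reference_clade_names <- function() {
  c("Chordata", "Ecdysozoa", "Platyhelminthes", "Alveolates", "Stramenopiles",
    "Fungi", "Viridiplantae", "Mammalia", "Archelosuria", "Arthropoda",
    "Nematoda", "Basidiomycota", "Ascomycota", "Fungi incertae sedis",
    "Liliopsida", "Eudicotyledons")
}

#' @export
print.clade_map <- function(x, ...) {
  cat("<clade_map> ", length(x$clades), " clades, ", length(x$species),
      " species\n", sep = "")
  invisible(x)
}

.check_gene <- function(matrix, gene) {
  if (!gene %in% matrix$genes) stop("unknown gene: ", gene)
}

.clade_species <- function(matrix, clade, cmap) {
  if (!clade %in% names(cmap$clades)) stop("unknown clade: ", clade)
  intersect(cmap$clades[[clade]], matrix$species)
}

#' Does a gene have an ortholog in a clade?
#'
#' A gene counts as present in a clade when a best hit was observed (before
#' imputation) in at least `min_species` of the clade's species.
#'
#' @param matrix A `conservation_matrix`.
#' @param gene Gene identifier.
#' @param clade Clade name.
#' @param clade_map A [clade_map()].
#' @param min_species Minimum number of clade species with an observed hit.
#'   Default `NULL` means `max(3, ceiling(0.10 * clade size))`: Pearson
#'   correlation needs at least 3 points and the 10% rule guards against
#'   clades supported by a stray single hit.
#' @return `TRUE` or `FALSE`.
#' @export
has_ortholog <- function(matrix, gene, clade, clade_map, min_species = NULL) {
  stopifnot(inherits(matrix, "conservation_matrix"))
  .check_gene(matrix, gene)
  sp <- .clade_species(matrix, clade, clade_map)
  if (is.null(min_species)) min_species <- max(3, ceiling(0.10 * length(sp)))
  if (min_species < 1) stop("`min_species` must be >= 1")
  sum(matrix$presence[gene, sp]) >= min_species
}

#' Top co-evolved genes of a query within one clade
#'
#' Pearson correlation between the query gene's normalized profile and every
#' other gene's profile, restricted to the clade's species columns (using the
#' full imputed matrix, so every pair is compared over the same fixed
#' columns). Returns the `k` highest-correlation partners ranked 1..k; ties in
#' r are broken lexicographically by gene identifier so results are identical
#' across platforms.
#'
#' @inheritParams has_ortholog
#' @param query Query gene identifier.
#' @param k Number of partners to return (default 50, the tuned cutoff).
#' @return Data frame with columns `gene`, `rank`, `r`.
#' @export
top_coevolved <- function(matrix, query, clade, clade_map, k = 50) {
  stopifnot(inherits(matrix, "conservation_matrix"), k >= 1)
  .check_gene(matrix, query)
  sp <- .clade_species(matrix, clade, clade_map)
  if (length(sp) < 3)
    stop("clade '", clade, "' has fewer than 3 species columns; Pearson correlation is degenerate")
  sub <- matrix$values[, sp, drop = FALSE]
  qv <- sub[query, ]
  if (stats::sd(qv) == 0)
    stop("query profile is constant within clade '", clade, "'")
  others <- setdiff(matrix$genes, query)
  r <- as.vector(stats::cor(qv, t(sub[others, , drop = FALSE])))
  names(r) <- others
  r <- r[!is.na(r)]  # partners constant within the clade carry no signal
  ord <- order(-r, names(r))
  top <- utils::head(ord, k)
  data.frame(gene = names(r)[top], rank = seq_along(top), r = unname(r[top]),
             stringsAsFactors = FALSE)
}

#' Clade-merged co-evolution profile of a query gene
#'
#' Runs [top_coevolved()] in every clade (including Eukaryota) where the query
#' passes the ortholog-presence criterion, then merges the per-clade partner
#' lists into a unique partner set, keeping for each partner its best (lowest)
#' rank and the clade achieving it. Rank ties across clades resolve to the
#' first clade in the clade map's order.
#'
#' @inheritParams top_coevolved
#' @param min_species Passed to [has_ortholog()].
#' @return An object of class `coevolution_result`: list with `query`,
#'   `per_clade` (named list of per-clade rank tables) and `merged` (data
#'   frame `gene`, `best_rank`, `clade`, `r`).
#' @export
coevolution_profile <- function(matrix, query, clade_map, k = 50, min_species = NULL) {
  .check_gene(matrix, query)
  per_clade <- list()
  for (cl in names(clade_map$clades)) {
    sp <- .clade_species(matrix, cl, clade_map)
    if (length(sp) < 3) next
    if (!has_ortholog(matrix, query, cl, clade_map, min_species)) next
    per_clade[[cl]] <- top_coevolved(matrix, query, cl, clade_map, k)
  }
  if (!length(per_clade)) stop("no clade coverage for gene ", query)
  long <- do.call(rbind, lapply(names(per_clade), function(cl)
    cbind(per_clade[[cl]], clade = cl, stringsAsFactors = FALSE)))
  long <- long[order(long$rank, match(long$clade, names(clade_map$clades))), ]
  merged <- long[!duplicated(long$gene), c("gene", "rank", "clade", "r")]
  names(merged)[2] <- "best_rank"
  merged <- merged[order(merged$best_rank, merged$gene), ]
  rownames(merged) <- NULL
  structure(list(query = query, per_clade = per_clade, merged = merged),
            class = "coevolution_result")
}

#' @export
print.coevolution_result <- function(x, ...) {
  cat("<coevolution_result> query ", x$query, ": ", nrow(x$merged),
      " unique partners across ", length(x$per_clade), " clade(s)\n", sep = "")
  invisible(x)
}
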