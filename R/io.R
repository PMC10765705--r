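# Tabular I/O for the pipeline's standard file dialects.

#' Read a conservation / bitscore matrix TSV
#'
#' Dialect: first column gene id, header row of species ids, tab-separated.
#' With `self_hits_path` given, the values are interpreted as raw best-hit
#' bitscores and a [bitscore_table()] is returned; otherwise the values are
#' taken as an already-normalized matrix and wrapped as a
#' [conservation_matrix()].
#'
#' @param path Matrix TSV path.
#' @param self_hits_path Optional two-column TSV (gene, self-hit bitscore).
#' @return A `bitscore_table` or `conservation_matrix`.
#' @export
read_matrix_tsv <- function(path, self_hits_path = NULL) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- as.character(df[[1]])
  if (is.null(self_hits_path)) return(conservation_matrix(m))
  sh <- utils::read.delim(self_hits_path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  bitscore_table(m, stats::setNames(as.numeric(sh[[2]]), as.character(sh[[1]])))
}

#' Write a conservation matrix (or bitscore matrix) to TSV
#'
#' @param x A `conservation_matrix`, `bitscore_table`, or plain matrix.
#' @param path Output path.
#' @param self_hits_path For a `bitscore_table`, where to write the companion
#'   self-hit TSV (default: `path` with a `.self.tsv` suffix).
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(x, path, self_hits_path = NULL) {
  m <- if (inherits(x, "conservation_matrix")) x$values
       else if (inherits(x, "bitscore_table")) x$best_hit
       else x
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (inherits(x, "bitscore_table")) {
    if (is.null(self_hits_path)) self_hits_path <- paste0(path, ".self.tsv")
    utils::write.table(
      data.frame(gene = names(x$self_hit), self_hit = unname(x$self_hit)),
      self_hits_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a clade map from a two-column TSV
#'
#' Dialect: `species <tab> clade`, header optional (auto-detected by a
#' "species" first header field); species may repeat across nested clades.
#'
#' @param path TSV path.
#' @return A [clade_map()].
#' @export
read_clade_map <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (tolower(df[1, 1]) == "species") df <- df[-1, , drop = FALSE]
  clade_map(split(as.character(df[[1]]), as.character(df[[2]])))
}

#' Write a clade map to a two-column TSV
#'
#' The synthetic Eukaryota superset row set is written too, so the file
#' round-trips through [read_clade_map()].
#'
#' @param cmap A `clade_map`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clade_map <- function(cmap, path) {
  df <- do.call(rbind, lapply(names(cmap$clades), function(cl)
    data.frame(species = cmap$clades[[cl]], clade = cl, stringsAsFactors = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a gene annotation TSV
#'
#' Dialect: `gene <tab> term_id` (HPOA-style extraction), one pair per line,
#' header auto-detected.
#'
#' @param path TSV path.
#' @return Named list: gene -> character vector of term ids.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (tolower(df[1, 1]) %in% c("gene", "gene_symbol")) df <- df[-1, , drop = FALSE]
  lapply(split(as.character(df[[2]]), as.character(df[[1]])), unique)
}

#' Write gene annotations to TSV
#' @param annotations Named list gene -> term ids.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  df <- do.call(rbind, lapply(names(annotations), function(g)
    data.frame(gene = g, term = annotations[[g]], stringsAsFactors = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Serialize a parsed ontology back to OBO
#'
#' Writes `[Term]` stanzas with `id`, `name` and `is_a` lines only; used by
#' the simulator to emit its random ontologies in the standard dialect.
#'
#' @param obo A [read_obo()]-shaped list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(obo, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("format-version: 1.2", con)
  for (t in obo$terms) {
    writeLines(c("", "[Term]", paste0("id: ", t),
                 paste0("name: ", if (!is.null(obo$name[t]) && !is.na(obo$name[t])) obo$name[t] else t),
                 if (length(obo$parents[[t]])) paste0("is_a: ", obo$parents[[t]])), con)
  }
  invisible(path)
}

#' Write a phenotype ranking to TSV
#' @param ranking A `phenotype_ranking`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ranking <- function(ranking, path) {
  utils::write.table(as.data.frame(ranking), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export a candidate's evidence subnetwork as a Cytoscape-loadable edge TSV
#'
#' One row per evidence edge from the candidate to a partner gene:
#' co-evolution edges are labeled with the clade achieving the partner's best
#' rank (weight = Pearson r), interaction edges with source `STRING`
#' (weight = combined score).
#'
#' @param coevo A `coevolution_result` for the candidate (or `NULL`).
#' @param network An `interaction_network` (or `NULL`).
#' @param gene The candidate gene id.
#' @param path Output path.
#' @param restrict_to Optional gene set (e.g. high-scoring phenotype-related
#'   genes); only edges to these partners are exported.
#' @return The edge data frame, invisibly; written to `path` when non-NULL.
#' @export
export_subnetwork <- function(coevo = NULL, network = NULL, gene, path = NULL,
                              restrict_to = NULL) {
  rows <- list()
  if (!is.null(coevo)) {
    m <- coevo$merged
    if (!is.null(restrict_to)) m <- m[m$gene %in% restrict_to, , drop = FALSE]
    if (nrow(m))
      rows$coevo <- data.frame(gene1 = gene, gene2 = m$gene, source = m$clade,
                               weight = m$r, stringsAsFactors = FALSE)
  }
  if (!is.null(network)) {
    e <- network$edges
    hit <- e$gene1 == gene | e$gene2 == gene
    e <- e[hit, , drop = FALSE]
    other <- ifelse(e$gene1 == gene, e$gene2, e$gene1)
    keep <- if (is.null(restrict_to)) rep(TRUE, nrow(e)) else other %in% restrict_to
    if (any(keep))
      rows$string <- data.frame(gene1 = gene, gene2 = other[keep],
                                source = "STRING", weight = e$score[keep],
                                stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene1 = character(0), gene2 = character(0),
               source = character(0), weight = numeric(0))
  rownames(out) <- NULL
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
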