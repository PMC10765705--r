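# STRING-style functional interaction networks: loading, thresholding and
# partner lookup.

#' Build an interaction network from an edge table
#'
#' @param edges Data frame with three columns: gene1, gene2 and a combined
#'   confidence score (any column names accepted; order matters). Scores on
#'   the STRING 0-1000 integer dialect are auto-detected (any score > 1) and
#'   divided by 1000. Self-edges are dropped; duplicate edges (in either
#'   orientation) collapse keeping the maximum score.
#' @param threshold Minimum combined score kept; default 0.5, the
#'   medium-confidence cutoff.
#' @param aliases Optional two-column data frame (protein/alias id, gene id)
#'   used to map edge endpoints; edges with an unmapped endpoint are dropped
#'   and counted in `meta$n_unmapped`.
#' @return An object of class `interaction_network`: list with `edges`
#'   (data frame `gene1`, `gene2`, `score`; `gene1 < gene2`), `threshold`,
#'   `meta`.
#' @export
interaction_network <- function(edges, threshold = 0.5, aliases = NULL) {
  if (threshold < 0 || threshold > 1) stop("`threshold` must be in [0, 1]")
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 3) stop("edge table needs 3 columns: gene1, gene2, score")
  df <- data.frame(gene1 = as.character(edges[[1]]),
                   gene2 = as.character(edges[[2]]),
                   score = suppressWarnings(as.numeric(edges[[3]])),
                   stringsAsFactors = FALSE)
  bad <- which(is.na(df$score) | !nzchar(df$gene1) | !nzchar(df$gene2))
  if (length(bad))
    stop("malformed edge row(s) at line(s): ", paste(utils::head(bad, 5), collapse = ", "))
  n_unmapped <- 0L
  if (!is.null(aliases)) {
    map <- stats::setNames(as.character(aliases[[2]]), as.character(aliases[[1]]))
    g1 <- unname(map[df$gene1]); g2 <- unname(map[df$gene2])
    keep <- !is.na(g1) & !is.na(g2)
    n_unmapped <- sum(!keep)
    df <- data.frame(gene1 = g1[keep], gene2 = g2[keep], score = df$score[keep],
                     stringsAsFactors = FALSE)
  }
  if (nrow(df) && any(df$score > 1)) df$score <- df$score / 1000
  if (any(df$score < 0 | df$score > 1)) stop("scores outside [0, 1] after normalization")
  df <- df[df$gene1 != df$gene2, , drop = FALSE]
  swap <- df$gene1 > df$gene2
  tmp <- df$gene1[swap]; df$gene1[swap] <- df$gene2[swap]; df$gene2[swap] <- tmp
  if (nrow(df)) {
    key <- paste(df$gene1, df$gene2, sep = "\r")
    df <- df[order(key, -df$score), ]
    df <- df[!duplicated(paste(df$gene1, df$gene2, sep = "\r")), ]
  }
  df <- df[df$score >= threshold, , drop = FALSE]
  rownames(df) <- NULL
  structure(list(edges = df, threshold = threshold,
                 meta = list(n_unmapped = n_unmapped)),
            class = "interaction_network")
}

#' Load an interaction network from a TSV file
#'
#' Accepts the STRING links dialect (`protein1 protein2 combined_score`,
#' whitespace- or tab-separated) or any generic three-column edge file with a
#' header row.
#'
#' @param path Path to the edge file.
#' @inheritParams interaction_network
#' @param alias_path Optional path to a two-column alias TSV.
#' @return An `interaction_network`.
#' @export
load_network <- function(path, threshold = 0.5, alias_path = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "", stringsAsFactors = FALSE,
                          comment.char = "")
  aliases <- if (!is.null(alias_path))
    utils::read.table(alias_path, header = FALSE, sep = "\t", stringsAsFactors = FALSE)
  interaction_network(df, threshold = threshold, aliases = aliases)
}

#' Interaction partners of a gene
#'
#' @param network An `interaction_network`.
#' @param gene Gene identifier.
#' @return Character vector of neighbors (empty when the gene is absent).
#' @export
partners <- function(network, gene) {
  stopifnot(inherits(network, "interaction_network"))
  e <- network$edges
  sort(unique(c(e$gene2[e$gene1 == gene], e$gene1[e$gene2 == gene])))
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("<interaction_network> ", nrow(x$edges), " edges at threshold ",
      x$threshold, "\n", sep = "")
  invisible(x)
}
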