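# Phenotype semantic similarity: OBO ontology handling, annotation-frequency
# information content, Lin similarity with best-match-average set scoring, and
# ranking of the annotated gene universe against a patient's HPO term set.

#' Parse an OBO ontology file
#'
#' Minimal reader for OBO 1.2/1.4 `[Term]` stanzas. Only `is_a` edges define
#' the DAG; other relationship types are counted and ignored. Obsolete terms
#' are dropped; their ids and all `alt_id`s are kept in an alias table so
#' annotations using them can be resolved to primary ids.
#'
#' @param path Path to an `.obo` file.
#' @return List with `terms` (character vector of primary ids), `parents`
#'   (named list: term -> character vector of is_a parents), `alt`
#'   (named character vector alias -> primary id), `name` (term names),
#'   `n_ignored_relations` (count of non-is_a relationship lines).
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  starts <- grep("^\\[", lines)
  if (!length(starts)) stop("no stanzas found in ", path)
  terms <- character(); parents <- list(); alt <- character()
  nm <- character(); n_rel <- 0L
  ends <- c(starts[-1] - 1L, length(lines))
  for (i in seq_along(starts)) {
    if (lines[starts[i]] != "[Term]") next
    block <- lines[(starts[i] + 1L):ends[i]]
    block <- block[nzchar(block)]
    get <- function(key) {
      v <- sub(paste0("^", key, ":\\s*"), "", grep(paste0("^", key, ":"), block, value = TRUE))
      sub("\\s*!.*$", "", v)  # strip trailing comments
    }
    id <- get("id")
    if (!length(id)) next
    id <- id[1]
    if (any(grepl("^is_obsolete:\\s*true", block))) {
      rep_to <- get("replaced_by")
      if (length(rep_to)) alt[id] <- rep_to[1]
      next
    }
    isa <- vapply(get("is_a"), function(v) sub("\\s.*$", "", v), "", USE.NAMES = FALSE)
    n_rel <- n_rel + length(grep("^relationship:", block))
    terms <- c(terms, id)
    parents[[id]] <- unique(isa)
    for (a in get("alt_id")) alt[a] <- id
    title <- get("name")
    nm[id] <- if (length(title)) title[1] else id
  }
  alt[terms] <- terms  # primary ids resolve to themselves
  list(terms = terms, parents = parents, alt = alt, name = nm,
       n_ignored_relations = n_rel)
}

# Topological order (parents before children); errors on cycles.
.topo_order <- function(terms, parents) {
  indeg <- vapply(terms, function(t) length(intersect(parents[[t]], terms)), 0L)
  children <- list()
  for (t in terms) for (p in intersect(parents[[t]], terms))
    children[[p]] <- c(children[[p]], t)
  queue <- terms[indeg == 0L]
  out <- character(0)
  while (length(queue)) {
    t <- queue[1]; queue <- queue[-1]
    out <- c(out, t)
    for (ch in children[[t]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) != length(terms)) stop("cycle detected in ontology is_a graph")
  out
}

#' Build an ontology index with information content
#'
#' Computes, for every term, the annotation-frequency information content
#' `ic(t) = -ln(n_t / N)` where `n_t` is the number of genes annotated to `t`
#' or any of its descendants (annotations propagate to all ancestors) and `N`
#' is the total number of annotated genes. The root therefore has ic 0 and ic
#' grows monotonically towards the leaves.
#'
#' @param obo Result of [read_obo()] (or a list with the same shape).
#' @param annotations Named list: gene -> character vector of term ids
#'   (direct annotations). Alt/obsolete ids are resolved via the ontology's
#'   alias table; unresolvable ids are an error.
#' @param unannotated How to score terms annotating zero genes:
#'   `"max_ic"` (default) assigns the maximum observed ic, `"drop"` removes
#'   them from the index.
#' @return An object of class `ontology_index`: list with `terms`, `parents`,
#'   `ancestors` (named list, each including the term itself), `ic` (named
#'   numeric, nats), `root`, `annotations` (resolved), `genes`.
#' @export
build_ontology_index <- function(obo, annotations, unannotated = c("max_ic", "drop")) {
  unannotated <- match.arg(unannotated)
  if (!length(annotations)) stop("at least one annotated gene is required")
  if (any(!lengths(annotations))) stop("empty annotation sets are not allowed")
  terms <- obo$terms
  parents <- obo$parents
  roots <- terms[!vapply(terms, function(t) length(intersect(parents[[t]], terms)) > 0, TRUE)]
  if (length(roots) != 1L)
    stop("ontology must have exactly one root; found: ", paste(roots, collapse = ", "))
  ord <- .topo_order(terms, parents)
  ancestors <- list()
  for (t in ord) {
    ps <- intersect(parents[[t]], terms)
    ancestors[[t]] <- unique(c(t, unlist(ancestors[ps], use.names = FALSE)))
  }
  # resolve annotation ids to primary ids
  resolved <- lapply(annotations, function(ts) {
    prim <- unname(obo$alt[ts])
    bad <- ts[is.na(prim) | !(prim %in% terms)]
    if (length(bad))
      stop("annotation term(s) absent from ontology: ", paste(unique(bad), collapse = ", "))
    unique(prim)
  })
  n_genes <- length(resolved)
  counts <- stats::setNames(integer(length(terms)), terms)
  for (ts in resolved) {
    anc <- unique(unlist(ancestors[ts], use.names = FALSE))
    counts[anc] <- counts[anc] + 1L
  }
  ic <- ifelse(counts > 0, -log(counts / n_genes), NA_real_)
  names(ic) <- terms
  if (unannotated == "drop") {
    keep <- !is.na(ic)
    terms <- terms[keep]
    ic <- ic[keep]
    ancestors <- lapply(ancestors[terms], intersect, terms)
  } else {
    ic[is.na(ic)] <- max(ic, na.rm = TRUE)
  }
  structure(
    list(terms = terms, parents = parents, ancestors = ancestors, ic = ic,
         root = roots, annotations = resolved, genes = names(resolved)),
    class = "ontology_index")
}

#' @export
print.ontology_index <- function(x, ...) {
  cat("<ontology_index> ", length(x$terms), " terms, root ", x$root, ", ",
      length(x$genes), " annotated genes\n", sep = "")
  invisible(x)
}

#' Lin semantic similarity of two terms
#'
#' `lin(t1, t2) = 2 ic(MICA) / (ic(t1) + ic(t2))` where MICA is the common
#' ancestor with maximal information content. Returns 0 when the denominator
#' is 0 (both terms uninformative).
#'
#' @param t1,t2 Term ids present in the index.
#' @param index An [build_ontology_index()] result.
#' @return Similarity in `[0, 1]`.
#' @export
lin_similarity <- function(t1, t2, index) {
  for (t in c(t1, t2)) if (!t %in% index$terms) stop("term not in index: ", t)
  common <- intersect(index$ancestors[[t1]], index$ancestors[[t2]])
  mica_ic <- if (length(common)) max(index$ic[common]) else 0
  denom <- index$ic[[t1]] + index$ic[[t2]]
  if (denom == 0) return(0)
  unname(2 * mica_ic / denom)
}

# lin(t, u) for one fixed t against a vector of terms; used by the ranker.
.lin_row <- function(t, terms, index) {
  anc_t <- index$ancestors[[t]]
  ic_t <- index$ic[[t]]
  vapply(terms, function(u) {
    common <- intersect(anc_t, index$ancestors[[u]])
    denom <- ic_t + index$ic[[u]]
    if (denom == 0) return(0)
    mica <- if (length(common)) max(index$ic[common]) else 0
    2 * mica / denom
  }, 0)
}

#' Best-match-average similarity of two term sets
#'
#' Symmetric best-match-average: for each term in A take its best Lin match in
#' B, average; do the mirror direction; average the two means. Symmetric by
#' construction, 1 for identical informative sets.
#'
#' @param A,B Non-empty character vectors of term ids.
#' @param index An ontology index.
#' @return Similarity in `[0, 1]`.
#' @export
bma_similarity <- function(A, B, index) {
  if (!length(A) || !length(B)) stop("term sets must be non-empty")
  sim <- outer(seq_along(A), seq_along(B),
               Vectorize(function(i, j) lin_similarity(A[i], B[j], index)))
  (mean(apply(sim, 1, max)) + mean(apply(sim, 2, max))) / 2
}

#' Rank every annotated gene by phenotype similarity
#'
#' Scores each gene in the annotated universe by the best-match-average Lin
#' similarity between the query HPO term set and the gene's annotation set,
#' then orders genes by decreasing score (ties broken lexicographically by
#' gene id). This is the "HPO-ranked genes" list against which enrichment of
#' co-evolved and interacting genes is tested; no score threshold is applied.
#'
#' @param query Character vector of query term ids (the patient's HPO terms).
#' @param index An ontology index carrying gene annotations.
#' @param method `"lin_bma"` (default) or `"resnik_product"`, an alternative
#'   scorer multiplying the two directional normalized Resnik best-match
#'   averages; kept as an opt-in robustness check.
#' @return An object of class `phenotype_ranking`: data frame `gene`, `score`,
#'   `rank`, with the query stored in `attr(, "query")`.
#' @export
rank_genes_by_phenotype <- function(query, index,
                                    method = c("lin_bma", "resnik_product")) {
  method <- match.arg(method)
  query <- unique(query)
  missing_terms <- setdiff(query, index$terms)
  if (length(missing_terms))
    stop("query term(s) not in ontology: ", paste(missing_terms, collapse = ", "))
  all_terms <- unique(unlist(index$annotations, use.names = FALSE))
  if (method == "lin_bma") {
    lin_rows <- lapply(query, .lin_row, terms = all_terms, index = index)
    lin_mat <- do.call(rbind, lin_rows)            # |query| x |all_terms|
    colnames(lin_mat) <- all_terms
    scores <- vapply(index$annotations, function(ts) {
      sub <- lin_mat[, ts, drop = FALSE]
      (mean(apply(sub, 1, max)) + mean(apply(sub, 2, max))) / 2
    }, 0)
  } else {
    res_rows <- lapply(query, .resnik_row, terms = all_terms, index = index)
    res_mat <- do.call(rbind, res_rows)
    colnames(res_mat) <- all_terms
    max_ic <- max(index$ic)
    scores <- vapply(index$annotations, function(ts) {
      sub <- res_mat[, ts, drop = FALSE]
      a <- mean(apply(sub, 1, max)) / max_ic
      b <- mean(apply(sub, 2, max)) / max_ic
      a * b
    }, 0)
  }
  ord <- order(-scores, names(scores))
  out <- data.frame(gene = names(scores)[ord], score = unname(scores[ord]),
                    rank = seq_along(ord), stringsAsFactors = FALSE)
  attr(out, "query") <- query
  attr(out, "method") <- method
  class(out) <- c("phenotype_ranking", "data.frame")
  out
}

# Resnik similarity (ic of MICA) of one term against a vector of terms.
.resnik_row <- function(t, terms, index) {
  anc_t <- index$ancestors[[t]]
  vapply(terms, function(u) {
    common <- intersect(anc_t, index$ancestors[[u]])
    if (length(common)) max(index$ic[common]) else 0
  }, 0)
}
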