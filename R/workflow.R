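# Two-step workflow mirroring the interactive tool: step 1 ranks candidates
# by phenotype semantic similarity alone; step 2 adds the co-evolution and
# interaction enrichment prioritization.

#' Step 1: semantic-similarity ranking of the candidates
#'
#' Scores the patient's candidate genes by semantic similarity to the query
#' HPO terms and reports each candidate's score and rank within the full
#' annotated universe. Candidates outside the annotated universe are retained
#' with a `not in HPO universe` note (step 2 can still rank them through
#' co-evolution and interactions).
#'
#' @param query Character vector of query term ids.
#' @param candidates Character vector of candidate gene ids.
#' @param index An [build_ontology_index()] result.
#' @param method Passed to [rank_genes_by_phenotype()].
#' @return Data frame `gene`, `score`, `rank`, `note`, ordered by rank with
#'   unannotated candidates last.
#' @export
step1 <- function(query, candidates, index, method = "lin_bma") {
  ranking <- rank_genes_by_phenotype(query, index, method = method)
  hit <- match(candidates, ranking$gene)
  out <- data.frame(gene = candidates,
                    score = ranking$score[hit],
                    rank = ranking$rank[hit],
                    note = ifelse(is.na(hit), "not in HPO universe", ""),
                    stringsAsFactors = FALSE)
  out <- out[order(is.na(out$rank), out$rank, out$gene), ]
  rownames(out) <- NULL
  if (all(is.na(out$rank)))
    message("no candidate gene is annotated in the ontology; ",
            "use step 2 for co-evolution / interaction evidence")
  out
}

#' Step 2: co-evolution and interaction-based prioritization
#'
#' The full pipeline for one patient: clade-merged co-evolution retrieval and
#' network partner lookup per candidate, one-sided KS enrichment of each
#' channel against the phenotype ranking, p-value combination and final
#' candidate ordering. Optionally exports per-candidate evidence subnetworks.
#'
#' @param query Character vector of query term ids.
#' @param candidates Character vector of candidate gene ids.
#' @param index An ontology index (with annotations).
#' @param matrix A `conservation_matrix` (or `NULL` to skip the channel).
#' @param cmap A `clade_map` (required with `matrix`).
#' @param network An `interaction_network` (or `NULL` to skip the channel).
#' @param k Co-evolved partners per clade (default 50).
#' @param min_overlap,combine_method,p_floor Passed to [prioritize()].
#' @param subnetwork_dir If non-NULL, writes one edge TSV per candidate
#'   (via [export_subnetwork()]) into this directory.
#' @return List with `result` (an `enrichment_result`), `ranking` (the
#'   phenotype ranking), `coevo` (per-candidate `coevolution_result`s).
#' @export
step2 <- function(query, candidates, index, matrix = NULL, cmap = NULL,
                  network = NULL, k = 50, min_overlap = 3,
                  combine_method = "fisher", p_floor = 1e-300,
                  subnetwork_dir = NULL) {
  if (!length(candidates)) stop("no candidate genes supplied")
  if (!is.null(matrix) && is.null(cmap))
    stop("a clade map is required with a conservation matrix")
  ranking <- rank_genes_by_phenotype(query, index)
  profiles <- list()
  coevo <- list()
  if (!is.null(matrix)) {
    for (g in intersect(candidates, matrix$genes)) {
      prof <- tryCatch(coevolution_profile(matrix, g, cmap, k = k),
                       error = function(e) NULL)
      if (is.null(prof)) next
      profiles[[g]] <- prof
      coevo[[g]] <- prof$merged$gene
    }
  }
  netp <- list()
  if (!is.null(network)) {
    netp <- stats::setNames(lapply(candidates, partners, network = network),
                            candidates)
    netp <- netp[lengths(netp) > 0]
  }
  res <- prioritize(candidates, ranking, coevo, netp,
                    combine_method = combine_method,
                    min_overlap = min_overlap, p_floor = p_floor)
  if (!is.null(subnetwork_dir)) {
    dir.create(subnetwork_dir, showWarnings = FALSE, recursive = TRUE)
    for (g in candidates)
      export_subnetwork(profiles[[g]], network, g,
                        file.path(subnetwork_dir, paste0(g, "_subnetwork.tsv")))
  }
  list(result = res, ranking = ranking, coevo = profiles)
}
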