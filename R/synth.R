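# Synthetic data generators: conservation matrices with planted co-evolving
# modules, random ontologies with gene annotations, spike-in patients, and
# the benchmark harness that measures top-k recovery of the planted gene.

#' Build a synthetic clade map
#'
#' Partitions `n_species` species evenly into `n_clades` clades (names drawn
#' from [reference_clade_names()]), plus the all-species Eukaryota superset.
#'
#' @param n_species Number of species (default 120).
#' @param n_clades Number of disjoint clades (default 4).
#' @return A [clade_map()].
#' @export
synth_clade_map <- function(n_species = 120, n_clades = 4) {
  species <- sprintf("sp%03d", seq_len(n_species))
  nm <- utils::head(reference_clade_names(), n_clades)
  grp <- rep_len(seq_len(n_clades), n_species)
  clade_map(split(species, nm[grp]))
}

#' Generate a conservation matrix with planted co-evolving modules
#'
#' Background genes have i.i.d. standard-normal latent conservation values.
#' Each planted module shares a per-species latent factor inside its allowed
#' clades: a module gene's value is `sqrt(rho) * factor + sqrt(1-rho) *
#' noise`, giving expected pairwise Pearson correlation `rho` within the
#' module (exactly 1 at `rho = 1`). Latent values are mapped onto a raw
#' bitscore table (`best_hit = self_hit * 2^(value - 8)`, so log2 ratios stay
#' negative) which round-trips through [normalize_bitscores()].
#'
#' @param n_genes,n_species Matrix dimensions (defaults 500 x 120).
#' @param clade_map A [clade_map()]; default [synth_clade_map()] over
#'   `n_species`.
#' @param modules List of modules, each a list with `genes` (ids drawn from
#'   the generated `G0001...` namespace), `rho` in (0, 1], and optional
#'   `clades` (default: all clades, i.e. the module co-evolves everywhere).
#'   Module gene sets must be disjoint.
#' @param missing_rate Fraction of best hits set missing at random
#'   (default 0).
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return List with `bitscores` (a [bitscore_table()]), `matrix` (the
#'   normalized [conservation_matrix()]), and `clade_map`.
#' @export
gen_conservation_matrix <- function(n_genes = 500, n_species = 120,
                                    clade_map = NULL, modules = list(),
                                    missing_rate = 0, seed = 1) {
  if (is.null(clade_map)) clade_map <- synth_clade_map(n_species)
  if (length(clade_map$species) != n_species)
    stop("clade map covers ", length(clade_map$species), " species, not ", n_species)
  genes <- sprintf("G%04d", seq_len(n_genes))
  all_module_genes <- unlist(lapply(modules, `[[`, "genes"))
  if (anyDuplicated(all_module_genes)) stop("module gene sets must be disjoint")
  if (any(!all_module_genes %in% genes)) stop("module genes outside the gene namespace")
  species <- clade_map$species
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  v <- matrix(stats::rnorm(n_genes * n_species), n_genes, n_species,
              dimnames = list(genes, species))
  for (mod in modules) {
    rho <- mod$rho
    if (rho <= 0 || rho > 1) stop("module rho must be in (0, 1]")
    clades <- if (is.null(mod$clades)) setdiff(names(clade_map$clades), "Eukaryota")
              else mod$clades
    sp <- unique(unlist(clade_map$clades[clades]))
    factor_s <- stats::rnorm(length(sp))
    for (g in mod$genes)
      v[g, sp] <- sqrt(rho) * factor_s + sqrt(1 - rho) * stats::rnorm(length(sp))
  }
  self_hit <- stats::setNames(round(stats::runif(n_genes, 300, 800)), genes)
  best_hit <- self_hit * 2^(v - 8)
  if (missing_rate > 0) {
    drop <- matrix(stats::runif(n_genes * n_species) < missing_rate,
                   n_genes, n_species)
    # never blank out a whole species column
    full_cols <- colSums(!drop) == 0
    drop[1, full_cols] <- FALSE
    best_hit[drop] <- NA_real_
  }
  bt <- bitscore_table(best_hit, self_hit)
  list(bitscores = bt, matrix = normalize_bitscores(bt), clade_map = clade_map)
}

# Save/restore the global RNG state so generators do not disturb callers.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a random ontology DAG with gene annotations
#'
#' Builds a rooted DAG in levels (each term picks 1-2 parents from the level
#' above) and annotates genes with randomly chosen terms, weighted towards
#' deeper levels so the resulting information contents span 0 (root) up to
#' `ln(n_genes)`. One leaf is always annotated to exactly one gene, pinning
#' the maximum achievable IC.
#'
#' @param n_terms Total number of terms including the root (default 60).
#' @param depth Number of levels below the root (default 4).
#' @param n_genes Number of genes to annotate.
#' @param terms_per_gene Range of direct annotations per gene (default 2:4).
#' @param seed Integer seed.
#' @return List with `obo` (a [read_obo()]-shaped ontology) and
#'   `annotations` (named list gene -> term ids).
#' @export
gen_ontology_and_annotations <- function(n_terms = 60, depth = 4, n_genes = 100,
                                         terms_per_gene = 2:4, seed = 1) {
  stopifnot(n_terms >= depth + 1, n_genes >= 2)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ids <- sprintf("T:%04d", seq_len(n_terms))
  root <- ids[1]
  # split non-root terms across levels, growing with depth
  lv_sizes <- table(sort(c(seq_len(depth), sample(seq_len(depth), n_terms - 1 - depth,
                                                  replace = TRUE, prob = seq_len(depth)))))
  levels <- split(ids[-1], rep(seq_len(depth), lv_sizes))
  parents <- stats::setNames(vector("list", n_terms), ids)
  parents[[root]] <- character(0)
  prev <- root
  for (d in seq_len(depth)) {
    for (t in levels[[d]]) {
      n_par <- min(length(prev), 1 + stats::rbinom(1, 1, 0.3))
      parents[[t]] <- sample(prev, n_par)
    }
    prev <- levels[[d]]
  }
  genes <- sprintf("G%04d", seq_len(n_genes))
  pool <- ids[-1]
  w <- rep(seq_len(depth), lengths(levels))  # deeper terms drawn more often
  ann <- lapply(genes, function(g)
    sample(pool, sample(terms_per_gene, 1), prob = w))
  names(ann) <- genes
  # pin a max-IC leaf: deepest-level term annotated to exactly one gene
  leaf <- levels[[depth]][1]
  ann <- lapply(ann, setdiff, leaf)
  ann[[genes[1]]] <- unique(c(ann[[genes[1]]], leaf))
  ann <- lapply(ann, function(ts) if (length(ts)) ts else pool[1])
  obo <- list(terms = ids, parents = parents,
              alt = stats::setNames(ids, ids),
              name = stats::setNames(ids, ids), n_ignored_relations = 0L)
  list(obo = obo, annotations = ann)
}

#' Generate a spike-in scenario
#'
#' Assembles every input of a simulated patient: a conservation matrix with
#' one planted co-evolving module containing the causal gene, a random
#' ontology whose query terms annotate a tunable fraction of the module
#' partners, a random interaction network (identically distributed for causal
#' and decoy genes, so the network channel carries no planted signal), and an
#' annotated variant table in which the causal gene and `n_decoys` decoy
#' genes each carry one filter-surviving variant.
#'
#' @param seed Integer seed; drives every random choice.
#' @param n_genes,n_species,n_clades Matrix scale (defaults 500 x 120, 4
#'   clades plus Eukaryota).
#' @param module_size Planted module size including the causal gene
#'   (default 50, matching the top-50 co-evolution cutoff).
#' @param rho_within Within-module correlation (0 disables the module).
#' @param clade_restriction Clades where the module co-evolves (default all).
#' @param n_decoys Number of decoy candidate genes (default 20, for 21
#'   recessive candidates, inside the 11-80 range typical of a filtered
#'   exome).
#' @param annotation_overlap Fraction of module partners annotated with the
#'   query terms (default 0.8).
#' @param n_terms,ontology_depth Ontology scale (defaults 60 terms, depth 4).
#' @return A `synthetic_scenario` list: all generated inputs plus bookkeeping
#'   (`causal_gene`, `module_genes`, `decoy_genes`, `query`).
#' @export
gen_scenario <- function(seed, n_genes = 500, n_species = 120, n_clades = 4,
                         module_size = 50, rho_within = 0.9,
                         clade_restriction = NULL, n_decoys = 20,
                         annotation_overlap = 0.8, n_terms = 60,
                         ontology_depth = 4) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  genes <- sprintf("G%04d", seq_len(n_genes))
  module_genes <- sample(genes, module_size)
  causal <- module_genes[1]
  decoys <- sample(setdiff(genes, module_genes), n_decoys)
  modules <- if (rho_within > 0)
    list(list(genes = module_genes, rho = rho_within, clades = clade_restriction))
  else list()
  mat <- gen_conservation_matrix(n_genes, n_species, modules = modules,
                                 seed = seed + 1003L)
  onto <- gen_ontology_and_annotations(n_terms = n_terms, depth = ontology_depth,
                                       n_genes = n_genes, seed = seed + 2003L)
  # query = a small informative term set; overlap fraction of module partners
  # (never the causal gene itself: a novel disease gene has no annotations
  # matching the phenotype) is re-annotated with it
  deep_terms <- names(onto$obo$parents)[lengths(onto$obo$parents) > 0]
  query <- sample(utils::tail(deep_terms, ceiling(length(deep_terms) / 2)), 3)
  partnerset <- setdiff(module_genes, causal)
  n_overlap <- round(annotation_overlap * length(partnerset))
  if (n_overlap > 0) {
    chosen <- sample(partnerset, n_overlap)
    extra <- setdiff(deep_terms, query)
    for (g in chosen)
      onto$annotations[[g]] <- unique(c(query, sample(extra, 1)))
  }
  # random medium/high-confidence network, identically built for all genes
  n_edges <- 6L * (n_decoys + 1L)
  ends <- cbind(sample(genes, n_edges, replace = TRUE),
                sample(genes, n_edges, replace = TRUE))
  anchor <- rep(c(causal, decoys), length.out = n_edges %/% 2)
  ends[seq_along(anchor), 1] <- anchor
  net <- interaction_network(
    data.frame(g1 = ends[, 1], g2 = ends[, 2],
               score = stats::runif(n_edges, 0.5, 1)),
    threshold = 0.5)
  patient <- gen_patient(causal, decoys, genes, seed = seed + 3003L)
  structure(
    list(seed = seed, causal_gene = causal, module_genes = module_genes,
         decoy_genes = decoys, rho_within = rho_within,
         annotation_overlap = annotation_overlap, query = query,
         matrix = mat$matrix, bitscores = mat$bitscores,
         clade_map = mat$clade_map, obo = onto$obo,
         annotations = onto$annotations, network = net,
         variants = patient$variants, mode = patient$mode),
    class = "synthetic_scenario")
}

#' Generate a spike-in patient variant table
#'
#' Emits an annotated variant table containing one planted passing variant in
#' the causal gene (homozygous, novel, truncating), one passing variant per
#' decoy gene, and noise variants engineered to fail each filter stage
#' (common, intronic/UTR/ncRNA, and predicted-benign nonsynonymous), so the
#' recessive candidate set is exactly `{causal} + decoys`.
#'
#' @param causal_gene,decoy_genes,all_genes Gene ids; noise variants are
#'   placed on genes outside the candidate set.
#' @param seed Integer seed.
#' @param n_noise Number of filter-failing noise variants (default 60).
#' @return List with `variants` (a [variant_table()]) and `mode`
#'   (`"recessive"`).
#' @export
gen_patient <- function(causal_gene, decoy_genes, all_genes, seed = 1,
                        n_noise = 60) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  passing <- data.frame(
    gene = c(causal_gene, decoy_genes),
    effect_class = c("nonsense",
                     sample(c("nonsense", "frameshift", "nonsynonymous"),
                            length(decoy_genes), replace = TRUE)),
    zygosity = "hom",
    freq_gnomad = NA_real_, freq_popmax = NA_real_, freq_inhouse = NA_real_,
    polyphen2_hdiv = NA_real_, revel = NA_real_, sift = NA_real_,
    stringsAsFactors = FALSE)
  passing$revel[passing$effect_class == "nonsynonymous"] <- 0.9
  bg <- sample(setdiff(all_genes, passing$gene), n_noise, replace = TRUE)
  kind <- rep_len(c("common", "intronic", "benign"), n_noise)
  noise <- data.frame(
    gene = bg,
    effect_class = ifelse(kind == "intronic",
                          sample(c("intronic", "UTR", "ncRNA"), n_noise, replace = TRUE),
                          "nonsynonymous"),
    zygosity = sample(c("hom", "het"), n_noise, replace = TRUE),
    freq_gnomad = ifelse(kind == "common", stats::runif(n_noise, 0.05, 0.5), NA),
    freq_popmax = NA_real_, freq_inhouse = NA_real_,
    polyphen2_hdiv = ifelse(kind == "benign", stats::runif(n_noise, 0, 0.3), NA),
    revel = ifelse(kind == "benign", stats::runif(n_noise, 0, 0.3), NA),
    sift = ifelse(kind == "benign", stats::runif(n_noise, 0.7, 1), NA),
    stringsAsFactors = FALSE)
  tab <- rbind(passing, noise)
  tab <- tab[sample(nrow(tab)), ]
  rownames(tab) <- NULL
  list(variants = variant_table(tab), mode = "recessive")
}

#' Run the full prioritization pipeline on one scenario
#'
#' Variant filtering -> phenotype ranking -> per-candidate clade-merged
#' co-evolution retrieval and network partner lookup -> KS enrichment and
#' p-value combination.
#'
#' @param scenario A [gen_scenario()] result.
#' @param k Co-evolved partners kept per clade (default 50).
#' @param min_overlap Minimum channel overlap with the universe (default 3).
#' @param combine_method `"fisher"` or `"simes"`.
#' @return List with `result` (an `enrichment_result`), `candidates`, and
#'   `causal_rank`.
#' @export
run_scenario <- function(scenario, k = 50, min_overlap = 3,
                         combine_method = "fisher") {
  stopifnot(inherits(scenario, "synthetic_scenario"))
  cand <- filter_variants(scenario$variants, scenario$mode)$genes
  index <- build_ontology_index(scenario$obo, scenario$annotations)
  ranking <- rank_genes_by_phenotype(scenario$query, index)
  coevo <- list()
  for (g in cand) {
    if (!g %in% scenario$matrix$genes) next
    prof <- tryCatch(
      coevolution_profile(scenario$matrix, g, scenario$clade_map, k = k),
      error = function(e) NULL)
    if (!is.null(prof)) coevo[[g]] <- prof$merged$gene
  }
  netp <- stats::setNames(lapply(cand, partners, network = scenario$network), cand)
  netp <- netp[lengths(netp) > 0]
  res <- prioritize(cand, ranking, coevo, netp, combine_method = combine_method,
                    min_overlap = min_overlap)
  list(result = res, candidates = cand,
       causal_rank = res$rank[res$gene == scenario$causal_gene])
}

#' Spike-in benchmark over many scenarios
#'
#' Generates `n_scenarios` scenarios with consecutive seeds, runs the full
#' pipeline on each, and reports per-scenario causal-gene ranks plus top-k
#' recovery percentages.
#'
#' @param n_scenarios Number of scenarios.
#' @param base_seed First scenario seed; scenario i uses `base_seed + i - 1`.
#' @param scenario_args Named list of overrides passed to [gen_scenario()].
#' @param k,min_overlap,combine_method Passed to [run_scenario()].
#' @return An object of class `benchmark_result`: data frame with columns
#'   `seed`, `causal_rank`, `n_candidates`; the summary of
#'   [benchmark_summary()] is attached as `attr(, "summary")`.
#' @export
run_benchmark <- function(n_scenarios, base_seed = 1, scenario_args = list(),
                          k = 50, min_overlap = 3, combine_method = "fisher") {
  rows <- lapply(seq_len(n_scenarios), function(i) {
    sc <- do.call(gen_scenario, c(list(seed = base_seed + i - 1L), scenario_args))
    run <- run_scenario(sc, k = k, min_overlap = min_overlap,
                        combine_method = combine_method)
    data.frame(seed = sc$seed, causal_rank = run$causal_rank,
               n_candidates = length(run$candidates))
  })
  out <- do.call(rbind, rows)
  attr(out, "summary") <- benchmark_summary(out$causal_rank)
  class(out) <- c("benchmark_result", "data.frame")
  out
}

#' Top-k recovery percentages from causal-gene ranks
#'
#' @param ranks Integer vector of per-scenario causal ranks.
#' @param ks Cutoffs to report (default 1, 3, 5, 10).
#' @return Named numeric vector of percentages (e.g. `top1 = 75`).
#' @export
benchmark_summary <- function(ranks, ks = c(1, 3, 5, 10)) {
  stopifnot(length(ranks) > 0, !anyNA(ranks))
  stats::setNames(vapply(ks, function(k) 100 * mean(ranks <= k), 0),
                  paste0("top", ks))
}

#' Write every input file of a scenario in its standard dialect
#'
#' Emits the matrix (raw bitscores + self-hits and the normalized form), the
#' clade map, the ontology (OBO), the annotation TSV, the interaction TSV,
#' the variant TSV and the query term list into a directory, so the
#' command-line workflow can be exercised end to end on synthetic data.
#'
#' @param scenario A [gen_scenario()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_matrix_tsv(scenario$bitscores, p("bitscores.tsv"), p("self_hits.tsv"))
  write_matrix_tsv(scenario$matrix, p("npp_matrix.tsv"))
  write_clade_map(scenario$clade_map, p("clades.tsv"))
  write_obo(scenario$obo, p("ontology.obo"))
  write_annotations(scenario$annotations, p("annotations.tsv"))
  utils::write.table(scenario$network$edges, p("string.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(scenario$variants), p("variants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(scenario$query, p("query_terms.txt"))
  writeLines(c(paste0("causal_gene\t", scenario$causal_gene),
               paste0("mode\t", scenario$mode)), p("truth.tsv"))
  invisible(dir)
}
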