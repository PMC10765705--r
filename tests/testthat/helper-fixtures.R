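# Shared fixtures: a hand-checkable toy ontology, a tiny bitscore table, and
# independent brute-force oracles used to validate the implementation paths.

# Toy DAG: root R; A under R; B, C under A; D under R.
# Genes: g1 -> {B}, g2 -> {C}, g3 -> {D}, g4 -> {D}.
# Hand-derived ICs (propagated counts over 4 genes):
#   R: 4/4 -> 0;  A: 2/4 -> ln 2;  B: 1/4 -> ln 4;  C: 1/4 -> ln 4;  D: 2/4 -> ln 2
toy_obo <- function() {
  list(terms = c("R", "A", "B", "C", "D"),
       parents = list(R = character(0), A = "R", B = "A", C = "A", D = "R"),
       alt = c(R = "R", A = "A", B = "B", C = "C", D = "D"),
       name = c(R = "root", A = "A", B = "B", C = "C", D = "D"),
       n_ignored_relations = 0L)
}

toy_annotations <- function() {
  list(g1 = "B", g2 = "C", g3 = "D", g4 = "D")
}

toy_index <- function() build_ontology_index(toy_obo(), toy_annotations())

# Independent IC oracle: counts genes annotated to a term or any descendant,
# with descendants enumerated by hand for the toy DAG.
toy_ic_oracle <- function() {
  desc <- list(R = c("R", "A", "B", "C", "D"), A = c("A", "B", "C"),
               B = "B", C = "C", D = "D")
  ann <- toy_annotations()
  vapply(names(desc), function(t) {
    n <- sum(vapply(ann, function(ts) any(ts %in% desc[[t]]), TRUE))
    -log(n / length(ann))
  }, 0)
}

# Independent Lin oracle from the hand-derived ICs and explicit ancestor sets.
toy_lin_oracle <- function(t1, t2) {
  anc <- list(R = "R", A = c("A", "R"), B = c("B", "A", "R"),
              C = c("C", "A", "R"), D = c("D", "R"))
  ic <- toy_ic_oracle()
  common <- intersect(anc[[t1]], anc[[t2]])
  denom <- ic[[t1]] + ic[[t2]]
  if (denom == 0) return(0)
  2 * max(ic[common]) / denom
}

toy_bma_oracle <- function(A, B) {
  s <- outer(A, B, Vectorize(toy_lin_oracle))
  (mean(apply(s, 1, max)) + mean(apply(s, 2, max))) / 2
}

# Small deterministic bitscore table with one missing hit.
toy_bitscores <- function() {
  set.seed(11)
  genes <- paste0("g", 1:6)
  species <- paste0("s", 1:8)
  self <- stats::setNames(rep(400, 6), genes)
  best <- matrix(runif(48, 10, 390), 6, 8, dimnames = list(genes, species))
  best[2, 5] <- NA
  bitscore_table(best, self)
}

# Brute-force per-clade co-evolution oracle: all-pairs Pearson over the
# clade's columns, sorted by decreasing r then gene id.
coevo_oracle <- function(cm, query, species, k) {
  others <- setdiff(cm$genes, query)
  r <- vapply(others, function(g)
    stats::cor(cm$values[query, species], cm$values[g, species]), 0)
  r <- r[!is.na(r)]
  ord <- order(-r, names(r))
  data.frame(gene = names(r)[head(ord, k)], r = unname(r[head(ord, k)]),
             stringsAsFactors = FALSE)
}

# Brute-force one-sided KS D- over the pooled values.
d_minus_oracle <- function(s, r) {
  xs <- sort(unique(c(s, r)))
  max(0, max(vapply(xs, function(x) mean(r <= x) - mean(s <= x), 0)))
}

# Full-enumeration permutation p-value oracle.
ks_exact_oracle <- function(s, r) {
  pooled <- c(s, r)
  n <- length(s)
  d_obs <- d_minus_oracle(s, r)
  idx <- utils::combn(length(pooled), n)
  mean(apply(idx, 2, function(j)
    d_minus_oracle(pooled[j], pooled[-j]) >= d_obs - 1e-12))
}

# The six-variant toy table forced by the filtering rules:
# gene A: two homozygous rare deleterious variants; gene B: one common;
# gene C: one predicted-benign nonsynonymous; gene D: two rare het variants.
toy_variants <- function() {
  variant_table(data.frame(
    gene = c("A", "A", "B", "C", "D", "D"),
    effect_class = c("nonsense", "nonsynonymous", "nonsynonymous",
                     "nonsynonymous", "nonsynonymous", "frameshift"),
    zygosity = c("hom", "hom", "hom", "hom", "het", "het"),
    freq_gnomad = c(NA, 0.0005, 0.15, 0.0002, 0.01, 0.015),
    polyphen2_hdiv = c(NA, 0.9, 0.8, 0.2, 0.7, NA),
    revel = c(NA, 0.8, 0.9, 0.3, 0.6, NA),
    sift = c(NA, 0.1, 0.2, 0.8, 0.3, NA),
    stringsAsFactors = FALSE))
}
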