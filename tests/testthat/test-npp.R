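# Normalized phylogenetic profiling: bitscore normalization and per-clade
# co-evolution retrieval.

test_that("normalization follows log2(best/self) then per-column z-scoring", {
  genes <- c("g1", "g2", "g3")
  # single species column with pre-z log2 values {0, -2, -4}
  best <- matrix(c(400, 100, 25), 3, 1, dimnames = list(genes, "s1"))
  self <- setNames(rep(400, 3), genes)
  # a second constant-free column so sd > 0 everywhere
  best <- cbind(best, s2 = c(200, 50, 400))
  cm <- normalize_bitscores(bitscore_table(best, self))
  # {0,-2,-4}: mean -2, sample sd 2 -> z = {1, 0, -1}
  expect_equal(unname(cm$values[, "s1"]), c(1, 0, -1))
  # identity case best = self -> log2 ratio 0, the column maximum pre-z
  expect_true(which.max(cm$values[, "s1"]) == 1)
})

test_that("normalized columns have mean 0 and sd 1, and ratios > 1 are clipped", {
  bt <- toy_bitscores()
  bt$best_hit[1, 1] <- bt$self_hit[["g1"]] * 1.5  # cross-hit outscores self-hit
  cm <- normalize_bitscores(bt)
  expect_equal(unname(colMeans(cm$values)), rep(0, 8), tolerance = 1e-12)
  expect_equal(unname(apply(cm$values, 2, sd)), rep(1, 8), tolerance = 1e-12)
  expect_identical(cm$meta$n_clipped, 1L)
  expect_false(cm$presence[2, 5])
})

test_that("missing-hit imputation policies order absent genes as least conserved", {
  bt <- toy_bitscores()
  flo <- normalize_bitscores(bt, "floor_epsilon")
  cmn <- normalize_bitscores(bt, "column_min")
  # under floor_epsilon the imputed gene is strictly the least conserved
  expect_equal(which.min(flo$values[, 5]), c(g2 = 2L))
  # under column_min it ties the observed column minimum
  expect_equal(min(cmn$values[, 5]), cmn$values[2, 5])
})

test_that("degenerate inputs are rejected with the offending column named", {
  genes <- c("g1", "g2")
  best <- matrix(c(100, 100, 50, 60), 2, 2, dimnames = list(genes, c("sA", "sB")))
  self <- setNames(c(200, 200), genes)
  expect_error(normalize_bitscores(bitscore_table(best, self)), "sA")
  expect_error(bitscore_table(best, setNames(c(0, 200), genes)), "positive")
})

test_that("ortholog presence counts observed clade hits against min_species", {
  bt <- toy_bitscores()
  cm <- normalize_bitscores(bt)
  cmap <- clade_map(list(CladeA = paste0("s", 1:4), CladeB = paste0("s", 5:8)))
  # g2 has 3 of 4 observed hits in CladeB (s5 missing)
  expect_true(has_ortholog(cm, "g2", "CladeB", cmap, min_species = 3))
  expect_false(has_ortholog(cm, "g2", "CladeB", cmap, min_species = 4))
  expect_true(has_ortholog(cm, "g2", "CladeA", cmap, min_species = 4))
  expect_error(has_ortholog(cm, "nope", "CladeA", cmap), "unknown gene")
  expect_error(has_ortholog(cm, "g1", "nope", cmap), "unknown clade")
})

test_that("top co-evolved ranking matches the exhaustive all-pairs Pearson oracle", {
  set.seed(5)
  vals <- matrix(rnorm(40 * 20), 40, 20,
                 dimnames = list(sprintf("g%02d", 1:40), sprintf("s%02d", 1:20)))
  cm <- conservation_matrix(vals)
  cmap <- clade_map(list(Left = sprintf("s%02d", 1:10), Right = sprintf("s%02d", 11:20)))
  for (clade in c("Left", "Right", "Eukaryota")) {
    sp <- cmap$clades[[clade]]
    got <- top_coevolved(cm, "g01", clade, cmap, k = 15)
    want <- coevo_oracle(cm, "g01", sp, 15)
    expect_equal(got$gene, want$gene)
    expect_equal(got$r, want$r, tolerance = 1e-12)
    expect_equal(got$rank, 1:15)
  }
})

test_that("a duplicated profile ranks first with r = 1 and the query is never returned", {
  set.seed(6)
  vals <- matrix(rnorm(10 * 12), 10, 12,
                 dimnames = list(paste0("g", 1:10), paste0("s", 1:12)))
  vals[2, ] <- vals[1, ]  # g2 duplicates the query profile
  cm <- conservation_matrix(vals)
  cmap <- clade_map(list(All = paste0("s", 1:12)))
  top <- top_coevolved(cm, "g1", "All", cmap, k = 9)
  expect_equal(top$gene[1], "g2")
  expect_equal(top$r[1], 1)
  expect_false("g1" %in% top$gene)
  # Pearson symmetry on the same column restriction
  top2 <- top_coevolved(cm, "g2", "All", cmap, k = 9)
  expect_equal(top2$r[top2$gene == "g1"], top$r[top$gene == "g2"])
})

test_that("smaller k returns a prefix of larger k (monotone nesting)", {
  set.seed(7)
  vals <- matrix(rnorm(30 * 15), 30, 15,
                 dimnames = list(sprintf("g%02d", 1:30), paste0("s", 1:15)))
  cm <- conservation_matrix(vals)
  cmap <- clade_map(list(All = paste0("s", 1:15)))
  t10 <- top_coevolved(cm, "g05", "All", cmap, k = 10)
  t25 <- top_coevolved(cm, "g05", "All", cmap, k = 25)
  expect_equal(t25$gene[1:10], t10$gene)
})

test_that("degenerate clades and constant query profiles are errors", {
  vals <- matrix(rnorm(5 * 6), 5, 6,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:6)))
  vals[3, 1:3] <- 2  # constant within the Small clade
  cm <- conservation_matrix(vals)
  cmap <- clade_map(list(Tiny = c("s1", "s2"), Small = c("s1", "s2", "s3")))
  expect_error(top_coevolved(cm, "g1", "Tiny", cmap), "fewer than 3")
  expect_error(top_coevolved(cm, "g3", "Small", cmap), "constant")
})

test_that("clade-merged profile keeps each partner's best rank and clade", {
  set.seed(8)
  vals <- matrix(rnorm(20 * 24), 20, 24,
                 dimnames = list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:24)))
  cm <- conservation_matrix(vals)
  cmap <- clade_map(list(A = sprintf("s%02d", 1:12), B = sprintf("s%02d", 13:24)))
  prof <- coevolution_profile(cm, "g01", cmap, k = 10)
  expect_setequal(names(prof$per_clade), c("A", "B", "Eukaryota"))
  expect_false("g01" %in% prof$merged$gene)
  expect_false(anyDuplicated(prof$merged$gene) > 0)
  for (i in seq_len(nrow(prof$merged))) {
    g <- prof$merged$gene[i]
    ranks <- vapply(prof$per_clade, function(tab) {
      j <- match(g, tab$gene); if (is.na(j)) NA_integer_ else tab$rank[j]
    }, 1L)
    expect_equal(prof$merged$best_rank[i], min(ranks, na.rm = TRUE))
    expect_true(ranks[[prof$merged$clade[i]]] == prof$merged$best_rank[i])
  }
})

test_that("a planted co-evolving module is recovered within its clade restriction", {
  mod <- sprintf("G%04d", 11:20)
  gen <- gen_conservation_matrix(
    n_genes = 60, n_species = 40, clade_map = synth_clade_map(40, 2),
    modules = list(list(genes = mod, rho = 0.95, clades = "Chordata")),
    seed = 123)
  prof <- coevolution_profile(gen$matrix, "G0011", gen$clade_map, k = 9)
  expect_setequal(prof$per_clade$Chordata$gene[1:9], setdiff(mod, "G0011"))
  # outside the restricted clade the module carries no signal, so the best
  # clade for module partners is Chordata or Eukaryota (which contains it),
  # never the uncorrelated sister clade alone
  expect_true(all(prof$merged$clade[prof$merged$gene %in% mod] %in%
                    c("Chordata", "Eukaryota")))
})

test_that("matrix and clade-map files round-trip through their TSV dialects", {
  dir <- withr::local_tempdir()
  bt <- toy_bitscores()
  write_matrix_tsv(bt, file.path(dir, "bits.tsv"), file.path(dir, "self.tsv"))
  bt2 <- read_matrix_tsv(file.path(dir, "bits.tsv"), file.path(dir, "self.tsv"))
  expect_equal(bt2$best_hit, bt$best_hit, tolerance = 1e-9)
  expect_equal(bt2$self_hit, bt$self_hit)
  cm <- normalize_bitscores(bt)
  write_matrix_tsv(cm, file.path(dir, "npp.tsv"))
  cm2 <- read_matrix_tsv(file.path(dir, "npp.tsv"))
  expect_equal(cm2$values, cm$values, tolerance = 1e-9)
  cmap <- clade_map(list(A = c("s1", "s2"), B = c("s3", "s4")))
  write_clade_map(cmap, file.path(dir, "clades.tsv"))
  expect_equal(read_clade_map(file.path(dir, "clades.tsv"))$clades[c("A", "B")],
               cmap$clades[c("A", "B")])
})
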