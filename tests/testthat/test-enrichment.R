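# One-sided KS enrichment, p-value combination, and candidate prioritization.

test_that("D- and the exact permutation p match hand-enumerable cases", {
  # identical samples: ECDFs coincide
  r <- ks_one_sided(c(0.1, 0.5, 0.9), c(0.1, 0.5, 0.9))
  expect_equal(r$d_minus, 0)
  expect_equal(r$p_value, 1)
  # both sample values above all reference values: D- = 1, p = 1 / C(6,2)
  r <- ks_one_sided(c(0.8, 0.9), c(0.1, 0.2, 0.3, 0.4))
  expect_equal(r$d_minus, 1)
  expect_equal(r$p_value, 1 / 15)
  expect_equal(r$method, "exact_permutation")
  # sample entirely below the reference: no positive deviation
  r <- ks_one_sided(c(0.01, 0.02), c(0.5, 0.6, 0.7))
  expect_equal(r$d_minus, 0)
  expect_equal(r$p_value, 1)
  expect_error(ks_one_sided(numeric(0), c(0.1, 0.2)), "empty sample")
  expect_error(ks_one_sided(0.5, 0.1), "at least 2")
})

test_that("implementation equals enumeration and ks.test over all small splits", {
  # fixed 12-value score set; every split into sample/reference with n+m = 12
  set.seed(42)
  pool <- round(runif(12), 3)
  for (n in c(1, 2, 3, 5, 8, 10)) {
    for (rep in 1:5) {
      pick <- sample(12, n)
      s <- pool[pick]; r <- pool[-pick]
      got <- ks_one_sided(s, r)
      expect_equal(got$d_minus, d_minus_oracle(s, r), tolerance = 1e-12)
      expect_equal(got$p_value, ks_exact_oracle(s, r), tolerance = 1e-12)
      # independent library cross-check of the statistic
      kk <- suppressWarnings(stats::ks.test(s, r, alternative = "less"))
      expect_equal(got$d_minus, unname(kk$statistic), tolerance = 1e-12)
    }
  }
  # smaller pooled sets too (n + m < 12)
  for (rep in 1:10) {
    s <- runif(3); r <- runif(5)
    got <- ks_one_sided(s, r)
    expect_equal(got$p_value, ks_exact_oracle(s, r), tolerance = 1e-12)
  }
})

test_that("the asymptotic branch matches ks.test's one-sided approximation", {
  set.seed(1)
  for (rep in 1:20) {
    s <- runif(8); r <- runif(40)
    got <- ks_one_sided(s, r)
    expect_equal(got$method, "asymptotic")
    kk <- suppressWarnings(stats::ks.test(s, r, alternative = "less", exact = FALSE))
    expect_equal(got$d_minus, unname(kk$statistic), tolerance = 1e-12)
    expect_equal(got$p_value, kk$p.value, tolerance = 1e-12)
  }
})

test_that("D- is invariant under strictly increasing transforms of the scores", {
  set.seed(2)
  s <- runif(10); r <- runif(25)
  base <- ks_one_sided(s, r)
  for (f in list(function(x) 3 * x + 2, function(x) x^3, function(x) exp(x))) {
    tr <- ks_one_sided(f(s), f(r))
    expect_equal(tr$d_minus, base$d_minus, tolerance = 1e-12)
    expect_equal(tr$p_value, base$p_value, tolerance = 1e-12)
  }
})

test_that("type-I error of the enrichment test is controlled at the nominal level", {
  set.seed(2024)
  hits <- mean(replicate(1000, {
    reference <- runif(500)
    ks_one_sided(runif(50), reference)$p_value < 0.05
  }))
  expect_gte(hits, 0.03)
  expect_lte(hits, 0.07)
})

test_that("Fisher combination reduces to the identity for one p-value", {
  for (p in c(1e-15, 1e-9, 1e-4, 0.01, 0.2, 0.5, 0.75, 0.99)) {
    expect_equal(fisher_combine(p)$p_combined, p, tolerance = 1e-12)
  }
})

test_that("Fisher combination matches the closed-form df = 4 survival function", {
  # for k = 2, P(X > x) = exp(-x/2) * (1 + x/2)
  cases <- list(c(0.05, 0.05), c(0.01, 0.8), c(0.3, 0.6), c(1e-6, 0.99))
  for (ps in cases) {
    x <- -2 * sum(log(ps))
    expect_equal(fisher_combine(ps)$p_combined, exp(-x / 2) * (1 + x / 2),
                 tolerance = 1e-12)
  }
  got <- fisher_combine(c(0.05, 0.05))
  expect_equal(got$statistic, -4 * log(0.05))
  expect_equal(got$df, 4L)
  expect_equal(got$p_combined, 0.01747866, tolerance = 1e-6)
})

test_that("Fisher combination is permutation-invariant and rejects invalid p", {
  ps <- c(0.003, 0.4, 0.77)
  expect_equal(fisher_combine(ps)$p_combined, fisher_combine(rev(ps))$p_combined)
  expect_error(fisher_combine(c(0.5, 0)), "floor")
  expect_error(fisher_combine(numeric(0)), "no p-values")
  # appending an uninformative p = 1 component changes only the df penalty:
  # the combined p never drops below the original
  for (p in c(1e-8, 0.01, 0.3)) {
    expect_gte(fisher_combine(c(p, 1))$p_combined, fisher_combine(p)$p_combined)
  }
})

test_that("Simes combination matches direct enumeration of k * p(i) / i", {
  expect_equal(simes_combine(0.37)$p_combined, 0.37)
  expect_equal(simes_combine(c(0.01, 0.04))$p_combined, 0.02)
  expect_equal(simes_combine(rep(0.2, 5))$p_combined, 0.2)
  set.seed(77)
  for (rep in 1:1000) {
    k <- sample(1:6, 1)
    ps <- runif(k)
    want <- min(k * sort(ps) / seq_len(k))
    expect_equal(simes_combine(ps)$p_combined, want, tolerance = 1e-14)
  }
})

test_that("prioritize orders candidates by combined p with degenerate-input rules", {
  idx <- toy_index()
  # a larger synthetic universe for meaningful KS samples
  gen <- gen_ontology_and_annotations(n_terms = 40, depth = 3, n_genes = 120, seed = 5)
  index <- build_ontology_index(gen$obo, gen$annotations)
  query <- gen$annotations$G0001[1]
  ranking <- rank_genes_by_phenotype(query, index)
  top_genes <- ranking$gene[1:10]
  low_genes <- ranking$gene[101:110]
  res <- prioritize(
    candidates = c("candA", "candB", "candC", "candD"),
    ranking = ranking,
    coevo = list(candA = top_genes, candB = low_genes,
                 candC = top_genes[1:2]),              # below min_overlap
    network_partners = list(candA = low_genes, candB = low_genes))
  expect_s3_class(res, "enrichment_result")
  expect_equal(res$gene[1], "candA")                    # enriched channel wins
  expect_equal(res$rank, 1:4)
  # candC's only channel is under min_overlap -> no evidence, placed last, p = 1
  rowC <- res[res$gene == "candC", ]
  expect_match(rowC$flags, "coevo_insufficient_overlap")
  expect_match(rowC$flags, "no_evidence")
  expect_equal(rowC$p_combined, 1)
  expect_true(rowC$rank >= 3L)   # no-evidence block sits at the bottom
  # candD has no channel at all and ties with candC at p = 1
  expect_match(res$flags[res$gene == "candD"], "no_evidence")
  expect_equal(res$rank[res$gene == "candD"], 4L)  # lexicographic tie-break
  # df adapts to the number of available channels
  expect_equal(res$df[res$gene == "candB"], 4L)
  # a single candidate is always rank 1
  solo <- prioritize("only", ranking, coevo = list(only = top_genes))
  expect_equal(solo$rank, 1L)
  expect_equal(solo$df, 2L)
})

test_that("channel samples intersect the universe and drop duplicates", {
  gen <- gen_ontology_and_annotations(n_terms = 30, depth = 3, n_genes = 60, seed = 6)
  index <- build_ontology_index(gen$obo, gen$annotations)
  ranking <- rank_genes_by_phenotype(gen$annotations$G0001[1], index)
  inside <- ranking$gene[1:5]
  # duplicated and out-of-universe partners must not inflate the sample
  res <- prioritize("x", ranking,
                    coevo = list(x = c(inside, inside, "ghost1", "ghost2")))
  expect_equal(res$n_coevo, 5L)
})
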