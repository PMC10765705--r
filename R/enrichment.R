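# Statistical core: one-sided two-sample Kolmogorov-Smirnov enrichment of a
# gene set against the phenotype ranking, p-value combination, and candidate
# prioritization.

#' One-sided two-sample Kolmogorov-Smirnov enrichment test
#'
#' Tests whether the sample scores (semantic-similarity scores of a
#' candidate's co-evolved or interacting genes) are shifted towards the
#' high-scoring end of the reference distribution (the full HPO-ranked gene
#' list). With `Fi` the sample ECDF and `Fj` the reference ECDF, the statistic
#' is `D- = max(0, sup_x(Fj(x) - Fi(x)))`; under H1 `Fi(x) < Fj(x)`, i.e. the
#' sample ECDF lags because its mass sits at high scores.
#'
#' @param sample_scores Numeric vector, at least 1 value.
#' @param reference_scores Numeric vector, at least 2 values.
#' @param exact_cap When `length(sample) + length(reference) <= exact_cap`,
#'   the p-value is computed exactly by enumerating every assignment of the
#'   pooled values into sample/reference labels (permutation null). Above the
#'   cap the asymptotic one-sided formula `exp(-2 * (n*m/(n+m)) * D^2)` is
#'   used. Default 12.
#' @return An object of class `ks_result`: list with `d_minus`, `p_value`,
#'   `n_sample`, `n_reference`, `method` (`"exact_permutation"` or
#'   `"asymptotic"`).
#' @details Both ECDFs are right-continuous step functions evaluated at the
#'   pooled unique score values, so ties between and within samples are
#'   handled by the discrete supremum. The statistic is invariant under any
#'   strictly increasing transform of the scores.
#' @export
ks_one_sided <- function(sample_scores, reference_scores, exact_cap = 12) {
  if (!length(sample_scores)) stop("empty sample: no scores to test")
  if (length(reference_scores) < 2) stop("reference must contain at least 2 scores")
  stopifnot(is.numeric(sample_scores), is.numeric(reference_scores),
            !anyNA(sample_scores), !anyNA(reference_scores))
  n <- length(sample_scores); m <- length(reference_scores)
  d <- .d_minus(sample_scores, reference_scores)
  if (n + m <= exact_cap) {
    p <- .ks_exact_p(sample_scores, reference_scores, d)
    method <- "exact_permutation"
  } else {
    neff <- n * m / (n + m)
    p <- exp(-2 * neff * d^2)
    method <- "asymptotic"
  }
  structure(list(d_minus = d, p_value = min(1, p), n_sample = n,
                 n_reference = m, method = method),
            class = "ks_result")
}

# sup over pooled unique values of (F_reference - F_sample), floored at 0.
.d_minus <- function(sample, reference) {
  x <- sort(unique(c(sample, reference)))
  Fi <- vapply(x, function(v) mean(sample <= v), 0)
  Fj <- vapply(x, function(v) mean(reference <= v), 0)
  max(0, max(Fj - Fi))
}

# Exact permutation p: P(D- >= observed) over all C(n+m, n) label assignments.
.ks_exact_p <- function(sample, reference, d_obs) {
  pooled <- c(sample, reference)
  n <- length(sample)
  idx <- utils::combn(length(pooled), n)
  hits <- 0L
  for (j in seq_len(ncol(idx))) {
    s <- pooled[idx[, j]]
    r <- pooled[-idx[, j]]
    if (.d_minus(s, r) >= d_obs - 1e-12) hits <- hits + 1L
  }
  hits / ncol(idx)
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("<ks_result> D- = %.4f, p = %.4g (%s; n = %d vs m = %d)\n",
              x$d_minus, x$p_value, x$method, x$n_sample, x$n_reference))
  invisible(x)
}

#' Fisher's combined probability test
#'
#' Combines k independent p-values with the statistic `X = -2 * sum(ln p_i)`,
#' referred to a chi-square distribution with 2k degrees of freedom. For a
#' single p-value the combination is the identity.
#'
#' @param p_values Numeric vector of p-values in (0, 1]; zero is an error
#'   (floor p-values at a machine minimum first, see [prioritize()]).
#' @param sources Optional character vector naming each component.
#' @return An object of class `combined_score`: list with `components`,
#'   `statistic`, `df`, `p_combined`, `method`.
#' @export
fisher_combine <- function(p_values, sources = NULL) {
  .check_pvalues(p_values)
  stat <- -2 * sum(log(p_values))
  df <- 2L * length(p_values)
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)
  .combined_score(p_values, sources, stat, df, p, "fisher")
}

#' Simes' method for combining p-values
#'
#' `p_combined = min_i (k * p_(i) / i)` over the sorted p-values; valid under
#' positive dependence and used here as the alternative to Fisher's method.
#'
#' @inheritParams fisher_combine
#' @return A `combined_score` (with `statistic` and `df` set to `NA`).
#' @export
simes_combine <- function(p_values, sources = NULL) {
  .check_pvalues(p_values)
  k <- length(p_values)
  ps <- sort(p_values)
  p <- min(k * ps / seq_len(k))
  .combined_score(p_values, sources, NA_real_, NA_integer_, min(1, p), "simes")
}

.check_pvalues <- function(p) {
  if (!length(p)) stop("no p-values to combine")
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]; floor zeros at a machine minimum first")
}

.combined_score <- function(p, sources, stat, df, p_comb, method) {
  if (is.null(sources)) sources <- paste0("p", seq_along(p))
  structure(list(components = stats::setNames(as.numeric(p), sources),
                 statistic = stat, df = df, p_combined = p_comb,
                 method = method),
            class = "combined_score")
}

#' @export
print.combined_score <- function(x, ...) {
  cat(sprintf("<combined_score> %s: p = %.4g (k = %d)\n",
              x$method, x$p_combined, length(x$components)))
  invisible(x)
}

#' Prioritize patient candidate genes
#'
#' For each candidate gene, tests whether (a) its clade-merged co-evolved
#' genes and (b) its network interaction partners rank significantly high
#' within the phenotype ranking, using the one-sided KS test against the full
#' ranked universe; the available channel p-values are combined (Fisher by
#' default) and candidates are ordered by combined p-value ascending, ties
#' broken by gene id.
#'
#' Co-evolved/interacting genes outside the annotated universe are dropped
#' from the KS sample (both ECDFs must live on the same score scale); a
#' channel with fewer than `min_overlap` genes in the universe is skipped and
#' the combination degrees of freedom shrink accordingly. A candidate with no
#' usable channel is flagged `"no_evidence"` and placed last with combined
#' p = 1.
#'
#' @param candidates Character vector of candidate gene ids.
#' @param ranking A [rank_genes_by_phenotype()] result.
#' @param coevo Named list: candidate -> character vector of co-evolved
#'   partner genes (e.g. `coevolution_profile(...)$merged$gene`). Candidates
#'   absent from the list (not in the conservation matrix) simply lack the
#'   channel.
#' @param network_partners Named list: candidate -> character vector of
#'   interaction partners; may omit candidates.
#' @param combine_method `"fisher"` or `"simes"`.
#' @param min_overlap Minimum channel genes inside the universe for a valid
#'   KS test (default 3).
#' @param p_floor Lower clamp applied to channel p-values before combination
#'   (default 1e-300), avoiding -Inf in the log.
#' @return An object of class `enrichment_result`: a data frame with one row
#'   per candidate: `gene`, `n_coevo`, `d_coevo`, `p_coevo`, `n_string`,
#'   `d_string`, `p_string`, `statistic`, `df`, `p_combined`, `p_adjust`
#'   (Benjamini-Hochberg across candidates, informational), `rank`, `flags`.
#' @export
prioritize <- function(candidates, ranking, coevo = list(),
                       network_partners = list(),
                       combine_method = c("fisher", "simes"),
                       min_overlap = 3, p_floor = 1e-300) {
  combine_method <- match.arg(combine_method)
  if (!length(candidates)) stop("no candidate genes supplied")
  stopifnot(inherits(ranking, "phenotype_ranking"))
  candidates <- unique(as.character(candidates))
  universe <- stats::setNames(ranking$score, ranking$gene)
  reference <- unname(universe)

  one <- function(g) {
    row <- list(gene = g, n_coevo = NA_integer_, d_coevo = NA_real_,
                p_coevo = NA_real_, n_string = NA_integer_, d_string = NA_real_,
                p_string = NA_real_, statistic = NA_real_, df = NA_integer_,
                p_combined = 1, flags = "")
    ps <- numeric(0); src <- character(0); flags <- character(0)
    chan <- list(coevo = coevo[[g]], string = network_partners[[g]])
    for (nm in names(chan)) {
      genes <- setdiff(unique(chan[[nm]]), g)
      if (is.null(chan[[nm]])) next
      in_univ <- intersect(genes, names(universe))
      nfield <- if (nm == "coevo") "n_coevo" else "n_string"
      row[[nfield]] <- length(in_univ)
      if (length(in_univ) < min_overlap) {
        flags <- c(flags, paste0(nm, "_insufficient_overlap"))
        next
      }
      ks <- ks_one_sided(unname(universe[in_univ]), reference)
      if (nm == "coevo") {
        row$d_coevo <- ks$d_minus; row$p_coevo <- ks$p_value
      } else {
        row$d_string <- ks$d_minus; row$p_string <- ks$p_value
      }
      ps <- c(ps, max(ks$p_value, p_floor)); src <- c(src, nm)
    }
    if (!length(ps)) {
      row$flags <- paste(c(flags, "no_evidence"), collapse = ";")
      return(row)
    }
    comb <- if (combine_method == "fisher") fisher_combine(ps, src)
            else simes_combine(ps, src)
    row$statistic <- comb$statistic
    row$df <- comb$df
    row$p_combined <- comb$p_combined
    row$flags <- paste(flags, collapse = ";")
    row
  }

  rows <- lapply(candidates, one)
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  no_ev <- grepl("no_evidence", out$flags)
  ord <- order(no_ev, out$p_combined, out$gene)
  out <- out[ord, ]
  out$p_adjust <- stats::p.adjust(out$p_combined, method = "BH")
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "combine_method") <- combine_method
  class(out) <- c("enrichment_result", "data.frame")
  out
}
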