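## The package's central statistic: per-gene deviance from additivity and
## its permutation null. Everything here operates on per-gene standardized
## expression (see per_gene_standardize), so effects are in SD units.

# Interaction-contrast weights, aligned to the design's sample order:
# +1/n_control on control, -1/n on each single signal, +1/n_both on both.
# w %*% z_g  =  mean(both) - mean(sigA) - mean(sigB) + mean(control)
#            =  e_AB - (e_A + e_B).
interaction_weights <- function(design) {
  n <- table(design$treatment)
  sgn <- c(control = 1, sigA = -1, sigB = -1, both = 1)
  tr <- as.character(design$treatment)
  unname(sgn[tr] / as.integer(n[tr]))
}

#' Per-gene treatment effects and deviance from additivity
#'
#' For each gene, the effect of a treatment is the mean of its samples minus
#' the mean of the control samples: `e_A`, `e_B`, `e_AB`. Under additivity
#' the combined effect should equal the sum of the single-signal effects, so
#' the test statistic is the squared deviation
#' \deqn{D = \delta^2,\qquad \delta = e_{AB} - (e_A + e_B),}
#' which is algebraically the interaction contrast
#' `mean(both) - mean(sigA) - mean(sigB) + mean(control)`.
#'
#' @param z genes x samples matrix of per-gene standardized expression.
#' @param design design table, see [validate_design()].
#' @return data.frame `gene_id`, `e_A`, `e_B`, `e_AB`, `sum_null`, `delta`,
#'   `deviance`.
#' @export
compute_effects <- function(z, design) {
  check_expression_matrix(z, "z")
  design <- validate_design(design, colnames(z))
  tr <- design$treatment
  mn <- sapply(TREATMENTS, function(t) rowMeans(z[, tr == t, drop = FALSE]))
  if (is.null(dim(mn))) mn <- matrix(mn, nrow = 1, dimnames = list(NULL, TREATMENTS))
  e_A <- mn[, "sigA"] - mn[, "control"]
  e_B <- mn[, "sigB"] - mn[, "control"]
  e_AB <- mn[, "both"] - mn[, "control"]
  delta <- e_AB - (e_A + e_B)
  data.frame(gene_id = rownames(z), e_A = e_A, e_B = e_B, e_AB = e_AB,
             sum_null = e_A + e_B, delta = delta, deviance = delta^2,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Tie tolerance for counting null deviances >= observed: identity
# relabelings reproduce the observed statistic exactly in real arithmetic,
# but floating-point summation order may perturb the last bits. A null
# value within tol of D counts as a tie (the ">=" convention).
deviance_tie_tol <- function(D) 1e-9 * (1 + abs(D))

#' Permutation p-values for the deviance from additivity
#'
#' Ranks each gene's observed deviance `D` against null deviances obtained
#' by shuffling the sample-to-treatment labels across all `N` samples,
#' independently for every gene and permutation. Three null modes:
#' \describe{
#'   \item{`pooled` (default)}{null deviances from all genes are pooled into
#'     one reference distribution; `p_g = (#\{pooled D* >= D_g\} + 1) /
#'     (G * B + 1)`. Assumes deviances are exchangeable across genes, which
#'     per-gene standardization supports, and gives much finer p-value
#'     resolution than a single gene's `B` permutations.}
#'   \item{`per_gene`}{each gene is ranked only against its own null:
#'     `p_g = (#\{D*_g >= D_g\} + 1) / (B + 1)`.}
#'   \item{`exact_per_gene`}{full enumeration of all distinct assignments of
#'     the `N` samples into the four treatment groups (e.g. `8!/(2!)^4 =
#'     2520` for duplicates), with `p_g` the exact tail proportion
#'     `#\{D* >= D_g\} / n_assign` (the identity assignment is included, so
#'     `p_g >= 1/n_assign`). Refused for `N > 12`; use `per_gene` there.}
#' }
#' Null values equal to the observed deviance count toward the tail (ties
#' use the `>=` convention, up to a relative tolerance of `1e-9`), and the
#' add-one formula keeps Monte-Carlo p-values away from zero. Results are
#' reproducible for a given `seed`.
#'
#' @param z genes x samples matrix of per-gene standardized expression.
#' @param design design table.
#' @param B number of random permutations per gene (ignored in exact mode).
#' @param mode `"pooled"`, `"per_gene"` or `"exact_per_gene"`.
#' @param seed RNG seed for the permutation stream; `NULL` uses the ambient
#'   stream.
#' @return numeric vector of p-values named by gene, with attributes
#'   `mode`, `B`, `B_effective`, `n_pool` and `seed`.
#' @export
permutation_pvalues <- function(z, design, B = 10000,
                                mode = c("pooled", "per_gene", "exact_per_gene"),
                                seed = NULL) {
  mode <- match.arg(mode)
  check_expression_matrix(z, "z")
  design <- validate_design(design, colnames(z))
  if (mode != "exact_per_gene") {
    if (!is.numeric(B) || length(B) != 1L || !is.finite(B) || B < 1) {
      stop_field("B", "must be a single number >= 1")
    }
    B <- as.integer(B)
  }
  w <- interaction_weights(design)
  G <- nrow(z)
  N <- ncol(z)
  D <- as.vector(z %*% w)^2
  thr <- D - deviance_tie_tol(D)

  if (mode == "exact_per_gene") {
    if (N > 12L) {
      stop_field("mode", sprintf(
        "exact enumeration refused for N = %d samples (limit 12): %s",
        N, "the assignment count explodes; use mode = 'per_gene' with large B"))
    }
    W <- enumerate_weight_rows(design, w)
    n_assign <- nrow(W)
    counts <- numeric(G)
    step <- max(1L, 2e6 %/% n_assign)
    for (start in seq(1L, G, by = step)) {
      i <- start:min(G, start + step - 1L)
      Dstar <- (W %*% t(z[i, , drop = FALSE]))^2
      counts[i] <- colSums(Dstar >= rep(thr[i], each = n_assign))
    }
    p <- counts / n_assign
    return(structure(stats::setNames(p, rownames(z)),
                     mode = mode, B = NA_integer_, B_effective = n_assign,
                     n_pool = NA_integer_, seed = seed))
  }

  with_local_seed(seed, {
    counts <- numeric(G)       # per-gene tail counts
    pool_counts <- numeric(G)  # pooled tail counts
    pool_total <- 0
    # deterministic chunking (a pure function of G) keeps the RNG stream,
    # and hence the result, independent of memory conditions
    chunk <- max(1L, min(B, as.integer(ceiling(2^21 / G))))
    done <- 0L
    while (done < B) {
      b <- min(chunk, B - done)
      nr <- G * b
      U <- matrix(stats::runif(nr * N), nr, N)
      rk <- matrix(0L, nr, N)
      for (i in seq_len(N)) rk[, i] <- rowSums(U <= U[, i])
      Wp <- matrix(w[rk], nr, N)
      Zr <- z[rep.int(seq_len(G), b), , drop = FALSE]
      Dstar <- rowSums(Wp * Zr)^2
      if (mode == "per_gene") {
        counts <- counts + rowSums(matrix(Dstar >= thr, G, b))
      } else {
        srt <- sort(Dstar)
        pool_counts <- pool_counts + (nr - findInterval(thr, srt))
        pool_total <- pool_total + nr
      }
      done <- done + b
    }
    p <- if (mode == "per_gene") {
      (counts + 1) / (B + 1)
    } else {
      (pool_counts + 1) / (pool_total + 1)
    }
    structure(stats::setNames(p, rownames(z)),
              mode = mode, B = B, B_effective = B,
              n_pool = if (mode == "pooled") pool_total else NA_integer_,
              seed = seed)
  })
}

# All distinct assignments of sample positions to the four treatment groups,
# returned as rows of interaction-contrast weights. Group sizes follow the
# design; the weight of a position depends only on the group it lands in.
enumerate_weight_rows <- function(design, w) {
  tr <- design$treatment
  counts <- as.integer(table(tr)[TREATMENTS])
  N <- length(tr)
  wt <- c(1, -1, -1, 1) / counts  # weight per treatment group
  idx <- seq_len(N)
  n_assign <- factorial(N) / prod(factorial(counts)) *
    1  # multinomial coefficient
  W <- matrix(0, nrow = n_assign, ncol = N)
  row <- 0L
  for (a in utils::combn(idx, counts[1], simplify = FALSE)) {
    rest1 <- setdiff(idx, a)
    for (b in utils::combn(rest1, counts[2], simplify = FALSE)) {
      rest2 <- setdiff(rest1, b)
      for (cc in utils::combn(rest2, counts[3], simplify = FALSE)) {
        d <- setdiff(rest2, cc)
        row <- row + 1L
        W[row, a] <- wt[1]; W[row, b] <- wt[2]
        W[row, cc] <- wt[3]; W[row, d] <- wt[4]
      }
    }
  }
  stopifnot(row == n_assign)
  W
}

#' Holm step-down adjusted p-values
#'
#' Family-wise error-rate control: with the p-values sorted ascending,
#' `adjusted_(i) = max_(j <= i) (n - j + 1) * p_(j)`, capped at 1 and
#' returned in the original order (wraps [stats::p.adjust()] with
#' validation). Holm-adjusted values are always >= BH-adjusted values.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted p-values, same length and order.
#' @export
holm_adjust <- function(p) {
  check_pvalues(p)
  stats::p.adjust(p, method = "holm")
}

#' Direction of the deviation from additivity
#'
#' `positive` when the observed combined effect exceeds the summed
#' single-signal effects (`delta > 0`), `negative` when the sum exceeds the
#' observed combination (`delta < 0`). A gene with `delta = 0` has deviance
#' 0, cannot beat any permutation (p = 1 under the `>=` tie convention) and
#' gets `NA`.
#'
#' @param delta numeric vector of deviations, or an effect-profile
#'   data.frame from [compute_effects()].
#' @return character vector: `"positive"`, `"negative"` or `NA`.
#' @export
classify_direction <- function(delta) {
  if (is.data.frame(delta)) delta <- delta$delta
  if (!is.numeric(delta)) stop_field("delta", "must be numeric")
  ifelse(delta > 0, "positive", ifelse(delta < 0, "negative", NA_character_))
}

#' Exact binomial enrichment test with Clopper-Pearson interval
#'
#' Tests whether `x` successes among `n` trials exceed what a success
#' probability of `p0` allows — here, whether more genes beat the nominal
#' per-gene threshold than expected by chance. The p-value is exact
#' (binomial tail; default one-sided `greater`, matching the question "more
#' than expected?"), and the confidence interval for the success proportion
#' is the exact Clopper-Pearson interval from beta quantiles.
#'
#' @param x number of successes (0 <= x <= n).
#' @param n number of trials.
#' @param p0 null success probability, in (0, 1).
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @param conf_level confidence level for the (two-sided) interval.
#' @return list of class `enrichment_result`: `x`, `n`, `p0`, `estimate`,
#'   `p_value`, `ci_low`, `ci_high`, `alternative`, `conf_level`.
#' @examples
#' enrichment_test(22, 242, 0.05)
#' @export
enrichment_test <- function(x, n, p0 = 0.05,
                            alternative = c("greater", "two.sided"),
                            conf_level = 0.95) {
  alternative <- match.arg(alternative)
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n)) {
    stop_field("n", "must be a positive integer")
  }
  if (!is.numeric(x) || length(x) != 1L || x < 0 || x > n || x != round(x)) {
    stop_field("x", "must be an integer in [0, n]")
  }
  if (!is.numeric(p0) || length(p0) != 1L || p0 <= 0 || p0 >= 1) {
    stop_field("p0", "must be in (0, 1)")
  }
  if (!is.numeric(conf_level) || length(conf_level) != 1L ||
      conf_level <= 0 || conf_level >= 1) {
    stop_field("conf_level", "must be in (0, 1)")
  }
  x <- as.integer(x); n <- as.integer(n)
  p_value <- if (alternative == "greater") {
    stats::pbinom(x - 1L, n, p0, lower.tail = FALSE)
  } else {
    # minimum-likelihood two-sided convention (as in binom.test)
    d <- stats::dbinom(x, n, p0)
    dd <- stats::dbinom(0:n, n, p0)
    sum(dd[dd <= d * (1 + 1e-7)])
  }
  a <- (1 - conf_level) / 2
  ci_low <- if (x == 0L) 0 else stats::qbeta(a, x, n - x + 1)
  ci_high <- if (x == n) 1 else stats::qbeta(1 - a, x + 1L, n - x)
  structure(
    list(x = x, n = n, p0 = p0, estimate = x / n,
         p_value = min(p_value, 1), ci_low = ci_low, ci_high = ci_high,
         alternative = alternative, conf_level = conf_level),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "Exact binomial test (%s): x = %d, n = %d, p0 = %g\n  probability = %.3f, %d%% CI: %.3f-%.3f, p = %.4g\n",
    x$alternative, x$x, x$n, x$p0, x$estimate,
    round(100 * x$conf_level), x$ci_low, x$ci_high, x$p_value))
  invisible(x)
}

#' Test genes for non-additive responses to the signal combination
#'
#' The core analysis: per-gene deviance from additivity on standardized
#' expression, permutation p-values ([permutation_pvalues()]), Holm
#' correction, directional classification, and the binomial enrichment test
#' on the count of genes below `alpha` before correction.
#'
#' A finite permutation count bounds the smallest achievable p-value; when
#' it cannot undercut the Holm threshold `alpha / n_genes` a warning is
#' emitted, since no gene could then be flagged no matter how strong its
#' interaction.
#'
#' @param z per-gene standardized genes x samples matrix (see
#'   [per_gene_standardize()]).
#' @param design design table.
#' @param genes optional character vector restricting the analysis (and the
#'   permutation pool) to a gene subset, e.g. the regulated set.
#' @param B,mode,seed passed to [permutation_pvalues()].
#' @param alpha threshold used both for the per-gene count entering the
#'   enrichment test and for the Holm family-wise cut.
#' @return list of class `synergy_result`:
#' \describe{
#'   \item{table}{per-gene `gene_id`, effects, `delta`, `deviance`,
#'     `p_perm`, `p_holm`, `direction`, `flagged`.}
#'   \item{enrichment}{[enrichment_test()] result on
#'     `x = #\{p_perm < alpha\}`, `n` genes tested, `p0 = alpha`.}
#'   \item{meta}{`B`, `B_effective`, `mode`, `seed`, `alpha`, `n_pool`.}
#' }
#' @export
synergy_test <- function(z, design, genes = NULL, B = 10000,
                         mode = c("pooled", "per_gene", "exact_per_gene"),
                         seed = NULL, alpha = 0.05) {
  mode <- match.arg(mode)
  check_expression_matrix(z, "z")
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(z))
    if (length(missing)) {
      stop_field("genes", paste("not in matrix:",
                                paste(utils::head(missing, 5), collapse = ", ")))
    }
    z <- z[genes, , drop = FALSE]
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop_field("alpha", "must be in (0, 1)")
  }
  eff <- compute_effects(z, design)
  p_perm <- permutation_pvalues(z, design, B = B, mode = mode, seed = seed)
  G <- nrow(z)
  min_p <- if (mode == "pooled") {
    1 / (attr(p_perm, "n_pool") + 1)
  } else if (mode == "per_gene") {
    1 / (attr(p_perm, "B_effective") + 1)
  } else {
    1 / attr(p_perm, "B_effective")
  }
  if (min_p >= alpha / G) {
    warning(sprintf(paste0(
      "permutation resolution too coarse for the Holm cut: smallest ",
      "achievable p is %.3g but alpha/n = %.3g; no gene can be flagged. ",
      "Increase B (needs B >= %d in per-gene mode) or use pooled mode."),
      min_p, alpha / G, ceiling(G / alpha)), call. = FALSE)
  }
  p_holm <- holm_adjust(as.vector(p_perm))
  tab <- eff
  tab$p_perm <- as.vector(p_perm)
  tab$p_holm <- p_holm
  tab$direction <- classify_direction(eff$delta)
  tab$flagged <- p_holm < alpha
  enr <- enrichment_test(sum(tab$p_perm < alpha), G, p0 = alpha)
  structure(
    list(table = tab, enrichment = enr,
         meta = list(B = attr(p_perm, "B"),
                     B_effective = attr(p_perm, "B_effective"),
                     mode = mode, seed = seed, alpha = alpha,
                     n_pool = attr(p_perm, "n_pool"),
                     n_genes = G)),
    class = "synergy_result"
  )
}

#' @export
print.synergy_result <- function(x, ...) {
  tab <- x$table
  cat(sprintf("Deviance-from-additivity test on %d genes (mode = %s, B = %s)\n",
              x$meta$n_genes, x$meta$mode, format(x$meta$B_effective)))
  cat(sprintf("  genes with p_perm < %g: %d\n", x$meta$alpha, x$enrichment$x))
  cat(sprintf("  Holm-flagged: %d (%d positive, %d negative)\n",
              sum(tab$flagged),
              sum(tab$flagged & tab$direction == "positive", na.rm = TRUE),
              sum(tab$flagged & tab$direction == "negative", na.rm = TRUE)))
  print(x$enrichment)
  invisible(x)
}
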