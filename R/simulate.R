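#' Parameters for the synthetic factorial-expression generator
#'
#' Bundles and validates the knobs of [generate_dataset()]. Defaults describe
#' a two-signal quorum-sensing microarray experiment: a genome-scale gene set
#' of which roughly 5\% respond to at least one signal, a small minority of
#' responders carrying a non-additive (interaction) component, duplicate
#' cultures per treatment, and gene-wise residual variances drawn from a
#' heavy-tailed scaled inverse chi-square prior, the distribution assumed by
#' the empirical-Bayes variance moderation used downstream.
#'
#' @param n_genes number of genes.
#' @param n_replicates replicate cultures per treatment (>= 2).
#' @param frac_regulated proportion of genes with a non-zero response to at
#'   least one signal.
#' @param frac_synergistic proportion of *regulated* genes whose response to
#'   the combination carries a non-zero interaction term.
#' @param effect_size_sd standard deviation (log2 units) of the main effects
#'   `beta_A`, `beta_B` of regulated genes.
#' @param synergy_size_sd standard deviation (log2 units) of the interaction
#'   term `gamma` of synergistic genes; ignored when `synergy_snr` is given.
#' @param d0_true,s0sq_true prior degrees of freedom and scale of the scaled
#'   inverse chi-square variance prior: `sigma2_g = d0*s0sq / chisq(d0)`.
#' @param array_distortion apply a sample-specific strictly increasing smooth
#'   (monotone cubic) distortion to each column, emulating between-array
#'   intensity differences that quantile normalization must remove.
#' @param baseline_mean,baseline_sd Normal hyperparameters of the per-gene
#'   baseline expression `mu_g` (log2 scale).
#' @param synergy_snr optional signal-to-noise control for planted
#'   interactions: when non-`NULL`, each synergistic gene gets
#'   `|gamma| = synergy_snr * sigma_g` (random sign) instead of a Normal
#'   draw, so power studies can plant interactions at a fixed multiple of
#'   the gene's own residual SD.
#' @param seed RNG seed; identical parameters (including seed) give
#'   bit-identical datasets. `NULL` uses the ambient RNG stream.
#' @return A validated list of class `simulation_params`.
#' @seealso [generate_dataset()]
#' @export
simulation_params <- function(n_genes = 5570L,
                              n_replicates = 2L,
                              frac_regulated = 0.05,
                              frac_synergistic = 0.07,
                              effect_size_sd = 1,
                              synergy_size_sd = 1,
                              d0_true = 4,
                              s0sq_true = 0.05,
                              array_distortion = TRUE,
                              baseline_mean = 8,
                              baseline_sd = 2,
                              synergy_snr = NULL,
                              seed = NULL) {
  chk_num <- function(x, field, lo = -Inf, hi = Inf, int = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      stop_field(field, "must be a single finite number")
    }
    if (x < lo || x > hi) {
      stop_field(field, sprintf("must be in [%s, %s]", lo, hi))
    }
    if (int && x != round(x)) stop_field(field, "must be an integer")
    x
  }
  p <- list(
    n_genes = as.integer(chk_num(n_genes, "n_genes", lo = 1, int = TRUE)),
    n_replicates = as.integer(chk_num(n_replicates, "n_replicates", lo = 2, int = TRUE)),
    frac_regulated = chk_num(frac_regulated, "frac_regulated", 0, 1),
    frac_synergistic = chk_num(frac_synergistic, "frac_synergistic", 0, 1),
    effect_size_sd = chk_num(effect_size_sd, "effect_size_sd", lo = 0),
    synergy_size_sd = chk_num(synergy_size_sd, "synergy_size_sd", lo = 0),
    d0_true = chk_num(d0_true, "d0_true", lo = .Machine$double.eps),
    s0sq_true = chk_num(s0sq_true, "s0sq_true", lo = .Machine$double.eps),
    array_distortion = isTRUE(array_distortion),
    baseline_mean = chk_num(baseline_mean, "baseline_mean"),
    baseline_sd = chk_num(baseline_sd, "baseline_sd", lo = 0),
    synergy_snr = if (!is.null(synergy_snr)) chk_num(synergy_snr, "synergy_snr", lo = 0),
    seed = if (!is.null(seed)) as.integer(chk_num(seed, "seed", int = TRUE))
  )
  class(p) <- "simulation_params"
  p
}

#' Simulate a four-treatment factorial expression dataset with known truth
#'
#' Generates a genes x samples log2 expression matrix under the additive
#' factorial model
#' \deqn{y_{gi} = \mu_g + \beta_A 1[i \in \{A, both\}] + \beta_B 1[i \in \{B, both\}]
#'   + \gamma 1[i \in both] + \varepsilon_{gi},\qquad
#'   \varepsilon_{gi} \sim N(0, \sigma^2_g),}
#' with \eqn{\sigma^2_g} drawn from a scaled inverse chi-square prior with
#' parameters `(d0_true, s0sq_true)`. A gene is `null` (all effects zero),
#' `additive` (main effects only, \eqn{\gamma = 0}), or synergistic
#' (`synergy_pos` when \eqn{\gamma > 0}: the combined response exceeds the
#' additive sum; `synergy_neg` the reverse). When `array_distortion` is on,
#' each column is passed through its own strictly increasing monotone cubic,
#' strong enough that quantile normalization matters but rank-preserving.
#'
#' @param params a [simulation_params()] object.
#' @return A list of class `combsig_dataset`:
#' \describe{
#'   \item{expression}{numeric matrix, `n_genes` rows x `4 * n_replicates`
#'     columns, gene/sample ids in dimnames.}
#'   \item{design}{data.frame `sample_id`, `treatment`, `replicate`.}
#'   \item{truth}{data.frame `gene_id`, `class`, `beta_A`, `beta_B`,
#'     `gamma`, `sigma2`.}
#' }
#' @examples
#' d <- generate_dataset(simulation_params(n_genes = 100, seed = 1))
#' table(d$truth$class)
#' @export
generate_dataset <- function(params) {
  if (!inherits(params, "simulation_params")) {
    params <- do.call(simulation_params, as.list(params))
  }
  p <- params
  with_local_seed(p$seed, {
    G <- p$n_genes
    r <- p$n_replicates
    N <- 4L * r
    treatment <- factor(rep(TREATMENTS, each = r), levels = TREATMENTS)
    design <- data.frame(
      sample_id = paste(rep(TREATMENTS, each = r), rep(seq_len(r), 4L), sep = "_"),
      treatment = treatment,
      replicate = rep(seq_len(r), 4L),
      stringsAsFactors = FALSE
    )
    gene_id <- sprintf("gene_%05d", seq_len(G))

    ## variance prior: sigma2 = d0 * s0sq / chisq_d0
    sigma2 <- p$d0_true * p$s0sq_true / stats::rchisq(G, df = p$d0_true)

    n_reg <- round(G * p$frac_regulated)
    n_syn <- round(n_reg * p$frac_synergistic)
    cls <- rep("null", G)
    if (n_reg > 0) {
      reg_idx <- sample.int(G, n_reg)
      cls[reg_idx] <- "additive"
      syn_idx <- if (n_syn > 0) reg_idx[seq_len(n_syn)] else integer(0)
    } else {
      reg_idx <- syn_idx <- integer(0)
    }

    beta_A <- beta_B <- gamma <- numeric(G)
    if (n_reg > 0) {
      beta_A[reg_idx] <- stats::rnorm(n_reg, 0, p$effect_size_sd)
      beta_B[reg_idx] <- stats::rnorm(n_reg, 0, p$effect_size_sd)
    }
    if (n_syn > 0) {
      if (is.null(p$synergy_snr)) {
        g <- stats::rnorm(n_syn, 0, p$synergy_size_sd)
        # a zero interaction would contradict the class label; nudge off zero
        g[g == 0] <- p$synergy_size_sd * 1e-8
      } else {
        g <- p$synergy_snr * sqrt(sigma2[syn_idx]) *
          sample(c(-1, 1), n_syn, replace = TRUE)
      }
      gamma[syn_idx] <- g
      cls[syn_idx] <- ifelse(g > 0, "synergy_pos", "synergy_neg")
    }

    mu <- stats::rnorm(G, p$baseline_mean, p$baseline_sd)
    in_A <- as.numeric(treatment %in% c("sigA", "both"))
    in_B <- as.numeric(treatment %in% c("sigB", "both"))
    in_AB <- as.numeric(treatment == "both")
    mean_mat <- mu + outer(beta_A, in_A) + outer(beta_B, in_B) + outer(gamma, in_AB)
    y <- mean_mat + matrix(stats::rnorm(G * N, 0, sqrt(sigma2)), G, N)

    if (p$array_distortion) {
      # per-array strictly increasing cubic: slope in (0.85, 1.15),
      # small non-negative cubic coefficient, additive offset
      for (j in seq_len(N)) {
        b <- stats::runif(1, -0.15, 0.15)
        cc <- stats::runif(1, 0, 0.01)
        a <- stats::rnorm(1, 0, 0.3)
        m <- mean(y[, j])
        x <- y[, j] - m
        y[, j] <- m + a + (1 + b) * x + cc * x^3
      }
    }

    dimnames(y) <- list(gene_id, design$sample_id)
    out <- list(
      expression = y,
      design = design,
      truth = data.frame(
        gene_id = gene_id, class = cls,
        beta_A = beta_A, beta_B = beta_B, gamma = gamma, sigma2 = sigma2,
        stringsAsFactors = FALSE
      ),
      params = p
    )
    class(out) <- "combsig_dataset"
    out
  })
}

#' Confusion counts for the synergy flag against simulated truth
#'
#' Compares flagged status from a synergy analysis with the generator's
#' class labels. A gene counts as a true positive when its class is
#' `synergy_pos` or `synergy_neg` and it was flagged. Genes absent from
#' `table` (e.g. not in the regulated set) count as unflagged.
#'
#' @param truth `truth` data.frame from [generate_dataset()].
#' @param table a `SynergyTable` data.frame with columns `gene_id` and
#'   `flagged` (e.g. `synergy_test(...)$table`).
#' @return named integer vector `c(TP, FP, TN, FN)`; the four counts
#'   partition the truth's gene set.
#' @export
truth_confusion <- function(truth, table) {
  if (!all(c("gene_id", "class") %in% names(truth))) {
    stop_field("truth", "needs columns gene_id and class")
  }
  if (!all(c("gene_id", "flagged") %in% names(table))) {
    stop_field("table", "needs columns gene_id and flagged")
  }
  unknown <- setdiff(table$gene_id, truth$gene_id)
  if (length(unknown)) {
    stop_field("table", paste("gene ids absent from truth:",
                              paste(utils::head(unknown, 5), collapse = ", ")))
  }
  flagged <- truth$gene_id %in% table$gene_id[as.logical(table$flagged)]
  is_syn <- truth$class %in% c("synergy_pos", "synergy_neg")
  c(TP = sum(is_syn & flagged), FP = sum(!is_syn & flagged),
    TN = sum(!is_syn & !flagged), FN = sum(is_syn & !flagged))
}
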