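#' Fit per-gene treatment means in the one-way four-treatment layout
#'
#' Ordinary least squares for the cell-means parameterization: per-gene
#' means for each of the four treatments plus the pooled residual variance
#' `s2` on `N - 4` degrees of freedom.
#'
#' @param m numeric genes x samples matrix (typically quantile-normalized
#'   log2 expression).
#' @param design design table, see [validate_design()]; every treatment
#'   needs at least two samples.
#' @return list of class `group_fit`: `means` (genes x 4 matrix), `s2`,
#'   `df_resid`, `n_per_treatment`, `gene_ids`, `design`.
#' @export
fit_group_means <- function(m, design) {
  check_expression_matrix(m, "m")
  design <- validate_design(design, colnames(m))
  tr <- design$treatment
  n_per <- as.integer(table(tr))
  names(n_per) <- TREATMENTS
  means <- vapply(TREATMENTS, function(t) {
    rowMeans(m[, tr == t, drop = FALSE])
  }, numeric(nrow(m)))
  if (is.null(dim(means))) {
    means <- matrix(means, nrow = 1,
                    dimnames = list(rownames(m), TREATMENTS))
  }
  fitted <- means[, as.integer(tr), drop = FALSE]
  resid <- m - fitted
  df_resid <- ncol(m) - 4L
  s2 <- rowSums(resid^2) / df_resid
  structure(
    list(means = means, s2 = s2, df_resid = df_resid,
         n_per_treatment = n_per, gene_ids = rownames(m), design = design),
    class = "group_fit"
  )
}

#' Empirical-Bayes shrinkage of gene-wise variances
#'
#' Estimates the prior degrees of freedom `d0` and prior scale `s0sq` of a
#' scaled inverse chi-square variance prior by moment matching on the log
#' variances (the digamma/trigamma method of the moderated-t model, via
#' [limma::squeezeVar()]), and returns the posterior (shrunken) variances
#' \deqn{\tilde s^2_g = \frac{d_0 s_0^2 + d\, s^2_g}{d_0 + d}.}
#' When the log-variance dispersion is no larger than expected from the
#' chi-square sampling noise alone, the fit degenerates to `d0 = Inf` and
#' all shrunken variances equal `s0sq`; this is reported via `infinite_d0`.
#'
#' @param s2 per-gene residual variances (>= 0, not all zero).
#' @param df residual degrees of freedom (scalar, >= 1).
#' @return list of class `ebayes_fit`: `d0`, `s0sq`, `s2_tilde`,
#'   `infinite_d0`.
#' @export
ebayes_shrink <- function(s2, df) {
  if (!is.numeric(s2) || length(s2) < 2L) {
    stop_field("s2", "needs at least two gene variances")
  }
  if (any(!is.finite(s2)) || any(s2 < 0)) {
    stop_field("s2", "variances must be finite and non-negative")
  }
  if (all(s2 == 0)) stop_field("s2", "all variances are zero; nothing to estimate")
  if (!is.numeric(df) || length(df) != 1L || df < 1) {
    stop_field("df", "must be a single value >= 1")
  }
  sq <- limma::squeezeVar(s2, df = df)
  d0 <- sq$df.prior
  structure(
    list(d0 = d0, s0sq = sq$var.prior, s2_tilde = sq$var.post,
         infinite_d0 = !is.finite(d0)),
    class = "ebayes_fit"
  )
}

#' Attach empirical-Bayes moderation to a group fit
#'
#' Convenience wrapper: runs [ebayes_shrink()] on the fit's residual
#' variances and stores the result, after which [moderated_t()] and
#' [select_regulated()] can be used.
#'
#' @param fit a `group_fit` from [fit_group_means()].
#' @return the fit with elements `d0`, `s0sq`, `s2_tilde`, `infinite_d0`.
#' @export
ebayes_moderate <- function(fit) {
  if (!inherits(fit, "group_fit")) stop_field("fit", "must be a group_fit")
  eb <- ebayes_shrink(fit$s2, fit$df_resid)
  fit[c("d0", "s0sq", "s2_tilde", "infinite_d0")] <-
    eb[c("d0", "s0sq", "s2_tilde", "infinite_d0")]
  fit
}

CONTRASTS <- c("sigA", "sigB", "both")

#' Moderated t-statistics for a treatment-vs-control contrast
#'
#' For contrast `T - control`, computes
#' `t = beta_hat / (s_tilde * u)` with `u = sqrt(1/n_T + 1/n_control)` and
#' two-sided p-values from a Student t distribution on `d0 + df_resid`
#' degrees of freedom (standard Normal in the `d0 = Inf` limit). With
#' `d0 = 0` this reduces to the ordinary t-statistic.
#'
#' @param fit a moderated `group_fit` (see [ebayes_moderate()]).
#' @param contrast one of `"sigA"`, `"sigB"`, `"both"`.
#' @return data.frame `gene_id`, `beta`, `t`, `p`.
#' @export
moderated_t <- function(fit, contrast) {
  if (!inherits(fit, "group_fit") || is.null(fit$s2_tilde)) {
    stop_field("fit", "must be a group_fit with moderation attached (ebayes_moderate)")
  }
  if (!is.character(contrast) || length(contrast) != 1L ||
      !contrast %in% CONTRASTS) {
    stop_field("contrast", sprintf("unknown contrast; expected one of %s",
                                   paste(CONTRASTS, collapse = ", ")))
  }
  n <- fit$n_per_treatment
  u <- sqrt(1 / n[[contrast]] + 1 / n[["control"]])
  beta <- fit$means[, contrast] - fit$means[, "control"]
  tt <- beta / (sqrt(fit$s2_tilde) * u)
  df_total <- fit$d0 + fit$df_resid
  p <- if (is.finite(df_total)) {
    2 * stats::pt(-abs(tt), df = df_total)
  } else {
    2 * stats::pnorm(-abs(tt))
  }
  # beta = 0 must give p = 1 exactly, also when s2_tilde = 0 makes t NaN
  zero <- beta == 0
  tt[zero] <- 0
  p[zero] <- 1
  data.frame(gene_id = fit$gene_ids, beta = beta, t = tt, p = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment (wraps
#' [stats::p.adjust()] with input validation): monotone, capped at 1,
#' returned in the original order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted values (q-values), same length and order.
#' @export
bh_fdr <- function(p) {
  check_pvalues(p)
  stats::p.adjust(p, method = "BH")
}

check_pvalues <- function(p, arg = "p") {
  if (!is.numeric(p) || length(p) < 1L) stop_field(arg, "must be a numeric vector")
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop_field(arg, "p-values must lie in [0, 1]")
  }
  invisible(p)
}

#' Select the regulated gene set
#'
#' A gene is *regulated* when its FDR-adjusted p-value is below `alpha` in
#' at least one of the three treatment-vs-control contrasts. By default each
#' contrast is its own BH family (`fdr_family = "per_contrast"`); with
#' `"global"` all three p-value vectors are adjusted as one family.
#'
#' @param fit moderated `group_fit`.
#' @param alpha FDR threshold (default 0.05).
#' @param fdr_family `"per_contrast"` or `"global"`.
#' @return list of class `regulated_set`: `table` (per-gene beta/t/p/q for
#'   each contrast, `regulated` flag and the triggering contrasts),
#'   `gene_ids` (the regulated genes), `alpha`, `fdr_family`.
#' @export
select_regulated <- function(fit, alpha = 0.05,
                             fdr_family = c("per_contrast", "global")) {
  fdr_family <- match.arg(fdr_family)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop_field("alpha", "must be in (0, 1)")
  }
  res <- lapply(CONTRASTS, function(ct) moderated_t(fit, ct))
  names(res) <- CONTRASTS
  if (fdr_family == "per_contrast") {
    q <- lapply(res, function(r) bh_fdr(r$p))
  } else {
    allq <- bh_fdr(unlist(lapply(res, `[[`, "p"), use.names = FALSE))
    idx <- split(seq_along(allq),
                 rep(seq_along(res), each = length(fit$gene_ids)))
    q <- lapply(idx, function(i) allq[i])
    names(q) <- CONTRASTS
  }
  sig <- sapply(CONTRASTS, function(ct) q[[ct]] < alpha)
  if (is.null(dim(sig))) sig <- matrix(sig, nrow = 1, dimnames = list(NULL, CONTRASTS))
  regulated <- rowSums(sig) > 0
  tab <- data.frame(gene_id = fit$gene_ids, stringsAsFactors = FALSE)
  for (ct in CONTRASTS) {
    tab[[paste0("beta_", ct)]] <- res[[ct]]$beta
    tab[[paste0("t_", ct)]] <- res[[ct]]$t
    tab[[paste0("p_", ct)]] <- res[[ct]]$p
    tab[[paste0("q_", ct)]] <- q[[ct]]
  }
  tab$regulated <- regulated
  tab$contrasts <- apply(sig, 1L, function(s) paste(CONTRASTS[s], collapse = ","))
  structure(
    list(table = tab, gene_ids = fit$gene_ids[regulated],
         alpha = alpha, fdr_family = fdr_family,
         s2 = fit$s2, s2_tilde = fit$s2_tilde, d0 = fit$d0, s0sq = fit$s0sq),
    class = "regulated_set"
  )
}
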