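#' Quantile-normalize expression columns
#'
#' Forces every sample (column) onto the same empirical distribution: the
#' across-column mean of order statistics. Tied values within a column
#' receive the mean of the reference values they span. Row and column
#' labels are preserved, and within-column rank order is unchanged.
#' The computation is delegated to [limma::normalizeQuantiles()].
#'
#' @param m numeric genes x samples matrix with dimnames; all values finite.
#' @return matrix of the same shape; all column means equal.
#' @export
quantile_normalize <- function(m) {
  check_expression_matrix(m, "m")
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Standardize each gene to mean 0, SD 1
#'
#' Centres and scales every gene (row) over *all* samples pooled, using the
#' sample (n - 1) standard deviation, so that downstream treatment effects
#' are expressed in units of the gene's own standard deviation. Genes with
#' zero variance cannot be standardized; they are excluded with a warning
#' and recorded in the `excluded_genes` attribute of the result rather than
#' silently dropped.
#'
#' @param m numeric genes x samples matrix with dimnames.
#' @return standardized matrix (possibly fewer rows), with attribute
#'   `excluded_genes`: character vector of zero-variance gene ids.
#' @export
per_gene_standardize <- function(m) {
  check_expression_matrix(m, "m")
  n <- ncol(m)
  ctr <- m - rowMeans(m)
  sdev <- sqrt(rowSums(ctr^2) / (n - 1))
  zero <- sdev == 0
  if (any(zero)) {
    warning(sprintf("excluding %d zero-variance gene(s): %s",
                    sum(zero),
                    paste(utils::head(rownames(m)[zero], 5), collapse = ", ")),
            call. = FALSE)
    ctr <- ctr[!zero, , drop = FALSE]
    sdev <- sdev[!zero]
  }
  out <- ctr / sdev
  attr(out, "excluded_genes") <- rownames(m)[zero]
  out
}
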