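#' Run the full combinatorial-response pipeline
#'
#' Executes the stages in order: quantile normalization, moderated-t
#' differential expression against the control (union over the three
#' signal-addition contrasts at FDR `alpha_de`), per-gene standardization,
#' and the permutation deviance-from-additivity test with Holm correction
#' and binomial enrichment on the regulated set. All randomness flows from
#' one stream seeded once with `seed`, so identical inputs and
#' configuration give identical outputs.
#'
#' @param expression genes x samples matrix, or path to an expression TSV.
#' @param design design table, or path to a design TSV.
#' @param alpha_de FDR threshold defining the regulated set.
#' @param alpha_synergy threshold for the per-gene permutation cut and the
#'   Holm family.
#' @param B permutation count per gene.
#' @param mode permutation null mode, see [permutation_pvalues()].
#' @param seed run-level RNG seed.
#' @param fdr_family `"per_contrast"` or `"global"`, see
#'   [select_regulated()].
#' @param out_dir optional directory; when given, stage outputs are written
#'   there (`diffexpr.tsv`, `synergy.tsv`, `fig2.tsv`, `enrichment.json`,
#'   `report.json`).
#' @return list of class `combsig_report`: `counts` (genes in, excluded,
#'   regulated, flagged, positive/negative split), `enrichment`, `synergy`
#'   (full [synergy_test()] result), `regulated` (full
#'   [select_regulated()] result), `fig2` (per-gene deviation report),
#'   `excluded_genes`, and `meta` (thresholds, B, mode, seed, package
#'   version).
#' @export
run_pipeline <- function(expression, design,
                         alpha_de = 0.05, alpha_synergy = 0.05,
                         B = 10000,
                         mode = c("pooled", "per_gene", "exact_per_gene"),
                         seed = NULL,
                         fdr_family = c("per_contrast", "global"),
                         out_dir = NULL) {
  mode <- match.arg(mode)
  fdr_family <- match.arg(fdr_family)
  if (is.character(expression)) expression <- read_expression_tsv(expression)
  if (is.character(design)) design <- read_design_tsv(design)
  check_expression_matrix(expression, "expression")
  design <- validate_design(design, colnames(expression))

  with_local_seed(seed, {
    norm <- quantile_normalize(expression)
    fit <- ebayes_moderate(fit_group_means(norm, design))
    reg <- select_regulated(fit, alpha = alpha_de, fdr_family = fdr_family)
    z <- per_gene_standardize(norm)
    excluded <- attr(z, "excluded_genes")
    genes <- setdiff(reg$gene_ids, excluded)
    if (length(genes) == 0L) {
      syn <- NULL
    } else {
      syn <- synergy_test(z, design, genes = genes, B = B, mode = mode,
                          seed = NULL, alpha = alpha_synergy)
    }
    tab <- if (is.null(syn)) NULL else syn$table
    counts <- list(
      n_genes = nrow(expression),
      n_excluded = length(excluded),
      n_regulated = length(reg$gene_ids),
      n_tested = if (is.null(tab)) 0L else nrow(tab),
      n_flagged = if (is.null(tab)) 0L else sum(tab$flagged),
      n_positive = if (is.null(tab)) 0L else
        sum(tab$flagged & tab$direction == "positive", na.rm = TRUE),
      n_negative = if (is.null(tab)) 0L else
        sum(tab$flagged & tab$direction == "negative", na.rm = TRUE)
    )
    report <- structure(
      list(counts = counts,
           enrichment = if (is.null(syn)) NULL else syn$enrichment,
           synergy = syn, regulated = reg,
           fig2 = if (is.null(syn)) NULL else fig2_table(syn$table),
           excluded_genes = excluded,
           meta = list(alpha_de = alpha_de, alpha_synergy = alpha_synergy,
                       B = B, mode = mode, seed = seed,
                       fdr_family = fdr_family,
                       package_version = as.character(utils::packageVersion("combsig")))),
      class = "combsig_report"
    )
    if (!is.null(out_dir)) write_report(report, out_dir)
    report
  })
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_table_tsv(report$regulated$table, file.path(out_dir, "diffexpr.tsv"))
  if (!is.null(report$synergy)) {
    write_table_tsv(report$synergy$table, file.path(out_dir, "synergy.tsv"))
    write_table_tsv(report$fig2, file.path(out_dir, "fig2.tsv"))
    jsonlite::write_json(unclass(report$enrichment),
                         file.path(out_dir, "enrichment.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(
    list(counts = report$counts, meta = report$meta,
         excluded_genes = as.list(report$excluded_genes)),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' Per-gene deviation report (expression-profile figure data)
#'
#' One row per tested gene: the deviation `delta` of the combined response
#' from the summed single-signal expectation (SD units), its direction and
#' flagged status — the data behind the classic profile plot where each
#' regulated gene is a point around the additive expectation at 0 and
#' flagged genes are highlighted. A histogram of the deltas is attached as
#' attribute `histogram` (`breaks`, `counts`).
#'
#' @param table a `SynergyTable` data.frame (from [synergy_test()]).
#' @return data.frame `gene_id`, `delta`, `direction`, `flagged`, sorted by
#'   `delta`, with attribute `histogram`.
#' @export
fig2_table <- function(table) {
  need <- c("gene_id", "delta", "direction", "flagged")
  if (!all(need %in% names(table))) {
    stop_field("table", paste("needs columns", paste(need, collapse = ", ")))
  }
  out <- table[order(table$delta), need]
  rownames(out) <- NULL
  h <- graphics::hist(out$delta, breaks = "Sturges", plot = FALSE)
  attr(out, "histogram") <- list(breaks = h$breaks, counts = h$counts)
  out
}

#' Plot the deviation-from-additivity profile
#'
#' Points are the per-gene deviations from the summed expectation (dotted
#' line at 0), filled black when Holm-flagged; the right margin shows the
#' marginal histogram of deviations.
#'
#' @param x a `synergy_result` or a `combsig_report`.
#' @param ... ignored.
#' @export
plot_fig2 <- function(x, ...) {
  tab <- if (inherits(x, "combsig_report")) x$synergy$table else x$table
  if (is.null(tab)) stop_field("x", "no synergy table to plot")
  tab <- tab[order(tab$delta), ]
  old <- graphics::par(no.readonly = TRUE)
  on.exit(graphics::par(old))
  graphics::layout(matrix(1:2, 1, 2), widths = c(4, 1))
  graphics::par(mar = c(4, 4, 1, 0))
  graphics::plot(seq_len(nrow(tab)), tab$delta,
                 pch = 21, bg = ifelse(tab$flagged, "black", "white"),
                 xlab = "genes (ordered)",
                 ylab = "observed - summed expectation (SD units)")
  graphics::abline(h = 0, lty = 3)
  graphics::par(mar = c(4, 0, 1, 1))
  h <- graphics::hist(tab$delta, breaks = "Sturges", plot = FALSE)
  graphics::barplot(h$counts, horiz = TRUE, space = 0, axes = FALSE)
  invisible(x)
}

#' @export
print.combsig_report <- function(x, ...) {
  c <- x$counts
  cat("Combinatorial-response pipeline report\n")
  cat(sprintf("  genes: %d (excluded zero-variance: %d)\n", c$n_genes, c$n_excluded))
  cat(sprintf("  regulated (FDR < %g in >= 1 contrast): %d\n",
              x$meta$alpha_de, c$n_regulated))
  cat(sprintf("  flagged non-additive (Holm < %g): %d (%d positive, %d negative)\n",
              x$meta$alpha_synergy, c$n_flagged, c$n_positive, c$n_negative))
  if (!is.null(x$enrichment)) print(x$enrichment)
  invisible(x)
}

#' Read a pipeline configuration from YAML
#'
#' Thin helper mapping a YAML file of [run_pipeline()] arguments (paths and
#' thresholds) to a named list: `do.call(run_pipeline, read_run_config(f))`.
#'
#' @param path YAML file path.
#' @return named list of arguments.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the 'yaml' package is required to read YAML configs", call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  allowed <- names(formals(run_pipeline))
  bad <- setdiff(names(cfg), allowed)
  if (length(bad)) {
    stop_field("config", paste("unknown field(s):", paste(bad, collapse = ", ")))
  }
  cfg
}

#' Write a simulated dataset to a directory as TSV files
#'
#' Writes `expression.tsv`, `design.tsv` and `truth.tsv` in the package's
#' interchange formats.
#'
#' @param dataset a `combsig_dataset` from [generate_dataset()].
#' @param dir output directory (created if needed).
#' @export
write_dataset <- function(dataset, dir) {
  if (!inherits(dataset, "combsig_dataset")) {
    stop_field("dataset", "must be a combsig_dataset")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression_tsv(dataset$expression, file.path(dir, "expression.tsv"))
  write_design_tsv(dataset$design, file.path(dir, "design.tsv"))
  write_table_tsv(dataset$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
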