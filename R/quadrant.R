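#' Load a dual-contrast differential-expression gene table
#'
#' Reads a CSV/TSV of per-gene statistics for the two contrasts the quadrant
#' analysis needs — microbial status (CV vs GF, within EECs) and cell fate
#' (EEC vs other intestinal epithelial cells) — mapping arbitrary column names
#' through `columns`. Rows with a missing fold change on either axis are
#' dropped with a message; duplicate gene ids are an error.
#'
#' @param path CSV or TSV file (delimiter guessed from content).
#' @param columns Named list mapping the required fields `gene`, `log2fc_cv`,
#'   `padj_cv`, `log2fc_eec`, `padj_eec` to column names in the file.
#' @return A tibble of class `eec_gene_table`.
#' @export
load_gene_table <- function(path,
                            columns = list(gene = "gene",
                                           log2fc_cv = "log2fc_cv",
                                           padj_cv = "padj_cv",
                                           log2fc_eec = "log2fc_eec",
                                           padj_eec = "padj_eec")) {
  required <- c("gene", "log2fc_cv", "padj_cv", "log2fc_eec", "padj_eec")
  missing_map <- setdiff(required, names(columns))
  if (length(missing_map)) {
    rlang::abort(paste("column map is missing:", paste(missing_map, collapse = ", ")))
  }
  raw <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE)
  for (f in required) {
    if (!columns[[f]] %in% names(raw)) {
      rlang::abort(sprintf("required column `%s` (mapped to field `%s`) not in file",
                           columns[[f]], f))
    }
  }
  tab <- tibble::tibble(
    gene = as.character(raw[[columns$gene]]),
    log2fc_cv = as.numeric(raw[[columns$log2fc_cv]]),
    padj_cv = as.numeric(raw[[columns$padj_cv]]),
    log2fc_eec = as.numeric(raw[[columns$log2fc_eec]]),
    padj_eec = as.numeric(raw[[columns$padj_eec]]))
  if (anyDuplicated(tab$gene)) rlang::abort("duplicate gene ids in table")
  drop <- is.na(tab$log2fc_cv) | is.na(tab$log2fc_eec)
  if (any(drop)) {
    rlang::inform(sprintf("dropping %d row(s) with missing fold changes", sum(drop)))
    tab <- tab[!drop, , drop = FALSE]
  }
  bad_p <- c(tab$padj_cv, tab$padj_eec)
  bad_p <- bad_p[!is.na(bad_p)]
  if (any(bad_p < 0 | bad_p > 1)) rlang::abort("adjusted p-values outside [0, 1]")
  class(tab) <- c("eec_gene_table", class(tab))
  tab
}

#' Quadrant statistics of the dual-contrast fold changes
#'
#' Among genes significant on the microbial contrast (`padj_cv < alpha`),
#' counts the four sign quadrants of (CV-vs-GF, EEC-vs-IEC) fold change and
#' reports the headline percentage: of the significantly CV-upregulated
#' genes, the share that is EEC-enriched (positive EEC-vs-IEC fold change).
#' With `strict = TRUE`, EEC enrichment additionally requires
#' `padj_eec < alpha`.
#'
#' @param table An `eec_gene_table`.
#' @param alpha Significance level on the CV contrast (default 0.05).
#' @param strict Require significance on the EEC axis too?
#' @return An `eec_quadrant` list: `counts` (tibble of the four quadrants),
#'   `pct_cv_up_eec_enriched`, `n_significant`, `alpha`, `strict`. Use
#'   [tidy()] / [glance()] for tabular access.
#' @export
quadrant_fractions <- function(table, alpha = 0.05, strict = FALSE) {
  if (!nrow(table)) rlang::abort("gene table is empty")
  sig <- !is.na(table$padj_cv) & table$padj_cv < alpha
  s <- table[sig, , drop = FALSE]
  enriched <- s$log2fc_eec > 0
  if (strict) enriched <- enriched & !is.na(s$padj_eec) & s$padj_eec < alpha
  counts <- tibble::tibble(
    cv_direction = rep(c("up", "up", "down", "down"), 1),
    eec_direction = rep(c("enriched", "depleted"), 2),
    n = c(sum(s$log2fc_cv > 0 & enriched),
          sum(s$log2fc_cv > 0 & !enriched),
          sum(s$log2fc_cv <= 0 & enriched),
          sum(s$log2fc_cv <= 0 & !enriched)))
  n_up <- sum(s$log2fc_cv > 0)
  pct <- if (n_up == 0) {
    rlang::warn("no significantly CV-upregulated genes: percentage undefined")
    NA_real_
  } else {
    100 * counts$n[1] / n_up
  }
  structure(list(counts = counts, pct_cv_up_eec_enriched = pct,
                 n_significant = nrow(s), alpha = alpha, strict = strict),
            class = "eec_quadrant")
}

#' @export
print.eec_quadrant <- function(x, ...) {
  cat(sprintf("<eec_quadrant> %d significant genes (alpha %.3g%s)\n",
              x$n_significant, x$alpha, if (x$strict) ", strict" else ""))
  cat(sprintf("  CV-up genes EEC-enriched: %.1f%%\n", x$pct_cv_up_eec_enriched))
  invisible(x)
}

#' @export
tidy.eec_quadrant <- function(x, ...) x$counts

#' @export
glance.eec_quadrant <- function(x, ...) {
  tibble::tibble(pct_cv_up_eec_enriched = x$pct_cv_up_eec_enriched,
                 n_significant = x$n_significant,
                 alpha = x$alpha, strict = x$strict)
}

#' Upregulation of conserved signature genes
#'
#' Percentage of the conserved EEC signature genes, among those present in the
#' table, whose CV-vs-GF fold change is positive. Signature genes absent from
#' the table are excluded from the denominator and reported.
#'
#' @param table An `eec_gene_table`.
#' @param signature Character vector of signature gene ids, or `NULL` to use
#'   the table's own `signature` column (as produced by [generate_de_table()]).
#' @return A list: `pct_upregulated`, `n_signature`, `n_found`, `missing`.
#' @export
signature_upregulation <- function(table, signature = NULL) {
  if (is.null(signature)) {
    if (!"signature" %in% names(table)) {
      rlang::abort("no `signature` column and no signature ids given")
    }
    signature <- table$gene[table$signature]
  }
  if (!length(signature)) rlang::abort("signature list is empty")
  found <- intersect(signature, table$gene)
  if (!length(found)) rlang::abort("no signature gene overlaps the table")
  sub <- table[table$gene %in% found, , drop = FALSE]
  list(pct_upregulated = 100 * mean(sub$log2fc_cv > 0),
       n_signature = length(signature), n_found = length(found),
       missing = setdiff(signature, table$gene))
}

#' Correlation between the two fold-change axes
#'
#' Pearson correlation, with two-sided test, of the CV-vs-GF fold change
#' against the EEC-vs-IEC fold change over all genes.
#'
#' @param table An `eec_gene_table` (>= 3 genes).
#' @return A tibble: `r`, `p_value`, `n`.
#' @export
de_axis_correlation <- function(table) {
  d <- table[complete.cases(table[, c("log2fc_cv", "log2fc_eec")]), ]
  if (nrow(d) < 3L) rlang::abort("need at least 3 genes")
  if (sd(d$log2fc_cv) == 0 || sd(d$log2fc_eec) == 0) {
    rlang::warn("constant fold-change column: correlation undefined")
    return(tibble::tibble(r = NA_real_, p_value = NA_real_, n = nrow(d)))
  }
  ct <- cor.test(d$log2fc_cv, d$log2fc_eec, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(d))
}
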