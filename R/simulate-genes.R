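#' Generate a synthetic dual-contrast differential-expression gene table
#'
#' Builds a gene table with the statistical structure the quadrant analysis
#' expects: one log2 fold change per gene for the microbial contrast
#' (conventionalized vs germ-free, measured in EECs) and one for the cell-fate
#' contrast (EEC vs other intestinal epithelial cells), with adjusted p-values
#' for both. Quadrant membership among the significantly CV-regulated genes is
#' assigned by exact counts, so the requested fractions are recovered exactly
#' after rounding; the overall correlation between the two fold-change columns
#' is tuned by root-finding the latent correlation of the remaining genes
#' against the empirical Pearson r.
#'
#' A conserved EEC signature subset is marked in the `signature` column, with
#' exactly `round(signature_frac_up * n_signature)` of its members CV-upregulated.
#'
#' @param n_genes Number of genes (>= 10).
#' @param frac_cv_sig Fraction of genes significant on the CV-vs-GF contrast.
#' @param frac_cv_up Fraction of the significant genes that are CV-upregulated.
#' @param frac_cv_up_eec_enriched Fraction of significant CV-up genes that are
#'   EEC-enriched (positive EEC-vs-IEC fold change).
#' @param signature_frac_up Fraction of signature genes that are CV-upregulated.
#' @param n_signature Number of conserved signature genes.
#' @param axis_correlation Target Pearson correlation between the two
#'   fold-change columns (|r| <= 1), achieved within about +/-0.02.
#' @param seed Integer seed; same seed, same table.
#' @return A tibble (`gene`, `log2fc_cv`, `padj_cv`, `log2fc_eec`, `padj_eec`,
#'   `signature`) of class `eec_gene_table`.
#' @examples
#' tab <- generate_de_table(n_genes = 500, frac_cv_up_eec_enriched = 0.75, seed = 1)
#' quadrant_fractions(tab)$pct_cv_up_eec_enriched  # 75
#' @export
generate_de_table <- function(n_genes = 5000,
                              frac_cv_sig = 0.3,
                              frac_cv_up = 0.5,
                              frac_cv_up_eec_enriched = 0.745,
                              signature_frac_up = 0.72,
                              n_signature = 100,
                              axis_correlation = 0.3,
                              seed = 1L) {
  if (n_genes < 10) rlang::abort("`n_genes` must be >= 10")
  for (p in c("frac_cv_sig", "frac_cv_up", "frac_cv_up_eec_enriched",
              "signature_frac_up")) {
    .check_prob(get(p), p)
  }
  if (abs(axis_correlation) > 1) rlang::abort("|axis_correlation| must be <= 1")
  set.seed(.derive_seed(seed, "genes"))

  n_sig <- round(frac_cv_sig * n_genes)
  n_sig_up <- round(frac_cv_up * n_sig)
  n_sig_dn <- n_sig - n_sig_up
  n_up_enr <- round(frac_cv_up_eec_enriched * n_sig_up)

  lfc_cv <- numeric(n_genes)
  lfc_eec <- numeric(n_genes)
  sig <- rep(FALSE, n_genes)
  idx_up <- seq_len(n_sig_up)
  idx_dn <- seq_len(n_sig_dn) + n_sig_up
  sig[seq_len(n_sig)] <- TRUE

  # significant genes: magnitudes drawn, EEC-axis signs assigned by exact count
  lfc_cv[idx_up] <- abs(rnorm(n_sig_up, 1, 0.6)) + 0.1
  lfc_cv[idx_dn] <- -(abs(rnorm(n_sig_dn, 1, 0.6)) + 0.1)
  eec_mag_up <- abs(rnorm(n_sig_up, 0.8, 0.5)) + 0.05
  sign_up <- rep(c(1, -1), c(n_up_enr, n_sig_up - n_up_enr))[sample.int(n_sig_up)]
  lfc_eec[idx_up] <- eec_mag_up * sign_up
  lfc_eec[idx_dn] <- rnorm(n_sig_dn, 0, 0.8)

  # remaining genes: bivariate normal with latent correlation chosen so the
  # whole-table Pearson r hits the target
  n_rest <- n_genes - n_sig
  if (n_rest > 2) {
    u <- rnorm(n_rest, 0, 0.8)
    e <- rnorm(n_rest, 0, 0.8)
    lfc_cv[seq_len(n_rest) + n_sig] <- u
    fill <- function(rho) {
      v <- rho * u + sqrt(max(0, 1 - rho^2)) * e
      lfc_eec[seq_len(n_rest) + n_sig] <- v
      lfc_eec
    }
    obj <- function(rho) cor(lfc_cv, fill(rho)) - axis_correlation
    lo <- obj(-1); hi <- obj(1)
    if (lo > 0) {
      lfc_eec <- fill(-1)
    } else if (hi < 0) {
      lfc_eec <- fill(1)
    } else {
      rho <- stats::uniroot(obj, c(-1, 1), tol = 1e-6)$root
      lfc_eec <- fill(rho)
    }
  }

  padj_cv <- ifelse(sig, runif(n_genes, 0, 0.045), runif(n_genes, 0.06, 1))
  padj_eec <- pmin(1, pmax(0, 10^(-2 * abs(lfc_eec)) * runif(n_genes, 0.5, 1.5)))

  # conserved signature: pick genes so the CV-up share is exact by count
  n_signature <- min(n_signature, n_genes)
  n_sig_up_genes <- round(signature_frac_up * n_signature)
  up_pool <- which(lfc_cv > 0)
  dn_pool <- which(lfc_cv <= 0)
  if (length(up_pool) < n_sig_up_genes ||
      length(dn_pool) < n_signature - n_sig_up_genes) {
    rlang::abort("cannot satisfy `signature_frac_up` with this table composition")
  }
  sig_genes <- c(sample(up_pool, n_sig_up_genes),
                 sample(dn_pool, n_signature - n_sig_up_genes))

  ord <- sample.int(n_genes)  # shuffle so quadrant membership is not positional
  tab <- tibble::tibble(
    gene = sprintf("gene%05d", seq_len(n_genes)),
    log2fc_cv = lfc_cv[ord],
    padj_cv = padj_cv[ord],
    log2fc_eec = lfc_eec[ord],
    padj_eec = padj_eec[ord],
    signature = ord %in% sig_genes
  )
  class(tab) <- c("eec_gene_table", class(tab))
  tab
}
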