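write_gene_csv <- function(df, path = withr::local_tempfile(fileext = ".csv",
                                                            .local_envir = parent.frame())) {
  readr::write_csv(df, path)
  path
}

test_that("gene tables load through the column map with validation", {
  df <- data.frame(id = paste0("g", 1:5), fc_cv = c(1, -1, 2, 0.5, -0.2),
                   p_cv = c(0.01, 0.2, 0.03, 0.5, 0.04),
                   fc_eec = c(2, 1, -1, 0.3, 0.8),
                   p_eec = c(0.1, 0.2, 0.3, 0.4, 0.5))
  map <- list(gene = "id", log2fc_cv = "fc_cv", padj_cv = "p_cv",
              log2fc_eec = "fc_eec", padj_eec = "p_eec")
  tab <- load_gene_table(write_gene_csv(df), map)
  expect_equal(nrow(tab), 5L)
  expect_s3_class(tab, "eec_gene_table")

  df_na <- df
  df_na$fc_cv[2] <- NA
  expect_message(tab2 <- load_gene_table(write_gene_csv(df_na), map),
                 "dropping 1")
  expect_equal(nrow(tab2), 4L)

  df_dup <- df
  df_dup$id[2] <- "g1"
  expect_error(load_gene_table(write_gene_csv(df_dup), map), "duplicate")

  expect_error(load_gene_table(write_gene_csv(df),
                               utils::modifyList(map, list(padj_cv = "nope"))),
               "nope")
})

test_that("quadrant fractions follow the hand-counted definition", {
  # 4 significant CV-up genes, 3 EEC-enriched -> 75%
  tab <- tibble::tibble(
    gene = paste0("g", 1:6),
    log2fc_cv = c(1, 2, 0.5, 1.5, -1, 1),
    padj_cv = c(0.01, 0.01, 0.01, 0.01, 0.01, 0.9),
    log2fc_eec = c(1, 2, 0.1, -1, 1, -5),
    padj_eec = rep(0.01, 6))
  class(tab) <- c("eec_gene_table", class(tab))
  q <- quadrant_fractions(tab)
  expect_equal(q$pct_cv_up_eec_enriched, 75)
  expect_equal(q$n_significant, 5L)
  expect_equal(sum(q$counts$n), 5L)
  expect_equal(q$counts$n[1], 3L)

  all_up <- tab
  all_up$log2fc_eec <- abs(all_up$log2fc_eec)
  expect_equal(quadrant_fractions(all_up)$pct_cv_up_eec_enriched, 100)

  none <- tab
  none$log2fc_cv <- -abs(none$log2fc_cv)
  expect_warning(q0 <- quadrant_fractions(none), "undefined")
  expect_true(is.na(q0$pct_cv_up_eec_enriched))
})

test_that("strict mode additionally screens the EEC axis", {
  tab <- tibble::tibble(
    gene = paste0("g", 1:4),
    log2fc_cv = c(1, 1, 1, 1),
    padj_cv = rep(0.01, 4),
    log2fc_eec = c(1, 1, 1, -1),
    padj_eec = c(0.01, 0.01, 0.5, 0.01))
  class(tab) <- c("eec_gene_table", class(tab))
  expect_equal(quadrant_fractions(tab)$pct_cv_up_eec_enriched, 75)
  expect_equal(quadrant_fractions(tab, strict = TRUE)$pct_cv_up_eec_enriched, 50)
})

test_that("signature upregulation counts only genes present in the table", {
  tab <- tibble::tibble(
    gene = paste0("g", 1:10),
    log2fc_cv = c(rep(1, 7), rep(-1, 3)),
    padj_cv = rep(0.01, 10),
    log2fc_eec = rep(1, 10),
    padj_eec = rep(0.01, 10))
  class(tab) <- c("eec_gene_table", class(tab))
  s <- signature_upregulation(tab, paste0("g", 1:10))
  expect_equal(s$pct_upregulated, 70)

  s2 <- signature_upregulation(tab, c(paste0("g", 1:7), "absent1", "absent2"))
  expect_equal(s2$pct_upregulated, 100)
  expect_equal(s2$missing, c("absent1", "absent2"))
  expect_error(signature_upregulation(tab, c("x", "y")), "overlap")
})

test_that("axis correlation behaves under collinearity and sign flips", {
  tab <- tibble::tibble(gene = paste0("g", 1:20),
                        log2fc_cv = seq(-2, 2, length.out = 20),
                        padj_cv = rep(0.5, 20),
                        log2fc_eec = 2 * seq(-2, 2, length.out = 20),
                        padj_eec = rep(0.5, 20))
  class(tab) <- c("eec_gene_table", class(tab))
  expect_equal(de_axis_correlation(tab)$r, 1)
  flipped <- tab
  flipped$log2fc_eec <- -flipped$log2fc_eec
  expect_equal(de_axis_correlation(flipped)$r, -1)
  expect_error(de_axis_correlation(tab[1:2, ]), "at least 3")
})

test_that("generator round trip recovers the requested statistics", {
  tab <- generate_de_table(n_genes = 4000, frac_cv_up_eec_enriched = 0.745,
                           signature_frac_up = 0.72, axis_correlation = 0.3,
                           seed = 77)
  expect_equal(quadrant_fractions(tab)$pct_cv_up_eec_enriched,
               74.5, tolerance = 0.002)
  expect_equal(signature_upregulation(tab)$pct_upregulated, 72)
  expect_lt(abs(de_axis_correlation(tab)$r - 0.3), 0.05)
  # quadrant counts sum to the significance screen, percentages in range
  q <- quadrant_fractions(tab)
  expect_equal(sum(q$counts$n), q$n_significant)
  expect_true(q$pct_cv_up_eec_enriched >= 0 && q$pct_cv_up_eec_enriched <= 100)
})
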