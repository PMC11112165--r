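#' Classify cells as spontaneously active or quiet
#'
#' A cell counts as active when its t0-normalized cytoplasmic trace exceeds
#' `1 + fluctuation_threshold` for at least `min_frames_above` consecutive
#' frames. The paper-style "active" call is shown only graphically in the
#' source experiments; the default operationalization (threshold 0.2,
#' persistence 2 frames) matches the scale of low-amplitude spontaneous
#' firing, and both knobs are exposed.
#'
#' @param traces A normalized `eec_traces` (see [normalize_traces()]; the
#'   normalization is applied here if the `cyto_norm` column is missing).
#' @param fluctuation_threshold Relative excursion above baseline.
#' @param min_frames_above Consecutive frames the excursion must persist.
#' @param frames Optional 0-based frame window to evaluate (e.g. pre-stimulus).
#' @return A tibble of class `eec_activity`: `cell`, `frames_above` (longest
#'   consecutive run), `active`; the active percentage is available via
#'   [glance()].
#' @export
classify_spontaneous <- function(traces, fluctuation_threshold = 0.2,
                                 min_frames_above = 2L, frames = NULL) {
  traces <- .ensure_norm(traces)
  if (!is.null(frames)) traces <- traces[traces$frame %in% frames, , drop = FALSE]
  out <- dplyr::summarise(
    dplyr::group_by(traces, .data$cell),
    frames_above = .max_run(.data$cyto_norm > 1 + fluctuation_threshold),
    .groups = "drop")
  out$active <- out$frames_above >= min_frames_above
  class(out) <- c("eec_activity", class(out))
  attr(out, "percent_active") <- 100 * mean(out$active)
  out
}

#' @export
glance.eec_activity <- function(x, ...) {
  tibble::tibble(n_cells = nrow(x), n_active = sum(x$active),
                 percent_active = attr(x, "percent_active"))
}

#' Detect stimulus responders
#'
#' A cell is a responder when its post-stimulus cytoplasmic amplitude — the
#' maximum of the t0-normalized cytoplasmic trace over frames at or after the
#' stimulus, minus 1 — reaches `amp_threshold`.
#'
#' @param traces An `eec_traces` (normalized on the fly if needed).
#' @param stimulus_frame 0-based stimulus frame; must lie in the recording.
#' @param amp_threshold Minimum relative amplitude (default 0.25).
#' @return A tibble of class `eec_responders`: `cell`, `cyto_amplitude`,
#'   `responder`; percentage via [glance()].
#' @export
detect_stimulus_responders <- function(traces, stimulus_frame,
                                       amp_threshold = 0.25) {
  traces <- .ensure_norm(traces)
  nf <- attr(traces, "n_frames")
  if (missing(stimulus_frame) || is.null(stimulus_frame)) {
    rlang::abort("`stimulus_frame` is required to detect responders")
  }
  if (stimulus_frame < 0 || stimulus_frame >= nf) {
    rlang::abort("`stimulus_frame` outside the recording")
  }
  post <- traces[traces$frame >= stimulus_frame, , drop = FALSE]
  out <- dplyr::summarise(
    dplyr::group_by(post, .data$cell),
    cyto_amplitude = .safe_max(.data$cyto_norm) - 1,
    .groups = "drop")
  out$responder <- !is.na(out$cyto_amplitude) & out$cyto_amplitude >= amp_threshold
  class(out) <- c("eec_responders", class(out))
  attr(out, "percent_responders") <- 100 * mean(out$responder)
  attr(out, "stimulus_frame") <- stimulus_frame
  out
}

#' @export
glance.eec_responders <- function(x, ...) {
  tibble::tibble(n_cells = nrow(x), n_responders = sum(x$responder),
                 percent_responders = attr(x, "percent_responders"))
}

#' Per-cell stimulus response metrics
#'
#' Computes, per cell, the record of post-stimulus behaviour:
#' \describe{
#'   \item{cyto_amplitude}{max post-stimulus normalized cytoplasmic value - 1.}
#'   \item{mito_amplitude}{max post-stimulus normalized mitochondrial value - 1.}
#'   \item{sustained_index}{mean over the final quartile of post-stimulus
#'     frames of the normalized mitochondrial trace, minus 1 — the sustained
#'     elevation that outlasts the cytoplasmic transient.}
#'   \item{ratio_change}{mean post-peak (after the cytoplasmic peak frame)
#'     normalized mito/cyto ratio, minus 1.}
#' }
#' Absent frames are excluded from maxima and means, never interpolated. With
#' fewer than 4 post-stimulus frames the sustained index is undefined and
#' flagged `NA`.
#'
#' @param traces An `eec_traces`.
#' @param stimulus_frame 0-based stimulus frame.
#' @param amp_threshold Responder threshold forwarded to
#'   [detect_stimulus_responders()].
#' @return A tibble of class `eec_response_records` with the fields above plus
#'   `responder`.
#' @export
response_metrics <- function(traces, stimulus_frame, amp_threshold = 0.25) {
  traces <- .ensure_norm(traces)
  resp <- detect_stimulus_responders(traces, stimulus_frame, amp_threshold)
  post <- traces[traces$frame >= stimulus_frame, , drop = FALSE]
  nf_post <- attr(traces, "n_frames") - stimulus_frame
  sustained_ok <- nf_post >= 4L
  if (!sustained_ok) {
    rlang::warn("fewer than 4 post-stimulus frames: sustained_index undefined")
  }
  q_start <- stimulus_frame + ceiling(3 / 4 * nf_post)  # final quartile
  rec <- dplyr::summarise(
    dplyr::group_by(post, .data$cell),
    cyto_amplitude = .safe_max(.data$cyto_norm) - 1,
    mito_amplitude = .safe_max(.data$mito_norm) - 1,
    sustained_index = if (sustained_ok) {
      mean(.data$mito_norm[.data$frame >= q_start], na.rm = TRUE) - 1
    } else NA_real_,
    peak_frame = .data$frame[.safe_which_max(.data$cyto_norm)],
    ratio_change = mean(.data$ratio_norm[.data$frame >
                                           .data$frame[.safe_which_max(.data$cyto_norm)]],
                        na.rm = TRUE) - 1,
    .groups = "drop")
  rec$peak_frame <- NULL
  rec <- dplyr::left_join(rec, dplyr::select(resp, "cell", "responder"),
                          by = "cell")
  class(rec) <- c("eec_response_records", class(rec))
  attr(rec, "stimulus_frame") <- stimulus_frame
  attr(rec, "percent_responders") <- attr(resp, "percent_responders")
  rec
}

#' @export
glance.eec_response_records <- function(x, ...) {
  r <- x[x$responder, , drop = FALSE]
  tibble::tibble(
    n_cells = nrow(x), n_responders = nrow(r),
    percent_responders = attr(x, "percent_responders"),
    mean_cyto_amplitude = mean(r$cyto_amplitude),
    mean_mito_amplitude = mean(r$mito_amplitude),
    mean_sustained_index = mean(r$sustained_index))
}

#' Classify ATP responders from paired sensor/reference ratios
#'
#' A cell is an ATP responder when its sensor-over-reference ratio increased
#' by strictly more than `threshold` (default 15%) between the paired t0 and
#' end-point measurements. Cells with non-positive t0 ratio cannot be
#' evaluated and are excluded with a message.
#'
#' @param ratios A data frame with columns `cell`, `ratio_t0`, `ratio_end`.
#' @param threshold Relative increase required (strict inequality).
#' @return A tibble: `cell`, `ratio_t0`, `ratio_end`, `increase`, `responder`.
#' @examples
#' classify_atp_responders(
#'   data.frame(cell = 1:2, ratio_t0 = c(1, 1), ratio_end = c(1.2, 1.1)))
#' @export
classify_atp_responders <- function(ratios, threshold = 0.15) {
  stopifnot(all(c("cell", "ratio_t0", "ratio_end") %in% names(ratios)))
  bad <- is.na(ratios$ratio_t0) | ratios$ratio_t0 <= 0
  if (any(bad)) {
    rlang::inform(sprintf("excluding %d cell(s) with non-positive t0 ratio",
                          sum(bad)))
  }
  out <- tibble::as_tibble(ratios[!bad, , drop = FALSE])
  out$increase <- out$ratio_end / out$ratio_t0 - 1
  out$responder <- out$increase > threshold
  out
}

#' Correlation between cytoplasmic and mitochondrial response amplitudes
#'
#' Pearson correlation, with a two-sided test, of `cyto_amplitude` against
#' `mito_amplitude` over responder cells.
#'
#' @param records An `eec_response_records` (or any data frame with the two
#'   amplitude columns and a `responder` flag).
#' @param responders_only Restrict to responder cells?
#' @return A tibble: `r`, `p_value`, `n`. With fewer than 3 usable points the
#'   estimate is undefined (`NA`) and a warning is raised.
#' @export
amplitude_correlation <- function(records, responders_only = TRUE) {
  d <- records
  if (responders_only && "responder" %in% names(d)) {
    d <- d[d$responder, , drop = FALSE]
  }
  d <- d[complete.cases(d[, c("cyto_amplitude", "mito_amplitude")]), ]
  if (nrow(d) < 3L) {
    rlang::warn("fewer than 3 points: amplitude correlation undefined")
    return(tibble::tibble(r = NA_real_, p_value = NA_real_, n = nrow(d)))
  }
  ct <- cor.test(d$cyto_amplitude, d$mito_amplitude, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(d))
}

#' Hierarchical clustering of temporal dynamics
#'
#' Agglomerative clustering of per-cell normalized traces with correlation
#' distance (1 - Pearson r between trace pairs) and average linkage, the
#' classic recipe for grouping cells by the shape of their temporal dynamics.
#' Deterministic given the input.
#'
#' @param traces An `eec_traces` (cells with any absent frames are dropped,
#'   since the distance needs complete equal-length traces).
#' @param k Number of clusters to cut.
#' @param value Trace column to cluster on.
#' @return A tibble `cell`, `cluster`; the `hclust` tree is attached as
#'   attribute `"tree"`.
#' @export
cluster_traces <- function(traces, k, value = "cyto_norm") {
  traces <- .ensure_norm(traces)
  wide <- tidyr::pivot_wider(traces[, c("cell", "frame", value)],
                             names_from = "frame",
                             values_from = dplyr::all_of(value))
  m <- as.matrix(wide[, -1])
  ok <- stats::complete.cases(m) & apply(m, 1, sd, na.rm = TRUE) > 0
  m <- m[ok, , drop = FALSE]
  if (nrow(m) < k) rlang::abort("fewer usable traces than clusters")
  d <- as.dist(1 - cor(t(m)))
  tree <- hclust(d, method = "average")
  tibble::tibble(cell = wide$cell[ok], cluster = cutree(tree, k = k)) |>
    structure(tree = tree)
}

#' Two-group comparison the way the source experiments report it
#'
#' Two-sided Student's t-test: pooled variance when unpaired, paired
#' otherwise. Degenerate inputs (zero variance everywhere) are flagged rather
#' than erroring, with `statistic = 0, p_value = 1` when the group means are
#' equal.
#'
#' @param values_a,values_b Numeric vectors (equal length when paired).
#' @param paired Paired test?
#' @return A tibble: `statistic`, `p_value`, `df`, `method`, `degenerate`.
#' @export
compare_groups <- function(values_a, values_b, paired = FALSE) {
  if (length(values_a) < 2L || length(values_b) < 2L) {
    rlang::abort("need at least 2 values per group")
  }
  if (paired && length(values_a) != length(values_b)) {
    rlang::abort("paired comparison requires equal group sizes")
  }
  degenerate <- if (paired) sd(values_a - values_b) == 0
                else sd(values_a) == 0 && sd(values_b) == 0
  if (degenerate) {
    equal <- isTRUE(all.equal(mean(values_a), mean(values_b)))
    rlang::warn("zero variance: degenerate comparison flagged")
    return(tibble::tibble(
      statistic = if (equal) 0 else Inf,
      p_value = if (equal) 1 else 0,
      df = NA_real_,
      method = if (paired) "paired t-test" else "pooled-variance t-test",
      degenerate = TRUE))
  }
  tt <- t.test(values_a, values_b, paired = paired, var.equal = !paired)
  tibble::tibble(statistic = unname(tt$statistic), p_value = tt$p.value,
                 df = unname(tt$parameter), method = tt$method,
                 degenerate = FALSE)
}

#' One-way ANOVA with Tukey's post test
#'
#' For comparisons across more than two groups: single-factor ANOVA followed
#' by Tukey honest significant differences.
#'
#' @param values Numeric vector.
#' @param group Factor (or coercible) of the same length.
#' @return A list: `anova` tibble (`statistic`, `p_value`, `df_between`,
#'   `df_within`) and `tukey` tibble (one row per pairwise contrast).
#' @export
compare_groups_anova <- function(values, group) {
  group <- as.factor(group)
  fit <- aov(values ~ group)
  s <- summary(fit)[[1]]
  tk <- TukeyHSD(fit)$group
  list(
    anova = tibble::tibble(statistic = s$`F value`[1],
                           p_value = s$`Pr(>F)`[1],
                           df_between = s$Df[1], df_within = s$Df[2]),
    tukey = tibble::tibble(contrast = rownames(tk), diff = tk[, "diff"],
                           lwr = tk[, "lwr"], upr = tk[, "upr"],
                           p_adj = tk[, "p adj"])
  )
}

# --- internals ---------------------------------------------------------------

.ensure_norm <- function(traces) {
  stopifnot(inherits(traces, "eec_traces"))
  if (!"cyto_norm" %in% names(traces)) traces <- normalize_traces(traces)
  traces
}

.safe_max <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) NA_real_ else max(x)
}

.safe_which_max <- function(x) {
  if (all(is.na(x))) 1L else which.max(x)
}
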