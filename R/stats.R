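#' Two-sample Wilcoxon rank-sum comparison
#'
#' Two-sided Mann-Whitney form of the rank-sum test (the longitudinal groups
#' have unequal n because of missed exams, so a paired test is not possible).
#' Uses the exact null distribution for group sizes up to 10 without ties and
#' the normal approximation otherwise.
#'
#' @param a,b Numeric observation vectors, each with >= 2 values.
#' @param exact_max Largest per-group n for which the exact distribution is
#'   used (default 10).
#' @return List: `statistic` (Mann-Whitney U of the first group), `p_value`,
#'   `exact` (logical).
#' @export
wilcoxon_compare <- function(a, b, exact_max = 10) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 observations")
  use_exact <- length(a) <= exact_max && length(b) <= exact_max &&
    !any(duplicated(c(a, b)))
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = use_exact, correct = !use_exact))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       exact = use_exact)
}

#' Spearman rank correlation with strength category
#'
#' Mid-ranks for ties; pairs with a missing member are dropped. The absolute
#' coefficient is categorized as weak (|rho| <= 0.3), moderate
#' (0.3 < |rho| <= 0.7) or strong (|rho| > 0.7); the published banding has
#' gaps at the boundaries, which are assigned to the closure of the lower
#' band.
#'
#' @param x,y Paired numeric vectors.
#' @return List: `rho`, `p_value`, `n` (pairs used), `category`.
#' @export
spearman_corr <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant input: Spearman correlation undefined")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  rho <- unname(ct$estimate)
  category <- if (abs(rho) <= 0.3) "weak" else
    if (abs(rho) <= 0.7) "moderate" else "strong"
  list(rho = rho, p_value = ct$p.value, n = length(x), category = category)
}

#' Percent change between two means
#'
#' `100 * (comparison - reference) / reference`.
#'
#' @param reference Reference (earlier) mean, non-zero.
#' @param comparison Comparison (later) mean.
#' @return Percent change (positive = increase).
#' @export
percent_change <- function(reference, comparison) {
  if (reference == 0) stop("reference mean is zero; percent change undefined")
  100 * (comparison - reference) / reference
}

#' Published cohort summary values
#'
#' Reported longitudinal means and SDs for the PDAC SBRT cohort: tumor
#' K^trans (1/min), simulated interstitial fluid pressure (kPa) and velocity
#' (m/s) at pre-treatment, after the first fraction (D1-TX) and six weeks
#' post-treatment (D2-TX). These literature values serve as inputs for
#' percent-change arithmetic and as target scales for the synthetic cohort
#' generator.
#'
#' @return Tibble with columns `timepoint`, `ktrans_mean`, `ktrans_sd`,
#'   `ifp_kpa_mean`, `ifp_kpa_sd`, `ifv_ms_mean`, `ifv_ms_sd`, `n`.
#' @export
reference_cohort_summary <- function() {
  tibble::tibble(
    timepoint = c("pre-TX", "D1-TX", "D2-TX"),
    ktrans_mean = c(0.14, 0.27, 0.19),
    ktrans_sd = c(0.06, 0.035, 0.06),
    ifp_kpa_mean = c(2.63, 2.57, 2.60),
    ifp_kpa_sd = c(0.23, 0.19, 0.25),
    ifv_ms_mean = c(1.15e-7, 1.71e-7, 1.39e-7),
    ifv_ms_sd = c(0.50e-7, 0.75e-7, 0.31e-7),
    n = c(8L, 8L, 9L))
}

#' Longitudinal cohort table and statistical report
#'
#' Aggregates per-subject time-point summaries into the three-time-point
#' layout: mean +/- SD of K^trans, IFP and IFV per time point, all pairwise
#' two-sided rank-sum p-values, and per-time-point Spearman correlations of
#' tumor volume against IFP and IFV. Subjects missing a time point are
#' excluded pairwise. No multiple-testing correction is applied (flagged in
#' the report footer).
#'
#' @param summaries Tibble of per-subject rows as produced by
#'   [summarize_fields()] (columns `subject`, `timepoint`, `vt_cm3`,
#'   `ktrans_mean`, `ifp_kpa_mean`, `ifv_ms_mean`).
#' @return List: `table` (per-subject records, ordered), `by_timepoint`
#'   (mean +/- SD per metric), `wilcoxon` (pairwise tests per metric),
#'   `spearman` (V_t vs IFP/IFV per time point), `report` (character,
#'   Markdown), `notes`.
#' @export
cohort_table <- function(summaries) {
  stopifnot(nrow(summaries) >= 1L)
  tps <- c("pre-TX", "D1-TX", "D2-TX")
  stopifnot(all(summaries$timepoint %in% tps))
  tab <- summaries[order(match(summaries$timepoint, tps), summaries$subject), ]
  metrics <- c(ktrans = "ktrans_mean", ifp = "ifp_kpa_mean",
               ifv = "ifv_ms_mean")
  sd0 <- function(x) if (length(x) > 1L) stats::sd(x) else 0
  by_tp <- do.call(rbind, lapply(tps, function(tp) {
    d <- tab[tab$timepoint == tp, ]
    if (nrow(d) == 0L) return(NULL)
    tibble::tibble(timepoint = tp, n = nrow(d),
                   ktrans_mean = mean(d$ktrans_mean),
                   ktrans_sd = sd0(d$ktrans_mean),
                   ifp_kpa_mean = mean(d$ifp_kpa_mean),
                   ifp_kpa_sd = sd0(d$ifp_kpa_mean),
                   ifv_ms_mean = mean(d$ifv_ms_mean),
                   ifv_ms_sd = sd0(d$ifv_ms_mean))
  }))
  notes <- character()
  single <- nrow(tab) == length(unique(tab$timepoint))
  present <- tps[tps %in% tab$timepoint]
  pairs <- if (length(present) >= 2L)
    utils::combn(present, 2, simplify = FALSE) else list()
  wil <- NULL
  if (!single && length(pairs)) {
    wil <- do.call(rbind, lapply(pairs, function(pr) {
      do.call(rbind, lapply(names(metrics), function(m) {
        va <- tab[[metrics[m]]][tab$timepoint == pr[1]]
        vb <- tab[[metrics[m]]][tab$timepoint == pr[2]]
        if (length(va) < 2L || length(vb) < 2L) return(NULL)
        wt <- wilcoxon_compare(va, vb)
        tibble::tibble(metric = m, group_a = pr[1], group_b = pr[2],
                       statistic = wt$statistic, p_value = wt$p_value,
                       exact = wt$exact)
      }))
    }))
  } else {
    notes <- c(notes, "single subject: rank-sum tests skipped")
  }
  spr <- NULL
  if (!single) {
    spr <- do.call(rbind, lapply(tps[tps %in% tab$timepoint], function(tp) {
      d <- tab[tab$timepoint == tp, ]
      if (nrow(d) < 3L) return(NULL)
      res <- lapply(c(ifp = "ifp_kpa_mean", ifv = "ifv_ms_mean"),
                    function(col) tryCatch(spearman_corr(d$vt_cm3, d[[col]]),
                                           error = function(e) NULL))
      do.call(rbind, lapply(names(res), function(m) {
        if (is.null(res[[m]])) return(NULL)
        tibble::tibble(timepoint = tp, metric = paste0("vt_vs_", m),
                       rho = res[[m]]$rho, p_value = res[[m]]$p_value,
                       n = res[[m]]$n, category = res[[m]]$category)
      }))
    }))
  }
  fmt <- function(m, s, d = 3) paste0(signif(m, d), " ± ", signif(s, 2))
  lines <- c("| Parameter | pre-TX | D1-TX | D2-TX |",
             "|---|---|---|---|")
  row_of <- function(label, mcol, scol, d = 3) {
    vals <- vapply(tps, function(tp) {
      r <- by_tp[by_tp$timepoint == tp, ]
      if (nrow(r) == 0L) "--" else fmt(r[[mcol]], r[[scol]], d)
    }, "")
    paste0("| ", label, " | ", paste(vals, collapse = " | "), " |")
  }
  lines <- c(lines,
             row_of("K^trans (min^-1)", "ktrans_mean", "ktrans_sd"),
             row_of("IFP (kPa)", "ifp_kpa_mean", "ifp_kpa_sd"),
             row_of("IFV (m/s)", "ifv_ms_mean", "ifv_ms_sd"))
  notes <- c(notes, "p-values are unadjusted (no multiple-testing correction)")
  report <- paste(c(lines, "", paste0("_", notes, "_")), collapse = "\n")
  list(table = tab, by_timepoint = by_tp, wilcoxon = wil, spearman = spr,
       report = report, notes = notes)
}
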