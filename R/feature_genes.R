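#' Per-gene differential-mean test (DEG)
#'
#' Two-sided t test of equal means between control and case samples for
#' every gene.  The Welch (unequal-variance) statistic is the default;
#' `var_equal = TRUE` gives the pooled-variance Student variant.  Genes
#' with zero variance in both groups get p = 1 when the means are equal
#' (no evidence, no 0/0) and p = 0 when they differ exactly.
#'
#' @param dataset an [ExpressionDataset].
#' @param var_equal use the pooled-variance statistic (default `FALSE`).
#' @return Data frame with columns `gene`, `mean_control`, `mean_case`,
#'   `var_control`, `var_case`, `t`, `df`, `p_mean`.
#' @export
deg_test <- function(dataset, var_equal = FALSE) {
  x <- condition_values(dataset, "control")
  y <- condition_values(dataset, "case")
  n1 <- ncol(x); n2 <- ncol(y)
  if (n1 < 2 || n2 < 2) stop("each condition needs >= 2 samples")
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, length(m1))
  } else {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tstat <- (m2 - m1) / sqrt(se2)
  p <- 2 * pt(-abs(tstat), df)
  degenerate <- se2 == 0
  p[degenerate & m1 == m2] <- 1
  p[degenerate & m1 != m2] <- 0
  data.frame(gene = rownames(dataset$values),
             mean_control = m1, mean_case = m2,
             var_control = v1, var_case = v2,
             t = tstat, df = df, p_mean = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Per-gene differential-deviation test (DEVG)
#'
#' For every gene the absolute deviations from the condition's own mean,
#' `|x - mean(control)|` within control and `|x' - mean(case)|` within
#' case, are compared by a two-sided Wilcoxon rank-sum test.  For
#' combined sample sizes up to 25 the exact null distribution is used:
#' the classical tie-free distribution when the deviations are
#' tie-free, and otherwise full enumeration of all group assignments of
#' the (average-rank) statistic while that enumeration stays below
#' 50,000 assignments.  Larger samples use the normal approximation
#' with continuity correction.  A pure mean shift leaves the deviations
#' unchanged, so it can never register as differential variance.
#'
#' @inheritParams deg_test
#' @return Data frame with columns `gene`, `var_control`, `var_case`,
#'   `p_dev`.
#' @export
devg_test <- function(dataset) {
  x <- condition_values(dataset, "control")
  y <- condition_values(dataset, "case")
  n1 <- ncol(x); n2 <- ncol(y)
  if (n1 < 2 || n2 < 2) stop("each condition needs >= 2 samples")
  d1 <- abs(x - rowMeans(x))
  d2 <- abs(y - rowMeans(y))
  v1 <- rowSums((x - rowMeans(x))^2) / (n1 - 1)
  v2 <- rowSums((y - rowMeans(y))^2) / (n2 - 1)
  p <- vapply(seq_len(nrow(x)), function(i)
    ranksum_pvalue(d1[i, ], d2[i, ]), numeric(1))
  data.frame(gene = rownames(dataset$values),
             var_control = v1, var_case = v2, p_dev = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

# Two-sided rank-sum p-value with a tie-aware exact small-sample path.
ranksum_pvalue <- function(a, b, max_enum = 50000) {
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  v <- c(a, b)
  if (diff(range(v)) < .Machine$double.eps * 64) return(1)
  ties <- anyDuplicated(v) > 0
  if (n <= 25) {
    if (!ties) {
      pv <- wilcox.test(a, b, alternative = "two.sided",
                        exact = TRUE)$p.value
      return(pv)
    }
    if (choose(n, n1) <= max_enum) {
      r <- rank(v)
      w_obs <- sum(r[seq_len(n1)])
      mu <- n1 * (n + 1) / 2
      combos <- utils::combn(n, n1)
      w_all <- colSums(matrix(r[combos], nrow = n1))
      return(mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9))
    }
  }
  pv <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = FALSE,
                correct = TRUE)$p.value)
  if (is.na(pv)) 1 else pv
}

#' Full per-gene statistics for feature-gene classification
#'
#' Combines [deg_test] and [devg_test] and adds fold changes and BH
#' adjusted q-values.  With `log_scale = TRUE` (the default, matching
#' log2 expression data) the mean fold change is `2^|mean_case -
#' mean_control|`; otherwise the larger/smaller mean ratio.  The variance
#' "fold change" used for DEVG selection is the larger/smaller variance
#' ratio.  Genes with zero variance in both conditions are flagged
#' ineligible and are never selected.
#'
#' @inheritParams deg_test
#' @param log_scale expression values are log2-scale (default `TRUE`).
#' @return Data frame (one row per gene) with test statistics, fold
#'   changes, `q_mean`, `q_dev`, and an `eligible` flag.
#' @export
gene_stats <- function(dataset, var_equal = FALSE, log_scale = TRUE) {
  gs <- deg_test(dataset, var_equal = var_equal)
  dv <- devg_test(dataset)
  gs$p_dev <- dv$p_dev
  gs$fc_mean <- if (log_scale) {
    2^abs(gs$mean_case - gs$mean_control)
  } else {
    pmax(gs$mean_case, gs$mean_control) /
      pmin(gs$mean_case, gs$mean_control)
  }
  gs$fc_var <- pmax(gs$var_control, gs$var_case) /
    pmin(gs$var_control, gs$var_case)
  gs$eligible <- !(gs$var_control == 0 & gs$var_case == 0)
  gs$q_mean <- p.adjust(gs$p_mean, method = "BH")
  gs$q_dev <- p.adjust(gs$p_dev, method = "BH")
  gs
}

#' Tiered feature-gene selection
#'
#' Applies the three-tier selection protocol used for both DEG and DEVG
#' categories: (1) all genes with BH-adjusted p at most `fdr1`; (2) if
#' fewer than `min_genes` were selected, all genes with raw p at most
#' `p2` and fold change at least `fc2`; (3) if still fewer than
#' `min_genes`, the top `ceiling(top_frac * n_genes)` genes by ascending
#' p (ties broken by gene id).  For the DEVG category the tier-2 fold
#' change is the variance ratio.
#'
#' @param stats data frame from [gene_stats].
#' @param category `"DEG"` (uses `p_mean`/`q_mean`/`fc_mean`) or
#'   `"DEVG"` (uses `p_dev`/`q_dev`/`fc_var`).
#' @param fdr1 tier-1 FDR threshold (default 0.1).
#' @param p2 tier-2 raw p threshold (default 0.05).
#' @param fc2 tier-2 fold-change threshold (default 1.5).
#' @param top_frac tier-3 fraction of all genes (default 0.01).
#' @param min_genes selection floor that triggers the next tier
#'   (default 200).
#' @return List with `genes` (character vector) and `tier` (1, 2 or 3).
#' @export
tiered_select <- function(stats, category = c("DEG", "DEVG"),
                          fdr1 = 0.1, p2 = 0.05, fc2 = 1.5,
                          top_frac = 0.01, min_genes = 200) {
  category <- match.arg(category)
  cols <- if (category == "DEG") {
    c(p = "p_mean", q = "q_mean", fc = "fc_mean")
  } else {
    c(p = "p_dev", q = "q_dev", fc = "fc_var")
  }
  p <- stats[[cols[["p"]]]]
  q <- stats[[cols[["q"]]]]
  fc <- stats[[cols[["fc"]]]]
  elig <- if ("eligible" %in% names(stats)) stats$eligible else
    rep(TRUE, nrow(stats))
  n_total <- nrow(stats)
  sel1 <- stats$gene[elig & q <= fdr1]
  if (length(sel1) >= min_genes)
    return(list(genes = sel1, tier = 1L))
  sel2 <- stats$gene[elig & p <= p2 & fc >= fc2]
  if (length(sel2) >= min_genes)
    return(list(genes = sel2, tier = 2L))
  k <- ceiling(top_frac * n_total)
  ord <- order(p, stats$gene)
  ord <- ord[elig[ord]]
  sel3 <- stats$gene[head(ord, k)]
  if (length(sel3) == 0)
    message("tier-3 selection empty for category ", category)
  list(genes = sel3, tier = 3L)
}

#' Classify genes as DEG, DEVG or none
#'
#' DEGs are selected by [tiered_select] on the differential-mean p-values;
#' DEVGs by the same protocol on the deviation p-values, applied only to
#' genes *not* selected as DEGs (a gene passing both tests is a DEG by
#' priority, so the two sets are always disjoint).  Directions follow the
#' sign of the mean difference (`up`/`down`) and of the variance
#' difference (`relax` = larger case variance / `tight` = smaller).
#'
#' @inheritParams gene_stats
#' @inheritParams tiered_select
#' @return An object of class `GeneLabeling`: list with `stats` (the
#'   per-gene table including a `label` column), `label` (named character
#'   vector), `deg`, `devg` (gene id vectors), `x1`, `x2` (their sizes)
#'   and `tier` (tier used per category).
#' @export
classify_genes <- function(dataset, fdr1 = 0.1, p2 = 0.05, fc2 = 1.5,
                           top_frac = 0.01, min_genes = 200,
                           var_equal = FALSE, log_scale = TRUE) {
  stats <- gene_stats(dataset, var_equal = var_equal,
                      log_scale = log_scale)
  deg_sel <- tiered_select(stats, "DEG", fdr1 = fdr1, p2 = p2, fc2 = fc2,
                           top_frac = top_frac, min_genes = min_genes)
  rest <- stats[!stats$gene %in% deg_sel$genes, , drop = FALSE]
  devg_sel <- tiered_select(rest, "DEVG", fdr1 = fdr1, p2 = p2, fc2 = fc2,
                            top_frac = top_frac, min_genes = min_genes)
  label <- setNames(rep("none", nrow(stats)), stats$gene)
  up <- stats$mean_case >= stats$mean_control
  relax <- stats$var_case >= stats$var_control
  is_deg <- stats$gene %in% deg_sel$genes
  is_devg <- stats$gene %in% devg_sel$genes
  label[is_deg & up] <- "DEG_up"
  label[is_deg & !up] <- "DEG_down"
  label[is_devg & relax] <- "DEVG_relax"
  label[is_devg & !relax] <- "DEVG_tight"
  stats$label <- unname(label[stats$gene])
  structure(list(stats = stats,
                 label = label,
                 deg = deg_sel$genes,
                 devg = devg_sel$genes,
                 x1 = length(deg_sel$genes),
                 x2 = length(devg_sel$genes),
                 tier = c(DEG = deg_sel$tier, DEVG = devg_sel$tier)),
            class = "GeneLabeling")
}

#' @export
print.GeneLabeling <- function(x, ...) {
  cat(sprintf("GeneLabeling: %d genes; x1 = %d DEGs (tier %s), x2 = %d DEVGs (tier %s)\n",
              length(x$label), x$x1, x$tier[["DEG"]],
              x$x2, x$tier[["DEVG"]]))
  tab <- table(x$label)
  print(tab)
  invisible(x)
}

#' Construct a gene labeling from known label assignments
#'
#' Used to score enrichment or crosstalk against externally defined (for
#' instance, planted) DEG/DEVG labels without re-running the tests.
#'
#' @param label named character vector over all genes with values in
#'   `DEG_up`, `DEG_down`, `DEVG_relax`, `DEVG_tight`, `none`.
#' @return A `GeneLabeling` (with empty `stats`).
#' @export
as_gene_labeling <- function(label) {
  allowed <- c("DEG_up", "DEG_down", "DEVG_relax", "DEVG_tight", "none")
  if (is.null(names(label)) || !all(label %in% allowed))
    stop("'label' must be a named vector over ",
         paste(allowed, collapse = ", "))
  deg <- names(label)[label %in% c("DEG_up", "DEG_down")]
  devg <- names(label)[label %in% c("DEVG_relax", "DEVG_tight")]
  structure(list(stats = data.frame(gene = names(label),
                                    label = unname(label),
                                    stringsAsFactors = FALSE),
                 label = label, deg = deg, devg = devg,
                 x1 = length(deg), x2 = length(devg),
                 tier = c(DEG = NA_integer_, DEVG = NA_integer_)),
            class = "GeneLabeling")
}
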