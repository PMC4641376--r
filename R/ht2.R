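#' Joint two-category hypergeometric probability mass (HT2)
#'
#' Probability that a uniformly random draw of `y` genes out of a universe
#' of `N` genes containing `x1` DEGs and `x2` DEVGs contains exactly `k1`
#' DEGs and `k2` DEVGs:
#' `C(x1,k1) C(x2,k2) C(N-x1-x2, y-k1-k2) / C(N,y)`,
#' with a binomial coefficient of zero whenever its lower index is out of
#' range.  Computed in log space for stability.
#'
#' @param N universe size (total background genes).
#' @param x1 number of DEGs in the universe.
#' @param x2 number of DEVGs in the universe.
#' @param y draw size (pathway size within the universe).
#' @param k1,k2 observed DEG / DEVG counts in the draw (may be vectors of
#'   equal length).
#' @return Numeric vector of probabilities.
#' @export
ht2_pmf <- function(N, x1, x2, y, k1, k2) {
  check_ht2_input(N, x1, x2, y)
  if (length(k1) != length(k2))
    stop("'k1' and 'k2' must have equal length")
  exp(ht2_lpmf(N, x1, x2, y, k1, k2))
}

ht2_lpmf <- function(N, x1, x2, y, k1, k2) {
  lp <- rep(-Inf, length(k1))
  k3 <- y - k1 - k2
  ok <- k1 >= 0 & k1 <= x1 & k2 >= 0 & k2 <= x2 &
    k3 >= 0 & k3 <= (N - x1 - x2)
  lp[ok] <- lchoose(x1, k1[ok]) + lchoose(x2, k2[ok]) +
    lchoose(N - x1 - x2, k3[ok]) - lchoose(N, y)
  lp
}

check_ht2_input <- function(N, x1, x2, y, k1 = NULL, k2 = NULL) {
  stopifnot(length(N) == 1, length(x1) == 1, length(x2) == 1,
            length(y) == 1)
  if (N < 0) stop("invariant violated: N >= 0")
  if (x1 < 0 || x2 < 0 || x1 + x2 > N)
    stop("invariant violated: 0 <= x1 + x2 <= N")
  if (y < 0 || y > N) stop("invariant violated: 0 <= y <= N")
  if (!is.null(k1)) {
    stopifnot(length(k1) == 1, length(k2) == 1)
    if (k1 < 0 || k1 > min(x1, y))
      stop("invariant violated: 0 <= k1 <= min(x1, y)")
    if (k2 < 0 || k2 > min(x2, y))
      stop("invariant violated: 0 <= k2 <= min(x2, y)")
    if (k1 + k2 > y) stop("invariant violated: k1 + k2 <= y")
  }
  invisible(TRUE)
}

#' Joint upper-tail p-value of the HT2 statistic
#'
#' The dysregulation p-value of a pathway holding `k1` DEGs and `k2`
#' DEVGs among its `y` genes.  The default is the strict joint upper
#' tail `P(X1 > k1, X2 > k2)`, i.e. the sum of [ht2_pmf] over the
#' rectangle `(k1, x1] x (k2, x2]` (equivalently, one minus the mass of
#' its complement).  `inclusive = TRUE` replaces both strict inequalities
#' with `>=`, the convention in which the observed outcome contributes to
#' its own p-value; it is never smaller than the strict value.
#'
#' @inheritParams ht2_pmf
#' @param k1,k2 observed DEG / DEVG counts (scalars).
#' @param inclusive use `P(X1 >= k1, X2 >= k2)` instead of the strict
#'   tail (default `FALSE`).
#' @return A single probability in `[0, 1]`.
#' @export
ht2_pvalue <- function(N, x1, x2, y, k1, k2, inclusive = FALSE) {
  check_ht2_input(N, x1, x2, y, k1, k2)
  lo1 <- if (inclusive) k1 else k1 + 1
  lo2 <- if (inclusive) k2 else k2 + 1
  hi1 <- min(x1, y)
  hi2 <- min(x2, y)
  if (lo1 > hi1 || lo2 > hi2) return(0)
  grid <- expand.grid(i1 = lo1:hi1, i2 = lo2:hi2)
  lp <- ht2_lpmf(N, x1, x2, y, grid$i1, grid$i2)
  lp <- lp[lp > -Inf]
  if (length(lp) == 0) return(0)
  mx <- max(lp)
  min(1, exp(mx) * sum(exp(lp - mx)))
}

#' One-category hypergeometric enrichment p-value (ORA baseline)
#'
#' Classical over-representation tail for `k1` DEGs among `y` pathway
#' genes in a universe of `N` genes with `x1` DEGs:
#' `P(X1 >= k1)` by default (`inclusive = FALSE` gives the strict
#' `P(X1 > k1)`).
#'
#' @inheritParams ht2_pvalue
#' @return A single probability in `[0, 1]`.
#' @export
ora_pvalue <- function(N, x1, y, k1, inclusive = TRUE) {
  check_ht2_input(N, x1, 0, y, k1, 0)
  q <- if (inclusive) k1 - 1 else k1
  phyper(q, x1, N - x1, y, lower.tail = FALSE)
}

#' Score every pathway of a collection with HT2 and ORA
#'
#' Intersects each gene set with the background universe, counts its DEG
#' and DEVG members, and computes the HT2 joint tail and the ORA
#' one-category tail, BH-adjusted q-values, and average ranks (smaller p
#' = stronger dysregulation; ties get the mean rank).  Pathways empty
#' after intersection are skipped and counted.
#'
#' @param labeling a `GeneLabeling` (from [classify_genes] or
#'   [as_gene_labeling]).
#' @param collection a [GeneSetCollection].
#' @param background character vector of universe gene ids; defaults to
#'   all genes in the labeling (the full expression background).
#' @param inclusive tail convention passed to [ht2_pvalue] (default
#'   strict).
#' @return Data frame (class `EnrichmentTable`) ordered by `p_ht2` with
#'   columns `pathway`, `y`, `k1`, `k2`, `p_ht2`, `q_ht2`, `p_ora`,
#'   `q_ora`, `rank`, `norm_rank`, `rank_ora`, `norm_rank_ora`,
#'   `frac_deg`, `frac_devg`; attribute `n_skipped` counts empty
#'   pathways.
#' @export
enrich_pathways <- function(labeling, collection, background = NULL,
                            inclusive = FALSE) {
  if (is.null(background)) background <- names(labeling$label)
  background <- unique(background)
  if (length(background) == 0) stop("empty background universe")
  N <- length(background)
  deg <- intersect(labeling$deg, background)
  devg <- intersect(labeling$devg, background)
  x1 <- length(deg); x2 <- length(devg)
  rows <- lapply(names(collection), function(nm) {
    members <- intersect(collection[[nm]], background)
    y <- length(members)
    if (y == 0) return(NULL)
    k1 <- length(intersect(members, deg))
    k2 <- length(intersect(members, devg))
    data.frame(pathway = nm, y = y, k1 = k1, k2 = k2,
               p_ht2 = ht2_pvalue(N, x1, x2, y, k1, k2,
                                  inclusive = inclusive),
               p_ora = ora_pvalue(N, x1, y, k1),
               frac_deg = k1 / y, frac_devg = k2 / y,
               stringsAsFactors = FALSE)
  })
  n_skipped <- sum(vapply(rows, is.null, logical(1)))
  if (n_skipped > 0)
    message(n_skipped, " pathway(s) empty after background ",
            "intersection skipped")
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no pathway overlaps the background universe")
  res$q_ht2 <- p.adjust(res$p_ht2, method = "BH")
  res$q_ora <- p.adjust(res$p_ora, method = "BH")
  n <- nrow(res)
  res$rank <- rank(res$p_ht2, ties.method = "average")
  res$norm_rank <- 100 * res$rank / n
  res$rank_ora <- rank(res$p_ora, ties.method = "average")
  res$norm_rank_ora <- 100 * res$rank_ora / n
  res <- res[order(res$p_ht2, res$pathway), , drop = FALSE]
  rownames(res) <- NULL
  res <- res[, c("pathway", "y", "k1", "k2", "p_ht2", "q_ht2",
                 "p_ora", "q_ora", "rank", "norm_rank",
                 "rank_ora", "norm_rank_ora", "frac_deg", "frac_devg")]
  attr(res, "N") <- N
  attr(res, "x1") <- x1
  attr(res, "x2") <- x2
  attr(res, "n_skipped") <- n_skipped
  class(res) <- c("EnrichmentTable", "data.frame")
  res
}

#' Per-pathway DEG and DEVG fractions (gene-distribution graph data)
#'
#' For every pathway the fraction of its genes labeled DEG and DEVG
#' (`k1/y`, `k2/y`).  Because the labels are disjoint the two fractions
#' always sum to at most one.  Pathways with no measured genes are
#' skipped.
#'
#' @inheritParams enrich_pathways
#' @return Data frame with columns `pathway`, `y`, `frac_deg`,
#'   `frac_devg`.
#' @export
gene_distribution <- function(labeling, collection, background = NULL) {
  if (is.null(background)) background <- names(labeling$label)
  rows <- lapply(names(collection), function(nm) {
    members <- intersect(collection[[nm]], background)
    y <- length(members)
    if (y == 0) return(NULL)
    data.frame(pathway = nm, y = y,
               frac_deg = length(intersect(members, labeling$deg)) / y,
               frac_devg = length(intersect(members, labeling$devg)) / y,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(pathway = character(0), y = integer(0),
                      frac_deg = numeric(0), frac_devg = numeric(0))
  rownames(out) <- NULL
  out
}

#' Scatter plot of the gene-distribution graph
#'
#' Each pathway is a point at (fraction of DEGs, fraction of DEVGs); the
#' top-ranked pathways by the chosen score are highlighted in red.
#'
#' @param enrichment an `EnrichmentTable` from [enrich_pathways].
#' @param top number of top pathways to highlight (default 30).
#' @param by ranking column, `"p_ht2"` (default) or `"p_ora"`.
#' @param ... passed to [graphics::plot].
#' @return Invisibly, the highlighted pathway names.
#' @export
plot_gene_distribution <- function(enrichment, top = 30,
                                   by = c("p_ht2", "p_ora"), ...) {
  by <- match.arg(by)
  ord <- order(enrichment[[by]], enrichment$pathway)
  hi <- seq_len(nrow(enrichment)) %in% head(ord, top)
  plot(enrichment$frac_deg, enrichment$frac_devg,
       col = ifelse(hi, "red", "grey40"),
       pch = ifelse(hi, 19, 1),
       xlab = "fraction of DEGs", ylab = "fraction of DEVGs", ...)
  legend("topright", legend = c(paste("top", top), "other"),
         col = c("red", "grey40"), pch = c(19, 1), bty = "n")
  invisible(enrichment$pathway[hi])
}

#' Rank of a target pathway in an enrichment table
#'
#' @param records an `EnrichmentTable`.
#' @param target pathway name.
#' @return List with `rank` (average rank of the target's p-value),
#'   `norm_rank` (0-100 scale) and `p` (its HT2 p-value).
#' @export
target_rank <- function(records, target) {
  i <- match(target, records$pathway)
  if (is.na(i)) stop("target pathway '", target, "' not in records")
  list(rank = records$rank[i], norm_rank = records$norm_rank[i],
       p = records$p_ht2[i])
}
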