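#' Binarize expression of one sample group against the other's means
#'
#' For each listed gene and each sample of `group`, the bit is 1 iff the
#' expression value is strictly larger than the reference group's mean
#' for that gene (ties give 0).  The reference group is the opposite
#' condition.
#'
#' @param dataset an [ExpressionDataset].
#' @param genes gene ids to binarize (must be measured).
#' @param group samples to binarize, `"case"` (default) or `"control"`.
#' @return Integer 0/1 matrix, samples in rows, genes in columns.
#' @export
binarize <- function(dataset, genes, group = c("case", "control")) {
  group <- match.arg(group)
  genes <- as.character(genes)
  if (length(genes) == 0) stop("empty gene list")
  missing <- setdiff(genes, rownames(dataset$values))
  if (length(missing) > 0)
    stop("gene(s) not measured: ", paste(missing, collapse = ", "))
  ref <- if (group == "case") "control" else "case"
  ref_mean <- rowMeans(condition_values(dataset, ref)[genes, ,
                                                      drop = FALSE])
  target <- condition_values(dataset, group)[genes, , drop = FALSE]
  B <- t(target > ref_mean) * 1L
  storage.mode(B) <- "integer"
  B
}

#' Two-cluster supervised-like clustering of binary sample vectors
#'
#' Hierarchical clustering on Hamming distance with average linkage,
#' cut into two clusters (deterministic default), or k-means with k = 2
#' under a fixed seed with 10 restarts.  When all binary vectors are
#' identical there is nothing to split: a single-cluster assignment is
#' returned with a warning so callers can skip the pathway.
#'
#' @param binary_matrix samples-by-genes 0/1 matrix (from [binarize]).
#' @param method `"hierarchical"` (default) or `"kmeans"`.
#' @param seed RNG seed for the k-means restarts (default 1).
#' @return Named integer vector of cluster labels (1/2; all 1 when the
#'   vectors are indistinguishable).
#' @export
slc_cluster <- function(binary_matrix,
                        method = c("hierarchical", "kmeans"),
                        seed = 1L) {
  method <- match.arg(method)
  if (nrow(binary_matrix) < 2)
    stop("clustering needs at least 2 samples")
  if (ncol(binary_matrix) < 1) stop("clustering needs at least 1 gene")
  if (all(apply(binary_matrix, 2, function(col)
    all(col == col[1])))) {
    warning("all binary vectors identical; single cluster returned")
    return(setNames(rep(1L, nrow(binary_matrix)),
                    rownames(binary_matrix)))
  }
  if (method == "hierarchical") {
    d <- dist(binary_matrix, method = "manhattan") / ncol(binary_matrix)
    cl <- cutree(hclust(d, method = "average"), k = 2)
  } else {
    cl <- with_local_seed(seed, {
      kmeans(binary_matrix, centers = 2, nstart = 10)$cluster
    })
  }
  setNames(as.integer(cl), rownames(binary_matrix))
}

with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(),
                    inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Clinical-index difference between two sample clusters
#'
#' Continuous indices are compared by a two-sided Wilcoxon rank-sum test
#' (or t test via `test = "t"`), categorical ones by Fisher's exact test
#' on the cluster-by-level table.  Samples missing the index are removed
#' first; if either cluster then falls below `min_cluster`, `NA` is
#' returned with the reason in the `"reason"` attribute.
#'
#' @param assignment named cluster vector from [slc_cluster] (two
#'   clusters).
#' @param clinical a `ClinicalTable`.
#' @param index_name clinical index to test.
#' @param min_cluster minimal per-cluster size after removing missing
#'   values (default 3).
#' @param test `"auto"` (Wilcoxon/Fisher by declared type) or `"t"` for
#'   a t test on continuous indices.
#' @return A p-value, or `NA` when the comparison is degenerate.
#' @export
clinical_association <- function(assignment, clinical, index_name,
                                 min_cluster = 3,
                                 test = c("auto", "t")) {
  test <- match.arg(test)
  types <- index_types(clinical)
  if (!index_name %in% names(types))
    stop("unknown clinical index '", index_name, "'")
  samples <- intersect(names(assignment), rownames(clinical))
  v <- clinical[samples, index_name]
  cl <- assignment[samples]
  ok <- !is.na(v)
  v <- v[ok]; cl <- cl[ok]
  sizes <- table(factor(cl, levels = sort(unique(assignment))))
  if (length(sizes) < 2 || any(sizes < min_cluster))
    return(structure(NA_real_, reason = "cluster below min_cluster"))
  if (types[[index_name]] == "continuous") {
    a <- v[cl == sort(unique(cl))[1]]
    b <- v[cl == sort(unique(cl))[2]]
    if (diff(range(v)) < .Machine$double.eps * 64) return(1)
    p <- if (test == "t") {
      stats::t.test(a, b)$p.value
    } else {
      ranksum_pvalue(a, b)
    }
    if (is.na(p)) 1 else p
  } else {
    tab <- table(cl, v)
    if (ncol(tab) < 2) return(1)
    fisher.test(tab)$p.value
  }
}

screen_one <- function(dataset, genes, group, clinical, method, seed,
                       min_cluster, test) {
  B <- binarize(dataset, genes, group = group)
  cl <- withCallingHandlers(
    slc_cluster(B, method = method, seed = seed),
    warning = function(w) invokeRestart("muffleWarning"))
  if (length(unique(cl)) < 2) return(NULL)
  rows <- lapply(names(index_types(clinical)), function(idx) {
    p <- clinical_association(cl, clinical, idx,
                              min_cluster = min_cluster, test = test)
    if (is.na(p)) return(NULL)
    data.frame(index = idx, group = group, n_genes = length(genes),
               n1 = sum(cl == 1), n2 = sum(cl == 2), p = p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Screen pathways as subtype-factors by supervised-like clustering
#'
#' For every pathway with at least `min_devg` DEVGs measured, the case
#' samples (when the pathway's DEVGs are majority relax-regulated) or the
#' control samples (majority tight; ties cluster cases) are binarized
#' against the opposite group's gene means, split into two clusters, and
#' each clinical index is tested for a difference between the clusters.
#' All tested (pathway, index) pairs are reported with BH-adjusted
#' q-values; pairs with raw `p < alpha` are flagged as subtype-factors.
#'
#' @param dataset an [ExpressionDataset].
#' @param labeling a `GeneLabeling`.
#' @param collection a [GeneSetCollection].
#' @param clinical a `ClinicalTable`.
#' @param alpha flagging threshold on the raw p-value (default 0.05).
#' @param min_devg minimal number of measured pathway DEVGs (default 3).
#' @param min_cluster minimal cluster size for the association test
#'   (default 3).
#' @param method clustering method, see [slc_cluster].
#' @param test association test, see [clinical_association].
#' @param seed seed for the k-means variant.
#' @return Data frame (class `SubtypeFactorTable`) with columns
#'   `pathway`, `index`, `method`, `group`, `n_genes`, `n1`, `n2`, `p`,
#'   `q`, `flagged`; attribute `n_skipped` counts pathways below
#'   `min_devg` or with indistinguishable samples.
#' @export
screen_subtype_factors <- function(dataset, labeling, collection,
                                   clinical, alpha = 0.05, min_devg = 3,
                                   min_cluster = 3,
                                   method = c("hierarchical", "kmeans"),
                                   test = c("auto", "t"), seed = 1L) {
  method <- match.arg(method); test <- match.arg(test)
  measured <- rownames(dataset$values)
  relax <- labeling$stats$gene[labeling$stats$label == "DEVG_relax"]
  n_skipped <- 0L
  rows <- lapply(names(collection), function(nm) {
    devgs <- intersect(intersect(collection[[nm]], labeling$devg),
                       measured)
    if (length(devgs) < min_devg) {
      n_skipped <<- n_skipped + 1L
      return(NULL)
    }
    group <- if (sum(devgs %in% relax) * 2 >= length(devgs))
      "case" else "control"
    out <- screen_one(dataset, devgs, group, clinical, method, seed,
                      min_cluster, test)
    if (is.null(out)) { n_skipped <<- n_skipped + 1L; return(NULL) }
    cbind(data.frame(pathway = nm, stringsAsFactors = FALSE), out)
  })
  finish_subtype_table(rows, "SLC", alpha, n_skipped)
}

finish_subtype_table <- function(rows, method_name, alpha, n_skipped) {
  res <- do.call(rbind, rows)
  if (is.null(res))
    res <- data.frame(pathway = character(0), index = character(0),
                      group = character(0), n_genes = integer(0),
                      n1 = integer(0), n2 = integer(0), p = numeric(0))
  res$method <- rep(method_name, nrow(res))
  res$q <- p.adjust(res$p, method = "BH")
  res$flagged <- res$p < alpha
  res <- res[, c("pathway", "index", "method", "group", "n_genes",
                 "n1", "n2", "p", "q", "flagged")]
  rownames(res) <- NULL
  attr(res, "n_skipped") <- n_skipped
  class(res) <- c("SubtypeFactorTable", "data.frame")
  res
}

#' Whole-pathway-expression clustering baseline (PGC)
#'
#' Comparator to [screen_subtype_factors]: the same association screen,
#' but clustering the raw expression of *all* measured pathway genes
#' (Euclidean distance, average linkage) instead of binarized DEVGs.
#'
#' @inheritParams screen_subtype_factors
#' @param group which sample group to cluster (default `"case"`).
#' @param min_genes minimal number of measured pathway genes
#'   (default 3).
#' @return A `SubtypeFactorTable` with `method = "PGC"`.
#' @export
pgc_baseline <- function(dataset, collection, clinical, alpha = 0.05,
                         min_genes = 3, min_cluster = 3,
                         group = c("case", "control"),
                         test = c("auto", "t")) {
  group <- match.arg(group); test <- match.arg(test)
  measured <- rownames(dataset$values)
  n_skipped <- 0L
  rows <- lapply(names(collection), function(nm) {
    genes <- intersect(collection[[nm]], measured)
    if (length(genes) < min_genes) {
      n_skipped <<- n_skipped + 1L
      return(NULL)
    }
    M <- t(condition_values(dataset, group)[genes, , drop = FALSE])
    if (all(dist(M) == 0)) { n_skipped <<- n_skipped + 1L; return(NULL) }
    cl <- cutree(hclust(dist(M), method = "average"), k = 2)
    cl <- setNames(as.integer(cl), rownames(M))
    if (length(unique(cl)) < 2) {
      n_skipped <<- n_skipped + 1L
      return(NULL)
    }
    out <- lapply(names(index_types(clinical)), function(idx) {
      p <- clinical_association(cl, clinical, idx,
                                min_cluster = min_cluster, test = test)
      if (is.na(p)) return(NULL)
      data.frame(pathway = nm, index = idx, group = group,
                 n_genes = length(genes), n1 = sum(cl == 1),
                 n2 = sum(cl == 2), p = p, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
  finish_subtype_table(rows, "PGC", alpha, n_skipped)
}
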