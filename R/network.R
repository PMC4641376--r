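#' Build an undirected gene network from an edge table
#'
#' Self-loops are removed (counted), duplicate edges keep the last
#' occurrence (counted), and the resulting graph is undirected and simple.
#' Nodes are defined by the edges, so isolated nodes cannot occur.
#'
#' @param edges data frame whose first two columns are gene symbols;
#'   an optional `weight` column carries non-negative edge weights.
#' @param uppercase uppercase gene symbols (default `TRUE`).
#' @return An `igraph` object (class also tagged `GeneNetwork`);
#'   attributes `n_self_loops` and `n_duplicates` count removed rows.
#' @export
gene_network <- function(edges, uppercase = TRUE) {
  if (!is.data.frame(edges) || ncol(edges) < 2)
    stop("'edges' must be a data frame with at least two columns")
  a <- as.character(edges[[1]])
  b <- as.character(edges[[2]])
  if (uppercase) { a <- toupper(a); b <- toupper(b) }
  w <- if ("weight" %in% names(edges)) as.numeric(edges[["weight"]]) else NULL
  loops <- a == b
  n_loops <- sum(loops)
  if (n_loops > 0) {
    message(n_loops, " self-loop(s) removed")
    a <- a[!loops]; b <- b[!loops]
    if (!is.null(w)) w <- w[!loops]
  }
  key <- ifelse(a < b, paste(a, b, sep = "\r"), paste(b, a, sep = "\r"))
  dup <- duplicated(key, fromLast = TRUE)  # last occurrence wins
  n_dup <- sum(dup)
  if (n_dup > 0) {
    message(n_dup, " duplicate edge(s) dropped (last read wins)")
    a <- a[!dup]; b <- b[!dup]
    if (!is.null(w)) w <- w[!dup]
  }
  df <- data.frame(from = a, to = b, stringsAsFactors = FALSE)
  if (!is.null(w)) df$weight <- w
  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  class(g) <- unique(c(class(g), "GeneNetwork"))
  attr(g, "n_self_loops") <- n_loops
  attr(g, "n_duplicates") <- n_dup
  g
}

#' Read an edge-list TSV as a gene network
#'
#' Accepts a two-column edge list or a wider table with a named score
#' column (e.g. a STRING-style `combined_score`).  When `min_score` is
#' given, only edges with score `>= min_score` are kept; the threshold is
#' interpreted on the same scale as the column unless `string_scale = TRUE`,
#' which divides the column by 1000 first (STRING's 0-1000 integers).
#'
#' @param path file path.
#' @param score_column name of the score column, or `NULL` for an
#'   unweighted two-column list.
#' @param min_score minimal score for an edge to be kept; requires
#'   `score_column`.
#' @param string_scale divide the score column by 1000 before applying
#'   `min_score` (so a 0.9 confidence cut is written as `min_score = 0.9`).
#' @param header does the file have a header line (default `TRUE`).
#' @param uppercase uppercase gene symbols (default `TRUE`).
#' @return A [gene_network] graph; filtered edge counts are reported.
#' @export
read_network <- function(path, score_column = NULL, min_score = NULL,
                         string_scale = FALSE, header = TRUE,
                         uppercase = TRUE) {
  tab <- read.delim(path, header = header, stringsAsFactors = FALSE,
                    check.names = FALSE)
  if (ncol(tab) < 2) stop("edge list needs at least two columns")
  if (!is.null(score_column)) {
    if (!score_column %in% names(tab))
      stop("score column '", score_column, "' not found in ", path)
    score <- as.numeric(tab[[score_column]])
    if (string_scale) score <- score / 1000
  } else {
    if (!is.null(min_score))
      stop("'min_score' given but no 'score_column' named: ",
           "a two-column edge list carries no score")
    score <- NULL
  }
  if (!is.null(min_score)) {
    keep <- !is.na(score) & score >= min_score
    message(sum(!keep), " edge(s) below min_score removed, ",
            sum(keep), " kept")
    tab <- tab[keep, , drop = FALSE]
    score <- score[keep]
  }
  edges <- data.frame(from = tab[[1]], to = tab[[2]],
                      stringsAsFactors = FALSE)
  if (!is.null(score)) edges$weight <- score
  gene_network(edges, uppercase = uppercase)
}

#' Export a gene network as an edge-list TSV
#' @param network a [gene_network] graph.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  df <- igraph::as_data_frame(network, what = "edges")
  write_table(df, path)
}
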