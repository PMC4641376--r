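#' Specification of a synthetic IEA study
#'
#' Defines a case/control expression study with planted differential
#' expression (mean shifts), planted differential expression variance
#' (bimodal or heteroscedastic case samples), pathways carrying DEG-only
#' or mixed DEG+DEVG signal, an interaction network with within-pathway
#' and background edges plus crosstalk pairs wired through shared
#' dysregulated interactor hubs, and clinical indices separated between
#' the planted case subtypes.  All downstream modules can be calibrated
#' and power-tested against the emitted ground truth.
#'
#' @param seed mandatory RNG seed (integer).
#' @param n_genes,n_control,n_case problem size (defaults 2000, 50, 50).
#' @param deg_fraction fraction of genes with a planted mean shift
#'   (default 0.08; half up, half down).
#' @param deg_shift mean shift in units of the gene's baseline SD
#'   (default 2).
#' @param devg_fraction fraction of genes with planted differential
#'   variance (default 0.05).
#' @param devg_mode `"bimodal"` (case samples split by subtype into
#'   opposite arms; relax-regulation), `"heteroscedastic"` (case SD
#'   shrunk by `sqrt(var_ratio)`; tight-regulation), or `"both"`
#'   (alternating).
#' @param devg_sep arm separation of bimodal genes in baseline-SD units
#'   (default 3; the case variance inflates by `1 + devg_sep^2`).
#' @param var_ratio variance shrinkage factor of tight genes (default 4).
#' @param n_pathways total number of gene sets (default 20); the first
#'   `n_deg_pathways` carry DEG-only signal, the next `n_mixed_pathways`
#'   mixed DEG+DEVG signal, the rest are null.  Pathways are disjoint.
#' @param pathway_size inclusive size range (default `c(20, 40)`).
#' @param n_deg_pathways,n_mixed_pathways planted pathway counts
#'   (defaults 3 and 3).
#' @param frac_deg_only fraction of a DEG-only pathway's members that are
#'   planted DEGs (default 0.5).
#' @param frac_deg_mixed,frac_devg_mixed planted member fractions of a
#'   mixed pathway (defaults 0.1 and 0.4: weak mean signal, strong
#'   variance signal).
#' @param p_within within-pathway edge probability (default 0.25).
#' @param bg_degree expected number of background edges per gene
#'   (default 1).
#' @param n_crosstalk_pairs number of planted crosstalk pairs, wired
#'   between consecutive mixed pathways (default 1; requires
#'   `2 * n_crosstalk_pairs <= n_mixed_pathways`).
#' @param n_interactors shared dysregulated interactor hubs per planted
#'   pair (default 6), drawn from planted DEGs outside any pathway and
#'   connected to every dysregulated member of both pathways.
#' @param clinical named list of indices; each element is
#'   `list(type = "continuous"|"categorical", effect = <numeric>)`.
#'   For continuous indices `effect` is the separation between the two
#'   planted case subtypes in index-SD units; for categorical indices it
#'   is a log-odds shift of the second level in subtype B.
#' @param subtype_balance fraction of case samples in subtype arm A
#'   (default 0.5).
#' @return A validated list of class `SimulationSpec`.
#' @export
sim_spec <- function(seed,
                     n_genes = 2000, n_control = 50, n_case = 50,
                     deg_fraction = 0.08, deg_shift = 2,
                     devg_fraction = 0.05,
                     devg_mode = c("bimodal", "heteroscedastic", "both"),
                     devg_sep = 3, var_ratio = 4,
                     n_pathways = 20, pathway_size = c(20, 40),
                     n_deg_pathways = 3, n_mixed_pathways = 3,
                     frac_deg_only = 0.5,
                     frac_deg_mixed = 0.1, frac_devg_mixed = 0.4,
                     p_within = 0.25, bg_degree = 1,
                     n_crosstalk_pairs = 1, n_interactors = 6,
                     clinical = list(
                       age = list(type = "continuous", effect = 3),
                       bmi = list(type = "continuous", effect = 0),
                       sex = list(type = "categorical", effect = 0)),
                     subtype_balance = 0.5) {
  if (missing(seed)) stop("'seed' is mandatory")
  devg_mode <- match.arg(devg_mode)
  spec <- list(seed = as.integer(seed), n_genes = n_genes,
               n_control = n_control, n_case = n_case,
               deg_fraction = deg_fraction, deg_shift = deg_shift,
               devg_fraction = devg_fraction, devg_mode = devg_mode,
               devg_sep = devg_sep, var_ratio = var_ratio,
               n_pathways = n_pathways, pathway_size = pathway_size,
               n_deg_pathways = n_deg_pathways,
               n_mixed_pathways = n_mixed_pathways,
               frac_deg_only = frac_deg_only,
               frac_deg_mixed = frac_deg_mixed,
               frac_devg_mixed = frac_devg_mixed,
               p_within = p_within, bg_degree = bg_degree,
               n_crosstalk_pairs = n_crosstalk_pairs,
               n_interactors = n_interactors, clinical = clinical,
               subtype_balance = subtype_balance)
  validate_sim_spec(spec)
  structure(spec, class = "SimulationSpec")
}

validate_sim_spec <- function(s) {
  fr <- c(s$deg_fraction, s$devg_fraction, s$frac_deg_only,
          s$frac_deg_mixed, s$frac_devg_mixed, s$subtype_balance)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (s$deg_fraction + s$devg_fraction > 1)
    stop("deg_fraction + devg_fraction must be <= 1")
  if (s$n_control < 2 || s$n_case < 2)
    stop("need >= 2 samples per condition")
  if (s$n_deg_pathways + s$n_mixed_pathways > s$n_pathways)
    stop("planted pathways exceed n_pathways")
  if (2 * s$n_crosstalk_pairs > max(s$n_mixed_pathways, 0) &&
      s$n_crosstalk_pairs > 0)
    stop("crosstalk pairs need 2 mixed pathways each")
  demand <- sim_gene_demand(s)
  if (demand$deg > round(s$deg_fraction * s$n_genes))
    stop("infeasible spec: planted pathways and interactors need ",
         demand$deg, " DEGs but deg_fraction provides only ",
         round(s$deg_fraction * s$n_genes))
  if (demand$devg > round(s$devg_fraction * s$n_genes))
    stop("infeasible spec: mixed pathways need ", demand$devg,
         " DEVGs but devg_fraction provides only ",
         round(s$devg_fraction * s$n_genes))
  if (demand$total_members > s$n_genes)
    stop("infeasible spec: pathway sizes exceed gene count")
  invisible(TRUE)
}

sim_gene_demand <- function(s) {
  max_size <- s$pathway_size[length(s$pathway_size)]
  deg <- s$n_deg_pathways * ceiling(s$frac_deg_only * max_size) +
    s$n_mixed_pathways * ceiling(s$frac_deg_mixed * max_size) +
    s$n_crosstalk_pairs * s$n_interactors
  devg <- s$n_mixed_pathways * ceiling(s$frac_devg_mixed * max_size)
  list(deg = deg, devg = devg,
       total_members = s$n_pathways * max_size +
         s$n_crosstalk_pairs * s$n_interactors)
}

#' Simulate a full synthetic IEA study
#'
#' Draws expression, gene sets, network, clinical table and ground truth
#' from a [sim_spec].  Baseline expression is Normal with per-gene mean
#' `~ U(4, 12)` and SD `~ U(0.5, 1.5)` (log2-microarray scale); planted
#' effects are applied to case samples only.  Fully reproducible from
#' the spec's seed, which is used through a local RNG scope (the
#' caller's RNG state is untouched).
#'
#' @param spec a [sim_spec].
#' @return List with elements `dataset` ([ExpressionDataset]),
#'   `collection` ([GeneSetCollection]), `network` ([gene_network]),
#'   `clinical` (`ClinicalTable`) and `truth` (list with `gene_label`,
#'   `pathway_status`, `crosstalk_pairs`, `subtype`,
#'   `clinical_effects`).
#' @export
simulate_iea <- function(spec) {
  stopifnot(inherits(spec, "SimulationSpec"))
  with_local_seed(spec$seed, simulate_iea_impl(spec))
}

simulate_iea_impl <- function(s) {
  genes <- sprintf("G%05d", seq_len(s$n_genes))
  mu <- runif(s$n_genes, 4, 12)
  sigma <- runif(s$n_genes, 0.5, 1.5)
  names(mu) <- names(sigma) <- genes

  n_deg <- round(s$deg_fraction * s$n_genes)
  n_devg <- round(s$devg_fraction * s$n_genes)
  planted <- sample(genes, n_deg + n_devg)
  deg_pool <- planted[seq_len(n_deg)]
  devg_pool <- setdiff(planted, deg_pool)
  label <- setNames(rep("none", s$n_genes), genes)
  if (n_deg > 0)
    label[deg_pool] <- rep(c("DEG_up", "DEG_down"),
                           length.out = n_deg)
  if (n_devg > 0) {
    label[devg_pool] <- switch(s$devg_mode,
      bimodal = "DEVG_relax",
      heteroscedastic = "DEVG_tight",
      both = rep(c("DEVG_relax", "DEVG_tight"), length.out = n_devg))
  }

  ## pathways: disjoint member sets drawn from the labeled pools
  sizes <- if (s$n_pathways > 0)
    sample(seq(s$pathway_size[1], s$pathway_size[length(s$pathway_size)]),
           s$n_pathways, replace = TRUE) else integer(0)
  status <- rep("null", s$n_pathways)
  if (s$n_deg_pathways > 0) status[seq_len(s$n_deg_pathways)] <- "deg"
  if (s$n_mixed_pathways > 0)
    status[s$n_deg_pathways + seq_len(s$n_mixed_pathways)] <- "mixed"
  free_deg <- sample(deg_pool)
  free_devg <- sample(devg_pool)
  take <- function(pool, k) {
    if (k > length(pool)) stop("internal: pool exhausted")
    pool[seq_len(k)]
  }
  ## planted members first; interactor hubs reserved next; filler
  ## members are then drawn from *all* remaining genes, so null
  ## pathways carry dysregulated genes at the background rate rather
  ## than being artificially depleted
  sets <- vector("list", s$n_pathways)
  planted_devg <- character(0)
  for (i in seq_len(s$n_pathways)) {
    nd <- switch(status[i],
                 deg = round(s$frac_deg_only * sizes[i]),
                 mixed = round(s$frac_deg_mixed * sizes[i]),
                 null = 0L)
    nv <- if (status[i] == "mixed")
      round(s$frac_devg_mixed * sizes[i]) else 0L
    m_deg <- take(free_deg, nd); free_deg <- setdiff(free_deg, m_deg)
    m_devg <- take(free_devg, nv); free_devg <- setdiff(free_devg, m_devg)
    planted_devg <- c(planted_devg, m_devg)
    sets[[i]] <- c(m_deg, m_devg)
  }
  names(sets) <- sprintf("PW%02d", seq_len(s$n_pathways))
  names(status) <- names(sets)
  reserved_hubs <- take(free_deg,
                        s$n_crosstalk_pairs * s$n_interactors)
  free_deg <- setdiff(free_deg, reserved_hubs)
  free_rest <- sample(setdiff(genes,
                              c(unlist(sets), reserved_hubs)))
  for (i in seq_len(s$n_pathways)) {
    fill <- take(free_rest, sizes[i] - length(sets[[i]]))
    free_rest <- setdiff(free_rest, fill)
    sets[[i]] <- c(sets[[i]], fill)
  }
  collection <- if (s$n_pathways > 0) GeneSetCollection(sets) else
    GeneSetCollection(structure(list(), names = character(0)))

  ## crosstalk pairs between consecutive mixed pathways, wired through
  ## shared dysregulated interactor hubs
  mixed_names <- names(sets)[status == "mixed"]
  pair_list <- lapply(seq_len(s$n_crosstalk_pairs), function(j)
    c(mixed_names[2 * j - 1], mixed_names[2 * j]))
  interactors <- list()
  edge_from <- character(0); edge_to <- character(0)
  dys_members <- function(nm)
    intersect(sets[[nm]], names(label)[label != "none"])
  for (j in seq_along(pair_list)) {
    u <- pair_list[[j]][1]; v <- pair_list[[j]][2]
    hubs <- reserved_hubs[(j - 1) * s$n_interactors +
                            seq_len(s$n_interactors)]
    interactors[[j]] <- hubs
    targets <- c(dys_members(u), dys_members(v))
    edge_from <- c(edge_from, rep(hubs, each = length(targets)))
    edge_to <- c(edge_to, rep(targets, times = length(hubs)))
  }

  ## within-pathway and background edges
  for (i in seq_len(s$n_pathways)) {
    m <- sets[[i]]
    if (length(m) >= 2) {
      pr <- utils::combn(m, 2)
      keep <- runif(ncol(pr)) < s$p_within
      edge_from <- c(edge_from, pr[1, keep])
      edge_to <- c(edge_to, pr[2, keep])
    }
  }
  if (s$bg_degree > 0 && s$n_genes >= 2) {
    n_bg <- round(s$bg_degree * s$n_genes / 2)
    bf <- sample(genes, n_bg, replace = TRUE)
    bt <- sample(genes, n_bg, replace = TRUE)
    ok <- bf != bt
    edge_from <- c(edge_from, bf[ok])
    edge_to <- c(edge_to, bt[ok])
  }
  network <- if (length(edge_from) > 0) {
    suppressMessages(gene_network(
      data.frame(from = edge_from, to = edge_to,
                 stringsAsFactors = FALSE)))
  } else {
    igraph::make_empty_graph(0, directed = FALSE)
  }

  ## samples, subtype arms, expression
  ctrl_ids <- sprintf("CTRL%03d", seq_len(s$n_control))
  case_ids <- sprintf("CASE%03d", seq_len(s$n_case))
  n_armA <- round(s$subtype_balance * s$n_case)
  subtype <- setNames(rep("B", s$n_case), case_ids)
  subtype[sample(s$n_case, n_armA)] <- "A"
  arm_sign <- ifelse(subtype == "A", 1, -1)

  vals <- matrix(rnorm(s$n_genes * (s$n_control + s$n_case)),
                 nrow = s$n_genes)
  vals <- mu + sigma * vals
  rownames(vals) <- genes
  colnames(vals) <- c(ctrl_ids, case_ids)
  case_col <- s$n_control + seq_len(s$n_case)
  up <- label == "DEG_up"; down <- label == "DEG_down"
  vals[up, case_col] <- vals[up, case_col] +
    s$deg_shift * sigma[up]
  vals[down, case_col] <- vals[down, case_col] -
    s$deg_shift * sigma[down]
  ## bimodal genes planted in pathways split the case samples by the
  ## clinical subtype; background bimodal genes get independent
  ## per-gene splits (variance heterogeneity unrelated to the subtype)
  relax <- label == "DEVG_relax"
  if (any(relax)) {
    relax_genes <- genes[relax]
    linked <- relax_genes %in% planted_devg
    split_sign <- matrix(0, nrow = sum(relax), ncol = s$n_case)
    split_sign[linked, ] <- matrix(rep(arm_sign, each = sum(linked)),
                                   nrow = sum(linked))
    for (r in which(!linked))
      split_sign[r, ] <- sample(rep(c(1, -1),
                                    length.out = s$n_case))
    gene_sign <- sample(c(-1, 1), sum(relax), replace = TRUE)
    shift <- (gene_sign * split_sign) * (s$devg_sep * sigma[relax])
    vals[relax, case_col] <- vals[relax, case_col] + shift
  }
  tight <- label == "DEVG_tight"
  if (any(tight)) {
    base <- mu[tight] + (sigma[tight] / sqrt(s$var_ratio)) *
      matrix(rnorm(sum(tight) * s$n_case), nrow = sum(tight))
    vals[tight, case_col] <- base
  }
  dataset <- ExpressionDataset(vals,
    setNames(c(rep("control", s$n_control), rep("case", s$n_case)),
             c(ctrl_ids, case_ids)))

  ## clinical indices
  all_ids <- c(ctrl_ids, case_ids)
  clin <- list()
  types <- character(0)
  for (idx in names(s$clinical)) {
    cfg <- s$clinical[[idx]]
    types[idx] <- cfg$type
    if (cfg$type == "continuous") {
      v <- 50 + 10 * rnorm(length(all_ids))
      shift_b <- all_ids %in% case_ids[subtype[case_ids] == "B"]
      v[shift_b] <- v[shift_b] + cfg$effect * 10
      clin[[idx]] <- v
    } else {
      pr <- rep(0.5, length(all_ids))
      pr[all_ids %in% case_ids[subtype[case_ids] == "B"]] <-
        stats::plogis(cfg$effect)
      clin[[idx]] <- ifelse(runif(length(all_ids)) < pr, "M", "F")
    }
  }
  clinical <- clinical_table(as.data.frame(clin,
                                           stringsAsFactors = FALSE),
                             all_ids, types)

  truth <- list(
    gene_label = label,
    pathway_status = status,
    crosstalk_pairs = if (length(pair_list) > 0)
      data.frame(u = vapply(pair_list, `[`, character(1), 1),
                 v = vapply(pair_list, `[`, character(1), 2),
                 stringsAsFactors = FALSE)
      else data.frame(u = character(0), v = character(0)),
    interactors = interactors,
    subtype_linked_genes = planted_devg,
    subtype = subtype,
    clinical_effects = vapply(s$clinical, function(cfg)
      cfg$effect, numeric(1)))
  list(dataset = dataset, collection = collection, network = network,
       clinical = clinical, truth = truth, spec = s)
}

#' Write every artifact of a simulated study to a directory
#'
#' Emits `expression.tsv`, `conditions.tsv`, `sets.gmt`, `network.tsv`,
#' `clinical.tsv` and `truth_gene_labels.tsv` in the package's standard
#' external formats.
#'
#' @param sim result of [simulate_iea] (or [toy_fixture]).
#' @param dir output directory, created if needed.
#' @return Invisibly, the directory path.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  expr <- data.frame(gene = gene_ids(sim$dataset),
                     sim$dataset$values, check.names = FALSE)
  write_table(expr, file.path(dir, "expression.tsv"))
  write_table(data.frame(sample_id = sample_ids(sim$dataset),
                         condition = unname(sim$dataset$condition)),
              file.path(dir, "conditions.tsv"))
  write_gmt(sim$collection, file.path(dir, "sets.gmt"))
  write_network(sim$network, file.path(dir, "network.tsv"))
  clin <- data.frame(sample_id = rownames(sim$clinical),
                     as.data.frame(sim$clinical), check.names = FALSE)
  write_table(clin, file.path(dir, "clinical.tsv"))
  write_table(data.frame(gene = names(sim$truth$gene_label),
                         label = unname(sim$truth$gene_label)),
              file.path(dir, "truth_gene_labels.tsv"))
  invisible(dir)
}

#' Deterministic toy study for documentation and smoke tests
#'
#' A 20-gene, 3-pathway, 12-edge instance: pathway `P1` carries three
#' up-regulated DEGs, `P2` three bimodal (relax) DEVGs, `P3` is null;
#' two dysregulated interactor hubs wire `P1` and `P2` into a planted
#' crosstalk.  Expression (8 control / 8 case samples) is drawn under a
#' fixed internal seed, so repeated calls are identical.
#'
#' @return The same structure as [simulate_iea].
#' @export
toy_fixture <- function() {
  with_local_seed(20150L, toy_fixture_impl())
}

toy_fixture_impl <- function() {
  genes <- c(paste0("A", 1:6), paste0("B", 1:6), paste0("C", 1:6),
             "I1", "I2")
  n_g <- length(genes)
  mu <- setNames(seq(5, 9.75, length.out = n_g), genes)
  sigma <- setNames(rep(1, n_g), genes)
  ctrl_ids <- sprintf("N%02d", 1:8)
  case_ids <- sprintf("T%02d", 1:8)
  vals <- mu + matrix(rnorm(n_g * 16), nrow = n_g)
  rownames(vals) <- genes
  colnames(vals) <- c(ctrl_ids, case_ids)
  label <- setNames(rep("none", n_g), genes)
  label[c("A1", "A2", "A3", "I1", "I2")] <- "DEG_up"
  label[c("B1", "B2", "B3")] <- "DEVG_relax"
  subtype <- setNames(rep(c("A", "B"), each = 4), case_ids)
  arm_sign <- ifelse(subtype == "A", 1, -1)
  deg <- names(label)[label == "DEG_up"]
  vals[deg, case_ids] <- vals[deg, case_ids] + 3
  devg <- names(label)[label == "DEVG_relax"]
  vals[devg, case_ids] <- vals[devg, case_ids] +
    rep(arm_sign, each = length(devg)) * 3
  dataset <- ExpressionDataset(vals,
    setNames(c(rep("control", 8), rep("case", 8)),
             c(ctrl_ids, case_ids)))
  sets <- list(P1 = paste0("A", 1:6), P2 = paste0("B", 1:6),
               P3 = paste0("C", 1:6))
  collection <- GeneSetCollection(sets)
  edges <- data.frame(
    from = c("A1", "A2", "A1", "B1", "B2", "B1",
             "I1", "I1", "I1", "I2", "I2", "I2"),
    to   = c("A2", "A3", "A3", "B2", "B3", "B3",
             "A1", "B1", "A2", "B2", "A3", "B3"),
    stringsAsFactors = FALSE)
  network <- gene_network(edges)
  age <- 50 + 2 * rnorm(16)
  age[match(case_ids[subtype == "B"], c(ctrl_ids, case_ids))] <-
    age[match(case_ids[subtype == "B"], c(ctrl_ids, case_ids))] + 8
  sex <- rep(c("M", "F"), 8)
  clinical <- clinical_table(
    data.frame(age = age, sex = sex, stringsAsFactors = FALSE),
    c(ctrl_ids, case_ids),
    c(age = "continuous", sex = "categorical"))
  truth <- list(
    gene_label = label,
    pathway_status = c(P1 = "deg", P2 = "mixed", P3 = "null"),
    crosstalk_pairs = data.frame(u = "P1", v = "P2",
                                 stringsAsFactors = FALSE),
    interactors = list(c("I1", "I2")),
    subtype = subtype,
    clinical_effects = c(age = 4, sex = 0))
  list(dataset = dataset, collection = collection, network = network,
       clinical = clinical, truth = truth, spec = NULL)
}
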