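# Small fixture builders shared across test files.

make_dataset <- function(control, case) {
  stopifnot(nrow(control) == nrow(case))
  genes <- rownames(control)
  if (is.null(genes)) genes <- sprintf("G%03d", seq_len(nrow(control)))
  m <- cbind(control, case)
  rownames(m) <- genes
  colnames(m) <- c(sprintf("C%02d", seq_len(ncol(control))),
                   sprintf("D%02d", seq_len(ncol(case))))
  ExpressionDataset(m, c(rep("control", ncol(control)),
                         rep("case", ncol(case))))
}

# One gene per row of (control_values, case_values).
one_gene_dataset <- function(control_values, case_values) {
  make_dataset(matrix(control_values, nrow = 1),
               matrix(case_values, nrow = 1))
}

labeling_from_sets <- function(universe, deg, devg) {
  label <- setNames(rep("none", length(universe)), universe)
  label[deg] <- "DEG_up"
  label[devg] <- "DEVG_relax"
  as_gene_labeling(label)
}

write_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
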