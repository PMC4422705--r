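# Shared fixtures: small synthetic datasets built in code.

# gene-level log2 matrix from a synth_expression() result
gene_matrix <- function(se) {
  m <- se$matrix[se$truth$probe, , drop = FALSE]
  rownames(m) <- se$truth$gene
  m
}

# small classified universe: expression + classes, deterministic
fixture_universe <- function(n_genes = 600, seed = 42,
                             noise_sd = 0.25) {
  d <- synth_design(n_genes = n_genes, noise_sd = noise_sd, seed = seed)
  se <- synth_expression(d)
  m <- gene_matrix(se)
  cls <- classify_genes(m)
  list(design = d, expr = se, matrix = m, classes = cls$table,
       calibration = cls$calibration)
}

# toy two-strand domains at controlled separation along x
strand_domain <- function(n_res, x = 0, z0 = 0, protein = "p",
                          domain_type = "strand") {
  i <- seq_len(n_res)
  atoms <- do.call(rbind, lapply(i, function(r) {
    data.frame(resno = r, elety = c("N", "CA", "C", "O"),
               x = x + c(0, 0.5, 1.0, 1.2),
               y = 0,
               z = z0 + 3.5 * (r - 1) + c(0, 0.4, 0.8, 1.0))
  }))
  structure(list(protein = protein, domain_type = domain_type,
                 atoms = atoms), class = "domain_instance")
}
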