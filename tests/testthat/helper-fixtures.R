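# Shared fixtures: tiny datasets built in code.

# Evaluate expr under a local seed without disturbing the session RNG.
with_seed_local <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# Small separable two-class dataset: informative genes shift the class
# means far apart relative to the noise.
make_separable <- function(n_per_class = c(10, 10), n_genes = 30,
                           n_informative = 4, effect = 5, seed = 101) {
  generate_synthetic(synth_spec(n_per_class = n_per_class, n_genes = n_genes,
                                n_informative = n_informative,
                                effect_size = effect, sigma = 0.5,
                                seed = seed))
}

# Minimal 4-sample, 3-gene CSV on disk; returns the path.
write_tiny_csv <- function(path = tempfile(fileext = ".csv")) {
  writeLines(c(
    "sample_id,gA,gB,gC,label",
    "s1,0.1,2.0,5.5,1",
    "s2,0.3,1.8,5.0,1",
    "s3,1.1,0.2,4.0,2",
    "s4,1.3,0.1,4.5,2"
  ), path)
  path
}

# A level-1 pool over explicit gene indices, with IIC values attached.
make_pool <- function(indices, iic = rev(seq_along(indices))) {
  scipso:::new_gene_pool(1L, indices, scores = iic, iic = iic)
}

# A ranked gene_subset list constructed by hand (rank r, members m).
make_ranked <- function(members, accuracies = NULL) {
  l <- length(members)
  lapply(seq_len(l), function(r) {
    structure(list(gene_indices = members[[r]],
                   cv_accuracy = if (is.null(accuracies)) 1 - (r - 1) / l
                                 else accuracies[r],
                   rank = r),
              class = "gene_subset")
  })
}
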