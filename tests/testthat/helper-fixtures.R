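# Fixtures built in code: a small screen count matrix with a controllable
# layout, used across the screen-level tests.

toy_count_matrix <- function(n_genes = 10, guides_per_gene = 3, n_nt = 60,
                             base = 100, conditions = c("T0", "untreated", "treated"),
                             n_replicates = 2, mirna_genes = character()) {
  genes <- sprintf("G%03d", seq_len(n_genes))
  guides <- data.frame(
    sgrna_id = c(sprintf("%s_sg%d", rep(genes, each = guides_per_gene),
                         rep(seq_len(guides_per_gene), n_genes)),
                 sprintf("NT_%03d", seq_len(n_nt))),
    gene = c(rep(genes, each = guides_per_gene), rep("NONTARGETING", n_nt)),
    stringsAsFactors = FALSE
  )
  guides$is_mirna <- guides$gene %in% mirna_genes
  samples <- expand.grid(replicate = seq_len(n_replicates),
                         condition = conditions, stringsAsFactors = FALSE)
  samples$sample_id <- sprintf("%s_%d", samples$condition, samples$replicate)
  samples <- samples[, c("sample_id", "condition", "replicate")]
  counts <- matrix(base, nrow(guides), nrow(samples),
                   dimnames = list(guides$sgrna_id, samples$sample_id))
  count_matrix(counts, guides, samples)
}

default_design <- function(...) assay_design(...)
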