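# Pooled-screen count handling: ingest MAGeCK-style count tables, trim
# low-abundance and miRNA guides, normalize depth against non-targeting
# guides, compute guide- and gene-level log2 fold changes, and score genes
# against a non-targeting pseudo-gene null.

NONTARGETING_LABEL <- "NONTARGETING"

#' Build a count-matrix object from components
#'
#' @param counts non-negative numeric matrix, guides x samples, with sgRNA
#'   ids as rownames and sample ids as colnames.
#' @param guides data frame with columns `sgrna_id`, `gene`, and optionally
#'   `is_nontargeting`, `is_mirna` (inferred / defaulted if absent).
#' @param samples data frame with columns `sample_id`, `condition` (one of
#'   `"T0"`, `"untreated"`, `"treated"`), `replicate`.
#' @return An object of class `count_matrix`.
#' @export
count_matrix <- function(counts, guides, samples) {
  counts <- as.matrix(counts)
  check_that(all(c("sgrna_id", "gene") %in% names(guides)),
             "`guides` needs columns sgrna_id, gene")
  check_that(all(c("sample_id", "condition", "replicate") %in% names(samples)),
             "`samples` needs columns sample_id, condition, replicate")
  if (anyDuplicated(guides$sgrna_id)) {
    dup <- guides$sgrna_id[duplicated(guides$sgrna_id)][1]
    stop(sprintf("duplicate sgRNA id: %s", dup), call. = FALSE)
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample ids in sample sheet", call. = FALSE)
  }
  bad_cond <- setdiff(unique(samples$condition), c("T0", "untreated", "treated"))
  if (length(bad_cond)) {
    stop(sprintf("unknown condition label(s) in sample sheet: %s",
                 paste(bad_cond, collapse = ", ")), call. = FALSE)
  }
  if (any(counts < 0)) {
    idx <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at guide '%s', sample '%s'",
                 rownames(counts)[idx[1]], colnames(counts)[idx[2]]),
         call. = FALSE)
  }
  check_that(nrow(counts) == nrow(guides), "counts rows must match guides")
  check_that(ncol(counts) == nrow(samples), "counts columns must match samples")
  rownames(counts) <- guides$sgrna_id
  colnames(counts) <- samples$sample_id
  if (is.null(guides$is_nontargeting)) {
    guides$is_nontargeting <- guides$gene == NONTARGETING_LABEL
  }
  if (is.null(guides$is_mirna)) guides$is_mirna <- FALSE
  for (cond in c("T0", "untreated", "treated")) {
    if (!cond %in% samples$condition) {
      warning(sprintf("sample sheet has no '%s' samples: contrasts involving it are unavailable",
                      cond))
    }
  }
  structure(list(counts = counts, guides = guides, samples = samples,
                 size_factors = NULL),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("Screen count matrix: %d guides x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  %d targeting genes, %d non-targeting guides, %d miRNA guides\n",
              length(unique(x$guides$gene[!x$guides$is_nontargeting])),
              sum(x$guides$is_nontargeting), sum(x$guides$is_mirna)))
  cat(sprintf("  conditions: %s\n",
              paste(sprintf("%s x%d", names(table(x$samples$condition)),
                            table(x$samples$condition)), collapse = ", ")))
  if (!is.null(x$size_factors)) {
    cat(sprintf("  depth-normalized (size factors %.3g-%.3g)\n",
                min(x$size_factors), max(x$size_factors)))
  }
  invisible(x)
}

#' Read a screen count table and sample sheet from disk
#'
#' The count table is tab-delimited with header
#' `sgRNA<TAB>gene<TAB><sample1>...`; an optional `is_mirna` column (TRUE /
#' FALSE or 0 / 1) may follow `gene`. Non-targeting guides are identified by
#' `gene == "NONTARGETING"`. The sample sheet is a CSV with header
#' `sample_id,condition,replicate`.
#'
#' @param counts_path path to the tab-delimited count table.
#' @param sample_sheet_path path to the sample-sheet CSV.
#' @return A [count_matrix()] object.
#' @export
read_counts <- function(counts_path, sample_sheet_path) {
  check_that(file.exists(counts_path), sprintf("no such file: %s", counts_path))
  check_that(file.exists(sample_sheet_path),
             sprintf("no such file: %s", sample_sheet_path))
  tab <- utils::read.delim(counts_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3 || names(tab)[1] != "sgRNA" || names(tab)[2] != "gene") {
    stop("malformed count table header: expected 'sgRNA<TAB>gene<TAB><samples>'",
         call. = FALSE)
  }
  guides <- data.frame(sgrna_id = tab$sgRNA, gene = tab$gene,
                       stringsAsFactors = FALSE)
  sample_cols <- setdiff(names(tab), c("sgRNA", "gene", "is_mirna"))
  if ("is_mirna" %in% names(tab)) {
    guides$is_mirna <- as.logical(tab$is_mirna)
  }
  counts <- as.matrix(tab[, sample_cols, drop = FALSE])
  if (!is.numeric(counts)) stop("non-numeric counts in count table", call. = FALSE)
  rownames(counts) <- guides$sgrna_id

  sheet <- utils::read.csv(sample_sheet_path, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "condition", "replicate") %in% names(sheet))) {
    stop("malformed sample sheet header: expected sample_id,condition,replicate",
         call. = FALSE)
  }
  missing_samples <- setdiff(sheet$sample_id, colnames(counts))
  if (length(missing_samples)) {
    stop(sprintf("sample sheet row(s) not found in count table: %s",
                 paste(missing_samples, collapse = ", ")), call. = FALSE)
  }
  counts <- counts[, sheet$sample_id, drop = FALSE]
  count_matrix(counts, guides, sheet)
}

#' Write a count matrix back to the on-disk format
#'
#' @param cm a [count_matrix()] object.
#' @param counts_path output path for the tab-delimited count table.
#' @param sample_sheet_path optional output path for the sample-sheet CSV.
#' @return Invisibly, `cm`.
#' @export
write_counts <- function(cm, counts_path, sample_sheet_path = NULL) {
  stopifnot(inherits(cm, "count_matrix"))
  tab <- data.frame(sgRNA = cm$guides$sgrna_id, gene = cm$guides$gene,
                    cm$counts, check.names = FALSE)
  utils::write.table(tab, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(sample_sheet_path)) {
    utils::write.csv(cm$samples[, c("sample_id", "condition", "replicate")],
                     sample_sheet_path, row.names = FALSE, quote = FALSE)
  }
  invisible(cm)
}

#' Remove low-abundance and miRNA guides
#'
#' Guides are ranked by total raw count summed across all samples and the
#' lowest `bottom_frac` (default 5%) are removed, with ties at the cutoff
#' broken by lexicographic sgRNA id; all miRNA-flagged guides are also
#' removed. If the removal would eliminate every guide of more than 20% of
#' genes, the screen is considered bottlenecked and the function aborts.
#'
#' @param cm a [count_matrix()] of raw counts.
#' @param bottom_frac fraction of guides to trim from the bottom.
#' @return The filtered [count_matrix()]; the removal log is attached as
#'   attribute `"removal_log"`.
#' @export
filter_guides <- function(cm, bottom_frac = 0.05) {
  stopifnot(inherits(cm, "count_matrix"))
  totals <- rowSums(cm$counts)
  n_remove <- floor(nrow(cm$counts) * bottom_frac)
  ord <- order(totals, cm$guides$sgrna_id)
  low_ids <- cm$guides$sgrna_id[ord[seq_len(n_remove)]]
  mirna_ids <- cm$guides$sgrna_id[cm$guides$is_mirna]
  drop_ids <- union(low_ids, mirna_ids)

  keep <- !(cm$guides$sgrna_id %in% drop_ids)
  genes_all <- unique(cm$guides$gene[!cm$guides$is_nontargeting])
  genes_left <- unique(cm$guides$gene[keep & !cm$guides$is_nontargeting])
  lost <- setdiff(genes_all, genes_left)
  if (length(lost) > 0.2 * length(genes_all)) {
    stop(sprintf(
      "filtering would remove all guides of %d/%d genes (> 20%%): population bottleneck suspected",
      length(lost), length(genes_all)), call. = FALSE)
  }

  out <- count_matrix(cm$counts[keep, , drop = FALSE],
                      cm$guides[keep, , drop = FALSE], cm$samples)
  attr(out, "removal_log") <- data.frame(
    sgrna_id = drop_ids,
    reason = ifelse(drop_ids %in% mirna_ids, "miRNA", "low_count"),
    stringsAsFactors = FALSE
  )
  out
}

#' Normalize sequencing depth against the non-targeting guide distribution
#'
#' Median-of-ratios size factors computed on non-targeting guides only: for
#' each sample, the size factor is the median over non-targeting guides of
#' `count / geometric mean of that guide across samples`. Guides with a zero
#' in any sample are excluded from size-factor estimation (they are kept in
#' the matrix). Counts are divided by the size factors, so normalizing an
#' already-normalized matrix yields size factors of 1.
#'
#' @param cm a [count_matrix()].
#' @param min_nontargeting minimum number of usable non-targeting guides.
#' @return The normalized [count_matrix()] with `size_factors` set.
#' @export
normalize_depth <- function(cm, min_nontargeting = 50) {
  stopifnot(inherits(cm, "count_matrix"))
  nt <- cm$guides$is_nontargeting
  check_that(sum(nt) >= min_nontargeting,
             sprintf("need >= %d non-targeting guides, found %d",
                     min_nontargeting, sum(nt)))
  ntc <- cm$counts[nt, , drop = FALSE]
  all_zero <- colSums(ntc) == 0
  if (any(all_zero)) {
    stop(sprintf("all non-targeting guides are zero in sample(s): %s",
                 paste(colnames(ntc)[all_zero], collapse = ", ")), call. = FALSE)
  }
  usable <- rowSums(ntc == 0) == 0
  check_that(sum(usable) >= 1,
             "no non-targeting guide is nonzero in every sample")
  ntc <- ntc[usable, , drop = FALSE]
  geo <- exp(rowMeans(log(ntc)))
  sf <- apply(ntc / geo, 2, stats::median)
  cm$counts <- sweep(cm$counts, 2, sf, "/")
  cm$size_factors <- sf
  cm
}

#' Guide-level log2 fold change between two conditions
#'
#' Per guide, `L2FC = log2((mean normalized count in numerator + pc) /
#' (mean normalized count in denominator + pc))` where means are taken over
#' the replicates of each condition.
#'
#' @param cm a depth-normalized [count_matrix()].
#' @param contrast character vector `c(numerator, denominator)` of condition
#'   labels.
#' @param pseudocount pseudocount added to both means (normalized scale).
#' @return Data frame with columns `sgrna_id`, `gene`, `is_nontargeting`,
#'   `l2fc`, `mean_num`, `mean_den`.
#' @export
compute_l2fc <- function(cm, contrast = c("treated", "untreated"),
                         pseudocount = 1) {
  stopifnot(inherits(cm, "count_matrix"))
  check_that(length(contrast) == 2, "`contrast` must be c(numerator, denominator)")
  for (cond in contrast) {
    check_that(cond %in% cm$samples$condition,
               sprintf("condition '%s' not present in sample sheet", cond))
  }
  num <- cm$counts[, cm$samples$condition == contrast[1], drop = FALSE]
  den <- cm$counts[, cm$samples$condition == contrast[2], drop = FALSE]
  m_num <- rowMeans(num)
  m_den <- rowMeans(den)
  data.frame(
    sgrna_id = cm$guides$sgrna_id, gene = cm$guides$gene,
    is_nontargeting = cm$guides$is_nontargeting,
    l2fc = log2((m_num + pseudocount) / (m_den + pseudocount)),
    mean_num = m_num, mean_den = m_den,
    stringsAsFactors = FALSE
  )
}

#' Collapse guide-level values to gene level by the mean
#'
#' @param guide_values data frame with columns `gene` and a value column.
#' @param value name of the value column to collapse.
#' @return Data frame with columns `gene`, `n_guides`, and the collapsed
#'   value column.
#' @export
collapse_genes <- function(guide_values, value = "l2fc") {
  check_that(all(c("gene", value) %in% names(guide_values)),
             sprintf("`guide_values` needs columns gene, %s", value))
  keep <- !is.na(guide_values[[value]])
  dropped <- setdiff(unique(guide_values$gene), unique(guide_values$gene[keep]))
  if (length(dropped)) {
    message(sprintf("dropped %d gene(s) with no surviving guide values", length(dropped)))
  }
  gv <- guide_values[keep, , drop = FALSE]
  agg <- stats::aggregate(gv[[value]], by = list(gene = gv$gene),
                          FUN = function(v) c(mean(v), length(v)))
  out <- data.frame(gene = agg$gene, n_guides = agg$x[, 2],
                    stringsAsFactors = FALSE)
  out[[value]] <- agg$x[, 1]
  out[order(out$gene), c("gene", "n_guides", value)]
}

#' Assign non-targeting guides to randomized pseudo-genes
#'
#' Shuffles the non-targeting guides deterministically under `seed` and
#' groups them into `floor(n / guides_per_gene)` pseudo-genes of
#' `guides_per_gene` guides each; leftover guides are discarded. Pseudo-genes
#' are the empirical null for gene-level statistics.
#'
#' @param cm a [count_matrix()] (or a character vector of non-targeting
#'   sgRNA ids).
#' @param guides_per_gene guides per pseudo-gene (library default 6).
#' @param seed RNG seed for the shuffle.
#' @return Data frame with columns `sgrna_id`, `pseudo_gene`.
#' @export
make_pseudo_genes <- function(cm, guides_per_gene = 6, seed = 1) {
  ids <- if (inherits(cm, "count_matrix")) {
    cm$guides$sgrna_id[cm$guides$is_nontargeting]
  } else {
    as.character(cm)
  }
  n <- length(ids)
  check_that(n >= guides_per_gene,
             sprintf("need >= %d non-targeting guides, found %d",
                     guides_per_gene, n))
  n_pseudo <- n %/% guides_per_gene
  shuffled <- with_seed(seed, sample(ids))
  used <- shuffled[seq_len(n_pseudo * guides_per_gene)]
  data.frame(
    sgrna_id = used,
    pseudo_gene = sprintf("NT_PSEUDO_%04d",
                          rep(seq_len(n_pseudo), each = guides_per_gene)),
    stringsAsFactors = FALSE
  )
}

#' Score gene values against an empirical (pseudo-gene) null
#'
#' Values are z-scored against the mean and standard deviation of the null;
#' a two-sided empirical p-value is obtained by comparing each `|z|` with
#' `n_boot` bootstrap resamples (with replacement) of the null z-scores,
#' floored at `1 / n_boot`; p-values are then Benjamini-Hochberg adjusted
#' across the scored genes.
#'
#' @param gene_values numeric vector of gene-level values.
#' @param null_values numeric vector of pseudo-gene values (>= 30).
#' @param n_boot number of bootstrap resamples.
#' @param seed RNG seed for the bootstrap.
#' @return Data frame with columns `z`, `p_empiric`, `fdr`, aligned with
#'   `gene_values`.
#' @export
score_vs_null <- function(gene_values, null_values, n_boot = 10000, seed = 1) {
  check_that(length(null_values) >= 30, "need >= 30 null (pseudo-gene) values")
  mu <- mean(null_values)
  sigma <- stats::sd(null_values)
  if (sigma == 0) stop("null distribution has zero spread", call. = FALSE)
  z <- (gene_values - mu) / sigma
  z_null <- (null_values - mu) / sigma
  boot <- with_seed(seed, sample(abs(z_null), n_boot, replace = TRUE))
  boot_sorted <- sort(boot)
  # p = fraction of bootstrap null |z| at least as extreme, floored at 1/n_boot
  n_ge <- n_boot - findInterval(abs(z) - 1e-12, boot_sorted)
  p <- pmax(n_ge / n_boot, 1 / n_boot)
  p[is.na(z)] <- NA_real_
  data.frame(z = z, p_empiric = p, fdr = stats::p.adjust(p, method = "BH"))
}

#' One-tailed Fisher's exact test for directional concordance
#'
#' Odds ratio computed as `(a * d) / (b * c)` on the 2x2 table, with a
#' Haldane correction of 0.5 added to every cell when any cell is zero (the
#' `corrected` flag reports this); the one-tailed p-value for enrichment is
#' from the hypergeometric distribution (`fisher.test`, alternative
#' "greater").
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return List with `odds_ratio`, `p_value`, `corrected`.
#' @export
concordance_test <- function(table) {
  table <- as.matrix(table)
  check_that(all(dim(table) == c(2, 2)), "`table` must be 2x2")
  check_that(all(table >= 0) && all(table == round(table)),
             "`table` must contain non-negative integers")
  corrected <- any(table == 0)
  tc <- if (corrected) table + 0.5 else table
  or <- (tc[1, 1] * tc[2, 2]) / (tc[1, 2] * tc[2, 1])
  p <- stats::fisher.test(table, alternative = "greater")$p.value
  list(odds_ratio = or, p_value = p, corrected = corrected)
}
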