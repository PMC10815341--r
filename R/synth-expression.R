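#' Synthetic expression-side inputs
#'
#' Seeded generators for a gene x cell-type read-count matrix with known
#' group enrichment, a qPCR plate (dilution series + stretched/control
#' comparison) with prescribed amplification efficiency and fold changes,
#' and a differential-expression table with planted signal genes.
#'
#' @name synthetic-expression
NULL

#' Generate a gene x cell-type count matrix
#'
#' Reads per gene are multinomial across cell types, proportional to the
#' supplied nonnegative weights.
#'
#' @param genes character vector of gene names.
#' @param celltypes character vector of unique cell-type labels.
#' @param enrichment matrix (genes x celltypes) of nonnegative weights; no
#'   gene may have all-zero weights.
#' @param depth total reads per gene; a zero-depth gene yields an all-zero
#'   row and a message.
#' @param seed integer seed.
#' @return Integer matrix (genes x celltypes) of read counts.
#' @export
generate_counts_table <- function(genes, celltypes, enrichment,
                                  depth = 10000L, seed = 1L) {
  if (length(genes) == 0L || length(celltypes) == 0L) {
    stop("genes and celltypes must be non-empty")
  }
  if (anyDuplicated(celltypes)) stop("cell-type labels must be unique")
  enrichment <- as.matrix(enrichment)
  stopifnot(nrow(enrichment) == length(genes),
            ncol(enrichment) == length(celltypes),
            all(enrichment >= 0))
  if (any(rowSums(enrichment) == 0)) {
    stop("every gene needs at least one positive weight")
  }
  depth <- rep_len(depth, length(genes))
  withr::with_seed(seed, {
    counts <- t(vapply(seq_along(genes), function(i) {
      if (depth[i] == 0L) {
        message(sprintf("gene '%s' has zero depth: all-zero row", genes[i]))
        return(integer(length(celltypes)))
      }
      as.integer(stats::rmultinom(1L, depth[i], enrichment[i, ]))
    }, integer(length(celltypes))))
    dimnames(counts) <- list(genes, celltypes)
    counts
  })
}

#' Generate a qPCR plate with known efficiency and fold changes
#'
#' Ct model per well: a gene-specific baseline plus `d * log_E(5)` for the
#' d-th fivefold dilution, minus `log_E(fold)` in the stretched condition,
#' plus Gaussian noise. Two reference genes (`odc`, `ef1a`) have fold 1 by
#' construction. Each (gene, condition, dilution) has `n_replicates` wells.
#'
#' @param true_E named per-gene amplification efficiency in (1, 5]
#'   (fold per cycle; fivefold-dilution chemistry bounds it by 5).
#' @param fold_changes named per-gene fold change (stretched vs control),
#'   all > 0; reference genes are added automatically with fold 1.
#' @param ct_noise_sd Gaussian Ct noise, cycles.
#' @param dilution_steps number of fivefold dilutions (>= 2; protocol
#'   uses 4).
#' @param n_replicates wells per (gene, condition, dilution).
#' @param ct_base baseline Ct at dilution 0, control condition.
#' @param reference_genes names of the two reference genes.
#' @param seed integer seed.
#' @return Tibble of class `qpcr_plate`: `gene`, `condition` in
#'   `{"control", "stretched"}`, `dilution` (0-based), `replicate`, `ct`;
#'   attributes `true_E`, `fold_changes`, `reference_genes`.
#' @export
generate_qpcr_plate <- function(true_E, fold_changes, ct_noise_sd = 0.1,
                                dilution_steps = 4L, n_replicates = 3L,
                                ct_base = 20, reference_genes = c("odc", "ef1a"),
                                seed = 1L) {
  stopifnot(all(true_E > 1), all(true_E <= 5), dilution_steps >= 2L,
            ct_noise_sd >= 0, n_replicates >= 1L)
  if (any(fold_changes <= 0)) stop("fold changes must be positive")
  genes <- union(names(fold_changes), reference_genes)
  fc <- stats::setNames(rep(1, length(genes)), genes)
  fc[names(fold_changes)] <- fold_changes
  ee <- stats::setNames(rep_len(true_E, length(genes)), genes)
  if (!is.null(names(true_E))) ee[names(true_E)] <- true_E
  grid <- expand.grid(gene = genes, condition = c("control", "stretched"),
                      dilution = seq_len(dilution_steps) - 1L,
                      replicate = seq_len(n_replicates),
                      stringsAsFactors = FALSE)
  withr::with_seed(seed, {
    e <- ee[grid$gene]
    ct <- unname(ct_base + grid$dilution * log(5, base = e) -
      ifelse(grid$condition == "stretched", log(fc[grid$gene], base = e), 0))
    if (ct_noise_sd > 0) ct <- ct + stats::rnorm(nrow(grid), 0, ct_noise_sd)
    out <- tibble::tibble(gene = grid$gene, condition = grid$condition,
                          dilution = grid$dilution, replicate = grid$replicate,
                          ct = ct)
    attr(out, "true_E") <- ee
    attr(out, "fold_changes") <- fc
    attr(out, "reference_genes") <- reference_genes
    class(out) <- c("qpcr_plate", class(out))
    out
  })
}

#' Generate a differential-expression table with planted signals
#'
#' Null genes get near-zero log2 fold changes and uniform p-values; planted
#' signal genes get |LFC| in `lfc_signal_range` (random sign) and strongly
#' sub-uniform p-values. Adjusted p-values are Benjamini-Hochberg.
#'
#' @param n_genes total genes.
#' @param n_signal planted signal genes.
#' @param lfc_signal_range magnitude range of planted log2 fold changes.
#' @param seed integer seed.
#' @return Tibble of class `de_table`: `gene`, `lfc`, `p_value`, `padj`,
#'   `planted` (logical).
#' @export
generate_de_table <- function(n_genes = 10000L, n_signal = 84L,
                              lfc_signal_range = c(1.5, 3), seed = 1L) {
  stopifnot(n_signal <= n_genes)
  withr::with_seed(seed, {
    planted <- c(rep(TRUE, n_signal), rep(FALSE, n_genes - n_signal))
    lfc <- ifelse(planted,
                  sample(c(-1, 1), n_genes, replace = TRUE) *
                    stats::runif(n_genes, lfc_signal_range[1L], lfc_signal_range[2L]),
                  stats::rnorm(n_genes, 0, 0.2))
    p <- ifelse(planted, 10^stats::runif(n_genes, -8, -4),
                stats::runif(n_genes))
    tibble::tibble(gene = sprintf("gene%05d", seq_len(n_genes)),
                   lfc = lfc, p_value = p,
                   padj = stats::p.adjust(p, method = "BH"),
                   planted = planted)
  })
}
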