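#' Expression-side statistics
#'
#' Five-group single-cell read-percentage aggregation, dilution-series qPCR
#' amplification efficiency, dual-reference delta-delta-Ct fold changes,
#' differential-expression candidate filtering, and stretch-response
#' classification.
#'
#' @name expression-analysis
NULL

#' Default cell-type group map
#'
#' The five-group assignment of stage-14 cell types used for the
#' percentage aggregation: anterior neural = anterior neural plate;
#' anterior non-neural = anterior placodal area, cement gland primordium,
#' eye primordium, anterior neural crest; posterior neural = posterior
#' neural plate; posterior non-neural = presomitic mesoderm, somite, tail
#' bud; every other cell type falls into "other".
#'
#' @return Named character vector mapping cell-type label to group label.
#' @export
default_group_map <- function() {
  c("anterior neural plate"   = "anterior neural",
    "anterior placodal area"  = "anterior non-neural",
    "cement gland primordium" = "anterior non-neural",
    "eye primordium"          = "anterior non-neural",
    "anterior neural crest"   = "anterior non-neural",
    "posterior neural plate"  = "posterior neural",
    "presomitic mesoderm"     = "posterior non-neural",
    "somite"                  = "posterior non-neural",
    "tail bud"                = "posterior non-neural")
}

expression_groups <- c("anterior neural", "anterior non-neural",
                       "posterior neural", "posterior non-neural", "other")

#' Group read percentages per gene
#'
#' For each gene, 100 * (reads over the cell types of each group) / (total
#' reads of the gene). Cell types absent from the map count as "other";
#' zero-total genes are skipped with a message and are absent from the
#' output.
#'
#' @param counts genes x cell-types matrix of nonnegative read counts with
#'   unique cell-type column names.
#' @param groups named character vector (cell type -> group), e.g.
#'   [default_group_map()].
#' @return Tibble: `gene` plus one percentage column per group (columns in
#'   the canonical five-group order); rows sum to 100.
#' @export
group_percentages <- function(counts, groups = default_group_map()) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be nonnegative")
  cts <- colnames(counts)
  if (is.null(cts) || anyDuplicated(cts)) {
    stop("counts needs unique cell-type column names")
  }
  grp <- unname(groups[cts])
  grp[is.na(grp)] <- "other"
  totals <- rowSums(counts)
  skip <- totals == 0
  if (any(skip)) {
    message(sprintf("skipping %d zero-total gene(s): %s", sum(skip),
                    paste(rownames(counts)[skip], collapse = ", ")))
  }
  counts <- counts[!skip, , drop = FALSE]
  totals <- totals[!skip]
  pct <- vapply(expression_groups, function(g) {
    sel <- grp == g
    if (!any(sel)) return(rep(0, nrow(counts)))
    100 * rowSums(counts[, sel, drop = FALSE]) / totals
  }, numeric(nrow(counts)))
  if (nrow(counts) == 1L) pct <- matrix(pct, 1L, dimnames = list(NULL, expression_groups))
  out <- tibble::as_tibble(pct)
  out <- tibble::add_column(out, gene = rownames(counts), .before = 1L)
  out
}

#' qPCR amplification efficiency from a fivefold dilution series
#'
#' Averages replicate Ct values per dilution, regresses the fivefold
#' dilution exponent d on mean Ct, and converts the slope to the per-cycle
#' amplification efficiency E = 1/5^(-slope) = 5^slope. Perfect doubling
#' (E = 2) corresponds to a Ct step of log2(5) ~ 2.3219 cycles per
#' dilution; E = 5 to one cycle.
#'
#' @param series data frame with columns `dilution` (0-based fivefold
#'   steps) and `ct`; replicates are averaged per dilution. Needs >= 3
#'   distinct dilutions for a stable slope (2 allowed with a warning).
#' @return List of class `qpcr_efficiency`: `E`, `slope`, `n_dilutions`;
#'   E outside (1, 5] is flagged with a warning.
#' @export
qpcr_efficiency <- function(series) {
  stopifnot(all(c("dilution", "ct") %in% names(series)))
  mean_ct <- tapply(series$ct, series$dilution, mean)
  d <- as.numeric(names(mean_ct))
  if (length(d) < 2L) stop("need at least 2 dilutions")
  if (length(d) == 2L) warning("only 2 dilutions: slope is unstable")
  if (stats::sd(mean_ct) == 0) stop("constant Ct across dilutions: slope undefined")
  slope <- unname(stats::coef(stats::lm(d ~ mean_ct))[2L])
  E <- 5^slope
  if (E <= 1 || E > 5) {
    warning(sprintf("efficiency %.3f outside (1, 5]: check the series", E))
  }
  structure(list(E = E, slope = slope, n_dilutions = length(d)),
            class = "qpcr_efficiency")
}

#' Delta-delta-Ct fold change with dual-reference normalization
#'
#' The normalization Ct per condition is the arithmetic mean of the two
#' reference-gene Cts (the geometric mean of reference expression).
#' Delta-Ct = target - normalizer per condition, delta-delta-Ct =
#' stretched - control, fold change = E^(-ddCt). E defaults to perfect
#' doubling; supply a measured per-gene efficiency for Pfaffl-style
#' correction.
#'
#' @param target_ct named list/vector with `control` and `stretched` target
#'   Ct values (replicates averaged).
#' @param ref_cts list with `control` and `stretched`, each a length-2
#'   vector of the two reference-gene Cts.
#' @param E amplification efficiency (default 2).
#' @return Scalar fold change (stretched vs control).
#' @export
ddct_fold_change <- function(target_ct, ref_cts, E = 2) {
  for (cond in c("control", "stretched")) {
    if (is.null(target_ct[[cond]])) stop(sprintf("missing target Ct for %s", cond))
    if (is.null(ref_cts[[cond]]) || length(ref_cts[[cond]]) != 2L) {
      stop(sprintf("need exactly two reference Cts for %s", cond))
    }
  }
  dct <- function(cond) mean(target_ct[[cond]]) - mean(ref_cts[[cond]])
  E^(-(dct("stretched") - dct("control")))
}

#' Efficiency and fold change for every gene of a plate
#'
#' Convenience wrapper over [qpcr_efficiency()] and [ddct_fold_change()]:
#' efficiency from each gene's control-condition dilution series; fold
#' change from the undiluted (dilution 0) wells with the plate's two
#' reference genes, using either the measured per-gene efficiency or
#' `E = 2`.
#'
#' @param plate a `qpcr_plate` tibble (see [generate_qpcr_plate()]) or any
#'   table with the same columns.
#' @param reference_genes length-2 character vector; defaults to the
#'   plate's `reference_genes` attribute.
#' @param use_measured_E use the gene's measured efficiency in the fold
#'   change (otherwise assume doubling).
#' @return Tibble of class `qpcr_result`: `gene`, `E`, `fold_change` (NA
#'   for the reference genes' own rows is avoided by reporting them too,
#'   with fold ~ 1), `n`.
#' @export
qpcr_results <- function(plate, reference_genes = NULL, use_measured_E = TRUE) {
  if (is.null(reference_genes)) reference_genes <- attr(plate, "reference_genes")
  if (is.null(reference_genes) || length(reference_genes) != 2L) {
    stop("two reference genes required")
  }
  genes <- setdiff(unique(plate$gene), reference_genes)
  d0 <- plate[plate$dilution == 0, ]
  ref_mean <- function(cond) {
    vapply(reference_genes, function(g) {
      mean(d0$ct[d0$gene == g & d0$condition == cond])
    }, numeric(1))
  }
  refs <- list(control = ref_mean("control"), stretched = ref_mean("stretched"))
  rows <- lapply(genes, function(g) {
    eff <- qpcr_efficiency(plate[plate$gene == g & plate$condition == "control", ])
    tgt <- list(
      control = d0$ct[d0$gene == g & d0$condition == "control"],
      stretched = d0$ct[d0$gene == g & d0$condition == "stretched"])
    fc <- ddct_fold_change(tgt, refs, E = if (use_measured_E) eff$E else 2)
    tibble::tibble(gene = g, E = eff$E, fold_change = fc,
                   n = length(tgt$control))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("qpcr_result", class(out))
  out
}

#' Filter differential-expression candidates
#'
#' Genes with |LFC| >= `lfc_min` and (adjusted) p <= `p_max`, ordered by
#' p-value then |LFC| descending, labelled up/down by LFC sign.
#'
#' @param de data frame with columns `gene`, `lfc`, `p_value` and (if
#'   `use_adjusted`) `padj`.
#' @param lfc_min minimum |log2 fold change|.
#' @param p_max maximum (adjusted) p-value.
#' @param use_adjusted filter on `padj` instead of `p_value`.
#' @return Tibble of passing genes with a `direction` column in
#'   `{"up", "down"}`, ordered by significance.
#' @export
candidate_filter <- function(de, lfc_min, p_max, use_adjusted = TRUE) {
  need <- c("gene", "lfc", if (use_adjusted) "padj" else "p_value")
  missing_cols <- setdiff(need, names(de))
  if (length(missing_cols) > 0L) {
    stop(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")))
  }
  p <- if (use_adjusted) de$padj else de$p_value
  keep <- abs(de$lfc) >= lfc_min & p <= p_max
  out <- de[keep, , drop = FALSE]
  p <- p[keep]
  out <- out[order(p, -abs(out$lfc)), , drop = FALSE]
  out$direction <- ifelse(out$lfc >= 0, "up", "down")
  tibble::as_tibble(out)
}

#' Classify stretch response from fold changes
#'
#' A gene is stretch-activated when its fold change is at least
#' `up_threshold` with a confidence interval excluding 1, stretch-inhibited
#' when at most `1/up_threshold` likewise, and unchanged otherwise.
#'
#' @param fold_change numeric vector of fold changes.
#' @param ci_lo,ci_hi confidence bounds per gene (same length); pass NA to
#'   classify on the point estimate alone.
#' @param up_threshold activation threshold (default 1.5).
#' @return Character vector in
#'   `{"stretch-activated", "stretch-inhibited", "unchanged"}`.
#' @export
classify_response <- function(fold_change, ci_lo = NA, ci_hi = NA,
                              up_threshold = 1.5) {
  ci_lo <- rep_len(ci_lo, length(fold_change))
  ci_hi <- rep_len(ci_hi, length(fold_change))
  mapply(function(fc, lo, hi) {
    excl_up <- is.na(lo) || lo > 1
    excl_dn <- is.na(hi) || hi < 1
    if (fc >= up_threshold && excl_up) "stretch-activated"
    else if (fc <= 1 / up_threshold && excl_dn) "stretch-inhibited"
    else "unchanged"
  }, fold_change, ci_lo, ci_hi, USE.NAMES = FALSE)
}

#' Summarize fold changes over replicate experiments
#'
#' Geometric-mean fold change with a t-based confidence interval on the
#' log2 scale, plus the stretch-response label.
#'
#' @param folds numeric vector of per-experiment fold-change estimates for
#'   one gene (n >= 2).
#' @param conf_level confidence level.
#' @param up_threshold passed to [classify_response()].
#' @return List: `fold`, `ci`, `n`, `label`.
#' @export
fold_change_summary <- function(folds, conf_level = 0.95, up_threshold = 1.5) {
  stopifnot(length(folds) >= 2L, all(folds > 0))
  lg <- log2(folds)
  m <- mean(lg)
  half <- stats::qt(1 - (1 - conf_level) / 2, length(lg) - 1L) *
    stats::sd(lg) / sqrt(length(lg))
  ci <- 2^c(m - half, m + half)
  list(fold = 2^m, ci = ci, n = length(folds),
       label = classify_response(2^m, ci[1L], ci[2L], up_threshold))
}
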