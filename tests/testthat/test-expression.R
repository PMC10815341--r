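toy_counts <- function() {
  m <- matrix(0, 3, 4, dimnames = list(
    c("gA", "gB", "gC"),
    c("anterior neural plate", "tail bud", "posterior neural plate",
      "notochord")))
  m["gA", "posterior neural plate"] <- 50
  m["gB", "anterior neural plate"] <- 10
  m["gB", "tail bud"] <- 30
  m["gC", "notochord"] <- 7
  m
}

test_that("group percentages match hand arithmetic and sum to 100", {
  pct <- group_percentages(toy_counts())
  a <- pct[pct$gene == "gA", ]
  expect_equal(a[["posterior neural"]], 100)
  expect_equal(a[["anterior neural"]] + a[["anterior non-neural"]] +
                 a[["posterior non-neural"]] + a[["other"]], 0)
  b <- pct[pct$gene == "gB", ]
  expect_equal(b[["anterior neural"]], 25)
  expect_equal(b[["posterior non-neural"]], 75)
  cc <- pct[pct$gene == "gC", ]
  expect_equal(cc[["other"]], 100)  # unlisted cell type defaults to other

  sums <- rowSums(pct[, setdiff(names(pct), "gene")])
  expect_true(all(abs(sums - 100) < 1e-9))
})

test_that("zero-total genes are skipped and duplicates rejected", {
  m <- toy_counts()
  m["gC", ] <- 0
  expect_message(pct <- group_percentages(m), "zero-total")
  expect_false("gC" %in% pct$gene)

  bad <- toy_counts()
  colnames(bad)[2] <- "anterior neural plate"
  expect_error(group_percentages(bad), "unique")
})

test_that("group percentages are invariant to cell-type column order", {
  m <- toy_counts()
  perm <- m[, c(3, 1, 4, 2)]
  expect_equal(group_percentages(m), group_percentages(perm))
})

test_that("the default group map carries the canonical five-group assignment", {
  gm <- default_group_map()
  expect_equal(unname(gm["eye primordium"]), "anterior non-neural")
  expect_equal(unname(gm["somite"]), "posterior non-neural")
  expect_equal(unname(gm["anterior neural plate"]), "anterior neural")
  expect_equal(unname(gm["posterior neural plate"]), "posterior neural")
  expect_setequal(
    names(gm)[gm == "anterior non-neural"],
    c("anterior placodal area", "cement gland primordium", "eye primordium",
      "anterior neural crest"))
  expect_setequal(names(gm)[gm == "posterior non-neural"],
                  c("presomitic mesoderm", "somite", "tail bud"))
  expect_false("notochord" %in% names(gm))  # unlisted -> other by default
})

test_that("dilution-series efficiency follows the slope formula", {
  s <- data.frame(dilution = 0:3, ct = c(20.00, 22.32, 24.64, 26.97))
  expect_equal(qpcr_efficiency(s)$E, 2.00, tolerance = 0.01)

  s5 <- data.frame(dilution = 0:3, ct = c(20, 21, 22, 23))
  expect_equal(qpcr_efficiency(s5)$E, 5.0, tolerance = 1e-9)

  expect_warning(qpcr_efficiency(data.frame(dilution = 0:1, ct = c(20, 22.32))),
                 "unstable")
  expect_error(qpcr_efficiency(data.frame(dilution = 0:3, ct = rep(20, 4))),
               "undefined")
  expect_warning(qpcr_efficiency(data.frame(dilution = 0:3,
                                            ct = c(20, 20.5, 21, 21.5))),
                 "outside")
})

test_that("ddCt fold changes honor dual-reference normalization", {
  refs_flat <- list(control = c(15, 17), stretched = c(15, 17))
  # all equal -> fold 1
  expect_equal(ddct_fold_change(list(control = 20, stretched = 20), refs_flat), 1)
  # target one cycle lower in stretched -> fold 2 at E = 2
  expect_equal(ddct_fold_change(list(control = 20, stretched = 19), refs_flat), 2)
  # references shift +1 in stretched, target unchanged -> fold 2
  refs_up <- list(control = c(15, 17), stretched = c(16, 18))
  expect_equal(ddct_fold_change(list(control = 20, stretched = 20), refs_up), 2)
  # swapping the two reference genes changes nothing
  refs_sw <- list(control = c(17, 15), stretched = c(18, 16))
  expect_equal(ddct_fold_change(list(control = 20, stretched = 20), refs_sw), 2)
  # Pfaffl-style with measured E
  expect_equal(ddct_fold_change(list(control = 20, stretched = 19), refs_flat,
                                E = 1.9), 1.9)
  expect_error(ddct_fold_change(list(control = 20, stretched = 20),
                                list(control = c(15, 17))), "stretched")
})

test_that("plate-level results recover truth in the noise-free limit", {
  plate <- generate_qpcr_plate(true_E = 2,
                               fold_changes = c(up = 3, down = 1 / 3, flat = 1),
                               ct_noise_sd = 0, seed = 1)
  res <- qpcr_results(plate)
  expect_equal(res$E[match(c("up", "down", "flat"), res$gene)],
               rep(2, 3), tolerance = 1e-9)
  expect_equal(res$fold_change[match(c("up", "down", "flat"), res$gene)],
               c(3, 1 / 3, 1), tolerance = 1e-9)
  expect_equal(classify_response(res$fold_change[match(c("up", "down", "flat"),
                                                       res$gene)]),
               c("stretch-activated", "stretch-inhibited", "unchanged"))
})

test_that("candidate filter selects, orders and labels genes", {
  de <- tibble::tibble(gene = c("A", "B", "C"),
                       lfc = c(2, 0.1, 2),
                       p_value = c(0.001, 0.001, 0.5),
                       padj = c(0.001, 0.001, 0.5))
  expect_equal(candidate_filter(de, 1, 0.05)$gene, "A")
  all_pass <- candidate_filter(de, 0, 1)
  expect_equal(all_pass$gene, c("A", "B", "C"))  # p then |lfc| descending
  expect_equal(all_pass$direction, rep("up", 3))
  expect_error(candidate_filter(de[, 1:2], 1, 0.05), "missing column")
})

test_that("tightening filter thresholds never adds a gene", {
  de <- generate_de_table(n_genes = 500L, n_signal = 20L, seed = 4)
  loose <- candidate_filter(de, 0.5, 0.2)$gene
  for (thr in list(c(1, 0.2), c(0.5, 0.05), c(2, 0.01))) {
    tight <- candidate_filter(de, thr[1], thr[2])$gene
    expect_true(all(tight %in% loose))
  }
})

test_that("stretch-response classification respects CIs", {
  expect_equal(classify_response(3.0, 2.1, 4.2), "stretch-activated")
  expect_equal(classify_response(0.4, 0.3, 0.55), "stretch-inhibited")
  expect_equal(classify_response(1.1, 0.8, 1.5), "unchanged")
  # large fold with CI spanning 1 stays unchanged
  expect_equal(classify_response(2.0, 0.9, 4.0), "unchanged")

  fs <- fold_change_summary(c(2.8, 3.1, 3.3, 2.9))
  expect_equal(fs$label, "stretch-activated")
  expect_equal(fs$fold, 3.0, tolerance = 0.05)
})
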