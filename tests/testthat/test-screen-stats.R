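make_counts_pair <- function(initial, final, line = "hela", rep_i = 1L) {
  lib <- toy_library()
  dplyr::bind_rows(
    tibble::tibble(guide_id = lib$guide_id, cell_line = line,
                   replicate = rep_i, timepoint = "initial",
                   count = as.integer(initial)),
    tibble::tibble(guide_id = lib$guide_id, cell_line = line,
                   replicate = rep_i, timepoint = "final",
                   count = as.integer(final))
  )
}

test_that("log fold changes reflect relative abundance with pseudocounts", {
  # equal relative abundance at both timepoints -> logFC 0 everywhere
  counts <- make_counts_pair(rep(10, 6), rep(40, 6))
  lfc <- guide_logfc(counts, pseudocount = 0)
  expect_equal(lfc$logfc, rep(0, 6))

  # one guide's relative share doubles -> logFC 1 (pseudocount 0)
  init <- c(10, 10, 10, 10, 10, 10)       # g1 share 1/6
  fin <- c(20, 8, 8, 8, 8, 8)             # g1 share 1/3
  lfc2 <- guide_logfc(make_counts_pair(init, fin), pseudocount = 0)
  expect_equal(lfc2$logfc[lfc2$guide_id == "g1"], 1, tolerance = 1e-12)

  # zero final count stays finite and matches hand arithmetic with c = 0.5
  init3 <- c(10, 10, 10, 10, 10, 10)
  fin3 <- c(0, 12, 12, 12, 12, 12)
  lfc3 <- guide_logfc(make_counts_pair(init3, fin3))
  expected <- log2(((0 + 0.5) / 60) / ((10 + 0.5) / 60))
  expect_equal(lfc3$logfc[lfc3$guide_id == "g1"], expected)
  expect_true(all(is.finite(lfc3$logfc)))

  # replicate missing a timepoint errors
  broken <- dplyr::filter(counts, !(replicate == 1 & timepoint == "final"))
  expect_error(guide_logfc(broken), "missing a timepoint")
})

test_that("Z-scores standardize medians against the chosen baseline", {
  lib <- toy_library()
  lfc <- tibble::tibble(
    guide_id = rep(lib$guide_id, 2),
    cell_line = "hela",
    replicate = rep(1:2, each = 6),
    logfc = rep(c(-2, -1, 0, 1, 0.5, -0.5), 2)
  )
  z <- zscore_guides(lfc, lib, baseline = "library")
  mu <- mean(c(-2, -1, 0, 1, 0.5, -0.5))
  sg <- sd(c(-2, -1, 0, 1, 0.5, -0.5))
  expect_equal(z$z[z$guide_id == "g3"], (0 - mu) / sg)
  # a guide one baseline SD below the mean scores z = -1
  expect_equal(z$z[abs(z$median_logfc - (mu - sg)) < 1e-9],
               numeric(0))  # none exactly at mu - sg in this fixture
  expect_equal(z$z, (z$median_logfc - mu) / sg)

  # degenerate baseline errors
  flat <- dplyr::mutate(lfc, logfc = 1)
  expect_error(zscore_guides(flat, lib), "SD is zero")
})

test_that("NTC-baseline standardization gives the NTC population mean 0, SD 1", {
  set.seed(3)
  lib <- toy_library()
  lfc <- tidyr::expand_grid(guide_id = lib$guide_id, cell_line = c("l1", "l2"),
                            replicate = 1:3) |>
    dplyr::mutate(logfc = rnorm(dplyr::n()))
  z <- zscore_guides(lfc, lib, baseline = "ntc")
  ntc <- dplyr::filter(z, gene == "NTC")
  for (cl in c("l1", "l2")) {
    expect_equal(mean(ntc$z[ntc$cell_line == cl]), 0, tolerance = 1e-12)
    expect_equal(sd(ntc$z[ntc$cell_line == cl]), 1, tolerance = 1e-12)
  }
})

test_that("Z-scores are invariant to scaling a sample's sequencing depth", {
  set.seed(4)
  lib <- toy_library()
  init <- sample(50:150, 6)
  fin <- sample(50:150, 6)
  counts <- make_counts_pair(init, fin)
  scaled <- dplyr::mutate(counts,
                          count = ifelse(timepoint == "final",
                                         count * 7L, count))
  z1 <- score_guides(counts, lib, pseudocount = 0)
  z2 <- score_guides(scaled, lib, pseudocount = 0)
  expect_equal(z1$z, z2$z, tolerance = 1e-9)
})

test_that("flagged guides are dropped with an audit trail", {
  lib <- toy_library()
  lib$flag_yrich[1:2] <- TRUE
  lib$flag_tttt[3] <- TRUE
  scores <- tibble::tibble(guide_id = lib$guide_id, gene = lib$gene,
                           mean_z = 0)
  out <- filter_guides(scores, lib, drop = c("tttt", "yrich"))
  expect_equal(out$guide_id, c("g4", "n1", "n2"))
  expect_equal(sort(attr(out, "audit")$guide_id), c("g1", "g2", "g3"))

  # drop nothing is the identity
  out2 <- filter_guides(scores, lib, drop = character(0))
  expect_equal(out2$guide_id, scores$guide_id)

  lib_all <- dplyr::mutate(lib, flag_tttt = TRUE)
  expect_error(filter_guides(scores, lib_all), "no guides remain")
})

test_that("gene essentiality follows the >9% of guides below Z = -1 rule", {
  scores <- tibble::tibble(
    guide_id = sprintf("g%02d", 1:10), gene = "A", cell_line = "hela",
    median_logfc = 0, z = c(-1.5, rep(0, 9))
  )
  call <- call_gene_essentiality(scores)
  expect_equal(call$fraction, 0.10)
  expect_true(call$line_hit)       # 0.10 > 0.09
  expect_true(call$essential)

  # exactly at the threshold does not count (strict inequality)
  scores9 <- dplyr::bind_rows(
    scores,
    dplyr::mutate(scores, guide_id = sprintf("h%02d", 1:10), z = 0)
  ) |> dplyr::mutate(z = c(-1.5, rep(0, 19)))
  call9 <- call_gene_essentiality(scores9)
  expect_equal(call9$fraction, 0.05)
  expect_false(call9$essential)

  # no guides below the cut anywhere -> not essential
  none <- dplyr::mutate(scores, z = 0)
  expect_false(call_gene_essentiality(none)$essential)
})

test_that("essentiality calls are monotone in the fraction threshold", {
  set.seed(8)
  scores <- tidyr::expand_grid(gene = sprintf("G%d", 1:10),
                               idx = 1:20, cell_line = c("l1", "l2")) |>
    dplyr::mutate(guide_id = paste0(gene, "_", idx), median_logfc = 0,
                  z = rnorm(dplyr::n(), mean = -0.5))
  frs <- c(0.05, 0.09, 0.2, 0.4)
  ess <- lapply(frs, function(fr) {
    call_gene_essentiality(scores, min_fraction = fr) |>
      dplyr::distinct(gene, essential)
  })
  for (i in seq_along(frs)[-1]) {
    # lowering min_fraction never removes an essential call
    now <- ess[[i]]$gene[ess[[i]]$essential]
    before <- ess[[i - 1]]$gene[ess[[i - 1]]$essential]
    expect_true(all(now %in% before))
  }
})

test_that("genotype fractions implement the editing mixture arithmetic", {
  g <- genotype_fractions(0.2, 2)
  expect_equal(g$all_frameshift, 0.64)
  expect_equal(g$at_least_one_inframe, 0.36)
  expect_equal(genotype_fractions(0, 2)$all_frameshift, 1)
  expect_equal(genotype_fractions(1, 2)$at_least_one_inframe, 1)

  # outputs sum to one across the parameter space
  for (p in seq(0, 1, by = 0.1)) {
    for (k in 1:4) {
      g <- genotype_fractions(p, k)
      expect_equal(g$all_frameshift + g$at_least_one_inframe, 1)
    }
  }
  expect_error(genotype_fractions(1.2), "\\[0, 1\\]")
})

test_that("feature-bin comparison is a two-sided Mann-Whitney with brute-force U", {
  set.seed(12)
  n <- 50
  mean_z <- tibble::tibble(guide_id = sprintf("g%03d", 1:(2 * n)),
                           gene = "A",
                           mean_z = c(rnorm(n), rnorm(n) - 5))
  bin_a <- mean_z$guide_id[1:n]
  bin_b <- mean_z$guide_id[(n + 1):(2 * n)]
  res <- compare_feature_bins(mean_z, bin_a, bin_b)
  expect_lt(res$p_value, 1e-6)

  # brute-force pair-counting U statistic
  za <- mean_z$mean_z[1:n]
  zb <- mean_z$mean_z[(n + 1):(2 * n)]
  u_brute <- sum(outer(za, zb, ">")) + 0.5 * sum(outer(za, zb, "=="))
  expect_equal(res$u, u_brute)

  # identical samples: no evidence of a shift
  same <- tibble::tibble(guide_id = c("a1", "a2", "a3", "b1", "b2", "b3"),
                         gene = "A", mean_z = rep(c(1, 2, 3), 2))
  res2 <- suppressWarnings(
    compare_feature_bins(same, c("a1", "a2", "a3"), c("b1", "b2", "b3")))
  expect_gt(res2$p_value, 0.9)

  # degenerate (1, 1) bins use the exact method without blowups
  tiny <- tibble::tibble(guide_id = c("x", "y"), gene = "A",
                         mean_z = c(0, 1))
  res3 <- compare_feature_bins(tiny, "x", "y")
  expect_true(res3$p_value >= 0 && res3$p_value <= 1)

  expect_error(compare_feature_bins(tiny, character(0), "y"), "empty bin")
  expect_error(compare_feature_bins(tiny, "x", "x"), "disjoint")
})

test_that("cell-line correlations form a symmetric unit-diagonal matrix", {
  set.seed(21)
  lib_genes <- c(rep("A", 500), rep("NTC", 100))
  ids <- sprintf("g%04d", seq_along(lib_genes))
  base <- rnorm(600)
  scores <- dplyr::bind_rows(
    tibble::tibble(guide_id = ids, gene = lib_genes, cell_line = "l1",
                   median_logfc = 0, z = base),
    tibble::tibble(guide_id = ids, gene = lib_genes, cell_line = "l2",
                   median_logfc = 0, z = base),          # duplicate line
    tibble::tibble(guide_id = ids, gene = lib_genes, cell_line = "l3",
                   median_logfc = 0, z = rnorm(600)),    # independent line
    tibble::tibble(guide_id = ids, gene = lib_genes, cell_line = "l4",
                   median_logfc = 0, z = -base)           # anti-correlated
  )
  m <- cell_line_correlation(scores)
  expect_equal(unname(diag(m)), rep(1, 4))
  expect_equal(unclass(m), t(unclass(m)))
  expect_equal(m["l1", "l2"], 1.0)
  expect_equal(m["l1", "l4"], -1.0)
  expect_lt(abs(m["l1", "l3"]), 0.15)
})
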