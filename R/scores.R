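#' Per-guide log2 fold changes from paired counts
#'
#' For each guide and `(cell_line, replicate)` pair, computes
#' `log2(((final + c) / F) / ((initial + c) / I))` where `F` and `I` are the
#' library-size totals (raw read sums) of the final and initial samples and
#' `c` is a pseudocount.
#'
#' @param counts Long counts tibble from [read_count_matrix()].
#' @param pseudocount Pseudocount added to each guide's reads (default 0.5).
#' @return A tibble `guide_id`, `cell_line`, `replicate`, `logfc`.
#' @export
guide_logfc <- function(counts, pseudocount = 0.5) {
  pairing <- counts |>
    dplyr::distinct(.data$cell_line, .data$replicate, .data$timepoint) |>
    dplyr::count(.data$cell_line, .data$replicate)
  abort_if(any(pairing$n != 2L), "replicate missing a timepoint")
  counts |>
    dplyr::group_by(.data$cell_line, .data$replicate, .data$timepoint) |>
    dplyr::mutate(rel = (.data$count + pseudocount) / sum(.data$count)) |>
    dplyr::ungroup() |>
    dplyr::select("guide_id", "cell_line", "replicate", "timepoint", "rel") |>
    tidyr::pivot_wider(names_from = "timepoint", values_from = "rel") |>
    dplyr::mutate(logfc = log2(.data$final / .data$initial)) |>
    dplyr::select("guide_id", "cell_line", "replicate", "logfc")
}

#' Median log fold changes and per-cell-line Z-scores
#'
#' Collapses replicate log fold changes to a per-cell-line median, then
#' standardizes the medians within each cell line against a baseline
#' population: the whole library (default) or the nontargeting controls.
#' NTC guides are scored identically to targeting guides.
#'
#' @param logfc Tibble from [guide_logfc()].
#' @param library Guide library tibble (supplies `gene` and NTC identity).
#' @param baseline `"library"` or `"ntc"`; the population whose moment mean
#'   and SD define the Z transformation within each cell line.
#' @return A tibble `guide_id`, `gene`, `cell_line`, `median_logfc`, `z`.
#' @export
zscore_guides <- function(logfc, library, baseline = c("library", "ntc")) {
  baseline <- match.arg(baseline)
  med <- logfc |>
    dplyr::group_by(.data$guide_id, .data$cell_line) |>
    dplyr::summarise(median_logfc = median(.data$logfc), .groups = "drop") |>
    dplyr::inner_join(dplyr::select(library, "guide_id", "gene"),
                      by = "guide_id")
  base_stats <- med |>
    dplyr::filter(if (baseline == "ntc") .data$gene == "NTC" else TRUE) |>
    dplyr::group_by(.data$cell_line) |>
    dplyr::summarise(mu = mean(.data$median_logfc),
                     sigma = sd(.data$median_logfc), .groups = "drop")
  abort_if(baseline == "ntc" && nrow(base_stats) == 0,
           "no NTC guides available for the ntc baseline")
  abort_if(any(!is.finite(base_stats$sigma) | base_stats$sigma == 0),
           "baseline SD is zero or undefined")
  med |>
    dplyr::inner_join(base_stats, by = "cell_line") |>
    dplyr::mutate(z = (.data$median_logfc - .data$mu) / .data$sigma) |>
    dplyr::select("guide_id", "gene", "cell_line", "median_logfc", "z")
}

#' Counts to Z-scores in one call
#'
#' Convenience wrapper chaining [guide_logfc()] and [zscore_guides()].
#'
#' @inheritParams guide_logfc
#' @inheritParams zscore_guides
#' @return A tibble `guide_id`, `gene`, `cell_line`, `median_logfc`, `z`.
#' @export
score_guides <- function(counts, library, pseudocount = 0.5,
                         baseline = c("library", "ntc")) {
  counts |>
    guide_logfc(pseudocount = pseudocount) |>
    zscore_guides(library, baseline = baseline)
}

#' Cross-cell-line mean Z per guide
#'
#' @param scores Tibble from [zscore_guides()].
#' @return A tibble `guide_id`, `gene`, `mean_z`.
#' @export
guide_mean_z <- function(scores) {
  scores |>
    dplyr::group_by(.data$guide_id, .data$gene) |>
    dplyr::summarise(mean_z = mean(.data$z), .groups = "drop")
}

#' Remove quality-flagged guides from a score table
#'
#' Drops guides carrying the requested flags (TTTT stretches and/or
#' pyrimidine-rich 3' ends) from downstream analysis; removed guides are
#' retained in the `"audit"` attribute.
#'
#' @param scores Score tibble keyed by `guide_id`.
#' @param library Guide library tibble with flag columns.
#' @param drop Character subset of `c("tttt", "yrich")`.
#' @return The filtered score tibble with an `"audit"` attribute listing
#'   removed guides and the flag responsible.
#' @export
filter_guides <- function(scores, library, drop = c("tttt", "yrich")) {
  abort_if(length(drop) > 0 && !all(drop %in% c("tttt", "yrich")),
           "drop must be a subset of c('tttt', 'yrich')")
  flagged <- rep(FALSE, nrow(library))
  reason <- rep(NA_character_, nrow(library))
  if ("yrich" %in% drop) {
    reason[library$flag_yrich] <- "yrich"
    flagged <- flagged | library$flag_yrich
  }
  if ("tttt" %in% drop) {
    reason[library$flag_tttt] <- "tttt"
    flagged <- flagged | library$flag_tttt
  }
  bad_ids <- library$guide_id[flagged]
  out <- dplyr::filter(scores, !.data$guide_id %in% bad_ids)
  abort_if(nrow(out) == 0, "no guides remain after filtering")
  attr(out, "audit") <- tibble::tibble(
    guide_id = library$guide_id[flagged],
    flag = reason[flagged]
  )
  out
}

#' Gene-level essentiality calls
#'
#' A cell line counts as a hit for a gene when more than `min_fraction` of
#' the gene's scored guides have `z < z_cut` in that line; the gene is
#' called essential when at least `min_lines` lines are hits. Defaults
#' follow the operative screen rule: fraction of guides with Z below -1.0
#' exceeding 9%.
#'
#' @param scores Tibble from [zscore_guides()] (NTC rows are ignored).
#' @param z_cut Z threshold (default -1.0).
#' @param min_fraction Hit fraction threshold, exclusive (default 0.09).
#' @param min_lines Minimum number of hit lines (default 1).
#' @return A tibble with one row per gene and cell line: `gene`,
#'   `cell_line`, `n_guides`, `fraction`, `line_hit`, plus per-gene
#'   `n_lines_hit` and `essential` repeated within gene.
#' @export
call_gene_essentiality <- function(scores, z_cut = -1.0, min_fraction = 0.09,
                                   min_lines = 1) {
  scores <- dplyr::filter(scores, .data$gene != "NTC")
  abort_if(nrow(scores) == 0, "no scored targeting guides")
  abort_if(any(!is.finite(scores$z)), "gene with unscored guides: z not finite")
  scores |>
    dplyr::group_by(.data$gene, .data$cell_line) |>
    dplyr::summarise(n_guides = dplyr::n(),
                     fraction = mean(.data$z < z_cut), .groups = "drop") |>
    dplyr::mutate(line_hit = .data$fraction > min_fraction) |>
    dplyr::group_by(.data$gene) |>
    dplyr::mutate(n_lines_hit = sum(.data$line_hit),
                  essential = .data$n_lines_hit >= min_lines) |>
    dplyr::ungroup()
}

#' Expected editing genotype fractions in a cell population
#'
#' With in-frame repair probability `p_inframe` per edited allele and
#' `ploidy` independently edited alleles per cell, the fraction of cells
#' with frameshifts on all alleles is `(1 - p)^ploidy` and the remainder
#' carry at least one in-frame (but mutagenized) allele. For the commonly
#' observed p = 0.2 in diploid cells this gives 64% biallelic frameshift
#' and 36% with an in-frame allele.
#'
#' @param p_inframe In-frame repair fraction per edit, in `[0, 1]`.
#' @param ploidy Number of edited alleles per cell (integer >= 1).
#' @return A tibble `p_inframe`, `ploidy`, `all_frameshift`,
#'   `at_least_one_inframe`.
#' @export
#' @examples
#' genotype_fractions(0.2, 2)
genotype_fractions <- function(p_inframe = 0.2, ploidy = 2) {
  abort_if(any(p_inframe < 0 | p_inframe > 1), "p_inframe must be in [0, 1]")
  abort_if(any(ploidy < 1), "ploidy must be >= 1")
  all_fs <- (1 - p_inframe)^ploidy
  tibble::tibble(p_inframe = p_inframe, ploidy = ploidy,
                 all_frameshift = all_fs,
                 at_least_one_inframe = 1 - all_fs)
}

#' Compare two guide feature bins by Mann-Whitney test
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) U test on the cross-line mean
#' Z-scores of two disjoint guide bins (e.g. guides targeting a domain type
#' versus the rest).
#'
#' @param mean_z Tibble from [guide_mean_z()].
#' @param bin_a,bin_b Character vectors of guide ids; disjoint, non-empty.
#' @return A one-row tibble `n_a`, `n_b`, `median_a`, `median_b`, `u`,
#'   `p_value`.
#' @export
compare_feature_bins <- function(mean_z, bin_a, bin_b) {
  abort_if(length(bin_a) == 0 || length(bin_b) == 0, "empty bin")
  abort_if(length(intersect(bin_a, bin_b)) > 0, "bins must be disjoint")
  za <- mean_z$mean_z[match(bin_a, mean_z$guide_id)]
  zb <- mean_z$mean_z[match(bin_b, mean_z$guide_id)]
  abort_if(any(is.na(za)) || any(is.na(zb)), "bin guide absent from scores")
  wt <- wilcox.test(za, zb, alternative = "two.sided")
  tibble::tibble(n_a = length(za), n_b = length(zb),
                 median_a = median(za), median_b = median(zb),
                 u = unname(wt$statistic), p_value = wt$p.value)
}

#' Between-cell-line correlation of guide Z-scores
#'
#' Pearson correlations of per-guide Z-scores between cell lines,
#' nontargeting controls excluded by default.
#'
#' @param scores Tibble from [zscore_guides()].
#' @param exclude_ntc Drop NTC guides first (default `TRUE`).
#' @return A symmetric correlation matrix (class `tile_cor`) with unit
#'   diagonal.
#' @export
cell_line_correlation <- function(scores, exclude_ntc = TRUE) {
  if (exclude_ntc) scores <- dplyr::filter(scores, .data$gene != "NTC")
  wide <- scores |>
    dplyr::select("guide_id", "cell_line", "z") |>
    tidyr::pivot_wider(names_from = "cell_line", values_from = "z")
  abort_if(ncol(wide) < 3, "need >= 2 cell lines")
  m <- cor(as.matrix(wide[-1]), use = "pairwise.complete.obs")
  class(m) <- c("tile_cor", class(m))
  m
}
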