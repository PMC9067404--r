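#' Count overlaps between two region sets
#'
#' A region in `regions_a` counts as overlapping when some region of
#' `regions_b` on the same gene intersects it by at least `min_aa` amino
#' acids (1-based inclusive coordinates, so touching boundaries overlap by
#' one residue).
#'
#' @param regions_a,regions_b Region tibbles (`gene`, `aa_start`, `aa_end`).
#' @param min_aa Minimum intersection length in amino acids (default 1).
#' @return A list: `n_a_overlapping_b` and a `pairs` tibble of every
#'   overlapping pair with its intersection length.
#' @export
overlap_count <- function(regions_a, regions_b, min_aa = 1) {
  a <- tibble::as_tibble(regions_a) |>
    dplyr::mutate(.id_a = dplyr::row_number())
  b <- tibble::as_tibble(regions_b) |>
    dplyr::mutate(.id_b = dplyr::row_number())
  if (nrow(a) == 0 || nrow(b) == 0) {
    return(list(n_a_overlapping_b = 0L,
                pairs = tibble::tibble(id_a = integer(), id_b = integer(),
                                       gene = character(),
                                       overlap_aa = integer())))
  }
  pairs <- dplyr::inner_join(
    dplyr::select(a, ".id_a", "gene", a_start = "aa_start", a_end = "aa_end"),
    dplyr::select(b, ".id_b", "gene", b_start = "aa_start", b_end = "aa_end"),
    by = "gene", relationship = "many-to-many"
  ) |>
    dplyr::mutate(overlap_aa = pmin(.data$a_end, .data$b_end) -
                    pmax(.data$a_start, .data$b_start) + 1L) |>
    dplyr::filter(.data$overlap_aa >= min_aa) |>
    dplyr::select(id_a = ".id_a", id_b = ".id_b", "gene", "overlap_aa")
  list(n_a_overlapping_b = dplyr::n_distinct(pairs$id_a), pairs = pairs)
}

#' Categorize regions by annotation overlap
#'
#' Records every annotation source (Pfam domain, literature-curated
#' functional region, predicted disorder) overlapping each region by at
#' least one amino acid, and assigns a primary display category by
#' precedence `pfam > literature > disorder`; regions overlapping nothing
#' are `"other"`.
#'
#' @param regions Region tibble.
#' @param annotations Annotation tibble from [read_annotations()] (may be
#'   empty).
#' @param precedence Category precedence order for the display category.
#' @return `regions` with list-column `categories` and character column
#'   `category`.
#' @export
categorize_regions <- function(regions, annotations,
                               precedence = c("pfam", "literature", "disorder")) {
  regions <- tibble::as_tibble(regions)
  if (nrow(regions) == 0) {
    regions$categories <- list()
    regions$category <- character(0)
    return(regions)
  }
  annotations <- tibble::as_tibble(annotations)
  cats <- lapply(seq_len(nrow(regions)), function(i) {
    if (nrow(annotations) == 0) return(character(0))
    ann <- annotations[annotations$gene == regions$gene[i], , drop = FALSE]
    if (nrow(ann) == 0) return(character(0))
    ov <- pmin(regions$aa_end[i], ann$aa_end) -
      pmax(regions$aa_start[i], ann$aa_start) + 1L
    sort(unique(ann$source[ov >= 1L]))
  })
  regions$categories <- cats
  regions$category <- vapply(cats, function(cs) {
    hit <- precedence[precedence %in% cs]
    if (length(hit) == 0) "other" else hit[1]
  }, character(1))
  regions
}

#' Average conservation over regions
#'
#' Averages a per-CDS-nucleotide conservation score (phyloP-style,
#' -log10 p scale) over each region's codons (nucleotides
#' `aa_start * 3 - 2` through `aa_end * 3`). A region is conserved when
#' its mean score meets the -log10(alpha) significance level
#' (1.301 at alpha = 0.05).
#'
#' @param regions Region tibble.
#' @param track Per-nucleotide track tibble from [read_conservation()]
#'   (`gene`, `nt`, `score`).
#' @param alpha Significance level for the conservation call (default 0.05).
#' @return `regions` with `mean_phylop` and logical `conserved` columns.
#' @export
conservation_score <- function(regions, track, alpha = 0.05) {
  regions <- tibble::as_tibble(regions)
  thr <- -log10(alpha)
  vals <- vapply(seq_len(nrow(regions)), function(i) {
    tr <- track[track$gene == regions$gene[i], , drop = FALSE]
    nts <- seq.int(regions$aa_start[i] * 3L - 2L, regions$aa_end[i] * 3L)
    sc <- tr$score[match(nts, tr$nt)]
    abort_if(any(is.na(sc)),
             paste0("conservation track does not cover ", regions$gene[i],
                    " aa ", regions$aa_start[i], "-", regions$aa_end[i]))
    mean(sc)
  }, numeric(1))
  regions$mean_phylop <- vals
  regions$conserved <- vals >= thr
  regions
}

#' Fraction of a protein covered by its regions
#'
#' Union length of a gene's regions divided by the protein length
#' (overlapping regions are not double-counted).
#'
#' @param regions Region tibble (may span several genes).
#' @param protein_length Named numeric vector of protein lengths (aa), or a
#'   single number when `regions` has one gene.
#' @return A tibble `gene`, `covered_aa`, `protein_length`, `fraction`.
#' @export
coverage_fraction <- function(regions, protein_length) {
  regions <- tibble::as_tibble(regions)
  genes <- if (nrow(regions) == 0) character(0) else unique(regions$gene)
  if (is.null(names(protein_length))) {
    abort_if(length(genes) > 1 && length(protein_length) == 1,
             "protein_length must be named for multi-gene input")
    if (length(genes) <= 1) {
      names(protein_length) <- if (length(genes) == 1) genes else "gene"
      if (length(genes) == 0) genes <- names(protein_length)
    }
  } else {
    genes <- union(genes, names(protein_length))
  }
  purrr::map_dfr(genes, function(g) {
    L <- unname(protein_length[g])
    abort_if(is.na(L), paste("no protein length for", g))
    r <- regions[regions$gene == g, , drop = FALSE]
    abort_if(nrow(r) > 0 && (any(r$aa_start < 1) || any(r$aa_end > L)),
             paste("region exceeds protein bounds for", g))
    covered <- 0L
    if (nrow(r) > 0) {
      r <- r[order(r$aa_start), , drop = FALSE]
      cur_s <- r$aa_start[1]
      cur_e <- r$aa_end[1]
      for (i in seq_len(nrow(r))[-1]) {
        if (r$aa_start[i] <= cur_e + 0L) {
          cur_e <- max(cur_e, r$aa_end[i])
        } else {
          covered <- covered + (cur_e - cur_s + 1L)
          cur_s <- r$aa_start[i]
          cur_e <- r$aa_end[i]
        }
      }
      covered <- covered + (cur_e - cur_s + 1L)
    }
    tibble::tibble(gene = g, covered_aa = as.integer(covered),
                   protein_length = L, fraction = covered / L)
  })
}
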