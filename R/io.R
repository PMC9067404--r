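#' Read an sgRNA library table
#'
#' Reads a TSV/CSV table of guides with columns `guide_id`, `gene`,
#' `protospacer` and optionally `strand`, `cut_nt` (1-based CDS coordinate of
#' the base immediately 5' of the blunt Cas9 cut on the coding strand) and
#' `p_inframe` (externally predicted in-frame repair fraction). Nontargeting
#' controls carry the reserved gene name `"NTC"` and no cut coordinates.
#'
#' The amino-acid cut position `cut_aa = floor((cut_nt - 1) / 3) + 1` and the
#' sequence-quality flags (`flag_tttt`: contains a TTTT stretch;
#' `flag_yrich`: pyrimidine-rich 3' end) are derived when absent.
#'
#' @param path Path to a TSV or CSV file with a header.
#' @param cds_lengths Optional named integer vector of CDS lengths (nt) per
#'   gene, used to validate `cut_nt`.
#' @return A tibble with one row per guide: `guide_id`, `gene`,
#'   `protospacer`, `strand`, `cut_nt`, `cut_aa`, `flag_tttt`, `flag_yrich`,
#'   and `p_inframe` when supplied.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("guide_id\tgene\tprotospacer\tcut_nt",
#'              "g1\tAURKB\tACGTACGTACGTACGTACGT\t4"), tf)
#' read_library_table(tf)
read_library_table <- function(path, cds_lengths = NULL) {
  tbl <- read_delim_auto(path)
  required <- c("guide_id", "gene", "protospacer")
  missing_cols <- setdiff(required, names(tbl))
  abort_if(length(missing_cols) > 0,
           paste("library table missing columns:",
                 paste(missing_cols, collapse = ", ")))
  validate_library(tbl, cds_lengths)
}

#' @noRd
validate_library <- function(tbl, cds_lengths = NULL) {
  tbl <- tibble::as_tibble(tbl)
  dup <- tbl$guide_id[duplicated(tbl$guide_id)]
  abort_if(length(dup) > 0,
           paste("duplicate guide_id:", paste(unique(dup), collapse = ", ")))
  bad <- !is_dna(tbl$protospacer)
  abort_if(any(bad), "protospacer contains non-ACGT characters")
  abort_if(any(nchar(tbl$protospacer) != 20L),
           "protospacer must be exactly 20 nt")

  if (!"strand" %in% names(tbl)) tbl$strand <- NA_character_
  tbl$strand <- as.character(tbl$strand)
  if (!"cut_nt" %in% names(tbl)) tbl$cut_nt <- NA_integer_
  tbl$cut_nt <- as.integer(tbl$cut_nt)
  targeting <- tbl$gene != "NTC"
  abort_if(any(targeting & !is.na(tbl$cut_nt) & tbl$cut_nt < 1L),
           "cut_nt must be >= 1")
  tbl$cut_nt[!targeting] <- NA_integer_
  tbl$cut_aa <- ifelse(is.na(tbl$cut_nt), NA_integer_, nt_to_aa(tbl$cut_nt))

  if (!is.null(cds_lengths)) {
    known <- targeting & !is.na(tbl$cut_nt) & tbl$gene %in% names(cds_lengths)
    over <- known & tbl$cut_nt > cds_lengths[tbl$gene]
    abort_if(any(over),
             paste("cut_nt exceeds CDS length for:",
                   paste(tbl$guide_id[over], collapse = ", ")))
  }

  if (!all(c("flag_tttt", "flag_yrich") %in% names(tbl))) {
    fl <- flag_guides(tbl$protospacer)
    if (!"flag_tttt" %in% names(tbl)) tbl$flag_tttt <- fl$flag_tttt
    if (!"flag_yrich" %in% names(tbl)) tbl$flag_yrich <- fl$flag_yrich
  }
  if ("p_inframe" %in% names(tbl)) {
    ok <- is.na(tbl$p_inframe) | (tbl$p_inframe >= 0 & tbl$p_inframe <= 1)
    abort_if(!all(ok), "p_inframe must lie in [0, 1]")
  }
  tbl
}

#' Read a guide count matrix with its sample sheet
#'
#' Reads a wide table keyed by `guide_id` whose remaining columns are samples,
#' plus a sample sheet mapping each sample column to `(cell_line, replicate,
#' timepoint)` with timepoint one of `"initial"`/`"final"`. Returns counts in
#' long (tidy) form, one row per guide and sample.
#'
#' @param path Path to the wide counts TSV/CSV.
#' @param sample_sheet A data frame (or path to one) with columns `sample`,
#'   `cell_line`, `replicate`, `timepoint`.
#' @param library Optional library tibble; guides present in the counts but
#'   absent from the library are reported with a warning and recorded in the
#'   `"unknown_guides"` attribute.
#' @return A tibble `guide_id`, `cell_line`, `replicate`, `timepoint`,
#'   `count` with integer counts.
#' @export
read_count_matrix <- function(path, sample_sheet, library = NULL) {
  wide <- read_delim_auto(path)
  abort_if(!"guide_id" %in% names(wide), "counts table must have guide_id")
  if (is.character(sample_sheet)) sample_sheet <- read_delim_auto(sample_sheet)
  sample_sheet <- tibble::as_tibble(sample_sheet)
  need <- c("sample", "cell_line", "replicate", "timepoint")
  abort_if(!all(need %in% names(sample_sheet)),
           "sample sheet needs columns sample, cell_line, replicate, timepoint")
  abort_if(!all(sample_sheet$timepoint %in% c("initial", "final")),
           "timepoint must be 'initial' or 'final'")

  sample_cols <- setdiff(names(wide), "guide_id")
  unmapped <- setdiff(sample_cols, sample_sheet$sample)
  abort_if(length(unmapped) > 0,
           paste("sample columns without metadata:",
                 paste(unmapped, collapse = ", ")))

  long <- wide |>
    tidyr::pivot_longer(dplyr::all_of(sample_cols),
                        names_to = "sample", values_to = "count") |>
    dplyr::inner_join(sample_sheet, by = "sample") |>
    dplyr::select("guide_id", "sample", "cell_line", "replicate",
                  "timepoint", "count")
  abort_if(any(is.na(long$count)), "missing counts")
  abort_if(any(long$count < 0), "negative counts")
  long$count <- as.integer(round(long$count))
  long$replicate <- as.integer(long$replicate)

  # each (cell_line, replicate) must pair one initial with one final sample
  pairing <- long |>
    dplyr::distinct(.data$cell_line, .data$replicate, .data$timepoint,
                    .data$sample) |>
    dplyr::count(.data$cell_line, .data$replicate)
  two_tp <- long |>
    dplyr::distinct(.data$cell_line, .data$replicate, .data$timepoint) |>
    dplyr::count(.data$cell_line, .data$replicate)
  abort_if(any(pairing$n != 2L) || any(two_tp$n != 2L),
           "each (cell_line, replicate) needs exactly one initial and one final sample")
  long <- dplyr::select(long, "guide_id", "cell_line", "replicate",
                        "timepoint", "count")

  unknown <- character(0)
  if (!is.null(library)) {
    unknown <- setdiff(unique(long$guide_id), library$guide_id)
    if (length(unknown) > 0) {
      warning(length(unknown), " guide(s) in counts absent from library: ",
              paste(head(unknown, 5), collapse = ", "), call. = FALSE)
    }
  }
  attr(long, "unknown_guides") <- unknown
  long
}

#' Write called regions to TSV or BED
#'
#' TSV output preserves 1-based inclusive amino-acid coordinates. BED output
#' is 0-based half-open in amino-acid units (`start = aa_start - 1`,
#' `end = aa_end`), with the region score in column 5. Rows are sorted by
#' gene then `aa_start`.
#'
#' @param regions A regions tibble with `gene`, `aa_start`, `aa_end`, `score`.
#' @param path Output file path.
#' @param format `"tsv"` (default) or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  regions <- tibble::as_tibble(regions) |>
    dplyr::arrange(.data$gene, .data$aa_start)
  if (format == "tsv") {
    readr::write_tsv(regions, path, progress = FALSE)
  } else {
    bed <- tibble::tibble(
      chrom = regions$gene,
      start = regions$aa_start - 1L,
      end = regions$aa_end,
      name = paste0(regions$gene, ":", regions$aa_start, "-", regions$aa_end),
      score = regions$score
    )
    readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  }
  invisible(path)
}

#' Read a regions TSV written by [write_regions()]
#'
#' @param path Path to a regions TSV.
#' @return A regions tibble.
#' @export
read_regions <- function(path) {
  tbl <- read_delim_auto(path)
  abort_if(!all(c("gene", "aa_start", "aa_end") %in% names(tbl)),
           "regions table needs gene, aa_start, aa_end")
  abort_if(nrow(tbl) > 0 && any(tbl$aa_start > tbl$aa_end),
           "aa_start must be <= aa_end")
  tbl
}

#' Read an annotation interval table
#'
#' Intervals are 1-based inclusive amino-acid coordinates with a `source`
#' column in `pfam`, `literature`, `disorder`.
#'
#' @param path TSV/CSV with columns `gene`, `aa_start`, `aa_end`, `source`.
#' @return A tibble of annotation intervals.
#' @export
read_annotations <- function(path) {
  tbl <- read_delim_auto(path)
  need <- c("gene", "aa_start", "aa_end", "source")
  abort_if(!all(need %in% names(tbl)),
           "annotation table needs gene, aa_start, aa_end, source")
  abort_if(nrow(tbl) > 0 && any(tbl$aa_start > tbl$aa_end),
           "aa_start must be <= aa_end")
  abort_if(!all(tbl$source %in% c("pfam", "literature", "disorder")),
           "source must be pfam, literature or disorder")
  tbl
}

#' Read a per-CDS-nucleotide conservation track
#'
#' Accepts a bedGraph-style file (`gene`, 0-based `start`, `end`, `score`;
#' no header) or a long per-nucleotide TSV with header columns `gene`, `nt`,
#' `score`. Returns the expanded per-nucleotide track.
#'
#' @param path Path to the track file.
#' @return A tibble `gene`, `nt` (1-based CDS position), `score`.
#' @export
read_conservation <- function(path) {
  first <- readLines(path, n = 1)
  if (grepl("\\bscore\\b", first) && grepl("\\bnt\\b", first)) {
    tbl <- read_delim_auto(path)
    abort_if(!all(c("gene", "nt", "score") %in% names(tbl)),
             "per-nucleotide track needs gene, nt, score")
    return(tibble::as_tibble(tbl[c("gene", "nt", "score")]))
  }
  bg <- readr::read_tsv(path, col_names = c("gene", "start", "end", "score"),
                        show_col_types = FALSE, progress = FALSE)
  purrr::pmap_dfr(bg, function(gene, start, end, score) {
    tibble::tibble(gene = gene, nt = seq.int(start + 1L, end), score = score)
  })
}

#' Read CDS sequences from a FASTA file
#'
#' @param path Path to an uncompressed FASTA of coding sequences.
#' @return A named character vector of uppercase DNA sequences.
#' @export
read_cds_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    seqs <- Biostrings::readDNAStringSet(path)
    out <- toupper(as.character(seqs))
    names(out) <- sub("\\s.*$", "", names(seqs))
    return(out)
  }
  # minimal fallback
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  ids <- sub("^>\\s*", "", sub("\\s.*$", "", lines[hdr]))
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) toupper(paste(x, collapse = "")), character(1))
  setNames(seqs, ids)
}
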