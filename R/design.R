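#' Sequence-quality flags for protospacers
#'
#' `flag_tttt` is `TRUE` when the 20-nt protospacer contains a TTTT stretch
#' (a Pol III terminator-like signal; such guides are excluded from
#' analysis). `flag_yrich` marks pyrimidine-rich 3' ends, which cause
#' premature transcriptional termination of the sgRNA: at least `yrich_min`
#' of the final `yrich_window` protospacer bases (those adjacent to the
#' scaffold) are C or T.
#'
#' @param protospacer Character vector of 20-nt protospacers.
#' @param yrich_window Number of 3'-terminal bases examined (default 4).
#' @param yrich_min Minimum pyrimidine count in that window (default 3).
#' @return A tibble with logical columns `flag_tttt` and `flag_yrich`.
#' @export
#' @examples
#' flag_guides(c("ACGTACGTACGTACGTTTTT", "ACGTACGTACGTACGTGTCT"))
flag_guides <- function(protospacer, yrich_window = 4, yrich_min = 3) {
  abort_if(any(nchar(protospacer) != 20L), "protospacer must be 20 nt")
  tail_seq <- substring(protospacer,
                        nchar(protospacer) - yrich_window + 1L,
                        nchar(protospacer))
  n_py <- nchar(gsub("[^CT]", "", tail_seq))
  tibble::tibble(
    flag_tttt = grepl("TTTT", protospacer, fixed = TRUE),
    flag_yrich = n_py >= yrich_min
  )
}

#' Enumerate all tiling sgRNAs in a coding sequence
#'
#' Scans both strands of a CDS for 20-nt protospacers immediately 5' of an
#' NGG PAM (S. pyogenes Cas9). The blunt cut falls between protospacer
#' positions 17 and 18 (3 bp 5' of the PAM); `cut_nt` is the coding-strand
#' base immediately 5' of the cut, in 1-based CDS coordinates. Only guides
#' whose full 23-mer lies within the CDS can be identified. Protospacers
#' occurring more than once in the CDS (either strand) are ambiguous and
#' are dropped.
#'
#' @param cds_sequence An ACGT string, length divisible by 3.
#' @param gene_name Gene symbol used for `gene` and to derive `guide_id`s.
#' @return A guide tibble (as from [read_library_table()]) ordered by
#'   `cut_nt`.
#' @export
enumerate_guides <- function(cds_sequence, gene_name) {
  abort_if(!is_dna(cds_sequence), "CDS contains non-ACGT characters")
  n <- nchar(cds_sequence)
  if (n < 23L) {
    return(empty_guide_tbl())
  }
  pairs <- substring(cds_sequence, 1:(n - 1), 2:n)

  # plus strand: PAM N at p, GG at p+1..p+2; protospacer p-20..p-1; cut after p-5
  p <- which(pairs == "GG")  # position of first G => p_pam + 1
  p_pam <- p - 1L
  p_pam <- p_pam[p_pam >= 21L & p_pam + 2L <= n]
  plus <- if (length(p_pam) == 0) NULL else tibble::tibble(
    protospacer = substring(cds_sequence, p_pam - 20L, p_pam - 1L),
    strand = "+",
    cut_nt = p_pam - 4L
  )

  # minus strand: CCN at q..q+2 on the coding strand; protospacer is the
  # reverse complement of q+3..q+22; blunt cut between q+5 and q+6
  q <- which(pairs == "CC")
  q <- q[q + 22L <= n]
  minus <- if (length(q) == 0) NULL else tibble::tibble(
    protospacer = revcomp(substring(cds_sequence, q + 3L, q + 22L)),
    strand = "-",
    cut_nt = q + 5L
  )

  guides <- dplyr::bind_rows(plus, minus)
  if (is.null(guides) || nrow(guides) == 0) return(empty_guide_tbl())
  # drop ambiguous protospacers (multiple target sites in this CDS)
  guides <- guides |>
    dplyr::group_by(.data$protospacer) |>
    dplyr::filter(dplyr::n() == 1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$cut_nt, .data$strand)
  if (nrow(guides) == 0) return(empty_guide_tbl())
  guides |>
    dplyr::mutate(
      gene = gene_name,
      guide_id = sprintf("%s_%03d", gene_name, dplyr::row_number()),
      cut_aa = nt_to_aa(.data$cut_nt)
    ) |>
    dplyr::bind_cols(flag_guides(guides$protospacer)) |>
    dplyr::select("guide_id", "gene", "protospacer", "strand",
                  "cut_nt", "cut_aa", "flag_tttt", "flag_yrich")
}

#' @noRd
empty_guide_tbl <- function() {
  tibble::tibble(guide_id = character(), gene = character(),
                 protospacer = character(), strand = character(),
                 cut_nt = integer(), cut_aa = integer(),
                 flag_tttt = logical(), flag_yrich = logical())
}

#' Flag or drop guides matching more than one CDS
#'
#' Exact-match specificity screen: a guide is multi-targeting when its
#' protospacer followed by an NGG PAM occurs in more than one gene's CDS
#' (either strand).
#'
#' @param guides A guide tibble.
#' @param all_cds_sequences Named character vector of every CDS in the
#'   design space.
#' @param action `"flag"` (default) adds a `multi_target` column; `"drop"`
#'   removes multi-targeting guides.
#' @return The guide tibble, flagged or filtered.
#' @export
uniqueness_filter <- function(guides, all_cds_sequences,
                              action = c("flag", "drop")) {
  action <- match.arg(action)
  abort_if(length(all_cds_sequences) == 0,
           "cannot assess uniqueness: empty CDS collection")
  abort_if(is.null(names(all_cds_sequences)),
           "CDS collection must be named by gene")
  rc <- revcomp(all_cds_sequences)
  n_genes_hit <- vapply(guides$protospacer, function(ps) {
    pat <- paste0(ps, "[ACGT]GG")
    sum(grepl(pat, all_cds_sequences) | grepl(pat, rc))
  }, integer(1), USE.NAMES = FALSE)
  guides$multi_target <- n_genes_hit > 1L
  if (action == "drop") {
    guides <- dplyr::filter(guides, !.data$multi_target)
    guides$multi_target <- NULL
  }
  guides
}

#' Cut-site spacing statistics per gene
#'
#' Spacings are successive differences of the sorted unique cut sites of a
#' gene's guides (duplicated cut sites collapse first).
#'
#' @param guides A guide tibble with `gene` and `cut_nt`.
#' @return A tibble `gene`, `n_guides`, `median_nt`, `max_nt`.
#' @export
#' @examples
#' g <- tibble::tibble(gene = "X", cut_nt = c(3, 17, 31))
#' spacing_stats(g)  # median 14, max 14
spacing_stats <- function(guides) {
  guides <- dplyr::filter(guides, !is.na(.data$cut_nt))
  n_sites <- guides |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(n_sites = dplyr::n_distinct(.data$cut_nt),
                     .groups = "drop")
  abort_if(any(n_sites$n_sites < 2L), "spacing needs >= 2 distinct cut sites")
  guides |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      n_guides = dplyr::n(),
      median_nt = median(diff(sort(unique(.data$cut_nt)))),
      max_nt = max(diff(sort(unique(.data$cut_nt)))),
      .groups = "drop"
    )
}

#' Design a tiling library from CDS sequences
#'
#' Enumerates guides for every CDS, screens them for cross-gene
#' exact matches, and applies sequence-quality flags.
#'
#' @param cds_sequences Named character vector of CDSs (or path to a FASTA).
#' @param uniqueness `"flag"`, `"drop"`, or `"none"`.
#' @inheritParams flag_guides
#' @return A guide tibble covering all genes.
#' @export
design_library <- function(cds_sequences, uniqueness = c("flag", "drop", "none"),
                           yrich_window = 4, yrich_min = 3) {
  uniqueness <- match.arg(uniqueness)
  if (is.character(cds_sequences) && length(cds_sequences) == 1 &&
      file.exists(cds_sequences)) {
    cds_sequences <- read_cds_fasta(cds_sequences)
  }
  cds_sequences <- setNames(as.character(cds_sequences),
                            names(cds_sequences))
  abort_if(is.null(names(cds_sequences)),
           "CDS sequences must be named by gene")
  guides <- purrr::imap_dfr(cds_sequences,
                            function(s, g) enumerate_guides(s, g))
  if (nrow(guides) > 0) {
    fl <- flag_guides(guides$protospacer, yrich_window, yrich_min)
    guides$flag_tttt <- fl$flag_tttt
    guides$flag_yrich <- fl$flag_yrich
    if (uniqueness != "none") {
      guides <- uniqueness_filter(guides, cds_sequences, action = uniqueness)
    }
  }
  guides
}
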