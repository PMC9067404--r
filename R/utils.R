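# internal helpers shared across modules

#' @noRd
revcomp <- function(x) {
  comp <- chartr("ACGTacgt", "TGCAtgca", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(b) paste(rev(b), collapse = ""), character(1))
}

#' @noRd
is_dna <- function(x) grepl("^[ACGT]+$", x)

# amino-acid index of a 1-based CDS nucleotide
#' @noRd
nt_to_aa <- function(cut_nt) (cut_nt - 1L) %/% 3L + 1L

#' @noRd
abort_if <- function(cond, msg) if (cond) stop(msg, call. = FALSE)

# reader dispatching on file extension (TSV default)
#' @noRd
read_delim_auto <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  } else {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
}
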