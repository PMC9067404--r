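# Small fixtures built in code.

toy_library <- function() {
  tibble::tibble(
    guide_id = c("g1", "g2", "g3", "g4", "n1", "n2"),
    gene = c("A", "A", "B", "B", "NTC", "NTC"),
    protospacer = c("ACGTACGTACGTACGTACGA", "ACGTACGTACGTACGTACGC",
                    "ACGTACGTACGTACGTACGG", "ACGTACGTACGTACGTAAAA",
                    "CCCCACGTACGTACGTAAAG", "ACGTACGTACGTACGTAAAC"),
    strand = c("+", "+", "+", "-", NA, NA),
    cut_nt = c(4L, 30L, 10L, 40L, NA, NA),
    cut_aa = c(2L, 10L, 4L, 14L, NA, NA),
    flag_tttt = FALSE,
    flag_yrich = FALSE
  )
}

# counts with exact relative-abundance structure; list of per-sample totals
toy_counts <- function(values) {
  # values: named list sample -> integer vector over toy_library guides
  purrr::imap_dfr(values, function(cnt, nm) {
    parts <- strsplit(nm, "\\.")[[1]]  # cell_line.replicate.timepoint
    tibble::tibble(
      guide_id = toy_library()$guide_id,
      cell_line = parts[1],
      replicate = as.integer(parts[2]),
      timepoint = parts[3],
      count = as.integer(cnt)
    )
  })
}

# independent position-by-position guide scan (brute force, loop-based)
brute_force_guides <- function(cds) {
  n <- nchar(cds)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  bases <- strsplit(cds, "")[[1]]
  rc <- function(i, j) paste(rev(unname(comp[bases[i:j]])), collapse = "")
  out <- list()
  for (p in seq_len(n)) {
    # plus strand: PAM N at p, GG at p+1, p+2; protospacer p-20..p-1
    if (p >= 21 && p + 2 <= n && bases[p + 1] == "G" && bases[p + 2] == "G") {
      out[[length(out) + 1]] <- list(
        protospacer = paste(bases[(p - 20):(p - 1)], collapse = ""),
        strand = "+", cut_nt = p - 4L)
    }
    # minus strand: CC at p, p+1 (PAM is CCN read on the minus strand)
    if (p + 22 <= n && bases[p] == "C" && bases[p + 1] == "C") {
      out[[length(out) + 1]] <- list(
        protospacer = rc(p + 3, p + 22), strand = "-", cut_nt = p + 5L)
    }
  }
  tbl <- dplyr::bind_rows(lapply(out, tibble::as_tibble))
  if (nrow(tbl) == 0) return(tbl)
  # drop ambiguous protospacers, mirroring the documented dedup rule
  keep <- names(which(table(tbl$protospacer) == 1))
  tbl <- tbl[tbl$protospacer %in% keep, , drop = FALSE]
  tbl[order(tbl$cut_nt, tbl$strand), ]
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# quick small simulation for pipeline-level tests
small_sim <- function(seed = 7, ...) {
  simulate_screen(sim_config(n_genes = 6, protein_length_range = c(200, 300),
                             n_ntc = 80, n_cell_lines = 2, n_replicates = 2,
                             ...),
                  seed = seed)
}
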