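#' Configuration for a synthetic tiling screen
#'
#' Describes a pooled CRISPR-Cas9 tiling outgrowth screen with known ground
#' truth. Defaults emulate the screened library: cut sites spaced a median
#' of 14 nt apart along each CDS, 601 nontargeting controls, 650x library
#' representation, three replicates of four cell lines grown out over eight
#' days, and a 20% in-frame repair rate in diploid cells. Three-quarters of
#' the genes are frameshift-lethal (essential), mirroring the screened
#' gene panel, and each lethal gene carries two planted essential regions
#' whose in-frame disruption is also lethal; neutral genes carry none.
#'
#' A guide's expected dropout (log2 units) is
#' `effect * ((1-p)^ploidy * lethal + (1 - (1-p)^ploidy) * in_region)`:
#' frameshifted alleles kill cells only in lethal genes, while in-frame
#' repairs kill only when they hit an essential region. Inactive guides and
#' NTCs have no effect.
#'
#' @param n_genes Number of tiled genes (default 40).
#' @param protein_length_range Protein length range in aa (default 300-1000).
#' @param spacing_nt Mean cut-site spacing in nt (default 14).
#' @param n_ntc Number of nontargeting controls (default 601).
#' @param frac_lethal Fraction of genes that are frameshift-lethal
#'   (default 0.75).
#' @param regions_per_gene Planted essential regions per lethal gene
#'   (default 2).
#' @param region_length_range Region length range in aa (default 30-80).
#' @param effect Full dropout effect in log2/Z units (default -3).
#' @param p_inframe_edit In-frame repair fraction per edit (default 0.2).
#' @param ploidy Edited alleles per cell (default 2).
#' @param frac_inactive Fraction of targeting guides that edit nothing
#'   (default 0.10).
#' @param coverage Mean reads/cells per guide (default 650).
#' @param n_cell_lines,n_replicates Screen layout (defaults 4 and 3).
#' @param growth_days Outgrowth duration; a common factor cancelling in
#'   normalized log fold changes (default 8).
#' @param noise_sd Per-guide, per-replicate biological noise SD in log2
#'   units (default 1).
#' @param dispersion Gamma shape of guide abundance heterogeneity in the
#'   plasmid pool (default 10; larger is more even).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 40, protein_length_range = c(300, 1000),
                       spacing_nt = 14, n_ntc = 601, frac_lethal = 0.75,
                       regions_per_gene = 2, region_length_range = c(30, 80),
                       effect = -3, p_inframe_edit = 0.2, ploidy = 2,
                       frac_inactive = 0.10, coverage = 650,
                       n_cell_lines = 4, n_replicates = 3, growth_days = 8,
                       noise_sd = 1, dispersion = 10) {
  fr <- c(frac_lethal, p_inframe_edit, frac_inactive)
  abort_if(any(fr < 0 | fr > 1), "fractions must lie in [0, 1]")
  abort_if(n_genes < 1, "need at least one gene")
  structure(as.list(environment()), class = "sim_config")
}

#' @noRd
random_protospacers <- function(n) {
  m <- matrix(sample(c("A", "C", "G", "T"), 20L * n, replace = TRUE), nrow = n)
  apply(m, 1, paste, collapse = "")
}

#' @noRd
place_regions <- function(n_regions, region_length_range, protein_len) {
  if (n_regions == 0) {
    return(tibble::tibble(aa_start = integer(), aa_end = integer()))
  }
  for (try in 1:200) {
    lens <- sample(seq(region_length_range[1], region_length_range[2]),
                   n_regions, replace = TRUE)
    if (sum(lens) > protein_len) next
    starts <- sort(sample.int(protein_len - min(lens) + 1L, n_regions))
    ends <- starts + lens - 1L
    if (all(ends <= protein_len) &&
        (n_regions == 1 || all(starts[-1] > head(ends, -1) + 1L))) {
      return(tibble::tibble(aa_start = starts, aa_end = ends))
    }
  }
  stop("infeasible region placement", call. = FALSE)
}

#' Simulate a tiling screen with known ground truth
#'
#' Generates a guide library, planted essential regions, and initial/final
#' read counts for every cell line and replicate. Guide abundances follow a
#' gamma-Poisson (negative binomial) model of library representation;
#' outgrowth multiplies abundance by `2^(shift + noise)` where `shift` is
#' the genotype-mixture dropout described in [sim_config()]; final samples
#' are resampled to the same sequencing depth.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; identical seeds give identical screens.
#' @return A list of class `tile_sim`: `library` (guide tibble), `counts`
#'   (long counts tibble), `truth` (list with `regions` and per-guide
#'   `guides` tibbles), and `config`.
#' @export
simulate_screen <- function(config = sim_config(), seed = 0) {
  set.seed(seed)
  cfg <- config
  genes <- sprintf("G%02d", seq_len(cfg$n_genes))
  n_lethal <- round(cfg$frac_lethal * cfg$n_genes)
  lethal <- setNames(seq_along(genes) <= n_lethal, genes)
  protein_len <- setNames(
    sample(seq(cfg$protein_length_range[1], cfg$protein_length_range[2]),
           cfg$n_genes, replace = TRUE), genes)

  # per-gene guides tiled along the CDS
  lib <- purrr::map_dfr(genes, function(g) {
    cds_len <- protein_len[[g]] * 3L
    gaps <- pmax(2L, rpois(ceiling(cds_len / max(cfg$spacing_nt - 2, 1)),
                           cfg$spacing_nt))
    cuts <- cumsum(c(sample(3:16, 1), gaps))
    cuts <- unique(cuts[cuts <= cds_len - 3L])
    tibble::tibble(gene = g, cut_nt = as.integer(cuts))
  })
  lib <- dplyr::bind_rows(
    lib, tibble::tibble(gene = "NTC", cut_nt = NA_integer_)[rep(1, cfg$n_ntc), ]
  )
  lib$guide_id <- sprintf("%s_%04d", lib$gene,
                          stats::ave(seq_len(nrow(lib)), lib$gene,
                                     FUN = seq_along))
  lib$protospacer <- random_protospacers(nrow(lib))
  lib$strand <- ifelse(is.na(lib$cut_nt), NA_character_,
                       sample(c("+", "-"), nrow(lib), replace = TRUE))
  lib$cut_aa <- ifelse(is.na(lib$cut_nt), NA_integer_, nt_to_aa(lib$cut_nt))
  fl <- flag_guides(lib$protospacer)
  lib$flag_tttt <- fl$flag_tttt
  lib$flag_yrich <- fl$flag_yrich
  lib <- dplyr::select(lib, "guide_id", "gene", "protospacer", "strand",
                       "cut_nt", "cut_aa", "flag_tttt", "flag_yrich")

  # planted truth
  true_regions <- purrr::map_dfr(genes, function(g) {
    k <- if (lethal[[g]]) cfg$regions_per_gene else 0L
    r <- place_regions(k, cfg$region_length_range, protein_len[[g]])
    if (nrow(r) > 0) r$gene <- g
    r
  })
  if (nrow(true_regions) > 0) {
    true_regions <- dplyr::select(true_regions, "gene", "aa_start", "aa_end")
  }

  targeting <- lib$gene != "NTC"
  in_region <- rep(FALSE, nrow(lib))
  if (nrow(true_regions) > 0) {
    for (i in seq_len(nrow(true_regions))) {
      hit <- lib$gene == true_regions$gene[i] &
        !is.na(lib$cut_aa) &
        lib$cut_aa >= true_regions$aa_start[i] &
        lib$cut_aa <= true_regions$aa_end[i]
      in_region <- in_region | hit
    }
  }
  inactive <- targeting & runif(nrow(lib)) < cfg$frac_inactive
  p_allfs <- (1 - cfg$p_inframe_edit)^cfg$ploidy
  mixture <- p_allfs * as.numeric(targeting & lethal[lib$gene]) +
    (1 - p_allfs) * as.numeric(in_region)
  mixture[is.na(mixture)] <- 0
  shift <- cfg$effect * mixture * as.numeric(!inactive)
  shift[!targeting] <- 0

  truth_guides <- tibble::tibble(
    guide_id = lib$guide_id, gene = lib$gene, inactive = inactive,
    in_region = in_region, mixture = mixture, shift = shift
  )

  # counts: shared pool abundance, Poisson sampling, outgrowth with noise
  n_g <- nrow(lib)
  abundance <- rgamma(n_g, shape = cfg$dispersion,
                      scale = cfg$coverage / cfg$dispersion)
  lines <- sprintf("line%d", seq_len(cfg$n_cell_lines))
  counts <- purrr::map_dfr(lines, function(cl) {
    purrr::map_dfr(seq_len(cfg$n_replicates), function(rep_i) {
      initial <- rpois(n_g, abundance)
      eps <- rnorm(n_g, sd = cfg$noise_sd)
      fin_mean <- abundance * 2^(cfg$growth_days / 8 * shift + eps)
      fin_mean <- fin_mean * (cfg$coverage * n_g / sum(fin_mean))
      final <- rpois(n_g, fin_mean)
      tibble::tibble(
        guide_id = rep(lib$guide_id, 2L),
        cell_line = cl, replicate = rep_i,
        timepoint = rep(c("initial", "final"), each = n_g),
        count = c(initial, final)
      )
    })
  })

  structure(list(library = lib, counts = counts,
                 truth = list(regions = true_regions, guides = truth_guides,
                              protein_length = protein_len, lethal = lethal),
                 config = cfg),
            class = "tile_sim")
}

#' @export
print.tile_sim <- function(x, ...) {
  cat(sprintf(paste0("<tile_sim> %d genes, %d guides (%d NTC), ",
                     "%d planted regions, %d cell lines x %d replicates\n"),
              x$config$n_genes, nrow(x$library),
              sum(x$library$gene == "NTC"), nrow(x$truth$regions),
              x$config$n_cell_lines, x$config$n_replicates))
  invisible(x)
}

#' Replace a fraction of each gene's guide scores with NTC-range noise
#'
#' Emulates low-efficiency guides: per gene, `round(fraction * n_guides)`
#' guides are chosen uniformly without replacement and their score is
#' replaced by a uniform draw from the observed nontargeting-control score
#' range.
#'
#' @param mean_z Per-guide score tibble (`guide_id`, `gene`, `mean_z`).
#' @param fraction Fraction of guides to replace per gene, in `[0, 1]`.
#' @param ntc_z Numeric vector of NTC scores defining the replacement range.
#' @param seed Optional seed for reproducible replacement.
#' @return `mean_z` with replaced scores and a logical `replaced` column.
#' @export
perturb_with_ntc <- function(mean_z, fraction, ntc_z, seed = NULL) {
  abort_if(length(ntc_z) == 0 || all(is.na(ntc_z)), "no NTC values supplied")
  abort_if(fraction < 0 || fraction > 1, "fraction must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  lo <- min(ntc_z, na.rm = TRUE)
  hi <- max(ntc_z, na.rm = TRUE)
  out <- tibble::as_tibble(mean_z)
  out$replaced <- FALSE
  for (g in setdiff(unique(out$gene), "NTC")) {
    idx <- which(out$gene == g)
    k <- round(fraction * length(idx))
    if (k > 0) {
      pick <- sample(idx, k)
      out$mean_z[pick] <- runif(k, lo, hi)
      out$replaced[pick] <- TRUE
    }
  }
  out
}

#' Region-level precision and recall
#'
#' Precision is the fraction of called regions overlapping at least one
#' true region by `min_aa` amino acids or more; recall is the fraction of
#' true regions overlapped by at least one called region. With no called
#' regions precision is reported as 1 with `precision_defined = FALSE`.
#'
#' @param called,truth Region tibbles (`gene`, `aa_start`, `aa_end`).
#' @param min_aa Minimum overlap (default 1 aa).
#' @return A one-row tibble: `precision`, `recall`, `n_called`, `n_true`,
#'   `precision_defined`.
#' @export
precision_recall <- function(called, truth, min_aa = 1) {
  n_called <- nrow(called)
  n_true <- nrow(truth)
  prec_def <- n_called > 0
  precision <- if (prec_def) {
    overlap_count(called, truth, min_aa)$n_a_overlapping_b / n_called
  } else 1.0
  recall <- if (n_true > 0) {
    overlap_count(truth, called, min_aa)$n_a_overlapping_b / n_true
  } else 1.0
  tibble::tibble(precision = precision, recall = recall,
                 n_called = n_called, n_true = n_true,
                 precision_defined = prec_def)
}

#' Nontargeting-substitution robustness experiment
#'
#' Measures how region calls degrade as guide signal is lost: for each
#' replacement fraction and seed, a fraction of every gene's guide scores
#' is replaced by NTC-range noise ([perturb_with_ntc()]), profiles are
#' refit, regions recalled, and scored by precision/recall against the
#' unperturbed baseline regions.
#'
#' @param mean_z Per-guide score tibble (including NTC rows).
#' @param library Guide library tibble.
#' @param fractions Replacement fractions (default 0, 0.1, ..., 0.5).
#' @param n_seeds Replacement randomizations per fraction (default 5).
#' @param config A [solver_config()].
#' @param tau Region-calling margin (default 1.0).
#' @param method Deconvolution method, `"tivex"` or `"fused"`.
#' @param min_aa Overlap rule for precision/recall (default 1).
#' @param seed Base seed; per-run seeds are derived deterministically.
#' @return A tibble with one row per fraction x seed: `fraction`, `seed`,
#'   `precision`, `recall`, `n_called`, `n_true`; baseline regions in
#'   attribute `"baseline"`.
#' @export
robustness_experiment <- function(mean_z, library,
                                  fractions = seq(0, 0.5, by = 0.1),
                                  n_seeds = 5, config = solver_config(),
                                  tau = 1.0, method = c("tivex", "fused"),
                                  min_aa = 1, seed = 0) {
  method <- match.arg(method)
  ntc_z <- mean_z$mean_z[mean_z$gene == "NTC"]
  abort_if(length(ntc_z) == 0, "no NTC values supplied")
  ntc_sd <- sd(ntc_z)
  base_fits <- fit_profiles(mean_z, library, config, method = method)
  baseline <- call_regions(base_fits, tau = tau, ntc_sd = ntc_sd)

  out <- purrr::map_dfr(seq_along(fractions), function(fi) {
    purrr::map_dfr(seq_len(n_seeds), function(s) {
      run_seed <- seed * 1013L + fi * 131L + s
      pert <- perturb_with_ntc(mean_z, fractions[fi], ntc_z, seed = run_seed)
      fits <- fit_profiles(pert, library, config, method = method)
      regions <- call_regions(fits, tau = tau, ntc_sd = ntc_sd)
      pr <- precision_recall(regions, baseline, min_aa = min_aa)
      tibble::tibble(fraction = fractions[fi], seed = s,
                     precision = pr$precision, recall = pr$recall,
                     n_called = pr$n_called, n_true = pr$n_true)
    })
  })
  attr(out, "baseline") <- baseline
  out
}

#' Summarize a robustness experiment over seeds
#'
#' @param robustness Tibble from [robustness_experiment()].
#' @return A tibble per fraction with seed-averaged precision/recall and
#'   95% normal confidence half-widths.
#' @export
summarize_robustness <- function(robustness) {
  robustness |>
    dplyr::group_by(.data$fraction) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_precision = mean(.data$precision),
      mean_recall = mean(.data$recall),
      ci_precision = 1.96 * sd(.data$precision) / sqrt(dplyr::n()),
      ci_recall = 1.96 * sd(.data$recall) / sqrt(dplyr::n()),
      .groups = "drop"
    )
}
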