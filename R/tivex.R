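#' Solver configuration for piecewise-constant deconvolution
#'
#' Bundles the sparsity weight `lambda0`, the fusion weight `lambda1`, the
#' curvature parameters `a0`, `a1` of the concave penalty transform
#' `f(t, a) = (1 - exp(-a * |t|)) / a`, and convergence controls. The
#' transformed objective is convex exactly when
#' `1 - a0 * lambda0 - 4 * a1 * lambda1 >= 0` (the transform's curvature is
#' bounded by `a` and the squared spectral norm of the first-difference
#' operator by 4).
#'
#' @param lambda0 Sparsity weight, >= 0.
#' @param lambda1 Fusion weight, >= 0.
#' @param a0,a1 Transform curvature parameters, >= 0; 0 recovers the plain
#'   fused lasso penalties.
#' @param tol Relative objective-change convergence tolerance.
#' @param max_iter Maximum majorize-minimize iterations.
#' @return A `tivex_config` list.
#' @export
solver_config <- function(lambda0 = 0.05, lambda1 = 3, a0 = 0.5, a1 = 0.05,
                          tol = 1e-8, max_iter = 100) {
  abort_if(lambda0 < 0 || lambda1 < 0 || a0 < 0 || a1 < 0,
           "lambda0, lambda1, a0, a1 must be >= 0")
  structure(list(lambda0 = lambda0, lambda1 = lambda1, a0 = a0, a1 = a1,
                 tol = tol, max_iter = max_iter),
            class = "tivex_config")
}

#' Convexity gate for the transformed objective
#'
#' `TRUE` iff `1 - a0 * lambda0 - 4 * a1 * lambda1 >= 0` (boundary
#' included), the condition under which the transformed fused-lasso
#' objective remains convex.
#'
#' @param config A `tivex_config`, or `lambda0` given all four numbers.
#' @param lambda1,a0,a1 Used when `config` is numeric.
#' @return Logical.
#' @export
#' @examples
#' check_convexity(solver_config(lambda0 = 0.5, lambda1 = 0, a0 = 2, a1 = 0))
check_convexity <- function(config, lambda1 = NULL, a0 = NULL, a1 = NULL) {
  if (is.numeric(config)) {
    config <- list(lambda0 = config, lambda1 = lambda1, a0 = a0, a1 = a1)
  }
  1 - config$a0 * config$lambda0 - 4 * config$a1 * config$lambda1 >= 0
}

#' @noRd
new_step_fit <- function(gene, y, positions, x_hat, objective, config,
                         iterations = 1L, converged = TRUE, trace = objective,
                         method = "fused", seg_tol = 1e-5) {
  segments <- segments_from_fit(x_hat, seg_tol)
  structure(list(gene = gene, y = y, positions = positions, x_hat = x_hat,
                 segments = segments, objective = objective, config = config,
                 iterations = iterations, converged = converged,
                 trace = trace, method = method),
            class = "tile_step_fit")
}

#' @noRd
segments_from_fit <- function(x_hat, seg_tol = 1e-5) {
  n <- length(x_hat)
  if (n == 0) {
    return(tibble::tibble(start_idx = integer(), end_idx = integer(),
                          value = numeric()))
  }
  new_seg <- c(TRUE, abs(diff(x_hat)) > seg_tol)
  id <- cumsum(new_seg)
  tibble::tibble(idx = seq_len(n), id = id, x = x_hat) |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(start_idx = min(.data$idx), end_idx = max(.data$idx),
                     value = mean(.data$x), .groups = "drop") |>
    dplyr::select("start_idx", "end_idx", "value")
}

#' Fused lasso fit of a depletion profile
#'
#' Exact global minimizer of
#' `0.5 * ||y - x||^2 + lambda0 * ||x||_1 + lambda1 * sum_i |x_i - x_{i-1}|`,
#' the piecewise-constant deconvolution baseline. Solved via the
#' box-constrained dual with a duality-gap certificate.
#'
#' @param y Numeric vector of per-guide mean Z-scores ordered by cut site.
#' @param lambda0 Sparsity weight.
#' @param lambda1 Fusion weight.
#' @param positions Optional cut-site coordinates (`cut_nt`) for `y`.
#' @param gene Optional gene name carried into the fit object.
#' @return A `tile_step_fit` object; see [tidy.tile_step_fit()].
#' @export
fused_lasso_fit <- function(y, lambda0, lambda1, positions = NULL,
                            gene = NA_character_) {
  abort_if(length(y) < 1, "y must have length >= 1")
  abort_if(any(!is.finite(y)), "y contains non-finite values")
  abort_if(lambda0 < 0 || lambda1 < 0, "penalties must be >= 0")
  n <- length(y)
  sol <- cpp_weighted_fused(y, rep(lambda0, n), rep(lambda1, max(n - 1, 0)))
  x <- as.numeric(sol$x)
  obj <- 0.5 * sum((y - x)^2) + lambda0 * sum(abs(x)) +
    lambda1 * sum(abs(diff(x)))
  cfg <- solver_config(lambda0 = lambda0, lambda1 = lambda1, a0 = 0, a1 = 0)
  new_step_fit(gene, y, positions %||% seq_len(n), x, obj, cfg,
               method = "fused")
}

#' Convex fused lasso (TiVex) fit of a depletion profile
#'
#' Minimizes
#' `0.5 * ||y - x||^2 + lambda0 * sum_i f(|x_i|, a0) +
#'  lambda1 * sum_i f(|x_i - x_{i-1}|, a1)` with the concave transform
#' `f(t, a) = (1 - exp(-a t)) / a`, by majorize-minimize over exactly
#' solved elementwise-weighted fused-lasso subproblems. The transform
#' relaxes the over-shrinkage of large depletion blocks while the
#' convexity gate ([check_convexity()]) guarantees a global optimum; the
#' objective is non-increasing across iterations.
#'
#' @inheritParams fused_lasso_fit
#' @param config A [solver_config()]; must satisfy the convexity condition.
#' @return A `tile_step_fit` object with the objective `trace` across MM
#'   iterations.
#' @export
convex_fused_fit <- function(y, config = solver_config(), positions = NULL,
                             gene = NA_character_) {
  abort_if(length(y) < 1, "y must have length >= 1")
  abort_if(any(!is.finite(y)), "y contains non-finite values")
  abort_if(!check_convexity(config),
           "convexity condition 1 - a0*lambda0 - 4*a1*lambda1 >= 0 violated")
  sol <- cpp_convex_fused(y, config$lambda0, config$lambda1,
                          config$a0, config$a1,
                          tol = config$tol, max_iter = config$max_iter)
  if (!sol$converged) {
    warning("convex fused fit did not converge in ", config$max_iter,
            " iterations; returning last iterate", call. = FALSE)
  }
  new_step_fit(gene, y, positions %||% seq_along(y), as.numeric(sol$x),
               sol$objective, config, iterations = sol$iterations,
               converged = sol$converged, trace = as.numeric(sol$trace),
               method = "tivex")
}

#' @export
print.tile_step_fit <- function(x, ...) {
  cat(sprintf("<tile_step_fit> gene=%s n=%d segments=%d objective=%.6g (%s)\n",
              x$gene, length(x$y), nrow(x$segments), x$objective, x$method))
  invisible(x)
}

#' Tidy a step fit into its segments
#'
#' @param x A `tile_step_fit`.
#' @param ... Unused.
#' @return A tibble with one row per fitted segment: index range, cut-site
#'   range, fitted value.
#' @export
tidy.tile_step_fit <- function(x, ...) {
  seg <- x$segments
  seg |>
    dplyr::mutate(gene = x$gene,
                  pos_start = x$positions[seg$start_idx],
                  pos_end = x$positions[seg$end_idx],
                  n_guides = seg$end_idx - seg$start_idx + 1L) |>
    dplyr::select("gene", "start_idx", "end_idx", "pos_start", "pos_end",
                  "n_guides", "value")
}

#' One-row summary of a step fit
#'
#' @param x A `tile_step_fit`.
#' @param ... Unused.
#' @return A one-row tibble with fit size, objective, segment count and
#'   solver settings.
#' @export
glance.tile_step_fit <- function(x, ...) {
  tibble::tibble(gene = x$gene, n = length(x$y), objective = x$objective,
                 n_segments = nrow(x$segments), iterations = x$iterations,
                 converged = x$converged, method = x$method,
                 lambda0 = x$config$lambda0, lambda1 = x$config$lambda1,
                 a0 = x$config$a0, a1 = x$config$a1)
}

#' Fit depletion profiles for every gene
#'
#' Orders each gene's guides by cut site and fits the chosen
#' piecewise-constant model to the cross-line mean Z profile. NTC guides
#' and guides without cut coordinates are excluded.
#'
#' @param mean_z Tibble from [guide_mean_z()].
#' @param library Guide library tibble (cut coordinates).
#' @param config A [solver_config()].
#' @param method `"tivex"` (convex fused lasso, default) or `"fused"`.
#' @return A named list of `tile_step_fit` objects, one per gene.
#' @export
fit_profiles <- function(mean_z, library, config = solver_config(),
                         method = c("tivex", "fused")) {
  method <- match.arg(method)
  dat <- mean_z |>
    dplyr::inner_join(dplyr::select(library, "guide_id", "cut_nt", "cut_aa"),
                      by = "guide_id") |>
    dplyr::filter(.data$gene != "NTC", !is.na(.data$cut_nt)) |>
    dplyr::arrange(.data$gene, .data$cut_nt)
  abort_if(nrow(dat) == 0, "no targeting guides with cut coordinates")
  dat |>
    dplyr::group_split(.data$gene) |>
    purrr::map(function(d) {
      g <- d$gene[1]
      fit <- if (method == "tivex") {
        convex_fused_fit(d$mean_z, config, positions = d$cut_nt, gene = g)
      } else {
        fused_lasso_fit(d$mean_z, config$lambda0, config$lambda1,
                        positions = d$cut_nt, gene = g)
      }
      fit$cut_aa <- d$cut_aa
      fit$guide_id <- d$guide_id
      fit
    }) |>
    setNames(nm = purrr::map_chr(dat |> dplyr::group_split(.data$gene),
                                 ~ .x$gene[1]))
}

#' Call negatively enriched regions from fitted profiles
#'
#' Compares each gene's fitted depletion profile with the global average of
#' fitted values across all genes: maximal runs of consecutive guides whose
#' fitted value lies more than `tau * ntc_sd` below the global mean become
#' regions. The margin is expressed in units of the nontargeting-control
#' score SD when one is supplied (the neutral-proliferation noise scale);
#' without one the scores' own Z unit is used. Region boundaries are the
#' outermost qualifying guides' amino-acid cut positions; the region score
#' is the mean fitted value over the run.
#'
#' @param fits List of `tile_step_fit` objects from [fit_profiles()].
#' @param tau Depletion margin below the global mean, in units of `ntc_sd`
#'   (default 1.0).
#' @param min_len_aa Minimum region length in amino acids (default 1).
#' @param global_mean Optional override of the global baseline (e.g. from a
#'   larger screen); defaults to the guide-weighted mean fitted value
#'   across all genes.
#' @param ntc_sd Optional SD of the nontargeting-control scores on the same
#'   scale as the fitted input; defaults to 1.
#' @return A regions tibble: `gene`, `aa_start`, `aa_end`, `score`,
#'   `n_guides`, `method`, with attributes `"global_mean"` and
#'   `"threshold"`.
#' @export
call_regions <- function(fits, tau = 1.0, min_len_aa = 1, global_mean = NULL,
                         ntc_sd = NULL) {
  abort_if(length(fits) == 0, "no fits supplied")
  if (is.null(global_mean)) {
    global_mean <- mean(unlist(purrr::map(fits, "x_hat")))
  }
  thr <- global_mean - tau * (ntc_sd %||% 1)
  out <- purrr::map_dfr(fits, function(f) {
    abort_if(is.null(f$cut_aa), "fit lacks amino-acid cut positions")
    qual <- f$x_hat < thr
    if (!any(qual)) return(NULL)
    runs <- rle(qual)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    keep <- which(runs$values)
    tibble::tibble(
      gene = f$gene,
      aa_start = f$cut_aa[starts[keep]],
      aa_end = f$cut_aa[ends[keep]],
      score = vapply(keep, function(k) {
        mean(f$x_hat[starts[k]:ends[k]])
      }, numeric(1)),
      n_guides = runs$lengths[keep],
      method = f$method
    )
  })
  if (nrow(out) > 0) {
    out <- dplyr::filter(out, .data$aa_end - .data$aa_start + 1L >= min_len_aa)
    out <- dplyr::arrange(out, .data$gene, .data$aa_start)
  } else {
    out <- tibble::tibble(gene = character(), aa_start = integer(),
                          aa_end = integer(), score = numeric(),
                          n_guides = integer(), method = character())
  }
  attr(out, "global_mean") <- global_mean
  attr(out, "threshold") <- thr
  out
}

#' Select solver penalties by a BIC-type score
#'
#' Fits every configuration in a grid to each profile and scores the total
#' `n * log(RSS / n) + log(n) * (n_segments + n_nonzero_segments)`,
#' summed over genes; the configuration with the smallest total wins, ties
#' broken toward larger `lambda1` (smoother fits).
#'
#' @param y_list A list of numeric profiles (one per gene), or a single
#'   numeric vector.
#' @param grid A data frame with columns `lambda0`, `lambda1`, `a0`, `a1`;
#'   all rows must satisfy the convexity condition.
#' @return The selected [solver_config()], with the scored grid in
#'   attribute `"grid"`.
#' @export
lambda_select <- function(y_list, grid) {
  if (is.numeric(y_list)) y_list <- list(y_list)
  grid <- tibble::as_tibble(grid)
  abort_if(nrow(grid) == 0, "empty grid")
  ok <- vapply(seq_len(nrow(grid)), function(i) {
    check_convexity(grid$lambda0[i], grid$lambda1[i], grid$a0[i], grid$a1[i])
  }, logical(1))
  abort_if(!all(ok), "grid contains configurations violating convexity")

  grid$score <- vapply(seq_len(nrow(grid)), function(i) {
    cfg <- solver_config(grid$lambda0[i], grid$lambda1[i],
                         grid$a0[i], grid$a1[i])
    sum(vapply(y_list, function(y) {
      fit <- convex_fused_fit(y, cfg)
      n <- length(y)
      rss <- max(sum((y - fit$x_hat)^2), n * 1e-10)
      nseg <- nrow(fit$segments)
      nnz <- sum(abs(fit$segments$value) > 1e-8)
      n * log(rss / n) + log(n) * (nseg + nnz)
    }, numeric(1)))
  }, numeric(1))

  best <- grid |>
    dplyr::filter(.data$score <= min(.data$score) + 1e-9) |>
    dplyr::arrange(dplyr::desc(.data$lambda1)) |>
    dplyr::slice(1)
  out <- solver_config(best$lambda0, best$lambda1, best$a0, best$a1)
  attr(out, "grid") <- grid
  out
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
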