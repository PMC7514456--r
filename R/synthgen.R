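#' Specification of a synthetic compositional grid simulation
#'
#' Parameters of the seeded generator in [simulate_composition()]. The
#' generator emulates compositional land-cover-like data: per-cell category
#' fractions summing to 1, spatially autocorrelated dominant-category
#' patches, and smooth multi-decadal trends in category prevalence. The
#' defaults are a desk-scale analogue of a northern-latitudes vegetation
#' simulation: a few hundred cells, a few decades of annual steps, 11
#' categories.
#'
#' @param n_rows,n_cols grid dimensions (cells).
#' @param n_times number of time steps.
#' @param n_categories number of categories.
#' @param corr_length spatial correlation length in cells (Gaussian kernel
#'   sd); larger values produce larger dominant-category patches.
#' @param trend per-category temporal trend slopes on the logit (softmax
#'   score) scale per time step; default spreads slopes evenly in
#'   `[-0.03, 0.03]`.
#' @param field_sd standard deviation of the smoothed spatial score fields
#'   (patch-forcing intensity).
#' @param noise_sd standard deviation of the i.i.d. score noise added per
#'   (cell, time, category).
#' @param seed integer seed; a fixed seed yields byte-identical output.
#' @return an object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_rows = 24, n_cols = 24, n_times = 40,
                            n_categories = 11, corr_length = 3,
                            trend = seq(-0.03, 0.03,
                                        length.out = n_categories),
                            field_sd = 1.5, noise_sd = 0.25, seed = 1) {
  stopifnot(n_rows >= 1, n_cols >= 1, n_times >= 1, n_categories >= 2,
            corr_length > 0, field_sd >= 0, noise_sd >= 0,
            length(trend) == n_categories)
  structure(list(n_rows = n_rows, n_cols = n_cols, n_times = n_times,
                 n_categories = n_categories, corr_length = corr_length,
                 trend = trend, field_sd = field_sd, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

# Gaussian-kernel smoothing of a matrix (truncated at 3 sd, edge
# renormalised); separable convolution.
smooth_matrix <- function(m, sd) {
  half <- max(1L, ceiling(3 * sd))
  kern <- stats::dnorm(-half:half, sd = sd)
  smooth_1d <- function(x) {
    n <- length(x)
    out <- numeric(n)
    for (i in seq_len(n)) {
      lo <- max(1L, i - half); hi <- min(n, i + half)
      kk <- kern[(lo - i + half + 1L):(hi - i + half + 1L)]
      out[i] <- sum(x[lo:hi] * kk) / sum(kk)
    }
    out
  }
  m <- apply(m, 2, smooth_1d)
  t(apply(m, 1, smooth_1d))
}

#' Simulate a compositional grid time series
#'
#' Softmax-of-Gaussian-fields construction: each category receives a
#' spatially smoothed white-noise score field (scaled to `field_sd`), a
#' linear temporal trend on the score scale, and i.i.d. score noise; the
#' per-(cell, time) fractions are the softmax over categories, so they are
#' valid compositions summing exactly to 1, the dominant categories form
#' contiguous patches whose typical size grows with the correlation
#' length, and positive-trend categories expand smoothly over time.
#'
#' @param spec a [simulation_spec()].
#' @return a `composition_grid` with categories `cat01..catK` and times
#'   `1..n_times`.
#' @export
simulate_composition <- function(spec = simulation_spec()) {
  stopifnot(inherits(spec, "simulation_spec"))
  nr <- spec$n_rows; nc <- spec$n_cols
  nt <- spec$n_times; nk <- spec$n_categories
  withr_seed(spec$seed, {
    fields <- lapply(seq_len(nk), function(k) {
      f <- smooth_matrix(matrix(stats::rnorm(nr * nc), nr, nc),
                         spec$corr_length)
      s <- stats::sd(f)
      if (s > 0) f <- f / s * spec$field_sd
      f
    })
    scores <- array(0, dim = c(nr * nc, nt, nk))
    for (k in seq_len(nk)) {
      base <- as.vector(t(fields[[k]]))  # row-major cell order
      for (j in seq_len(nt))
        scores[, j, k] <- base + spec$trend[k] * (j - 1)
    }
    if (spec$noise_sd > 0)
      scores <- scores + array(stats::rnorm(length(scores),
                                            sd = spec$noise_sd),
                               dim = dim(scores))
    escore <- exp(scores - as.vector(apply(scores, c(1, 2), max)))
    frac <- escore / as.vector(apply(escore, c(1, 2), sum))
    cells <- expand.grid(col = 0:(nc - 1), row = 0:(nr - 1))
    cells <- cells[order(cells$row, cells$col), c("row", "col")]
    cells$cell_id <- paste0("c", cells$row, "_", cells$col)
    composition_grid(frac, cells[, c("cell_id", "row", "col")],
                     times = seq_len(nt),
                     categories = sprintf("cat%02d", seq_len(nk)))
  })
}

#' Rank-structured multiway table with known decomposition
#'
#' Builds a table `margins-product + sigma_star * weighted rank-one
#' perturbation` with known component vectors: the perturbation vectors are
#' centred (margin-orthogonal to the all-ones vector) and normalised in the
#' margin-weighted metric, so a multiway correspondence analysis of the
#' table must recover `sigma_1 = sigma_star` and the margins are preserved
#' for any admissible `sigma_star`.
#'
#' @param dims label counts per mode (length 2 or 3).
#' @param sigma_star perturbation magnitude; must keep all cells
#'   non-negative.
#' @param seed seed for the random margins and vectors.
#' @return a `multiway_table` with attributes `"sigma_star"` and
#'   `"vectors"` (the construction's component vectors).
#' @export
make_rank_structured_table <- function(dims, sigma_star = 0.05, seed = 1) {
  stopifnot(length(dims) %in% c(2L, 3L), all(dims >= 2))
  withr_seed(seed, {
    margins <- lapply(dims, function(k) {
      m <- stats::runif(k, 0.5, 1.5); m / sum(m)
    })
    vecs <- lapply(margins, function(m) {
      v <- stats::rnorm(length(m))
      v <- v - sum(m * v)              # centred: orthogonal to 1 under m
      v / sqrt(sum(m * v^2))           # weighted unit norm
    })
  })
  indep <- Reduce(`%o%`, margins)
  pert <- Reduce(`%o%`, mapply(function(m, v) m * v, margins, vecs,
                               SIMPLIFY = FALSE))
  p <- indep + sigma_star * pert
  if (any(p < 0))
    stop("negative cells; use a smaller sigma_star (max admissible ~",
         format(sigma_star * min(indep / pmax(-sigma_star * pert, 1e-300))),
         ")")
  labs <- lapply(seq_along(dims), function(m)
    paste0(c("s", "t", "c")[m], seq_len(dims[m])))
  dimnames(p) <- labs
  names(dimnames(p)) <- c("S", "T", "C")[seq_along(dims)]
  tb <- multiway_table(p, kind = "occurrence")
  attr(tb, "sigma_star") <- sigma_star
  attr(tb, "vectors") <- vecs
  tb
}

#' Worked-example fixtures
#'
#' Published summary values for a land-cover patch analysis (7 spatial size
#' classes, 8 temporal size classes, 11 categories), usable as reference
#' inputs: the per-year normalized entropy decomposition table, the
#' log-cardinality weights for cardinalities (7, 11), the per-component CTR
#' entropies and variability shares of the multiway correspondence
#' analysis, and the default size classings.
#'
#' @return named list of fixtures.
#' @export
worked_example_fixtures <- function() {
  entropy_table <- data.frame(
    quantity = c("Si", "C|Si", "C", "Si|C", "Si,C"),
    y2020 = c(0.7030593, 0.6548033, 0.8520292, 0.4600228, 0.6764207),
    y2050 = c(0.7933917, 0.5613683, 0.8745148, 0.4075092, 0.6653087),
    y2100 = c(0.7640653, 0.6314215, 0.9297879, 0.3963961, 0.6908424))
  ctr_entropies <- data.frame(
    tensor_share = c(40.9, 16.70, 9.54, 3.55),
    Si = c(0.786, 0.661, 0.786, 0.929),
    Ti = c(0.596, 0.596, 0.908, 0.830),
    C = c(0.894, 0.830, 0.452, 0.356),
    combined = c(0.765, 0.703, 0.701, 0.683))
  list(
    table1 = entropy_table,
    weights_7_11 = c(S = 0.4479736, C = 0.5520264),
    t4_tensor1 = c(Si = 0.786, Ti = 0.595, C = 0.894, combined = 0.764),
    table4 = ctr_entropies,
    si_classes = spatial_size_classes(),
    ti_classes = temporal_size_classes(),
    n_categories = 11L,
    margins_si = c("1" = 2, "2" = 2, ">2" = 5, ">7" = 14, ">25" = 12,
                   ">50" = 23, ">100" = 42),
    margins_ti = c("1" = 1, "2" = 1, ">2" = 1, ">4" = 2, ">7" = 8,
                   ">20" = 7, ">30" = 21, ">60" = 59))
}
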