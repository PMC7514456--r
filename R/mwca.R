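#' Ratio-to-independence tensor
#'
#' Elementwise ratio `p / (pS %o% pT %o% pC ...)` of the joint probability
#' tensor to the product of its margins — the quantity whose weighted
#' rank-one decomposition generalises correspondence analysis to multiway
#' tables. Labels with zero margin are dropped first (and reported), since
#' the ratio is undefined there.
#'
#' @param table a `multiway_table`.
#' @return list with `ratio` (array), `margins` (after dropping),
#'   `dropped` (named list of dropped labels per mode), and the reduced
#'   probability array `p`.
#' @export
independence_ratio_tensor <- function(table) {
  stopifnot(inherits(table, "multiway_table"))
  p <- table$p
  dropped <- lapply(table$margins, function(mg) names(mg)[mg <= 0])
  if (any(lengths(dropped) > 0)) {
    keep <- lapply(table$margins, function(mg) which(mg > 0))
    p <- do.call(`[`, c(list(p), keep, list(drop = FALSE)))
    p <- p / sum(p)
  }
  margins <- lapply(seq_along(dim(p)), function(m) apply(p, m, sum))
  names(margins) <- table$modes
  if (any(unlist(margins) <= 0)) stop("zero margin remained after dropping")
  indep <- Reduce(`%o%`, margins)
  list(ratio = p / indep, margins = margins, dropped = dropped, p = p)
}

#' Chi-square statistic of departure from independence
#'
#' `chi^2 / N = sum (p - prod(margins))^2 / prod(margins)` over all cells,
#' the total weighted variability that the rank-one decomposition splits:
#' the squared singular values of a complete decomposition satisfy
#' `sum sigma_r^2 = 1 + chi^2 / N`.
#'
#' @param table a `multiway_table`.
#' @return `chi^2 / N` (dimensionless).
#' @export
chi_square <- function(table) {
  irt <- independence_ratio_tensor(table)
  indep <- Reduce(`%o%`, irt$margins)
  sum((irt$p - indep)^2 / indep)
}

# higher-order power iteration for the leading rank-one term of a 3-d array
# Y (unweighted metric). Deterministic SVD-based init; seeded random
# restarts guard against local maxima.
hopm_rank1 <- function(Y, tol = 1e-12, max_iter = 1000, n_restarts = 3,
                       seed = 1) {
  d <- dim(Y)
  unfold1 <- matrix(Y, nrow = d[1])
  best <- NULL
  inits <- list(svd(unfold1, nu = 1, nv = 0)$u[, 1])
  if (n_restarts > 1) {
    rng <- withr_seed(seed, lapply(seq_len(n_restarts - 1), function(i)
      stats::rnorm(d[1])))
    inits <- c(inits, lapply(rng, function(v) v / sqrt(sum(v^2))))
  }
  zero_fit <- list(sigma = 0, a = c(1, rep(0, d[1] - 1))[seq_len(d[1])],
                   b = c(1, rep(0, d[2] - 1))[seq_len(d[2])],
                   c = c(1, rep(0, d[3] - 1))[seq_len(d[3])],
                   converged = TRUE, iterations = 0L)
  if (sqrt(sum(Y^2)) < 1e-14) return(zero_fit)
  for (a0 in inits) {
    a <- a0; b <- rep(1 / sqrt(d[2]), d[2]); c <- rep(1 / sqrt(d[3]), d[3])
    sigma <- 0; converged <- FALSE; degenerate <- FALSE
    for (it in seq_len(max_iter)) {
      c_old <- c
      # contract over the other two modes in turn
      bc <- as.vector(outer(b, c))
      a_new <- unfold1 %*% bc
      na <- sqrt(sum(a_new^2))
      if (na < 1e-300) { degenerate <- TRUE; break }
      a <- as.vector(a_new) / na
      Ya <- apply(Y * array(a, d), c(2, 3), sum)
      b_new <- Ya %*% c
      nb <- sqrt(sum(b_new^2))
      if (nb < 1e-300) { degenerate <- TRUE; break }
      b <- as.vector(b_new) / nb
      c_new <- t(Ya) %*% b
      s_new <- sqrt(sum(c_new^2))
      if (s_new < 1e-300) { degenerate <- TRUE; break }
      c <- as.vector(c_new) / s_new
      # converge on both the value and the factor (sign-insensitive)
      dc <- min(max(abs(c - c_old)), max(abs(c + c_old)))
      if (abs(s_new - sigma) < tol * max(1, abs(s_new)) && dc < tol) {
        sigma <- s_new; converged <- TRUE; break
      }
      sigma <- s_new
    }
    if (degenerate) { if (is.null(best)) best <- zero_fit; next }
    if (is.null(best) || sigma > best$sigma + 1e-12)
      best <- list(sigma = sigma, a = a, b = b, c = c,
                   converged = converged, iterations = it)
  }
  best
}

#' Weighted multiway correspondence analysis
#'
#' Decomposes the ratio-to-independence tensor of a multiway table into
#' successive rank-one terms under the margin-weighted metric:
#' `p / (pS %o% pT %o% pC) = 1 + sum_r sigma_r (vS_r %o% vT_r %o% vC_r)`,
#' each mode vector normalised as `sum_s pS_s vS_rs^2 = 1`. Component 0 is
#' the exact independence term (`sigma_0 = 1`, all-ones vectors); later
#' components are extracted greedily by higher-order power iteration on the
#' deflated residual, which for 2-mode tables reduces exactly to classical
#' correspondence analysis (SVD of standardised residuals). The squared
#' singular values decompose the chi-square statistic:
#' `sum_r sigma_r^2 = 1 + chi^2 / N`, and each component's share of
#' variability is `sigma_r^2 / (1 + chi^2 / N)`.
#'
#' Sign indeterminacy of each rank-one term is resolved by making the
#' largest-magnitude entry of the last-mode (category) vector positive.
#'
#' @param table a `multiway_table` (2 or 3 modes).
#' @param n_components number of non-trivial components to extract.
#' @param tol relative convergence tolerance on sigma.
#' @param max_iter power-iteration cap per component.
#' @param seed seed for the restart initialisations.
#' @return an object of class `mwca_result`: `components` (list; element r+1
#'   is component r with fields `index`, `sigma`, `vectors`, `share`),
#'   `chi2_n`, `total_ss = 1 + chi2_n`, `margins`, `dropped`,
#'   `residual_norm` and convergence diagnostics.
#' @export
decompose_fca <- function(table, n_components = 4, tol = 1e-12,
                          max_iter = 1000, seed = 1) {
  stopifnot(n_components >= 1)
  irt <- independence_ratio_tensor(table)
  d <- dim(irt$p)
  two_mode <- length(d) == 2L
  if (two_mode) {
    dim(irt$ratio) <- c(d, 1L)
    irt$margins <- c(irt$margins, list(.dummy = 1))
    d <- c(d, 1L)
  }
  if (length(d) != 3L) stop("only 2- or 3-mode tables are supported")
  sq <- lapply(irt$margins, sqrt)
  W <- Reduce(`%o%`, sq)          # sqrt of margin-product weights
  Y <- irt$ratio * W              # unweighted metric equivalent
  chi2_n <- chi_square(table)
  total_ss <- 1 + chi2_n
  comps <- list()
  ones <- lapply(d, function(k) rep(1, k))
  comps[[1]] <- list(index = 0L, sigma = 1,
                     vectors = ones,
                     share = 100 * 1 / total_ss,
                     converged = TRUE, iterations = 0L)
  # deflate the exact independence component
  Y_res <- Y - Reduce(`%o%`, sq)
  for (r in seq_len(n_components)) {
    h <- hopm_rank1(Y_res, tol = tol, max_iter = max_iter,
                    seed = seed + r)
    v <- list(h$a / sq[[1]], h$b / sq[[2]], h$c / sq[[3]])
    # sign convention: dominant entry of the last real mode positive
    last <- if (two_mode) 2L else 3L
    sgn <- sign(v[[last]][which.max(abs(v[[last]]))])
    if (sgn < 0) { v[[1]] <- -v[[1]]; v[[last]] <- -v[[last]] }
    comps[[r + 1]] <- list(index = r, sigma = h$sigma, vectors = v,
                           share = 100 * h$sigma^2 / total_ss,
                           converged = h$converged,
                           iterations = h$iterations)
    if (!h$converged)
      warning("component ", r, " did not converge in ", max_iter,
              " iterations")
    Y_res <- Y_res - h$sigma * Reduce(`%o%`, list(h$a, h$b, h$c))
  }
  if (two_mode) {
    comps <- lapply(comps, function(cp) {
      cp$vectors <- cp$vectors[1:2]; cp
    })
    irt$margins <- irt$margins[1:2]
  }
  labs <- lapply(irt$margins, names)
  comps <- lapply(comps, function(cp) {
    cp$vectors <- mapply(function(v, nm) stats::setNames(v, nm),
                         cp$vectors, labs, SIMPLIFY = FALSE)
    names(cp$vectors) <- names(irt$margins)
    cp
  })
  structure(list(components = comps, chi2_n = chi2_n, total_ss = total_ss,
                 margins = irt$margins, dropped = irt$dropped,
                 modes = names(irt$margins),
                 residual_norm = sqrt(sum(Y_res^2)),
                 n_components = n_components, seed = seed),
            class = "mwca_result")
}

#' @export
print.mwca_result <- function(x, ...) {
  cat(sprintf("mwca_result: chi2/N = %.6f, total SS = %.6f, residual %.2e\n",
              x$chi2_n, x$total_ss, x$residual_norm))
  for (cp in x$components)
    cat(sprintf("  r=%d  sigma = %.6f  share = %.2f%%\n", cp$index,
                cp$sigma, cp$share))
  invisible(x)
}

#' Relative contributions (CTR) of a rank-one component
#'
#' The CTR tensor of component r is the outer product of the per-mode
#' vectors `p * v^2`; each of those vectors sums to 1 by the weighted
#' normalisation, so the tensor is a product distribution quantifying the
#' contribution of every label combination to the component. The signed
#' per-category percentages (100 * p * v^2, carrying the sign of v) are the
#' values reported in signed-CTR tables.
#'
#' @param result an `mwca_result`.
#' @param r component index (0 for the independence term).
#' @return list with `tensor`, `by_mode` (list of CTR vectors) and
#'   `signed_percent` (list of signed percentage vectors).
#' @export
ctr <- function(result, r) {
  cp <- component(result, r)
  by_mode <- mapply(function(m, v) m * v^2, result$margins, cp$vectors,
                    SIMPLIFY = FALSE)
  signed <- mapply(function(ct, v) 100 * ct * sign(v), by_mode,
                   cp$vectors, SIMPLIFY = FALSE)
  list(tensor = Reduce(`%o%`, by_mode), by_mode = by_mode,
       signed_percent = signed)
}

component <- function(result, r) {
  stopifnot(inherits(result, "mwca_result"))
  if (r < 0 || r > length(result$components) - 1)
    stop("component ", r, " not fitted")
  result$components[[r + 1]]
}

#' Normalized entropy of a CTR tensor
#'
#' The CTR tensor is a product distribution, so its normalized entropy is
#' the log-cardinality-weighted mean of the per-mode normalized entropies:
#' `Hu = (sum_m log(n_m) Hu_m) / log(prod n_m)`. For per-mode values
#' 0.786, 0.595 and 0.894 with cardinalities 7, 8 and 11 this gives 0.764.
#'
#' @param result an `mwca_result`, or `NULL` when `hu` is given directly.
#' @param r component index.
#' @param hu optional per-mode normalized entropies (bypasses `result`).
#' @param cardinalities label counts, required with `hu`.
#' @return list with `by_mode` (per-mode Hu) and `combined`.
#' @export
ctr_entropy <- function(result = NULL, r = NULL, hu = NULL,
                        cardinalities = NULL) {
  if (is.null(hu)) {
    ct <- ctr(result, r)
    cardinalities <- vapply(ct$by_mode, length, 0L)
    hu <- vapply(ct$by_mode, function(v) normalized_entropy(v), 0)
  }
  stopifnot(length(hu) == length(cardinalities))
  list(by_mode = hu,
       combined = combine_normalized(hu, cardinalities))
}

#' Analytic positive split of a rank-one tensor
#'
#' Writes a signed rank-one tensor `x %o% y %o% z` (here `x = pS vS_r`
#' etc., including the singular value) as the difference of two
#' non-negative parts, each a sum of at most 4 pairwise orthogonal rank-one
#' terms built from the positive/negative parts of the factors: terms with
#' an even number of negative-part factors form the positive part, odd ones
#' the negative part. Each non-negative term is renormalised into a latent
#' product distribution `mu * (p'S %o% p'T %o% p'C)` with
#' `p' = u / sum(u)` and `mu` the product of the factor sums, supporting an
#' additive entropy reading of each term.
#'
#' @param result an `mwca_result`.
#' @param r component index (> 0; component 0 is already non-negative).
#' @return an object of class `signed_split`: lists `positive` and
#'   `negative` of terms, each with `factors`, `mu` and normalised `latent`
#'   distributions; all-zero combinations are omitted.
#' @export
positive_split <- function(result, r) {
  cp <- component(result, r)
  factors <- mapply(function(m, v) m * v, result$margins, cp$vectors,
                    SIMPLIFY = FALSE)
  factors[[1]] <- factors[[1]] * cp$sigma
  split_rank_one(factors, modes = result$modes)
}

# factors: list of k signed vectors; returns the positive/negative split
split_rank_one <- function(factors, modes = names(factors)) {
  k <- length(factors)
  pos_part <- lapply(factors, function(u) pmax(u, 0))
  neg_part <- lapply(factors, function(u) pmax(-u, 0))
  signs <- expand.grid(rep(list(c(1, -1)), k))
  terms_pos <- list(); terms_neg <- list()
  for (i in seq_len(nrow(signs))) {
    sg <- unlist(signs[i, ], use.names = FALSE)
    term <- mapply(function(s, p, n) if (s > 0) p else n,
                   sg, pos_part, neg_part, SIMPLIFY = FALSE)
    if (any(vapply(term, function(u) all(u == 0), TRUE))) next
    names(term) <- modes
    mu <- prod(vapply(term, sum, 0))
    latent <- lapply(term, function(u) u / sum(u))
    entry <- list(factors = term, mu = mu, latent = latent,
                  sign_pattern = sg)
    if (prod(sg) > 0) terms_pos[[length(terms_pos) + 1]] <- entry
    else terms_neg[[length(terms_neg) + 1]] <- entry
  }
  structure(list(positive = terms_pos, negative = terms_neg,
                 factors = factors, modes = modes),
            class = "signed_split")
}

#' Reconstruct the two parts of a signed split
#'
#' @param split a `signed_split`.
#' @return list with arrays `positive`, `negative` and `tensor`
#'   (their difference, equal to the outer product of the factors).
#' @export
split_tensors <- function(split) {
  zero <- Reduce(`%o%`, lapply(split$factors, function(u) u * 0))
  add <- function(terms) Reduce(`+`, c(list(zero), lapply(terms, function(tm)
    Reduce(`%o%`, tm$factors))))
  pos <- add(split$positive); neg <- add(split$negative)
  list(positive = pos, negative = neg, tensor = pos - neg)
}

#' Per-mode entropic contribution ratios of a component
#'
#' For a non-negative product distribution `p'S %o% p'T %o% p'C` (a latent
#' term of a positive split, or a CTR tensor) the joint entropy is the sum
#' of the per-mode entropies, and the ratio `H(mode) / H(joint)` measures
#' the entropic contribution of that mode to the extracted structuring;
#' the remaining modes contribute the complement. Computed on the CTR
#' vectors this is the HRCTR statistic.
#'
#' @param x a `signed_split` (the first positive term's latent
#'   distributions are used), a list of non-negative per-mode vectors, or
#'   an `mwca_result` with `r` (CTR vectors are used).
#' @param r component index when `x` is an `mwca_result`.
#' @return list with `H_mode`, `H_joint` and `ratio` per mode (`NA` with
#'   attribute `"undefined"` when the joint entropy is zero).
#' @export
entropy_ratios <- function(x, r = NULL) {
  vecs <- if (inherits(x, "signed_split")) {
    if (!length(x$positive)) stop("split has no positive term")
    x$positive[[1]]$latent
  } else if (inherits(x, "mwca_result")) {
    ctr(x, r)$by_mode
  } else x
  H <- vapply(vecs, function(v) shannon_entropy(v / sum(v)), 0)
  Hj <- sum(H)
  if (Hj == 0) {
    out <- list(H_mode = H, H_joint = 0, ratio = NA)
    attr(out, "undefined") <- "zero joint entropy"
    return(out)
  }
  list(H_mode = H, H_joint = Hj, ratio = H / Hj)
}

#' Signed per-cell component scores
#'
#' For each grid cell carrying one label per mode (its local spatial-size
#' class, temporal-size class and category), the score is the geometric
#' mean of the three CTR weights at those labels, signed by the sign of the
#' category-mode vector entry — a spatial intensity of the component's
#' pattern.
#'
#' @param result an `mwca_result`.
#' @param r component index.
#' @param cell_labels data frame with a `cell_id` column and one column per
#'   mode holding the cell's label (NA allowed).
#' @return data frame with columns `cell_id` and `score` (`NA` where a
#'   label is missing or unknown).
#' @export
signed_scores <- function(result, r, cell_labels) {
  ct <- ctr(result, r)
  cp <- component(result, r)
  modes <- result$modes
  miss <- setdiff(modes, names(cell_labels))
  if (length(miss)) stop("cell_labels lack mode column(s): ",
                         paste(miss, collapse = ", "))
  c_mode <- modes[length(modes)]
  score <- rep(NA_real_, nrow(cell_labels))
  for (i in seq_len(nrow(cell_labels))) {
    labs <- vapply(modes, function(m) as.character(cell_labels[[m]][i]), "")
    if (anyNA(labs)) next
    w <- mapply(function(m, lb) ct$by_mode[[m]][lb], modes, labs)
    if (anyNA(w)) next
    sgn <- sign(cp$vectors[[c_mode]][labs[length(labs)]])
    if (is.na(sgn)) next
    score[i] <- sgn * prod(w)^(1 / length(modes))
  }
  data.frame(cell_id = cell_labels$cell_id, score = score,
             stringsAsFactors = FALSE)
}

#' Serialise an mwca result
#'
#' JSON with singular values, shares, vectors and diagnostics, plus one CSV
#' per requested component with the signed-CTR table layout
#' (mode, label, signed CTR %).
#'
#' @param result an `mwca_result`.
#' @param path JSON path; signed-CTR CSVs are written next to it as
#'   `<stem>_ctr_r<r>.csv`.
#' @param components component indices for CTR CSVs.
#' @return `path`, invisibly.
#' @export
write_mwca <- function(result, path,
                       components = seq_len(length(result$components) - 1)) {
  jsonlite::write_json(
    list(chi2_n = result$chi2_n, total_ss = result$total_ss,
         modes = result$modes,
         residual_norm = result$residual_norm,
         components = lapply(result$components, function(cp)
           list(index = cp$index, sigma = cp$sigma, share = cp$share,
                converged = cp$converged, vectors = cp$vectors))),
    path, auto_unbox = TRUE, digits = NA, force = TRUE)
  stem <- tools::file_path_sans_ext(path)
  for (r in components) {
    ct <- ctr(result, r)
    df <- do.call(rbind, lapply(result$modes, function(m)
      data.frame(mode = m, label = names(ct$signed_percent[[m]]),
                 signed_ctr_percent = unname(ct$signed_percent[[m]]),
                 stringsAsFactors = FALSE)))
    utils::write.csv(df, sprintf("%s_ctr_r%d.csv", stem, r),
                     row.names = FALSE)
  }
  invisible(path)
}
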