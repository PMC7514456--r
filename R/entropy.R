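#' Shannon entropy of a probability vector or tensor
#'
#' Computes `-sum(p * log(p))` in nats with the convention
#' `0 * log(0) = 0`. The input must be a proper probability mass function
#' (non-negative, summing to 1 within 1e-6).
#'
#' @param p numeric vector or array of probabilities.
#' @return entropy in nats.
#' @export
shannon_entropy <- function(p) {
  p <- as.vector(p)
  if (any(p < 0)) stop("negative probability mass")
  if (abs(sum(p) - 1) > 1e-6)
    stop("probabilities must sum to 1 (got ", format(sum(p)), ")")
  pos <- p > 0
  -sum(p[pos] * log(p[pos]))
}

#' Normalized Shannon entropy
#'
#' `Hu(p) = H(p) / log(n)` with `n` the number of support labels, spanning
#' `[0, 1]`: 1 for the uniform distribution, 0 for a degenerate one. The
#' normalization makes values comparable across label sets of different
#' sizes and independent of the logarithm base.
#'
#' @param p probability vector or tensor; `n` counts its cells, including
#'   zero-mass labels (the size of the label set, not of the support).
#' @param n override for the label count.
#' @return value in `[0, 1]`. A 1-label distribution returns 1 (degenerate
#'   uniform) with a warning.
#' @export
normalized_entropy <- function(p, n = length(p)) {
  if (n < 1) stop("empty label set")
  if (n == 1) {
    warning("normalized entropy of a 1-label mode defined as 1")
    return(1)
  }
  shannon_entropy(p) / log(n)
}

# entropy of the marginal over the given mode subset of a joint p-array
marginal_p <- function(p, modes_keep, mode_names) {
  keep <- match(modes_keep, mode_names)
  if (anyNA(keep)) stop("unknown mode(s): ",
                        paste(modes_keep[is.na(keep)], collapse = ", "))
  if (length(keep) == length(mode_names)) return(aperm(p, keep))
  apply(p, keep, sum)
}

#' Conditional entropy from a multiway table
#'
#' `H(target | given) = sum_g p_g H(target | given = g)`, the expectation
#' over the conditioning strata of the within-stratum entropies. The
#' per-stratum parts `p_g * H(target | given = g)` are returned so that
#' conditional-entropy ratio maps can be built from them. Zero-mass strata
#' contribute zero and are excluded. The normalized variant divides by
#' `log` of the number of target label combinations.
#'
#' @param table a `multiway_table`.
#' @param target mode name(s) whose entropy is measured.
#' @param given disjoint mode name(s) conditioned on.
#' @param normalized return `Hu(target | given)` and normalized parts.
#' @return list with `value`, `parts` (named by stratum), and
#'   `p_given` (stratum masses).
#' @export
conditional_entropy <- function(table, target, given, normalized = FALSE) {
  stopifnot(inherits(table, "multiway_table"))
  if (length(intersect(target, given)))
    stop("'target' and 'given' must be disjoint")
  p <- table$p
  mn <- table$modes
  p_joint <- marginal_p(p, c(given, target), mn)
  # reorder so conditioning modes come first
  ng <- length(given)
  dims <- dim(p_joint)
  g_cells <- prod(dims[seq_len(ng)])
  m <- matrix(aperm(p_joint, seq_along(dims)), nrow = g_cells)
  # strata labels
  g_labs <- do.call(expand.grid, dimnames(p_joint)[seq_len(ng)])
  g_names <- do.call(paste, c(g_labs, sep = "/"))
  p_g <- rowSums(m)
  parts <- vapply(seq_len(g_cells), function(i) {
    if (p_g[i] <= 0) return(0)
    cond <- m[i, ] / p_g[i]
    p_g[i] * shannon_entropy(cond)
  }, 0)
  names(parts) <- g_names
  n_target <- prod(vapply(dimnames(p_joint)[-seq_len(ng)], length, 0L))
  value <- sum(parts)
  if (normalized) {
    value <- value / log(n_target)
    parts <- parts / log(n_target)
  }
  list(value = value, parts = parts, p_given = stats::setNames(p_g, g_names))
}

#' Mutual information of a multiway table
#'
#' The Kullback-Leibler divergence between the joint distribution and the
#' product of its margins, `MI = sum p log(p / prod(margins))`, generalised
#' to any number of modes (for k modes this equals the total correlation
#' `sum_m H(mode m) - H(joint)`). For two modes it reduces to
#' `H(C) - H(C|S)`.
#'
#' @param table a `multiway_table` with at least 2 modes.
#' @return MI in nats, non-negative up to floating error.
#' @export
mutual_information <- function(table) {
  stopifnot(inherits(table, "multiway_table"))
  if (length(table$modes) < 2) stop("need at least 2 modes")
  p <- table$p
  indep <- Reduce(`%o%`, table$margins)
  pos <- p > 0
  sum(p[pos] * log(p[pos] / indep[pos]))
}

#' Log-cardinality weights of the normalized entropy decomposition
#'
#' The chain `Hu(X1, ..., Xk) = sum_i w_i Hu(X_i | X_1..i-1)` holds with
#' `w_i = log(n_i) / sum_j log(n_j)`, `n_i` the label count of mode i.
#' For label counts 7 and 11 the weights are 0.4479736 and 0.5520264.
#'
#' @param cardinalities per-mode label counts.
#' @return weights summing to 1.
#' @export
decomposition_weights <- function(cardinalities) {
  if (any(cardinalities < 2)) stop("mode cardinalities must be >= 2")
  w <- log(cardinalities)
  w / sum(w)
}

#' Combine normalized entropy components with log-cardinality weights
#'
#' Given normalized entropies of the terms of a decomposition chain (or of
#' the modes of a product distribution) and their label counts, returns the
#' weighted combination — the joint normalized entropy. E.g. combining
#' `Hu(Si) = 0.7030593` and `Hu(C | Si) = 0.6548033` with cardinalities
#' `(7, 11)` yields `Hu(Si, C) = 0.6764207`.
#'
#' @param hu normalized entropy values, one per chain term.
#' @param cardinalities label counts of the corresponding modes.
#' @return the combined normalized entropy.
#' @export
combine_normalized <- function(hu, cardinalities) {
  stopifnot(length(hu) == length(cardinalities))
  sum(decomposition_weights(cardinalities) * hu)
}

#' Full entropy decomposition of a multiway table
#'
#' Applies the entropy decomposition theorem along a chain of modes:
#' `H(joint) = H(m1) + H(m2 | m1) + H(m3 | m1, m2) + ...`, together with
#' the per-mode marginal entropies, the normalized (uniform-referenced)
#' variants with their log-cardinality weights, and the mutual information.
#' All identities (chain rule, MI as margins-minus-joint, the weighted
#' normalized identity) are asserted to 1e-9 and the maximum residual is
#' reported.
#'
#' @param table a `multiway_table`.
#' @param chain mode names in conditioning order (a permutation of the
#'   table's modes); defaults to table order.
#' @param normalized include the normalized quantities (default).
#' @return an object of class `entropy_report`.
#' @export
entropy_decompose <- function(table, chain = table$modes, normalized = TRUE) {
  stopifnot(inherits(table, "multiway_table"))
  if (!setequal(chain, table$modes))
    stop("'chain' must be a permutation of the table modes")
  p <- table$p
  mn <- table$modes
  card <- vapply(table$labels, length, 0L)[chain]
  H_joint <- shannon_entropy(p)
  H_mode <- vapply(chain, function(m)
    shannon_entropy(marginal_p(p, m, mn)), 0)
  chain_terms <- numeric(length(chain))
  chain_terms[1] <- H_mode[1]
  cond_parts <- list()
  for (i in seq_along(chain)[-1]) {
    ce <- conditional_entropy(table, target = chain[i],
                              given = chain[seq_len(i - 1)])
    chain_terms[i] <- ce$value
    cond_parts[[paste0(chain[i], "|", paste(chain[seq_len(i - 1)],
                                            collapse = ","))]] <- ce$parts
  }
  names(chain_terms) <- c(chain[1],
                          names(cond_parts))[seq_along(chain)]
  mi <- mutual_information(table)
  resid <- c(chain = abs(H_joint - sum(chain_terms)),
             mi = abs(mi - (sum(H_mode) - H_joint)))
  weights <- decomposition_weights(card)
  hu_mode <- H_mode / log(card)
  hu_terms <- chain_terms / log(card)
  hu_joint <- H_joint / log(prod(card))
  resid <- c(resid,
             normalized = abs(hu_joint - sum(weights * hu_terms)))
  if (max(resid) > 1e-9)
    warning("decomposition identity residual ", format(max(resid)))
  structure(list(chain = chain, H_joint = H_joint, H_mode = H_mode,
                 chain_terms = chain_terms, cond_parts = cond_parts,
                 MI = mi,
                 weights = if (normalized) stats::setNames(weights, chain),
                 Hu_mode = if (normalized) hu_mode,
                 Hu_terms = if (normalized) hu_terms,
                 Hu_joint = if (normalized) hu_joint,
                 cardinalities = stats::setNames(card, chain),
                 max_residual = max(resid)),
            class = "entropy_report")
}

#' @export
print.entropy_report <- function(x, ...) {
  cat("entropy_report — chain:", paste(x$chain, collapse = " -> "), "\n")
  cat(sprintf("  H(joint) = %.6f nats; MI = %.6f\n", x$H_joint, x$MI))
  for (i in seq_along(x$chain_terms))
    cat(sprintf("  H(%s) = %.6f\n", names(x$chain_terms)[i],
                x$chain_terms[i]))
  if (!is.null(x$Hu_joint)) {
    cat(sprintf("  Hu(joint) = %.7f; weights: %s\n", x$Hu_joint,
                paste(sprintf("%s=%.7f", names(x$weights), x$weights),
                      collapse = ", ")))
    for (i in seq_along(x$Hu_terms))
      cat(sprintf("  Hu(%s) = %.7f\n", names(x$chain_terms)[i],
                  x$Hu_terms[i]))
  }
  cat(sprintf("  max identity residual: %.2e\n", x$max_residual))
  invisible(x)
}

#' Serialise an entropy report
#'
#' One row per quantity as CSV, or the full report as JSON.
#'
#' @param report an `entropy_report`.
#' @param path output path; extension selects the format (`.csv` or
#'   `.json`).
#' @return `path`, invisibly.
#' @export
write_entropy_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         digits = NA, force = TRUE)
  } else {
    rows <- rbind(
      data.frame(quantity = "H_joint", value = report$H_joint),
      data.frame(quantity = paste0("H_", names(report$H_mode)),
                 value = unname(report$H_mode)),
      data.frame(quantity = paste0("H_", names(report$chain_terms)),
                 value = unname(report$chain_terms)),
      data.frame(quantity = "MI", value = report$MI))
    if (!is.null(report$Hu_joint))
      rows <- rbind(rows,
                    data.frame(quantity = "Hu_joint",
                               value = report$Hu_joint),
                    data.frame(quantity = paste0("Hu_",
                                                 names(report$chain_terms)),
                               value = unname(report$Hu_terms)),
                    data.frame(quantity = paste0("w_", names(report$weights)),
                               value = unname(report$weights)))
    utils::write.csv(rows, path, row.names = FALSE)
  }
  invisible(path)
}

#' Conditional-entropy ratio of a label subset
#'
#' The share of the conditional entropy `H(target | given)` contributed by
#' a subset of conditioning labels:
#' `sum_{s in subset} p_s H(target | given = s) / H(target | given)`.
#' The ratio over all labels is 1, it is additive over disjoint subsets,
#' and raw and uniform-normalized versions coincide.
#'
#' @param table a `multiway_table`.
#' @param target,given mode names as in [conditional_entropy()].
#' @param subset conditioning labels (stratum names, `/`-joined for
#'   multi-mode conditioning).
#' @return ratio in `[0, 1]`; `NA` with attribute `"undefined"` when
#'   `H(target | given) = 0`.
#' @export
conditional_entropy_ratio <- function(table, target, given, subset) {
  if (!length(subset)) stop("'subset' must be non-empty")
  ce <- conditional_entropy(table, target, given)
  if (ce$value == 0) {
    out <- NA_real_
    attr(out, "undefined") <- "H(target | given) is zero"
    return(out)
  }
  miss <- setdiff(subset, names(ce$parts))
  if (length(miss)) stop("unknown conditioning label(s): ",
                         paste(miss, collapse = ", "))
  sum(ce$parts[subset]) / ce$value
}

#' Per-cell map of locally restricted conditional-entropy parts
#'
#' For each grid cell, sums the conditional-entropy parts
#' `p_s H(target | given = s)` over the conditioning labels occurring at
#' that cell (e.g. the size classes of the patches covering it) and
#' expresses the sum as a percentage of the global conditional entropy.
#' Cells where no label occurs (no patch) get `NA`, readable as uniformity
#' through absence of patches.
#'
#' @param table a `multiway_table`.
#' @param target,given mode names.
#' @param local_labels named list: per cell id, the character vector of
#'   conditioning labels occurring there.
#' @return data frame with columns `cell_id` and `percent`.
#' @export
map_statistic <- function(table, target, given, local_labels) {
  ce <- conditional_entropy(table, target, given)
  pct <- vapply(local_labels, function(labs) {
    labs <- intersect(labs, names(ce$parts))
    if (!length(labs) || ce$value == 0) return(NA_real_)
    100 * sum(ce$parts[labs]) / ce$value
  }, 0)
  data.frame(cell_id = names(local_labels), percent = unname(pct),
             stringsAsFactors = FALSE)
}
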