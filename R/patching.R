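#' Spatial patches of a category at one time step
#'
#' A spatial patch is a maximal set of connected grid cells whose occupation
#' fraction for the category strictly exceeds the threshold at the given
#' time. Connectivity is 4-neighbour (rook) by default or 8-neighbour
#' (queen). Patches of different categories are computed independently and
#' may overlap spatially, so one cell can belong to several patches across
#' categories. The membership degree of a cell is its fraction, retaining
#' the fuzziness of compositional data.
#'
#' @param grid a `composition_grid`.
#' @param category a category label of the grid.
#' @param threshold minimum fraction, strict inequality (e.g. 0.15 for
#'   "greater than 15%").
#' @param connectivity 4 or 8.
#' @param time a time label of the grid.
#' @return an object of class `patch_set` with one element per connected
#'   component; each patch records its members (0-based `(row, col)` pairs),
#'   size (member count) and membership degrees.
#' @export
spatial_patches <- function(grid, category, threshold = 0.15,
                            connectivity = 4, time = grid$times[1]) {
  stopifnot(threshold > 0, threshold < 1, connectivity %in% c(4, 8))
  k <- match(category, grid$categories)
  if (is.na(k)) stop("unknown category: ", category)
  j <- match(time, grid$times)
  if (is.na(j)) stop("unknown time: ", time)
  frac <- grid$fractions[, j, k]
  on <- which(frac > threshold)
  patches <- list()
  if (length(on)) {
    comp <- connected_components(grid$cells$row[on], grid$cells$col[on],
                                 connectivity)
    for (ci in seq_len(max(comp))) {
      sel <- on[comp == ci]
      patches[[ci]] <- list(
        patch_id = sprintf("SP_%s_%s_%d", category, as.character(time), ci),
        kind = "spatial", category = category, time = time,
        members = cbind(row = grid$cells$row[sel], col = grid$cells$col[sel]),
        cell_ids = grid$cells$cell_id[sel],
        size = length(sel), membership = frac[sel])
    }
  }
  structure(list(patches = patches, kind = "spatial",
                 threshold = threshold, connectivity = connectivity),
            class = "patch_set")
}

# Label connected components of a set of lattice points. Rook moves for
# connectivity 4, rook + bishop for 8. Returns an integer label per point.
connected_components <- function(row, col, connectivity) {
  n <- length(row)
  if (n == 1L) return(1L)
  key <- function(r, c) paste(r, c, sep = ",")
  idx <- stats::setNames(seq_len(n), key(row, col))
  moves <- rbind(c(0L, 1L), c(1L, 0L))
  if (connectivity == 8) moves <- rbind(moves, c(1L, 1L), c(1L, -1L))
  from <- integer(0); to <- integer(0)
  for (m in seq_len(nrow(moves))) {
    nb <- idx[key(row + moves[m, 1], col + moves[m, 2])]
    hit <- !is.na(nb)
    from <- c(from, which(hit)); to <- c(to, nb[hit])
  }
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to),
    directed = FALSE,
    vertices = data.frame(name = seq_len(n)))
  comp <- igraph::components(g)$membership
  as.integer(comp[as.character(seq_len(n))])
}

#' Temporal patches of a category at one cell
#'
#' A temporal patch is a maximal run of consecutive time steps at which the
#' cell's occupation fraction for the category strictly exceeds the
#' threshold; its size is the run length in time steps.
#'
#' @param grid a `composition_grid`.
#' @param category a category label.
#' @param threshold minimum fraction, strict inequality.
#' @param cell a `cell_id` of the grid.
#' @return an object of class `patch_set`; members are 0-based time indices.
#' @export
temporal_patches <- function(grid, category, threshold = 0.15, cell) {
  stopifnot(threshold > 0, threshold < 1)
  k <- match(category, grid$categories)
  if (is.na(k)) stop("unknown category: ", category)
  i <- match(cell, grid$cells$cell_id)
  if (is.na(i)) stop("unknown cell: ", cell)
  frac <- grid$fractions[i, , k]
  r <- rle(frac > threshold)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  patches <- list()
  runs <- which(r$values)
  for (q in seq_along(runs)) {
    sel <- starts[runs[q]]:ends[runs[q]]
    patches[[q]] <- list(
      patch_id = sprintf("TP_%s_%s_%d", category, cell, q),
      kind = "temporal", category = category, cell = cell,
      members = sel - 1L, size = length(sel), membership = frac[sel])
  }
  structure(list(patches = patches, kind = "temporal", threshold = threshold),
            class = "patch_set")
}

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("patch_set (%s): %d patches, sizes %s\n", x$kind,
              length(x$patches),
              paste(vapply(x$patches, `[[`, 0, "size"), collapse = ", ")))
  invisible(x)
}

#' Patch-size classings
#'
#' Maps patch sizes (positive integers) to ordered class labels. Labels are
#' either exact integers (`"1"`, `"2"`) or open lower bounds (`">2"`,
#' `">25"`): a `">b"` class covers sizes `b + 1` up to the next class's
#' bound, the last one being unbounded. The defaults are the classings used
#' for land-cover patch analysis: spatial sizes
#' `1, 2, >2, >7, >25, >50, >100` (so `>25` groups sizes 26..50) and
#' temporal sizes `1, 2, >2, >4, >7, >20, >30, >60`.
#'
#' @param labels ordered character vector of class labels.
#' @return an object of class `size_classing`.
#' @export
size_classing <- function(labels = spatial_size_classes()) {
  open <- grepl("^>", labels)
  lower <- suppressWarnings(as.numeric(labels))
  lower[open] <- suppressWarnings(as.numeric(sub("^>", "", labels[open]))) + 1
  if (any(is.na(lower))) stop("labels must be integers or '>b' bounds")
  if (is.unsorted(lower, strictly = TRUE))
    stop("class lower bounds must be strictly increasing")
  exact <- !grepl("^>", labels)
  upper <- c(lower[-1] - 1, Inf)
  upper[exact] <- lower[exact]
  if (any(upper < lower)) stop("classes overlap or leave gaps")
  if (lower[1] != 1) stop("classing must start at size 1")
  structure(list(labels = labels, lower = lower, upper = upper),
            class = "size_classing")
}

#' @rdname size_classing
#' @export
spatial_size_classes <- function() c("1", "2", ">2", ">7", ">25", ">50", ">100")

#' @rdname size_classing
#' @export
temporal_size_classes <- function()
  c("1", "2", ">2", ">4", ">7", ">20", ">30", ">60")

#' Assign size classes to patches
#'
#' @param patches a `patch_set` or a vector of positive integer sizes.
#' @param classing a [size_classing()].
#' @return factor of class labels (levels in classing order), one per patch,
#'   with a `counts` attribute giving the per-class tally.
#' @export
assign_size_class <- function(patches, classing = size_classing()) {
  sizes <- if (inherits(patches, "patch_set"))
    vapply(patches$patches, `[[`, 0, "size") else patches
  if (length(sizes) && (any(sizes < 1) || any(sizes != round(sizes))))
    stop("patch sizes must be positive integers")
  lab <- classing$labels[findInterval(sizes, classing$lower)]
  f <- factor(lab, levels = classing$labels)
  attr(f, "counts") <- table(f)
  f
}

#' Geometric shape features of spatial patches
#'
#' Per spatial patch: area (cell count), perimeter (number of exposed cell
#' edges), compactness `4 * pi * area / perimeter^2` clipped to `(0, 1]`
#' (1 would be a disc; a unit cell scores `pi / 4`), and elongation (ratio
#' of the principal axes of the member coordinates, 1 for isotropic
#' patches).
#'
#' @param patches a spatial `patch_set`.
#' @return data frame with columns `patch_id, area, perimeter, compactness,
#'   elongation`.
#' @export
shape_features <- function(patches) {
  if (!inherits(patches, "patch_set") || patches$kind != "spatial")
    stop("unsupported kind: shape features are defined for spatial patches")
  out <- lapply(patches$patches, function(p) {
    m <- p$members
    area <- nrow(m)
    key <- paste(m[, 1], m[, 2], sep = ",")
    adj <- sum(paste(m[, 1], m[, 2] + 1, sep = ",") %in% key) +
      sum(paste(m[, 1] + 1, m[, 2], sep = ",") %in% key)
    perimeter <- 4 * area - 2 * adj
    compactness <- min(4 * pi * area / perimeter^2, 1)
    elongation <- if (area == 1) 1 else {
      ev <- eigen(stats::cov(m) * (area - 1) / area, symmetric = TRUE,
                  only.values = TRUE)$values
      # half-cell jitter floor keeps 1-d lines finite
      sqrt(max(ev[1], 1 / 12) / max(ev[2], 1 / 12))
    }
    data.frame(patch_id = p$patch_id, area = area, perimeter = perimeter,
               compactness = compactness, elongation = elongation,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Cluster patch shapes into classes
#'
#' Standardises the shape features and partitions the patches with seeded
#' k-means; the resulting labels define the shape categorical variable.
#'
#' @param features data frame from [shape_features()].
#' @param n_classes number of shape classes.
#' @param seed integer seed for reproducible clustering.
#' @return factor of shape-class labels `sh1..shK`, with the fitted centres
#'   (on the standardised scale) as attribute `"centers"`. Features with
#'   zero variance are dropped before clustering; if all patches share
#'   identical features a single effective class is returned with a warning.
#' @export
classify_shapes <- function(features, n_classes = 3, seed = 1) {
  x <- as.matrix(features[, c("area", "perimeter", "compactness",
                              "elongation")])
  if (nrow(x) < n_classes)
    stop("fewer patches (", nrow(x), ") than classes (", n_classes, ")")
  sds <- apply(x, 2, stats::sd)
  keep <- sds > 0
  if (!any(keep)) {
    warning("all patches have identical features; single effective class")
    return(factor(rep("sh1", nrow(x)), levels = paste0("sh", seq_len(n_classes))))
  }
  z <- scale(x[, keep, drop = FALSE])
  km <- withr_seed(seed, stats::kmeans(z, centers = n_classes, nstart = 10))
  # relabel by decreasing cluster size for determinism across platforms
  ord <- order(-km$size, km$centers[, 1])
  lab <- match(km$cluster, ord)
  f <- factor(paste0("sh", lab), levels = paste0("sh", seq_len(n_classes)))
  attr(f, "centers") <- km$centers[ord, , drop = FALSE]
  f
}

# evaluate expr under a temporary RNG state
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Ordinal motif (permutation) classes of a numeric series
#'
#' Every window `(x_t, x_{t+tau}, ..., x_{t+(l-1)tau})` is labelled by the
#' permutation that sorts its values ascending, the ordinal-pattern
#' construction of permutation entropy: for `l = 3`, a window whose first
#' value is lowest and second value highest belongs to class `(1,3,2)`.
#' Ties and differences smaller than `delta` are resolved by stable order
#' (earlier index first) and counted. With `refined = TRUE` each `l = 3`
#' class is split into a `t`/`b` pair by comparing the two successive change
#' magnitudes, separating e.g. a large increase followed by a small one from
#' the reverse.
#'
#' @param series ordered numeric values (e.g. a category's fraction at one
#'   cell over time).
#' @param l pattern length, 2 or 3.
#' @param tau lag between window elements, at least 1.
#' @param refined split `l = 3` classes by change-magnitude ordering.
#' @param delta minimum meaningful difference; differences below it are
#'   treated as ties.
#' @param tb_larger_first suffix `"t"` when the earlier change magnitude is
#'   at least the later one (default); `FALSE` flips the convention.
#' @return an object of class `motif_labeling`: per-window labels, label
#'   counts, and the tie count. The number of windows is
#'   `N - (l - 1) * tau`.
#' @export
motif_classes <- function(series, l = 3, tau = 1, refined = FALSE,
                          delta = 0, tb_larger_first = TRUE) {
  stopifnot(l %in% c(2L, 3L), tau >= 1, delta >= 0)
  n <- length(series)
  n_win <- n - (l - 1) * tau
  if (n_win < 1)
    stop("series too short: need length >= ", (l - 1) * tau + 1)
  labels <- character(n_win)
  n_ties <- 0L
  for (t0 in seq_len(n_win)) {
    w <- series[t0 + (0:(l - 1)) * tau]
    tied <- any(abs(outer(w, w, "-"))[lower.tri(diag(l))] < delta) ||
      anyDuplicated(w) > 0
    if (tied) n_ties <- n_ties + 1L
    # stable ascending order; equal/near-equal values keep time order
    ord <- order(w)  # order() is stable: earlier index first on ties
    lab <- paste(ord, collapse = "")
    if (refined && l == 3L) {
      g_early <- abs(w[2] - w[1]); g_late <- abs(w[3] - w[2])
      tb <- if ((g_early >= g_late) == tb_larger_first) "t" else "b"
      lab <- paste0(lab, tb)
    }
    labels[t0] <- lab
  }
  lev <- motif_levels(l, refined)
  f <- factor(labels, levels = lev)
  structure(list(labels = f, counts = table(f), n_windows = n_win,
                 n_ties = n_ties, l = l, tau = tau, refined = refined,
                 delta = delta),
            class = "motif_labeling")
}

motif_levels <- function(l, refined) {
  perms <- if (l == 2L) list(1:2, 2:1) else {
    idx <- expand.grid(a = 1:3, b = 1:3, c = 1:3)
    idx <- idx[apply(idx, 1, function(v) length(unique(v)) == 3L), ]
    lapply(seq_len(nrow(idx)), function(i) unlist(idx[i, ], use.names = FALSE))
  }
  base <- sort(vapply(perms, paste, "", collapse = ""))
  if (refined && l == 3L) as.vector(t(outer(base, c("t", "b"), paste0)))
  else base
}

#' @export
print.motif_labeling <- function(x, ...) {
  cat(sprintf("motif_labeling: l=%d tau=%d%s, %d windows, %d tie(s)\n",
              x$l, x$tau, if (x$refined) " refined" else "", x$n_windows,
              x$n_ties))
  print(x$counts)
  invisible(x)
}
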