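#' Construct a compositional grid time series
#'
#' A `composition_grid` holds, for every grid cell, time step and category,
#' a fraction of occupation in `[0, 1]`. This is the compositional form of
#' spatio-temporal categorical data: typical examples are land-cover class
#' fractions per raster cell per year, or species cover fractions per plot
#' per survey. Per (cell, time) the fractions may sum to less than 1; the
#' remainder is treated as unclassified (e.g. unobserved or bare ground when
#' bare ground is not itself a category).
#'
#' @param fractions numeric array of dimension `c(n_cells, n_times,
#'   n_categories)`; values in `[0, 1]`.
#' @param cells data frame with columns `cell_id`, `row`, `col` and optional
#'   `lon`, `lat`. Rows and columns are 0-based lattice addresses.
#' @param times strictly increasing numeric vector of time labels.
#' @param categories character vector of unique category labels.
#' @return an object of class `composition_grid`.
#' @seealso [read_composition()], [to_observations()], [validate_grid()]
#' @export
composition_grid <- function(fractions, cells, times, categories) {
  if (!is.array(fractions) || length(dim(fractions)) != 3L)
    stop("'fractions' must be a 3-d array (cell x time x category)")
  stopifnot(is.data.frame(cells))
  req <- c("cell_id", "row", "col")
  miss <- setdiff(req, names(cells))
  if (length(miss))
    stop("'cells' is missing column(s): ", paste(miss, collapse = ", "))
  if (dim(fractions)[1] != nrow(cells) ||
      dim(fractions)[2] != length(times) ||
      dim(fractions)[3] != length(categories))
    stop("dimension mismatch between fractions and cells/times/categories")
  if (anyDuplicated(categories))
    stop("duplicate category labels")
  if (is.unsorted(times, strictly = TRUE))
    stop("'times' must be strictly increasing")
  dimnames(fractions) <- list(as.character(cells$cell_id),
                              as.character(times),
                              categories)
  g <- structure(
    list(fractions = fractions,
         cells = as.data.frame(cells),
         times = times,
         categories = as.character(categories)),
    class = "composition_grid")
  rep <- validate_grid(g)
  if (nrow(rep))
    stop("invalid composition grid: ", rep$message[1],
         if (nrow(rep) > 1) sprintf(" (and %d more violations)", nrow(rep) - 1))
  g
}

#' @export
print.composition_grid <- function(x, ...) {
  d <- dim(x$fractions)
  cat(sprintf("composition_grid: %d cells x %d times x %d categories\n",
              d[1], d[2], d[3]))
  cat("  times:", x$times[1], "...", x$times[length(x$times)], "\n")
  cat("  categories:", paste(utils::head(x$categories, 6), collapse = ", "),
      if (length(x$categories) > 6) "...", "\n")
  invisible(x)
}

#' Validate a composition grid or observation set
#'
#' Report-only check of the container invariants: fractions within `[0, 1]`,
#' per-(cell, time) fraction sums at most 1 (tolerance 1e-9), finite
#' coordinates and non-negative weights for observations. Returns a data
#' frame of violations; zero rows means all invariants hold.
#'
#' @param x a `composition_grid` or `observation_set`.
#' @return data frame with columns `where` and `message` (0 rows if valid).
#' @export
validate_grid <- function(x) {
  viol <- list()
  add <- function(where, message)
    viol[[length(viol) + 1L]] <<- data.frame(where = where, message = message)
  if (inherits(x, "composition_grid")) {
    f <- x$fractions
    bad <- which(!is.finite(f) | f < 0 | f > 1, arr.ind = TRUE)
    if (nrow(bad))
      for (i in seq_len(min(nrow(bad), 20L)))
        add(sprintf("cell %s, time %s, category %s",
                    dimnames(f)[[1]][bad[i, 1]], dimnames(f)[[2]][bad[i, 2]],
                    dimnames(f)[[3]][bad[i, 3]]),
            "fraction outside [0, 1] or non-finite")
    sums <- apply(f, c(1, 2), sum)
    over <- which(sums > 1 + 1e-9, arr.ind = TRUE)
    if (length(over) && nrow(over))
      for (i in seq_len(min(nrow(over), 20L)))
        add(sprintf("cell %s, time %s",
                    rownames(sums)[over[i, 1]], colnames(sums)[over[i, 2]]),
            sprintf("fraction sum %.6f exceeds 1", sums[over[i, 1], over[i, 2]]))
  } else if (inherits(x, "observation_set")) {
    r <- x$records
    if (any(!is.finite(r$x)) || any(!is.finite(r$y)) || any(!is.finite(r$t)))
      add("records", "non-finite coordinate")
    if (any(r$weight < 0)) add("records", "negative weight")
    if (any(!r$category %in% x$categories))
      add("records", "category outside the declared label set")
  } else stop("no validation rules for class ", paste(class(x), collapse = "/"))
  if (length(viol)) do.call(rbind, viol)
  else data.frame(where = character(), message = character())
}

#' Construct an observation set
#'
#' Observational data: individual records located in space and time, each
#' carrying one category label and a non-negative weight.
#'
#' @param records data frame with columns `x`, `y`, `t`, `category`,
#'   `weight`, and optionally `unit_id` (a cell or sub-region reference) and
#'   `t_label` (a time stratum label; defaults to `t`).
#' @param categories declared label set; defaults to the labels present.
#' @return an object of class `observation_set`.
#' @export
observation_set <- function(records, categories = NULL) {
  stopifnot(is.data.frame(records))
  req <- c("x", "y", "t", "category", "weight")
  miss <- setdiff(req, names(records))
  if (length(miss))
    stop("'records' is missing column(s): ", paste(miss, collapse = ", "))
  records$category <- as.character(records$category)
  if (is.null(records$unit_id)) records$unit_id <- NA_character_
  if (is.null(records$t_label)) records$t_label <- as.character(records$t)
  if (is.null(categories)) categories <- sort(unique(records$category))
  obs <- structure(list(records = as.data.frame(records),
                        categories = as.character(categories)),
                   class = "observation_set")
  rep <- validate_grid(obs)
  if (nrow(rep)) stop("invalid observation set: ", rep$message[1])
  obs
}

#' @export
print.observation_set <- function(x, ...) {
  cat(sprintf("observation_set: %d records, %d categories\n",
              nrow(x$records), length(x$categories)))
  invisible(x)
}

#' Collocation and proximity parameters
#'
#' Bundles the parameters of order-k co-occurrence counting and
#' distance-ratio weighting: the co-occurrence order, per-dimension
#' collocation thresholds (a distance-rule applied separately in space, time
#' and category space rather than a composite metric), the border-overlap
#' distance, and the categorisation rule for symmetric co-occurrences.
#'
#' @param order_k co-occurrence order (number of observations per
#'   co-occurrence), at least 2.
#' @param d_eps_s,d_eps_t,d_eps_c collocation thresholds in space, time and
#'   category space.
#' @param d_border border-overlap distance `db`, must satisfy
#'   `0 <= d_border < d_eps_s`; observations within `db` outside a snapshot
#'   are admitted to its co-occurrences (at least one member must be inside).
#' @param dissimilarity_c either `NULL` (0/1 indicator: distance 0 for equal
#'   categories, 1 otherwise) or a symmetric matrix with zero diagonal and
#'   category labels as dimnames.
#' @param categorisation_rule how a symmetric co-occurrence is labelled:
#'   `"strict"` (all members share the label), `"fuzzy"` (all member label
#'   combinations valid when within the tighter radius `d_r`) or
#'   `"majority"` (per-dimension majority vote, ties to the lowest label
#'   index).
#' @param d_r tighter radius for the fuzzy rule; defaults to `d_eps_s / 2`.
#' @param d_w,d_b_ratio within/between neighbourhood radii of the symmetric
#'   distance-ratio weight; default to `d_eps_s`.
#' @param metric_s,metric_t metric names (only `"euclidean"` implemented).
#' @return an object of class `proximity_spec`.
#' @export
proximity_spec <- function(order_k = 3L, d_eps_s = 1, d_eps_t = 0,
                           d_eps_c = 0, d_border = d_eps_s / 2,
                           dissimilarity_c = NULL,
                           categorisation_rule = c("strict", "fuzzy", "majority"),
                           d_r = d_eps_s / 2, d_w = d_eps_s,
                           d_b_ratio = d_eps_s,
                           metric_s = "euclidean", metric_t = "euclidean") {
  categorisation_rule <- match.arg(categorisation_rule)
  order_k <- as.integer(order_k)
  if (order_k < 2L) stop("'order_k' must be at least 2")
  if (d_border < 0 || d_border >= d_eps_s)
    stop("'d_border' must satisfy 0 <= d_border < d_eps_s")
  if (!is.null(dissimilarity_c)) {
    if (!isSymmetric(unname(dissimilarity_c)) ||
        any(diag(dissimilarity_c) != 0))
      stop("'dissimilarity_c' must be symmetric with zero diagonal")
  }
  structure(list(order_k = order_k, d_eps_s = d_eps_s, d_eps_t = d_eps_t,
                 d_eps_c = d_eps_c, d_border = d_border,
                 dissimilarity_c = dissimilarity_c,
                 categorisation_rule = categorisation_rule,
                 d_r = d_r, d_w = d_w, d_b_ratio = d_b_ratio,
                 metric_s = metric_s, metric_t = metric_t),
            class = "proximity_spec")
}

#' Read a compositional grid time series from file
#'
#' Two dialects are supported. `"long-csv"` is a long table with columns
#' `cell_id, row, col, time, category, fraction` (plus optional `lon, lat`).
#' `"gridded-array"` is a dense JSON representation with dimensions
#' `(time, y, x, category)` and a flattened fraction vector, the text
#' analogue of a gridded array file.
#'
#' @param path file path.
#' @param dialect `"long-csv"` or `"gridded-array"`.
#' @return a validated [composition_grid()].
#' @export
read_composition <- function(path, dialect = c("long-csv", "gridded-array")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "long-csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    req <- c("cell_id", "row", "col", "time", "category", "fraction")
    miss <- setdiff(req, names(df))
    if (length(miss))
      stop("format error: missing column(s) ", paste(miss, collapse = ", "))
    key <- paste(df$cell_id, df$time, df$category, sep = "\r")
    if (anyDuplicated(key))
      stop("duplicate-key error: repeated (cell, time, category) rows, e.g. ",
           gsub("\r", "/", key[duplicated(key)][1]))
    bad <- !is.finite(df$fraction) | df$fraction < 0 | df$fraction > 1
    if (any(bad))
      stop("validation error: ", sum(bad), " row(s) with fraction outside [0, 1]")
    grid_from_long(df)
  } else {
    j <- jsonlite::read_json(path, simplifyVector = TRUE)
    req <- c("times", "categories", "n_rows", "n_cols", "fraction")
    miss <- setdiff(req, names(j))
    if (length(miss))
      stop("format error: missing field(s) ", paste(miss, collapse = ", "))
    nr <- j$n_rows; nc <- j$n_cols
    nt <- length(j$times); nk <- length(j$categories)
    if (length(j$fraction) != nt * nr * nc * nk)
      stop("format error: fraction length does not match dims (time, y, x, category)")
    # stored flattened in (time, y, x, category) order, category fastest
    a4 <- array(j$fraction, dim = c(nk, nc, nr, nt))  # reversed for fastest-first
    cells <- expand.grid(col = 0:(nc - 1), row = 0:(nr - 1))[, c("row", "col")]
    cells <- cells[order(cells$row, cells$col), , drop = FALSE]
    cells$cell_id <- paste0("c", cells$row, "_", cells$col)
    f <- array(0, dim = c(nr * nc, nt, nk))
    for (it in seq_len(nt))
      for (ik in seq_len(nk))
        f[, it, ik] <- as.vector(a4[ik, , , it])  # (x fastest) = row-major cells
    composition_grid(f, cells[, c("cell_id", "row", "col")],
                     times = j$times, categories = j$categories)
  }
}

grid_from_long <- function(df) {
  cells <- unique(df[, intersect(c("cell_id", "row", "col", "lon", "lat"),
                                 names(df))])
  cells <- cells[order(cells$row, cells$col), , drop = FALSE]
  rownames(cells) <- NULL
  times <- sort(unique(df$time))
  categories <- sort(unique(as.character(df$category)))
  f <- array(0, dim = c(nrow(cells), length(times), length(categories)))
  i <- match(df$cell_id, cells$cell_id)
  j <- match(df$time, times)
  k <- match(as.character(df$category), categories)
  f[cbind(i, j, k)] <- df$fraction
  composition_grid(f, cells, times, categories)
}

#' Write a compositional grid time series to file
#'
#' Inverse of [read_composition()]; round-trips to within 1e-12 on
#' fractions and exactly on labels.
#'
#' @param grid a `composition_grid`.
#' @param path output file path.
#' @param dialect `"long-csv"` or `"gridded-array"`.
#' @param keep_zero write zero-fraction rows too (long-csv only); default
#'   drops them.
#' @return `path`, invisibly.
#' @export
write_composition <- function(grid, path,
                              dialect = c("long-csv", "gridded-array"),
                              keep_zero = FALSE) {
  dialect <- match.arg(dialect)
  if (dialect == "long-csv") {
    df <- as_long(grid)
    if (!keep_zero) df <- df[df$fraction > 0, , drop = FALSE]
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    nr <- max(grid$cells$row) + 1L; nc <- max(grid$cells$col) + 1L
    nt <- length(grid$times); nk <- length(grid$categories)
    a4 <- array(0, dim = c(nk, nc, nr, nt))
    for (it in seq_len(nt))
      for (ik in seq_len(nk)) {
        m <- matrix(0, nr, nc)
        m[cbind(grid$cells$row + 1L, grid$cells$col + 1L)] <-
          grid$fractions[, it, ik]
        a4[ik, , , it] <- t(m)
      }
    jsonlite::write_json(
      list(times = grid$times, categories = grid$categories,
           n_rows = nr, n_cols = nc, dims = c("time", "y", "x", "category"),
           fraction = as.vector(a4)),
      path, auto_unbox = FALSE, digits = NA)
  }
  invisible(path)
}

#' Long-format view of a composition grid
#'
#' @param grid a `composition_grid`.
#' @return data frame with columns `cell_id, row, col (, lon, lat), time,
#'   category, fraction`, ordered by cell, time, category.
#' @export
as_long <- function(grid) {
  d <- dim(grid$fractions)
  idx <- expand.grid(k = seq_len(d[3]), j = seq_len(d[2]), i = seq_len(d[1]))
  idx <- idx[, c("i", "j", "k")]
  idx <- idx[order(idx$i, idx$j, idx$k), ]
  df <- data.frame(
    cell_id = grid$cells$cell_id[idx$i],
    row = grid$cells$row[idx$i],
    col = grid$cells$col[idx$i],
    time = grid$times[idx$j],
    category = grid$categories[idx$k],
    fraction = grid$fractions[cbind(idx$i, idx$j, idx$k)],
    stringsAsFactors = FALSE)
  if (!is.null(grid$cells$lon)) {
    df$lon <- grid$cells$lon[idx$i]
    df$lat <- grid$cells$lat[idx$i]
    df <- df[, c("cell_id", "row", "col", "lon", "lat", "time", "category",
                 "fraction")]
  }
  rownames(df) <- NULL
  df
}

#' Convert compositional data to observational data
#'
#' Two rules. `"dominant"` keeps, per (cell, time), the arg-max category
#' with its fraction as weight; ties are broken deterministically towards
#' the lowest category index and flagged. `"weighted-multiple"` emits one
#' record per (cell, time, category) whose fraction is at least `threshold`,
#' with the fraction as weight — every cell then contributes one observation
#' per sufficiently present category.
#'
#' @param grid a `composition_grid`.
#' @param rule `"dominant"` or `"weighted-multiple"`.
#' @param threshold minimum fraction for `"weighted-multiple"` (in `[0, 1]`).
#' @param renormalise divide fractions by their (cell, time) sum before
#'   applying the rule. Off by default: sub-unit sums are treated as an
#'   unclassified remainder.
#' @return an `observation_set`; attribute `"log"` carries counts of skipped
#'   all-zero units and of dominant ties, and the records of a dominant rule
#'   carry a logical `tie` column.
#' @export
to_observations <- function(grid, rule = c("dominant", "weighted-multiple"),
                            threshold = 0, renormalise = FALSE) {
  rule <- match.arg(rule)
  stopifnot(threshold >= 0, threshold <= 1)
  f <- grid$fractions
  d <- dim(f)
  if (renormalise) {
    s <- apply(f, c(1, 2), sum)
    s[s == 0] <- 1
    f <- f / as.vector(s)[rep(seq_len(d[1] * d[2]), times = d[3])]
  }
  cx <- grid$cells$col; cy <- grid$cells$row
  recs <- list(); n_skipped <- 0L; n_ties <- 0L
  if (rule == "dominant") {
    for (j in seq_len(d[2])) {
      m <- f[, j, , drop = FALSE]; dim(m) <- c(d[1], d[3])
      top <- apply(m, 1, max)
      keep <- top > 0
      n_skipped <- n_skipped + sum(!keep)
      if (!any(keep)) next
      which_top <- apply(m[keep, , drop = FALSE], 1, which.max) # lowest index on ties
      tie <- apply(m[keep, , drop = FALSE], 1,
                   function(v) sum(v == max(v)) > 1L)
      n_ties <- n_ties + sum(tie)
      recs[[length(recs) + 1L]] <- data.frame(
        x = cx[keep], y = cy[keep], t = grid$times[j],
        category = grid$categories[which_top],
        weight = top[keep],
        unit_id = grid$cells$cell_id[keep],
        t_label = as.character(grid$times[j]),
        tie = tie, stringsAsFactors = FALSE)
    }
  } else {
    for (j in seq_len(d[2])) {
      m <- f[, j, , drop = FALSE]; dim(m) <- c(d[1], d[3])
      hit <- which(m >= threshold & m > 0, arr.ind = TRUE)
      if (!nrow(hit)) next
      recs[[length(recs) + 1L]] <- data.frame(
        x = cx[hit[, 1]], y = cy[hit[, 1]], t = grid$times[j],
        category = grid$categories[hit[, 2]],
        weight = m[hit],
        unit_id = grid$cells$cell_id[hit[, 1]],
        t_label = as.character(grid$times[j]),
        stringsAsFactors = FALSE)
    }
  }
  records <- if (length(recs)) do.call(rbind, recs)
  else data.frame(x = numeric(), y = numeric(), t = numeric(),
                  category = character(), weight = numeric(),
                  unit_id = character(), t_label = character())
  obs <- observation_set(records, categories = grid$categories)
  attr(obs, "log") <- list(n_skipped = n_skipped, n_ties = n_ties,
                           rule = rule, threshold = threshold)
  obs
}
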