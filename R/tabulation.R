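#' Multiway distribution-like table
#'
#' A named-mode non-negative tensor of counts or weights, with its total
#' mass `N`, derived joint probability tensor `p = values / N` and per-mode
#' margins. This is the object the entropy decompositions and the multiway
#' correspondence analysis operate on: any non-negative statistic positively
#' correlated with occurrence counts may fill the cells (plain occurrences,
#' patch occurrences, order-k co-occurrences, distance-ratio weights).
#'
#' @param values non-negative array with complete `dimnames`.
#' @param kind statistic kind: `"occurrence"`, `"patch-occurrence"`,
#'   `"cooccurrence"` or `"distance-ratio"`.
#' @return an object of class `multiway_table` with fields `values`, `p`,
#'   `N`, `modes`, `labels`, `margins`, `kind`.
#' @export
multiway_table <- function(values, kind = "occurrence") {
  if (!is.array(values)) values <- as.array(values)
  if (is.null(dimnames(values)) || any(vapply(dimnames(values), is.null, TRUE)))
    stop("'values' must have complete dimnames")
  if (any(values < 0)) stop("table values must be non-negative")
  if (is.null(names(dimnames(values))))
    names(dimnames(values)) <- paste0("mode", seq_along(dim(values)))
  N <- sum(values)
  p <- if (N > 0) values / N else values
  margins <- lapply(seq_along(dim(values)), function(m) {
    mg <- apply(p, m, sum)
    names(mg) <- dimnames(values)[[m]]
    mg
  })
  names(margins) <- names(dimnames(values))
  structure(list(values = values, p = p, N = N,
                 modes = names(dimnames(values)),
                 labels = dimnames(values), margins = margins, kind = kind),
            class = "multiway_table")
}

#' @export
print.multiway_table <- function(x, ...) {
  cat(sprintf("multiway_table (%s): %s, N = %g\n", x$kind,
              paste(x$modes, "(", vapply(x$labels, length, 0L), ")",
                    sep = "", collapse = " x "), x$N))
  invisible(x)
}

#' Occurrence table from per-unit labelings
#'
#' Cross-tabulates labelled units into a multiway table: cell `(a, b, c)`
#' receives the total weight of units labelled `(a, b, c)`. With
#' `count_unit = "cell"` every unit (typically a grid cell at a time for one
#' category) is counted, so a cell inside a patch of m cells contributes m
#' times through its patch mates; with `count_unit = "patch"` each patch is
#' counted once — the units are deduplicated on the patch-id columns —
#' cancelling the monotonic baseline effect of large patches.
#'
#' @param labelings data frame holding one column per mode (factors
#'   preserve empty levels, giving tables of fixed shape) and optionally
#'   `weight` and patch-id columns.
#' @param modes character vector of mode column names, in table order.
#' @param weights optional per-unit weights (defaults to the `weight`
#'   column, else 1).
#' @param count_unit `"cell"` or `"patch"`.
#' @param patch_ids columns identifying a patch for `"patch"` counting;
#'   defaults to the columns ending in `"_id"`.
#' @return a `multiway_table` of kind `"occurrence"` or
#'   `"patch-occurrence"`.
#' @export
occurrence_table <- function(labelings, modes,
                             weights = NULL,
                             count_unit = c("cell", "patch"),
                             patch_ids = grep("_id$", names(labelings),
                                              value = TRUE)) {
  count_unit <- match.arg(count_unit)
  miss <- setdiff(modes, names(labelings))
  if (length(miss))
    stop("labelings lack mode column(s): ", paste(miss, collapse = ", "))
  if (is.null(weights))
    weights <- if ("weight" %in% names(labelings)) labelings$weight
    else rep(1, nrow(labelings))
  if (any(weights < 0)) stop("weights must be non-negative")
  df <- labelings
  df$.w <- weights
  if (count_unit == "patch") {
    if (!length(patch_ids))
      stop("patch counting needs patch-id columns (suffix '_id')")
    key <- do.call(paste, c(df[c(patch_ids, modes)], sep = "\r"))
    df <- df[!duplicated(key), , drop = FALSE]
    df$.w <- 1
  }
  for (m in modes) if (!is.factor(df[[m]])) df[[m]] <- factor(df[[m]])
  tab <- tapply(df$.w, df[modes], sum, default = 0)
  names(dimnames(tab)) <- modes
  multiway_table(tab, kind = if (count_unit == "patch") "patch-occurrence"
                 else "occurrence")
}

euclid <- function(a, b) sqrt(rowSums((a - b)^2))

pairwise_ok <- function(d, eps) all(d[upper.tri(d)] <= eps + 1e-12)

category_distance <- function(ci, cj, spec) {
  if (is.null(spec$dissimilarity_c)) as.numeric(ci != cj)
  else spec$dissimilarity_c[cbind(ci, cj)]
}

#' Order-k co-occurrence table
#'
#' Counts unordered k-subsets of observations that satisfy a collocation
#' rule, yielding a spatio-temporal distribution of the category variable.
#' In the asymmetric mode observations are first grouped into snapshots
#' `E_st` (same `unit_id` and time stratum); a co-occurrence is a k-subset
#' of same-category observations whose pairwise spatial distances are all
#' within `d_eps_s`. Observations of other snapshots within the
#' border-overlap distance `d_border` are admitted as long as at least one
#' member lies inside the snapshot (cross-border subsets may be counted in
#' more than one snapshot; the slight over-count is accepted). In the
#' symmetric mode the k-subsets range over all observations and the
#' per-dimension distance-rule applies: spatial, temporal and categorical
#' distances within `d_eps_s`, `d_eps_t`, `d_eps_c` respectively; the
#' co-occurrence is then labelled on all three modes by the spec's
#' categorisation rule.
#'
#' @param obs an `observation_set`; `unit_id` and `t_label` define the
#'   snapshots.
#' @param spec a [proximity_spec()].
#' @param grouping `"snapshot"` (asymmetric, default) or `"none"`
#'   (symmetric).
#' @return a `multiway_table` of kind `"cooccurrence"` with modes
#'   `S` (unit), `T` (time stratum), `C` (category). A warning is emitted
#'   and an empty table returned when fewer than k observations exist.
#' @export
cooccurrence_table <- function(obs, spec, grouping = c("snapshot", "none")) {
  grouping <- match.arg(grouping)
  r <- obs$records
  k <- spec$order_k
  s_levels <- sort(unique(r$unit_id))
  t_levels <- sort(unique(r$t_label))
  c_levels <- obs$categories
  counts <- array(0, dim = c(length(s_levels), length(t_levels),
                             length(c_levels)),
                  dimnames = list(S = s_levels, T = t_levels, C = c_levels))
  if (nrow(r) < k) {
    warning("fewer observations (", nrow(r), ") than order k = ", k)
    return(multiway_table(counts, kind = "cooccurrence"))
  }
  xy <- cbind(r$x, r$y)
  if (grouping == "snapshot") {
    groups <- split(seq_len(nrow(r)), list(r$unit_id, r$t_label), drop = TRUE)
    for (g in groups) {
      s_lab <- r$unit_id[g[1]]; t_lab <- r$t_label[g[1]]
      cand <- g
      if (spec$d_border > 0) {
        same_t <- which(r$t_label == t_lab & r$unit_id != s_lab)
        if (length(same_t)) {
          dmin <- vapply(same_t, function(i)
            min(sqrt((r$x[g] - r$x[i])^2 + (r$y[g] - r$y[i])^2)), 0)
          cand <- c(g, same_t[dmin <= spec$d_border])
        }
      }
      for (cc in unique(r$category[cand])) {
        pts <- cand[r$category[cand] == cc]
        if (length(pts) < k) next
        for (sub in subset_iter(pts, k)) {
          if (!any(sub %in% g)) next  # at least one member inside E_st
          d <- as.matrix(stats::dist(xy[sub, , drop = FALSE]))
          if (pairwise_ok(d, spec$d_eps_s))
            counts[s_lab, t_lab, cc] <- counts[s_lab, t_lab, cc] + 1
        }
      }
    }
  } else {
    for (sub in subset_iter(seq_len(nrow(r)), k)) {
      dS <- as.matrix(stats::dist(xy[sub, , drop = FALSE]))
      if (!pairwise_ok(dS, spec$d_eps_s)) next
      dT <- abs(outer(r$t[sub], r$t[sub], "-"))
      if (!pairwise_ok(dT, spec$d_eps_t)) next
      dC <- outer(r$category[sub], r$category[sub],
                  function(a, b) category_distance(a, b, spec))
      if (!pairwise_ok(dC, spec$d_eps_c)) next
      labs <- categorise_cooccurrence(r[sub, ], dS, dT, dC, spec)
      for (lb in labs)
        counts[lb[1], lb[2], lb[3]] <- counts[lb[1], lb[2], lb[3]] + 1
    }
  }
  multiway_table(counts, kind = "cooccurrence")
}

# iterate unordered k-subsets (list of index vectors)
subset_iter <- function(idx, k) {
  if (length(idx) < k) return(list())
  cm <- utils::combn(idx, k)
  lapply(seq_len(ncol(cm)), function(j) cm[, j])
}

categorise_cooccurrence <- function(members, dS, dT, dC, spec) {
  rule <- spec$categorisation_rule
  one <- function(v) {
    u <- unique(v)
    if (length(u) == 1L) u else NA_character_
  }
  majority <- function(v) {
    tb <- table(v)
    names(tb)[which.max(tb)]  # lowest label index on ties
  }
  if (rule == "strict") {
    s <- one(members$unit_id); t <- one(members$t_label)
    c <- one(members$category)
    if (anyNA(c(s, t, c))) return(list())
    list(c(s, t, c))
  } else if (rule == "majority") {
    list(c(majority(members$unit_id), majority(members$t_label),
           majority(members$category)))
  } else { # fuzzy: all member label combinations valid within radius d_r
    ok_s <- pairwise_ok(dS, spec$d_r)
    s_set <- if (ok_s) unique(members$unit_id) else one(members$unit_id)
    t_set <- if (pairwise_ok(dT, spec$d_r)) unique(members$t_label)
      else one(members$t_label)
    c_set <- if (pairwise_ok(dC, spec$d_r)) unique(members$category)
      else one(members$category)
    if (anyNA(s_set) || anyNA(t_set) || anyNA(c_set)) return(list())
    gg <- expand.grid(s = s_set, t = t_set, c = c_set,
                      stringsAsFactors = FALSE)
    lapply(seq_len(nrow(gg)), function(i) unlist(gg[i, ], use.names = FALSE))
  }
}

#' Distance-ratio weight table
#'
#' For each populated `(s, t, c)` cell, the mean within-category pair
#' distance divided by the mean between-category pair distance: values near
#' 0 indicate strong clustering of the category, values near 1 no
#' spatial preference. In the local asymmetric mode the pairs are taken
#' inside each snapshot `E_st`: within-pairs are both of category c,
#' between-pairs pair a c observation with a non-c observation. The
#' symmetric mode builds the pair sets from the neighbourhood rule around
#' the cell's observation set `O_stc`: within-pairs have both members within
#' `d_w` of some member of `O_stc`; between-pairs have one member within
#' `d_b_ratio` of some member and the other at distance at least
#' `d_b_ratio` from all members. Because a small ratio means strong
#' structure while the entropy machinery expects large mass for strong
#' presence, `invert = TRUE` (the default for analysis) stores `1 / ratio`;
#' the table is a non-negative distribution-like indicator either way.
#'
#' @param obs an `observation_set` with `unit_id` and `t_label` snapshots.
#' @param spec a [proximity_spec()].
#' @param mode `"local-asymmetric"` or `"symmetric"`.
#' @param invert store inverted ratios (clustering gets large mass).
#' @return a `multiway_table` of kind `"distance-ratio"`; cells with an
#'   empty between-pair set are flagged undefined in attribute
#'   `"undefined"` and excluded (zero mass).
#' @export
distance_ratio_table <- function(obs, spec,
                                 mode = c("local-asymmetric", "symmetric"),
                                 invert = FALSE) {
  mode <- match.arg(mode)
  r <- obs$records
  s_levels <- sort(unique(r$unit_id))
  t_levels <- sort(unique(r$t_label))
  c_levels <- obs$categories
  vals <- array(0, dim = c(length(s_levels), length(t_levels),
                           length(c_levels)),
                dimnames = list(S = s_levels, T = t_levels, C = c_levels))
  undef <- character(0)
  xy <- cbind(r$x, r$y)
  mean_pair_dist <- function(i_set, j_set, exclude_same = TRUE) {
    if (!length(i_set) || !length(j_set)) return(NA_real_)
    dd <- outer(seq_along(i_set), seq_along(j_set), function(a, b)
      sqrt((r$x[i_set[a]] - r$x[j_set[b]])^2 +
             (r$y[i_set[a]] - r$y[j_set[b]])^2))
    same <- outer(i_set, j_set, "==")
    dd <- dd[!same]
    if (!length(dd)) NA_real_ else mean(dd)
  }
  for (s in s_levels) for (t in t_levels) {
    in_st <- which(r$unit_id == s & r$t_label == t)
    if (!length(in_st)) next
    for (cc in unique(r$category[in_st])) {
      w_i <- in_st[r$category[in_st] == cc]
      if (mode == "local-asymmetric") {
        b_j <- in_st[r$category[in_st] != cc]
        mw <- if (length(w_i) >= 2) mean_pair_dist(w_i, w_i) else NA_real_
        mb <- mean_pair_dist(w_i, b_j)
      } else {
        # neighbourhoods around O_stc across all observations
        dmin <- vapply(seq_len(nrow(r)), function(i)
          min(sqrt((r$x[w_i] - r$x[i])^2 + (r$y[w_i] - r$y[i])^2)), 0)
        w_set <- which(dmin <= spec$d_w)
        near_b <- which(dmin <= spec$d_b_ratio)
        far_b <- which(dmin >= spec$d_b_ratio)
        mw <- if (length(w_set) >= 2) mean_pair_dist(w_set, w_set)
          else NA_real_
        mb <- mean_pair_dist(near_b, far_b, exclude_same = TRUE)
      }
      if (is.na(mb) || mb == 0 || is.na(mw)) {
        undef <- c(undef, paste(s, t, cc, sep = "/"))
        next
      }
      ratio <- mw / mb
      vals[s, t, cc] <- if (invert) {
        if (ratio == 0) NA else 1 / ratio
      } else ratio
    }
  }
  if (any(is.na(vals))) {
    undef <- c(undef, "inverted zero ratio(s)")
    vals[is.na(vals)] <- 0
  }
  tb <- multiway_table(vals, kind = "distance-ratio")
  attr(tb, "undefined") <- undef
  tb
}

#' Write / read a multiway table as long CSV plus JSON sidecar
#'
#' The CSV holds one row per cell (`mode1, mode2, ..., value`); the sidecar
#' (same path with extension `.json`) records mode names, labels, `N` and
#' the statistic kind, so the round trip is lossless.
#'
#' @param table a `multiway_table`.
#' @param path CSV path.
#' @return `path` invisibly (write) or the rebuilt table (read).
#' @export
write_multiway <- function(table, path) {
  df <- as.data.frame.table(table$values, responseName = "value",
                            stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(
    list(modes = table$modes, labels = table$labels, N = table$N,
         kind = table$kind),
    paste0(tools::file_path_sans_ext(path), ".json"),
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_multiway
#' @export
read_multiway <- function(path) {
  meta <- jsonlite::read_json(paste0(tools::file_path_sans_ext(path), ".json"),
                              simplifyVector = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  dims <- unname(vapply(meta$labels, length, 0L))
  arr <- array(0, dim = dims, dimnames = meta$labels)
  idx <- mapply(function(m) match(as.character(df[[m]]), meta$labels[[m]]),
                meta$modes)
  arr[idx] <- df$value
  names(dimnames(arr)) <- meta$modes
  multiway_table(arr, kind = meta$kind)
}
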