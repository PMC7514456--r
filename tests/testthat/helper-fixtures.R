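# In-code fixtures shared across the suite.

# tiny grid from a list of per-time category-fraction matrices
# masks: list over categories of (n_cell x n_time) fraction matrices
toy_grid <- function(fracs, n_rows, n_cols, times = NULL) {
  n_cells <- n_rows * n_cols
  n_times <- ncol(fracs[[1]])
  if (is.null(times)) times <- seq_len(n_times)
  cells <- expand.grid(col = 0:(n_cols - 1), row = 0:(n_rows - 1))
  cells <- cells[order(cells$row, cells$col), c("row", "col")]
  cells$cell_id <- paste0("c", cells$row, "_", cells$col)
  f <- array(0, dim = c(n_cells, n_times, length(fracs)))
  for (k in seq_along(fracs)) f[, , k] <- fracs[[k]]
  composition_grid(f, cells[, c("cell_id", "row", "col")], times,
                   categories = names(fracs))
}

# grid from a 0/1 occupancy matrix for one category at one time
mask_grid <- function(mask, value = 0.5) {
  n_rows <- nrow(mask); n_cols <- ncol(mask)
  frac <- matrix(as.vector(t(mask)) * value, ncol = 1)
  toy_grid(list(A = frac, B = 0.001 + 0 * frac), n_rows, n_cols)
}

# random multiway probability table
random_table <- function(dims, seed) {
  set.seed(seed)
  v <- stats::rexp(prod(dims)) + 0.05
  arr <- array(v / sum(v), dim = dims,
               dimnames = lapply(seq_along(dims), function(m)
                 paste0(letters[m], seq_len(dims[m]))))
  names(dimnames(arr)) <- c("S", "T", "C", "D")[seq_along(dims)]
  multiway_table(arr)
}

# independent flood fill oracle: label components of a 0/1 matrix by BFS
flood_fill_sizes <- function(mask, connectivity = 4) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  nb <- if (connectivity == 4)
    rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  else as.matrix(expand.grid(-1:1, -1:1))[-5, ]
  nxt <- 0L
  for (i in seq_len(nrow(mask))) for (j in seq_len(ncol(mask))) {
    if (!mask[i, j] || lab[i, j]) next
    nxt <- nxt + 1L
    queue <- list(c(i, j)); lab[i, j] <- nxt
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (q in seq_len(nrow(nb))) {
        r <- cur[1] + nb[q, 1]; c <- cur[2] + nb[q, 2]
        if (r >= 1 && r <= nrow(mask) && c >= 1 && c <= ncol(mask) &&
            mask[r, c] && !lab[r, c]) {
          lab[r, c] <- nxt
          queue[[length(queue) + 1]] <- c(r, c)
        }
      }
    }
  }
  if (nxt == 0L) integer(0) else tabulate(lab[lab > 0])
}

# classical CA oracle: singular values / vectors of standardised residuals
ca_oracle <- function(p) {
  r <- rowSums(p); c <- colSums(p)
  s <- (p - outer(r, c)) / sqrt(outer(r, c))
  sv <- svd(s)
  list(sigma = sv$d, u = sv$u / sqrt(r), v = sv$v / sqrt(c))
}

# observation set from a point table
pts_obs <- function(x, y, category, t = 0, unit = "u1", weight = 1) {
  observation_set(data.frame(
    x = x, y = y, t = t, category = category, weight = weight,
    unit_id = unit, t_label = as.character(t)))
}
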