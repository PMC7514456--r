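#' Label every above-threshold (cell, time, category) unit with its patches
#'
#' The unit-level labelling behind the occurrence tables: for every
#' category and time step the spatial patches are built and their size
#' classes assigned, for every category and cell the temporal patches, and
#' each (cell, time, category) with fraction above the threshold receives
#' its spatial patch id and size class (`Si`), temporal patch id and size
#' class (`Ti`), and its fraction as weight. Cells can appear once per
#' category exceeding the threshold, so overlapping patches of different
#' categories are preserved.
#'
#' @param grid a `composition_grid`.
#' @param threshold strict minimum fraction (default 0.15).
#' @param connectivity spatial connectivity, 4 or 8.
#' @param si_classing,ti_classing [size_classing()] objects for spatial and
#'   temporal sizes.
#' @return data frame with columns `cell_id, row, col, time, category,
#'   weight, sp_id, Si, tp_id, Ti` (`Si`, `Ti` are factors over the full
#'   classing levels).
#' @export
label_patch_units <- function(grid, threshold = 0.15, connectivity = 4,
                              si_classing = size_classing(spatial_size_classes()),
                              ti_classing = size_classing(temporal_size_classes())) {
  rows <- list()
  # spatial labels per (category, time)
  sp_lab <- list()
  for (cat in grid$categories) for (tm in grid$times) {
    ps <- spatial_patches(grid, cat, threshold, connectivity, time = tm)
    if (!length(ps$patches)) next
    cls <- assign_size_class(ps, si_classing)
    for (q in seq_along(ps$patches)) {
      p <- ps$patches[[q]]
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = p$cell_ids, time = tm, category = cat,
        weight = p$membership, sp_id = p$patch_id,
        Si = as.character(cls[q]), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    stop("no cell exceeds the threshold for any category")
  units <- do.call(rbind, rows)
  # temporal labels per (category, cell)
  tp_rows <- list()
  for (cat in grid$categories) for (cl in grid$cells$cell_id) {
    pt <- temporal_patches(grid, cat, threshold, cell = cl)
    if (!length(pt$patches)) next
    cls <- assign_size_class(pt, ti_classing)
    for (q in seq_along(pt$patches)) {
      p <- pt$patches[[q]]
      tp_rows[[length(tp_rows) + 1L]] <- data.frame(
        cell_id = cl, category = cat,
        time = grid$times[p$members + 1L],
        tp_id = p$patch_id, Ti = as.character(cls[q]),
        stringsAsFactors = FALSE)
    }
  }
  tp <- do.call(rbind, tp_rows)
  units <- merge(units, tp, by = c("cell_id", "category", "time"),
                 all.x = TRUE)
  units <- merge(units, grid$cells[, c("cell_id", "row", "col")],
                 by = "cell_id")
  units$Si <- factor(units$Si, levels = si_classing$labels)
  units$Ti <- factor(units$Ti, levels = ti_classing$labels)
  units$category <- factor(units$category, levels = grid$categories)
  units <- units[order(units$category, units$time, units$row, units$col), ]
  rownames(units) <- NULL
  units[, c("cell_id", "row", "col", "time", "category", "weight",
            "sp_id", "Si", "tp_id", "Ti")]
}

#' Write patch and member tables
#'
#' Patch table CSV: `patch_id, kind, category, time_or_cell, size,
#' size_class, n_members`; member table CSV: `patch_id, row, col` (spatial)
#' or `patch_id, time_index` (temporal), with membership degree.
#'
#' @param patches a `patch_set`.
#' @param classing a [size_classing()].
#' @param patch_path,member_path output CSV paths.
#' @return `patch_path`, invisibly.
#' @export
write_patches <- function(patches, classing, patch_path, member_path) {
  cls <- assign_size_class(patches, classing)
  ptab <- do.call(rbind, lapply(seq_along(patches$patches), function(q) {
    p <- patches$patches[[q]]
    data.frame(patch_id = p$patch_id, kind = p$kind, category = p$category,
               time_or_cell = as.character(
                 if (p$kind == "spatial") p$time else p$cell),
               size = p$size, size_class = as.character(cls[q]),
               n_members = p$size, stringsAsFactors = FALSE)
  }))
  utils::write.csv(ptab, patch_path, row.names = FALSE)
  mtab <- do.call(rbind, lapply(patches$patches, function(p) {
    if (p$kind == "spatial")
      data.frame(patch_id = p$patch_id, row = p$members[, "row"],
                 col = p$members[, "col"], membership = p$membership)
    else
      data.frame(patch_id = p$patch_id, time_index = p$members,
                 membership = p$membership)
  }))
  utils::write.csv(mtab, member_path, row.names = FALSE)
  invisible(patch_path)
}

#' Read a workflow configuration file
#'
#' YAML with nested sections `input` (path, dialect, or `simulate` with
#' [simulation_spec()] fields), `patches` (threshold, connectivity,
#' si_classes, ti_classes), `table` (statistic, count_unit, proximity
#' fields), `analysis` (chains, fca_components), `output` (dir), `seed`,
#' `verbose`. Unknown keys are rejected.
#'
#' @param path YAML config path.
#' @return validated config list of class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("input", "patches", "table", "analysis", "output", "seed",
             "verbose")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  defaults <- list(
    input = list(simulate = list()),
    patches = list(threshold = 0.15, connectivity = 4,
                   si_classes = spatial_size_classes(),
                   ti_classes = temporal_size_classes()),
    table = list(statistic = "occurrence"),
    analysis = list(chains = list(c("Si", "Ti", "category")),
                    fca_components = 4),
    output = list(dir = "patchentropy-out"),
    seed = 1, verbose = FALSE)
  cfg <- utils::modifyList(defaults, cfg)
  structure(cfg, class = "run_config")
}

#' Run the complete patch-entropy workflow
#'
#' Orchestrates the three major steps: (i) patch rules — building spatial
#' and temporal patches and their size classes; (ii) extraction of the
#' multiway table under the configured statistic; (iii) quantification —
#' entropy decomposition chains and multiway correspondence analysis —
#' with every artefact serialised to the output directory and listed, with
#' checksums, in a manifest.
#'
#' @param config a `run_config` (or path to one).
#' @param seed overrides the config seed.
#' @return the manifest: data frame with columns `artifact`, `path`,
#'   `md5`, invisibly. The run log goes to `run.log` in the output
#'   directory.
#' @export
run_workflow <- function(config, seed = NULL) {
  if (is.character(config)) config <- read_run_config(config)
  if (!is.null(seed)) config$seed <- seed
  out_dir <- config$output$dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) cat(format(Sys.time(), "%H:%M:%S "),
                            sprintf(...), "\n", sep = "",
                            file = log_path, append = TRUE)
  cat(sprintf("patchentropy %s run, seed %d\n",
              as.character(utils::packageVersion("patchentropy")),
              as.integer(config$seed)),
      file = log_path)
  manifest <- list()
  keep <- function(artifact, path)
    manifest[[length(manifest) + 1L]] <<-
      data.frame(artifact = artifact, path = path,
                 md5 = as.character(tools::md5sum(path)))

  # stage: input
  grid <- tryCatch({
    if (!is.null(config$input$path)) {
      read_composition(config$input$path,
                       dialect = config$input$dialect %||% "long-csv")
    } else {
      sim <- do.call(simulation_spec,
                     utils::modifyList(config$input$simulate,
                                       list(seed = config$seed)))
      simulate_composition(sim)
    }
  }, error = function(e) stop("stage 'input' failed: ",
                              conditionMessage(e)))
  gpath <- file.path(out_dir, "grid.csv")
  write_composition(grid, gpath)
  keep("grid", gpath)
  logf("input: %d cells, %d times, %d categories",
       nrow(grid$cells), length(grid$times), length(grid$categories))

  # stage: patches
  units <- tryCatch(
    label_patch_units(grid,
                      threshold = config$patches$threshold,
                      connectivity = config$patches$connectivity,
                      si_classing = size_classing(config$patches$si_classes),
                      ti_classing = size_classing(config$patches$ti_classes)),
    error = function(e) stop("stage 'patches' failed: ",
                             conditionMessage(e)))
  upath <- file.path(out_dir, "patch_units.csv")
  utils::write.csv(units, upath, row.names = FALSE)
  keep("patch_units", upath)
  logf("patches: %d labelled units, %d spatial, %d temporal patches",
       nrow(units), length(unique(units$sp_id)),
       length(unique(units$tp_id)))

  # stage: table
  tab <- tryCatch({
    stat <- config$table$statistic
    if (stat %in% c("occurrence", "patch-occurrence")) {
      occurrence_table(units, modes = c("Si", "Ti", "category"),
                       count_unit = if (stat == "patch-occurrence") "patch"
                       else "cell")
    } else {
      obs <- to_observations(grid, rule = "weighted-multiple",
                             threshold = config$patches$threshold)
      spec_args <- config$table[setdiff(names(config$table),
                                        c("statistic", "count_unit", "mode"))]
      pspec <- do.call(proximity_spec, spec_args)
      if (stat == "cooccurrence")
        cooccurrence_table(obs, pspec,
                           grouping = config$table$mode %||% "snapshot")
      else if (stat == "distance-ratio")
        distance_ratio_table(obs, pspec,
                             mode = config$table$mode %||% "local-asymmetric")
      else stop("unknown statistic: ", stat)
    }
  }, error = function(e) stop("stage 'table' failed: ",
                              conditionMessage(e)))
  tpath <- file.path(out_dir, "multiway_table.csv")
  write_multiway(tab, tpath)
  keep("multiway_table", tpath)
  keep("multiway_table_meta",
       paste0(tools::file_path_sans_ext(tpath), ".json"))
  logf("table: %s, shape %s, N = %g", tab$kind,
       paste(dim(tab$values), collapse = "x"), tab$N)

  # stage: entropy
  for (ch in config$analysis$chains) {
    rep <- tryCatch(entropy_decompose(tab, chain = ch),
                    error = function(e) stop("stage 'entropy' failed: ",
                                             conditionMessage(e)))
    epath <- file.path(out_dir, sprintf("entropy_%s.csv",
                                        paste(ch, collapse = "-")))
    write_entropy_report(rep, epath)
    keep(paste0("entropy_", paste(ch, collapse = "-")), epath)
    logf("entropy chain %s: Hu(joint) = %.7f",
         paste(ch, collapse = "->"), rep$Hu_joint)
  }

  # stage: fca
  if (config$analysis$fca_components >= 1) {
  fca <- tryCatch(
    decompose_fca(tab, n_components = config$analysis$fca_components,
                  seed = config$seed),
    error = function(e) stop("stage 'fca' failed: ", conditionMessage(e)))
  fpath <- file.path(out_dir, "fca.json")
  write_mwca(fca, fpath)
  keep("fca", fpath)
  for (r in seq_len(config$analysis$fca_components))
    keep(sprintf("fca_ctr_r%d", r),
         sprintf("%s_ctr_r%d.csv", tools::file_path_sans_ext(fpath), r))
  logf("fca: chi2/N = %.6f, shares %s", fca$chi2_n,
       paste(sprintf("%.2f%%", vapply(fca$components, `[[`, 0, "share")),
             collapse = ", "))
  }

  manifest <- do.call(rbind, manifest)
  mpath <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  if (isTRUE(config$verbose)) message(paste(readLines(log_path),
                                            collapse = "\n"))
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
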