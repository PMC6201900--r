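#' Hierarchical HDF5 experiment store
#'
#' Persists the full experiment hierarchy - parametrizations, final
#' states, steady-state reports, fluxes, memberships - in one HDF5 file
#' with the group layout `/model_meta`, `/parametrizations`,
#' `/conditions/<id>/runs/p<id>`, `/membership`, `/analysis`.  The layout
#' version is stored as a root attribute and checked on open.  Numeric
#' payloads round-trip losslessly.
#'
#' @param path Path of the HDF5 file.
#' @param create Create a new store (`TRUE`) or open an existing one.
#' @param overwrite When creating, replace an existing file.
#' @return An `experiment_store` handle (list with `path` and `version`).
#' @export
experiment_store <- function(path, create = !file.exists(path),
                             overwrite = FALSE) {
  version <- "1.0"
  if (create) {
    if (file.exists(path)) {
      if (!overwrite) {
        abort(paste0("Store already exists: ", path),
              class = "kin_storage_error")
      }
      unlink(path)
    }
    rhdf5::h5createFile(path)
    for (g in c("model_meta", "parametrizations", "conditions",
                "membership", "analysis")) {
      rhdf5::h5createGroup(path, g)
    }
    fid <- rhdf5::H5Fopen(path)
    rhdf5::h5writeAttribute(version, fid, "layout_version")
    rhdf5::H5Fclose(fid)
  } else {
    if (!file.exists(path)) {
      abort(paste0("No store at: ", path), class = "kin_storage_error")
    }
    on_disk <- tryCatch(rhdf5::h5readAttributes(path, "/")$layout_version,
                        error = function(e) NULL)
    if (is.null(on_disk) || !identical(as.character(on_disk), version)) {
      abort(paste0("Store layout version mismatch (found ",
                   if (is.null(on_disk)) "none" else on_disk,
                   ", expected ", version, ")."),
            class = "kin_storage_error")
    }
  }
  structure(list(path = path, version = version), class = "experiment_store")
}

#' @export
print.experiment_store <- function(x, ...) {
  cat("<experiment_store> ", x$path, " (layout ", x$version, ")\n", sep = "")
  invisible(x)
}

store_ls <- function(store) {
  rhdf5::h5ls(store$path, recursive = TRUE)
}

run_path <- function(condition_id, parametrization_id) {
  paste0("conditions/", condition_id, "/runs/p", parametrization_id)
}

# HDF5 compound datasets have no logical type: encode as integer on write,
# decode by column name on read.
encode_logicals <- function(df) {
  for (col in names(df)) if (is.logical(df[[col]])) df[[col]] <- as.integer(df[[col]])
  df
}

decode_logicals <- function(df, cols) {
  for (col in intersect(cols, names(df))) df[[col]] <- as.logical(df[[col]])
  df
}

# h5read returns 1d-array columns; flatten them to plain vectors
h5_tibble <- function(path, name) {
  df <- rhdf5::h5read(path, name)
  for (col in names(df)) df[[col]] <- as.vector(df[[col]])
  as_tibble(df)
}

#' Write one simulation run to the store
#'
#' @param store An open [experiment_store()].
#' @param parametrization_id,condition_id Record key.
#' @param final_state Named concentration vector (or `NULL` for solver
#'   failures).
#' @param steady_report A `steady_state_report` (or `NULL`).
#' @param fluxes A `kin_fluxes` tibble (or `NULL` for discarded runs).
#' @param overwrite Replace an existing record with the same key.
#' @return The record id string, invisibly.
#' @export
store_write_run <- function(store, parametrization_id, condition_id,
                            final_state = NULL, steady_report = NULL,
                            fluxes = NULL, overwrite = FALSE) {
  path <- store$path
  ls <- store_ls(store)
  cond_group <- paste0("/conditions/", condition_id)
  if (!any(ls$group == "/conditions" & ls$name == condition_id)) {
    rhdf5::h5createGroup(path, cond_group)
    rhdf5::h5createGroup(path, paste0(cond_group, "/runs"))
  }
  rp <- run_path(condition_id, parametrization_id)
  exists <- any(paste0(ls$group, "/", ls$name) == paste0("/", rp))
  if (exists) {
    if (!overwrite) {
      abort(paste0("Record already stored: ", rp),
            class = "kin_storage_error")
    }
    rhdf5::h5delete(path, rp)
  }
  rhdf5::h5createGroup(path, rp)
  meta <- encode_logicals(data.frame(
    parametrization_id = as.integer(parametrization_id),
    condition_id = as.character(condition_id),
    solver_ok = !is.null(steady_report),
    statistic = if (!is.null(steady_report)) steady_report$statistic else NA_real_,
    passed = !is.null(steady_report) && steady_report$passed,
    stringsAsFactors = FALSE
  ))
  rhdf5::h5write(meta, path, paste0(rp, "/meta"))
  if (!is.null(final_state)) {
    fs <- data.frame(species_id = names(final_state),
                     concentration = unname(final_state),
                     stringsAsFactors = FALSE)
    rhdf5::h5write(fs, path, paste0(rp, "/final_state"))
  }
  if (!is.null(fluxes)) {
    fl <- data.frame(reaction_id = fluxes$reaction_id, flux = fluxes$flux,
                     stringsAsFactors = FALSE)
    rhdf5::h5write(fl, path, paste0(rp, "/fluxes"))
  }
  invisible(rp)
}

#' Write the parametrization table / membership table to the store
#'
#' @param store An [experiment_store()].
#' @param params,membership Tibbles as produced by
#'   [sample_parametrizations()] / [assign_phenotypes()].
#' @return The store, invisibly.
#' @export
store_write_params <- function(store, params) {
  if (any(store_ls(store)$group == "/parametrizations")) {
    try(rhdf5::h5delete(store$path, "parametrizations/table"), silent = TRUE)
  }
  rhdf5::h5write(as.data.frame(params), store$path, "parametrizations/table")
  invisible(store)
}

#' @rdname store_write_params
#' @export
store_write_membership <- function(store, membership) {
  if (any(store_ls(store)$group == "/membership")) {
    try(rhdf5::h5delete(store$path, "membership/table"), silent = TRUE)
  }
  rhdf5::h5write(encode_logicals(as.data.frame(membership)), store$path,
                 "membership/table")
  invisible(store)
}

#' Read the parametrization / membership table back
#' @param store An [experiment_store()].
#' @return A tibble.
#' @export
store_read_params <- function(store) {
  h5_tibble(store$path, "parametrizations/table")
}

#' @rdname store_read_params
#' @export
store_read_membership <- function(store) {
  tbl <- h5_tibble(store$path, "membership/table")
  ph <- setdiff(names(tbl), c("record_id", "parametrization_id", "condition_id"))
  decode_logicals(tbl, ph)
}

#' Query stored runs
#'
#' Selects run records by condition, steady-state verdict,
#' parametrization id, or phenotype membership (the latter requires a
#' membership table written with [store_write_membership()]).  Selectors
#' combine conjunctively; no selector returns every record.
#'
#' @param store An [experiment_store()].
#' @param ... Named selectors among `condition`, `steady`,
#'   `parametrization`, `phenotype`.  Unknown names raise a query error.
#' @param include_payloads Attach `final_state` and `fluxes` list-columns.
#' @return A tibble with one row per matching run.
#' @export
store_query <- function(store, ..., include_payloads = FALSE) {
  sel <- list(...)
  unknown <- setdiff(names(sel), c("condition", "steady", "parametrization",
                                   "phenotype"))
  if (length(unknown) || (length(sel) && is.null(names(sel)))) {
    abort(paste0("Unknown query field(s): ",
                 paste(if (length(unknown)) unknown else "<unnamed>",
                       collapse = ", ")),
          class = "kin_query_error")
  }
  ls <- store_ls(store)
  metas <- ls[ls$name == "meta" & grepl("^/conditions/.*/runs/p", ls$group), ]
  if (nrow(metas) == 0L) return(tibble())
  recs <- map(seq_len(nrow(metas)), function(i) {
    grp <- metas$group[i]
    m <- decode_logicals(h5_tibble(store$path, paste0(grp, "/meta")),
                         c("passed", "solver_ok"))
    if (include_payloads) {
      kids <- ls[ls$group == grp, "name"]
      m$final_state <- list(if ("final_state" %in% kids)
        h5_tibble(store$path, paste0(grp, "/final_state")) else NULL)
      m$fluxes <- list(if ("fluxes" %in% kids)
        h5_tibble(store$path, paste0(grp, "/fluxes")) else NULL)
    }
    m
  })
  out <- bind_rows(recs) %>%
    arrange(.data$condition_id, .data$parametrization_id)
  if (!is.null(sel$condition)) {
    out <- out[out$condition_id %in% sel$condition, , drop = FALSE]
  }
  if (!is.null(sel$steady)) {
    out <- out[out$passed == sel$steady, , drop = FALSE]
  }
  if (!is.null(sel$parametrization)) {
    out <- out[out$parametrization_id %in% sel$parametrization, , drop = FALSE]
  }
  if (!is.null(sel$phenotype)) {
    mem <- tryCatch(store_read_membership(store), error = function(e) {
      abort("Phenotype query needs a stored membership table.",
            class = "kin_query_error")
    })
    ph <- sel$phenotype
    if (!ph %in% names(mem)) {
      abort(paste0("Unknown phenotype '", ph, "' in membership table."),
            class = "kin_query_error")
    }
    keep <- mem[as.logical(mem[[ph]]), c("parametrization_id", "condition_id")]
    out <- dplyr::semi_join(out, keep, by = c("parametrization_id", "condition_id"))
  }
  out
}

#' Export every store table as TSV
#'
#' Writes `runs.tsv` (run metadata), `fluxes.tsv` (wide flux table),
#' plus `parametrizations.tsv` and `membership.tsv` when present.
#'
#' @param store An [experiment_store()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
store_export_tsv <- function(store, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  runs <- store_query(store, include_payloads = TRUE)
  if (nrow(runs)) {
    readr::write_tsv(runs %>% select(-any_of(c("final_state", "fluxes"))),
                     file.path(dir, "runs.tsv"))
    with_flux <- runs[!map_lgl(runs$fluxes, is.null), , drop = FALSE]
    if (nrow(with_flux)) {
      wide <- map(seq_len(nrow(with_flux)), function(i) {
        fl <- with_flux$fluxes[[i]]
        bind_cols(
          tibble(parametrization_id = with_flux$parametrization_id[i],
                 condition_id = with_flux$condition_id[i]),
          as_tibble(as.list(stats::setNames(fl$flux, fl$reaction_id)))
        )
      })
      readr::write_tsv(bind_rows(wide), file.path(dir, "fluxes.tsv"))
    }
  }
  for (tblname in c("parametrizations", "membership")) {
    tbl <- tryCatch(
      h5_tibble(store$path, paste0(tblname, "/table")),
      error = function(e) NULL)
    if (!is.null(tbl)) {
      readr::write_tsv(tbl, file.path(dir, paste0(tblname, ".tsv")))
    }
  }
  invisible(dir)
}
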