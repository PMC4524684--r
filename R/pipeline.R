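# End-to-end orchestration: structure -> elastic network modes -> rigidity
# -> biased geometric simulation over a mode list (parallel and
# antiparallel) -> measures -> summary.

config_hash <- function(obj) {
  txt <- paste(deparse(obj), collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 97 + 1)) %% .Machine$integer.max)
}

normalize_mode_list <- function(mode_list) {
  out <- lapply(mode_list, function(m) {
    if (is.numeric(m) && is.null(names(m)) && length(m) == 1) {
      stats::setNames(1, as.character(m))
    } else m
  })
  out
}

#' Run the full cooperative-motion pipeline
#'
#' For each requested mode (single or weighted combination) and each
#' direction (parallel, antiparallel), runs a geometric simulation biased
#' along that mode and evaluates the measure specs on every saved frame.
#'
#' @param x a [make_toy_dimer()] object or a single-model atom tibble.
#' @param mode_list list of modes to bias along: bare mode numbers or named
#'   weight vectors, e.g. `list(7, 8, c("8" = 1, "7" = 1))`.
#' @param specs named list of measure specs; defaults to the toy's
#'   designated sites (for a `toy_dimer`) or the DcpS conventions.
#' @param enm_cutoff elastic-network distance cutoff, A.
#' @param e_cut hydrogen-bond energy cutoff, kcal/mol (all-atom inputs).
#' @param config a [geosim_config()]; each run derives its own seed from
#'   `config$seed` so runs are independent but reproducible.
#' @param directions directions to run for each mode.
#' @param out_dir optional output directory: per-run trajectory PDB, measure
#'   CSV and run header JSON, plus a pipeline summary JSON, are written
#'   there.
#' @return object of class `pipeline_result`: `modes`, `rigid`, `runs`
#'   (per run: `trajectory`, `measures`), `summary` (tibble run/measure/
#'   min/max/last), `run_id`, `config_hash`.
#' @examples
#' \donttest{
#' toy <- make_toy_dimer()
#' res <- run_pipeline(toy, mode_list = list(7),
#'                     config = geosim_config(max_steps = 30, save_interval = 10))
#' res$summary
#' }
#' @export
run_pipeline <- function(x, mode_list = list(7, 8, 9), specs = NULL,
                         enm_cutoff = 12, e_cut = -2.0,
                         config = geosim_config(),
                         directions = c("parallel", "antiparallel"),
                         out_dir = NULL) {
  if (inherits(x, "toy_dimer")) {
    atoms <- x$atoms
    domains <- x$domains
    if (is.null(specs)) specs <- x$sites[c("intersite", "hinge", "cleft")]
  } else {
    atoms <- one_model(x)
    domains <- NULL
    if (is.null(specs)) {
      specs <- list(intersite = intersite_spec(), hinge = hinge_spec())
    }
  }
  run_id <- format(Sys.time(), "run-%Y%m%d%H%M%S")
  chash <- config_hash(list(mode_list, enm_cutoff, e_cut, unclass(config)))
  stage <- "enm"
  runs <- list()
  result <- tryCatch({
    enm <- build_enm(atoms, cutoff = enm_cutoff)
    modes <- compute_modes(enm)
    stage <- "rigidity"
    net <- build_constraint_network(atoms, e_cut = e_cut, domains = domains)
    rigid <- pebble_game(net)
    stage <- "templates"
    tpl <- build_templates(atoms, rigid, net)
    stage <- "geosim"
    mode_list <- normalize_mode_list(mode_list)
    idx <- 0L
    for (m in mode_list) {
      bias_vec <- combine_modes(modes, m)
      for (dir in directions) {
        idx <- idx + 1L
        cfg <- config
        cfg$direction <- dir
        cfg$seed <- derive_seed(config$seed, idx)
        field <- atomize_bias(bias_vec, atoms, step = config$bias_step)
        attr(field, "label") <- attr(bias_vec, "label")
        trj <- run_geosim(atoms, field, tpl, net, cfg)
        meas <- measure_series(trj, specs)
        label <- sprintf("mode%s_%s", attr(bias_vec, "label"),
                         substr(dir, 1, 4))
        runs[[label]] <- list(trajectory = trj, measures = meas)
      }
    }
    stage <- "summary"
    summary <- dplyr::bind_rows(purrr::imap(runs, function(r, nm) {
      dplyr::summarise(dplyr::group_by(r$measures, .data$measure),
                       min = min(.data$value), max = max(.data$value),
                       last = dplyr::last(.data$value), .groups = "drop") |>
        dplyr::mutate(run = nm, jammed = r$trajectory$jammed, .before = 1)
    }))
    summary$run_id <- run_id
    summary$config_hash <- chash
    structure(list(modes = modes, rigid = rigid, network = net,
                   templates = tpl, runs = runs, summary = summary,
                   specs = specs, run_id = run_id, config_hash = chash,
                   config = config),
              class = "pipeline_result")
  }, error = function(e) {
    abort(sprintf("pipeline failed at stage '%s': %s", stage,
                  conditionMessage(e)))
  })
  if (!is.null(out_dir)) write_pipeline(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d runs (%s)\n", length(x$runs),
              paste(names(x$runs), collapse = ", ")))
  print(x$summary, n = Inf)
  invisible(x)
}

#' Write all pipeline outputs to a directory
#'
#' @param result a [run_pipeline()] result.
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(result$runs)) {
    r <- result$runs[[nm]]
    write_geosim(r$trajectory,
                 pdb = file.path(out_dir, paste0(nm, ".pdb")),
                 csv = file.path(out_dir, paste0(nm, "_stats.csv")),
                 header_json = file.path(out_dir, paste0(nm, "_header.json")))
    meas <- dplyr::mutate(r$measures, run_id = result$run_id, stage = "measures",
                          config_hash = result$config_hash)
    utils::write.csv(meas, file.path(out_dir, paste0(nm, "_measures.csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(run_id = result$run_id, config_hash = result$config_hash,
         config = unclass(result$config),
         summary = result$summary),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  invisible(out_dir)
}

#' RMSD of every trajectory frame against a reference structure
#'
#' @param x multi-model atom tibble or geosim trajectory.
#' @param reference single-model atom tibble (e.g. a closed crystal form or
#'   its chain-swapped variant).
#' @param fit_sel selection for the superposition (named list of
#'   [select_atoms()] arguments).
#' @param report_sel optional separate selection for the reported RMSD.
#' @return list of class `reference_comparison`: `series` (tibble
#'   frame/rmsd), `best_frame`, `best_rmsd`.
#' @export
compare_to_reference <- function(x, reference, fit_sel = list(name = "CA"),
                                 report_sel = NULL) {
  atoms <- as_trajectory_atoms(x)
  models <- split(atoms, atoms$model)
  rms <- vapply(models, function(m) {
    m$model <- 1L
    superpose(m, reference, fit_sel = fit_sel, report_sel = report_sel)$rmsd
  }, numeric(1))
  series <- tibble(frame = as.integer(names(models)), rmsd = unname(rms))
  best <- which.min(series$rmsd)
  structure(list(series = series, best_frame = series$frame[best],
                 best_rmsd = series$rmsd[best]),
            class = "reference_comparison")
}

#' @export
print.reference_comparison <- function(x, ...) {
  cat(sprintf("<reference_comparison> best frame %d at %.2f A over %d frames\n",
              x$best_frame, x$best_rmsd, nrow(x$series)))
  invisible(x)
}

#' @export
tidy.reference_comparison <- function(x, ...) x$series
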