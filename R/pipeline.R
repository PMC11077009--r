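# End-to-end orchestration: config validation, staged execution
# (synthesize / simulate -> stress -> structure -> percolate -> collapse)
# and a reproducible run manifest.  The exported functions are the
# programmatic equivalent of a subcommand interface; scripts/acceptance.R
# shows the Rscript usage.

read_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop(sprintf("config file '%s' not readable", config))
    cfg <- yaml::read_yaml(config)
    # YAML 1.1 reads a bare `N:` key as boolean; map it back
    if (!is.null(cfg$simulate$params)) {
      nm <- names(cfg$simulate$params)
      nm[nm %in% c("FALSE", "no")] <- "N"
      names(cfg$simulate$params) <- nm
    }
    attr(cfg, "path") <- config
    cfg
  } else if (is.list(config)) config
  else stop("config must be a file path or a list")
}

#' Validate a pipeline configuration
#'
#' Structural checks without running anything: model-parameter invariants
#' (positivity, interface resolution `lam >= 2*a0`, box sizing), subsystem
#' sizes against the analysis-field extent, and occupation-grid bounds.
#' Never mutates files.
#'
#' @param config path to a YAML config or an equivalent list.
#' @return `TRUE` when valid, otherwise a character vector of violations
#'   (invisibly `TRUE`/the vector, also printed).
#' @export
validate_config <- function(config) {
  cfg <- read_config(config)
  bad <- character()
  if (!is.null(cfg$simulate$params)) {
    p <- tryCatch(do.call(model_params, cfg$simulate$params),
                  error = function(e) conditionMessage(e))
    if (is.character(p)) bad <- c(bad, p)
    else {
      v <- validate_params(p, stop_on_error = FALSE)
      bad <- c(bad, v)
    }
  }
  pg <- cfg$percolate
  if (!is.null(pg)) {
    if (!is.null(pg$p_min) && (pg$p_min < 0 || pg$p_max > 1 || pg$p_min >= pg$p_max))
      bad <- c(bad, "occupation grid must satisfy 0 <= p_min < p_max <= 1")
    ext <- NULL
    if (!is.null(cfg$synth$sizes)) ext <- min(unlist(cfg$synth$sizes))
    if (!is.null(cfg$simulate$params$grid))
      ext <- min(unlist(cfg$simulate$params$grid)[1:2]) + 1
    if (!is.null(pg$ells) && !is.null(ext) && max(unlist(pg$ells)) + 1 > ext)
      bad <- c(bad, sprintf(
        "subsystem size %d needs (ell+1) <= field extent %d",
        max(unlist(pg$ells)), ext))
  }
  if (length(bad)) bad else TRUE
}

config_checksum <- function(config) {
  if (!is.null(attr(config, "path"))) return(unname(tools::md5sum(attr(config, "path"))))
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(config, tf)
  unname(tools::md5sum(tf))
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order on a single configuration:
#' * `synth` — generate an i.i.d. uniform field ensemble per size;
#' * `simulate` — run the monolayer model with stress recording;
#' * `structure` — pair-correlation solid/liquid classification of the
#'   time-averaged configuration;
#' * `percolate` — threshold-percolation curves of the normalized
#'   time-averaged isotropic stress (or the synthetic ensemble);
#' * `collapse` — finite-size-scaling fits for `P` and `S`.
#'
#' The returned report collects the threshold and exponent estimates with
#' bootstrap errors (the layout of a critical-exponent summary table) plus
#' the `g(r)` classification when a simulation was run.  A manifest records
#' the config checksum, seeds, package version and timestamps; rerunning
#' the same config and seed reproduces all deterministic outputs.
#'
#' @param config path to a YAML config or an equivalent list.  Recognized
#'   blocks: `stages` (character vector), `seed`, `synth` (`sizes`,
#'   `n_fields`), `simulate` (`params` as [model_params()] arguments,
#'   `record_every`, `stress_every`), `percolate` (`p_min`, `p_max`,
#'   `p_step`, `ells`, `connectivity`), `collapse` (`n_boot`, `xmax`).
#' @param out_dir optional directory; when given, the report (JSON), the
#'   curves (CSV) and the manifest (JSON) are written there.
#' @return List with `manifest`, `report`, and the intermediate objects
#'   (`fields`, `trajectory`, `curves`, `fits`).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- read_config(config)
  v <- validate_config(cfg)
  if (!isTRUE(v))
    stop("invalid config:\n  - ", paste(v, collapse = "\n  - "), call. = FALSE)
  stages <- cfg$stages %||% character(0)
  seed <- cfg$seed %||% 1L
  manifest <- list(config_checksum = config_checksum(cfg),
                   seed = seed, stages = stages,
                   package_version = as.character(utils::packageVersion("stresschains")),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  res <- list(manifest = manifest, report = list())
  if (!length(stages)) {
    res$manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
    return(res)
  }

  fields <- NULL; traj <- NULL; ells <- NULL

  if ("synth" %in% stages) {
    sizes <- as.integer(unlist(cfg$synth$sizes %||% c(64, 128, 256)))
    n_fields <- cfg$synth$n_fields %||% 50L
    fields <- list()
    ells <- integer(0)
    for (L in sizes) {
      fl <- lapply(seq_len(n_fields), function(i)
        iid_uniform_field(c(L, L), seed = seed * 100000L + L * 1000L + i))
      fields <- c(fields, fl)
      ells <- c(ells, L - 1L)
    }
    res$fields <- fields
  }

  if ("simulate" %in% stages) {
    pargs <- cfg$simulate$params %||% list()
    pargs$seed <- pargs$seed %||% seed
    params <- do.call(model_params, pargs)
    traj <- run_simulation(params,
                           record_every = cfg$simulate$record_every %||% 1L,
                           record_stress = TRUE,
                           stress_every = cfg$simulate$stress_every %||% 5L)
    res$trajectory <- traj
  }

  if ("structure" %in% stages) {
    if (is.null(traj)) stop("structure stage needs inputs from the simulate stage")
    pos <- time_averaged_positions(traj)
    gr <- pair_correlation(pos, box = traj$params$grid[1:2], R0 = traj$params$R0)
    cls <- classify_state(gr)
    res$gr <- gr
    res$report$structure <- list(label = cls$label, peaks = cls$peaks)
  }

  if ("percolate" %in% stages) {
    pg <- cfg$percolate
    p_grid <- seq(pg$p_min %||% 0.30, pg$p_max %||% 0.90, by = pg$p_step %||% 0.005)
    conn <- pg$connectivity %||% "face4"
    if (is.null(fields)) {
      if (is.null(traj) || is.null(traj$stress_mean))
        stop("percolate stage needs fields from the synth stage or a simulated stress field")
      iso <- isotropic_stress(traj$stress_mean, normalize = TRUE)
      fields <- list(iso)
      ells <- pg$ells %||% (min(dim(iso$values)) - 1L)
    }
    ells <- as.integer(unlist(pg$ells %||% ells))
    # a common ell list must fit every field; per-size ensembles analyse
    # each field at its own maximal subsystem when ells are per-field
    if (length(unique(vapply(fields, function(f) min(dim(field_values(f))), 1L))) > 1L) {
      curves_list <- lapply(unique(ells), function(l) {
        fl <- Filter(function(f) min(dim(field_values(f))) >= l + 1L, fields)
        fl <- Filter(function(f) min(dim(field_values(f))) < 2L * (l + 1L), fl)
        percolation_curves(fl, p_grid, l, connectivity = conn)
      })
      curves <- merge_curves(curves_list)
    } else {
      curves <- percolation_curves(fields, p_grid, ells, connectivity = conn)
    }
    res$curves <- curves
  }

  if ("collapse" %in% stages) {
    if (is.null(res$curves)) stop("collapse stage needs curves from the percolate stage")
    nb <- cfg$collapse$n_boot %||% 50L
    xmax <- cfg$collapse$xmax
    fitP <- fss_collapse(res$curves, "P", n_boot = nb, xmax = xmax)
    fitS <- fss_collapse(res$curves, "S", n_boot = nb, xmax = xmax,
                         pc_start = fitP$pc)
    res$fits <- list(P = fitP, S = fitS)
    res$report$exponents <- data.frame(
      quantity = c("pc", "nu", "beta", "gamma"),
      estimate = c(fitP$pc, fitP$nu, fitP$exponent, fitS$exponent),
      error = c(fitP$pc_err, fitP$nu_err, fitP$exponent_err, fitS$exponent_err))
  }

  res$manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    if (!is.null(res$curves))
      write.csv(res$curves$curves, file.path(out_dir, "curves.csv"),
                row.names = FALSE)
    rep_out <- res$report
    if (!is.null(rep_out$exponents)) rep_out$exponents <- as.list(rep_out$exponents)
    jsonlite::write_json(rep_out, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  res
}

# combine single-size curve objects into one multi-size object (same p grid)
merge_curves <- function(curve_list) {
  stopifnot(length(curve_list) >= 1L)
  p <- curve_list[[1]]$p
  nmin <- min(vapply(curve_list, function(cc) cc$n_realizations, 1L))
  arr <- list()
  for (ob in c("Pi", "P", "S", "xi")) {
    arr[[ob]] <- array(NA_real_, c(nmin, length(curve_list), length(p)))
    for (e in seq_along(curve_list))
      arr[[ob]][, e, ] <- curve_list[[e]]$arr[[ob]][seq_len(nmin), 1, ]
  }
  ells <- vapply(curve_list, function(cc) cc$ells[1], 1L)
  curves <- do.call(rbind, lapply(curve_list, function(cc) cc$curves))
  structure(list(curves = curves, arr = arr, ells = ells, p = p,
                 connectivity = curve_list[[1]]$connectivity,
                 n_realizations = nmin),
            class = "percolation_curves")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
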