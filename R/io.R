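#' Read and write single-cell value tables
#'
#' `write_cells()` writes a snapshot distribution or cytometry table as
#' delimited text (CSV, header included).  `read_cells()` reads one back,
#' validating the header and the values: a table with `FITC-H`, `SSC-H`,
#' `FSC-H`, `Width`, `replicate`, `condition` columns becomes a
#' `cytometry_table`; one with `cell_id`, `replicate`, `condition`, `value`
#' becomes a `snapshot_distribution`.  Malformed rows (non-numeric or
#' non-positive channel values) are reported with their line numbers.
#'
#' @param x a `snapshot_distribution` or `cytometry_table`.
#' @param path file path.
#' @return `read_cells()` the validated table; `write_cells()` `path`,
#'   invisibly.
#' @export
read_cells <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, check.names = FALSE)
  if (!nrow(tab) || !ncol(tab))
    stop("empty file: ", path, call. = FALSE)
  cyto_cols <- c("FITC-H", "SSC-H", "FSC-H", "Width", "replicate", "condition")
  snap_cols <- c("cell_id", "replicate", "condition", "value")
  if (all(snap_cols %in% names(tab))) {
    bad <- which(!is.finite(tab$value) | tab$value < 0)
    if (length(bad))
      stop("invalid value(s) at data line(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    out <- snapshot_distribution(tab$value, condition = tab$condition,
                                 replicate = tab$replicate,
                                 kind = attr_kind_guess(tab$value))
    out$cell_id <- tab$cell_id
    return(out)
  }
  missing_cyto <- setdiff(cyto_cols, names(tab))
  if (length(missing_cyto) && length(missing_cyto) < length(cyto_cols))
    stop("missing column(s): ", paste(missing_cyto, collapse = ", "),
         call. = FALSE)
  if (!length(missing_cyto)) {
    for (ch in c("FITC-H", "SSC-H", "FSC-H", "Width")) {
      v <- suppressWarnings(as.numeric(tab[[ch]]))
      bad <- which(!is.finite(v) | v <= 0)
      if (length(bad))
        stop("non-positive or non-numeric '", ch, "' at data line(s) ",
             paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
      tab[[ch]] <- v
    }
    return(as_cytometry_table(tab))
  }
  stop("unrecognised header: expected a snapshot table (",
       paste(snap_cols, collapse = ", "), ") or a cytometry table (",
       paste(cyto_cols, collapse = ", "), ")", call. = FALSE)
}

attr_kind_guess <- function(v) {
  if (all(v == round(v))) "count" else "intensity"
}

#' @rdname read_cells
#' @export
write_cells <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run a configured analysis pipeline
#'
#' Executes a sequence of named stages against one shared master seed and
#' returns (and optionally writes as JSON) a machine-readable report.  The
#' configuration is a named list — or the path of a YAML file holding one —
#' with a `seed` and a `stages` list.  Supported stages:
#'
#' * `synth`: `spec` (a `population_spec` or a list of its arguments) —
#'   generates a synthetic cytometry table.
#' * `simulate`: `rates` (a `rate_set` or list of its arguments), optional
#'   `n_cells`, `t_snap` — samples a model snapshot.
#' * `classify`: `input` (name of an earlier stage, or `path` of a table) —
#'   modality call on the merged sample.
#' * `shape`: `input` (name of a `classify` stage) — shape parameters.
#' * `sweep`: `param`, optional `factors`, `n_cells` — single-parameter
#'   sweep from the reference rates.
#'
#' Unknown stage types raise an error before any computation runs.  Given
#' the same configuration and seed the report is identical.
#'
#' @param config named list or YAML file path.
#' @param out optional path; the report is written there as JSON.
#' @return The report (a named list), invisibly when `out` is given.
#' @export
run_pipeline <- function(config, out = NULL) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  if (!is.list(config) || is.null(config$stages))
    stop("config must be a list with a 'stages' entry", call. = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  known <- c("synth", "simulate", "classify", "shape", "sweep")
  types <- vapply(config$stages, function(s) s$type %||% "", "")
  bad <- setdiff(types, known)
  if (length(bad))
    stop("unknown stage type(s): ", paste(bad, collapse = ", "), call. = FALSE)

  data_env <- list()
  report <- list(seed = seed, units = "minutes", stages = list())
  for (i in seq_along(config$stages)) {
    st <- config$stages[[i]]
    nm <- st$name %||% paste0(st$type, i)
    sseed <- derive_seed(seed, i)
    res <- switch(st$type,
      synth = {
        spec <- if (inherits(st$spec, "population_spec")) st$spec
                else do.call(population_spec, st$spec %||% list())
        tab <- generate_population(spec, seed = sseed)
        data_env[[nm]] <- tab
        list(type = "synth", n = nrow(tab), seed = sseed,
             condition = spec$condition)
      },
      simulate = {
        rates <- if (inherits(st$rates, "rate_set")) st$rates
                 else if (is.null(st$rates)) reference_rates()
                 else do.call(rate_set, st$rates)
        sys <- build_reduced_model(rates)
        snap <- sample_snapshot(sys, t_snap = st$t_snap,
                                n_cells = st$n_cells %||% 5000, seed = sseed)
        data_env[[nm]] <- snap
        list(type = "simulate", n = nrow(snap), seed = sseed,
             mean = mean(snap$value))
      },
      classify = {
        x <- if (!is.null(st$path)) read_cells(st$path)
             else data_env[[st$input]]
        if (is.null(x)) stop("classify stage: unknown input '", st$input, "'",
                             call. = FALSE)
        vals <- if (inherits(x, "cytometry_table"))
          snapshot_distribution(x[["FITC-H"]], condition = x$condition[1],
                                replicate = x$replicate, kind = "intensity")
        else x
        call <- classify_modality(vals)
        data_env[[nm]] <- list(call = call, values = vals)
        list(type = "classify", verdict = call$verdict,
             criteria = as.list(call$criteria),
             pk1 = call$pk1, pk2 = call$pk2,
             mixture = list(weights = call$fit2$weights,
                            means = call$fit2$means, sds = call$fit2$sds))
      },
      shape = {
        src <- data_env[[st$input]]
        if (is.null(src$call)) stop("shape stage needs a classify input",
                                    call. = FALSE)
        sp <- shape_params(src$call, src$values)
        list(type = "shape", d = sp$d, h = sp$h, o = sp$o,
             h_convention = sp$h_convention)
      },
      sweep = {
        spec <- sweep_spec(reference_rates(), st$param,
                           factors = st$factors %||% default_grid(),
                           n_cells = st$n_cells %||% 2000, seed = sseed)
        sw <- run_sweep(spec)
        s <- summary(sw)
        list(type = "sweep", param = st$param,
             table = lapply(seq_len(nrow(s)), function(r) as.list(s[r, ])))
      })
    report$stages[[nm]] <- res
  }
  if (!is.null(out)) {
    jsonlite::write_json(report, out, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(report))
  }
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a
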