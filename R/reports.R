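# Descriptive group summaries and the configuration-driven pipeline runner.
# Inferential statistics (normality tests, ANOVA, post-hoc corrections) are
# deliberately delegated: the package emits tidy per-sample tables ready for
# any stats environment.

#' Per-group descriptive summary
#'
#' Mean, sample standard deviation (n - 1 denominator), n and coefficient of
#' variation (`CV% = 100 sd / mean`) for each group.
#'
#' @param data A data frame.
#' @param value Column holding the measured values (tidy-eval).
#' @param group Column identifying groups (tidy-eval).
#' @return A tibble with one row per group: `group`, `n`, `mean`, `sd`,
#'   `cv_pct`.
#' @examples
#' df <- data.frame(side = rep(c("a", "b"), each = 3),
#'                  thickness = c(100, 130, 70, 120, 120, 120))
#' summarize_groups(df, thickness, side)
#' @export
summarize_groups <- function(data, value, group) {
  value <- rlang::enquo(value)
  group <- rlang::enquo(group)
  out <- dplyr::summarise(
    dplyr::group_by(data, group = !!group),
    n = dplyr::n(),
    mean = mean(!!value),
    sd = sd(!!value),
    .groups = "drop"
  )
  if (any(out$n < 2L)) {
    stop_data("every group needs n >= 2 for a standard deviation")
  }
  dplyr::mutate(out, cv_pct = 100 * .data$sd / .data$mean)
}

#' Read an AFM calibration file
#'
#' Flat YAML key/value text with the fields of [afm_calibration()] in SI
#' units (`kn`, `alpha`, `kt`, `delta`, `t_cant`, `d_tip`, and optionally
#' `roc`, `poisson`).
#'
#' @param path Path to the YAML calibration file.
#' @return An [afm_calibration()].
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("calibration file not found: %s", path))
  cfg <- yaml::read_yaml(path)
  required <- c("kn", "alpha", "kt", "delta", "t_cant", "d_tip")
  missing <- setdiff(required, names(cfg))
  if (length(missing) > 0) {
    stop_format(sprintf("calibration file missing field(s): %s",
                        paste(missing, collapse = ", ")))
  }
  afm_calibration(kn = cfg$kn, alpha = cfg$alpha, kt = cfg$kt,
                  delta = cfg$delta, t_cant = cfg$t_cant, d_tip = cfg$d_tip,
                  roc = cfg$roc %||% 10.25e-6, poisson = cfg$poisson %||% 0.45)
}

pipeline_stage_types <- c("tensile", "relax", "afm_indent", "afm_friction")

#' Run a configured analysis pipeline
#'
#' Executes the stages named in a YAML configuration. All configuration is
#' validated (stage types known, referenced files present) before any
#' computation starts or any file is written, so a bad configuration fails
#' fast. Every output is a [result_bundle()] carrying provenance (inputs,
#' parameters, seed where applicable, package version).
#'
#' @param config Path to a YAML configuration, or an equivalent list. Top
#'   level: `stages`, a list of blocks each with a `type` among `"tensile"`,
#'   `"relax"`, `"afm_indent"`, `"afm_friction"` plus stage-specific fields
#'   (`input`, `column_map`, `geometry`, `calibration`, ...), and optional
#'   `out_dir` to write each bundle as JSON.
#' @param verbose Log each stage via `message()`.
#' @return A named list of `result_bundle`s, one per stage.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) stop_config(sprintf("config file not found: %s", config))
    yaml::read_yaml(config)
  } else config
  stages <- cfg$stages
  if (is.null(stages) || length(stages) == 0) stop_config("config has no stages")

  # fail-fast validation pass
  for (i in seq_along(stages)) {
    st <- stages[[i]]
    if (is.null(st$type) || !st$type %in% pipeline_stage_types) {
      stop_config(sprintf("stage %d: unknown type '%s'", i, st$type %||% "<missing>"))
    }
    for (f in c("input", "column_map", "calibration", "manifest")) {
      if (!is.null(st[[f]]) && is.character(st[[f]]) && !file.exists(st[[f]])) {
        stop_config(sprintf("stage %d: %s file not found: %s", i, f, st[[f]]))
      }
    }
  }

  out <- lapply(seq_along(stages), function(i) {
    st <- stages[[i]]
    if (verbose) message(sprintf("[tissuemech] stage %d: %s", i, st$type))
    run_stage(st)
  })
  names(out) <- vapply(seq_along(stages), function(i) {
    stages[[i]]$name %||% sprintf("stage%d_%s", i, stages[[i]]$type)
  }, character(1))

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in names(out)) {
      write_results(out[[nm]], file.path(cfg$out_dir, paste0(nm, ".json")))
    }
  }
  out
}

stage_geometry <- function(st) {
  g <- st$geometry
  if (is.null(g)) stop_config("stage needs a geometry block (width/thickness/gauge_length, SI)")
  specimen_geometry(g$width, g$thickness, g$gauge_length)
}

stage_column_map <- function(st) {
  cm <- st$column_map
  if (is.character(cm)) read_column_map(cm) else
    lapply(cm, function(x) list(col = x$col %||% x$column, unit = x$unit %||% ""))
}

run_stage <- function(st) {
  switch(
    st$type,
    tensile = {
      rec <- read_tensile(st$input, stage_column_map(st), stage_geometry(st),
                          preload = st$preload %||% 0.040)
      ss <- to_engineering(zero_reference(rec))
      if (isTRUE(st$true)) ss <- to_true(ss)
      window <- unlist(st$window %||% c(0.40, 0.60))
      result_bundle(youngs_modulus(ss, window = window),
                    input = st$input, window = window,
                    preload = st$preload %||% 0.040,
                    convention = convention(ss))
    },
    relax = {
      df <- read_delimited(st$input)
      cm <- stage_column_map(st)
      trace <- relaxation_trace(
        time = mapped_column(df, cm, "time", st$input),
        stress = mapped_column(df, cm, "stress", st$input),
        strain = mapped_column(df, cm, "strain", st$input),
        hold_strain = st$hold_strain
      )
      seed <- st$seed %||% 1L
      # exact [[ ]] indexing: `$` would partial-match `n` to `n_max`
      fit <- if (!is.null(st[["n"]])) {
        fit_maxwell(trace, n = st[["n"]], restarts = st$restarts %||% 8,
                    seed = seed)
      } else {
        select_order(trace, n_max = st[["n_max"]] %||% 6,
                     drop_threshold = st$drop_threshold %||% 0.05,
                     restarts = st$restarts %||% 8, seed = seed)
      }
      result_bundle(
        list(fit = fit,
             relaxation_pct = relaxation_percent(trace, horizon = st$horizon %||% 200)),
        input = st$input, seed = seed,
        n = st[["n"]] %||% NA, n_max = st[["n_max"]] %||% 6,
        drop_threshold = st$drop_threshold %||% 0.05
      )
    },
    afm_indent = {
      cal <- read_calibration(st$calibration)
      curve <- read_force_curve(st$input, stage_column_map(st))
      names(curve) <- c("position", "force")
      fit <- fit_hertz(curve, cal, trigger = st$trigger %||% 5e-9)
      result_bundle(glance(fit), input = st$input,
                    calibration = st$calibration, trigger = st$trigger %||% 5e-9)
    },
    afm_friction = {
      cal <- read_calibration(st$calibration)
      manifest <- read_delimited(st$manifest)
      if (!all(c("file", "normal_force") %in% names(manifest))) {
        stop_config("friction manifest needs columns 'file' and 'normal_force'")
      }
      cm <- stage_column_map(st)
      base <- dirname(st$manifest)
      loops <- purrr::map2(manifest$file, manifest$normal_force, function(f, fn) {
        p <- if (file.exists(f)) f else file.path(base, f)
        df <- read_delimited(p)
        friction_loop(mapped_column(df, cm, "position", p),
                      mapped_column(df, cm, "v_trace", p),
                      mapped_column(df, cm, "v_retrace", p),
                      normal_force = fn)
      })
      res <- friction_coefficient(loops, cal)
      result_bundle(glance(res), manifest = st$manifest,
                    calibration = st$calibration)
    }
  )
}
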