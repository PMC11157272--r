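# CSV readers/writers with schema validation. Column names carry explicit
# units (conc_M, h_nm, time_h) to prevent unit drift; validators return
# row-indexed error reports and never silently coerce.

.tv_schemas <- function() {
  list(
    titration = list(
      required = c(curve_id = "character", conc_M = "numeric", signal = "numeric"),
      optional = c(signal_sd = "numeric", DT_hint_M = "numeric"),
      checks = list(
        conc_M = function(v) ifelse(is.na(v) | v < 0, "must be >= 0", NA),
        signal = function(v) ifelse(is.na(v), "must be non-missing", NA),
        signal_sd = function(v) ifelse(!is.na(v) & v <= 0, "must be > 0", NA),
        DT_hint_M = function(v) ifelse(!is.na(v) & v <= 0, "must be > 0", NA))),
    afm = list(
      required = c(peak_id = "character", h_nm = "numeric", w_long_nm = "numeric",
                   w_orth_nm = "numeric", dna_bound = "logical"),
      optional = c(h_dna_nm = "numeric", w_dna_nm = "numeric"),
      checks = list(
        h_nm = function(v) ifelse(is.na(v) | v <= 0, "must be > 0", NA),
        w_long_nm = function(v) ifelse(is.na(v) | v <= 0, "must be > 0", NA),
        w_orth_nm = function(v) ifelse(is.na(v) | v <= 0, "must be > 0", NA)),
      row_rule = function(df) {
        bound <- as.logical(df$dna_bound)
        h <- if ("h_dna_nm" %in% names(df)) df$h_dna_nm else rep(NA_real_, nrow(df))
        w <- if ("w_dna_nm" %in% names(df)) df$w_dna_nm else rep(NA_real_, nrow(df))
        bad <- which(bound & (is.na(h) | h <= 0 | is.na(w) | w <= 0))
        if (!length(bad)) return(NULL)
        data.frame(row = bad, column = "h_dna_nm/w_dna_nm",
                   message = "DNA-bound peak requires positive adjacent-DNA measurements")
      }),
    plate = list(
      required = c(condition = "character", substrate_mM = "numeric",
                   replicate = "numeric", luminescence = "numeric"),
      optional = c(experiment = "character"),
      checks = list(
        luminescence = function(v) ifelse(is.na(v) | v <= 0, "must be > 0", NA))),
    growth = list(
      required = c(strain = "character", time_h = "numeric", od600 = "numeric",
                   replicate = "numeric"),
      optional = character(),
      checks = list(
        time_h = function(v) ifelse(is.na(v), "must be non-missing", NA),
        od600 = function(v) ifelse(is.na(v) | v < 0, "must be >= 0", NA)))
  )
}

#' Validate a table against one of the pipeline schemas
#'
#' Type and range checks, per column and per row, against the named schema
#' (`"titration"`, `"afm"`, `"plate"`, `"growth"`). Returns the table
#' invisibly when clean; otherwise the row-indexed error report.
#'
#' @param df a `data.frame` (or path to a CSV file).
#' @param schema schema name.
#' @param stop_on_error raise an error naming file, row and column (default
#'   TRUE); when FALSE, return the error report `data.frame`.
#' @param file label used in error messages.
#' @return the validated `data.frame` (invisibly), or the error report when
#'   `stop_on_error = FALSE`.
#' @export
validate_table <- function(df, schema, stop_on_error = TRUE, file = "<data>") {
  schemas <- .tv_schemas()
  if (!schema %in% names(schemas)) stop_field("schema", "unknown schema")
  if (is.character(df)) {
    file <- df
    df <- utils::read.csv(df, stringsAsFactors = FALSE)
  }
  sc <- schemas[[schema]]
  errors <- list()
  miss <- setdiff(names(sc$required), names(df))
  if (length(miss)) {
    errors[[length(errors) + 1L]] <- data.frame(
      row = NA_integer_, column = miss, message = "missing required column")
  }
  for (col in intersect(names(c(sc$required, sc$optional)), names(df))) {
    want <- c(sc$required, sc$optional)[[col]]
    v <- df[[col]]
    ok_type <- switch(want,
                      numeric = is.numeric(v),
                      character = is.character(v) || is.factor(v),
                      logical = is.logical(v) ||
                        all(v %in% c(TRUE, FALSE, 0, 1, "TRUE", "FALSE", NA)))
    if (!ok_type) {
      errors[[length(errors) + 1L]] <- data.frame(
        row = NA_integer_, column = col, message = paste("expected type", want))
      next
    }
    chk <- sc$checks[[col]]
    if (!is.null(chk)) {
      msgs <- chk(v)
      bad <- which(!is.na(msgs))
      if (length(bad)) {
        errors[[length(errors) + 1L]] <- data.frame(
          row = bad, column = col, message = msgs[bad])
      }
    }
  }
  if (!is.null(sc$row_rule) && !length(errors)) {
    rr <- sc$row_rule(df)
    if (!is.null(rr)) errors[[length(errors) + 1L]] <- rr
  }
  report <- if (length(errors)) do.call(rbind, errors) else
    data.frame(row = integer(), column = character(), message = character())
  if (nrow(report) && stop_on_error) {
    lines <- sprintf("  row %s, column %s: %s",
                     ifelse(is.na(report$row), "-", report$row),
                     report$column, report$message)
    stop(sprintf("validation of '%s' (%s schema) failed:\n%s",
                 file, schema, paste(utils::head(lines, 20), collapse = "\n")),
         call. = FALSE)
  }
  if (stop_on_error) invisible(df) else report
}

#' Read pipeline CSV tables with validation
#'
#' Thin readers over [utils::read.csv()] that validate against the
#' corresponding schema and fail with row-level messages.
#'
#' @param path CSV file path.
#' @return a validated `data.frame`.
#' @export
read_titration_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_table(df, "titration", file = path)
  df
}

#' @rdname read_titration_csv
#' @export
read_afm_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("dna_bound" %in% names(df)) df$dna_bound <- as.logical(df$dna_bound)
  validate_table(df, "afm", file = path)
  df
}

#' @rdname read_titration_csv
#' @export
read_plate_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_table(df, "plate", file = path)
  df
}

#' @rdname read_titration_csv
#' @export
read_growth_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_table(df, "growth", file = path)
  df
}

#' @rdname read_titration_csv
#' @param df table to write.
#' @param schema schema name used to validate before writing.
#' @export
write_pipeline_csv <- function(df, path, schema) {
  validate_table(df, schema, file = path)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# deterministic hash of a config object (no timestamps: identical config +
# seed must reproduce outputs bit-for-bit)
.tv_config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config), tmp)
  unname(tools::md5sum(tmp))
}

.tv_provenance <- function(config, seed) {
  # the output location is not part of the analysis identity
  config$out_dir <- NULL
  list(config_hash = .tv_config_hash(config), seed = seed,
       package = "titravol",
       version = as.character(utils::packageVersion("titravol")))
}

#' Run pipeline stages from a configuration
#'
#' Executes the requested stages in order, reading and writing the package's
#' CSV/JSON formats. Supported stages: `"simulate"` (with `kind` one of
#' `"bli"`, `"afm"`, `"growth"`, `"plate"`), `"fit-bli"`, `"afm"`,
#' `"cluster"`, `"enzyme"`, `"growth"`. Every JSON report carries a
#' provenance block (config hash, seed, package version); no timestamps, so
#' identical config and seed reproduce outputs bit-for-bit.
#'
#' @param config a named list, or a path to a YAML/JSON config file, with
#'   elements `stages` (character vector), `out_dir`, `seed`, and per-stage
#'   parameter lists (`simulate`, `fit_bli`, `afm`, `cluster`, `enzyme`,
#'   `growth`) holding input paths and parameters.
#' @return invisibly, a named list of the artifact paths written.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("yaml package required for YAML configs", call. = FALSE)
      }
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  stages <- config$stages %||% stop_field("stages", "must be given")
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- check_seed(config$seed %||% 1)
  prov <- .tv_provenance(config, seed)
  artifacts <- list()
  w_json <- function(x, path) {
    jsonlite::write_json(c(list(provenance = prov), x), path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    path
  }

  for (stage in stages) {
    if (stage == "simulate") {
      p <- config$simulate %||% list()
      kind <- p$kind %||% "bli"
      p$kind <- NULL
      p$seed <- p$seed %||% seed
      if (kind == "bli") {
        sim <- do.call(simulate_titration, p)
        f <- file.path(out_dir, "titration.csv")
        write_pipeline_csv(sim$data, f, "titration")
        g <- w_json(list(truth = sim$truth), file.path(out_dir, "titration_truth.json"))
      } else if (kind == "afm") {
        sim <- do.call(simulate_afm_peaks, p)
        f <- file.path(out_dir, "afm_peaks.csv")
        write_pipeline_csv(sim$peaks, f, "afm")
        g <- w_json(list(truth = sim$truth), file.path(out_dir, "afm_truth.json"))
      } else if (kind == "growth") {
        sim <- do.call(simulate_growth, p)
        f <- file.path(out_dir, "growth.csv")
        write_pipeline_csv(sim$data, f, "growth")
        g <- w_json(list(truth = sim$truth), file.path(out_dir, "growth_truth.json"))
      } else if (kind == "plate") {
        sim <- do.call(simulate_plate, p)
        f <- file.path(out_dir, "plate.csv")
        write_pipeline_csv(sim$data, f, "plate")
        g <- w_json(list(truth = sim$truth), file.path(out_dir, "plate_truth.json"))
      } else {
        stop_field("simulate$kind", "unknown kind")
      }
      artifacts[[paste0("simulate_", kind)]] <- c(f, g)
    } else if (stage == "fit-bli") {
      p <- config$fit_bli %||% list()
      data <- read_titration_csv(p$input %||% file.path(out_dir, "titration.csv"))
      args <- p[setdiff(names(p), "input")]
      fit <- do.call(fit_titration, c(list(data = data), args))
      rep_path <- w_json(list(
        kd = fit$kd, kd_se = fit$kd_se, model = fit$model, rss = fit$rss,
        converged = fit$converged, curves = fit$curves),
        file.path(out_dir, "bli_fit.json"))
      fc <- data.frame(curve_id = rep(fit$curves$curve_id,
                                      vapply(fit$input, function(cv) length(cv$conc), 1L)))
      fc$conc_M <- unlist(lapply(fit$input, `[[`, "conc"), use.names = FALSE)
      fc$signal <- fitted(fit)
      f2 <- file.path(out_dir, "bli_fitted.csv")
      write_pipeline_csv(fc, f2, "titration")
      artifacts[["fit_bli"]] <- c(rep_path, f2)
    } else if (stage == "afm") {
      p <- config$afm %||% list()
      peaks <- read_afm_csv(p$input %||% file.path(out_dir, "afm_peaks.csv"))
      masses <- afm_mass_table(peaks, specific_volume = p$specific_volume %||% 0.67)
      f <- file.path(out_dir, "afm_masses.csv")
      utils::write.csv(masses, f, row.names = FALSE)
      artifacts[["afm"]] <- f
    } else if (stage == "cluster") {
      p <- config$cluster %||% list()
      masses <- utils::read.csv(p$input %||% file.path(out_dir, "afm_masses.csv"))
      cl <- cluster1d(masses$mass_da, k = p$k %||% 3,
                      fixed_top_class_size = p$fixed_top_class_size)
      calls <- assign_stoichiometry(cl)
      per_obs <- data.frame(peak_id = masses$peak_id, mass_da = masses$mass_da,
                            class = cl$assignments,
                            label = calls$label[cl$assignments])
      f <- file.path(out_dir, "clusters.csv")
      utils::write.csv(per_obs, f, row.names = FALSE)
      g <- w_json(list(k = cl$k, centers = cl$centers, sizes = cl$sizes,
                       wcss = cl$tot_withinss, constraint = cl$constraint,
                       calls = calls), file.path(out_dir, "clusters.json"))
      artifacts[["cluster"]] <- c(f, g)
    } else if (stage == "enzyme") {
      p <- config$enzyme %||% list()
      plate <- read_plate_csv(p$input %||% file.path(out_dir, "plate.csv"))
      fc <- fold_change(plate, control = p$control %||% "buffer")
      tr <- concentration_trend(fc$substrate_mM, fc$fold, seed = seed)
      g <- w_json(list(fold_change = fc, trend = tr),
                  file.path(out_dir, "enzyme.json"))
      artifacts[["enzyme"]] <- g
    } else if (stage == "growth") {
      p <- config$growth %||% list()
      gdat <- read_growth_csv(p$input %||% file.path(out_dir, "growth.csv"))
      per_strain <- lapply(split(gdat, gdat$strain), function(d) {
        half_max_time(d$time_h, d$od600)
      })
      ref <- p$reference %||% names(per_strain)[1]
      met <- do.call(rbind, lapply(names(per_strain), function(s) {
        m <- per_strain[[s]]
        data.frame(strain = s, max_od = m$max_od, t_half_h = m$t_half,
                   delay_h = growth_delay(m, per_strain[[ref]]))
      }))
      g <- w_json(list(reference = ref, metrics = met),
                  file.path(out_dir, "growth_metrics.json"))
      artifacts[["growth"]] <- g
    } else {
      stop_field("stages", sprintf("unknown stage '%s'", stage))
    }
  }
  invisible(artifacts)
}
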