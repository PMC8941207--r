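# Configuration, result serialization, and the end-to-end pipeline
# (rates -> cycling -> flux fit -> normalization -> redox).

#' Read a flat key = value configuration file
#'
#' Lines of the form `key = value`; blank lines and `#` comments ignored.
#' Numeric-looking values are converted to numbers.
#'
#' @param path Config file path.
#' @return Named list of class `run_config`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2L) stop("bad config line: ", ln, call. = FALSE)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  structure(out, class = c("run_config", "list"))
}

# djb2-style rolling hash of the canonicalized config (provenance stamp).
.config_hash <- function(config) {
  keys <- sort(names(config))
  txt <- paste(keys, vapply(config[keys], function(x) paste(x, collapse = ","),
                            ""), sep = "=", collapse = ";")
  h <- 5381
  for (b in utf8ToInt(txt)) h <- (h * 33 + b) %% 4294967296
  paste0(sprintf("%04x", as.integer(h %/% 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

#' Serialize fit results to JSON and TSV
#'
#' Writes a JSON bundle (fluxes, exchange fluxes, SSR, DOF, chi-square
#' acceptance, seed, restart log, package version, config hash) and a
#' companion flux TSV.
#'
#' @param fit An `mfa_fit`.
#' @param path Output JSON path (`.tsv` written alongside).
#' @param config Optional config list stamped into the output.
#' @param extra Optional named list merged into the JSON.
#' @return Invisibly, the JSON path.
#' @export
write_fit_results <- function(fit, path, config = NULL, extra = NULL) {
  gof <- chi_square_gof(fit)
  out <- list(
    package_version = as.character(utils::packageVersion("betaflux")),
    seed = fit$seed,
    config_hash = if (!is.null(config)) .config_hash(config) else NA,
    net_fluxes = as.list(fit$net),
    exchange_fluxes = as.list(fit$exch),
    ssr = fit$ssr, dof = fit$dof,
    chi_square = list(lower = gof$lower, upper = gof$upper,
                      accepted = gof$accepted),
    restarts = fit$restarts)
  if (!is.null(extra)) out <- c(out, extra)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  tsv <- sub("\\.json$", ".tsv", path)
  if (tsv == path) tsv <- paste0(path, ".tsv")
  utils::write.table(
    data.frame(flux = c(names(fit$net), paste0(names(fit$exch), ".exch")),
               value = c(unname(fit$net), unname(fit$exch))),
    tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis pipeline from a configuration
#'
#' Chains: exchange-rate estimation from time courses (when supplied) ->
#' measurement loading -> joint two-tracer flux regression ->
#' normalization -> goodness-of-fit -> optional redox panel. Results are
#' written as JSON + TSV under `out_dir` with seed and config hash
#' stamped for provenance.
#'
#' Recognized config keys: `network`, `fragments`, `mid_file`,
#' `rate_file`, `time_course_file` (optional, replaces `rate_file`),
#' `pool_file` (optional), `out_dir`, `n_starts`, `seed`,
#' `normalize_to` (reaction id), `k_deg_gln`, `alpha`.
#'
#' @param config A `run_config` (or path to one).
#' @return Invisibly, a list with the `mfa_fit`, normalization table and
#'   optional panels.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  for (key in c("network", "fragments", "mid_file", "out_dir")) {
    if (is.null(config[[key]])) stop("config missing '", key, "'",
                                     call. = FALSE)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- .stage("network", read_network(config$network))
  fragments <- .stage("fragments", read_fragments(config$fragments))

  rates_df <- NULL
  if (!is.null(config$time_course_file)) {
    rates_df <- .stage("rates", {
      tc <- utils::read.delim(config$time_course_file, comment.char = "#")
      kd <- c(Gln.ext = if (is.null(config$k_deg_gln)) 0.0031
              else config$k_deg_gln)
      er <- estimate_exchange_rates(tc, k_deg = kd)
      data.frame(metabolite = er$rates$metabolite, value = er$rates$q,
                 se = pmax(er$rates$se, 1e-3))
    })
  }
  ms <- .stage("measurements", {
    if (!is.null(rates_df)) {
      tmp <- tempfile(fileext = ".tsv")
      utils::write.table(
        data.frame(metabolite = rates_df$metabolite, rate = rates_df$value,
                   se = rates_df$se),
        tmp, sep = "\t", row.names = FALSE, quote = FALSE)
      load_measurements(config$mid_file, tmp)
    } else {
      load_measurements(config$mid_file, config$rate_file)
    }
  })
  tracers <- list(glc = tracer_spec("Glc.ext", c(1, 2)),
                  gln = tracer_spec("Gln.ext", 1:5))
  tracers <- tracers[names(tracers) %in% unique(ms$mids$tracer)]
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  n_starts <- if (is.null(config$n_starts)) 25L else as.integer(config$n_starts)
  fit <- .stage("fit", fit_fluxes(model, fragments, ms, tracers,
                                  n_starts = n_starts, seed = seed))
  norm <- NULL
  if (!is.null(config$normalize_to)) {
    norm <- .stage("normalize", normalize_fluxes(fit, config$normalize_to))
    utils::write.table(norm, file.path(config$out_dir, "fluxes_relative.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  cyc <- NULL
  if (!is.null(config$cycling_file)) {
    cyc <- .stage("cycling", {
      tab <- utils::read.delim(config$cycling_file, comment.char = "#")
      mids <- as.matrix(tab[paste0("M", 0:7)])
      cr <- cycling_rates(cycling_experiment(
        tab$time_h, mids, tab$conc_mM, tab$cells,
        volume = tab$volume_ml[1]))
      jsonlite::write_json(
        cr[c("V_release", "V_net_uptake", "V_total_uptake",
             "cycling_percent")],
        file.path(config$out_dir, "cycling.json"), auto_unbox = TRUE,
        digits = NA, pretty = TRUE)
      cr
    })
  }
  redox <- NULL
  if (!is.null(config$pool_file)) {
    redox <- .stage("redox", {
      pp <- utils::read.delim(config$pool_file, comment.char = "#")
      agg <- stats::aggregate(value ~ metabolite + unit, pp, mean)
      panel <- redox_panel(agg)
      jsonlite::write_json(
        list(cNADH_NAD = panel$cNADH_NAD, cNADPH_NADP = panel$cNADPH_NADP,
             mNADPH_NADP = panel$mNADPH_NADP, constants = panel$constants),
        file.path(config$out_dir, "redox.json"), auto_unbox = TRUE,
        digits = NA, pretty = TRUE)
      panel
    })
  }
  write_fit_results(fit, file.path(config$out_dir, "fit.json"),
                    config = config)
  invisible(list(fit = fit, normalized = norm, cycling = cyc,
                 redox = redox, rates = rates_df))
}
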