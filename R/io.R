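#' Write simulation outputs to disk
#'
#' Writes the sampled time series as CSV (one column per state variable and
#' derived channel, units as documented in [cvr_state_names()] /
#' [cvr_derived_names()]), the hemodynamic summary as JSON, and a
#' run-metadata JSON (parameter hash, integrator settings) for
#' reproducibility.
#'
#' @param result A `cvr_result`.
#' @param summary A `cvr_summary` (or NULL to recompute over 15 cycles).
#' @param outdir Output directory (created if missing).
#' @param prefix File name prefix (default `"cvrsim"`).
#' @param thin Keep every `thin`-th time sample in the CSV (default 10).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_outputs <- function(result, summary = NULL, outdir, prefix = "cvrsim",
                          thin = 10) {
  stopifnot(inherits(result, "cvr_result"))
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  if (is.null(summary)) summary <- cvr_summarize(result)
  ts_path <- file.path(outdir, paste0(prefix, "_timeseries.csv"))
  sm_path <- file.path(outdir, paste0(prefix, "_summary.json"))
  meta_path <- file.path(outdir, paste0(prefix, "_meta.json"))
  ts <- result$timeseries
  keep <- seq(1, nrow(ts), by = max(1L, as.integer(thin)))
  ok <- tryCatch({
    utils::write.csv(as.data.frame(ts[keep, , drop = FALSE]), ts_path,
                     row.names = FALSE)
    jsonlite::write_json(unclass(summary), sm_path, auto_unbox = TRUE,
                         digits = NA)
    jsonlite::write_json(
      list(param_hash = config_hash(result$params),
           n_samples = nrow(ts), final_time = result$final_time,
           n_suction = result$n_suction, n_o2_clamp = result$n_o2_clamp),
      meta_path, auto_unbox = TRUE, digits = NA)
    TRUE
  }, error = function(e) {
    stop("failed writing outputs to '", outdir, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(c(timeseries = ts_path, summary = sm_path, metadata = meta_path))
}

#' Read back a summary written by [write_outputs()]
#' @param path Path to the summary JSON.
#' @return A `cvr_summary`.
#' @export
read_summary <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE),
            class = "cvr_summary")
}

#' Deterministic hash of a parameter set
#'
#' Content hash over the sorted parameter names and values (full double
#' precision), so the hash changes if and only if some parameter changes.
#'
#' @param params Named parameter list.
#' @return Character scalar.
#' @export
config_hash <- function(params) {
  o <- order(names(params))
  txt <- paste(names(params)[o],
               vapply(params[o], function(v) sprintf("%.17g", as.numeric(v)),
                      character(1)),
               sep = "=", collapse = ";")
  # FNV-1a, reported as two 16-bit blocks: no external digest dependency
  # 32-bit FNV-1a carried in doubles: R's bitwXor is limited to signed
  # integers, so the XOR and the modular product run on 16-bit halves
  h <- 2166136261
  for (ch in utf8ToInt(txt)) {
    h <- bitwXor(h %% 65536, ch %% 65536) +
      65536 * bitwXor(h %/% 65536, ch %/% 65536)
    lo <- (h %% 65536) * 16777619
    hi <- ((h %/% 65536) * 16777619) %% 65536
    h <- (lo + hi * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Command-line interface
#'
#' Thin POSIX-style front end over the package API, used by the
#' `inst/cli/cvrsim` script. Subcommands:
#' \describe{
#'   \item{run}{`--scenario hf|hf-vad [--vo2 X] [--rq X] [--vad-speed X]
#'     [--out DIR]` — run the packaged protocol (optionally overriding the
#'     exercise phase targets) and write outputs.}
#'   \item{fit-stiffness}{`--points FILE.csv` with columns `V,P` — fit the
#'     exponential diastolic stiffness and print `a`, `b` and exclusions.}
#'   \item{summarize}{`--result FILE.csv` — recompute a hemodynamic summary
#'     from a written time-series CSV.}
#' }
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit code (0 on success), invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: cvrsim <run|fit-stiffness|summarize> [options]",
    "  run            --scenario hf|hf-vad [--vo2 X] [--rq X]",
    "                 [--vad-speed RPM] [--out DIR] [--quiet]",
    "  fit-stiffness  --points FILE.csv   (columns V,P)",
    "  summarize      --result FILE.csv", sep = "\n")
  if (length(args) < 1) { message(usage); return(invisible(1L)) }
  cmd <- args[[1]]
  opts <- parse_cli_opts(args[-1])
  if (!is.null(opts$error)) { message(opts$error, "\n", usage); return(invisible(1L)) }
  o <- opts$opts
  quiet <- isTRUE(o$quiet)
  note <- function(...) if (!quiet) message(...)
  if (cmd == "run") {
    sc <- o[["scenario"]]
    if (is.null(sc) || !sc %in% c("hf", "hf-vad")) {
      message("run: --scenario must be hf or hf-vad\n", usage)
      return(invisible(1L))
    }
    cond <- if (sc == "hf-vad") "hf_vad" else "hf"
    config <- load_config(scenario_fixture(cond))
    n <- length(config$protocol)
    if (!is.null(o[["vo2"]])) config$protocol[[n]]$vo2 <- as.numeric(o[["vo2"]])
    if (!is.null(o[["rq"]])) config$protocol[[n]]$rq <- as.numeric(o[["rq"]])
    if (!is.null(o[["vad-speed"]])) {
      config$protocol[[n]]$omega <- as.numeric(o[["vad-speed"]])
    }
    note("running ", sc, " protocol (", n, " phases)...")
    pr <- run_protocol(config)
    outdir <- o[["out"]] %||% "."
    for (nm in names(pr$summaries)) {
      if (!quiet) { cat("== ", nm, " ==\n", sep = ""); print(pr$summaries[[nm]]) }
      write_outputs(pr$results[[nm]], pr$summaries[[nm]], outdir,
                    prefix = paste0(cond, "_", nm))
    }
    note("outputs written to ", normalizePath(outdir))
    return(invisible(0L))
  }
  if (cmd == "fit-stiffness") {
    if (is.null(o[["points"]])) { message("fit-stiffness: --points required"); return(invisible(1L)) }
    pts <- utils::read.csv(o[["points"]])
    fit <- fit_diastolic_stiffness(pts$V, pts$P)
    cat(sprintf("a = %.6g mmHg\nb = %.6g 1/cm^3\nexcluded: %s\n",
                fit$a, fit$b,
                if (length(fit$excluded)) paste(fit$excluded, collapse = ", ")
                else "none"))
    return(invisible(0L))
  }
  if (cmd == "summarize") {
    if (is.null(o[["result"]])) { message("summarize: --result required"); return(invisible(1L)) }
    ts <- as.matrix(utils::read.csv(o[["result"]], check.names = FALSE))
    res <- structure(list(timeseries = ts, params = list(),
                          n_suction = 0, n_o2_clamp = 0),
                     class = "cvr_result")
    print(cvr_summarize(res))
    return(invisible(0L))
  }
  message("unknown subcommand: ", cmd, "\n", usage)
  invisible(1L)
}

parse_cli_opts <- function(args) {
  o <- list()
  i <- 1
  flags <- c("quiet")
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) {
      return(list(error = paste("unexpected argument:", a)))
    }
    key <- substring(a, 3)
    if (key %in% flags) { o[[key]] <- TRUE; i <- i + 1; next }
    if (i == length(args)) return(list(error = paste("missing value for", a)))
    o[[key]] <- args[[i + 1]]
    i <- i + 2
  }
  list(opts = o)
}
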