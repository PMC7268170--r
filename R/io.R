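#' Load a run configuration
#'
#' Reads a YAML (or JSON, by file extension) configuration with up to five
#' blocks and fills everything else with the package defaults:
#' \describe{
#'   \item{`parameters`}{named overrides of any [nf_params()] field.}
#'   \item{`experiment`}{`ne` (vector, umol/L), `duration_h`, `l0`,
#'     `mutant`, `init_pools`.}
#'   \item{`flags`}{either `preset: "L0".."L7"` or explicit layer booleans.}
#'   \item{`solver`}{`rtol`, `atol`, `sample_interval_h`,
#'     `allocation_mode`.}
#'   \item{`output`}{`dir`, `plot`.}
#' }
#' Unknown keys anywhere are rejected with an error naming the key. An empty
#' file yields the full default configuration (published parameter values,
#' wild type, full model).
#'
#' @param path Path to a readable `.yaml`/`.yml`/`.json` file.
#' @return An object of class `"nf_config"`: a list with elements `model`
#'   (a ready [foraging_model()]), `experiment` (an [nf_experiment()]) and
#'   `output`, plus the raw blocks as attributes.
#' @seealso [write_config()] for the round-trip counterpart.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(raw)) raw <- list()
  config_from_list(raw)
}

config_from_list <- function(raw) {
  known_blocks <- c("parameters", "experiment", "flags", "solver", "output")
  unknown <- setdiff(names(raw), known_blocks)
  if (length(unknown)) {
    stop("unknown config block: '", unknown[1], "'", call. = FALSE)
  }
  take <- function(block, allowed) {
    b <- raw[[block]]
    if (is.null(b)) return(list())
    bad <- setdiff(names(b), allowed)
    if (length(bad)) {
      stop("unknown key '", bad[1], "' in config block '", block, "'",
           call. = FALSE)
    }
    b
  }
  par_over <- take("parameters", names(formals(nf_params)))
  params <- do.call(nf_params, par_over)

  fb <- take("flags", c("preset", names(formals(nf_flags))))
  flags <- if (!is.null(fb$preset)) {
    if (length(fb) > 1L) {
      stop("config block 'flags' must give either a preset or explicit ",
           "booleans, not both", call. = FALSE)
    }
    nf_ladder(fb$preset)
  } else if (length(fb)) {
    full <- as.list(nf_ladder("L7"))
    full[names(fb)] <- fb
    do.call(nf_flags, full)
  } else {
    nf_ladder("L7")
  }

  ex <- take("experiment", c("ne", "duration_h", "l0", "mutant",
                             "init_pools"))
  mutant <- if (is.null(ex$mutant)) "WT" else ex$mutant
  experiment <- nf_experiment(
    ne = if (is.null(ex$ne)) c(25, 5000) else unlist(ex$ne),
    duration_h = if (is.null(ex$duration_h)) 144 else ex$duration_h,
    l0 = if (is.null(ex$l0)) 20 else unlist(ex$l0),
    init_pools = if (is.null(ex$init_pools)) "zero" else ex$init_pools)

  sv <- take("solver", c("rtol", "atol", "sample_interval_h",
                         "allocation_mode"))
  model <- foraging_model(
    params = params, flags = flags, mutant = mutant,
    allocation_mode = if (is.null(sv$allocation_mode)) "literal"
                      else sv$allocation_mode,
    rtol = if (is.null(sv$rtol)) 1e-8 else sv$rtol,
    atol = if (is.null(sv$atol)) 1e-10 else sv$atol,
    sample_interval_h = if (is.null(sv$sample_interval_h)) 1
                        else sv$sample_interval_h)

  out <- take("output", c("dir", "plot"))
  if (is.null(out$dir)) out$dir <- "."
  if (is.null(out$plot)) out$plot <- FALSE

  structure(list(model = model, experiment = experiment, output = out),
            raw = raw, class = "nf_config")
}

#' Write a run configuration
#'
#' Serialises an `nf_config` (or the raw block list it was built from) to
#' YAML such that [load_config()] reproduces it.
#'
#' @param config An `nf_config` object or a plain named list of blocks.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  raw <- if (inherits(config, "nf_config")) attr(config, "raw") else config
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' @export
print.nf_config <- function(x, ...) {
  cat("Run configuration\n")
  print(x$model)
  print(x$experiment)
  cat("Output dir:", x$output$dir, "\n")
  invisible(x)
}

#' Write a mutant split-root summary table as TSV
#'
#' Writes the four-column table `plant`, `length_low_N_mm`,
#' `length_high_N_mm`, `difference_mm` (integer-rounded) as a tab-separated,
#' UTF-8, Unix-newline file. Output is byte-identical across repeated runs of
#' the same configuration. An empty summary produces a header-only file.
#'
#' @param summary A data frame as returned by [run_mutant_table()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(summary, path) {
  cols <- c("plant", "length_low_N_mm", "length_high_N_mm", "difference_mm")
  if (!all(cols %in% names(summary))) {
    stop("'summary' must have columns ", paste(cols, collapse = ", "),
         call. = FALSE)
  }
  lines <- paste(cols, collapse = "\t")
  if (nrow(summary)) {
    body <- apply(summary[, cols], 1, function(row) {
      paste(c(row[1], as.integer(round(as.numeric(row[2:4])))),
            collapse = "\t")
    })
    lines <- c(lines, body)
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Write a trajectory as tidy TSV
#'
#' One row per time point and compartment with columns `time_h`,
#' `compartment`, `L_mm`, `Ni_umol`, `Ni_conc`, `r_factor`, `g_carbon` and
#' the systemic concentrations `Ns_conc`, `CEPs_conc`, `CKs_conc` repeated
#' per row.
#'
#' @param trajectory An `nf_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  stopifnot(inherits(trajectory, "nf_trajectory"))
  df <- as.data.frame(trajectory)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}
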