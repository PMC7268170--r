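#' Construct a root nitrate foraging model
#'
#' The central model object: a parameter set, a choice of active regulatory
#' layers, an optional in-silico mutant and the numerical settings of the
#' integrator. Experiments (single-root dose-response, split-root, nitrate
#' patch) are simulated from this object with [simulate()] or the
#' `run_*()` helpers.
#'
#' @param params An [nf_params()] parameter set (mutant overrides are applied
#'   on top of it).
#' @param flags An [nf_flags()] / [nf_ladder()] layer selection. Default is
#'   the full model (`"L7"`).
#' @param mutant One of `"WT"`, `"nrt1.1"`, `"cep"`, `"ck"`; see
#'   [apply_mutant()].
#' @param allocation_mode Growth equation variant, see [model_rhs()].
#' @param rtol,atol Relative and absolute integrator tolerances.
#' @param sample_interval_h Output sampling interval in hours.
#' @return An object of class `"foraging_model"` with methods `print`,
#'   `summary`, `coef`, `simulate` and `plot` (via the trajectory it
#'   produces).
#' @examples
#' m <- foraging_model(flags = nf_ladder("L1"))
#' coef(m)[["conv"]]
#' tr <- simulate(m, experiment = nf_experiment(ne = 1000, duration_h = 48))
#' final_lengths(tr)
#' @export
foraging_model <- function(params = nf_params(),
                           flags = nf_ladder("L7"),
                           mutant = c("WT", "nrt1.1", "cep", "ck"),
                           allocation_mode = c("literal", "replace_1_over_n"),
                           rtol = 1e-8, atol = 1e-10,
                           sample_interval_h = 1) {
  stopifnot(inherits(params, "nf_params"), inherits(flags, "nf_flags"))
  mutant <- match.arg(mutant)
  allocation_mode <- match.arg(allocation_mode)
  stopifnot(rtol > 0, atol > 0, sample_interval_h > 0)
  structure(
    list(params = apply_mutant(params, mutant),
         flags = flags,
         mutant = mutant,
         allocation_mode = allocation_mode,
         rtol = rtol, atol = atol,
         sample_interval_h = sample_interval_h),
    class = "foraging_model")
}

#' @export
print.foraging_model <- function(x, ...) {
  cat("Root nitrate foraging model\n")
  preset <- attr(x$flags, "preset")
  on <- names(x$flags)[unlist(x$flags)]
  cat("  layers: ",
      if (length(on)) paste(on, collapse = ", ") else "none (r = 1)",
      if (!is.null(preset)) paste0("  [preset ", preset, "]"), "\n", sep = "")
  cat("  mutant: ", x$mutant, "\n", sep = "")
  cat("  allocation: ", x$allocation_mode,
      "; solver rtol ", format(x$rtol), ", atol ", format(x$atol),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.foraging_model <- function(object, ...) {
  print(object)
  cat("\nParameters:\n")
  print(object$params)
  invisible(object)
}

#' @export
coef.foraging_model <- function(object, ...) {
  unlist(object$params[setdiff(names(object$params), "f_local_const")])
}

#' Experiment specification
#'
#' Describes one in-silico growth experiment: how many root compartments, the
#' external nitrate concentration each experiences, how long to grow, the
#' initial compartment lengths, and how the internal pools are initialised at
#' treatment onset.
#'
#' @param ne Vector of external nitrate concentrations, one per compartment
#'   (umol/L). Its length sets the compartment count `n`.
#' @param duration_h Simulated duration in hours (>= 0).
#' @param l0 Initial compartment lengths (mm), recycled to `n`.
#' @param init_pools `"zero"` starts every nitrate/CEP/CK pool empty;
#'   `"steady_state"` pre-equilibrates the pools at the initial lengths using
#'   the closed-form fixed points ([pool_steady_state()]).
#' @return An object of class `"nf_experiment"`.
#' @examples
#' nf_experiment(ne = c(25, 5000), duration_h = 144)
#' @export
nf_experiment <- function(ne, duration_h = 144, l0 = 20,
                          init_pools = c("zero", "steady_state")) {
  init_pools <- match.arg(init_pools)
  if (length(ne) < 1L || !is.numeric(ne) || anyNA(ne) || any(ne < 0)) {
    stop("'ne' must be a non-empty vector of non-negative concentrations",
         call. = FALSE)
  }
  if (!is.numeric(duration_h) || length(duration_h) != 1L || duration_h < 0) {
    stop("'duration_h' must be a single non-negative number", call. = FALSE)
  }
  l0 <- rep_len(as.numeric(l0), length(ne))
  if (any(l0 <= 0)) stop("'l0' entries must be positive", call. = FALSE)
  structure(list(n = length(ne), ne = as.numeric(ne),
                 duration_h = as.numeric(duration_h), l0 = l0,
                 init_pools = init_pools),
            class = "nf_experiment")
}

#' @export
print.nf_experiment <- function(x, ...) {
  cat("Experiment: n = ", x$n, ", duration ", x$duration_h, " h, pools ",
      x$init_pools, "\n", sep = "")
  cat("  Ne (umol/L):", paste(format(x$ne), collapse = " "), "\n")
  cat("  L0 (mm):    ", paste(format(x$l0), collapse = " "), "\n")
  invisible(x)
}
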