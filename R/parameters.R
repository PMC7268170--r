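#' Model parameters for the root nitrate foraging model
#'
#' Constructs the full parameter set of the compartmental root growth model:
#' nitrate uptake and turnover, the carbon conversion factor, and the
#' half-saturation constants and amplitudes of every growth-regulatory layer
#' (local nitrate stimulation, CEP demand signalling, cytokinin supply
#' signalling, and the systemic survival, foraging and repression responses).
#' Defaults are the published reference values; any subset can be overridden
#' by name.
#'
#' Units follow the model's per-unit-length convention: root length is in mm,
#' pool amounts in umol, so internal concentrations are umol/mm while external
#' nitrate `Ne` is a bath concentration in umol/L.
#'
#' @param up1 Maximum uptake rate of the high-affinity nitrate transporters
#'   (umol mm^-1 h^-1).
#' @param K_up External nitrate concentration at which high-affinity uptake is
#'   half-maximal (umol/L). The source material quotes both 50 (text) and 75
#'   (parameter table); the table value 75 is the default and 50 is one
#'   override away.
#' @param up2 Non-saturating low-affinity uptake rate (L mm^-1 h^-1).
#' @param T_up Transport rate from local to systemic nitrate pool (h^-1).
#' @param u_m Rate of systemic nitrate loss to tissue maintenance
#'   (umol mm^-1 h^-1).
#' @param e Rate of systemic nitrate loss to exudation (h^-1).
#' @param conv Conversion factor from carbon supply to root length growth
#'   (dimensionless); calibrated from the analytic growth solution, see
#'   [solve_conv()].
#' @param a_local Local-nitrate dependent fraction of the local stimulation
#'   factor (dimensionless, in `[0, 1]`).
#' @param K_local External nitrate level of half-maximal local stimulation
#'   (umol/L).
#' @param p_CEP Maximum CEP production rate (umol mm^-1 h^-1).
#' @param K_CEP External nitrate level at which CEP production is half-maximal
#'   (umol/L).
#' @param T_CEP Local-to-systemic CEP transport rate (h^-1).
#' @param d_CEP Systemic CEP degradation rate (h^-1).
#' @param a_CEP Maximum CEP-induced growth rate increase (dimensionless).
#' @param K_NRT21_CEP Systemic CEP concentration of half-maximal growth
#'   promotion (umol/mm).
#' @param K_CEP_NE Local external nitrate level of half-maximal CEP-mediated
#'   growth promotion (umol/L).
#' @param p_CK Maximum cytokinin production rate (umol mm^-1 h^-1).
#' @param K_CK External nitrate level at which CK production is half-maximal
#'   (umol/L).
#' @param T_CK Local-to-systemic CK transport rate (h^-1).
#' @param d_CK Systemic CK degradation rate (h^-1).
#' @param a_CK CK-independent fraction of CEP signalling efficacy
#'   (dimensionless, in `[0, 1]`).
#' @param K_CEP_CK Systemic CK concentration at which the CK-dependent
#'   fraction of CEP signalling is half-maximal (umol/mm).
#' @param a_basic Systemic-nitrate independent floor of the survival response
#'   (dimensionless; printed with a rate unit in the source table, but it
#'   enters the survival factor as a fraction).
#' @param K_basic Systemic nitrate concentration of half-maximal survival
#'   response (umol/mm).
#' @param a_systfor Amplitude of the systemic foraging boost (dimensionless).
#' @param K_systfor Systemic nitrate concentration at which the foraging boost
#'   is half-maximal (umol/mm).
#' @param K_systrepr Systemic nitrate concentration of half-maximal systemic
#'   repression (umol/mm).
#' @param f_local_const Optional constant replacing the local stimulation
#'   factor, used to encode the nrt1.1 mutant (`NA` = use the nitrate
#'   dependent factor).
#'
#' @return A named list of class `"nf_params"`.
#' @seealso [nf_flags()], [apply_mutant()], [foraging_model()]
#' @examples
#' p <- nf_params()
#' p$K_up
#' nf_params(K_up = 50)$K_up
#' @export
nf_params <- function(up1 = 0.6,
                      K_up = 75,
                      up2 = 0.000006,
                      T_up = 3.8,
                      u_m = 0.1,
                      e = 1.5,
                      conv = 0.01,
                      a_local = 0.35,
                      K_local = 200,
                      p_CEP = 0.1,
                      K_CEP = 250,
                      T_CEP = 0.1,
                      d_CEP = 0.001,
                      a_CEP = 0.5,
                      K_NRT21_CEP = 1,
                      K_CEP_NE = 750,
                      p_CK = 0.1,
                      K_CK = 750,
                      T_CK = 0.1,
                      d_CK = 0.001,
                      a_CK = 0.1,
                      K_CEP_CK = 2,
                      a_basic = 0.5,
                      K_basic = 0.04,
                      a_systfor = 1,
                      K_systfor = 0.12,
                      K_systrepr = 0.4,
                      f_local_const = NA_real_) {
  p <- list(
    up1 = up1, K_up = K_up, up2 = up2, T_up = T_up, u_m = u_m, e = e,
    conv = conv, a_local = a_local, K_local = K_local, p_CEP = p_CEP,
    K_CEP = K_CEP, T_CEP = T_CEP, d_CEP = d_CEP, a_CEP = a_CEP,
    K_NRT21_CEP = K_NRT21_CEP, K_CEP_NE = K_CEP_NE, p_CK = p_CK,
    K_CK = K_CK, T_CK = T_CK, d_CK = d_CK, a_CK = a_CK,
    K_CEP_CK = K_CEP_CK, a_basic = a_basic, K_basic = K_basic,
    a_systfor = a_systfor, K_systfor = K_systfor, K_systrepr = K_systrepr,
    f_local_const = f_local_const
  )
  validate_nf_params(p)
  structure(p, class = "nf_params")
}

validate_nf_params <- function(p) {
  num <- setdiff(names(p), "f_local_const")
  for (nm in num) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("parameter '", nm, "' must be a single finite number", call. = FALSE)
    }
    if (v < 0) stop("parameter '", nm, "' must be non-negative", call. = FALSE)
  }
  for (nm in c("a_local", "a_CEP", "a_CK", "a_basic")) {
    if (p[[nm]] > 1) {
      stop("parameter '", nm, "' must lie in [0, 1]", call. = FALSE)
    }
  }
  flc <- p$f_local_const
  if (!(length(flc) == 1L && (is.na(flc) ||
        (is.numeric(flc) && flc >= 0 && flc <= 1)))) {
    stop("'f_local_const' must be NA or a number in [0, 1]", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.nf_params <- function(x, ...) {
  cat("Root nitrate foraging model parameters\n")
  v <- unlist(x[setdiff(names(x), "f_local_const")])
  print(v, ...)
  if (!is.na(x$f_local_const)) {
    cat("f_local fixed at constant", x$f_local_const, "(mutant override)\n")
  }
  invisible(x)
}

#' Regulatory layer flags
#'
#' Selects which growth-regulatory layers of the model are active. The model
#' was built as an incremental ladder of variants, each adding one layer on
#' top of the previous ones; [nf_ladder()] returns the presets of that ladder.
#'
#' @param basic Survival response: saturating dependence of growth on systemic
#'   nitrate.
#' @param local Local stimulation: saturating dependence on the compartment's
#'   external nitrate.
#' @param cep CEP demand signalling: growth promotion by systemic CEP, gated
#'   by local nitrate presence.
#' @param systrepr Systemic repression at very high systemic nitrate.
#' @param systfor Systemic foraging boost at moderately low systemic nitrate.
#' @param carbon Sink-strength carbon allocation between compartments.
#' @param ck_gating Cytokinin supply signal gating CEP signalling efficacy;
#'   requires `cep` to be active.
#'
#' @return A named logical list of class `"nf_flags"`.
#' @examples
#' nf_flags(basic = TRUE, local = TRUE)
#' nf_ladder("L3")
#' @export
nf_flags <- function(basic = FALSE, local = FALSE, cep = FALSE,
                     systrepr = FALSE, systfor = FALSE, carbon = FALSE,
                     ck_gating = FALSE) {
  fl <- list(basic = basic, local = local, cep = cep, systrepr = systrepr,
             systfor = systfor, carbon = carbon, ck_gating = ck_gating)
  for (nm in names(fl)) {
    if (!(is.logical(fl[[nm]]) && length(fl[[nm]]) == 1L && !is.na(fl[[nm]]))) {
      stop("flag '", nm, "' must be TRUE or FALSE", call. = FALSE)
    }
  }
  if (fl$ck_gating && !fl$cep) {
    stop("'ck_gating' requires the 'cep' layer: CK gating modulates CEP ",
         "signalling and does not stand alone", call. = FALSE)
  }
  structure(fl, class = "nf_flags")
}

#' @rdname nf_flags
#' @param preset Ladder preset name: `"L0"` (no regulation, constant growth
#'   rate) through `"L7"` (full model with CK gating). Each step adds one
#'   layer in the order basic, local, cep, systrepr, systfor, carbon,
#'   ck_gating. `"full"` is an alias for `"L7"`.
#' @export
nf_ladder <- function(preset = "L7") {
  steps <- c("basic", "local", "cep", "systrepr", "systfor", "carbon",
             "ck_gating")
  if (identical(preset, "full")) preset <- "L7"
  if (!(is.character(preset) && length(preset) == 1L &&
        grepl("^L[0-7]$", preset))) {
    stop("unknown ladder preset: ", deparse(preset),
         " (expected \"L0\"..\"L7\" or \"full\")", call. = FALSE)
  }
  k <- as.integer(sub("L", "", preset))
  args <- as.list(seq_along(steps) <= k)
  names(args) <- steps
  fl <- do.call(nf_flags, args)
  attr(fl, "preset") <- preset
  fl
}

#' @export
print.nf_flags <- function(x, ...) {
  on <- names(x)[unlist(x)]
  cat("Active regulatory layers:",
      if (length(on)) paste(on, collapse = ", ") else "none (constant r = 1)",
      "\n")
  invisible(x)
}

#' Apply an in-silico mutant to a parameter set
#'
#' Mutants are encoded purely as parameter overrides:
#' \describe{
#'   \item{`"nrt1.1"`}{the local stimulation factor is replaced by the
#'     constant 0.6 (NRT1.1 is the local nitrate transceptor) and high-affinity
#'     uptake `up1` is reduced by 20\% (NRT1.1 also transports nitrate).}
#'   \item{`"cep"`}{CEP production `p_CEP` is set to zero.}
#'   \item{`"ck"`}{cytokinin production `p_CK` is set to zero.}
#'   \item{`"WT"`}{no change.}
#' }
#'
#' @param params An [nf_params()] object.
#' @param mutant One of `"WT"`, `"nrt1.1"`, `"cep"`, `"ck"`.
#' @return The modified `nf_params` object.
#' @examples
#' apply_mutant(nf_params(), "nrt1.1")$up1
#' @export
apply_mutant <- function(params, mutant = c("WT", "nrt1.1", "cep", "ck")) {
  stopifnot(inherits(params, "nf_params"))
  mutant <- match.arg(mutant)
  if (mutant == "nrt1.1") {
    params$up1 <- params$up1 * 0.8
    params$f_local_const <- 0.6
  } else if (mutant == "cep") {
    params$p_CEP <- 0
  } else if (mutant == "ck") {
    params$p_CK <- 0
  }
  validate_nf_params(params)
  params
}
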