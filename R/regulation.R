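#' Growth-regulatory factor library
#'
#' The effective growth rate of a root compartment is the product of a set of
#' dimensionless Hill-type factors, one per active regulatory layer. Each
#' function below evaluates one factor from the relevant concentration.
#' Systemic concentrations are amounts divided by total root length (umol/mm);
#' external nitrate `Ne` is a bath concentration (umol/L). All functions are
#' vectorised and reject negative inputs.
#'
#' \describe{
#'   \item{`f_basic`}{survival response: increasing from the floor `a_basic`
#'     towards 1 with systemic nitrate; second-order Hill with midpoint
#'     `K_basic`.}
#'   \item{`f_local`}{local stimulation: increasing from `1 - a_local` towards
#'     1 with the compartment's external nitrate (midpoint `K_local`). If
#'     `params$f_local_const` is set (nrt1.1 mutant) that constant is
#'     returned.}
#'   \item{`g_ne`}{local nitrate presence gate on CEP-mediated promotion:
#'     plain second-order Hill in `Ne` with midpoint `K_CEP_NE`.}
#'   \item{`g_ck`}{cytokinin supply gate on CEP signalling: increasing from
#'     `a_CK` towards 1 with systemic CK (midpoint `K_CEP_CK`).}
#'   \item{`f_cep`}{CEP demand promotion: `1 + a_CEP * Hill([CEPs]) * g_ne`,
#'     additionally multiplied by `g_ck` when `ck_gating` is `TRUE`; range
#'     `[1, 1 + a_CEP]`.}
#'   \item{`f_systrepr`}{systemic repression: fourth-order decreasing Hill in
#'     systemic nitrate with midpoint `K_systrepr`.}
#'   \item{`f_systfor`}{systemic foraging: decreasing from `1 + a_systfor`
#'     towards 1 with systemic nitrate; fourth-order with midpoint
#'     `K_systfor`.}
#' }
#'
#' @param Ns_conc Systemic nitrate concentration (umol/mm).
#' @param Ne External nitrate concentration (umol/L).
#' @param CEPs_conc Systemic CEP concentration (umol/mm).
#' @param CKs_conc Systemic cytokinin concentration (umol/mm).
#' @param params An [nf_params()] object.
#' @param ck_gating Should the cytokinin gate multiply the CEP factor?
#' @return A numeric vector of dimensionless factors.
#' @examples
#' p <- nf_params()
#' f_basic(0.04, p)        # midpoint: 0.75
#' f_local(0, p)           # baseline growth with no nitrate: 0.65
#' f_systfor(0, p)         # maximal foraging boost: 2
#' @name regulation
NULL

hill2 <- function(x, K) x^2 / (x^2 + K^2)
hill4 <- function(x, K) x^4 / (x^4 + K^4)

check_nonneg <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0)) {
    stop("'", what, "' must be non-negative", call. = FALSE)
  }
  invisible(x)
}

#' @rdname regulation
#' @export
f_basic <- function(Ns_conc, params) {
  check_nonneg(Ns_conc, "Ns_conc")
  params$a_basic + (1 - params$a_basic) * hill2(Ns_conc, params$K_basic)
}

#' @rdname regulation
#' @export
f_local <- function(Ne, params) {
  check_nonneg(Ne, "Ne")
  if (!is.na(params$f_local_const)) {
    return(rep_len(params$f_local_const, length(Ne)))
  }
  params$a_local * hill2(Ne, params$K_local) + (1 - params$a_local)
}

#' @rdname regulation
#' @export
g_ne <- function(Ne, params) {
  check_nonneg(Ne, "Ne")
  hill2(Ne, params$K_CEP_NE)
}

#' @rdname regulation
#' @export
g_ck <- function(CKs_conc, params) {
  check_nonneg(CKs_conc, "CKs_conc")
  params$a_CK + (1 - params$a_CK) * hill2(CKs_conc, params$K_CEP_CK)
}

#' @rdname regulation
#' @export
f_cep <- function(CEPs_conc, Ne, CKs_conc = 0, params, ck_gating = FALSE) {
  check_nonneg(CEPs_conc, "CEPs_conc")
  check_nonneg(Ne, "Ne")
  boost <- params$a_CEP * hill2(CEPs_conc, params$K_NRT21_CEP) * g_ne(Ne, params)
  if (ck_gating) boost <- boost * g_ck(CKs_conc, params)
  1 + boost
}

#' @rdname regulation
#' @export
f_systrepr <- function(Ns_conc, params) {
  check_nonneg(Ns_conc, "Ns_conc")
  params$K_systrepr^4 / (params$K_systrepr^4 + Ns_conc^4)
}

#' @rdname regulation
#' @export
f_systfor <- function(Ns_conc, params) {
  check_nonneg(Ns_conc, "Ns_conc")
  1 + params$a_systfor * (1 - hill4(Ns_conc, params$K_systfor))
}

#' Per-compartment effective growth rate factors
#'
#' Multiplies the factors of all active regulatory layers: survival
#' ([f_basic()]), local stimulation ([f_local()]), CEP demand promotion
#' ([f_cep()], CK-gated when `ck_gating` is on), systemic repression
#' ([f_systrepr()]) and systemic foraging ([f_systfor()]). Inactive layers
#' contribute 1, so with all layers off the growth rate factor is exactly 1
#' (the basic exponential-growth model).
#'
#' @param state An [nf_state()] object.
#' @param Ne Vector of external nitrate concentrations (umol/L), one per
#'   compartment.
#' @param params An [nf_params()] object.
#' @param flags An [nf_flags()] object.
#' @return Numeric vector `r` of length `n` (one factor per compartment).
#' @examples
#' st <- nf_state(L = c(20, 20))
#' growth_rate(st, Ne = c(25, 5000), nf_params(), nf_ladder("L1"))
#' @export
growth_rate <- function(state, Ne, params, flags) {
  stopifnot(inherits(state, "nf_state"), inherits(flags, "nf_flags"))
  n <- length(state$L)
  check_nonneg(Ne, "Ne")
  if (length(Ne) != n) stop("'Ne' must have one entry per compartment")
  sL <- sum(state$L)
  Ns_conc <- max(state$Ns, 0) / sL
  CEPs_conc <- max(state$CEPs, 0) / sL
  CKs_conc <- max(state$CKs, 0) / sL
  r <- rep(1, n)
  if (flags$basic) r <- r * f_basic(Ns_conc, params)
  if (flags$local) r <- r * f_local(Ne, params)
  if (flags$cep) {
    r <- r * f_cep(CEPs_conc, Ne, CKs_conc, params,
                   ck_gating = flags$ck_gating)
  }
  if (flags$systrepr) r <- r * f_systrepr(Ns_conc, params)
  if (flags$systfor) r <- r * f_systfor(Ns_conc, params)
  r
}

#' Sink-strength carbon allocation fractions
#'
#' With the carbon layer off every compartment receives the equal share
#' `1/n`. With it on, compartment `x` receives `r_x * L_x / sum(r * L)`:
#' allocation proportional to relative growth rate weighted by relative size
#' (sink strength). If every `r_x * L_x` is zero no growth occurs anywhere and
#' the uniform share is returned.
#'
#' @param r Vector of growth rate factors (dimensionless, >= 0).
#' @param L Vector of compartment lengths (mm, > 0).
#' @param carbon Is the carbon allocation layer active?
#' @return Numeric vector of allocation fractions summing to 1.
#' @examples
#' carbon_fractions(r = c(2, 1), L = c(10, 10))        # 2/3, 1/3
#' carbon_fractions(r = c(2, 1), L = c(10, 10), carbon = FALSE)
#' @export
carbon_fractions <- function(r, L, carbon = TRUE) {
  check_nonneg(r, "r")
  if (!is.numeric(L) || any(L <= 0)) stop("'L' entries must be positive")
  if (length(r) != length(L)) stop("'r' and 'L' must have equal length")
  n <- length(L)
  if (!carbon) return(rep(1 / n, n))
  w <- r * L
  s <- sum(w)
  if (s > 0) w / s else rep(1 / n, n)
}

#' Nitrate uptake, CEP production and CK production rates
#'
#' Per-compartment source terms of the pool equations, each proportional to
#' compartment length `L`:
#' \describe{
#'   \item{`uptake_rate`}{saturating high-affinity uptake
#'     (`up1 * Ne / (Ne + K_up)`) plus non-saturating low-affinity uptake
#'     (`up2 * Ne`), times `L` (umol/h).}
#'   \item{`cep_production`}{CEP production decreasing with local nitrate:
#'     second-order repressive Hill with midpoint `K_CEP`, maximal `p_CEP * L`
#'     at `Ne = 0`.}
#'   \item{`ck_production`}{cytokinin production increasing with local
#'     nitrate: second-order Hill with midpoint `K_CK`.}
#' }
#'
#' @param Ne External nitrate concentration (umol/L).
#' @param L Compartment length (mm).
#' @param params An [nf_params()] object.
#' @return Rate in umol/h (vectorised over `Ne` and `L`).
#' @examples
#' uptake_rate(Ne = 75, L = 1, nf_params())   # half-saturation of up1
#' cep_production(Ne = 0, L = 1, nf_params()) # maximal: p_CEP
#' @name pool_sources
NULL

#' @rdname pool_sources
#' @export
uptake_rate <- function(Ne, L, params) {
  check_nonneg(Ne, "Ne")
  check_nonneg(L, "L")
  (params$up1 * Ne / (Ne + params$K_up) + params$up2 * Ne) * L
}

#' @rdname pool_sources
#' @export
cep_production <- function(Ne, L, params) {
  check_nonneg(Ne, "Ne")
  check_nonneg(L, "L")
  params$p_CEP * (1 - hill2(Ne, params$K_CEP)) * L
}

#' @rdname pool_sources
#' @export
ck_production <- function(Ne, L, params) {
  check_nonneg(Ne, "Ne")
  check_nonneg(L, "L")
  params$p_CK * hill2(Ne, params$K_CK) * L
}

#' Model state container
#'
#' Holds the instantaneous state of the model: per-compartment root lengths
#' and local pools (internal nitrate, CEP, CK) plus the three systemic pools.
#' Lengths are in mm, all pool entries are amounts in umol; concentrations are
#' obtained by dividing by (total) length.
#'
#' @param L Vector of compartment lengths (mm, > 0).
#' @param Ni Vector of local internal nitrate amounts (umol).
#' @param CEP Vector of local CEP amounts (umol).
#' @param CK Vector of local CK amounts (umol).
#' @param Ns Systemic nitrate amount (umol).
#' @param CEPs Systemic CEP amount (umol).
#' @param CKs Systemic CK amount (umol).
#' @return A list of class `"nf_state"`.
#' @examples
#' nf_state(L = c(20, 20))
#' @export
nf_state <- function(L, Ni = 0, CEP = 0, CK = 0, Ns = 0, CEPs = 0, CKs = 0) {
  n <- length(L)
  if (n < 1L || !is.numeric(L) || any(L <= 0)) {
    stop("'L' must be a vector of positive lengths", call. = FALSE)
  }
  st <- list(L = as.numeric(L),
             Ni = rep_len(as.numeric(Ni), n),
             CEP = rep_len(as.numeric(CEP), n),
             CK = rep_len(as.numeric(CK), n),
             Ns = as.numeric(Ns), CEPs = as.numeric(CEPs),
             CKs = as.numeric(CKs))
  for (nm in c("Ni", "CEP", "CK", "Ns", "CEPs", "CKs")) {
    check_nonneg(st[[nm]], nm)
  }
  structure(st, class = "nf_state")
}

#' @export
print.nf_state <- function(x, ...) {
  cat("Model state (", length(x$L), " compartment",
      if (length(x$L) > 1) "s", ")\n", sep = "")
  cat("  L (mm):  ", paste(signif(x$L, 5), collapse = " "), "\n")
  cat("  Ni:      ", paste(signif(x$Ni, 5), collapse = " "), "\n")
  cat("  Ns/CEPs/CKs:", signif(x$Ns, 5), signif(x$CEPs, 5),
      signif(x$CKs, 5), "\n")
  invisible(x)
}

#' Right-hand side of the model ODE system
#'
#' Assembles the time derivatives of every state component:
#' \itemize{
#'   \item `dL_x/dt = g_x * conv * r_x * sum(L)` where `g` are the
#'     [carbon_fractions()] (equal shares `1/n` with the carbon layer off,
#'     recovering the basic growth equation);
#'   \item `dNi_x/dt = uptake_rate - T_up * Ni_x`;
#'   \item `dNs/dt = T_up * sum(Ni) - u_m * sum(L) - e * Ns`, with the
#'     maintenance sink capped by the influx whenever `Ns` has reached zero so
#'     the zeroth-order loss cannot drive the pool negative;
#'   \item CEP and CK pools: production minus first-order transport locally,
#'     transport minus degradation systemically. Pools of inactive layers keep
#'     zero derivatives.
#' }
#'
#' @param state An [nf_state()] object.
#' @param Ne Vector of external nitrate concentrations (umol/L).
#' @param params An [nf_params()] object.
#' @param flags An [nf_flags()] object.
#' @param allocation_mode `"literal"` uses the growth equation exactly as
#'   written above; `"replace_1_over_n"` instead distributes the total growth
#'   budget `conv * sum(r * L)`, i.e. `dL_x/dt = g_x * conv * sum(r * L)`.
#'   See the methods vignette for the distinction.
#' @return Named list of derivatives with the same shape as `state`, plus the
#'   attributes `r` (growth factors) and `g` (carbon fractions).
#' @examples
#' st <- nf_state(L = c(20, 20))
#' model_rhs(st, Ne = c(0, 0), nf_params(), nf_flags())$L  # 0.2 mm/h each
#' @export
model_rhs <- function(state, Ne, params, flags,
                      allocation_mode = c("literal", "replace_1_over_n")) {
  allocation_mode <- match.arg(allocation_mode)
  if (!all(is.finite(unlist(state[c("L", "Ni", "CEP", "CK", "Ns",
                                    "CEPs", "CKs")])))) {
    stop("non-finite model state", call. = FALSE)
  }
  n <- length(state$L)
  sL <- sum(state$L)
  r <- growth_rate(state, Ne, params, flags)
  g <- carbon_fractions(r, state$L, carbon = flags$carbon)
  dL <- if (allocation_mode == "literal") {
    g * params$conv * r * sL
  } else {
    g * params$conv * sum(r * state$L)
  }
  dNi <- uptake_rate(Ne, state$L, params) - params$T_up * state$Ni
  influx <- params$T_up * sum(state$Ni)
  maint <- params$u_m * sL
  if (state$Ns <= 0) maint <- min(maint, influx)
  dNs <- influx - maint - params$e * max(state$Ns, 0)
  if (flags$cep) {
    dCEP <- cep_production(Ne, state$L, params) - params$T_CEP * state$CEP
    dCEPs <- params$T_CEP * sum(state$CEP) - params$d_CEP * state$CEPs
  } else {
    dCEP <- rep(0, n)
    dCEPs <- 0
  }
  if (flags$ck_gating) {
    dCK <- ck_production(Ne, state$L, params) - params$T_CK * state$CK
    dCKs <- params$T_CK * sum(state$CK) - params$d_CK * state$CKs
  } else {
    dCK <- rep(0, n)
    dCKs <- 0
  }
  structure(list(L = dL, Ni = dNi, CEP = dCEP, CK = dCK,
                 Ns = dNs, CEPs = dCEPs, CKs = dCKs),
            r = r, g = g)
}
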