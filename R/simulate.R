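#' Integrate a foraging model over an experiment
#'
#' Numerically integrates the model ODE system ([model_rhs()]) over the
#' experiment duration with `deSolve::lsoda` (adaptive, stiffness-switching),
#' sampling the state on a uniform grid. The returned trajectory also carries
#' the derived per-compartment quantities (internal nitrate concentration,
#' growth rate factor, carbon fraction) and the systemic concentrations at
#' every sample time.
#'
#' `simulate()` on a `foraging_model` is a thin wrapper around
#' `integrate_model()`; the model is deterministic, so `nsim` and `seed` are
#' accepted for generic compatibility only.
#'
#' @param model A [foraging_model()].
#' @param experiment An [nf_experiment()].
#' @return An object of class `"nf_trajectory"`: a list with elements
#'   `times` (hours), matrices `L`, `Ni`, `CEP`, `CK`, `Ni_conc`, `r`, `g`
#'   (time x compartment), vectors `Ns`, `CEPs`, `CKs` and their
#'   concentrations, and the `model`/`experiment` used. Methods: `print`,
#'   `summary`, `plot`, `as.data.frame`.
#' @examples
#' m <- foraging_model(flags = nf_flags())  # no regulation: r = 1
#' tr <- integrate_model(m, nf_experiment(ne = 0, duration_h = 24, l0 = 20))
#' tail(as.data.frame(tr), 1)
#' @export
integrate_model <- function(model, experiment) {
  stopifnot(inherits(model, "foraging_model"),
            inherits(experiment, "nf_experiment"))
  p <- model$params
  fl <- model$flags
  n <- experiment$n
  ne <- experiment$ne
  y0 <- initial_state(model, experiment)
  times <- unique(c(seq(0, experiment$duration_h,
                        by = model$sample_interval_h),
                    experiment$duration_h))
  unpack <- function(y) {
    list(L = y[seq_len(n)], Ni = y[n + seq_len(n)],
         CEP = y[2 * n + seq_len(n)], CK = y[3 * n + seq_len(n)],
         Ns = y[4 * n + 1], CEPs = y[4 * n + 2], CKs = y[4 * n + 3])
  }
  deriv <- function(t, y, parms) {
    st <- unpack(y)
    class(st) <- "nf_state"
    d <- model_rhs(st, ne, p, fl, allocation_mode = model$allocation_mode)
    list(c(d$L, d$Ni, d$CEP, d$CK, d$Ns, d$CEPs, d$CKs))
  }
  if (experiment$duration_h == 0 || length(times) == 1L) {
    out <- matrix(c(0, y0), nrow = 1)
  } else {
    out <- deSolve::lsoda(y = y0, times = times, func = deriv, parms = NULL,
                          rtol = model$rtol, atol = model$atol)
    out <- unclass(out)
  }
  if (!all(is.finite(out))) {
    bad <- which(!apply(out, 1, function(row) all(is.finite(row))))[1]
    last_ok <- if (bad > 1) out[bad - 1, 1] else NA_real_
    stop("integration produced a non-finite state; last valid time: ",
         last_ok, " h", call. = FALSE)
  }
  tt <- out[, 1]
  nt <- length(tt)
  res <- list(times = tt,
              L = out[, 1 + seq_len(n), drop = FALSE],
              Ni = pmax(out[, 1 + n + seq_len(n), drop = FALSE], 0),
              CEP = pmax(out[, 1 + 2 * n + seq_len(n), drop = FALSE], 0),
              CK = pmax(out[, 1 + 3 * n + seq_len(n), drop = FALSE], 0),
              Ns = pmax(out[, 4 * n + 2], 0),
              CEPs = pmax(out[, 4 * n + 3], 0),
              CKs = pmax(out[, 4 * n + 4], 0))
  sL <- rowSums(res$L)
  res$Ni_conc <- res$Ni / res$L
  res$Ns_conc <- res$Ns / sL
  res$CEPs_conc <- res$CEPs / sL
  res$CKs_conc <- res$CKs / sL
  res$r <- matrix(NA_real_, nt, n)
  res$g <- matrix(NA_real_, nt, n)
  for (i in seq_len(nt)) {
    st <- structure(list(L = res$L[i, ], Ni = res$Ni[i, ],
                         CEP = res$CEP[i, ], CK = res$CK[i, ],
                         Ns = res$Ns[i], CEPs = res$CEPs[i],
                         CKs = res$CKs[i]), class = "nf_state")
    res$r[i, ] <- growth_rate(st, ne, p, fl)
    res$g[i, ] <- carbon_fractions(res$r[i, ], res$L[i, ],
                                   carbon = fl$carbon)
  }
  res$model <- model
  res$experiment <- experiment
  structure(res, class = "nf_trajectory")
}

initial_state <- function(model, experiment) {
  n <- experiment$n
  if (experiment$init_pools == "steady_state") {
    ss <- pool_steady_state(experiment$l0, experiment$ne, model$params,
                            model$flags)
    c(experiment$l0, ss$Ni, ss$CEP, ss$CK, ss$Ns, ss$CEPs, ss$CKs)
  } else {
    c(experiment$l0, rep(0, 3 * n), 0, 0, 0)
  }
}

#' @rdname integrate_model
#' @param object A `foraging_model`.
#' @param nsim,seed Ignored (deterministic model); present for the
#'   [stats::simulate()] generic.
#' @param ... Unused.
#' @export
simulate.foraging_model <- function(object, nsim = 1, seed = NULL,
                                    experiment, ...) {
  integrate_model(object, experiment)
}

#' Final compartment lengths of a trajectory
#'
#' @param trajectory An `nf_trajectory`.
#' @return Numeric vector of compartment lengths (mm) at the final sample.
#' @export
final_lengths <- function(trajectory) {
  stopifnot(inherits(trajectory, "nf_trajectory"))
  trajectory$L[nrow(trajectory$L), ]
}

#' @export
print.nf_trajectory <- function(x, ...) {
  n <- ncol(x$L)
  cat("Foraging model trajectory: ", n, " compartment",
      if (n > 1) "s", ", ", length(x$times) - 1, " x ",
      x$model$sample_interval_h, " h\n", sep = "")
  cat("  final lengths (mm):",
      paste(round(final_lengths(x), 1), collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.nf_trajectory <- function(object, ...) {
  print(object)
  i <- length(object$times)
  cat("  final [Ns] =", signif(object$Ns_conc[i], 4),
      "[CEPs] =", signif(object$CEPs_conc[i], 4),
      "[CKs] =", signif(object$CKs_conc[i], 4), "umol/mm\n")
  cat("  final r:", paste(signif(object$r[i, ], 4), collapse = " "), "\n")
  invisible(object)
}

#' @export
as.data.frame.nf_trajectory <- function(x, ...) {
  n <- ncol(x$L)
  nt <- length(x$times)
  data.frame(
    time_h = rep(x$times, each = n),
    compartment = rep(seq_len(n), times = nt),
    L_mm = as.vector(t(x$L)),
    Ni_umol = as.vector(t(x$Ni)),
    Ni_conc = as.vector(t(x$Ni_conc)),
    r_factor = as.vector(t(x$r)),
    g_carbon = as.vector(t(x$g)),
    Ns_conc = rep(x$Ns_conc, each = n),
    CEPs_conc = rep(x$CEPs_conc, each = n),
    CKs_conc = rep(x$CKs_conc, each = n)
  )
}

#' @export
plot.nf_trajectory <- function(x, log = "", ...) {
  graphics::matplot(x$times, x$L, type = "l", lty = 1,
                    xlab = "time (h)", ylab = "cumulative root length (mm)",
                    log = log, ...)
  graphics::legend("topleft", bty = "n", lty = 1,
                   col = seq_len(ncol(x$L)),
                   legend = paste0("compartment ", seq_len(ncol(x$L)),
                                   " (Ne = ", x$experiment$ne, ")"))
  invisible(x)
}

#' Analytic solution of the unregulated growth equation
#'
#' With a constant growth rate factor `r`, the single-compartment growth
#' equation has the closed form `L(t) = L0 * exp(conv * r * t)`. This is the
#' oracle used to verify the integrator and to calibrate `conv`
#' ([solve_conv()]).
#'
#' @param t Time (hours).
#' @param L0 Initial length (mm).
#' @param r Constant growth rate factor (dimensionless).
#' @param conv Conversion factor (dimensionless).
#' @return Length in mm (vectorised over `t`).
#' @examples
#' analytic_length(240, L0 = 20, r = 1.5, conv = 0.01)  # 720 mm
#' @export
analytic_length <- function(t, L0 = 20, r = 1, conv = 0.01) {
  check_nonneg(t, "t")
  check_nonneg(L0, "L0")
  check_nonneg(r, "r")
  check_nonneg(conv, "conv")
  L0 * exp(conv * r * t)
}

#' Closed-form pool fixed points at frozen root lengths
#'
#' For fixed compartment lengths and external nitrate the pool equations are
#' linear and their fixed points are available in closed form:
#' `Ni* = uptake_rate / T_up`;
#' `Ns* = max(0, (T_up * sum(Ni*) - u_m * sum(L)) / e)` (the maintenance sink
#' is capped so the systemic pool cannot rest below zero);
#' `CEP* = cep_production / T_CEP`, `CEPs* = T_CEP * sum(CEP*) / d_CEP`, and
#' analogously for CK. Pools of inactive layers are zero.
#'
#' @param L Vector of (frozen) compartment lengths (mm).
#' @param ne Vector of external nitrate concentrations (umol/L).
#' @param params An [nf_params()] object.
#' @param flags An [nf_flags()] object (controls which pools are active).
#' @return List with elements `Ni`, `Ns`, `CEP`, `CEPs`, `CK`, `CKs`.
#' @examples
#' pool_steady_state(L = 1, ne = 1000, nf_params(), nf_flags())$Ni  # 0.1485
#' @export
pool_steady_state <- function(L, ne, params, flags = nf_flags()) {
  check_nonneg(L, "L")
  check_nonneg(ne, "ne")
  if (length(ne) != length(L)) stop("'L' and 'ne' must have equal length")
  n <- length(L)
  Ni <- uptake_rate(ne, L, params) / params$T_up
  Ns <- max(0, (params$T_up * sum(Ni) - params$u_m * sum(L)) / params$e)
  if (flags$cep) {
    CEP <- cep_production(ne, L, params) / params$T_CEP
    CEPs <- params$T_CEP * sum(CEP) / params$d_CEP
  } else {
    CEP <- rep(0, n)
    CEPs <- 0
  }
  if (flags$ck_gating) {
    CK <- ck_production(ne, L, params) / params$T_CK
    CKs <- params$T_CK * sum(CK) / params$d_CK
  } else {
    CK <- rep(0, n)
    CKs <- 0
  }
  list(Ni = Ni, Ns = Ns, CEP = CEP, CEPs = CEPs, CK = CK, CKs = CKs)
}
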