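#' Single-root nitrate dose-response
#'
#' Grows a single-compartment root system (`n = 1`) at each external nitrate
#' level of `ne_grid` and reports the final cumulative length together with
#' the internal and systemic nitrate concentrations at the end of the run.
#' With only the survival layer active this reproduces the saturating effect
#' of external nitrate on root system size; with no layers active the final
#' length is independent of nitrate.
#'
#' @param ne_grid Vector of external nitrate concentrations (umol/L).
#' @param flags Layer selection, default `nf_ladder("L1")` (survival response
#'   only, the variant the dose-response was introduced with).
#' @param duration_h Duration in hours; default 192 (8 days).
#' @param params Parameter set.
#' @param l0 Initial length (mm).
#' @param ... Passed to [foraging_model()] (e.g. `allocation_mode`, `rtol`).
#' @return A data frame with columns `ne`, `final_length_mm`, `Ni_conc`,
#'   `Ns_conc`.
#' @examples
#' run_dose_response(c(110, 1000, 11000), duration_h = 48)
#' @export
run_dose_response <- function(ne_grid, flags = nf_ladder("L1"),
                              duration_h = 192, params = nf_params(),
                              l0 = 20, ...) {
  if (length(ne_grid) < 1L) stop("'ne_grid' must be non-empty", call. = FALSE)
  model <- foraging_model(params = params, flags = flags, ...)
  rows <- lapply(ne_grid, function(ne) {
    tr <- integrate_model(model, nf_experiment(ne = ne,
                                               duration_h = duration_h,
                                               l0 = l0))
    i <- length(tr$times)
    data.frame(ne = ne, final_length_mm = tr$L[i, 1],
               Ni_conc = tr$Ni_conc[i, 1], Ns_conc = tr$Ns_conc[i])
  })
  do.call(rbind, rows)
}

#' Split-root experiment
#'
#' Simulates the three split-root conditions (`n = 2`): both halves low
#' nitrate, both high, and the heterogeneous low/high plant. Conditions are
#' labelled focal-half/other-half, so the heterogeneous run supplies both the
#' `LN/HN` entry (its low side) and the `HN/LN` entry (its high side).
#'
#' @param flags Layer selection (default: full model).
#' @param mutant In-silico mutant, see [apply_mutant()].
#' @param duration_h Duration in hours; default 144 (6 days).
#' @param ne_low,ne_high Low/high external nitrate (umol/L); defaults 25 and
#'   5000.
#' @param l0 Initial length per half (mm).
#' @param params Parameter set.
#' @param init_pools Pool initialisation, see [nf_experiment()].
#' @param ... Passed to [foraging_model()].
#' @return An object of class `"split_root_summary"`: a data frame with one
#'   row per condition (`LN/LN`, `LN/HN`, `HN/LN`, `HN/HN`) and columns
#'   `condition`, `length_mm` (exact) and `length_mm_rounded`; the attribute
#'   `difference_mm` holds the preferential-foraging difference
#'   `HN/LN - LN/HN` of the exact lengths.
#' @examples
#' \donttest{
#' run_split_root(flags = nf_ladder("L2"), duration_h = 144)
#' }
#' @export
run_split_root <- function(flags = nf_ladder("L7"), mutant = "WT",
                           duration_h = 144, ne_low = 25, ne_high = 5000,
                           l0 = 20, params = nf_params(),
                           init_pools = "zero", ...) {
  model <- foraging_model(params = params, flags = flags, mutant = mutant,
                          ...)
  sim <- function(ne) {
    unname(final_lengths(integrate_model(model,
      nf_experiment(ne = ne, duration_h = duration_h, l0 = l0,
                    init_pools = init_pools))))
  }
  low <- sim(c(ne_low, ne_low))
  het <- sim(c(ne_low, ne_high))
  high <- sim(c(ne_high, ne_high))
  len <- c("LN/LN" = low[1], "LN/HN" = het[1],
           "HN/LN" = het[2], "HN/HN" = high[2])
  out <- data.frame(condition = names(len), length_mm = unname(len),
                    length_mm_rounded = round(unname(len)))
  structure(out, class = c("split_root_summary", "data.frame"),
            difference_mm = unname(len["HN/LN"] - len["LN/HN"]),
            mutant = mutant)
}

#' @export
print.split_root_summary <- function(x, ...) {
  cat("Split-root summary (", attr(x, "mutant"), ")\n", sep = "")
  print.data.frame(x, row.names = FALSE, ...)
  cat("preferential foraging difference (HN/LN - LN/HN):",
      round(attr(x, "difference_mm"), 1), "mm\n")
  invisible(x)
}

#' Single high-nitrate patch experiment
#'
#' Partitions the root system into `n` compartments with exactly one exposed
#' to high nitrate (a discovered nutrient patch) and all others to low
#' nitrate. Returns the growth time course of the patch compartment and the
#' summed time course of the remaining compartments. Comparing runs with the
#' cytokinin gate on and off shows how the supply signal limits excessive
#' proliferation in a single patch when demand far outstrips supply.
#'
#' @param ck_gating Is the CK supply gate active (full model) or not (CEP
#'   signalling independent of CK)?
#' @param n Number of compartments (default 16).
#' @param high_index Index of the high-nitrate compartment.
#' @param ne_low,ne_high Low/high external nitrate (umol/L).
#' @param duration_h Duration in hours.
#' @param l0 Initial length per compartment (mm).
#' @param params Parameter set.
#' @param ... Passed to [foraging_model()].
#' @return A list with data frames `high` (`time_h`, `L_mm`) and `low`
#'   (`time_h`, `L_mm_sum`) plus the full `trajectory`.
#' @examples
#' \donttest{
#' run_patch(ck_gating = TRUE, n = 16, duration_h = 144)
#' }
#' @export
run_patch <- function(ck_gating = TRUE, n = 16, high_index = 1,
                      ne_low = 25, ne_high = 5000, duration_h = 144,
                      l0 = 20, params = nf_params(), ...) {
  if (!(is.numeric(high_index) && length(high_index) == 1L &&
        high_index >= 1 && high_index <= n)) {
    stop("'high_index' must be a compartment index in 1..", n, call. = FALSE)
  }
  flags <- nf_ladder(if (ck_gating) "L7" else "L6")
  model <- foraging_model(params = params, flags = flags, ...)
  ne <- rep(ne_low, n)
  ne[high_index] <- ne_high
  tr <- integrate_model(model, nf_experiment(ne = ne,
                                             duration_h = duration_h,
                                             l0 = l0))
  low_sum <- rowSums(tr$L[, -high_index, drop = FALSE])
  list(high = data.frame(time_h = tr$times, L_mm = tr$L[, high_index]),
       low = data.frame(time_h = tr$times, L_mm_sum = low_sum),
       trajectory = tr)
}

#' In-silico mutant split-root table
#'
#' Runs the heterogeneous split-root experiment under the full model for the
#' wild type and the three mutants and tabulates the low-side length, the
#' high-side length and their difference, each rounded to integer mm.
#'
#' @inheritParams run_split_root
#' @return A data frame with columns `plant`, `length_low_N_mm`,
#'   `length_high_N_mm`, `difference_mm` (integers, one row per plant).
#' @examples
#' \donttest{
#' run_mutant_table()
#' }
#' @export
run_mutant_table <- function(duration_h = 144, ne_low = 25, ne_high = 5000,
                             l0 = 20, params = nf_params(),
                             init_pools = "zero", ...) {
  plants <- c("WT", "nrt1.1", "cep", "ck")
  rows <- lapply(plants, function(m) {
    model <- foraging_model(params = params, flags = nf_ladder("L7"),
                            mutant = m, ...)
    fin <- final_lengths(integrate_model(model,
      nf_experiment(ne = c(ne_low, ne_high), duration_h = duration_h,
                    l0 = l0, init_pools = init_pools)))
    data.frame(plant = m,
               length_low_N_mm = round(fin[1]),
               length_high_N_mm = round(fin[2]),
               difference_mm = round(fin[2]) - round(fin[1]))
  })
  do.call(rbind, rows)
}
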