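test_that("regulatory factors hit their anchor values", {
  # lower asymptotes, Hill midpoints, and directly evaluated interior points
  expect_equal(f_basic(0, P), 0.5)
  expect_equal(f_basic(0.04, P), 0.75)
  expect_equal(f_basic(0.4, P), 0.5 + 0.5 * 0.16 / 0.1616)

  expect_equal(f_local(0, P), 0.65)
  expect_equal(f_local(200, P), 0.825)
  expect_equal(f_local(5000, P), 0.65 + 0.35 * 25e6 / (25e6 + 4e4))

  expect_equal(g_ne(750, P), 0.5)
  expect_equal(g_ne(0, P), 0)
  expect_equal(g_ne(25, P), 625 / 563125)

  expect_equal(g_ck(0, P), 0.1)
  expect_equal(g_ck(2, P), 0.55)
  expect_equal(g_ck(1e9, P), 1, tolerance = 1e-6)

  expect_equal(f_cep(0, 5000, 0, P), 1)
  expect_equal(f_cep(1e9, 1e9, 0, P, ck_gating = FALSE), 1.5,
               tolerance = 1e-6)
  expect_equal(f_cep(1, 750, 2, P, ck_gating = TRUE),
               1 + 0.5 * 0.5 * 0.5 * 0.55)

  expect_equal(f_systrepr(0, P), 1)
  expect_equal(f_systrepr(0.4, P), 0.5)
  expect_equal(f_systrepr(0.8, P), 1 / 17)

  expect_equal(f_systfor(0, P), 2)
  expect_equal(f_systfor(0.12, P), 1.5)
  expect_equal(f_systfor(1e6, P), 1, tolerance = 1e-12)
})

test_that("regulatory factors reject negative inputs", {
  for (f in list(f_basic, f_systrepr, f_systfor, g_ck)) {
    expect_error(f(-0.1, P), "non-negative")
  }
  expect_error(f_local(-1, P), "non-negative")
  expect_error(g_ne(-1, P), "non-negative")
  expect_error(f_cep(-1, 0, 0, P), "non-negative")
  expect_error(uptake_rate(-1, 1, P), "non-negative")
  expect_error(cep_production(1, -1, P), "non-negative")
  expect_error(ck_production(-1, 1, P), "non-negative")
})

test_that("factors stay in their stated ranges on random inputs", {
  set.seed(41)
  x <- c(0, 10^runif(300, -4, 4))
  expect_true(all(f_basic(x, P) >= P$a_basic & f_basic(x, P) < 1))
  expect_true(all(f_local(x, P) >= 1 - P$a_local & f_local(x, P) < 1))
  expect_true(all(g_ne(x, P) >= 0 & g_ne(x, P) < 1))
  expect_true(all(g_ck(x, P) >= P$a_CK & g_ck(x, P) < 1))
  expect_true(all(f_systrepr(x, P) > 0 & f_systrepr(x, P) <= 1))
  expect_true(all(f_systfor(x, P) >= 1 &
                    f_systfor(x, P) <= 1 + P$a_systfor))
  fc <- f_cep(x, rev(x), x, P, ck_gating = TRUE)
  expect_true(all(fc >= 1 & fc <= 1 + P$a_CEP))
})

test_that("factors are monotone in their arguments", {
  set.seed(42)
  x <- sort(c(0, 10^runif(200, -4, 4)))
  expect_true(all(diff(f_basic(x, P)) >= 0))
  expect_true(all(diff(f_local(x, P)) >= 0))
  expect_true(all(diff(g_ne(x, P)) >= 0))
  expect_true(all(diff(g_ck(x, P)) >= 0))
  expect_true(all(diff(f_systrepr(x, P)) <= 0))
  expect_true(all(diff(f_systfor(x, P)) <= 0))
})

test_that("growth rate is the product of the enabled factors only", {
  st <- nf_state(L = c(20, 20), Ns = 0.04 * 40)  # [Ns] = 0.04
  expect_equal(growth_rate(st, c(25, 5000), P, nf_flags()), c(1, 1))
  expect_equal(growth_rate(st, c(25, 5000), P, nf_ladder("L1")),
               c(0.75, 0.75))
  st2 <- nf_state(L = c(20, 20), Ns = 0.4 * 40)  # [Ns] = 0.4
  r <- growth_rate(st2, c(200, 200), P, nf_ladder("L2"))
  expect_equal(r, rep(f_basic(0.4, P) * f_local(200, P), 2))
  expect_equal(round(r[1], 4), 0.8209)
})

test_that("nrt1.1 override freezes f_local at its constant", {
  pm <- apply_mutant(nf_params(), "nrt1.1")
  expect_equal(pm$up1, 0.48)
  expect_equal(f_local(c(0, 200, 5000), pm), rep(0.6, 3))
  expect_equal(apply_mutant(nf_params(), "cep")$p_CEP, 0)
  expect_equal(apply_mutant(nf_params(), "ck")$p_CK, 0)
  expect_identical(apply_mutant(nf_params(), "WT"), nf_params())
})

test_that("carbon fractions allocate by sink strength and sum to one", {
  expect_equal(carbon_fractions(c(1, 1), c(20, 20)), c(0.5, 0.5))
  expect_equal(carbon_fractions(c(1, 0), c(20, 20)), c(1, 0))
  expect_equal(carbon_fractions(c(2, 1), c(10, 10)), c(2 / 3, 1 / 3))
  expect_equal(carbon_fractions(c(2, 1), c(10, 10), carbon = FALSE),
               c(0.5, 0.5))
  # degenerate case: no compartment grows, share evenly
  expect_equal(carbon_fractions(c(0, 0, 0), c(5, 10, 20)), rep(1 / 3, 3))
  set.seed(43)
  for (i in 1:50) {
    n <- sample(2:16, 1)
    g <- carbon_fractions(runif(n, 0, 3), runif(n, 1, 100))
    expect_equal(sum(g), 1, tolerance = 1e-12)
  }
})

test_that("uptake and production rates match their closed forms", {
  expect_equal(uptake_rate(0, 5, P), 0)
  expect_equal(uptake_rate(75, 1, P), 0.3 + 0.000006 * 75)
  expect_equal(uptake_rate(5000, 20, P),
               20 * (0.6 * 5000 / 5075 + 0.000006 * 5000))
  expect_equal(cep_production(0, 1, P), 0.1)
  expect_equal(cep_production(250, 1, P), 0.05)
  expect_equal(cep_production(5000, 1, P), 0.1 * 62500 / (62500 + 25e6))
  expect_equal(ck_production(0, 7, P), 0)
  expect_equal(ck_production(750, 1, P), 0.05)
  expect_equal(ck_production(25, 1, P), 0.1 * 625 / 563125)
})

test_that("the assembled RHS reduces to the basic model with layers off", {
  st <- nf_state(L = c(20, 20))
  d <- model_rhs(st, c(0, 0), P, nf_flags())
  expect_equal(d$L, c(0.2, 0.2))  # 0.5 * conv * 1 * 40
  expect_equal(d$Ni, c(0, 0))
  # zeroth-order maintenance sink is capped once the systemic pool is empty
  expect_equal(d$Ns, 0)
  expect_equal(d$CEP, c(0, 0))
  expect_equal(d$CEPs, 0)
  # with systemic nitrate present the sink acts at full strength
  st2 <- nf_state(L = c(20, 20), Ns = 2)
  d2 <- model_rhs(st2, c(0, 0), P, nf_flags())
  expect_equal(d2$Ns, -P$u_m * 40 - P$e * 2)
})

test_that("RHS fixed point and symmetry properties hold", {
  ss <- pool_steady_state(L = 1, ne = 1000, P)
  st <- nf_state(L = 1, Ni = ss$Ni, Ns = ss$Ns)
  d <- model_rhs(st, 1000, P, nf_flags())
  expect_equal(d$Ni, 0)
  expect_equal(d$Ns, 0, tolerance = 1e-12)
  # symmetric split root: identical compartments get identical derivatives
  st2 <- nf_state(L = c(30, 30), Ni = c(1, 1), CEP = c(2, 2), CK = c(3, 3),
                  Ns = 4, CEPs = 5, CKs = 6)
  d2 <- model_rhs(st2, c(5000, 5000), P, nf_ladder("L7"))
  for (comp in c("L", "Ni", "CEP", "CK")) {
    expect_equal(d2[[comp]][1], d2[[comp]][2])
  }
})

test_that("layer flags validate the CK-gating dependency and presets nest", {
  expect_error(nf_flags(ck_gating = TRUE), "requires the 'cep' layer")
  expect_silent(nf_flags(cep = TRUE, ck_gating = TRUE))
  expect_error(nf_ladder("L8"), "unknown ladder preset")
  # each ladder step is a superset of the previous one
  prev <- nf_ladder("L0")
  for (k in 1:7) {
    cur <- nf_ladder(paste0("L", k))
    expect_true(all(names(prev)[unlist(prev)] %in%
                      names(cur)[unlist(cur)]))
    expect_equal(sum(unlist(cur)), k)
    prev <- cur
  }
  expect_identical(unclass(nf_ladder("full"))[1:7],
                   unclass(nf_ladder("L7"))[1:7])
})

test_that("parameter validation enforces sign and range invariants", {
  expect_error(nf_params(up1 = -1), "non-negative")
  expect_error(nf_params(a_CEP = 1.2), "\\[0, 1\\]")
  expect_error(nf_params(K_up = c(1, 2)), "single finite")
  expect_error(nf_params(f_local_const = 2), "f_local_const")
  expect_silent(nf_params(f_local_const = 0.6))
})
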