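test_that("system validation computes derived constants and rejects bad input", {
  sys <- ternary_system(100, 1e5, 100, 1000, 5)
  expect_equal(sys$k_c2, 1)
  expect_equal(sys$k_t2, 1000)
  expect_equal(sys$k_clt, 100 * 1e5 / 100)
  # path independence holds exactly for the derived constants
  expect_identical(sys$k_c1 / sys$k_c2, sys$k_t1 / sys$k_t2)
  # the weak-binder analogue of the derived constant: 100000/200 = 500 nM
  weak <- ternary_system(1, 1e5, 200, 1, 1)
  expect_identical(weak$k_t2, 500)

  expect_error(ternary_system(100, 1e5, 0, 1000, 5), "alpha")
  expect_error(ternary_system(-1, 1e5, 1, 1000, 5), "k_c1")
  expect_error(ternary_system(100, 0, 1, 1000, 5), "k_t1")
  expect_error(ternary_system(100, 1e5, 1, -2, 5), "c_tot")
  expect_error(ternary_system(100, 1e5, 1, 1000, NA), "t_tot")
  # negative cooperativity (alpha < 1) is admissible
  expect_s3_class(ternary_system(100, 1e5, 0.01, 1000, 5), "ternary_system")
})

test_that("CLT quadratic matches the fixed-point oracle and handles degeneracy", {
  sys <- ternary_system(100, 100, 1, 100, 100)
  expect_rel_equal(clt_given_free_ligand(sys, 100),
                   oracle_clt(100, 100, 1, 100, 100, 100), 1e-10)
  # no target (or ligand, or chaperone) means no ternary complex
  expect_identical(clt_given_free_ligand(ternary_system(100, 1e5, 100, 1000, 0), 50), 0)
  expect_identical(clt_given_free_ligand(ternary_system(100, 1e5, 100, 0, 5), 50), 0)
  expect_identical(clt_given_free_ligand(sys, 0), 0)
  expect_error(clt_given_free_ligand(sys, -1), "l_free")
})

test_that("equilibrium states satisfy conservation and the pathway identity", {
  cases <- list(
    list(s = occ_demo_system(), l = 9.8),
    list(s = cshift_system(), l = 5000),
    list(s = biophys_hook_system(), l = 316),
    list(s = ternary_system(3, 7, 0.2, 11, 13), l = 2.5))
  for (cs in cases) {
    st <- state_from_free_ligand(cs$s, cs$l)
    expect_true(all(unlist(st) >= 0))
    expect_rel_equal(st$c_free + st$cl + st$clt, cs$s$c_tot, 1e-9)
    expect_rel_equal(st$t_free + st$tl + st$clt, cs$s$t_tot, 1e-9)
    expect_lte(st$clt, min(cs$s$c_tot, cs$s$t_tot))
    expect_rel_equal(st$clt * cs$s$k_c1 * cs$s$k_t1,
                     cs$s$alpha * st$c_free * st$t_free * st$l_free, 1e-9)
    expect_equal(st$l_tot_implied, st$l_free + st$cl + st$tl + st$clt)
  }
  # zero ligand: everything free
  st0 <- state_from_free_ligand(occ_demo_system(), 0)
  expect_identical(st0$clt, 0)
  expect_identical(st0$cl, 0)
  expect_equal(st0$c_free, 1000)
  expect_equal(st0$t_free, 5)
})

test_that("quadratic agrees with the oracle over 200 random systems", {
  set.seed(42)
  n <- 200
  k_c1 <- 10^runif(n, 0, 6); k_t1 <- 10^runif(n, 0, 6)
  alpha <- 10^runif(n, -2, 4)
  c_tot <- 10^runif(n, -1, 5); t_tot <- 10^runif(n, -1, 5)
  l <- 10^runif(n, -3, 7)
  for (i in seq_len(n)) {
    sys <- ternary_system(k_c1[i], k_t1[i], alpha[i], c_tot[i], t_tot[i])
    got <- clt_given_free_ligand(sys, l[i])
    want <- oracle_clt(k_c1[i], k_t1[i], alpha[i], c_tot[i], t_tot[i], l[i])
    expect_lt(abs(got - want), 1e-8 * max(want, 1e-300))
  }
})

test_that("total<->free ligand transformation is monotone and round-trips", {
  sys <- occ_demo_system()
  ls <- 10^seq(-2, 6, length.out = 40)
  lt <- total_ligand_of_free(sys, ls)
  expect_true(all(diff(lt) > 0))
  expect_true(all(lt >= ls))
  back <- free_ligand_of_total(sys, lt)
  expect_true(all(abs(back - ls) <= 1e-9 * ls))
  # forward map agrees with the oracle's bookkeeping
  expect_rel_equal(total_ligand_of_free(sys, 100),
                   oracle_state(100, 1e5, 100, 1000, 5, 100)$l_tot_implied,
                   1e-10)
  # degenerate: no proteins, identity map; zero dose, zero free
  expect_identical(free_ligand_of_total(ternary_system(1, 1, 1, 0, 0), 42), 42)
  expect_identical(free_ligand_of_total(sys, 0), 0)
  expect_identical(total_ligand_of_free(ternary_system(1, 1, 1, 0, 0), 7), 7)
})

test_that("closed-system state conserves the applied total ligand", {
  sys <- biophys_hook_system()
  for (lt in c(1, 100, 3162, 1e5, 3e6)) {
    st <- state_from_total_ligand(sys, lt)
    expect_rel_equal(st$l_tot_implied, lt, 1e-9)
    want <- oracle_state(100, 1e4, 16, 25000, 1e4, st$l_free)
    expect_rel_equal(st$clt, want$clt, 1e-8)
  }
  st0 <- state_from_total_ligand(sys, 0)
  expect_identical(st0$clt, 0)
  expect_identical(st0$l_free, 0)
})

test_that("hook curve is symmetric about sqrt(k_c1*k_t1) on the free axis", {
  sys <- cshift_system()
  s_max <- free_ligand_at_max_clt(sys)
  expect_rel_equal(s_max, sqrt(100 * 1e5), 1e-9)
  for (x in c(2, 10, 100)) {
    expect_rel_equal(clt_given_free_ligand(sys, s_max * x),
                     clt_given_free_ligand(sys, s_max / x), 1e-9)
  }
  # argmax is independent of alpha and totals
  expect_rel_equal(free_ligand_at_max_clt(ternary_system(100, 1e5, 3, 17, 900)),
                   sqrt(100 * 1e5), 1e-9)
  expect_equal(free_ligand_at_max_clt(ternary_system(100, 100, 5, 10, 10)), 100)
  expect_error(free_ligand_at_max_clt(ternary_system(100, 100, 5, 10, 0)),
               "t_tot")
})

test_that("total-ligand hook maximum exceeds the free-ligand argmax", {
  for (sys in list(biophys_hook_system(), cshift_system(), tshift_system())) {
    expect_gt(ltot_at_max_clt(sys), free_ligand_at_max_clt(sys))
  }
  expect_gt(ltot_at_max_clt(biophys_hook_system()), 1000)  # sqrt(100*1e4) = 1000
  # vanishing totals: depletion disappears
  tiny <- ternary_system(100, 1e4, 16, 1e-8, 1e-8)
  expect_rel_equal(ltot_at_max_clt(tiny), free_ligand_at_max_clt(tiny), 1e-6)
  # the mapped maximum is the global maximum over a total-ligand grid
  sys <- cshift_system()
  lt_max <- ltot_at_max_clt(sys)
  clt_max <- state_from_total_ligand(sys, lt_max)$clt
  grid <- 10^seq(0, 7, length.out = 120)
  clt_grid <- vapply(grid, function(x) state_from_total_ligand(sys, x)$clt,
                     numeric(1))
  expect_gte(clt_max * (1 + 1e-9), max(clt_grid))
})

test_that("binary limit reduces to the Langmuir isotherm", {
  sys <- ternary_system(100, 1e5, 50, c_tot = 5, t_tot = 0)
  for (l in c(0.1, 10, 100, 1e4)) {
    st <- state_from_free_ligand(sys, l)
    expect_rel_equal(st$cl, 5 * l / (100 + l), 1e-12)
    expect_identical(st$clt, 0)
  }
})

test_that("ternary complex is non-decreasing in cooperativity", {
  alphas <- 10^seq(-2, 4, length.out = 13)
  clt <- vapply(alphas, function(a)
    clt_given_free_ligand(ternary_system(100, 1e5, a, 1000, 5), 50),
    numeric(1))
  expect_true(all(diff(clt) >= 0))
})
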