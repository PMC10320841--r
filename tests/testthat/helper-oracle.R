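# Independent oracle: damped fixed-point iteration on the coupled species
# equations (pathway identity + conservation), never touching the package's
# quadratic. Converges for any admissible system by heavy damping.
oracle_state <- function(k_c1, k_t1, alpha, c_tot, t_tot, l_free,
                         tol = 1e-13, max_iter = 20000L, damp = 0.5) {
  g <- function(clt) {
    c_free <- (c_tot - clt) / (1 + l_free / k_c1)
    t_free <- (t_tot - clt) / (1 + l_free / k_t1)
    min(max(alpha * c_free * t_free * l_free / (k_c1 * k_t1), 0),
        min(c_tot, t_tot))
  }
  clt <- 0
  r_prev <- Inf
  for (i in seq_len(max_iter)) {
    r <- g(clt) - clt
    if (abs(r) <= tol * max(clt, 1e-300)) break
    if (abs(r) > abs(r_prev)) damp <- damp / 2   # stiff map: damp harder
    clt <- clt + damp * r
    r_prev <- r
  }
  c_free <- (c_tot - clt) / (1 + l_free / k_c1)
  t_free <- (t_tot - clt) / (1 + l_free / k_t1)
  cl <- c_free * l_free / k_c1
  tl <- t_free * l_free / k_t1
  list(l_free = l_free, c_free = c_free, t_free = t_free,
       cl = cl, tl = tl, clt = clt,
       l_tot_implied = l_free + cl + tl + clt)
}

oracle_clt <- function(k_c1, k_t1, alpha, c_tot, t_tot, l_free)
  oracle_state(k_c1, k_t1, alpha, c_tot, t_tot, l_free)$clt

# Recurring systems from the worked examples
biophys_hook_system <- function() ternary_system(100, 1e4, 16, 25000, 1e4)
occ_demo_system <- function() ternary_system(100, 1e5, 100, 1000, 5)
cshift_system <- function() ternary_system(100, 1e5, 200, 5, 1000)
noncoop_system <- function() ternary_system(100, 100, 1, 5, 1000)
tshift_system <- function() ternary_system(100, 1e5, 200, 1000, 5)

expect_rel_equal <- function(object, expected, rel_tol) {
  expect_lt(abs(object - expected), rel_tol * abs(expected))
}
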