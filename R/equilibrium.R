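#' Ternary complex concentration at a given free-ligand level
#'
#' Solves the mass-action equilibrium for the ternary complex concentration
#' \[CLT\] given the free ligand concentration \[L\]. Substituting the
#' conservation relations for chaperone and target into the pathway-
#' independence identity
#' \deqn{[CLT] \cdot K_{C,1} K_{T,1} = \alpha\,[C][T][L]}
#' yields a quadratic in \[CLT\],
#' \deqn{a x^2 - b x + c = 0,\quad a = \alpha L,\;
#'   b = \alpha L (C_{tot}+T_{tot}) + K_{C,1}K_{T,1}(1+L/K_{C,1})(1+L/K_{T,1}),\;
#'   c = \alpha L\, C_{tot} T_{tot},}
#' whose smaller root is the only one below `min(c_tot, t_tot)` and hence
#' the physical solution. The root is computed with the numerically stable
#' q-formulation to avoid cancellation when b dominates.
#'
#' @param system A [ternary_system()].
#' @param l_free Free ligand concentration(s), nM, >= 0. Vectorised.
#' @return Ternary complex concentration(s), nM.
#' @examples
#' sys <- ternary_system(100, 1e5, 100, c_tot = 1000, t_tot = 5)
#' clt_given_free_ligand(sys, 9.8) / sys$t_tot * 100  # ~8.2% occupancy
#' @export
clt_given_free_ligand <- function(system, l_free) {
  system <- as_ternary_system(system)
  if (any(!is.finite(l_free)) || any(l_free < 0))
    stop("'l_free' must be finite and >= 0", call. = FALSE)
  vapply(l_free, function(l) clt_one(system, l), numeric(1))
}

clt_one <- function(s, l) {
  if (l == 0 || s$c_tot == 0 || s$t_tot == 0) return(0)
  a <- s$alpha * l
  b <- s$alpha * l * (s$c_tot + s$t_tot) +
    s$k_c1 * s$k_t1 * (1 + l / s$k_c1) * (1 + l / s$k_t1)
  cc <- s$alpha * l * s$c_tot * s$t_tot
  disc <- b * b - 4 * a * cc
  # clamp tiny negative discriminants from roundoff; b > 0 always here
  if (disc < 0) {
    if (disc > -1e-10 * b * b) disc <- 0
    else stop("negative discriminant in CLT quadratic", call. = FALSE)
  }
  q <- -0.5 * (-b - sqrt(disc))      # sign(-b) = -1 since b > 0
  # roots are q/a and cc/q; the smaller (physical) one is cc/q
  min(q / a, cc / q)
}

#' Full equilibrium state at a given free-ligand level
#'
#' Computes all six species concentrations from the free ligand level:
#' \[CLT\] from [clt_given_free_ligand()], then
#' `c_free = (c_tot - clt) / (1 + l/k_c1)`, `cl = c_free * l / k_c1`,
#' and symmetrically for the target side. The implied total ligand is
#' `l + cl + tl + clt`.
#'
#' @inheritParams clt_given_free_ligand
#' @param l_free Free ligand concentration, nM (scalar).
#' @return An object of class `equilibrium_state`: a list with components
#'   `l_free`, `c_free`, `t_free`, `cl`, `tl`, `clt`, `l_tot_implied` (nM).
#' @export
state_from_free_ligand <- function(system, l_free) {
  s <- as_ternary_system(system)
  if (length(l_free) != 1L || !is.finite(l_free) || l_free < 0)
    stop("'l_free' must be a single finite number >= 0", call. = FALSE)
  clt <- clt_one(s, l_free)
  c_free <- (s$c_tot - clt) / (1 + l_free / s$k_c1)
  t_free <- (s$t_tot - clt) / (1 + l_free / s$k_t1)
  cl <- c_free * l_free / s$k_c1
  tl <- t_free * l_free / s$k_t1
  structure(
    list(l_free = l_free, c_free = c_free, t_free = t_free,
         cl = cl, tl = tl, clt = clt,
         l_tot_implied = l_free + cl + tl + clt),
    class = "equilibrium_state")
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat("Equilibrium state (nM):\n")
  cat(sprintf("  [L] = %g   [C] = %g   [T] = %g\n",
              x$l_free, x$c_free, x$t_free))
  cat(sprintf("  [CL] = %g   [TL] = %g   [CLT] = %g\n", x$cl, x$tl, x$clt))
  cat(sprintf("  implied [L_tot] = %g\n", x$l_tot_implied))
  invisible(x)
}

#' Total ligand implied by a free-ligand level
#'
#' Evaluates `l_tot(l) = l + cl(l) + tl(l) + clt(l)`, the ligand bookkeeping
#' relation. The map is strictly increasing in `l`, which is what makes the
#' inverse ([free_ligand_of_total()]) well defined.
#'
#' @inheritParams clt_given_free_ligand
#' @return Implied total ligand concentration(s), nM. Vectorised.
#' @export
total_ligand_of_free <- function(system, l_free) {
  system <- as_ternary_system(system)
  vapply(l_free, function(l) state_from_free_ligand(system, l)$l_tot_implied,
         numeric(1))
}

#' Free ligand from total ligand (closed-system inversion)
#'
#' Solves `total_ligand_of_free(l) = l_tot` for the free ligand level in a
#' closed (biochemical-well) system by Brent-type bracketed root finding on
#' \[0, l_tot\]; the bracket is guaranteed because bound ligand is
#' non-negative and the map is strictly increasing.
#'
#' @inheritParams clt_given_free_ligand
#' @param l_tot Total ligand concentration(s), nM, >= 0. Vectorised.
#' @return Free ligand concentration(s), nM.
#' @examples
#' sys <- ternary_system(100, 1e5, 100, c_tot = 1000, t_tot = 5)
#' free_ligand_of_total(sys, 1000)  # 269 nM
#' @export
free_ligand_of_total <- function(system, l_tot) {
  system <- as_ternary_system(system)
  if (any(!is.finite(l_tot)) || any(l_tot < 0))
    stop("'l_tot' must be finite and >= 0", call. = FALSE)
  vapply(l_tot, function(lt) free_of_total_one(system, lt), numeric(1))
}

free_of_total_one <- function(s, l_tot) {
  if (l_tot == 0) return(0)
  if (s$c_tot == 0 && s$t_tot == 0) return(l_tot)
  f <- function(l) total_ligand_of_free(s, l) - l_tot
  # f(0) = -l_tot < 0, f(l_tot) >= 0: sign change guaranteed
  res <- stats::uniroot(f, interval = c(0, l_tot), tol = 1e-12 * l_tot,
                        maxiter = 200L)
  if (abs(res$f.root) > 1e-6 * l_tot)
    stop(sprintf(
      "free-ligand inversion did not converge: residual %.3g on [0, %g]",
      res$f.root, l_tot), call. = FALSE)
  res$root
}

#' Full equilibrium state at a given total-ligand level
#'
#' Composition of [free_ligand_of_total()] and [state_from_free_ligand()]:
#' the closed-system state in which the applied total ligand is conserved.
#'
#' @inheritParams free_ligand_of_total
#' @param l_tot Total ligand concentration, nM (scalar).
#' @return An `equilibrium_state` whose `l_tot_implied` equals `l_tot`.
#' @export
state_from_total_ligand <- function(system, l_tot) {
  system <- as_ternary_system(system)
  state_from_free_ligand(system, free_ligand_of_total(system, l_tot))
}

#' Free-ligand position of the ternary-complex maximum
#'
#' The CLT-versus-free-ligand curve is a symmetric bell ("hook effect"):
#' the quadratic's L-dependent coefficient is invariant under
#' `L -> k_c1*k_t1/L`, so the maximum sits at `sqrt(k_c1*k_t1)` regardless
#' of alpha and the protein totals. The argmax is located numerically by
#' bounded maximisation on a log10 axis and cross-checked against the
#' closed form; a discrepancy raises an error.
#'
#' @inheritParams clt_given_free_ligand
#' @return Free ligand concentration at maximal \[CLT\], nM.
#' @export
free_ligand_at_max_clt <- function(system) {
  s <- as_ternary_system(system)
  if (s$c_tot <= 0 || s$t_tot <= 0)
    stop("argmax undefined: c_tot and t_tot must be > 0", call. = FALSE)
  centre <- 0.5 * (log10(s$k_c1) + log10(s$k_t1))
  opt <- stats::optimize(function(lg) -clt_one(s, 10^lg),
                         interval = centre + c(-6, 6), tol = 1e-10)
  l_hat <- 10^opt$minimum
  l_closed <- sqrt(s$k_c1 * s$k_t1)
  if (abs(l_hat - l_closed) > 1e-6 * l_closed &&
      abs(clt_one(s, l_hat) - clt_one(s, l_closed)) >
        1e-9 * max(clt_one(s, l_closed), .Machine$double.xmin))
    stop("numerical argmax disagrees with sqrt(k_c1*k_t1)", call. = FALSE)
  l_closed
}

#' Total-ligand position of the ternary-complex maximum
#'
#' Maps the free-ligand argmax through the ligand bookkeeping relation.
#' In a closed system this exceeds the free-ligand argmax by the ligand
#' sequestered in complexes, so the CLT-versus-total-ligand curve loses the
#' geometric symmetry it has on the free-ligand axis.
#'
#' @inheritParams clt_given_free_ligand
#' @return Total ligand concentration at maximal \[CLT\], nM.
#' @export
ltot_at_max_clt <- function(system) {
  system <- as_ternary_system(system)
  total_ligand_of_free(system, free_ligand_at_max_clt(system))
}
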