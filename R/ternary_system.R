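#' Define a cooperative ternary-complex system
#'
#' Constructs and validates the parameter set of the three-body equilibrium
#' C + L + T <-> CLT formed through the binary intermediates CL and TL.
#' All concentrations and dissociation constants are in nM; no unit
#' conversion is performed anywhere in the package.
#'
#' The derived constants follow from path independence of the Gibbs free
#' energy: `k_c2 = k_c1/alpha`, `k_t2 = k_t1/alpha`, and the ternary potency
#' constant `k_clt = k_c1 * k_t2 = k_c1 * k_t1 / alpha`.
#'
#' @param k_c1 Dissociation constant of free ligand to free chaperone (nM).
#' @param k_t1 Dissociation constant of free ligand to free target (nM).
#' @param alpha Intrinsic cooperativity (dimensionless, > 0). Values below 1
#'   denote negative cooperativity and are permitted.
#' @param c_tot Total chaperone concentration (nM, >= 0).
#' @param t_tot Total target concentration (nM, >= 0).
#'
#' @return An object of class `ternary_system`: a list with the five input
#'   parameters plus derived `k_c2`, `k_t2`, `k_clt`.
#' @examples
#' sys <- ternary_system(k_c1 = 100, k_t1 = 1e5, alpha = 100,
#'                       c_tot = 1000, t_tot = 5)
#' sys$k_c2   # 1 nM
#' @export
ternary_system <- function(k_c1, k_t1, alpha, c_tot, t_tot) {
  chk_pos <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
      stop(sprintf("'%s' must be a single positive finite number (got %s)",
                   nm, format(x)), call. = FALSE)
  }
  chk_nonneg <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
      stop(sprintf("'%s' must be a single non-negative finite number (got %s)",
                   nm, format(x)), call. = FALSE)
  }
  chk_pos(k_c1, "k_c1"); chk_pos(k_t1, "k_t1"); chk_pos(alpha, "alpha")
  chk_nonneg(c_tot, "c_tot"); chk_nonneg(t_tot, "t_tot")
  structure(
    list(k_c1 = as.numeric(k_c1), k_t1 = as.numeric(k_t1),
         alpha = as.numeric(alpha),
         c_tot = as.numeric(c_tot), t_tot = as.numeric(t_tot),
         k_c2 = k_c1 / alpha, k_t2 = k_t1 / alpha,
         k_clt = k_c1 * k_t1 / alpha),
    class = "ternary_system")
}

#' @export
print.ternary_system <- function(x, ...) {
  cat("Ternary complex system (all concentrations in nM)\n")
  cat(sprintf("  K_C,1 = %g   K_T,1 = %g   alpha = %g\n",
              x$k_c1, x$k_t1, x$alpha))
  cat(sprintf("  K_C,2 = %g   K_T,2 = %g   K_CLT = %g nM^2\n",
              x$k_c2, x$k_t2, x$k_clt))
  cat(sprintf("  [C_tot] = %g   [T_tot] = %g\n", x$c_tot, x$t_tot))
  invisible(x)
}

as_ternary_system <- function(x) {
  if (inherits(x, "ternary_system")) return(x)
  stop("expected a 'ternary_system' object; see ternary_system()",
       call. = FALSE)
}
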