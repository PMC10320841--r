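#' Generate a synthetic noisy binding curve
#'
#' Produces an observed bound-fraction curve from the equilibrium model with
#' additive Gaussian noise, as a stand-in for an experimentally measured
#' binding readout in tests, demos and parameter-recovery studies. Noise is
#' added on the bound-fraction scale (sd `sigma`, uniform weighting) and the
#' observed values are truncated to \[0, 1\]. Output is reproducible
#' bit-for-bit for a fixed `(system, grid, sigma, seed)`.
#'
#' @param system A [ternary_system()] (the generating truth).
#' @param lmin,lmax,points Log-spaced total-ligand grid, nM.
#' @param monitor `"c_bound"` or `"t_bound"`.
#' @param sigma Noise standard deviation on the bound fraction (>= 0).
#' @param seed Integer seed; the generator uses an isolated RNG state and
#'   does not disturb the caller's.
#' @return A data.frame of class `noisy_curve` with columns `l_tot_nM`,
#'   `true_bound_fraction`, `bound_fraction`; the generating system, monitor,
#'   `sigma` and `seed` are stored as attributes.
#' @examples
#' sys <- ternary_system(100, 1e5, 200, c_tot = 5, t_tot = 1000)
#' nc <- generate_noisy_curve(sys, 0.1, 1e6, points = 12, sigma = 0.02,
#'                            seed = 1)
#' @export
generate_noisy_curve <- function(system, lmin, lmax, points = 12L,
                                 monitor = c("c_bound", "t_bound"),
                                 sigma = 0, seed = 1L) {
  s <- as_ternary_system(system)
  monitor <- match.arg(monitor)
  if (!is.finite(sigma) || sigma < 0)
    stop("'sigma' must be >= 0", call. = FALSE)
  if (!is.finite(lmin) || !is.finite(lmax) || lmin <= 0 || lmax <= lmin)
    stop("grid requires 0 < lmin < lmax", call. = FALSE)
  if (points < 2L) stop("grid requires at least 2 points", call. = FALSE)
  grid <- 10^seq(log10(lmin), log10(lmax), length.out = points)
  f <- bound_fraction_fun(s, monitor, "total_ligand")
  truth <- vapply(grid, f, numeric(1))
  obs <- if (sigma == 0) truth else {
    noise <- withr::with_seed(as.integer(seed), stats::rnorm(points, 0, sigma))
    pmin(pmax(truth + noise, 0), 1)
  }
  structure(
    data.frame(l_tot_nM = grid, true_bound_fraction = truth,
               bound_fraction = obs),
    system = s, monitor = monitor, sigma = sigma, seed = as.integer(seed),
    class = c("noisy_curve", "data.frame"))
}

#' Write a synthetic noisy curve to CSV
#'
#' Serialises a [generate_noisy_curve()] table in the observed-curve CSV
#' dialect ('#' metadata comments, columns `l_tot_nM`, `bound_fraction`,
#' plus the noiseless truth), readable by [read_observed_curve_csv()].
#'
#' @param curve A `noisy_curve`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_noisy_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "noisy_curve"))
  s <- attr(curve, "system")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# ternaq synthetic curve: k_c1=%g k_t1=%g alpha=%g c_tot=%g t_tot=%g monitor=%s sigma=%g seed=%d",
    s$k_c1, s$k_t1, s$alpha, s$c_tot, s$t_tot, attr(curve, "monitor"),
    attr(curve, "sigma"), attr(curve, "seed")), con)
  utils::write.csv(as.data.frame(curve), con, row.names = FALSE)
  invisible(path)
}
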