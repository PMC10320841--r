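#' Simulate a binding curve over a ligand grid
#'
#' Evaluates the equilibrium state on a log-spaced ligand grid and reports
#' the monitored bound fractions used in binding experiments:
#' `pct_c_bound = (cl + clt)/c_tot * 100`,
#' `pct_t_bound = (tl + clt)/t_tot * 100`, and the ternary-complex shares
#' `pct_clt_of_target = clt/t_tot * 100`,
#' `pct_clt_of_chaperone = clt/c_tot * 100`.
#' Percentages whose reference total is zero are reported as `NA` (undefined),
#' never as 0/0.
#'
#' The grid is a presentation artifact: quantitative outputs such as EC50s
#' and hook maxima are computed on the continuous model
#' (see [ec50()], [free_ligand_at_max_clt()]), not by grid interpolation.
#'
#' @param system A [ternary_system()].
#' @param lmin,lmax Grid range, nM (0 < lmin < lmax).
#' @param points Number of log-spaced grid points (>= 2).
#' @param axis `"total_ligand"` (closed system; states via
#'   [state_from_total_ligand()]) or `"free_ligand"` (states via
#'   [state_from_free_ligand()]).
#' @return A `binding_curve`: a data.frame with columns `l_axis_nM`,
#'   `l_free_nM`, `c_free_nM`, `t_free_nM`, `cl_nM`, `tl_nM`, `clt_nM`,
#'   `pct_c_bound`, `pct_t_bound`, `pct_clt_of_target`,
#'   `pct_clt_of_chaperone`, with the system and axis stored as attributes.
#' @examples
#' sys <- ternary_system(100, 1e5, 200, c_tot = 5, t_tot = 1000)
#' bc <- simulate_curve(sys, 0.1, 1e6, points = 50)
#' head(bc)
#' @export
simulate_curve <- function(system, lmin, lmax, points = 200L,
                           axis = c("total_ligand", "free_ligand")) {
  s <- as_ternary_system(system)
  axis <- match.arg(axis)
  if (!is.finite(lmin) || !is.finite(lmax) || lmin <= 0 || lmax <= lmin)
    stop("grid requires 0 < lmin < lmax", call. = FALSE)
  if (points < 2L) stop("grid requires at least 2 points", call. = FALSE)
  grid <- 10^seq(log10(lmin), log10(lmax), length.out = points)
  states <- lapply(grid, function(l)
    if (axis == "total_ligand") state_from_total_ligand(s, l)
    else state_from_free_ligand(s, l))
  col <- function(nm) vapply(states, `[[`, numeric(1), nm)
  pct <- function(num, tot) if (tot > 0) num / tot * 100 else rep(NA_real_, points)
  cl <- col("cl"); tl <- col("tl"); clt <- col("clt")
  out <- data.frame(
    l_axis_nM = grid,
    l_free_nM = col("l_free"),
    c_free_nM = col("c_free"),
    t_free_nM = col("t_free"),
    cl_nM = cl, tl_nM = tl, clt_nM = clt,
    pct_c_bound = pct(cl + clt, s$c_tot),
    pct_t_bound = pct(tl + clt, s$t_tot),
    pct_clt_of_target = pct(clt, s$t_tot),
    pct_clt_of_chaperone = pct(clt, s$c_tot))
  structure(out, system = s, axis = axis,
            class = c("binding_curve", "data.frame"))
}

# Monitored bound fraction (0..1) as a continuous function of the ligand axis.
bound_fraction_fun <- function(s, monitor = c("c_bound", "t_bound"),
                               axis = c("total_ligand", "free_ligand")) {
  monitor <- match.arg(monitor)
  axis <- match.arg(axis)
  tot <- if (monitor == "c_bound") s$c_tot else s$t_tot
  if (tot <= 0)
    stop(sprintf("monitored total is zero: cannot monitor %s", monitor),
         call. = FALSE)
  function(l) {
    st <- if (axis == "total_ligand") state_from_total_ligand(s, l)
          else state_from_free_ligand(s, l)
    if (monitor == "c_bound") (st$cl + st$clt) / tot
    else (st$tl + st$clt) / tot
  }
}

#' Half-maximal concentration of a monitored bound fraction
#'
#' Computes the EC50 of a simulated binding readout (percent bound chaperone
#' or target) as the ligand concentration at half the saturating plateau of
#' the monitored bound fraction. The plateau is the bound fraction at the
#' bracket maximum and must be saturated (>= 99% of the value at 100x the
#' bracket maximum); if not, the bracket is extended tenfold up to three
#' times before erroring. The EC50 itself is found by bracketed root finding
#' on the continuous model, never by grid interpolation.
#'
#' Note the plateau reference: EC50 is half of the achieved plateau, not
#' half of 100%, so the definition stays meaningful for readouts that
#' saturate below full occupancy.
#'
#' @inheritParams simulate_curve
#' @param monitor `"c_bound"` ((CL+CLT)/C_tot) or `"t_bound"` ((TL+CLT)/T_tot).
#' @param bracket Numeric length-2 search interval, nM.
#' @return An `ec50_result`: list with `ec50` (nM), `monitor`, `axis`,
#'   `plateau` (saturating bound fraction, 0..1) and `bracket`.
#' @examples
#' sys <- ternary_system(100, 1e5, 200, c_tot = 5, t_tot = 1000)
#' ec50(sys, monitor = "c_bound")$ec50  # ~37 nM
#' @export
ec50 <- function(system, monitor = c("c_bound", "t_bound"),
                 axis = c("total_ligand", "free_ligand"),
                 bracket = c(1e-3, 1e7)) {
  s <- as_ternary_system(system)
  monitor <- match.arg(monitor)
  axis <- match.arg(axis)
  if (length(bracket) != 2L || any(bracket <= 0) || bracket[2] <= bracket[1])
    stop("'bracket' must be two increasing positive concentrations",
         call. = FALSE)
  f <- bound_fraction_fun(s, monitor, axis)
  for (try in 0:3) {
    at_max <- f(bracket[2])
    if (at_max > 0 && at_max >= 0.99 * f(100 * bracket[2])) break
    if (try == 3)
      stop(sprintf(
        "EC50 not identifiable in bracket [%g, %g]: bound fraction not saturated",
        bracket[1], bracket[2]), call. = FALSE)
    bracket[2] <- bracket[2] * 10
  }
  # asymptotic reference evaluated at a system-determined saturating level,
  # so the EC50 does not move when the (already saturated) bracket is refined
  l_sat <- 1e6 * max(s$k_c1, s$k_t1, s$c_tot + s$t_tot, 1)
  plateau <- f(l_sat)
  g <- function(l) f(l) - plateau / 2
  if (g(bracket[1]) >= 0) bracket[1] <- bracket[1] * 1e-3
  res <- stats::uniroot(g, interval = bracket, tol = 1e-10 * bracket[2],
                        maxiter = 200L)
  structure(list(ec50 = res$root, monitor = monitor, axis = axis,
                 plateau = plateau, bracket = bracket),
            class = "ec50_result")
}

#' @export
print.ec50_result <- function(x, ...) {
  cat(sprintf("EC50 (%s, %s axis): %g nM  [plateau %.3f]\n",
              x$monitor, x$axis, x$ec50, x$plateau))
  invisible(x)
}

#' Write a binding curve to CSV
#'
#' Serialises a [simulate_curve()] table as comma-separated values with a
#' '#'-prefixed metadata header recording the system parameters and axis.
#'
#' @param curve A `binding_curve`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_curve_csv <- function(curve, path) {
  stopifnot(inherits(curve, "binding_curve"))
  s <- attr(curve, "system")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# ternaq binding curve: k_c1=%g k_t1=%g alpha=%g c_tot=%g t_tot=%g axis=%s (nM)",
    s$k_c1, s$k_t1, s$alpha, s$c_tot, s$t_tot, attr(curve, "axis")), con)
  utils::write.csv(as.data.frame(curve), con, row.names = FALSE)
  invisible(path)
}

#' Read an observed binding curve from CSV
#'
#' Reads a two-column table of total ligand (nM) and observed bound fraction
#' (0..1), as produced by [write_noisy_curve_csv()] or by an experimental
#' export. Lines starting with '#' are treated as comments.
#'
#' @param path CSV file with columns `l_tot_nM` and `bound_fraction`.
#' @return A data.frame with columns `l_tot_nM`, `bound_fraction`.
#' @export
read_observed_curve_csv <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("l_tot_nM", "bound_fraction")
  if (!all(need %in% names(df)))
    stop("observed curve CSV must have columns l_tot_nM, bound_fraction",
         call. = FALSE)
  df[need]
}
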