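#' Apparent cooperativity from an EC50 shift
#'
#' The apparent cooperativity of a monitored binding readout is the ratio of
#' the EC50 measured without the counter protein (a clean binary reference,
#' counter-protein total set to 0) to the EC50 with the counter protein
#' present, both on the total-ligand axis. Values > 1 indicate positive
#' apparent cooperativity. Unlike the intrinsic alpha, this ratio depends on
#' the protein concentrations and on which protein is monitored.
#'
#' @param system A [ternary_system()]; its `c_tot`/`t_tot` are the
#'   "counter present" condition.
#' @param monitor `"c_bound"` or `"t_bound"`.
#' @param ec50_without,ec50_with Optional measured EC50s (nM); when both are
#'   supplied the ratio `ec50_without / ec50_with` is returned directly and
#'   no simulation is run.
#' @return Dimensionless apparent cooperativity.
#' @examples
#' sys <- ternary_system(100, 1e5, 200, c_tot = 5, t_tot = 1000)
#' apparent_cooperativity(sys, "c_bound")  # ~2.7
#' @export
apparent_cooperativity <- function(system, monitor = c("c_bound", "t_bound"),
                                   ec50_without = NULL, ec50_with = NULL) {
  monitor <- match.arg(monitor)
  if (!is.null(ec50_without) && !is.null(ec50_with)) {
    if (ec50_without <= 0 || ec50_with <= 0)
      stop("measured EC50s must be positive", call. = FALSE)
    return(ec50_without / ec50_with)
  }
  s <- as_ternary_system(system)
  base <- if (monitor == "c_bound")
    ternary_system(s$k_c1, s$k_t1, s$alpha, s$c_tot, t_tot = 0)
  else
    ternary_system(s$k_c1, s$k_t1, s$alpha, c_tot = 0, s$t_tot)
  ec50(base, monitor)$ec50 / ec50(s, monitor)$ec50
}

# Model EC50 on the total-ligand axis as a function of alpha, holding the
# binary constants and totals fixed.
model_ec50_of_alpha <- function(k_c1, k_t1, c_tot, t_tot, monitor) {
  function(alpha)
    ec50(ternary_system(k_c1, k_t1, alpha, c_tot, t_tot), monitor)$ec50
}

#' Retrieve intrinsic cooperativity from a measured EC50
#'
#' Inverts the model's EC50-versus-alpha relationship: finds the unique
#' intrinsic cooperativity alpha whose simulated EC50 (total-ligand axis,
#' chosen monitor) matches an observed EC50. The search runs on log10(alpha)
#' over \[1e-6, 1e9\] with bracketed root finding, exploiting that the model
#' EC50 decreases monotonically in alpha; monotonicity at the bracket
#' endpoints is asserted before the search. Both binary dissociation
#' constants must be known — with only one, an EC50 shift cannot be
#' attributed uniquely to cooperativity.
#'
#' @param k_c1,k_t1 Binary dissociation constants, nM. `NA` marks an
#'   unmeasurably weak affinity (> 250 uM) and is replaced by
#'   `kd_ceiling`.
#' @param c_tot,t_tot Protein totals, nM, in the assay with the counter
#'   protein present.
#' @param observed_ec50 Measured EC50 of the monitored bound fraction, nM.
#' @param monitor `"c_bound"` or `"t_bound"`.
#' @param kd_ceiling Stand-in dissociation constant for unmeasurable
#'   affinities, nM.
#' @param tol Relative tolerance on the matched EC50.
#' @return An `alpha_fit`: list with `alpha_hat`, `target_ec50`,
#'   `achieved_ec50`, `monitor`, `bracket`, `converged`, `iterations`,
#'   and `kd_imputed` flagging ceiling substitution.
#' @examples
#' fit <- fit_alpha_from_ec50(100, 1e5, c_tot = 5, t_tot = 1000,
#'                            observed_ec50 = 37, monitor = "c_bound")
#' fit$alpha_hat  # ~200
#' @export
fit_alpha_from_ec50 <- function(k_c1, k_t1, c_tot, t_tot, observed_ec50,
                                monitor = c("c_bound", "t_bound"),
                                kd_ceiling = 1e6, tol = 1e-6) {
  monitor <- match.arg(monitor)
  kd_imputed <- is.na(k_c1) || is.na(k_t1)
  if (is.na(k_c1)) k_c1 <- kd_ceiling
  if (is.na(k_t1)) k_t1 <- kd_ceiling
  if (!is.finite(observed_ec50) || observed_ec50 <= 0)
    stop("'observed_ec50' must be positive", call. = FALSE)
  mod <- model_ec50_of_alpha(k_c1, k_t1, c_tot, t_tot, monitor)
  lg_lo <- -6; lg_hi <- 9
  e_lo <- mod(10^lg_lo)   # alpha -> 0 limit: weakest shift, largest EC50
  e_hi <- mod(10^lg_hi)   # alpha -> inf limit: smallest attainable EC50
  if (e_lo <= e_hi)
    stop("model EC50 is not decreasing in alpha over the search bracket",
         call. = FALSE)
  if (observed_ec50 > e_lo || observed_ec50 < e_hi)
    stop(sprintf(
      paste0("shift not explainable by cooperativity: observed EC50 %g nM ",
             "outside attainable range [%g, %g] nM"),
      observed_ec50, e_hi, e_lo), call. = FALSE)
  g <- function(lg) log(mod(10^lg)) - log(observed_ec50)
  res <- stats::uniroot(g, interval = c(lg_lo, lg_hi), tol = 1e-12,
                        maxiter = 200L)
  alpha_hat <- 10^res$root
  achieved <- mod(alpha_hat)
  structure(list(alpha_hat = alpha_hat, target_ec50 = observed_ec50,
                 achieved_ec50 = achieved, monitor = monitor,
                 bracket = c(10^lg_lo, 10^lg_hi),
                 converged = abs(achieved - observed_ec50) <=
                   tol * observed_ec50,
                 iterations = res$iter, kd_imputed = kd_imputed),
            class = "alpha_fit")
}

#' @export
print.alpha_fit <- function(x, ...) {
  cat(sprintf("alpha_hat = %g (%s; EC50 target %g nM, achieved %g nM; %s)\n",
              x$alpha_hat, x$monitor, x$target_ec50, x$achieved_ec50,
              if (isTRUE(x$converged)) "converged" else "NOT converged"))
  if (!is.null(x$residual_norm))
    cat(sprintf("  residual norm = %g over %d points\n",
                x$residual_norm, x$n_points))
  invisible(x)
}

#' Retrieve intrinsic cooperativity from observed binding curves
#'
#' Least-squares fit of log10(alpha) to one or several observed bound-
#' fraction curves, minimising the summed squared residuals between observed
#' and model bound fractions on the total-ligand axis. Several curves
#' recorded at different protein concentrations are fitted jointly, which
#' stabilises the estimate when single curves are noisy.
#'
#' @inheritParams fit_alpha_from_ec50
#' @param curves A data.frame with columns `l_tot_nM` and `bound_fraction`
#'   (0..1), or a list of such data.frames. A list element may carry
#'   attributes `c_tot`/`t_tot` overriding the shared totals.
#' @param monitor `"c_bound"` or `"t_bound"`.
#' @return An `alpha_fit` with `residual_norm` and `n_points` in addition
#'   to the EC50-fit fields (the achieved/target EC50s are the model EC50 at
#'   the fitted alpha, reported for reference).
#' @export
fit_alpha_from_curve <- function(k_c1, k_t1, c_tot, t_tot, curves,
                                 monitor = c("c_bound", "t_bound"),
                                 kd_ceiling = 1e6) {
  monitor <- match.arg(monitor)
  kd_imputed <- is.na(k_c1) || is.na(k_t1)
  if (is.na(k_c1)) k_c1 <- kd_ceiling
  if (is.na(k_t1)) k_t1 <- kd_ceiling
  if (is.data.frame(curves)) curves <- list(curves)
  curves <- lapply(curves, function(cv) {
    if (!all(c("l_tot_nM", "bound_fraction") %in% names(cv)))
      stop("each curve needs columns l_tot_nM and bound_fraction",
           call. = FALSE)
    if (nrow(cv) < 3L)
      stop("each curve needs at least 3 points", call. = FALSE)
    cv
  })
  # identifiability: the pooled observations must leave a plateau
  bf <- unlist(lapply(curves, `[[`, "bound_fraction"))
  if (max(bf) - min(bf) < 0.05)
    stop("curve not identifiable: all points lie on a plateau", call. = FALSE)
  ssr <- function(lg_alpha) {
    alpha <- 10^lg_alpha
    sum(vapply(curves, function(cv) {
      ct <- attr(cv, "c_tot"); tt <- attr(cv, "t_tot")
      s <- ternary_system(k_c1, k_t1, alpha,
                          if (is.null(ct)) c_tot else ct,
                          if (is.null(tt)) t_tot else tt)
      f <- bound_fraction_fun(s, monitor, "total_ligand")
      sum((vapply(cv$l_tot_nM, f, numeric(1)) - cv$bound_fraction)^2)
    }, numeric(1)))
  }
  opt <- stats::optimize(ssr, interval = c(-6, 9), tol = 1e-10)
  alpha_hat <- 10^opt$minimum
  mod <- model_ec50_of_alpha(k_c1, k_t1, c_tot, t_tot, monitor)
  achieved <- mod(alpha_hat)
  structure(list(alpha_hat = alpha_hat, target_ec50 = achieved,
                 achieved_ec50 = achieved, monitor = monitor,
                 bracket = c(1e-6, 1e9), converged = TRUE,
                 iterations = NA_integer_, kd_imputed = kd_imputed,
                 residual_norm = sqrt(opt$objective),
                 n_points = length(bf)),
            class = "alpha_fit")
}

#' Classify a ternary complex-forming compound
#'
#' Places a compound in the bifunctional/molecular-glue taxonomy from its
#' binary affinities and intrinsic cooperativity. "Significant" binary
#' binding means K_d below 1000 nM. Both affinities significant gives a
#' bifunctional, or a cooperative bifunctional when alpha > 10;
#' chaperone-only significant binding with alpha > 100 gives a molecular
#' glue of type I; neither affinity significant with alpha > 1000 gives a
#' molecular glue of type II; everything else is an unclassified/hybrid.
#' Glues of type III (acting through a pre-formed chaperone–target complex)
#' are outside this model.
#'
#' @inheritParams fit_alpha_from_ec50
#' @param alpha Intrinsic cooperativity.
#' @param kd_significant Significance threshold on the binary K_d, nM.
#' @return A length-1 character label, one of `"bifunctional"`,
#'   `"cooperative bifunctional"`, `"molecular glue I"`,
#'   `"molecular glue II"`, `"unclassified/hybrid"`.
#' @examples
#' classify_compound(100, 3e5, alpha = 500)   # molecular glue I
#' @export
classify_compound <- function(k_c1, k_t1, alpha, kd_significant = 1000,
                              kd_ceiling = 1e6) {
  if (is.na(k_c1)) k_c1 <- kd_ceiling
  if (is.na(k_t1)) k_t1 <- kd_ceiling
  if (k_c1 <= 0 || k_t1 <= 0 || alpha <= 0)
    stop("k_c1, k_t1 and alpha must be positive", call. = FALSE)
  c_sig <- k_c1 < kd_significant
  t_sig <- k_t1 < kd_significant
  if (c_sig && t_sig) {
    if (alpha > 10) "cooperative bifunctional" else "bifunctional"
  } else if (c_sig && !t_sig && alpha > 100) {
    "molecular glue I"
  } else if (!c_sig && !t_sig && alpha > 1000) {
    "molecular glue II"
  } else {
    "unclassified/hybrid"
  }
}
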