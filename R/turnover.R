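# The demethylation-cycle state model.
#
# A CpG site cycles through three states: unmethylated C, methylated 5-mC,
# and hydroxymethylated 5-hmC.  Methylation C -> 5-mC proceeds at a fixed
# unit rate; the first TET oxidation 5-mC -> 5-hmC at rate tau; the
# further oxidation to 5-fC/5-caC plus glycosylase excision and repair
# back to C is lumped into a single step 5-hmC -> C at rate rho.  Both
# rates are dimensionless (relative to the unit methylation rate): only
# ratios are identifiable from observed state proportions.  At the unique
# equilibrium the proportions are proportional to (1, 1/tau, 1/rho), so
# tau = %C/%5-mC and rho = %C/%5-hmC.

#' Right-hand side of the demethylation-cycle ODE
#'
#' dC/dt = rho*H - C; dM/dt = C - tau*M; dH/dt = tau*M - rho*H.
#' The components sum to zero (total mass is conserved).
#'
#' @param state Numeric vector `(C, MC, HMC)` of state proportions.
#' @param tau,rho Positive turnover rates.
#' @return Derivative vector `(dC, dMC, dHMC)`.
#' @export
#' @examples
#' ode_rhs(c(1, 0, 0), tau = 2, rho = 4)  # mass leaves C at unit rate
ode_rhs <- function(state, tau, rho) {
  stopifnot(length(state) == 3L, tau > 0, rho > 0)
  state <- unname(state)
  c(rho * state[3L] - state[1L],
    state[1L] - tau * state[2L],
    tau * state[2L] - rho * state[3L])
}

#' Closed-form equilibrium of the demethylation cycle
#'
#' The cycle's unique attracting fixed point: proportions proportional to
#' `(1, 1/tau, 1/rho)`, normalized to sum to 1.
#'
#' @param tau,rho Positive turnover rates.
#' @return Named numeric vector `c(C =, MC =, HMC =)` summing to 1.
#' @export
#' @examples
#' turnover_equilibrium(1, 1)   # (1/3, 1/3, 1/3)
#' turnover_equilibrium(2, 4)   # (4/7, 2/7, 1/7)
turnover_equilibrium <- function(tau, rho) {
  stopifnot(tau > 0, rho > 0)
  w <- c(C = 1, MC = 1 / tau, HMC = 1 / rho)
  w / sum(w)
}

#' Integrate the cycle ODE to its equilibrium
#'
#' Numerically integrates the state model until the maximum absolute
#' derivative falls below `tol`.  The equilibrium is independent of the
#' initial state; this integrator is retained as a testing oracle for the
#' closed form and for non-equilibrium extensions.
#'
#' @param tau,rho Positive turnover rates.
#' @param init Initial state (three non-negative proportions summing
#'   to 1).
#' @param tol Convergence tolerance on the derivatives.
#' @param max_time Integration horizon; exceeded means non-convergence.
#' @return Named state vector at equilibrium, with attributes `time`
#'   (time of convergence) and `max_deriv`.
#' @export
simulate_to_equilibrium <- function(tau, rho, init = c(C = 1, MC = 0, HMC = 0),
                                    tol = 1e-9, max_time = 1e6) {
  stopifnot(tau > 0, rho > 0, tol > 0, length(init) == 3L)
  if (any(init < 0) || abs(sum(init) - 1) > 1e-9)
    stop("init must be non-negative proportions summing to 1",
         call. = FALSE)
  fn <- function(t, y, parms) list(ode_rhs(y, tau, rho))
  rootfn <- function(t, y, parms) max(abs(ode_rhs(y, tau, rho))) - tol
  sol <- deSolve::lsodar(y = unname(init), times = c(0, max_time),
                         func = fn, parms = NULL, rootfunc = rootfn,
                         rtol = tol * 1e-3, atol = tol * 1e-3)
  final <- sol[nrow(sol), -1L]
  md <- max(abs(ode_rhs(final, tau, rho)))
  if (is.null(attr(sol, "iroot")) && md > tol)
    stop(sprintf(paste0("equilibrium not reached within t = %g ",
                        "(max |derivative| = %.3g, state = %s)"),
                 max_time, md, paste(signif(final, 6), collapse = ", ")),
         call. = FALSE)
  out <- setNames(as.numeric(final), c("C", "MC", "HMC"))
  attr(out, "time") <- unname(sol[nrow(sol), 1L])
  attr(out, "max_deriv") <- md
  out
}

#' Estimate turnover rates from observed base proportions
#'
#' Point estimates of the cycle rates from the equilibrium distribution:
#' with %C = 100 - %5-mC - %5-hmC,
#' `tau = %C / %5-mC` and `rho = %C / %5-hmC`.  The observed proportions
#' are typically mean modified fractions over CpG sites of a region class
#' (enhancers of PBMCs for the headline analysis), expressed in percent.
#'
#' @param pct_mc Observed %5-mC (0 < value).
#' @param pct_hmc Observed %5-hmC (0 < value); `pct_mc + pct_hmc < 100`.
#' @param sample_id,timepoint_months,region Optional provenance fields
#'   stored on the object.
#' @return An object of class `turnover_rates`: a list with `tau`, `rho`,
#'   `pct` (named percent vector C/MC/HMC) and the provenance fields.
#'   Methods: [print()], [coef()] (returns `c(tau, rho)`), [fitted()]
#'   (equilibrium proportions implied by the rates) and [simulate()]
#'   (synthetic site-call tables at the fitted equilibrium).
#' @export
#' @examples
#' r <- estimate_rates(25, 25)        # tau = 2, rho = 2
#' coef(estimate_rates(60, 3))        # enhancer-like magnitudes
estimate_rates <- function(pct_mc, pct_hmc, sample_id = NULL,
                           timepoint_months = NULL, region = NULL) {
  if (!is.finite(pct_hmc) || pct_hmc <= 0)
    stop("rho undefined: %5-hmC must be positive", call. = FALSE)
  if (!is.finite(pct_mc) || pct_mc <= 0)
    stop("tau undefined: %5-mC must be positive", call. = FALSE)
  if (pct_mc + pct_hmc >= 100)
    stop("%5-mC + %5-hmC must be below 100 (no unmodified C left)",
         call. = FALSE)
  pct_c <- 100 - pct_mc - pct_hmc
  structure(list(tau = pct_c / pct_mc, rho = pct_c / pct_hmc,
                 pct = c(C = pct_c, MC = pct_mc, HMC = pct_hmc),
                 sample_id = sample_id,
                 timepoint_months = timepoint_months, region = region),
            class = "turnover_rates")
}

#' @export
print.turnover_rates <- function(x, ...) {
  cat("Demethylation-cycle turnover rates",
      if (!is.null(x$sample_id)) paste0("(", x$sample_id,
        if (!is.null(x$timepoint_months))
          paste0(", ", x$timepoint_months, " months"), ")"), "\n")
  cat(sprintf("  observed: %%C = %.3f, %%5-mC = %.3f, %%5-hmC = %.3f\n",
              x$pct["C"], x$pct["MC"], x$pct["HMC"]))
  cat(sprintf("  tau (first oxidation)        = %.4f\n", x$tau))
  cat(sprintf("  rho (further oxidation+repair) = %.4f\n", x$rho))
  invisible(x)
}

#' @export
coef.turnover_rates <- function(object, ...) {
  c(tau = object$tau, rho = object$rho)
}

#' @export
fitted.turnover_rates <- function(object, ...) {
  turnover_equilibrium(object$tau, object$rho)
}

#' Simulate site calls at the fitted equilibrium
#'
#' Draws per-site modified fractions from beta distributions centred on
#' the fitted equilibrium proportions (5-mC and 5-hmC marks), coverage
#' from a Poisson, and modified calls binomially — the same observation
#' model as [simulate_cohort()].
#'
#' @param object A `turnover_rates` object.
#' @param nsim Number of replicate tables.
#' @param seed Optional RNG seed.
#' @param n_sites Number of CpG sites per table.
#' @param coverage Mean read depth.
#' @param precision Beta concentration parameter.
#' @param ... Unused.
#' @return A list of `nsim` site-call data.frames (both marks stacked).
#' @export
simulate.turnover_rates <- function(object, nsim = 1, seed = NULL,
                                    n_sites = 1000, coverage = 20,
                                    precision = 30, ...) {
  if (!is.null(seed)) set.seed(seed)
  eq <- fitted(object)
  lapply(seq_len(nsim), function(i) {
    do.call(rbind, lapply(c(mc = "mc", hmc = "hmc"), function(mk) {
      m <- if (mk == "mc") eq[["MC"]] else eq[["HMC"]]
      f <- .draw_beta(n_sites, m, precision)
      cs <- .draw_coverage(n_sites, coverage)
      cm <- .draw_binom(cs, f)
      data.frame(chrom = "chr1", pos = seq_len(n_sites) * 2L - 2L,
                 mark = mk, called_sites = cs, called_modified = cm,
                 modified_fraction = ifelse(cs > 0L, cm / cs, NA_real_),
                 stringsAsFactors = FALSE)
    }))
  })
}

#' Percent change of turnover rates between two timepoints
#'
#' @param earlier,later `turnover_rates` objects (or named vectors with
#'   `tau` and `rho`).
#' @return Named vector `c(d_tau_pct, d_rho_pct)`:
#'   `100 * (later - earlier) / earlier` for each rate.
#' @export
#' @examples
#' rate_change(estimate_rates(60, 3.7), estimate_rates(60, 2.9))
rate_change <- function(earlier, later) {
  g <- function(x) if (inherits(x, "turnover_rates")) coef(x) else x
  e <- g(earlier); l <- g(later)
  stopifnot(all(c("tau", "rho") %in% names(e)),
            all(c("tau", "rho") %in% names(l)))
  if (e[["tau"]] <= 0 || e[["rho"]] <= 0)
    stop("earlier rates must be positive", call. = FALSE)
  c(d_tau_pct = 100 * (l[["tau"]] - e[["tau"]]) / e[["tau"]],
    d_rho_pct = 100 * (l[["rho"]] - e[["rho"]]) / e[["rho"]])
}

#' Estimate per-sample turnover rates for a cohort
#'
#' Extracts, for each sample and timepoint, the mean 5-mC and 5-hmC
#' fractions over one region class from region summaries (both marks
#' required) and applies [estimate_rates()].
#'
#' @param summaries Region summaries from [summarize_regions()].
#' @param cell_type,label Region class (default PBMC enhancers).
#' @return Data.frame: `sample_id`, `timepoint_months`, `pct_mc`,
#'   `pct_hmc`, `tau`, `rho`.
#' @export
cohort_rates <- function(summaries, cell_type = "PBMC", label = "Enh") {
  dt <- as.data.table(summaries)
  ct <- cell_type; lb <- label
  dt <- dt[dt$cell_type == ct & dt$label == lb]
  if (nrow(dt) == 0L)
    stop("no summaries for (", ct, ", ", lb, ")", call. = FALSE)
  wide <- dcast(dt, sample_id + timepoint_months ~ mark,
                value.var = "mean_fraction")
  if (!all(c("mc", "hmc") %in% names(wide)))
    stop("both marks (mc, hmc) are required to estimate rates",
         call. = FALSE)
  wide[, pct_mc := 100 * mc][, pct_hmc := 100 * hmc]
  res <- wide[, {
    r <- estimate_rates(pct_mc, pct_hmc)
    list(pct_mc = pct_mc, pct_hmc = pct_hmc, tau = r$tau, rho = r$rho)
  }, by = list(sample_id, timepoint_months)]
  as.data.frame(res)
}

#' Per-sample rate changes between two timepoints
#'
#' @param rates Data.frame from [cohort_rates()].
#' @param t0,t1 Earlier and later timepoints in months.
#' @return Data.frame: `sample_id`, `d_tau_pct`, `d_rho_pct`.
#' @export
cohort_rate_changes <- function(rates, t0 = 0, t1 = 12) {
  a <- rates[rates$timepoint_months == t0, ]
  b <- rates[rates$timepoint_months == t1, ]
  m <- merge(a[, c("sample_id", "tau", "rho")],
             b[, c("sample_id", "tau", "rho")],
             by = "sample_id", suffixes = c("_0", "_1"))
  data.frame(sample_id = m$sample_id,
             d_tau_pct = 100 * (m$tau_1 - m$tau_0) / m$tau_0,
             d_rho_pct = 100 * (m$rho_1 - m$rho_0) / m$rho_0,
             stringsAsFactors = FALSE)
}

#' Bivariate kernel density of rate changes
#'
#' Gaussian-kernel density of `(d_tau_pct, d_rho_pct)` points on a regular
#' grid.  Bandwidths follow Silverman's rule of thumb per axis
#' (`stats::bw.nrd0`) with a floor for degenerate (all-identical) inputs;
#' the grid spans the data range padded by 3 bandwidths, so the density
#' integrates to 1 up to quadrature error.
#'
#' @param changes Data.frame with `d_tau_pct`, `d_rho_pct` (>= 2 rows).
#' @param gridsize Number of grid points per axis.
#' @param pad Padding of the grid, in bandwidths.
#' @param bw_floor Minimum bandwidth.
#' @return Object of class `rate_kde`: list with `x`, `y`, grid matrix
#'   `z`, and `bandwidth`.
#' @export
kde_rate_changes <- function(changes, gridsize = 101, pad = 3,
                             bw_floor = 1e-3) {
  x <- changes$d_tau_pct; y <- changes$d_rho_pct
  if (length(x) < 2L) stop("need at least 2 points", call. = FALSE)
  bw1 <- function(v) {
    b <- tryCatch(stats::bw.nrd0(v), error = function(e) 0)
    max(b, bw_floor)
  }
  bx <- bw1(x); by <- bw1(y)
  # MASS::kde2d uses h/4 as the kernel standard deviation
  k <- MASS::kde2d(x, y, h = c(4 * bx, 4 * by), n = gridsize,
                   lims = c(min(x) - pad * bx, max(x) + pad * bx,
                            min(y) - pad * by, max(y) + pad * by))
  structure(list(x = k$x, y = k$y, z = k$z, bandwidth = c(bx, by)),
            class = "rate_kde")
}

#' @export
print.rate_kde <- function(x, ...) {
  cat(sprintf(paste0("Bivariate Gaussian KDE on a %d x %d grid\n",
                     "  bandwidths (Silverman): %.4g, %.4g\n"),
              length(x$x), length(x$y), x$bandwidth[1L], x$bandwidth[2L]))
  invisible(x)
}

#' @export
plot.rate_kde <- function(x, xlab = "change of tau (%)",
                          ylab = "change of rho (%)", ...) {
  image(x$x, x$y, x$z, col = hcl.colors(32, "YlOrRd", rev = TRUE),
        xlab = xlab, ylab = ylab, ...)
  contour(x$x, x$y, x$z, add = TRUE)
  abline(h = 0, v = 0, lty = 3)
  invisible(x)
}

#' Arrow plot of per-sample rate changes
#'
#' One arrow per sample from the origin to its
#' `(d_tau_pct, d_rho_pct)`, coloured by mutation status when a sample
#' sheet is supplied.
#'
#' @param changes Data.frame from [cohort_rate_changes()].
#' @param meta Optional sample sheet for colouring.
#' @param ... Passed to [plot()].
#' @return Invisibly, `changes`.
#' @export
plot_rate_arrows <- function(changes, meta = NULL, ...) {
  col <- rep("grey30", nrow(changes))
  if (!is.null(meta)) {
    meta1 <- meta[!duplicated(meta$sample_id), ]
    st <- meta1$mutation_status[match(changes$sample_id, meta1$sample_id)]
    col <- ifelse(st == "carrier", "firebrick", "steelblue")
  }
  lim <- function(v) range(c(0, v)) * 1.15
  plot(NA, xlim = lim(changes$d_tau_pct), ylim = lim(changes$d_rho_pct),
       xlab = "change of tau (%)", ylab = "change of rho (%)", ...)
  abline(h = 0, v = 0, lty = 3)
  arrows(0, 0, changes$d_tau_pct, changes$d_rho_pct, col = col,
         length = 0.08, lwd = 2)
  if (!is.null(meta))
    legend("topleft", legend = c("carrier", "control"), lwd = 2,
           col = c("firebrick", "steelblue"), bty = "n")
  invisible(changes)
}
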