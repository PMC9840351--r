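# Synthetic cohort generator.
#
# Emulates the statistical structure of a nanopore-derived methylation
# study: a blood cohort of mutation carriers and controls sampled at 0, 6
# and 12 months, per-CpG 5-mC/5-hmC call tables over a synthetic genome
# segmented into chromatin-state blocks, TF binding tracks nested in
# enhancers, and a sample sheet.
#
# Observation model.  CpG 5-mC is bimodal: each site is either a
# "methylated-type" locus (high mode) or an "unmethylated-type" locus
# (low mode), with the regional mixing proportion chosen so the regional
# mean matches the turnover model's equilibrium %5-mC.  5-hmC is low and
# unimodal.  Per-site true fractions are beta-distributed around the
# site's mode, coverage is Poisson, modified calls binomial.
# Individual (sample-level) variability is mostly count-type — a
# persistent per-sample jitter in the proportion of methylated-type loci,
# shared across labels — plus a small rate dispersion realised as a
# location shift of the modes.  The carrier hypermethylation overload
# upgrades low-mode sites within a subset of enhancer intervals to a
# near-saturated level, changing the shape of the distribution the
# hyper/hypo partition statistic sees and raising the level of
# sample-specific hypermethylated positions at the binding sites located
# in those intervals.

.draw_beta <- function(n, m, precision) {
  m <- pmin(pmax(m, 1e-6), 1 - 1e-6)
  if (!is.finite(precision)) return(rep_len(m, n))
  rbeta(n, m * precision, (1 - m) * precision)
}

.draw_coverage <- function(n, mean_cov) {
  if (!is.finite(mean_cov)) return(rep.int(1000000000L, n))
  rpois(n, mean_cov)
}

.draw_binom <- function(cs, f) {
  exact <- cs > 100000000L
  out <- integer(length(cs))
  if (any(exact)) out[exact] <- as.integer(round(cs[exact] * f[exact]))
  if (any(!exact)) out[!exact] <- rbinom(sum(!exact), cs[!exact], f[!exact])
  out
}

#' Default per-label modification profile
#'
#' Plausible mean 5-mC and 5-hmC percentages for the 15 chromatin states
#' of blood cells: low methylation at active promoters, high in
#' transcribed/quiescent chromatin, intermediate at enhancers (about 60%
#' 5-mC, 3% 5-hmC), and genome-wide hydroxymethylation below 5%
#' everywhere.
#'
#' @return Data.frame with columns `label`, `pct_mc`, `pct_hmc`.
#' @export
default_region_profile <- function() {
  data.frame(
    label = chromatin_states(),
    pct_mc = c(15, 30, 55, 70, 70, 60, 60, 75, 70, 25, 35, 50, 45, 60, 65),
    pct_hmc = c(2, 2.5, 3, 3.5, 3, 3.5, 3, 3, 2, 2, 2.5, 3, 2.5, 2.5, 2.5),
    stringsAsFactors = FALSE)
}

#' Configure a synthetic cohort
#'
#' Builds the configuration object consumed by [simulate_cohort()].  The
#' defaults describe the emulated study: 3 unaffected mutation carriers
#' vs 3 controls sampled at 0/6/12 months; a genome of chromatin-state
#' blocks (per label, `n_intervals` intervals of `sites_per_interval`
#' CpGs); enhancer 5-mC about 60% and 5-hmC about 3%; a carrier
#' hypermethylation overload of +2 %-points at enhancers, concentrated on
#' a subset of enhancer intervals and fading under the intervention
#' (retention 1, 0.5, 0 at 0, 6, 12 months); and an intervention effect
#' multiplying the responding carriers' repair rate rho by 1.3 at 6 and
#' 12 months.
#'
#' @param n_carriers,n_controls Unaffected carriers and controls (>= 2
#'   each for the group tests; defaults 3 and 3).
#' @param n_lymphoma Additional lymphoma-affected carriers: they keep the
#'   overload at all timepoints and do not respond to the intervention,
#'   and the group-comparison analyses exclude them.
#' @param timepoints Sampling timepoints in months.
#' @param cell_type,chrom Annotation cell type and chromosome name.
#' @param region_profile Data.frame `label`/`pct_mc`/`pct_hmc` of target
#'   equilibrium percentages per chromatin state; subset it to simulate
#'   fewer labels.
#' @param n_intervals Intervals per label.
#' @param sites_per_interval CpG sites per interval.
#' @param site_spacing,interval_gap Base-pair layout of the synthetic
#'   genome.
#' @param coverage_mean Mean read depth per site (Poisson); `Inf` for the
#'   noise-free limit.
#' @param beta_precision Beta concentration of per-site true fractions
#'   around the site's mode; `Inf` for no between-site dispersion.
#' @param mode_low,mode_high The two 5-mC modes (fractions): each site is
#'   an unmethylated-type or methylated-type locus; the regional mixing
#'   proportion reproduces the regional mean.
#' @param overload_level True fraction of overload-upgraded sites
#'   (near-saturated methylation, above the normal methylated-locus
#'   level).
#' @param p_high_jitter Per-sample SD of the methylated-type proportion
#'   (one persistent draw per sample, applied to every label): the
#'   dominant individual variability, a global excess or deficit in the
#'   number of methylated loci.
#' @param p_region_jitter Additional per-(sample, label) SD of the
#'   methylated-type proportion (persistent across timepoints): regional
#'   individual variability not explained by the genome-wide level.
#' @param sdlog_sample Lognormal SD of the per-sample global rate
#'   multipliers (persistent across labels and timepoints; realised as a
#'   small location shift of the site modes).
#' @param sdlog_region Lognormal SD of the per-(sample, label) rate
#'   jitter (also persistent across timepoints).
#' @param carrier_effect_pts Carrier enhancer 5-mC excess in %-points,
#'   realised by upgrading low-mode sites within the affected enhancer
#'   intervals to `overload_level`.
#' @param affected_frac Fraction of enhancer intervals carrying the
#'   overload.
#' @param overload_retention Named vector mapping timepoint (months) to
#'   the fraction of the overload still present: the intervention
#'   progressively demethylates the upgraded loci.
#' @param rho_mult Multiplier on rho for responding carriers.
#' @param rho_mult_timepoints Timepoints at which `rho_mult` applies.
#' @param n_tf,n_effect_tf TF tracks to draw; the first `n_effect_tf`
#'   preferentially bind the overload-affected enhancer intervals.
#' @param tf_intervals_per_tf Binding intervals per TF.
#' @param tf_background_frac Fraction of a TF's intervals placed outside
#'   enhancers.
#' @param seed RNG seed, recorded in the cohort and its file outputs.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_carriers = 3, n_controls = 3, n_lymphoma = 0,
                       timepoints = c(0, 6, 12),
                       cell_type = "PBMC", chrom = "chr1",
                       region_profile = default_region_profile(),
                       n_intervals = 200, sites_per_interval = 50,
                       site_spacing = 10, interval_gap = 100,
                       coverage_mean = 20, beta_precision = 30,
                       mode_low = 0.08, mode_high = 0.88,
                       overload_level = 0.98, p_high_jitter = 0.004,
                       p_region_jitter = 0.0015,
                       sdlog_sample = 0.004, sdlog_region = 0.003,
                       carrier_effect_pts = 2, affected_frac = 0.10,
                       overload_retention = c("0" = 1, "6" = 0.5,
                                              "12" = 0),
                       rho_mult = 1.3, rho_mult_timepoints = c(6, 12),
                       n_tf = 20, n_effect_tf = 4,
                       tf_intervals_per_tf = 60,
                       tf_background_frac = 0.2, seed = 1) {
  stopifnot(n_carriers >= 0, n_controls >= 0, n_lymphoma >= 0,
            n_carriers + n_controls + n_lymphoma >= 1,
            length(timepoints) >= 1, !anyDuplicated(timepoints),
            is.data.frame(region_profile),
            all(c("label", "pct_mc", "pct_hmc") %in% names(region_profile)),
            n_intervals >= 1, sites_per_interval >= 1, site_spacing >= 1,
            coverage_mean > 0, beta_precision > 0,
            0 < mode_low, mode_low < mode_high, mode_high < 1,
            mode_high <= overload_level, overload_level < 1,
            p_high_jitter >= 0, p_region_jitter >= 0,
            sdlog_sample >= 0, sdlog_region >= 0,
            carrier_effect_pts >= 0, affected_frac > 0, affected_frac <= 1,
            rho_mult > 0, n_tf >= 0, n_effect_tf <= n_tf,
            tf_background_frac >= 0, tf_background_frac <= 1)
  with(region_profile, stopifnot(all(pct_mc > 0), all(pct_hmc > 0),
                                 all(pct_mc + pct_hmc < 100)))
  if (any(region_profile$pct_mc / 100 < mode_low) ||
        any(region_profile$pct_mc / 100 > mode_high))
    stop("regional pct_mc must lie between mode_low and mode_high",
         call. = FALSE)
  missing_tp <- setdiff(as.character(timepoints),
                        names(overload_retention))
  if (length(missing_tp) > 0L)
    overload_retention <- c(overload_retention,
                            setNames(rep(0, length(missing_tp)),
                                     missing_tp))
  cfg <- as.list(environment())
  cfg$missing_tp <- NULL
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "Synthetic cohort configuration\n",
    "  samples: %d carriers + %d controls + %d lymphoma-affected\n",
    "  timepoints (months): %s\n",
    "  genome: %d labels x %d intervals x %d CpGs (%s)\n",
    "  coverage ~ Poisson(%s), beta precision %s\n",
    "  carrier overload: +%g %%-pts on %.0f%% of Enh intervals\n",
    "  intervention: rho x %g at months %s\n  seed: %d\n"),
    x$n_carriers, x$n_controls, x$n_lymphoma,
    paste(x$timepoints, collapse = ", "),
    nrow(x$region_profile), x$n_intervals, x$sites_per_interval,
    x$cell_type, format(x$coverage_mean), format(x$beta_precision),
    x$carrier_effect_pts, 100 * x$affected_frac, x$rho_mult,
    paste(x$rho_mult_timepoints, collapse = ", "), as.integer(x$seed)))
  invisible(x)
}

.derive_seed <- function(seed, counter) {
  as.integer((as.double(seed) %% 65521 * 7919 + counter * 104729 + 11)
             %% 2147483647)
}

#' Simulate a synthetic methylation cohort
#'
#' Generates per-CpG 5-mC and 5-hmC call tables for every sample and
#' timepoint, chromatin-state annotations, TF binding tracks and a sample
#' sheet, with the statistical structure configured by [sim_config()].
#' Regional mean levels follow the turnover model's equilibrium for
#' per-sample rates drawn lognormally around the group rates; per-site
#' observations follow the bimodal beta-binomial model described in
#' [sim_config()].  Identical configurations (including the seed)
#' reproduce identical cohorts.
#'
#' @param config A [sim_config()] object.
#' @param null Force all carrier effects off (overload and intervention
#'   multipliers neutralised) while keeping the same genome, sample
#'   labels and random streams — a matched null cohort.
#' @return Object of class `meth_cohort`: list with `samples`,
#'   `annotations`, `tf_sites`, `calls` (long site-call table with
#'   `sample_id`, `timepoint_months`, `mark`), `truth` (per
#'   sample/timepoint/label rates and mean targets, affected intervals,
#'   effect TFs) and `config`.
#' @seealso [simulate_null()], [write_cohort()], [run_pipeline()]
#' @export
simulate_cohort <- function(config = sim_config(), null = FALSE) {
  cfg <- config
  stopifnot(inherits(cfg, "sim_config"))
  prof <- cfg$region_profile
  L <- nrow(prof)
  labels <- prof$label
  m0 <- prof$pct_mc / 100
  tau_l <- (100 - prof$pct_mc - prof$pct_hmc) / prof$pct_mc
  rho_l <- (100 - prof$pct_mc - prof$pct_hmc) / prof$pct_hmc
  mode_span <- cfg$mode_high - cfg$mode_low

  effect_pts <- if (null) 0 else cfg$carrier_effect_pts
  rho_mult <- if (null) 1 else cfg$rho_mult

  # genome layout: blocks assigned round-robin across labels
  n_blocks <- L * cfg$n_intervals
  block_label_idx <- ((seq_len(n_blocks) - 1L) %% L) + 1L
  span <- cfg$sites_per_interval * cfg$site_spacing
  block_start <- (seq_len(n_blocks) - 1L) * (span + cfg$interval_gap)
  annotations <- data.frame(chrom = cfg$chrom, start = block_start,
                            end = block_start + span,
                            label = labels[block_label_idx],
                            cell_type = cfg$cell_type,
                            stringsAsFactors = FALSE)
  site_offsets <- (seq_len(cfg$sites_per_interval) - 1L) * cfg$site_spacing
  enh_blocks <- which(annotations$label == "Enh")

  # samples
  ids <- c(if (cfg$n_carriers > 0) paste0("M", seq_len(cfg$n_carriers)),
           if (cfg$n_controls > 0) paste0("C", seq_len(cfg$n_controls)),
           if (cfg$n_lymphoma > 0) paste0("L", seq_len(cfg$n_lymphoma)))
  status <- c(rep("carrier", cfg$n_carriers),
              rep("control", cfg$n_controls),
              rep("carrier", cfg$n_lymphoma))
  lymph <- c(rep("unaffected", cfg$n_carriers + cfg$n_controls),
             rep("affected", cfg$n_lymphoma))
  n_s <- length(ids)
  samples <- do.call(rbind, lapply(cfg$timepoints, function(tp)
    data.frame(sample_id = ids, mutation_status = status,
               lymphoma_status = lymph, timepoint_months = as.integer(tp),
               stringsAsFactors = FALSE)))
  samples <- samples[order(samples$sample_id, samples$timepoint_months), ]
  rownames(samples) <- NULL

  # structural randomness: affected intervals, TF placement, site types,
  # per-sample dispersion
  set.seed(as.integer(cfg$seed))
  affected <- integer()
  if (length(enh_blocks) > 0L && cfg$affected_frac > 0)
    affected <- sort(sample(enh_blocks,
                            max(1L, round(cfg$affected_frac *
                                            length(enh_blocks)))))
  tf_sites <- data.frame()
  effect_tfs <- character()
  if (cfg$n_tf > 0L) {
    tf_names <- sprintf("TF%03d", seq_len(cfg$n_tf))
    effect_tfs <- head(tf_names, cfg$n_effect_tf)
    bg_pool <- setdiff(seq_len(n_blocks), enh_blocks)
    tf_rows <- lapply(seq_len(cfg$n_tf), function(j) {
      n_bg <- round(cfg$tf_background_frac * cfg$tf_intervals_per_tf)
      n_enh <- cfg$tf_intervals_per_tf - n_bg
      pool <- if (tf_names[j] %in% effect_tfs && length(affected) > 0L)
        affected else enh_blocks
      pick <- function(p, k) if (k == 0L || length(p) == 0L) integer()
        else sample(p, k, replace = k > length(p))
      blocks <- c(pick(pool, n_enh), pick(bg_pool, n_bg))
      data.frame(chrom = cfg$chrom, start = block_start[blocks],
                 end = block_start[blocks] + span, tf_name = tf_names[j],
                 stringsAsFactors = FALSE)
    })
    tf_sites <- do.call(rbind, tf_rows)
  }

  # per-label site-type assignment (shared across samples): per label,
  # round(p_high * n) methylated-type sites.  Within the affected
  # enhancer intervals a pool of upgradable low-mode sites realises the
  # carrier overload (true level `overload_level`), in a fixed order so
  # the retention schedule truncates it deterministically.  Each sample
  # additionally upgrades or downgrades a small number of sites per label
  # according to its persistent methylated-locus excess (p_high_jitter).
  n_sites_lab <- cfg$n_intervals * cfg$sites_per_interval
  high_base <- vector("list", L)
  for (li in seq_len(L)) {
    p_high <- (m0[li] - cfg$mode_low) / mode_span
    k <- round(p_high * n_sites_lab)
    flags <- logical(n_sites_lab)
    flags[sample(n_sites_lab, k)] <- TRUE
    high_base[[li]] <- flags
  }
  # drawn from the structural stream even for a null cohort, so matched
  # effect/null cohorts share every downstream random draw
  upgrade_order <- integer()
  enh_li <- match("Enh", labels)
  if (!is.na(enh_li) && length(affected) > 0L &&
        cfg$carrier_effect_pts > 0) {
    blocks <- which(block_label_idx == enh_li)
    site_block <- rep(blocks, each = cfg$sites_per_interval)
    pool <- which(!high_base[[enh_li]] & site_block %in% affected)
    k_up <- round(cfg$carrier_effect_pts / 100 * length(enh_blocks) *
                    cfg$sites_per_interval /
                    (cfg$overload_level - cfg$mode_low))
    if (k_up > length(pool)) k_up <- length(pool)
    upgrade_order <- sample(pool, k_up)
  }

  e_tau <- rnorm(n_s, 0, cfg$sdlog_sample)
  e_rho <- rnorm(n_s, 0, cfg$sdlog_sample)
  j_tau <- matrix(rnorm(n_s * L, 0, cfg$sdlog_region), n_s, L)
  j_rho <- matrix(rnorm(n_s * L, 0, cfg$sdlog_region), n_s, L)
  p_jit <- rnorm(n_s, 0, cfg$p_high_jitter)
  p_reg <- matrix(rnorm(n_s * L, 0, cfg$p_region_jitter), n_s, L)
  # per (sample, label): site indices flipped to realise the sample's
  # methylated-locus excess/deficit, drawn once (persistent)
  jitter_sites <- vector("list", n_s * L)
  for (si in seq_len(n_s)) {
    for (li in seq_len(L)) {
      dk <- round((p_jit[si] + p_reg[si, li]) * n_sites_lab)
      idx <- integer()
      if (dk > 0L) {
        pool <- which(!high_base[[li]])
        idx <- sample(pool, min(dk, length(pool)))
      } else if (dk < 0L) {
        pool <- which(high_base[[li]])
        idx <- -sample(pool, min(-dk, length(pool)))
      }
      jitter_sites[[(si - 1L) * L + li]] <- idx
    }
  }

  retention <- function(tp) {
    r <- cfg$overload_retention[as.character(tp)]
    if (is.na(r)) 0 else unname(r)
  }

  calls <- vector("list", n_s * length(cfg$timepoints) * L * 2L)
  truth_rates <- vector("list", n_s * length(cfg$timepoints) * L)
  counter <- 0L
  ti <- 0L
  for (si in seq_len(n_s)) {
    is_carrier <- status[si] == "carrier"
    responds <- is_carrier && lymph[si] == "unaffected"
    for (tp in cfg$timepoints) {
      for (li in seq_len(L)) {
        tau_s <- tau_l[li] * exp(e_tau[si] + j_tau[si, li])
        rho_s <- rho_l[li] * exp(e_rho[si] + j_rho[si, li])
        if (responds && tp %in% cfg$rho_mult_timepoints)
          rho_s <- rho_s * rho_mult
        blocks <- which(block_label_idx == li)
        pos <- as.integer(rep(block_start[blocks],
                              each = cfg$sites_per_interval) +
                            rep(site_offsets, length(blocks)))
        eq <- turnover_equilibrium(tau_s, rho_s)
        shift <- eq[["MC"]] - m0[li]
        high <- high_base[[li]]
        jidx <- jitter_sites[[(si - 1L) * L + li]]
        if (length(jidx) > 0L) high[abs(jidx)] <- jidx[1L] > 0L
        m_mc <- ifelse(high, cfg$mode_high, cfg$mode_low)
        if (li == (if (is.na(enh_li)) -1L else enh_li) && is_carrier &&
              effect_pts > 0 && length(upgrade_order) > 0L) {
          r <- if (lymph[si] == "affected") 1 else retention(tp)
          n_active <- round(r * length(upgrade_order))
          if (n_active > 0L)
            m_mc[upgrade_order[seq_len(n_active)]] <- cfg$overload_level
        }
        m_mc <- pmin(pmax(m_mc + shift, 0.002), 0.998)
        m_hmc <- eq[["HMC"]]
        ti <- ti + 1L
        truth_rates[[ti]] <- data.frame(
          sample_id = ids[si], timepoint_months = as.integer(tp),
          label = labels[li], tau = tau_s, rho = rho_s,
          mean_mc = mean(m_mc), mean_hmc = m_hmc,
          stringsAsFactors = FALSE)
        for (mk in c("mc", "hmc")) {
          counter <- counter + 1L
          set.seed(.derive_seed(cfg$seed, counter))
          m <- if (mk == "mc") m_mc else rep_len(m_hmc, length(pos))
          f <- .draw_beta(length(pos), m, cfg$beta_precision)
          cs <- .draw_coverage(length(pos), cfg$coverage_mean)
          cm <- .draw_binom(cs, f)
          calls[[counter]] <- data.table(
            sample_id = ids[si], timepoint_months = as.integer(tp),
            mark = mk, chrom = cfg$chrom, pos = pos,
            called_sites = cs, called_modified = cm,
            modified_fraction = ifelse(cs > 0L, cm / cs, NA_real_))
        }
      }
    }
  }
  calls <- rbindlist(calls)
  setorder(calls, sample_id, timepoint_months, mark, chrom, pos)
  structure(list(samples = samples, annotations = annotations,
                 tf_sites = tf_sites, calls = as.data.frame(calls),
                 truth = list(rates = do.call(rbind, truth_rates),
                              affected_intervals = affected,
                              effect_tfs = effect_tfs,
                              n_upgraded = length(upgrade_order),
                              null = null),
                 config = cfg),
            class = "meth_cohort")
}

#' Simulate a matched null cohort
#'
#' [simulate_cohort()] with all carrier effects removed (overload set to
#' zero, intervention multiplier to 1), same seed and genome: outputs
#' differ from the effect cohort only where the multipliers apply.
#'
#' @param config A [sim_config()] object.
#' @return A `meth_cohort`, as from [simulate_cohort()].
#' @export
simulate_null <- function(config = sim_config()) {
  simulate_cohort(config, null = TRUE)
}

#' @export
print.meth_cohort <- function(x, ...) {
  cat(sprintf(paste0(
    "Synthetic methylation cohort%s\n",
    "  %d samples x %d timepoints, %s site-call records\n",
    "  %d annotation intervals (%d labels), %d TF intervals (%d TFs)\n"),
    if (isTRUE(x$truth$null)) " (null)" else "",
    length(unique(x$samples$sample_id)),
    length(unique(x$samples$timepoint_months)),
    format(nrow(x$calls), big.mark = ","),
    nrow(x$annotations), length(unique(x$annotations$label)),
    nrow(x$tf_sites),
    length(unique(x$tf_sites$tf_name))))
  invisible(x)
}

#' Simulate per-sample hypermethylated proportions directly
#'
#' A focused generator for power and type-I-error studies of the
#' hypermethylated-proportion comparison: per-sample proportions are
#' drawn normally on the percent scale with a group mean shift for
#' carriers and a common between-sample standard deviation.
#'
#' @param n_carriers,n_controls Group sizes.
#' @param effect_pts Carrier mean excess, %-points.
#' @param sd_pts Between-sample SD, %-points.
#' @param base_pct Control group mean proportion, percent.
#' @param seed Optional RNG seed.
#' @return Data.frame with `sample_id`, `mutation_status`,
#'   `lymphoma_status`, `timepoint_months`, `prop_hyper` (fraction scale).
#' @export
simulate_hyper_proportions <- function(n_carriers = 3, n_controls = 3,
                                       effect_pts = 2, sd_pts = 0.3,
                                       base_pct = 64, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- n_carriers + n_controls
  mu <- c(rep(base_pct + effect_pts, n_carriers),
          rep(base_pct, n_controls))
  data.frame(
    sample_id = c(sprintf("M%d", seq_len(n_carriers)),
                  sprintf("C%d", seq_len(n_controls))),
    mutation_status = rep(c("carrier", "control"),
                          c(n_carriers, n_controls)),
    lymphoma_status = "unaffected", timepoint_months = 0L,
    prop_hyper = pmin(pmax(rnorm(n, mu, sd_pts) / 100, 0), 1),
    stringsAsFactors = FALSE)
}

#' Write a cohort to disk in the pipeline's file formats
#'
#' Site-call tables (tsv_freq dialect, one file per sample x timepoint x
#' mark), annotation BED per cell type, TF BED, CSV sample sheet, the
#' resolved configuration as YAML, and a manifest listing every file.
#'
#' @param cohort A `meth_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest data.frame.
#' @seealso [read_cohort()]
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- list()
  dt <- as.data.table(cohort$calls)
  keys <- unique(dt[, list(sample_id, timepoint_months, mark)])
  for (i in seq_len(nrow(keys))) {
    k <- keys[i]
    fn <- sprintf("calls_%s_%dm_%s.tsv", k$sample_id,
                  k$timepoint_months, k$mark)
    sub <- dt[sample_id == k$sample_id &
                timepoint_months == k$timepoint_months &
                dt$mark == k$mark]
    write_site_calls(as.data.frame(sub), file.path(dir, fn))
    man[[length(man) + 1L]] <- data.frame(
      file = fn, type = "site_calls", sample_id = k$sample_id,
      timepoint_months = k$timepoint_months, mark = k$mark,
      stringsAsFactors = FALSE)
  }
  for (ct in unique(cohort$annotations$cell_type)) {
    fn <- sprintf("annotations_%s.bed", ct)
    write_bed(cohort$annotations[cohort$annotations$cell_type == ct, ],
              file.path(dir, fn))
    man[[length(man) + 1L]] <- data.frame(
      file = fn, type = "annotations", sample_id = ct,
      timepoint_months = NA_integer_, mark = NA_character_,
      stringsAsFactors = FALSE)
  }
  if (nrow(cohort$tf_sites) > 0L) {
    write_bed(cohort$tf_sites, file.path(dir, "tf_sites.bed"))
    man[[length(man) + 1L]] <- data.frame(
      file = "tf_sites.bed", type = "tf_sites", sample_id = NA_character_,
      timepoint_months = NA_integer_, mark = NA_character_,
      stringsAsFactors = FALSE)
  }
  write_sample_sheet(cohort$samples, file.path(dir, "sample_sheet.csv"))
  man[[length(man) + 1L]] <- data.frame(
    file = "sample_sheet.csv", type = "sample_sheet",
    sample_id = NA_character_, timepoint_months = NA_integer_,
    mark = NA_character_, stringsAsFactors = FALSE)
  cfg <- cohort$config
  cfg$region_profile <- as.list(cfg$region_profile)
  yaml::write_yaml(cfg, file.path(dir, "config.yaml"))
  manifest <- do.call(rbind, man)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing a `manifest.csv` and the files it
#'   lists.
#' @return A list with `samples`, `annotations`, `tf_sites`, `calls`
#'   (long format), suitable for [run_pipeline()].
#' @export
read_cohort <- function(dir) {
  manifest <- read.csv(file.path(dir, "manifest.csv"),
                       stringsAsFactors = FALSE)
  samples <- read_sample_sheet(file.path(dir, "sample_sheet.csv"))
  ann_rows <- manifest[manifest$type == "annotations", ]
  annotations <- do.call(rbind, lapply(seq_len(nrow(ann_rows)), function(i)
    read_annotations(file.path(dir, ann_rows$file[i]),
                     cell_type = ann_rows$sample_id[i])))
  tf_sites <- data.frame()
  if (any(manifest$type == "tf_sites"))
    tf_sites <- read_tf_sites(
      file.path(dir, manifest$file[manifest$type == "tf_sites"][1L]))
  call_rows <- manifest[manifest$type == "site_calls", ]
  calls <- rbindlist(lapply(seq_len(nrow(call_rows)), function(i) {
    x <- read_site_calls(file.path(dir, call_rows$file[i]),
                         dialect = "tsv_freq", mark = call_rows$mark[i])
    x$sample_id <- call_rows$sample_id[i]
    x$timepoint_months <- as.integer(call_rows$timepoint_months[i])
    x
  }))
  list(samples = samples, annotations = annotations, tf_sites = tf_sites,
       calls = as.data.frame(calls))
}
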