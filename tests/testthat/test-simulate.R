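# The synthetic cohort generator.

test_that("identical configurations reproduce identical cohorts", {
  a <- simulate_cohort(tiny_config(seed = 3))
  b <- simulate_cohort(tiny_config(seed = 3))
  expect_identical(a$calls, b$calls)
  expect_identical(a$annotations, b$annotations)
  expect_identical(a$tf_sites, b$tf_sites)
  c2 <- simulate_cohort(tiny_config(seed = 4))
  expect_false(identical(a$calls, c2$calls))
})

test_that("the noise-free limit reproduces the equilibrium proportions", {
  prof <- default_region_profile()[c(1, 7, 9), ]
  cfg <- sim_config(region_profile = prof, n_intervals = 20,
                    sites_per_interval = 20, timepoints = 0,
                    coverage_mean = Inf, beta_precision = Inf,
                    p_high_jitter = 0, p_region_jitter = 0,
                    sdlog_sample = 0, sdlog_region = 0,
                    carrier_effect_pts = 0, n_tf = 0, n_effect_tf = 0,
                    seed = 6)
  co <- simulate_cohort(cfg)
  s <- summarize_regions(co$calls, co$annotations, genome_wide = FALSE)
  for (i in seq_len(nrow(prof))) {
    for (mk in c("mc", "hmc")) {
      want <- if (mk == "mc") prof$pct_mc[i] / 100 else
        prof$pct_hmc[i] / 100
      got <- s$mean_fraction[s$label == prof$label[i] & s$mark == mk]
      expect_equal(got, rep(want, length(got)), tolerance = 1e-3)
    }
  }
})

test_that("the carrier overload raises enhancer methylation in every replicate", {
  for (sd in 1:5) {
    co <- simulate_cohort(tiny_config(seed = sd, n_tf = 0,
                                      n_effect_tf = 0))
    s <- summarize_regions(co$calls, co$annotations, genome_wide = FALSE)
    s0 <- s[s$label == "Enh" & s$mark == "mc" & s$timepoint_months == 0, ]
    meta <- co$samples[!duplicated(co$samples$sample_id), ]
    m <- merge(s0, meta, by = "sample_id")
    diff <- mean(m$mean_fraction[m$mutation_status == "carrier"]) -
      mean(m$mean_fraction[m$mutation_status == "control"])
    expect_gt(diff, 0)
  }
})

test_that("null and effect cohorts differ only where carrier effects apply", {
  cfg <- tiny_config(seed = 9)
  eff <- simulate_cohort(cfg)
  nul <- simulate_null(cfg)
  expect_identical(eff$annotations, nul$annotations)
  key <- function(co, id, tp, mk, lab = NULL) {
    x <- co$calls[co$calls$sample_id == id &
                    co$calls$timepoint_months == tp &
                    co$calls$mark == mk, ]
    rownames(x) <- NULL
    x
  }
  # controls are byte-identical everywhere
  for (tp in c(0, 12)) for (mk in c("mc", "hmc"))
    expect_identical(key(eff, "C1", tp, mk), key(nul, "C1", tp, mk))
  # carriers differ at baseline only in 5-mC (the overload), not 5-hmC
  expect_false(identical(key(eff, "M1", 0, "mc"), key(nul, "M1", 0, "mc")))
  expect_identical(key(eff, "M1", 0, "hmc"), key(nul, "M1", 0, "hmc"))
  # at baseline the difference is confined to enhancer intervals
  enh <- eff$annotations[eff$annotations$label == "Enh", ]
  a <- key(eff, "M1", 0, "mc"); b <- key(nul, "M1", 0, "mc")
  changed <- a$pos[a$called_modified != b$called_modified |
                     a$called_sites != b$called_sites]
  in_enh <- vapply(changed, function(p)
    any(p >= enh$start & p < enh$end), logical(1))
  expect_true(all(in_enh))
  # at 12 months the rho multiplier acts on the carrier's 5-hmC
  expect_false(identical(key(eff, "M1", 12, "hmc"),
                         key(nul, "M1", 12, "hmc")))
})

test_that("written cohorts re-parse losslessly through the readers", {
  co <- simulate_cohort(tiny_config(seed = 15, n_intervals = 10,
                                    sites_per_interval = 8))
  dir <- withr::local_tempdir()
  man <- write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "config.yaml")))
  back <- read_cohort(dir)
  expect_equal(back$samples, co$samples)
  expect_equal(back$annotations, co$annotations)
  expect_equal(back$tf_sites, co$tf_sites)
  ord <- function(x) {
    x <- x[order(x$sample_id, x$timepoint_months, x$mark, x$chrom, x$pos),
           c("sample_id", "timepoint_months", "mark", "chrom", "pos",
             "called_sites", "called_modified", "modified_fraction")]
    rownames(x) <- NULL
    x
  }
  expect_equal(ord(back$calls), ord(co$calls))
})

test_that("lymphoma-affected carriers keep the overload and skip the response", {
  cfg <- tiny_config(seed = 21, n_lymphoma = 1, n_tf = 0, n_effect_tf = 0)
  co <- simulate_cohort(cfg)
  expect_true("L1" %in% co$samples$sample_id)
  tr <- co$truth$rates
  l_enh <- tr[tr$sample_id == "L1" & tr$label == "Enh", ]
  m_enh <- tr[tr$sample_id == "M1" & tr$label == "Enh", ]
  # no rho response at 12 months for the lymphoma-affected carrier
  expect_equal(l_enh$rho[l_enh$timepoint_months == 12] /
                 l_enh$rho[l_enh$timepoint_months == 0], 1,
               tolerance = 1e-12)
  expect_equal(m_enh$rho[m_enh$timepoint_months == 12] /
                 m_enh$rho[m_enh$timepoint_months == 0],
               cfg$rho_mult, tolerance = 1e-12)
  # overload persists at 12 months (mean 5-mC target stays elevated)
  expect_gt(l_enh$mean_mc[l_enh$timepoint_months == 12],
            m_enh$mean_mc[m_enh$timepoint_months == 12] + 0.005)
})

test_that("direct hyperproportion simulation has the configured moments", {
  set.seed(62)
  props <- do.call(rbind, lapply(1:50, function(i)
    simulate_hyper_proportions(effect_pts = 2, sd_pts = 0.3)))
  m <- 100 * tapply(props$prop_hyper, props$mutation_status, mean)
  expect_equal(unname(m["carrier"] - m["control"]), 2, tolerance = 0.25)
  s <- 100 * sd(props$prop_hyper[props$mutation_status == "control"])
  expect_equal(s, 0.3, tolerance = 0.1)
})
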