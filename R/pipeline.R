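# End-to-end orchestration of the analysis stages.

.write_stage <- function(x, out_dir, name) {
  if (is.null(out_dir)) return(invisible(NULL))
  write.table(x, file.path(out_dir, paste0(name, ".tsv")), sep = "\t",
              quote = FALSE, row.names = FALSE)
}

#' Run the full methylation-turnover pipeline
#'
#' Executes the stages in order — region aggregation, the
#' annotation-level mutation-status screen, the hydroxymethylation
#' change-over-time tests, the hypermethylated-proportion comparison, the
#' TF binding-site screen, and turnover-rate estimation — on a cohort
#' (in-memory [simulate_cohort()] output, or a directory written by
#' [write_cohort()]).  Stage outputs are returned and, when `out_dir` is
#' given, written as TSV; a manifest records each stage's status.  A
#' failing stage aborts its dependents and is reported in the manifest.
#' The pipeline is a pure function of its inputs and settings: reruns
#' with identical inputs reproduce identical outputs.
#'
#' @param cohort A `meth_cohort`, a list with `calls`, `annotations`,
#'   `tf_sites`, `samples`, or a directory path for [read_cohort()].
#' @param out_dir Optional output directory for stage TSVs.
#' @param stages Subset of
#'   `c("aggregate", "screen", "change", "hyper", "tf", "rates")`;
#'   `aggregate` is always run (every other stage depends on it).
#' @param cell_type,enh_label The region class used for the
#'   hyperproportion, TF and rate analyses (default PBMC enhancers).
#' @param mark_screen Mark for the annotation screen (default `"mc"`).
#' @param t0,t1 Baseline and follow-up timepoints in months.
#' @param min_calls Per-site coverage floor for the hyperproportion and
#'   TF stages.
#' @param screen_fdr,change_fdr FDR thresholds reported for the
#'   annotation screen and the change tests.
#' @param tf_restriction,tf_universe Settings for [tf_scores()].
#' @return List with `manifest` (stage status data.frame) and one entry
#'   per executed stage: `summaries`, `screen`, `change` (deltas +
#'   hmc-change screen), `hyper` (proportions + baseline/follow-up
#'   tests), `tf` (scores + per-timepoint screens), `rates` (per-sample
#'   rates + changes).
#' @export
run_pipeline <- function(cohort, out_dir = NULL,
                         stages = c("aggregate", "screen", "change",
                                    "hyper", "tf", "rates"),
                         cell_type = "PBMC", enh_label = "Enh",
                         mark_screen = "mc", t0 = 0, t1 = 12,
                         min_calls = 1L, screen_fdr = 0.05,
                         change_fdr = 0.1,
                         tf_restriction = "hyper_only",
                         tf_universe = "enhancer_overlap") {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  stages <- match.arg(stages, several.ok = TRUE)
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  calls <- cohort$calls
  meta <- cohort$samples
  annotations <- cohort$annotations
  res <- list()
  manifest <- data.frame(stage = character(), status = character(),
                         message = character(), stringsAsFactors = FALSE)
  note <- function(stage, status, message = "") {
    rbind(manifest, data.frame(stage = stage, status = status,
                               message = message, stringsAsFactors = FALSE))
  }

  # aggregate (always required)
  agg <- tryCatch(summarize_regions(calls, annotations),
                  error = function(e) e)
  if (inherits(agg, "error")) {
    manifest <- note("aggregate", "failed", conditionMessage(agg))
    for (s in setdiff(stages, "aggregate"))
      manifest <- note(s, "skipped", "aggregate failed")
    return(c(res, list(manifest = manifest)))
  }
  res$summaries <- agg
  .write_stage(agg, out_dir, "region_summaries")
  manifest <- note("aggregate", "complete")

  if ("screen" %in% stages) {
    out <- tryCatch({
      scr <- run_screen(res$summaries, meta, mark = mark_screen,
                        timepoint = t0)
      scr$significant <- scr$q_value < screen_fdr
      scr
    }, error = function(e) e)
    if (inherits(out, "error")) {
      manifest <- note("screen", "failed", conditionMessage(out))
    } else {
      res$screen <- out
      .write_stage(out, out_dir, "annotation_screen")
      manifest <- note("screen", "complete")
    }
  }

  if ("change" %in% stages) {
    out <- tryCatch({
      deltas <- suppressWarnings(delta_over_time(res$summaries,
                                                 t0 = t0, t1 = t1))
      hmc <- screen_hmc_change(deltas, meta, fdr = change_fdr)
      list(deltas = deltas, hmc_screen = hmc$results,
           n_significant = hmc$n_significant, n_tested = hmc$n_tested)
    }, error = function(e) e)
    if (inherits(out, "error")) {
      manifest <- note("change", "failed", conditionMessage(out))
    } else {
      res$change <- out
      .write_stage(out$deltas, out_dir, "deltas")
      .write_stage(out$hmc_screen, out_dir, "hmc_change_screen")
      manifest <- note("change", "complete")
    }
  }

  if ("hyper" %in% stages) {
    out <- tryCatch({
      props <- hyper_proportions(calls[calls$mark == "mc", ], annotations,
                                 cell_type = cell_type, label = enh_label,
                                 min_calls = min_calls)
      list(proportions = props,
           baseline = compare_hyper_proportions(props, meta,
                                                timepoint = t0),
           followup = compare_hyper_proportions(props, meta,
                                                timepoint = t1))
    }, error = function(e) e)
    if (inherits(out, "error")) {
      manifest <- note("hyper", "failed", conditionMessage(out))
    } else {
      res$hyper <- out
      .write_stage(out$proportions, out_dir, "hyper_proportions")
      manifest <- note("hyper", "complete")
    }
  }

  if ("tf" %in% stages) {
    if (is.null(cohort$tf_sites) || nrow(cohort$tf_sites) == 0L) {
      manifest <- note("tf", "skipped", "no TF intervals supplied")
    } else {
      out <- tryCatch({
        sc <- tf_scores(calls[calls$mark == "mc", ], cohort$tf_sites,
                        annotations, restriction = tf_restriction,
                        universe = tf_universe, cell_type = cell_type,
                        enh_label = enh_label, min_calls = min_calls)
        em <- res$summaries[res$summaries$cell_type == cell_type &
                              res$summaries$label == enh_label &
                              res$summaries$mark == "mc", ]
        em <- data.frame(sample_id = em$sample_id,
                         timepoint_months = em$timepoint_months,
                         enh_mean = em$mean_fraction)
        list(scores = sc,
             screen_t0 = tf_screen(sc, meta, em, timepoint = t0),
             screen_t1 = tf_screen(sc, meta, em, timepoint = t1))
      }, error = function(e) e)
      if (inherits(out, "error")) {
        manifest <- note("tf", "failed", conditionMessage(out))
      } else {
        res$tf <- out
        .write_stage(out$scores, out_dir, "tf_scores")
        .write_stage(out$screen_t0, out_dir, "tf_screen_t0")
        .write_stage(out$screen_t1, out_dir, "tf_screen_t1")
        manifest <- note("tf", "complete")
      }
    }
  }

  if ("rates" %in% stages) {
    out <- tryCatch({
      rates <- cohort_rates(res$summaries, cell_type = cell_type,
                            label = enh_label)
      list(rates = rates,
           changes = cohort_rate_changes(rates, t0 = t0, t1 = t1))
    }, error = function(e) e)
    if (inherits(out, "error")) {
      manifest <- note("rates", "failed", conditionMessage(out))
    } else {
      res$rates <- out
      .write_stage(out$rates, out_dir, "turnover_rates")
      .write_stage(out$changes, out_dir, "rate_changes")
      manifest <- note("rates", "complete")
    }
  }

  res$manifest <- manifest
  if (!is.null(out_dir))
    write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  res
}

#' Volcano plot of a screen result
#'
#' Effect estimate against `-log10(p)`, highlighting results below the
#' FDR threshold.
#'
#' @param screen Data.frame from [run_screen()] or [tf_screen()].
#' @param fdr Highlight threshold on `q_value`.
#' @param label_col Column used to label significant points.
#' @param ... Passed to [plot()].
#' @return Invisibly, `screen`.
#' @export
plot_volcano <- function(screen, fdr = 0.05, label_col = "label", ...) {
  sig <- screen$q_value < fdr
  plot(screen$estimate, -log10(screen$p_value),
       pch = 19, col = ifelse(sig, "firebrick", "grey60"),
       xlab = "carrier effect (fraction)", ylab = "-log10 p", ...)
  if (any(sig) && label_col %in% names(screen))
    text(screen$estimate[sig], -log10(screen$p_value[sig]),
         screen[[label_col]][sig], pos = 3, cex = 0.7)
  invisible(screen)
}
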