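# Hyper/hypomethylation partition: classify CpG sites against the
# sample's own regional average and compare hypermethylated proportions.

#' Partition sites into hyper- and hypomethylated
#'
#' Labels each site `hyper` when its modified fraction is strictly greater
#' than the reference mean (the sample's own average over the same site
#' set), `hypo` otherwise; ties count as `hypo`.
#'
#' @param fractions Numeric vector of per-site modified fractions.
#' @param mean_fraction Reference mean (computed over the same sites).
#' @return List with `labels` (character vector), `n_hyper`, `n_hypo`,
#'   `prop_hyper`.
#' @export
partition_sites <- function(fractions, mean_fraction) {
  fractions <- as.numeric(fractions)
  if (length(fractions) == 0L)
    stop("cannot partition an empty site set", call. = FALSE)
  labels <- ifelse(fractions > mean_fraction, "hyper", "hypo")
  n_hyper <- sum(labels == "hyper")
  list(labels = labels, n_hyper = n_hyper,
       n_hypo = length(labels) - n_hyper,
       prop_hyper = n_hyper / length(labels))
}

#' Per-sample hypermethylated proportion within a region class
#'
#' For each (sample, timepoint, mark) group, takes the informative sites
#' (`called_sites >= min_calls`) overlapping intervals of one
#' `(cell_type, label)` class, computes the sample's own mean fraction
#' over those sites, and reports the proportion of sites strictly above
#' it.  The reference mean is per sample and timepoint, never a
#' cross-sample mean.
#'
#' @param calls Site-call data.frame (long format across samples).
#' @param annotations Annotation intervals.
#' @param cell_type,label Region class (default PBMC enhancers).
#' @param min_calls Minimum `called_sites` for a site to qualify.
#' @return Data.frame with grouping columns plus `cell_type`, `label`,
#'   `prop_hyper` (in \[0,1\]), `mean_fraction`, `n_sites`.
#' @export
hyper_proportions <- function(calls, annotations, cell_type = "PBMC",
                              label = "Enh", min_calls = 1L) {
  ann <- annotations[annotations$cell_type == cell_type &
                       annotations$label == label, ]
  if (nrow(ann) == 0L)
    stop("no annotation intervals for (", cell_type, ", ", label, ")",
         call. = FALSE)
  dt <- as.data.table(calls)[called_sites >= min_calls]
  grp <- .group_cols(dt)
  map <- .site_label_map(dt, ann)
  merged <- merge(dt, map, by = c("chrom", "pos"))
  if (nrow(merged) == 0L)
    stop("no informative sites overlap the region class", call. = FALSE)
  out <- merged[, {
    m <- mean(modified_fraction)
    list(prop_hyper = mean(modified_fraction > m),
         mean_fraction = m, n_sites = .N)
  }, by = grp]
  out[, `:=`(cell_type = cell_type, label = label)]
  setorderv(out, grp)
  as.data.frame(out[, c(grp, "cell_type", "label", "prop_hyper",
                        "mean_fraction", "n_sites"), with = FALSE])
}

#' Compare hypermethylated proportions between carriers and controls
#'
#' Student pooled-variance two-sample t-test on per-sample hypermethylated
#' proportions, reported in percentage points (mean difference and 95% CI
#' on the 0--100 scale).  Lymphoma-affected samples are excluded by
#' default.
#'
#' @param props Per-sample proportions from [hyper_proportions()] (or any
#'   data.frame with `sample_id` and `prop_hyper`).
#' @param meta Sample sheet.
#' @param timepoint Timepoint to compare (ignored when `props` has no
#'   `timepoint_months` column).
#' @param include_lymphoma Keep lymphoma-affected samples.
#' @param variant Test variant, Student pooled by default.
#' @return One-row data.frame as from [ttest_change()], in percentage
#'   points.
#' @export
compare_hyper_proportions <- function(props, meta, timepoint = 0,
                                      include_lymphoma = FALSE,
                                      variant = "student") {
  p <- props
  if ("timepoint_months" %in% names(p))
    p <- p[p$timepoint_months == timepoint, ]
  p <- p[, setdiff(names(p), c("mutation_status", "lymphoma_status")),
         drop = FALSE]
  meta1 <- meta[!duplicated(meta$sample_id), ]
  if (!include_lymphoma)
    meta1 <- meta1[meta1$lymphoma_status == "unaffected", ]
  d <- merge(p, meta1[, c("sample_id", "mutation_status")],
             by = "sample_id")
  x <- 100 * d$prop_hyper[d$mutation_status == "carrier"]
  y <- 100 * d$prop_hyper[d$mutation_status == "control"]
  ttest_change(x, y, variant = variant)
}
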