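# Region-level aggregation: intersect site calls with annotation intervals
# and average per-site modified fractions per (sample, cell type, label).

#' Map CpG sites to the intervals containing them
#'
#' Half-open membership: a site at 0-based position `p` belongs to an
#' interval `[start, end)` iff `start <= p < end`.  Each site maps to every
#' containing interval; sites contained in no interval are absent from the
#' result.
#'
#' @param sites Data.frame with `chrom`, `pos` (0-based positions).
#' @param intervals Data.frame with `chrom`, `start`, `end` (0-based,
#'   half-open).
#' @return Data.frame with columns `site` and `interval`: row indices into
#'   `sites` and `intervals` for every membership pair.
#' @export
overlap_sites <- function(sites, intervals) {
  if (nrow(sites) == 0L || nrow(intervals) == 0L)
    return(data.frame(site = integer(), interval = integer()))
  qry <- GenomicRanges::GRanges(sites$chrom,
                                IRanges::IRanges(sites$pos + 1L, width = 1L))
  sbj <- GenomicRanges::GRanges(intervals$chrom,
                                IRanges::IRanges(intervals$start + 1L,
                                                 intervals$end))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(qry, sbj))
  data.frame(site = S4Vectors::queryHits(hits),
             interval = S4Vectors::subjectHits(hits))
}

# Unique (chrom, pos) -> (cell_type, label) map; a site inside several
# intervals of the same (cell_type, label) appears once for that pair.
.site_label_map <- function(sites_dt, annotations) {
  usites <- unique(sites_dt[, list(chrom, pos)])
  ov <- overlap_sites(as.data.frame(usites), annotations)
  if (nrow(ov) == 0L)
    return(data.table(chrom = character(), pos = integer(),
                      cell_type = character(), label = character()))
  map <- data.table(chrom = usites$chrom[ov$site],
                    pos = usites$pos[ov$site],
                    cell_type = annotations$cell_type[ov$interval],
                    label = annotations$label[ov$interval])
  unique(map)
}

.group_cols <- function(x) {
  intersect(c("sample_id", "timepoint_months", "mark"), names(x))
}

#' Summarize modification levels per annotation
#'
#' Computes, for each (sample, timepoint, mark) group present in `calls`
#' and each `(cell_type, label)` with at least one overlapping informative
#' site, the unweighted mean of per-site modified fractions and the number
#' of contributing sites; plus one `GENOME_WIDE` summary (cell type
#' `GENOME`) over all informative sites of the group.  Sites with
#' `called_sites = 0` are excluded.  A site covered by several intervals of
#' the same `(cell_type, label)` contributes once to that label; a site
#' under intervals of different labels contributes to each.
#'
#' @param calls Site-call data.frame (columns `chrom`, `pos`,
#'   `called_sites`, `modified_fraction`, optionally `sample_id`,
#'   `timepoint_months`, `mark`).
#' @param annotations Annotation data.frame (`chrom`, `start`, `end`,
#'   `label`, `cell_type`).
#' @param genome_wide Include the `GENOME_WIDE` summary rows.
#' @return Data.frame of region summaries with columns the grouping
#'   columns plus `cell_type`, `label`, `mean_fraction`, `n_sites`.
#' @export
summarize_regions <- function(calls, annotations, genome_wide = TRUE) {
  dt <- as.data.table(calls)[called_sites > 0L]
  grp <- .group_cols(dt)
  map <- .site_label_map(dt, annotations)
  merged <- merge(dt, map, by = c("chrom", "pos"), allow.cartesian = TRUE)
  summ <- merged[, list(mean_fraction = mean(modified_fraction),
                        n_sites = .N),
                 by = c(grp, "cell_type", "label")]
  if (genome_wide) {
    gw <- dt[, list(cell_type = "GENOME", label = "GENOME_WIDE",
                    mean_fraction = mean(modified_fraction),
                    n_sites = .N), by = grp]
    summ <- rbind(summ, gw, use.names = TRUE)
  }
  setorderv(summ, c(grp, "cell_type", "label"))
  as.data.frame(summ)
}

#' Per-sample change in regional modification between two timepoints
#'
#' For each sample and `(cell_type, label, mark)`, the later minus the
#' earlier `mean_fraction`.  Samples missing either timepoint for a region
#' are skipped with a warning.
#'
#' @param summaries Region summaries (from [summarize_regions()]) with a
#'   `timepoint_months` column.
#' @param t0,t1 Earlier and later timepoints in months.
#' @return Data.frame with `sample_id`, `cell_type`, `label`, `mark`,
#'   `change` (fraction scale), `mean_t0`, `mean_t1`.
#' @export
delta_over_time <- function(summaries, t0 = 0, t1 = 12) {
  dt <- as.data.table(summaries)
  stopifnot("timepoint_months" %in% names(dt))
  key <- c("sample_id", "cell_type", "label", "mark")
  key <- intersect(key, names(dt))
  a <- dt[timepoint_months == t0, c(key, "mean_fraction"), with = FALSE]
  b <- dt[timepoint_months == t1, c(key, "mean_fraction"), with = FALSE]
  setnames(a, "mean_fraction", "mean_t0")
  setnames(b, "mean_fraction", "mean_t1")
  m <- merge(a, b, by = key)
  n_skipped <- (nrow(a) - nrow(m)) + (nrow(b) - nrow(m))
  if (n_skipped > 0L)
    warning(n_skipped, " record(s) missing one timepoint were skipped",
            call. = FALSE)
  m[, change := mean_t1 - mean_t0]
  as.data.frame(m[, c(key, "change", "mean_t0", "mean_t1"), with = FALSE])
}
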