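#' Default depth-interval edges for minirhizotron images
#'
#' Eight 0.2 m bins spanning 0.4-2.0 m soil depth. The four bins
#' intersecting the analysis window 1.2-2.0 m are the analysis intervals
#' 1-4 used for interval root length.
#'
#' @return Numeric vector of nine strictly increasing bin edges (m).
#' @export
default_depth_edges <- function() round(seq(0.4, 2.0, by = 0.2), 10)

#' Label root-image records with depth intervals
#'
#' Bins are left-closed (`[edge_k, edge_{k+1})`), the last bin right-closed,
#' so a record at exactly 1.2 m falls into analysis interval 1 and one at
#' exactly 2.0 m into interval 4. Records outside all bins get interval
#' `NA` and `analysis_interval` `NA` (out of range).
#'
#' @param records data frame with a `depth_m` column.
#' @param edges strictly increasing bin edges in metres.
#' @param window analysis depth window (m), default `c(1.2, 2.0)`.
#' @return `records` with integer columns `interval` (1..n_bins) and
#'   `analysis_interval` (1..4 inside the window, `NA` outside).
#' @export
assign_depth_intervals <- function(records, edges = default_depth_edges(),
                                   window = c(1.2, 2.0)) {
  if (any(diff(edges) <= 0)) stop_domain("bin edges must strictly increase")
  d <- records$depth_m
  k <- findInterval(d, edges, rightmost.closed = TRUE)
  k[k == 0L | k == length(edges)] <- NA_integer_  # below first / above last edge
  records$interval <- k
  # analysis intervals: bins whose span intersects the window (with an
  # epsilon so accumulated floating-point error in seq()-built edges cannot
  # flag the bin that merely touches the window boundary)
  eps <- 1e-9
  lo <- edges[-length(edges)]; hi <- edges[-1L]
  is_analysis <- hi > window[1] + eps & lo < window[2] - eps
  aidx <- cumsum(is_analysis)
  records$analysis_interval <- ifelse(!is.na(k) & is_analysis[k], aidx[k],
                                      NA_integer_)
  records
}

#' Edit minirhizotron image records before genetic analysis
#'
#' Applies, in order: (1) remove records flagged as failed observations;
#' (2) assign depth intervals and remove records above 1.2 m or below 2.0 m
#' soil depth; (3) within each analysis interval, remove records outside
#' mean +/- `sd_mult` * sd, with mean and sd computed from the records
#' surviving steps 1-2 (ties at the boundary are kept); (4) remove records
#' from lines without genomic information.
#'
#' @param records data frame with columns `tube`, `depth_m`, `length_cm`,
#'   `line`, and optionally `valid` (logical; missing column means all valid).
#' @param lines_with_genotype character vector of genotyped line ids, or
#'   `NULL` to skip step 4.
#' @param edges depth-bin edges, see [assign_depth_intervals()].
#' @param window analysis depth window in metres.
#' @param sd_mult outlier multiplier for step 3 (default 3).
#' @param outlier_stats optional data frame (`interval`, `mean`, `sd`) of
#'   step-3 statistics to reuse (e.g. the `outlier_stats` attribute of an
#'   earlier pass); by default they are recomputed from the step-2
#'   survivors, so re-editing already-edited data can tighten the
#'   thresholds and remove further records.
#' @return The retained records, with a `retention` attribute (data frame of
#'   per-step record counts, step 0 = input) and an `outlier_stats`
#'   attribute holding the step-3 statistics used. An empty survivor set
#'   after any step raises an error naming the step.
#' @export
edit_root_images <- function(records, lines_with_genotype = NULL,
                             edges = default_depth_edges(),
                             window = c(1.2, 2.0), sd_mult = 3,
                             outlier_stats = NULL) {
  counts <- data.frame(step = "input", kept = nrow(records))
  note <- function(step, df) {
    counts <<- rbind(counts, data.frame(step = step, kept = nrow(df)))
    if (nrow(df) == 0L)
      stop_domain("no records survive editing step '", step, "'")
    df
  }
  # step 1: failed observations
  ok <- if ("valid" %in% names(records)) records$valid & !is.na(records$length_cm)
        else !is.na(records$length_cm)
  r <- note("1_remove_failures", records[ok, , drop = FALSE])
  # step 2: depth window
  r <- assign_depth_intervals(r, edges = edges, window = window)
  inwin <- !is.na(r$analysis_interval) &
    r$depth_m >= window[1] & r$depth_m <= window[2]
  r <- note("2_depth_window", r[inwin, , drop = FALSE])
  # step 3: per-interval mean +/- k sd, statistics from step-2 survivors
  # (or reused from an earlier pass)
  if (is.null(outlier_stats)) {
    stats_by <- split(r$length_cm, r$analysis_interval)
    outlier_stats <- data.frame(
      interval = as.integer(names(stats_by)),
      mean = vapply(stats_by, mean, 0),
      sd = vapply(stats_by, function(x)
        if (length(x) > 1L) stats::sd(x) else 0, 0))
    rownames(outlier_stats) <- NULL
  }
  keep <- rep(TRUE, nrow(r))
  for (j in seq_len(nrow(outlier_stats))) {
    idx <- which(r$analysis_interval == outlier_stats$interval[j])
    m <- outlier_stats$mean[j]; s <- outlier_stats$sd[j]
    keep[idx] <- r$length_cm[idx] >= m - sd_mult * s &
                 r$length_cm[idx] <= m + sd_mult * s
  }
  r <- note("3_outliers", r[keep, , drop = FALSE])
  # step 4: genotyped lines only
  if (!is.null(lines_with_genotype))
    r <- note("4_genotyped", r[r$line %in% lines_with_genotype, , drop = FALSE])
  attr(r, "retention") <- counts
  attr(r, "outlier_stats") <- outlier_stats
  r
}

#' Aggregate edited root images into per-tube traits
#'
#' Total root length (TRL) per tube is the sum of retained image lengths;
#' interval root length (IRL) is the same sum within each analysis interval,
#' so a tube's IRL values add up to its TRL by construction. Tubes with no
#' retained images emit no record.
#'
#' @param records edited, interval-labelled image records (see
#'   [edit_root_images()]); needs columns `tube`, `analysis_interval`,
#'   `length_cm`, plus pass-through metadata `line`, `bed`, `camera` if
#'   present.
#' @return List with data frames `trl` (`tube`, `value`, metadata) and
#'   `irl` (`tube`, `interval`, `value`, metadata).
#' @export
aggregate_root_traits <- function(records) {
  if (nrow(records) == 0L) stop_domain("no records to aggregate")
  meta_cols <- intersect(c("line", "bed", "camera"), names(records))
  first_meta <- function(df) df[!duplicated(df$tube),
                                c("tube", meta_cols), drop = FALSE]
  trl_v <- tapply(records$length_cm, records$tube, sum)
  trl <- data.frame(tube = names(trl_v), value = as.numeric(trl_v))
  trl <- merge(trl, first_meta(records), by = "tube", sort = TRUE)
  key <- paste(records$tube, records$analysis_interval, sep = "\r")
  irl_v <- tapply(records$length_cm, key, sum)
  parts <- do.call(rbind, strsplit(names(irl_v), "\r", fixed = TRUE))
  irl <- data.frame(tube = parts[, 1L], interval = as.integer(parts[, 2L]),
                    value = as.numeric(irl_v))
  irl <- merge(irl, first_meta(records), by = "tube", sort = TRUE)
  irl <- irl[order(irl$tube, irl$interval), ]
  rownames(irl) <- NULL
  list(trl = trl, irl = irl)
}
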