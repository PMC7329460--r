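# Synthetic-data generator.
#
# The stated world mirrors the facility the models were built for: 84 lines
# sown as single rows in 4 beds of 150 rows (one replicate per bed, the
# remaining rows filled at random, so ~7 rows/line), each row split into a
# wet and a dry harvest area, two-sided neighbors along each bed pair, an
# 11-position running-sum spatial field with 5 virtual border positions per
# end, and (for root data) minirhizotron tubes in one bed per pair, read by
# 4 cameras cycling along the bed, with four 0.2 m depth intervals.

#' Configuration for the synthetic-data generator
#'
#' Defaults state a grain-trait world with line-mean heritability around
#' 0.4 (the level reported for yield) and modest neighbor, row and spatial
#' variances; the root world has a small genomic variance dominated by
#' spatial and residual noise. All variances are in trait units squared.
#'
#' @param trait_kind `"grain"` or `"root"`.
#' @param n_lines,n_markers,maf_range marker-panel dimensions; minor-allele
#'   frequencies are drawn uniformly on `maf_range`.
#' @param n_founders founder-pool size for the related marker panel (see
#'   [simulate_markers()]); `NULL` gives independent unrelated lines.
#' @param beds,rows_per_bed facility dimensions.
#' @param variances named vector: `g`, `l`, `g_n`, `l_n`, `r`, `s_wet`,
#'   `s_dry` (grain) or `s` (root), `e`, optional `gxa` (genotype-by-area
#'   interaction, default 0; not part of the reference models, provided for
#'   power studies only).
#' @param root_level `"interval"` (four records per tube, the repeated-
#'   records world) or `"tube"` (one record per tube).
#' @param seed mandatory integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(trait_kind = c("grain", "root"), n_lines = 84,
                       n_markers = 2000, maf_range = c(0.05, 0.5),
                       beds = 4, rows_per_bed = 150, variances = NULL,
                       root_level = c("interval", "tube"), n_founders = 16,
                       seed) {
  trait_kind <- match.arg(trait_kind)
  root_level <- match.arg(root_level)
  if (missing(seed)) stop_domain("seed is mandatory")
  defaults <- if (trait_kind == "grain")
    c(g = 0.40, l = 0.35, g_n = 0.02, l_n = 0.04, r = 0.25,
      s_wet = 0.03, s_dry = 0.06, e = 1.0, gxa = 0)
  else
    c(g = 0.05, l = 0.25, r = 0.10, s = 0.15, e = 1.0, gxa = 0)
  if (!is.null(variances)) {
    unknown <- setdiff(names(variances), names(defaults))
    if (length(unknown) > 0L)
      stop_domain("unknown variance names: ", paste(unknown, collapse = ", "))
    defaults[names(variances)] <- variances
  }
  if (any(defaults < 0)) stop_domain("variances must be >= 0")
  structure(list(trait_kind = trait_kind, n_lines = n_lines,
                 n_markers = n_markers, maf_range = maf_range, beds = beds,
                 rows_per_bed = rows_per_bed, variances = defaults,
                 root_level = root_level, n_founders = n_founders,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a marker panel
#'
#' Base allele frequencies are uniform on `maf_range`. With
#' `n_founders = NULL` every line's dosage is Binomial(2, p), independent
#' across lines and markers (no relatedness, no linkage disequilibrium).
#' By default lines are instead bred from a founder pool: each line is the
#' cross of two founders, one gamete sampled from each, which produces the
#' family relatedness (half/full sibs sharing founders) that genomic
#' prediction of unphenotyped lines relies on -- with unrelated lines the G
#' matrix is near-diagonal and leave-one-line-out prediction has nothing to
#' carry information across lines.
#'
#' @param n_lines,n_markers panel dimensions.
#' @param maf_range frequency range, a subset of (0, 0.5].
#' @param seed RNG seed.
#' @param n_founders size of the founder pool (default 16), or `NULL` for
#'   independent unrelated lines.
#' @return A [marker_matrix()].
#' @export
simulate_markers <- function(n_lines, n_markers, maf_range = c(0.05, 0.5),
                             seed, n_founders = 16) {
  stopifnot(maf_range[1] > 0, maf_range[2] <= 0.5)
  with_seed(seed, {
    p <- stats::runif(n_markers, maf_range[1], maf_range[2])
    if (is.null(n_founders)) {
      d <- matrix(stats::rbinom(n_lines * n_markers, 2,
                                rep(p, each = n_lines)), nrow = n_lines)
    } else {
      founders <- matrix(stats::rbinom(n_founders * n_markers, 2,
                                       rep(p, each = n_founders)),
                         nrow = n_founders)
      d <- matrix(0L, n_lines, n_markers)
      for (i in seq_len(n_lines)) {
        pa <- sample.int(n_founders, 2)
        d[i, ] <- stats::rbinom(n_markers, 1, founders[pa[1], ] / 2) +
          stats::rbinom(n_markers, 1, founders[pa[2], ] / 2)
      }
    }
    marker_matrix(d, line_ids = sprintf("L%03d", seq_len(n_lines)),
                  marker_ids = sprintf("M%05d", seq_len(n_markers)))
  })
}

#' Simulate a facility layout
#'
#' Each line is sown at least once per bed (one replicate per bed); the
#' remaining rows are filled by random draws, and the order within each bed
#' is shuffled, so a line can occasionally neighbor itself, as imperfect
#' field randomization allows. For root worlds the first bed of each pair
#' carries minirhizotron tubes.
#'
#' @param config a [sim_config()].
#' @return A [build_layout()] result.
#' @export
simulate_layout <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_lines; R <- config$rows_per_bed
  if (n > R) stop_domain("more lines than rows per bed: infeasible replication")
  lines <- sprintf("L%03d", seq_len(n))
  with_seed(derive_seed(config$seed, "layout"), {
    tabs <- lapply(seq_len(config$beds), function(b) {
      fill <- if (R > n) sample(lines, R - n, replace = TRUE) else character(0)
      data.frame(bed = paste0("B", b), row = seq_len(R),
                 line = sample(c(lines, fill)))
    })
    rows_table <- do.call(rbind, tabs)
    tube_beds <- if (config$trait_kind == "root")
      paste0("B", seq(1, config$beds, by = 2)) else NULL
    build_layout(rows_table, tube_beds = tube_beds)
  })
}

# eigen-based PSD square root, for sampling N(0, G sigma2)
psd_sqrt <- function(K) {
  eig <- eigen((K + t(K)) / 2, symmetric = TRUE)
  v <- pmax(eig$values, 0)
  eig$vectors %*% diag(sqrt(v), length(v))
}

#' Simulate trait records under the generative mixed model
#'
#' Draws every random effect of the neighbor model (grain) or the repeated-
#' records root model from its assumed distribution -- `g, g_n ~ N(0, G s2)`
#' through the marker-derived G, `l, l_n, r` iid normal, an iid spatial
#' effect at every real and virtual field location, iid residuals -- and
#' sums them into records: one per row and harvest area for grain, one per
#' tube and depth interval (or per tube) for root. Models without neighbor
#' terms are the zero-variance special case.
#'
#' @param config a [sim_config()].
#' @param markers optional [marker_matrix()] (default: simulated from
#'   `config`).
#' @param layout optional [build_layout()] result (default: simulated).
#' @return A `simulated_dataset`: list with `markers`, `layout`, `G`,
#'   `records`, `truth` (all sampled effect vectors, fixed cells and the
#'   config).
#' @export
simulate_trait <- function(config, markers = NULL, layout = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(markers))
    markers <- simulate_markers(config$n_lines, config$n_markers,
                                config$maf_range,
                                derive_seed(config$seed, "markers"),
                                n_founders = config$n_founders)
  if (is.null(layout)) layout <- simulate_layout(config)
  G <- vanraden_G(impute_and_filter(markers))
  v <- config$variances
  lines <- G$line_ids
  nl <- length(lines)
  LG <- psd_sqrt(G$G)
  rt <- layout$rows
  with_seed(derive_seed(config$seed, "trait"), {
    g <- stats::setNames(as.numeric(LG %*% stats::rnorm(nl)) * sqrt(v[["g"]]),
                         lines)
    l <- stats::setNames(stats::rnorm(nl, 0, sqrt(v[["l"]])), lines)
    truth <- list(g = g, l = l)
    if (config$trait_kind == "grain") {
      g_n <- stats::setNames(
        as.numeric(LG %*% stats::rnorm(nl)) * sqrt(v[["g_n"]]), lines)
      l_n <- stats::setNames(stats::rnorm(nl, 0, sqrt(v[["l_n"]])), lines)
      r <- stats::setNames(stats::rnorm(nrow(rt), 0, sqrt(v[["r"]])),
                           rt$row_id)
      fs <- layout$field_size
      s_wet <- stats::rnorm(fs, 0, sqrt(v[["s_wet"]]))
      s_dry <- stats::rnorm(fs, 0, sqrt(v[["s_dry"]]))
      beds <- sort(unique(rt$bed))
      fixed <- outer(seq_along(beds) * 0.4, c(wet = 0.8, dry = 0), "+") + 10
      rownames(fixed) <- beds
      gxa <- if (v[["gxa"]] > 0)
        matrix(stats::rnorm(2 * nl, 0, sqrt(v[["gxa"]])), nl, 2,
               dimnames = list(lines, c("wet", "dry")))
      else NULL
      recs <- do.call(rbind, lapply(c("wet", "dry"), function(a) {
        data.frame(bed = rt$bed, row = rt$row, area = a, line = rt$line,
                   position = rt$position, row_id = rt$row_id)
      }))
      nb_eff <- function(nbl) ifelse(is.na(nbl), 0,
                                     g_n[nbl] + l_n[nbl])
      win <- function(pos, s) vapply(pos, function(pp)
        sum(s[(pp - 5):(pp + 5) + layout$n_virtual]), 0)
      idx <- match(recs$row_id, rt$row_id)
      val <- fixed[cbind(recs$bed, recs$area)] +
        g[recs$line] + l[recs$line] +
        nb_eff(rt$west_line[idx]) + nb_eff(rt$east_line[idx]) +
        r[recs$row_id] +
        ifelse(recs$area == "wet", win(recs$position, s_wet),
               win(recs$position, s_dry)) +
        stats::rnorm(nrow(recs), 0, sqrt(v[["e"]]))
      if (!is.null(gxa)) val <- val + gxa[cbind(recs$line, recs$area)]
      recs$value <- as.numeric(val)
      truth <- c(truth, list(g_n = g_n, l_n = l_n, r = r, s_wet = s_wet,
                             s_dry = s_dry, fixed = fixed, gxa = gxa))
    } else {
      tubes <- rt[rt$has_tubes, , drop = FALSE]
      r <- stats::setNames(stats::rnorm(nrow(tubes), 0, sqrt(v[["r"]])),
                           tubes$row_id)
      fs <- layout$root_field_size
      s <- stats::rnorm(fs, 0, sqrt(v[["s"]]))
      camera <- ((tubes$root_position - 1L) %% 4L) + 1L
      bed_fx <- stats::setNames(
        20 + 2 * seq_along(unique(tubes$bed)), sort(unique(tubes$bed)))
      cam_fx <- c(0, 0.5, 1.0, 1.5)
      int_fx <- c(8, 6, 4, 2)  # living-root length declines with depth
      swin <- vapply(tubes$root_position, function(pp)
        sum(s[(pp - 5):(pp + 5) + layout$n_virtual]), 0)
      base <- bed_fx[tubes$bed] + cam_fx[camera] + g[tubes$line] +
        l[tubes$line] + swin
      if (config$root_level == "interval") {
        nrec <- nrow(tubes) * 4L
        recs <- data.frame(
          bed = rep(tubes$bed, each = 4L), row = rep(tubes$row, each = 4L),
          camera = rep(camera, each = 4L), interval = rep(1:4, nrow(tubes)),
          line = rep(tubes$line, each = 4L))
        recs$value <- rep(base + r[tubes$row_id], each = 4L) +
          int_fx[recs$interval] + stats::rnorm(nrec, 0, sqrt(v[["e"]]))
      } else {
        recs <- data.frame(bed = tubes$bed, row = tubes$row, camera = camera,
                           line = tubes$line)
        recs$value <- base + stats::rnorm(nrow(tubes), 0, sqrt(v[["e"]]))
      }
      truth <- c(truth, list(r = r, s = s, bed_fx = bed_fx, cam_fx = cam_fx,
                             int_fx = int_fx))
    }
    truth$config <- config
    structure(list(markers = markers, layout = layout, G = G,
                   records = recs, truth = truth),
              class = "simulated_dataset")
  })
}

#' Simulate raw minirhizotron image records
#'
#' A fixture generator for the editing pipeline: images every 5 cm from
#' 0.725 m down to 2.675 m per tube, mean living-root length declining with
#' depth, a small failure rate, and occasional gross outliers. Not a model
#' of real image noise -- it exists so the editing rules can be checked
#' against brute-force filters.
#'
#' @param tubes data frame with `bed`, `tube`, `camera`, `line`.
#' @param seed RNG seed.
#' @param p_fail probability an image is a failed observation.
#' @param p_outlier probability of a gross (x10) outlier.
#' @return Data frame of image records (`bed`, `tube`, `camera`, `depth_m`,
#'   `length_cm`, `valid`, `line`).
#' @export
simulate_root_images <- function(tubes, seed, p_fail = 0.02,
                                 p_outlier = 0.01) {
  depths <- seq(0.725, 2.675, by = 0.05)
  with_seed(seed, {
    recs <- do.call(rbind, lapply(seq_len(nrow(tubes)), function(i) {
      mu <- pmax(3 - depths, 0.3)
      len <- stats::rgamma(length(depths), shape = 2, scale = mu / 2)
      out <- stats::runif(length(depths)) < p_outlier
      len[out] <- len[out] * 10
      data.frame(bed = tubes$bed[i], tube = tubes$tube[i],
                 camera = tubes$camera[i], depth_m = depths,
                 length_cm = len,
                 valid = stats::runif(length(depths)) >= p_fail,
                 line = tubes$line[i])
    }))
    rownames(recs) <- NULL
    recs
  })
}
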