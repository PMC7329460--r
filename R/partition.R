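#' Average replication counts per line
#'
#' The line-mean phenotypic variance weights each variance component by how
#' often it is averaged over in a line mean: `n_r` is the average number of
#' distinct rows per line, `n_s` (per harvest area) the average number of
#' distinct field positions with records per line, and `n_e` the average
#' number of records per line across all areas.
#'
#' @param records trait records with columns `line`, `bed`, `row` and
#'   (grain) `area`.
#' @param layout a [build_layout()] result (used to validate row ids).
#' @param model a [model_spec()] or preset name.
#' @return List with `n_r`, `n_s` (named per area, or single-element `"all"`
#'   for root models), `n_e`, `n_lines`.
#' @export
replicate_counts <- function(records, layout, model) {
  if (is.character(model)) model <- model_spec(model)
  records <- as.data.frame(records)
  records <- records[!is.na(records$value), , drop = FALSE]
  layout_index(layout, records)  # validation only
  rows <- paste0(records$bed, ":", records$row)
  per_line <- split(seq_len(nrow(records)), records$line)
  n_r <- mean(vapply(per_line, function(i) length(unique(rows[i])), 0))
  n_e <- mean(lengths(per_line))
  areas <- if (model$kind == "grain") c(wet = "wet", dry = "dry")
           else c(all = "all")
  n_s <- vapply(areas, function(a) {
    sel <- if (a == "all") rep(TRUE, nrow(records)) else records$area == a
    with_rec <- split(rows[sel], records$line[sel])
    mean(vapply(with_rec, function(r) length(unique(r)), 0))
  }, 0)
  list(n_r = n_r, n_s = n_s, n_e = n_e, n_lines = length(per_line))
}

# weighted components entering the line-mean phenotypic variance of `area`
partition_weights <- function(vcs, counts, model, g_bar, area) {
  w <- c()
  add <- function(label, weight) {
    if (label %in% names(vcs)) w[label] <<- weight * vcs[[label]]
  }
  add("g", g_bar)
  add("l", 1)
  add("g_n", 2 * g_bar)
  add("l_n", 2)
  add("r", 1 / counts$n_r)
  slab <- if (model$kind == "grain") paste0("s_", area) else "s"
  if (slab %in% names(vcs))
    w[slab] <- 11 * vcs[[slab]] / counts$n_s[[area]]
  add("e", 1 / counts$n_e)
  w
}

#' Line-mean phenotypic variance from the weighted-component formulas
#'
#' For the grain models, `sigma2_P = Gbar sigma2_g + sigma2_l
#' [+ 2 Gbar sigma2_gn + 2 sigma2_ln] + sigma2_r / n_r + 11 sigma2_si / n_si
#' + sigma2_e / n_e`, computed separately per harvest area because the
#' spatial variance is heterogeneous; the root models use their single
#' spatial field (and RM1 carries no row term).
#'
#' @param vcs named variance components (from [reml_fit()] or by hand).
#' @param counts replication counts, see [replicate_counts()].
#' @param model a [model_spec()] or preset name.
#' @param g_bar average diagonal of the G matrix.
#' @return Named vector of `sigma2_P`, one entry per area.
#' @export
line_mean_pvar <- function(vcs, counts, model, g_bar) {
  if (is.character(model)) model <- model_spec(model)
  need <- c(model$terms, "e")
  if (!all(need %in% names(vcs)))
    stop_domain("missing components for ", model$name, ": ",
                paste(setdiff(need, names(vcs)), collapse = ", "))
  areas <- names(counts$n_s)
  vapply(areas, function(a)
    sum(partition_weights(vcs, counts, model, g_bar, a)), 0)
}

#' Variance partition: RVCs, heritabilities and genetic CV
#'
#' Relative variance components (RVCs) divide each weighted component by the
#' line-mean phenotypic variance of the area, so they sum to one. The RVC
#' of the genomic term is the line-mean narrow-sense heritability `h2`; the
#' genomic plus line RVCs give the broad-sense `H2`. Grain traits report
#' each area and the unweighted wet/dry average; root traits a single area.
#'
#' @param fit a [reml_fit()] result (or any named component vector via
#'   `vcs`).
#' @param counts replication counts from [replicate_counts()].
#' @param g_bar average diagonal of G.
#' @param trait_mean mean of the observations (for the genetic CV).
#' @param model a [model_spec()] or preset name.
#' @return An object of class `partition_report`: `table` (area, term,
#'   variance, weighted, rvc), `sigma2_P`, `h2` (per area), `h2_mean`,
#'   `H2` (per area), `H2_mean`, `cv_pct`, `trait_mean`.
#' @export
partition_report <- function(fit, counts, g_bar, trait_mean, model) {
  if (is.character(model)) model <- model_spec(model)
  vcs <- if (inherits(fit, "mixed_model_fit")) fit$vcs else fit
  s2p <- line_mean_pvar(vcs, counts, model, g_bar)
  if (any(s2p <= 0)) stop_domain("non-positive line-mean variance")
  tabs <- lapply(names(s2p), function(a) {
    w <- partition_weights(vcs, counts, model, g_bar, a)
    data.frame(area = a, term = names(w),
               variance = as.numeric(vcs[names(w)]),
               weighted = as.numeric(w),
               rvc = as.numeric(w) / s2p[[a]])
  })
  tab <- do.call(rbind, tabs)
  h2 <- vapply(names(s2p), function(a)
    tab$rvc[tab$area == a & tab$term == "g"], 0)
  H2 <- vapply(names(s2p), function(a)
    sum(tab$rvc[tab$area == a & tab$term %in% c("g", "l")]), 0)
  structure(list(table = tab, sigma2_P = s2p, h2 = h2, h2_mean = mean(h2),
                 H2 = H2, H2_mean = mean(H2),
                 cv_pct = genetic_cv(vcs, trait_mean),
                 trait_mean = trait_mean, model = model$name),
            class = "partition_report")
}

#' @export
print.partition_report <- function(x, ...) {
  cat(sprintf("<partition_report> %s: h2 = %.3f, H2 = %.3f, cv = %.2f%%\n",
              x$model, x$h2_mean, x$H2_mean, x$cv_pct))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Coefficient of genetic variation
#'
#' `100 * sqrt(sigma2_g) / mean`: the genomic standard deviation relative to
#' the trait mean, in percent. The genomic variance enters unweighted
#' (no G-bar weighting); set `use_g_bar` to scale the genomic variance by
#' the average G diagonal instead.
#'
#' @param vcs named variance components containing `g`.
#' @param trait_mean positive trait mean.
#' @param use_g_bar multiply `sigma2_g` by `g_bar` first (default `FALSE`).
#' @param g_bar average diagonal of G (needed when `use_g_bar`).
#' @return CV in percent.
#' @export
genetic_cv <- function(vcs, trait_mean, use_g_bar = FALSE, g_bar = NULL) {
  if (trait_mean <= 0) stop_domain("trait mean must be positive")
  v <- as.numeric(vcs[["g"]])
  if (use_g_bar) v <- v * g_bar
  100 * sqrt(v) / trait_mean
}
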