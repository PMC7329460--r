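#' Model presets for grain and root traits
#'
#' Four presets are available:
#' \describe{
#'   \item{GM1}{grain: fixed bed x area cell means; random direct genomic
#'     (`g`, G-structured) and line (`l`) effects, row effects (`r`), and a
#'     running-sum spatial field per harvest area (`s_wet`, `s_dry`).}
#'   \item{GM2}{GM1 plus combined east+west neighbor effects: genomic
#'     (`g_n`, G-structured) and line (`l_n`).}
#'   \item{RM1}{root, one record per tube: fixed bed cell means plus camera
#'     contrasts; random `g`, `l` and a single spatial field `s`.}
#'   \item{RM2}{root, repeated records per tube (one per depth interval):
#'     RM1 plus fixed depth-interval contrasts and random tube effects `r`.}
#' }
#' East and west neighbor effects share one effect vector and one variance
#' (summed incidence), and the genotype-by-water-availability interaction is
#' deliberately absent from all presets.
#'
#' @param name one of `"GM1"`, `"GM2"`, `"RM1"`, `"RM2"`.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(name = c("GM1", "GM2", "RM1", "RM2")) {
  name <- match.arg(name)
  kind <- if (startsWith(name, "G")) "grain" else "root"
  terms <- switch(name,
    GM1 = c("g", "l", "r", "s_wet", "s_dry"),
    GM2 = c("g", "l", "g_n", "l_n", "r", "s_wet", "s_dry"),
    RM1 = c("g", "l", "s"),
    RM2 = c("g", "l", "r", "s"))
  structure(list(name = name, kind = kind, terms = terms),
            class = "model_spec")
}

# Full-rank fixed design: cell means for the first factor, drop-first-level
# contrasts for the rest. Errors name the aliased factor on rank deficiency.
build_fixed_design <- function(factors) {
  stopifnot(length(factors) >= 1L)
  nm <- names(factors)
  f1 <- factor(factors[[1L]])
  X <- if (nlevels(f1) > 1L) stats::model.matrix(~ f1 - 1)
       else matrix(1, length(f1), 1)
  colnames(X) <- paste0(nm[1L], levels(f1))
  for (k in seq_along(factors)[-1L]) {
    fk <- factor(factors[[k]])
    if (nlevels(fk) > 1L) {
      Xk <- stats::model.matrix(~ fk)[, -1L, drop = FALSE]
      colnames(Xk) <- paste0(nm[k], levels(fk)[-1L])
      X <- cbind(X, Xk)
    }
    if (qr(X)$rank < ncol(X))
      stop_domain("fixed design rank-deficient after adding factor '",
                  nm[k], "'")
  }
  if (qr(X)$rank < ncol(X))
    stop_domain("fixed design rank-deficient in factor '", nm[1L], "'")
  X
}

# incidence of records on a set of levels
indicator <- function(values, levels) {
  Z <- matrix(0, length(values), length(levels),
              dimnames = list(NULL, levels))
  j <- match(as.character(values), levels)
  if (anyNA(j)) stop_domain("records reference unknown levels")
  Z[cbind(seq_along(values), j)] <- 1
  Z
}

#' Assemble response, fixed design and random incidences for a model
#'
#' Turns trait records, the facility layout and a genomic relationship
#' matrix into the dense design matrices of the chosen model preset. Grain
#' records need columns `bed`, `row`, `area` (`"wet"`/`"dry"`), `line`,
#' `value`; root records need `bed`, `row` (the tube), `camera`, `line`,
#' `value`, plus `interval` for RM2.
#'
#' @param spec a [model_spec()] (or preset name).
#' @param records trait record data frame.
#' @param layout a [build_layout()] result.
#' @param G a `genomic_relationship` (see [vanraden_G()]) covering every
#'   line in `records`; its full line set defines the `g` levels, so lines
#'   without records still receive genomic predictions.
#' @return An object of class `model_bundle`: list with `y`, `X`, `random`
#'   (list of `(label, Z, K, ids)`; `K = NULL` means identity covariance),
#'   `meta` (per-record line/area/row/position), `spec`, `g_bar`.
#' @export
assemble_model <- function(spec, records, layout, G) {
  if (is.character(spec)) spec <- model_spec(spec)
  stopifnot(inherits(spec, "model_spec"), inherits(layout, "facility_layout"),
            inherits(G, "genomic_relationship"))
  records <- as.data.frame(records)
  if (anyNA(records$value)) {
    records <- records[!is.na(records$value), , drop = FALSE]
  }
  miss <- setdiff(unique(records$line), G$line_ids)
  if (length(miss) > 0L)
    stop_domain("lines without genomic information: ",
                paste(utils::head(miss, 3), collapse = ", "))
  y <- as.numeric(records$value)
  idx <- layout_index(layout, records)
  lines <- G$line_ids
  Zl <- indicator(records$line, lines)

  if (spec$kind == "grain") {
    if (!all(records$area %in% c("wet", "dry")))
      stop_domain("grain records need area 'wet'/'dry'")
    X <- build_fixed_design(list(bed_area = paste0(records$bed, ".",
                                                   records$area)))
    row_levels <- layout$rows$row_id
  } else {
    fx <- list(bed = records$bed, camera = records$camera)
    if (spec$name == "RM2") fx$interval <- records$interval
    X <- build_fixed_design(fx)
    tube_rows <- layout$rows$row_id[layout$rows$has_tubes]
    row_levels <- if (length(tube_rows) > 0L) tube_rows else layout$rows$row_id
  }

  random <- list()
  add <- function(label, Z, K = NULL)
    random[[length(random) + 1L]] <<- list(label = label, Z = Z, K = K,
                                           ids = colnames(Z))
  for (term in spec$terms) {
    switch(term,
      g = add("g", Zl, G$G),
      l = add("l", Zl),
      g_n = add("g_n", neighbor_incidence(layout, records, lines), G$G),
      l_n = add("l_n", neighbor_incidence(layout, records, lines)),
      r = add("r", indicator(paste0(records$bed, ":", records$row),
                             row_levels)),
      s_wet = add("s_wet", spatial_incidence(layout, records, area = "wet")),
      s_dry = add("s_dry", spatial_incidence(layout, records, area = "dry")),
      s = add("s", spatial_incidence(layout, records, field = "root")))
  }
  meta <- data.frame(line = records$line,
                     area = if ("area" %in% names(records)) records$area
                            else "all",
                     row = paste0(records$bed, ":", records$row),
                     bed = records$bed,
                     position = layout$rows$position[idx],
                     stringsAsFactors = FALSE)
  structure(list(y = y, X = X, random = random, meta = meta, spec = spec,
                 g_bar = G$mean_diagonal),
            class = "model_bundle")
}

#' Export a design matrix in MatrixMarket coordinate format
#'
#' A debugging aid: writes the fixed design (`term = "X"`) or a random
#' term's incidence matrix as sparse MatrixMarket text.
#'
#' @param bundle a [assemble_model()] result.
#' @param term `"X"` or a random-term label (e.g. `"g"`, `"s_wet"`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_incidence_mm <- function(bundle, term, path) {
  stopifnot(inherits(bundle, "model_bundle"))
  M <- if (identical(term, "X")) bundle$X else {
    labels <- vapply(bundle$random, `[[`, "", "label")
    k <- match(term, labels)
    if (is.na(k)) stop_domain("no term '", term, "'")
    bundle$random[[k]]$Z
  }
  # 0/1 incidences come out in "pattern" format, general matrices as "real"
  Matrix::writeMM(Matrix::drop0(Matrix::Matrix(M, sparse = TRUE)), path)
  invisible(path)
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf("<model_bundle> %s: %d records, %d fixed columns\n",
              x$spec$name, length(x$y), ncol(x$X)))
  for (b in x$random)
    cat(sprintf("  random %-6s q=%4d  %s\n", b$label, ncol(b$Z),
                if (is.null(b$K)) "identity" else "G-structured"))
  invisible(x)
}
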