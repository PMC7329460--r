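#' Construct a validated marker matrix
#'
#' A `marker_matrix` holds allele dosages (counts of the alternate allele,
#' 0/1/2 or `NA`) for a set of lines, the raw material for the genomic
#' relationship matrix.
#'
#' @param dosages numeric matrix, lines in rows, markers in columns; entries
#'   must be 0, 1, 2 or `NA`.
#' @param line_ids character vector of unique line identifiers, one per row.
#' @param marker_ids character vector of marker identifiers, one per column.
#' @param validate_dosages check that entries are 0/1/2/`NA`; internal callers
#'   disable this after mean imputation, which leaves fractional dosages.
#' @return An object of class `marker_matrix` with fields `dosages`,
#'   `line_ids`, `marker_ids`.
#' @export
marker_matrix <- function(dosages, line_ids = rownames(dosages),
                          marker_ids = colnames(dosages),
                          validate_dosages = TRUE) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(line_ids)) line_ids <- paste0("L", seq_len(nrow(dosages)))
  if (is.null(marker_ids)) marker_ids <- paste0("M", seq_len(ncol(dosages)))
  line_ids <- as.character(line_ids)
  marker_ids <- as.character(marker_ids)
  if (ncol(dosages) < 1L) stop_domain("marker matrix needs at least one marker")
  if (anyDuplicated(line_ids))
    stop_domain("duplicate line ids: ",
                paste(unique(line_ids[duplicated(line_ids)]), collapse = ", "))
  bad <- if (validate_dosages)
    which(!is.na(dosages) & !(dosages %in% c(0, 1, 2)), arr.ind = TRUE)
  else matrix(integer(0), 0, 2)
  if (nrow(bad) > 0L)
    stop_domain(sprintf(
      "invalid dosage %s at line '%s', marker '%s' (must be 0/1/2 or missing)",
      format(dosages[bad[1, , drop = FALSE]]),
      line_ids[bad[1, 1]], marker_ids[bad[1, 2]]))
  dimnames(dosages) <- list(line_ids, marker_ids)
  structure(list(dosages = dosages, line_ids = line_ids,
                 marker_ids = marker_ids),
            class = "marker_matrix")
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat(sprintf("<marker_matrix> %d lines x %d markers (%d missing entries)\n",
              nrow(x$dosages), ncol(x$dosages), sum(is.na(x$dosages))))
  invisible(x)
}

#' Read a marker dosage table from delimited text
#'
#' The first column is the line id; remaining columns are allele dosages with
#' marker ids in the header. Field separator is sniffed from the header line
#' (comma or tab) unless given. A PLINK `.raw` additive-coding file (header
#' starting `FID IID ...`, whitespace-separated, six leading pedigree
#' columns) is detected automatically; the IID column becomes the line id.
#'
#' @param path file path.
#' @param sep field separator, or `NULL` to autodetect.
#' @param missing_codes values treated as missing besides empty/`NA`.
#' @return A [marker_matrix()].
#' @export
load_markers <- function(path, sep = NULL, missing_codes = c("NA", ".", "")) {
  if (!file.exists(path)) stop_domain("marker file not found: ", path)
  first <- readLines(path, n = 1L)
  if (grepl("^FID[ \t]+IID", first)) {            # PLINK .raw additive coding
    df <- utils::read.table(path, header = TRUE, colClasses = "character",
                            check.names = FALSE)
    ids <- df[["IID"]]
    raw <- as.matrix(df[, -(1:6), drop = FALSE])
  } else {
    if (is.null(sep)) sep <- if (grepl("\t", first)) "\t" else ","
    df <- utils::read.table(path, header = TRUE, sep = sep,
                            colClasses = "character", check.names = FALSE,
                            strip.white = TRUE)
    if (ncol(df) < 2L)
      stop_domain("marker file needs id column plus >=1 marker")
    ids <- df[[1L]]
    raw <- as.matrix(df[, -1L, drop = FALSE])
  }
  raw[raw %in% missing_codes] <- NA
  num <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw),
                                 dimnames = dimnames(raw)))
  nonnum <- which(is.na(num) & !is.na(raw), arr.ind = TRUE)
  if (nrow(nonnum) > 0L)
    stop_domain(sprintf("non-numeric dosage '%s' at row %d, column '%s'",
                        raw[nonnum[1, , drop = FALSE]], nonnum[1, 1],
                        colnames(raw)[nonnum[1, 2]]))
  marker_matrix(num, line_ids = ids, marker_ids = colnames(raw))
}

#' Write a marker matrix as CSV
#'
#' @param m a [marker_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_markers <- function(m, path) {
  df <- data.frame(line = m$line_ids, m$dosages, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Mean-impute missing dosages and drop monomorphic markers
#'
#' Missing entries are replaced by the marker's mean observed dosage (which
#' preserves the allele-frequency estimate). Markers with zero variance after
#' imputation carry no information for the relationship matrix and are
#' removed when `drop_monomorphic` is set.
#'
#' @param m a [marker_matrix()].
#' @param drop_monomorphic drop zero-variance markers (default `TRUE`).
#' @return A [marker_matrix()] without missing values, marker order preserved.
#' @export
impute_and_filter <- function(m, drop_monomorphic = TRUE) {
  stopifnot(inherits(m, "marker_matrix"))
  d <- m$dosages
  mu <- colMeans(d, na.rm = TRUE)
  if (anyNA(mu)) {
    allmiss <- which(is.na(mu))
    stop_domain("marker(s) with no observed dosages: ",
                paste(m$marker_ids[allmiss], collapse = ", "))
  }
  na_idx <- which(is.na(d), arr.ind = TRUE)
  if (nrow(na_idx) > 0L) d[na_idx] <- mu[na_idx[, 2L]]
  if (drop_monomorphic) {
    v <- apply(d, 2L, stats::var)
    keep <- v > 0
    if (!any(keep)) stop_domain("all markers monomorphic: empty panel")
    d <- d[, keep, drop = FALSE]
  }
  # imputed entries are fractional marker means, so skip the 0/1/2 check
  marker_matrix(d, line_ids = m$line_ids, marker_ids = colnames(d),
                validate_dosages = FALSE)
}

#' Genomic relationship matrix, VanRaden method 1
#'
#' With `p_j` the observed alternate-allele frequency of marker `j` and
#' `Z = M - 2P` the column-centred dosage matrix, the additive relationship
#' matrix is `G = Z Z' / (2 * sum_j p_j (1 - p_j))`. Allele frequencies are
#' computed from the lines supplied (no base-population frequencies).
#'
#' @param m a [marker_matrix()] without missing entries (fractional imputed
#'   dosages are allowed).
#' @param ridge optional non-negative scalar added to the diagonal for
#'   downstream solver stability (default 0: the plain method-1 matrix).
#' @return An object of class `genomic_relationship`: list with `G`
#'   (n x n symmetric), `mean_diagonal` (the average diagonal, often written
#'   G-bar), `line_ids`, `denominator`.
#' @export
vanraden_G <- function(m, ridge = 0) {
  stopifnot(inherits(m, "marker_matrix"))
  d <- m$dosages
  if (anyNA(d)) stop_domain("missing dosages: run impute_and_filter() first")
  p <- colMeans(d) / 2
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop_domain("degenerate panel: all markers monomorphic")
  Z <- sweep(d, 2L, 2 * p, "-")
  G <- tcrossprod(Z) / denom
  G <- (G + t(G)) / 2
  if (ridge > 0) G <- G + diag(ridge, nrow(G))
  dimnames(G) <- list(m$line_ids, m$line_ids)
  structure(list(G = G, mean_diagonal = mean(diag(G)),
                 line_ids = m$line_ids, denominator = denom),
            class = "genomic_relationship")
}

#' @export
print.genomic_relationship <- function(x, ...) {
  cat(sprintf("<genomic_relationship> %d lines, mean diagonal %.4f\n",
              length(x$line_ids), x$mean_diagonal))
  invisible(x)
}

#' Write a genomic relationship matrix as square CSV
#'
#' @param g a `genomic_relationship`.
#' @param path output path.
#' @export
write_G <- function(g, path) {
  df <- data.frame(line = g$line_ids, g$G, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
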