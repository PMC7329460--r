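#' Build a facility layout with neighbor map and spatial fields
#'
#' Rows sit side by side along each pair of beds. The two beds of a pair are
#' treated as one contiguous line of real positions, and where data span two
#' bed-pairs both pairs map onto the same spatial location levels by
#' within-pair position; this is what makes a four-bed facility with 150
#' rows per bed produce a 310-location spatial field per harvest area
#' (2 x 150 real positions plus 5 virtual border positions at each end).
#' Neighbors are the lines at positions +/-1 within the same pair (rows at
#' pair ends have a single neighbor).
#'
#' @param rows_table data frame with columns `bed`, `row` (within-bed index),
#'   `line`, and optionally `pair` and `position`. When absent, beds are
#'   paired in sorted order (1-2, 3-4, ...) and the position runs 1..150 in
#'   the first bed of the pair and 151..300 in the second.
#' @param n_virtual virtual border positions per field end (default 5).
#' @param tube_beds bed ids equipped with minirhizotron tubes, or `NULL`.
#'   Tube beds are concatenated (in sorted bed order) into a single root
#'   spatial field with its own position index.
#' @param segment_breaks optional numeric positions (e.g. `150.5`) across
#'   which neither the neighbor relation nor spatial windows may reach.
#' @return An object of class `facility_layout`: list with `rows` (one row
#'   per facility row, including `row_id`, `position`, `west_line`,
#'   `east_line`, `root_position`), `n_virtual`, `field_size`,
#'   `root_field_size`, `segment_breaks`.
#' @export
build_layout <- function(rows_table, n_virtual = 5, tube_beds = NULL,
                         segment_breaks = NULL) {
  req <- c("bed", "row", "line")
  if (!all(req %in% names(rows_table)))
    stop_domain("rows_table needs columns: ", paste(req, collapse = ", "))
  rt <- as.data.frame(rows_table)
  rt$bed <- as.character(rt$bed)
  if (anyDuplicated(rt[c("bed", "row")]))
    stop_domain("duplicate (bed, row) in layout")
  beds <- sort(unique(rt$bed))
  if (!"pair" %in% names(rt))
    rt$pair <- ceiling(match(rt$bed, beds) / 2)
  if (!"position" %in% names(rt)) {
    rt <- rt[order(rt$pair, rt$bed, rt$row), ]
    pos <- integer(nrow(rt))
    for (p in unique(rt$pair)) {
      idx <- which(rt$pair == p)
      pbeds <- sort(unique(rt$bed[idx]))
      off <- 0L
      for (b in pbeds) {
        bi <- idx[rt$bed[idx] == b]
        bi <- bi[order(rt$row[bi])]
        pos[bi] <- off + seq_along(bi)
        off <- off + length(bi)
      }
    }
    rt$position <- pos
  }
  for (p in unique(rt$pair)) {
    pp <- sort(rt$position[rt$pair == p])
    if (anyDuplicated(pp)) stop_domain("duplicate position in pair ", p)
    if (!all(diff(pp) == 1L))
      stop_domain("gaps in position index within pair ", p,
                  " (declare positions explicitly if intended)")
  }
  rt$row_id <- paste0(rt$bed, ":", rt$row)
  # neighbor map within pair, not crossing declared segment breaks
  crosses <- function(a, b) {
    if (is.null(segment_breaks)) return(rep(FALSE, length(a)))
    vapply(seq_along(a), function(i)
      any(segment_breaks > min(a[i], b[i]) & segment_breaks < max(a[i], b[i])),
      logical(1))
  }
  key <- paste(rt$pair, rt$position)
  line_at <- stats::setNames(rt$line, key)
  wkey <- paste(rt$pair, rt$position - 1L)
  ekey <- paste(rt$pair, rt$position + 1L)
  rt$west_line <- unname(line_at[wkey])
  rt$east_line <- unname(line_at[ekey])
  rt$west_line[crosses(rt$position, rt$position - 1L)] <- NA
  rt$east_line[crosses(rt$position, rt$position + 1L)] <- NA
  # root spatial field: tube beds concatenated in sorted order
  rt$has_tubes <- rt$bed %in% (tube_beds %||% character(0))
  rt$root_position <- NA_integer_
  root_field_size <- NA_integer_
  if (!is.null(tube_beds)) {
    tb <- sort(unique(as.character(tube_beds)))
    off <- 0L
    for (b in tb) {
      bi <- which(rt$bed == b)
      if (length(bi) == 0L) stop_domain("tube bed '", b, "' not in layout")
      bi <- bi[order(rt$row[bi])]
      rt$root_position[bi] <- off + seq_along(bi)
      off <- off + length(bi)
    }
    root_field_size <- off + 2L * n_virtual
  }
  rt <- rt[order(rt$pair, rt$position), ]
  rownames(rt) <- NULL
  structure(list(rows = rt, n_virtual = as.integer(n_virtual),
                 field_size = max(rt$position) + 2L * n_virtual,
                 root_field_size = root_field_size,
                 segment_breaks = segment_breaks),
            class = "facility_layout")
}

#' @export
print.facility_layout <- function(x, ...) {
  cat(sprintf(
    "<facility_layout> %d rows, %d beds, field size %d (%d virtual/end)\n",
    nrow(x$rows), length(unique(x$rows$bed)), x$field_size, x$n_virtual))
  invisible(x)
}

# Look up layout rows for a record table by (bed, row); errors on unknown rows.
layout_index <- function(layout, records) {
  ids <- paste0(as.character(records$bed), ":", records$row)
  idx <- match(ids, layout$rows$row_id)
  if (anyNA(idx))
    stop_domain("records reference unknown rows: ",
                paste(utils::head(unique(ids[is.na(idx)]), 3), collapse = ", "))
  idx
}

#' Neighbor incidence matrix
#'
#' Entry (i, j) counts how many of record i's row neighbors (west and east)
#' carry line j: 0, 1 or 2. Border rows contribute a single 1; rows with no
#' neighbors give a zero row. This is the summed east+west incidence used
#' for the combined indirect genetic (neighbor) effect.
#'
#' @param layout a [build_layout()] result.
#' @param records data frame with `bed` and `row` columns.
#' @param line_ids column order of the result (default: lines in layout).
#' @return Matrix of dimension `nrow(records)` x `length(line_ids)`.
#' @export
neighbor_incidence <- function(layout, records,
                               line_ids = sort(unique(layout$rows$line))) {
  idx <- layout_index(layout, records)
  Z <- matrix(0, nrow(records), length(line_ids),
              dimnames = list(NULL, line_ids))
  for (side in c("west_line", "east_line")) {
    nb <- layout$rows[[side]][idx]
    j <- match(nb, line_ids)
    ok <- which(!is.na(j))
    for (i in ok) Z[i, j[i]] <- Z[i, j[i]] + 1
  }
  Z
}

#' Running-sum spatial incidence matrix
#'
#' Each record's spatial effect is the sum of the effects of the 11 field
#' locations centred on its own position (offsets -5..+5); offsets past the
#' field ends land on virtual border locations, so every in-area record has
#' exactly 11 ones. Records from other areas (when `area` is given) get a
#' zero row, and declared segment breaks truncate windows.
#'
#' @param layout a [build_layout()] result.
#' @param records data frame with `bed`, `row`, and (for grain) `area`.
#' @param area restrict ones to records of this area (`NULL`: all records).
#' @param field `"grain"` uses the within-pair position shared across pairs;
#'   `"root"` uses the concatenated tube-bed position.
#' @return Matrix `nrow(records)` x field size.
#' @export
spatial_incidence <- function(layout, records, area = NULL,
                              field = c("grain", "root")) {
  field <- match.arg(field)
  idx <- layout_index(layout, records)
  if (field == "grain") {
    pos <- layout$rows$position[idx]
    fs <- layout$field_size
  } else {
    pos <- layout$rows$root_position[idx]
    fs <- layout$root_field_size
    if (is.na(fs)) stop_domain("layout has no root field (no tube beds)")
    if (anyNA(pos)) stop_domain("root records on rows without tubes")
  }
  nv <- layout$n_virtual
  use <- if (is.null(area)) rep(TRUE, nrow(records))
         else records$area == area
  Z <- matrix(0, nrow(records), fs,
              dimnames = list(NULL, paste0("loc", seq_len(fs) - nv)))
  half <- 5L
  for (i in which(use)) {
    offs <- (pos[i] - half):(pos[i] + half)
    if (!is.null(layout$segment_breaks)) {
      blocked <- vapply(offs, function(o)
        any(layout$segment_breaks > min(o, pos[i]) &
            layout$segment_breaks < max(o, pos[i])), logical(1))
      offs <- offs[!blocked]
    }
    cols <- offs + nv
    if (any(cols < 1L | cols > fs))
      stop_domain("position outside field after virtual margin")
    Z[i, cols] <- 1
  }
  Z
}
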