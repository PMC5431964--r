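#' Classify hotspot cells by nature-reserve coverage
#'
#' Each hotspot cell's coverage fraction is `reserve_area / land_area`.
#' Cells are classified as `uncovered` (coverage exactly 0),
#' `under_protected` (0 < coverage < threshold) or `protected` (coverage >=
#' threshold). A conservation gap is any non-protected hotspot cell. The
#' boundary case of coverage exactly at the threshold is counted as
#' protected by default; `strict_protected = TRUE` demands strictly greater
#' coverage instead (sources describing the rule as "more than" vs "less
#' than" the threshold differ on this point).
#'
#' @param hotspots a `hotspot_set`, a data frame with a `cell_id` column
#'   (e.g. from [hotspot_union()], whose `n_metrics` column is carried
#'   through), or a character vector of cell ids.
#' @param cells cell table containing every hotspot cell.
#' @param threshold coverage fraction in (0, 1) separating gaps from
#'   protected cells; default 0.10, the conventional 10% protection target.
#' @param strict_protected if `TRUE`, coverage exactly at the threshold is
#'   still a gap.
#' @return an object of class `gap_report`: list with `cells` (data frame
#'   `cell_id`, `coverage`, `class`, and `n_metrics` when supplied),
#'   `summary` (named proportions of hotspot cells per class plus
#'   `gap_fraction`), and `per_n` (data frame of per-n-metric gap area
#'   fractions) when `n_metrics` was supplied.
#' @export
classify_gaps <- function(hotspots, cells, threshold = 0.10,
                          strict_protected = FALSE) {
  stopifnot(length(threshold) == 1L, threshold > 0, threshold < 1)
  cells <- validate_cells(cells)
  n_metrics <- NULL
  if (inherits(hotspots, "hotspot_set")) {
    ids <- hotspots$cells
  } else if (is.data.frame(hotspots)) {
    stopifnot("cell_id" %in% names(hotspots))
    ids <- as.character(hotspots$cell_id)
    if ("n_metrics" %in% names(hotspots)) n_metrics <- hotspots$n_metrics
  } else {
    ids <- as.character(hotspots)
  }
  idx <- match(ids, cells$cell_id)
  if (anyNA(idx)) {
    stop("hotspot cell(s) absent from the cell table: ",
         paste(utils::head(ids[is.na(idx)], 5), collapse = ", "), call. = FALSE)
  }
  land <- cells$land_area[idx]
  cov <- ifelse(land > 0, cells$reserve_area[idx] / land, 0)
  protected <- if (strict_protected) cov > threshold else cov >= threshold
  cls <- ifelse(cov == 0, "uncovered",
                ifelse(protected, "protected", "under_protected"))
  out <- data.frame(cell_id = ids, coverage = cov, class = cls)
  if (!is.null(n_metrics)) out$n_metrics <- n_metrics

  summary <- c(
    prop_uncovered = mean(cls == "uncovered"),
    prop_under_protected = mean(cls == "under_protected"),
    prop_protected = mean(cls == "protected")
  )
  summary["gap_fraction"] <- summary[["prop_uncovered"]] +
    summary[["prop_under_protected"]]

  per_n <- NULL
  if (!is.null(n_metrics)) {
    gap <- cls != "protected"
    per_n <- do.call(rbind, lapply(sort(unique(n_metrics)), function(n) {
      in_n <- n_metrics == n
      data.frame(n_metrics = n,
                 n_cells = sum(in_n),
                 gap_area_fraction = sum(land[in_n & gap]) / sum(land[in_n]))
    }))
  }
  structure(list(cells = out, summary = summary, per_n = per_n,
                 threshold = threshold, strict_protected = strict_protected),
            class = "gap_report")
}

#' @export
print.gap_report <- function(x, ...) {
  cat(sprintf("Gap report (%d hotspot cells, threshold %.0f%%%s)\n",
              nrow(x$cells), 100 * x$threshold,
              if (x$strict_protected) ", strict" else ""))
  cat(sprintf("  uncovered %.2f%%, under-protected %.2f%%, protected %.2f%%\n",
              100 * x$summary[["prop_uncovered"]],
              100 * x$summary[["prop_under_protected"]],
              100 * x$summary[["prop_protected"]]))
  if (!is.null(x$per_n)) {
    cat("  gap area fraction by number of selecting metrics:\n")
    print(x$per_n, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Reserve area within hotspot cells
#'
#' Total reserve-covered area inside a hotspot cell set, with its fraction
#' of the study's total land area and of the study's total reserve area.
#'
#' @param hotspot_cells character vector of cell ids (or a `hotspot_set`).
#' @param cells cell table.
#' @return list with `reserve_area_in_hotspots`, `fraction_of_land`,
#'   `fraction_of_reserves`.
#' @export
overlap_area <- function(hotspot_cells, cells) {
  cells <- validate_cells(cells)
  if (inherits(hotspot_cells, "hotspot_set")) hotspot_cells <- hotspot_cells$cells
  idx <- match(as.character(hotspot_cells), cells$cell_id)
  if (anyNA(idx)) stop("hotspot cell(s) absent from the cell table", call. = FALSE)
  ra <- sum(cells$reserve_area[idx])
  total_land <- sum(cells$land_area)
  total_res <- sum(cells$reserve_area)
  list(reserve_area_in_hotspots = ra,
       fraction_of_land = if (total_land > 0) ra / total_land else NA_real_,
       fraction_of_reserves = if (total_res > 0) ra / total_res else NA_real_)
}
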