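# Cohort-summary arithmetic for the offspring-assessment and karyotype
# screening tables of the two-subline experimental design.

#' Summarize a cohort count table
#'
#' Two table shapes are supported. An offspring table has a `group` column,
#' an optional pool identifier column, a `total` column and further numeric
#' category columns (e.g. normal / died / abnormal); per group the counts
#' are summed and percentages computed as `100 * category_sum / total_sum`.
#' A karyotype table has a class column and a single `count` column;
#' percentages are of the grand total. Percentages are rounded half-up to
#' two decimals, matching the printed-table convention.
#'
#' @param table a data.frame.
#' @param group name of the grouping column (ignored if absent).
#' @param total name of the total-count column; if the table has no such
#'   column but has a `count` column, the karyotype shape is assumed.
#' @return a data.frame of per-group sums and percentages (or per-class
#'   counts and percentages).
#' @export
summarize_cohort <- function(table, group = "group", total = "total") {
  stopifnot(is.data.frame(table))
  if (!nrow(table)) return(data.frame())
  num_cols <- names(table)[vapply(table, is.numeric, logical(1))]
  if (any(unlist(table[num_cols]) < 0, na.rm = TRUE))
    stop("summarize_cohort: negative counts")

  if (!total %in% names(table) && "count" %in% names(table)) {
    cls <- setdiff(names(table), "count")[1]
    tot <- sum(table$count)
    pct <- if (tot > 0) round_half_up(100 * table$count / tot) else NA_real_
    return(data.frame(class = table[[cls]], count = table$count,
                      percent = pct))
  }
  if (!total %in% names(table))
    stop("summarize_cohort: no '", total, "' or 'count' column")
  cats <- setdiff(num_cols, total)
  bad <- abs(rowSums(table[, cats, drop = FALSE]) - table[[total]]) > 0
  if (any(bad))
    stop("summarize_cohort: category counts do not sum to total in row(s) ",
         paste(which(bad), collapse = ", "))
  groups <- if (group %in% names(table)) table[[group]] else "all"
  out <- lapply(split(table, groups), function(df) {
    sums <- colSums(df[, c(total, cats), drop = FALSE])
    tot <- sums[[total]]
    pct <- if (tot > 0) round_half_up(100 * sums[cats] / tot) else
      rep(NA_real_, length(cats))
    row <- as.data.frame(as.list(sums))
    for (cc in cats) row[[paste0(cc, "_pct")]] <- pct[[cc]]
    row
  })
  res <- do.call(rbind, out)
  data.frame(group = names(out), res, row.names = NULL)
}
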