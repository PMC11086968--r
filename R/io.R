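# File input, region scanning, and result tables.

.read_delim_auto <- function(path, header = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  utils::read.table(path, header = header, sep = sep,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "#")
}

#' Read long-format paired-curve data
#'
#' Reads a delimited text file (TSV or CSV, autodetected) with one row per
#' observation and builds a validated [design_points()] object.  Column
#' names are configurable; group labels other than 0/1 are mapped via
#' `group_map` (or, for exactly two levels, automatically with a message).
#' Positions on a native coordinate scale are min-max rescaled to
#' \eqn{[0, 1]} with the map recorded.
#'
#' @param path Path to the file.
#' @param columns Named character vector mapping the roles `position`,
#'   `group`, `value` and optionally `subject` to column names in the file.
#' @param group_map Optional named vector mapping the file's group labels to
#'   0/1, e.g. `c(control = 0, case = 1)`.
#' @param ... Passed to [design_points()] (e.g. `allow_unbalanced`).
#' @return A [design_points()] object.
#' @export
read_long_table <- function(path,
                            columns = c(position = "position",
                                        group = "group",
                                        subject = "subject",
                                        value = "value"),
                            group_map = NULL, ...) {
  df <- .read_delim_auto(path)
  need <- c("position", "group", "value")
  for (role in need)
    if (!columns[[role]] %in% names(df))
      stop("missing column '", columns[[role]], "' (role: ", role, ")",
           call. = FALSE)
  pos <- suppressWarnings(as.numeric(df[[columns[["position"]]]]))
  if (anyNA(pos))
    stop("unparseable position value at row(s) ",
         paste(utils::head(which(is.na(pos)), 5), collapse = ", "),
         call. = FALSE)
  val <- suppressWarnings(as.numeric(df[[columns[["value"]]]]))
  if (anyNA(val))
    stop("unparseable response value at row(s) ",
         paste(utils::head(which(is.na(val)), 5), collapse = ", "),
         call. = FALSE)
  grp_raw <- df[[columns[["group"]]]]
  if (!is.null(group_map)) {
    unknown <- setdiff(unique(as.character(grp_raw)), names(group_map))
    if (length(unknown))
      stop("group level(s) not covered by 'group_map': ",
           paste(unknown, collapse = ", "), call. = FALSE)
    grp <- as.integer(group_map[as.character(grp_raw)])
  } else if (all(grp_raw %in% c(0, 1))) {
    grp <- as.integer(grp_raw)
  } else {
    lev <- sort(unique(as.character(grp_raw)))
    if (length(lev) != 2L)
      stop("group column has ", length(lev),
           " levels (need exactly 2): ", paste(lev, collapse = ", "),
           call. = FALSE)
    message("mapping group labels: ", lev[1], " -> 0, ", lev[2], " -> 1")
    grp <- as.integer(as.character(grp_raw) == lev[2])
  }
  subj <- if (!is.na(columns["subject"]) &&
              columns[["subject"]] %in% names(df))
    df[[columns[["subject"]]]] else NULL
  design_points(pos, grp, val, subject = subj, ...)
}

#' Read a BED-like region file
#'
#' Reads regions as `chrom`, `start`, `end` (half-open, 0-based by
#' convention) from a headerless BED-like file or a delimited file whose
#' header contains those names.
#'
#' @param path Path to the file.
#' @return Data frame with columns `chrom`, `start`, `end`.
#' @export
read_regions <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("start", first, ignore.case = TRUE)
  df <- .read_delim_auto(path, header = has_header)
  if (!has_header) {
    if (ncol(df) < 3L) stop("region file needs >= 3 columns", call. = FALSE)
    df <- df[, 1:3]
    names(df) <- c("chrom", "start", "end")
  }
  df <- df[, c("chrom", "start", "end")]
  df$start <- as.numeric(df$start); df$end <- as.numeric(df$end)
  if (any(!is.finite(df$start)) || any(!is.finite(df$end)))
    stop("unparseable region coordinates", call. = FALSE)
  if (any(df$start >= df$end))
    stop("regions must satisfy start < end", call. = FALSE)
  df
}

#' Region-wise parallelism scan
#'
#' Applies the parallelism test independently to each region of a track
#' (e.g. promoter windows along a genome): observations falling in
#' `[start, end)` (matched on `chrom` when present) are rescaled to
#' \eqn{[0, 1]} within the region and tested; p-values are then adjusted
#' across all tested regions by Benjamini-Hochberg.  Regions with fewer than
#' `min_obs` observations in either group are reported as skipped (`NA`
#' statistics, reason in `status`), never silently dropped.
#'
#' @param data A data frame with columns `position`, `group`, `value`,
#'   optionally `subject` and `chrom`, or a path to such a file
#'   ([read_long_table()] columns).
#' @param regions A data frame with `chrom`, `start`, `end`, or a path to a
#'   BED-like file ([read_regions()]).
#' @param alpha Level used for the `significant` column (applied to
#'   q-values).
#' @param min_obs Minimum observations per group per region (default 20).
#' @param m Spline order.
#' @param allow_overlap Permit overlapping regions (default `TRUE`; set
#'   `FALSE` to error on overlaps within a chromosome).
#' @param group_map Passed to [read_long_table()] when `data` is a path.
#' @param ... Passed to [parallelism_test()].
#' @return An object of class `"region_scan"`: data frame with one row per
#'   input region (`chrom`, `start`, `end`, `n_obs`, `n_group0`,
#'   `n_group1`, `statistic`, `lambda_star`, `p_value`, `q_value`,
#'   `significant`, `status`), in input order.
#' @export
scan_regions <- function(data, regions, alpha = 0.05, min_obs = 20, m = 2,
                         allow_overlap = TRUE, group_map = NULL, ...) {
  if (is.character(data)) {
    df <- .read_delim_auto(data)
  } else df <- as.data.frame(data)
  need <- c("position", "group", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("data lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (!"chrom" %in% names(df)) df$chrom <- "track"
  if (!is.null(group_map)) {
    unknown <- setdiff(unique(as.character(df$group)), names(group_map))
    if (length(unknown))
      stop("group level(s) not covered by 'group_map': ",
           paste(unknown, collapse = ", "), call. = FALSE)
    df$group <- as.integer(group_map[as.character(df$group)])
  }
  if (is.character(regions)) regions <- read_regions(regions)
  regions <- as.data.frame(regions)
  if (!"chrom" %in% names(regions)) regions$chrom <- "track"
  if (!allow_overlap) {
    for (ch in unique(regions$chrom)) {
      r <- regions[regions$chrom == ch, ]
      r <- r[order(r$start), ]
      if (nrow(r) > 1L && any(r$start[-1] < r$end[-nrow(r)]))
        stop("overlapping regions on ", ch,
             " (set allow_overlap = TRUE to permit)", call. = FALSE)
    }
  }

  rows <- lapply(seq_len(nrow(regions)), function(i) {
    rg <- regions[i, ]
    sel <- df$chrom == rg$chrom & df$position >= rg$start & df$position < rg$end
    sub <- df[sel, , drop = FALSE]
    out <- data.frame(chrom = rg$chrom, start = rg$start, end = rg$end,
                      n_obs = nrow(sub),
                      n_group0 = sum(sub$group == 0),
                      n_group1 = sum(sub$group == 1),
                      statistic = NA_real_, lambda_star = NA_real_,
                      p_value = NA_real_, status = "tested",
                      stringsAsFactors = FALSE)
    if (out$n_group0 < min_obs || out$n_group1 < min_obs) {
      out$status <- sprintf("skipped: < %d observations in a group", min_obs)
      message(sprintf("region %s:%g-%g skipped (%d/%d observations per group)",
                      rg$chrom, rg$start, rg$end, out$n_group0, out$n_group1))
      return(out)
    }
    pos01 <- (sub$position - rg$start) / (rg$end - rg$start)
    dp <- design_points(pos01, sub$group, sub$value,
                        subject = if ("subject" %in% names(sub)) sub$subject,
                        allow_unbalanced = TRUE)
    tst <- parallelism_test(dp, alpha = alpha, m = m, ...)
    out$statistic <- tst$statistic
    out$lambda_star <- tst$lambda_star
    out$p_value <- tst$p_value
    out
  })
  res <- do.call(rbind, rows)
  res$q_value <- NA_real_
  tested <- res$status == "tested"
  res$q_value[tested] <- bh_adjust(res$p_value[tested])
  res$significant <- !is.na(res$q_value) & res$q_value <= alpha
  class(res) <- c("region_scan", "data.frame")
  attr(res, "alpha") <- alpha
  res
}

#' @export
print.region_scan <- function(x, ...) {
  cat(sprintf("Region-wise parallelism scan: %d region(s), %d tested, %d significant at FDR %g\n",
              nrow(x), sum(x$status == "tested"), sum(x$significant),
              attr(x, "alpha")))
  print.data.frame(x, digits = 4, ...)
  invisible(x)
}

#' Write / read a region-scan result table
#'
#' TSV round-trip at full double precision (17 significant digits), so that
#' re-reading reproduces every numeric field exactly.
#'
#' @param x A [scan_regions()] result (or any data frame).
#' @param path Output path.
#' @return `write_region_results`: `path`, invisibly.
#' @export
write_region_results <- function(x, path) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_region_results
#' @export
read_region_results <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  for (nm in intersect(c("start", "end", "n_obs", "n_group0", "n_group1",
                         "statistic", "lambda_star", "p_value", "q_value"),
                       names(df)))
    df[[nm]] <- as.numeric(df[[nm]])
  df
}
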