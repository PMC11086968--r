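#' Construct a paired-curve design
#'
#' Bundles the observations the parallelism model is fitted on: a continuous
#' position on \eqn{[0, 1]}, a binary group label, a subject (curve)
#' identifier and the observed response.  Each subject contributes one curve;
#' with the default of one subject per group there are two curves in total.
#'
#' Positions outside \eqn{[0, 1]} are rescaled to it by the affine min-max
#' map, with a warning; the map is recorded in the `"position_scale"`
#' attribute so results can be reported on the native coordinate scale.
#'
#' @param position Numeric vector of positions (time points, genomic
#'   coordinates, ...).  Rescaled to \eqn{[0, 1]} if necessary.
#' @param group Integer vector of group labels, 0 (control) or 1 (case).
#' @param value Numeric vector of responses, same length as `position`.
#' @param subject Optional vector of subject (curve) identifiers.  Defaults to
#'   one subject per group.  Every subject must carry a single group label.
#' @param allow_unbalanced Logical; if `FALSE` (default) all subjects must
#'   contribute the same number of observations (the complete
#'   positions-by-subjects layout the asymptotics are stated for).  Region
#'   scanning of observational data sets this to `TRUE`.
#'
#' @return An object of class `"design_points"`: a data frame with columns
#'   `position`, `group`, `subject`, `value` and attributes `n` (observations
#'   per subject, when balanced), `s` (number of subjects) and
#'   `position_scale`.
#'
#' @examples
#' d <- design_points(position = runif(40), group = rep(0:1, each = 20),
#'                    value = rnorm(40))
#' d
#' @export
design_points <- function(position, group, value, subject = NULL,
                          allow_unbalanced = FALSE) {
  position <- as.numeric(position)
  value <- as.numeric(value)
  nobs <- length(position)
  if (length(group) != nobs || length(value) != nobs)
    stop("'position', 'group' and 'value' must have equal length", call. = FALSE)
  if (nobs < 4L)
    stop("need at least 4 observations", call. = FALSE)
  if (anyNA(position) || any(!is.finite(position)))
    stop("positions must be finite and non-missing", call. = FALSE)
  if (anyNA(value) || any(!is.finite(value)))
    stop("responses must be finite and non-missing", call. = FALSE)
  if (is.logical(group)) group <- as.integer(group)
  group <- as.integer(group)
  if (anyNA(group) || !all(group %in% c(0L, 1L)))
    stop("group labels must be 0 or 1 (use read_long_table() to map labels)",
         call. = FALSE)
  if (length(unique(group)) < 2L)
    stop("invalid design: both groups must be present", call. = FALSE)

  scale <- c(offset = 0, scale = 1)
  if (min(position) < 0 || max(position) > 1) {
    rng <- range(position)
    if (rng[1] == rng[2])
      stop("positions are constant and outside [0, 1]; cannot rescale",
           call. = FALSE)
    warning(sprintf(
      "positions outside [0, 1]; min-max rescaled from [%g, %g]",
      rng[1], rng[2]), call. = FALSE)
    scale <- c(offset = rng[1], scale = rng[2] - rng[1])
    position <- (position - rng[1]) / (rng[2] - rng[1])
  }

  if (is.null(subject)) subject <- group + 1L
  if (length(subject) != nobs)
    stop("'subject' must match the number of observations", call. = FALSE)
  subject <- as.integer(factor(subject, levels = unique(subject)))

  grp_per_subj <- tapply(group, subject, function(g) length(unique(g)))
  if (any(grp_per_subj != 1L))
    stop("each subject must belong to exactly one group", call. = FALSE)
  cnt <- tabulate(subject)
  if (!allow_unbalanced && length(unique(cnt)) != 1L)
    stop("incomplete design: all subjects must have the same number of ",
         "observations (or set allow_unbalanced = TRUE)", call. = FALSE)
  if (any(cnt < 2L))
    stop("each subject needs at least 2 observations", call. = FALSE)

  out <- data.frame(position = position, group = group,
                    subject = subject, value = value)
  attr(out, "n") <- if (length(unique(cnt)) == 1L) cnt[1L] else NA_integer_
  attr(out, "s") <- length(cnt)
  attr(out, "position_scale") <- scale
  class(out) <- c("design_points", "data.frame")
  out
}

#' Coerce to a design-points object
#'
#' @param x A data frame with columns `position`, `group`, `value` and
#'   optionally `subject`.
#' @param ... Passed on to [design_points()].
#' @return A `"design_points"` object.
#' @export
as.design_points <- function(x, ...) {
  if (inherits(x, "design_points")) return(x)
  x <- as.data.frame(x)
  need <- c("position", "group", "value")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  design_points(x$position, x$group, x$value,
                subject = if ("subject" %in% names(x)) x$subject else NULL, ...)
}

#' @export
print.design_points <- function(x, ...) {
  cat(sprintf("Paired-curve design: %d observations, %d subject(s), groups 0/1 (%d/%d obs)\n",
              nrow(x), attr(x, "s"), sum(x$group == 0), sum(x$group == 1)))
  sc <- attr(x, "position_scale")
  if (!is.null(sc) && sc["scale"] != 1)
    cat(sprintf("  positions rescaled from [%g, %g]\n",
                sc["offset"], sc["offset"] + sc["scale"]))
  print.data.frame(utils::head(as.data.frame(x), 6), ...)
  if (nrow(x) > 6) cat("  ...", nrow(x) - 6, "more rows\n")
  invisible(x)
}
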