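#' Coarse posture label from TPA
#'
#' Maps a transverse pelvic angle to `left` / `supine` / `right`. Supine is
#' the open band (-22.5, +22.5) degrees; boundary angles belong to the side.
#' Negative angles are left-side lying, positive right-side lying.
#'
#' @param tpa Numeric TPA in degrees, |tpa| <= 180 (vectorised).
#' @return Character vector in `c("left", "supine", "right")`.
#' @examples
#' coarse_label(c(0, -90, 22.5)) # supine, left, right
#' @export
coarse_label <- function(tpa) {
  if (any(abs(tpa) > 180)) stop("|tpa| must be <= 180", call. = FALSE)
  ifelse(tpa > -22.5 & tpa < 22.5, "supine",
         ifelse(tpa < 0, "left", "right"))
}

#' Bin scheme for side-lying precision
#'
#' Side-lying angles between 22.5 and 112.5 degrees absolute are divided
#' into equal bins: 2 bins of 45 degrees, 3 of 30, or 6 of 15. `coarse3`
#' denotes the three-class scheme with no side subdivision.
#'
#' @param precision One of `"coarse3"`, `"bins45"`, `"bins30"`, `"bins15"`.
#' @return A `bin_scheme`: list with `precision`, `bin_width` and per-side
#'   ascending `edges` over \[22.5, 112.5\] (NULL for `coarse3`).
#' @examples
#' scheme_edges("bins45")$edges # 22.5 67.5 112.5
#' @export
scheme_edges <- function(precision = c("bins45", "bins30", "bins15",
                                       "coarse3")) {
  precision <- match.arg(precision)
  width <- switch(precision, coarse3 = NA_real_, bins45 = 45,
                  bins30 = 30, bins15 = 15)
  edges <- if (is.na(width)) NULL else seq(22.5, 112.5, by = width)
  structure(list(precision = precision, bin_width = width, edges = edges),
            class = "bin_scheme")
}

#' Side bin label for a side-lying TPA
#'
#' Bins the absolute TPA into the scheme's half-open intervals
#' \[edge_i, edge_{i+1}); the outermost bin additionally includes 112.5.
#' Angles beyond 112.5 absolute return `"out_of_range"` (too little data in
#' that range to classify). Supine input is an error: the supine band has
#' fixed width and is never subdivided.
#'
#' @param tpa Numeric TPA in degrees (vectorised); no element may be supine.
#' @param scheme A `bin_scheme` from [scheme_edges()] (not `coarse3`).
#' @return Character labels like `"left_b2"` / `"right_b1"`, bins numbered
#'   from the supine boundary outward, or `"out_of_range"`.
#' @examples
#' side_bin_label(45, scheme_edges("bins45")) # right_b1
#' @export
side_bin_label <- function(tpa, scheme) {
  stopifnot(inherits(scheme, "bin_scheme"))
  if (is.null(scheme$edges)) {
    stop("coarse3 has no side bins; use coarse_label()", call. = FALSE)
  }
  side <- coarse_label(tpa)
  if (any(side == "supine")) {
    stop("supine angles cannot be side-binned", call. = FALSE)
  }
  a <- abs(tpa)
  k <- findInterval(a, scheme$edges, rightmost.closed = TRUE)
  out <- ifelse(a > 112.5, "out_of_range", paste0(side, "_b", k))
  out
}
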