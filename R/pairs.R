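## Full-sibling pairs and their sufficient statistics.
##
## The pair likelihood of the AE liability model depends on each pair only
## through (outcome1, outcome2, sex1, sex2, birth_year1, birth_year2), so
## pairs are aggregated into counted cells; fitting cost then scales with the
## number of distinct cells, not with the number of pairs.

# pair index patterns within a family of size k (columns of combn(k, 2))
.pair_patterns <- lapply(2:5, function(k) utils::combn(k, 2L))

#' Form full-sibling pairs and aggregate them into outcome cells
#'
#' All possible pairs within each family (`all_pairs`), or one randomly
#' chosen pair per family (`one_per_family`, the sensitivity design).  The
#' two members of a pair are stored in a canonical order (sorted by birth
#' year, then sex, then outcome) so that mirrored pairs collapse to one cell.
#'
#' @param cohort A cohort `data.table` (needs `family_id`, `sex`,
#'   `birth_year` and the outcome column).
#' @param mode `"all_pairs"` or `"one_per_family"`.
#' @param outcome Name of the binary outcome column (default `"t1d"`).
#' @return A `data.table` of class `pair_cells` with columns `y1`, `y2`,
#'   `sex1`, `sex2`, `by1`, `by2`, `count`; attribute `n_pairs` holds the
#'   total number of pairs.
#' @export
make_sibling_pairs <- function(cohort, mode = c("all_pairs", "one_per_family"),
                               outcome = "t1d") {
  mode <- match.arg(mode)
  stopifnot(all(c("family_id", "sex", "birth_year", outcome) %in%
                  names(cohort)))
  dt <- data.table::as.data.table(cohort)
  ord <- order(dt$family_id)
  fam <- dt$family_id[ord]
  y <- as.integer(dt[[outcome]][ord])
  sx <- as.integer(dt$sex[ord])
  by <- as.integer(dt$birth_year[ord])

  rl <- rle(fam)
  sizes <- rl$lengths
  starts <- cumsum(sizes) - sizes + 1L
  i1 <- integer(0)
  i2 <- integer(0)
  if (mode == "all_pairs") {
    for (k in 2:5) {
      sk <- starts[sizes == k]
      if (!length(sk)) next
      pat <- .pair_patterns[[k - 1L]]
      for (cidx in seq_len(ncol(pat))) {
        i1 <- c(i1, sk + pat[1L, cidx] - 1L)
        i2 <- c(i2, sk + pat[2L, cidx] - 1L)
      }
    }
  } else {
    for (k in 2:5) {
      sel <- sizes == k
      sk <- starts[sel]
      if (!length(sk)) next
      pat <- .pair_patterns[[k - 1L]]
      pick <- sample.int(ncol(pat), length(sk), replace = TRUE)
      i1 <- c(i1, sk + pat[1L, pick] - 1L)
      i2 <- c(i2, sk + pat[2L, pick] - 1L)
    }
  }
  pairs <- data.table::data.table(
    y1 = y[i1], y2 = y[i2], sex1 = sx[i1], sex2 = sx[i2],
    by1 = by[i1], by2 = by[i2])
  # canonical member order: (birth year, sex, outcome) lexicographic
  swap <- (pairs$by1 > pairs$by2) |
    (pairs$by1 == pairs$by2 & pairs$sex1 > pairs$sex2) |
    (pairs$by1 == pairs$by2 & pairs$sex1 == pairs$sex2 & pairs$y1 > pairs$y2)
  if (any(swap)) {
    tmp <- pairs[swap]
    pairs[swap, `:=`(y1 = tmp$y2, y2 = tmp$y1, sex1 = tmp$sex2,
                     sex2 = tmp$sex1, by1 = tmp$by2, by2 = tmp$by1)]
  }
  cells <- pairs[, .(count = .N), by = c("y1", "y2", "sex1", "sex2",
                                         "by1", "by2")]
  data.table::setattr(cells, "n_pairs", nrow(pairs))
  data.table::setattr(cells, "class",
                      c("pair_cells", class(cells)))
  cells[]
}

#' @export
print.pair_cells <- function(x, ...) {
  np <- attr(x, "n_pairs")
  n11 <- sum(x$count[x$y1 == 1 & x$y2 == 1])
  n10 <- sum(x$count[x$y1 + x$y2 == 1])
  cat(sprintf(
    "Sibling-pair outcome cells: %d cells, %s pairs (%s concordant-affected, %s discordant)\n",
    nrow(x), format(np, big.mark = ","), format(n11, big.mark = ","),
    format(n10, big.mark = ",")))
  invisible(x)
}

#' Redefine the outcome as diagnosis within an onset-age window
#'
#' The endotype analyses treat diagnosis at ages 0-6, 7-12 or 13-18 as the
#' outcome.  A child is a window case when the onset age falls inside the
#' window; children diagnosed before the window are excluded (they are no
#' longer at risk of the window outcome), as are event-free children whose
#' administrative follow-up ends before the window does (their window status
#' is unobserved).
#'
#' @param cohort A cohort `data.table` with `t1d`, `onset_age`,
#'   `followup_end_age`.
#' @param window Length-2 integer vector of inclusive whole-year bounds,
#'   e.g. `c(0, 6)`, `c(7, 12)`, `c(13, 18)`.
#' @return The filtered cohort with `t1d` and `onset_age` redefined to the
#'   window outcome.
#' @export
window_outcome <- function(cohort, window) {
  stopifnot(length(window) == 2L, window[1] >= 0, window[2] >= window[1])
  lo <- window[1]
  hi_excl <- window[2] + 1
  dt <- data.table::copy(data.table::as.data.table(cohort))
  case_w <- dt$t1d == 1L & !is.na(dt$onset_age) &
    dt$onset_age >= lo & dt$onset_age < hi_excl
  pre_window_case <- dt$t1d == 1L & !is.na(dt$onset_age) & dt$onset_age < lo
  unobserved <- !case_w & !pre_window_case & dt$followup_end_age < hi_excl &
    !(dt$t1d == 1L & !is.na(dt$onset_age) & dt$onset_age >= hi_excl)
  keep <- !pre_window_case & !unobserved
  dt <- dt[keep]
  cw <- case_w[keep]
  dt[, t1d := as.integer(cw)]
  dt[t1d == 0L, onset_age := NA_real_]
  if (nrow(dt) == 0L) {
    stop("window_outcome: no children remain for this window", call. = FALSE)
  }
  dt[]
}
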