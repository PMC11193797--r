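#' Asset-based household wealth index via pooled PCA
#'
#' Standardises the asset items on the pooled household-wave matrix (both
#' survey waves stacked), extracts the first principal component, orients it
#' to correlate positively with the unweighted item sum, and assigns pooled
#' quintiles (1 = poorest, 5 = wealthiest) from the empirical quantiles of
#' the pooled score distribution.  Equal scores always receive equal
#' quintiles, so a household whose responses are identical in both waves
#' cannot change quintile.
#'
#' @param wave1,wave2 data frames with a `household_id` column followed by
#'   numeric asset item columns (same items in both waves); households may
#'   be missing from one wave.
#' @return object of class `"wealth_index"`: a data frame with
#'   `household_id`, `score_w1`, `score_w2`, `q_w1`, `q_w2` (NA where a wave
#'   is missing), plus attributes `breaks` and `loadings`.
#' @export
wealth_index <- function(wave1, wave2) {
  stopifnot("household_id" %in% names(wave1), "household_id" %in% names(wave2))
  items <- setdiff(names(wave1), "household_id")
  if (!identical(items, setdiff(names(wave2), "household_id")))
    stop("waves must share the same asset items")
  x <- rbind(as.matrix(wave1[items]), as.matrix(wave2[items]))
  wave <- rep(1:2, c(nrow(wave1), nrow(wave2)))
  hh <- c(wave1$household_id, wave2$household_id)

  sds <- apply(x, 2, sd)
  drop <- sds == 0 | !is.finite(sds)
  if (any(drop)) {
    warning("dropping constant item(s): ", paste(items[drop], collapse = ", "))
    x <- x[, !drop, drop = FALSE]
  }
  if (ncol(x) < 2L) stop("fewer than 2 usable asset items")
  xs <- scale(x)
  pc <- prcomp(xs, center = FALSE, scale. = FALSE)
  score <- pc$x[, 1]
  if (cor(score, rowSums(xs)) < 0) score <- -score

  breaks <- quantile(score, c(.2, .4, .6, .8), names = FALSE)
  q <- findInterval(score, breaks) + 1L

  ids <- sort(unique(hh))
  out <- data.frame(household_id = ids,
                    score_w1 = NA_real_, score_w2 = NA_real_,
                    q_w1 = NA_integer_, q_w2 = NA_integer_,
                    stringsAsFactors = FALSE)
  m1 <- match(hh[wave == 1], ids); m2 <- match(hh[wave == 2], ids)
  out$score_w1[m1] <- score[wave == 1]; out$q_w1[m1] <- q[wave == 1]
  out$score_w2[m2] <- score[wave == 2]; out$q_w2[m2] <- q[wave == 2]
  structure(out, breaks = breaks,
            loadings = setNames(pc$rotation[, 1], colnames(x)),
            class = c("wealth_index", "data.frame"))
}

#' Binary household wealth-change outcome
#'
#' Main definition (`any_change`) flags any movement between wealth
#' quintiles across the two waves; `up`, `down` and `stable` are the
#' sensitivity definitions.  Households missing either wave get `NA`.
#'
#' @param index a [wealth_index()].
#' @param mode one of `"any_change"`, `"up"`, `"down"`, `"stable"`.
#' @return integer vector (0/1/NA) aligned with `index$household_id`.
#' @export
household_outcome <- function(index, mode = c("any_change", "up", "down",
                                              "stable")) {
  mode <- match.arg(mode)
  d <- index$q_w2 - index$q_w1
  switch(mode,
         any_change = as.integer(d != 0L),
         up = as.integer(d > 0L),
         down = as.integer(d < 0L),
         stable = as.integer(d == 0L))
}

#' Quintile-Gini inequality score of one region
#'
#' Gini mean-difference index `G = sum_ij |x_i - x_j| / (2 n^2 xbar)` over
#' the household wealth quintile values of a region.  Zero for a region
#' whose households all share a quintile, and by convention for a
#' single-household region.
#'
#' @param x numeric vector of (positive) quintile values.
#' @return the inequality score in `[0, 1)`.
#' @export
quintile_gini <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n <= 1L) return(0)
  x <- sort(x)
  # sum_ij |x_i - x_j| = 2 * sum_i (2i - n - 1) x_(i)
  s <- 2 * sum((2 * seq_len(n) - n - 1) * x)
  s / (2 * n^2 * mean(x))
}

#' Regional inequality per wave and its change
#'
#' Computes the quintile-Gini for every region in each wave (households
#' missing a wave are excluded from that wave's score) and the change
#' `delta = inq_w2 - inq_w1`.
#'
#' @param index a [wealth_index()].
#' @param affiliations data frame `household_id`, `region_id`.
#' @return data frame `region_id`, `n_households`, `inq_w1`, `inq_w2`,
#'   `delta`.
#' @export
regional_inequality <- function(index, affiliations) {
  reg <- affiliations$region_id[match(index$household_id,
                                      affiliations$household_id)]
  if (anyNA(reg)) stop("households missing from affiliations")
  region_ids <- sort(unique(affiliations$region_id))
  rows <- lapply(region_ids, function(r) {
    sel <- reg == r
    data.frame(region_id = r, n_households = sum(sel),
               inq_w1 = quintile_gini(index$q_w1[sel]),
               inq_w2 = quintile_gini(index$q_w2[sel]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$delta <- out$inq_w2 - out$inq_w1
  out
}

#' Binary regional inequality outcome
#'
#' A region is flagged when its inequality score rose by at least
#' `threshold` (default 2 percentage points of the score), the operational
#' form of selecting increases above the 75th percentile of the change
#' distribution.  The normal-theory 75th-percentile cut
#' (`mean + 0.675 sd` of the deltas) is reported as a diagnostic.
#'
#' @param inequality output of [regional_inequality()].
#' @param threshold absolute increase in the score required; default 0.02.
#' @return integer 0/1 vector aligned with `inequality$region_id`, with
#'   attributes `selected` (region ids), `percentile_cut` (mu + 0.675 sigma)
#'   and `threshold`.
#' @export
regional_outcome <- function(inequality, threshold = 0.02) {
  Y <- as.integer(inequality$delta >= threshold)
  structure(Y,
            selected = inequality$region_id[Y == 1L],
            percentile_cut = mean(inequality$delta) +
              0.675 * sd(inequality$delta),
            threshold = threshold)
}
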