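#' Stimulus-pair selectivity of one neuron
#'
#' For the four stimulus-pair responses of a neuron, selectivity is the
#' maximum rate minus the mean rate, normalized by the mean rate, so the
#' overall rate does not determine selectivity. A cell responding
#' equally to all four pairs scores 0; a cell responding to a single
#' pair scores 3. Silent cells (all four rates zero) score 0.
#'
#' @param rates numeric vector of 4 nonnegative rates (Hz), or a matrix
#'   with 4 columns (one row per cell)
#' @return selectivity value(s) in [0, 3]
#' @export
selectivity <- function(rates) {
  if (is.matrix(rates)) {
    stopifnot(ncol(rates) == 4)
    return(apply(rates, 1, selectivity))
  }
  stopifnot(length(rates) == 4)
  if (any(rates < 0)) stop("rates must be nonnegative", call. = FALSE)
  m <- mean(rates)
  if (m == 0) return(0)
  (max(rates) - m) / m
}

#' Network-level stimulus-pair selectivity
#'
#' Per-cell selectivity for a matrix of cue-window rates (cells x 4
#' pairs), and the network value as the mean across all excitatory cells
#' or, in the active-only variant, across cells whose mean rate exceeds
#' a floor.
#'
#' @param rates matrix, cells x 4 stimulus pairs, Hz
#' @param include `"all"` or `"active_only"`
#' @param active_floor minimal mean rate (Hz) for a cell to count as
#'   active in the active-only variant
#' @return list of class `selectivity_result` with per-cell values,
#'   the network mean, and the cell inclusion mask
#' @export
network_selectivity <- function(rates, include = c("all", "active_only"),
                                active_floor = 0.5) {
  include <- match.arg(include)
  stopifnot(is.matrix(rates), ncol(rates) == 4, all(is.finite(rates)))
  s <- selectivity(rates)
  active <- rowMeans(rates) >= active_floor
  used <- if (include == "active_only") active else rep(TRUE, nrow(rates))
  mean_s <- if (any(used)) mean(s[used]) else 0
  structure(list(per_cell = s, mean = mean_s, include = include,
                 active = active, n_used = sum(used)),
            class = "selectivity_result")
}

#' @export
print.selectivity_result <- function(x, ...) {
  cat(sprintf(
    "Stimulus-pair selectivity: network mean %.3f over %d cells (%s)\n",
    x$mean, x$n_used, x$include))
  invisible(x)
}

#' Bin decision outcomes into performance blocks
#'
#' Fraction of correct trials per consecutive bin (40 trials by
#' default), with the network classified from the final bin as reliable
#' (>= 85% correct), borderline (76-84%) or unreliable (<= 75%).
#'
#' @param correct logical vector of per-trial correctness
#' @param bin bin width in trials
#' @param final_k number of final bins to average for classification
#' @return list of class `performance_trace`
#' @export
performance_bins <- function(correct, bin = 40, final_k = 1) {
  stopifnot(length(correct) >= bin)
  n_bins <- length(correct) %/% bin
  idx <- rep(seq_len(n_bins), each = bin)
  used <- correct[seq_len(n_bins * bin)]
  frac <- as.numeric(tapply(used, idx, mean))
  final <- mean(frac[seq(max(1, n_bins - final_k + 1), n_bins)])
  classification <- if (final >= 0.85) "reliable"
    else if (final > 0.75) "borderline" else "unreliable"
  structure(list(fraction_correct = frac, bin = bin,
                 n_trials = length(correct), final = final,
                 classification = classification),
            class = "performance_trace")
}

#' @export
print.performance_trace <- function(x, ...) {
  cat(sprintf(
    "Decision performance: final %.1f%% correct (%s), %d bins of %d\n",
    100 * x$final, x$classification,
    length(x$fraction_correct), x$bin))
  invisible(x)
}

#' Classify a network's selectivity change
#'
#' Improved if the final network-mean selectivity exceeds the initial by
#' more than 5%, worsened if it falls short by more than 5%, unchanged
#' otherwise. A network starting at exactly zero that gains any
#' selectivity counts as improved.
#'
#' @param initial,final network-mean selectivity before and after
#'   training
#' @return `"improved"`, `"worsened"` or `"unchanged"`
#' @export
classify_change <- function(initial, final) {
  stopifnot(initial >= 0, final >= 0)
  if (initial == 0) return(if (final > 0) "improved" else "unchanged")
  if (final > 1.05 * initial) "improved"
  else if (final < 0.95 * initial) "worsened"
  else "unchanged"
}

#' Mean weight change between preferred-pair groups
#'
#' Cells are grouped by the stimulus pair producing their greatest
#' response after training; entry (g, h) is the mean weight change over
#' existing synapses from cells preferring pair g to cells preferring
#' pair h. The diagonal-subtracted variant subtracts each row's diagonal
#' entry, exposing cross-inhibition as positive off-diagonal structure.
#'
#' @param w_before,w_after weight matrices (pre x post)
#' @param mask logical connectivity matrix (pre x post)
#' @param pref_pre,pref_post preferred-pair index (1..4) per pre/post
#'   cell
#' @param pair_names labels for the four pairs
#' @return list of class `group_weight_matrix` with `delta` (4 x 4 mean
#'   change, NA where a group pairing has no synapses) and
#'   `delta_diagsub` (row-diagonal subtracted)
#' @export
group_weight_matrix <- function(w_before, w_after, mask, pref_pre,
                                pref_post,
                                pair_names = c("AB", "AD", "CB", "CD")) {
  stopifnot(all(dim(w_before) == dim(w_after)),
            all(dim(mask) == dim(w_before)),
            length(pref_pre) == nrow(mask),
            length(pref_post) == ncol(mask))
  dw <- w_after - w_before
  out <- matrix(NA_real_, 4, 4, dimnames = list(pair_names, pair_names))
  for (g in 1:4) for (h in 1:4) {
    sel <- outer(pref_pre == g, pref_post == h, "&") & mask
    if (any(sel)) out[g, h] <- mean(dw[sel])
  }
  diagsub <- sweep(out, 1, diag(out), "-")
  structure(list(delta = out, delta_diagsub = diagsub),
            class = "group_weight_matrix")
}

#' Assign preferred pairs from probe rates
#'
#' Argmax of each cell's four pair responses; exact ties break toward
#' the lowest pair index.
#'
#' @param rates matrix, cells x 4 pairs
#' @return integer vector of preferred pair indices (1..4)
#' @export
preferred_pair <- function(rates) {
  stopifnot(is.matrix(rates), ncol(rates) == 4)
  apply(rates, 1, which.max)
}

#' Cross-correlogram of two spike trains
#'
#' Histogram of time lags `t_b - t_a` over all spike pairs within a
#' symmetric window.
#'
#' @param train_a,train_b spike time vectors, ms
#' @param max_lag half-width of the lag window, ms
#' @param bin_width histogram bin width, ms
#' @return list of class `correlogram` with bin centers (`lag`) and
#'   counts
#' @export
cross_correlogram <- function(train_a, train_b, max_lag = 50,
                              bin_width = 2) {
  # bins centered on 0, +/- bin_width, ..., +/- max_lag, so that
  # synchronous spikes land in the zero-lag bin
  breaks <- seq(-max_lag - bin_width / 2, max_lag + bin_width / 2,
                by = bin_width)
  counts <- integer(length(breaks) - 1)
  if (length(train_a) > 0 && length(train_b) > 0) {
    train_a <- sort(train_a); train_b <- sort(train_b)
    # windowed pair enumeration without the full outer difference
    lo <- findInterval(train_a - max_lag, train_b) + 1
    hi <- findInterval(train_a + max_lag, train_b)
    lags <- unlist(lapply(seq_along(train_a), function(k) {
      if (hi[k] >= lo[k]) train_b[lo[k]:hi[k]] - train_a[k] else numeric(0)
    }))
    lags <- lags[lags >= -max_lag & lags <= max_lag]
    if (length(lags) > 0) {
      h <- hist(lags, breaks = breaks, plot = FALSE)
      counts <- h$counts
    }
  }
  structure(list(lag = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 counts = counts, bin_width = bin_width,
                 max_lag = max_lag), class = "correlogram")
}

#' @export
plot.correlogram <- function(x, ...) {
  graphics::barplot(x$counts, names.arg = x$lag, space = 0,
                    xlab = "lag (ms)", ylab = "coincidences", ...)
  invisible(x)
}

#' Sigmoidal fit of performance against selectivity
#'
#' Nonlinear least-squares fit of
#' `y = 50 + 50 / (1 + exp(-(x - x0) / delta))` with performance `y` on
#' the 50-100% scale and selectivity `x`, returning the fitted midpoint
#' `x0`, slope `delta` and the r-squared of the fit.
#'
#' @param x selectivity values
#' @param y performance values, percent (50-100 scale)
#' @return object of class `sigmoid_fit` with `coef`, `r_squared`,
#'   `fitted` and the underlying `nls` fit
#' @export
sigmoid_fit <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (sd(y) == 0)
    stop(structure(class = c("pairnet_degenerate_fit", "error",
                             "condition"),
                   list(message = "degenerate data: constant performance",
                        call = sys.call())))
  start <- list(x0 = median(x), delta = max(sd(x), 0.05))
  fit <- minpack.lm::nlsLM(
    y ~ 50 + 50 / (1 + exp(-(x - x0) / delta)),
    start = start, control = minpack.lm::nls.lm.control(maxiter = 200))
  r2 <- 1 - sum(resid(fit)^2) / sum((y - mean(y))^2)
  structure(list(coef = coef(fit), r_squared = r2,
                 fitted = fitted(fit), fit = fit),
            class = "sigmoid_fit")
}

#' @export
coef.sigmoid_fit <- function(object, ...) object$coef

#' @export
predict.sigmoid_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  x <- if (is.list(newdata)) newdata$x else newdata
  50 + 50 / (1 + exp(-(x - object$coef[["x0"]]) / object$coef[["delta"]]))
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf(
    "Sigmoid fit: x0 = %.3f, delta = %.3f, r^2 = %.3f\n",
    x$coef[["x0"]], x$coef[["delta"]], x$r_squared))
  invisible(x)
}

#' @export
summary.sigmoid_fit <- function(object, ...) summary(object$fit)
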