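#' Sample heterogeneous cell parameters
#'
#' Draws per-cell leak reversal, membrane time constant, leak
#' conductance, firing threshold, reset voltage and refractory time
#' constant from uniform distributions centred on the printed means with
#' the printed half-spreads. Decision-layer cells are homogeneous
#' (spread zero).
#'
#' @param n number of cells
#' @param cell_class `"excitatory"` or `"inhibitory"`
#' @param layer `"associative"` or `"decision"`
#' @param seed integer seed
#' @param regime regime name (affects the associative leak conductance in
#'   the high-threshold regimes); `"homogeneous_cells"` zeroes all spreads
#' @return data.frame with one row per cell
#' @export
sample_cell_params <- function(n, cell_class = c("excitatory", "inhibitory"),
                               layer = c("associative", "decision"),
                               seed = 1L, regime = "standard") {
  stopifnot(n > 0)
  cell_class <- match.arg(cell_class)
  layer <- match.arg(layer)
  tab <- .cell_param_table(regime)
  if (is.null(tab[[layer]]) || is.null(tab[[layer]][[cell_class]]))
    stop("unknown class/layer combination", call. = FALSE)
  p <- tab[[layer]][[cell_class]]
  spread <- p$spread
  if (identical(regime, "homogeneous_cells")) spread[] <- 0
  set.seed(seed)
  draw <- function(field) {
    m <- p$mean[[field]]; s <- spread[[field]]
    if (s == 0) rep(m, n) else runif(n, m - s, m + s)
  }
  out <- data.frame(
    V_L = draw("V_L"), tau_m = draw("tau_m"), g_L = draw("g_L"),
    V_th = draw("V_th"), V_reset = draw("V_reset"),
    tau_reset = draw("tau_reset"))
  out$cell_class <- cell_class
  out$layer <- layer
  out
}

# Random binary adjacency (pre x post) at a given probability.
# `no_self` removes the diagonal (only meaningful for square blocks).
.random_mask <- function(n_pre, n_post, probability, no_self = FALSE) {
  m <- matrix(runif(n_pre * n_post) < probability, n_pre, n_post)
  if (no_self) diag(m) <- FALSE
  m
}

# Initial weights: uniform W0 +/- 50% on existing connections, 0 elsewhere.
.init_weights <- function(mask, w0) {
  w <- matrix(0, nrow(mask), ncol(mask))
  k <- sum(mask)
  if (k > 0) w[mask] <- runif(k, w0 * 0.5, w0 * 1.5)
  w
}

#' Build a set of Poisson input groups
#'
#' Four stimuli (A, B, C, D), each represented by `groups_per_stimulus`
#' independent input groups firing homogeneous Poisson trains at
#' `480 / groups_per_stimulus` Hz, so the total rate per active stimulus
#' is always 480 Hz. Each group projects to associative excitatory and
#' inhibitory cells independently with the given connection probability.
#'
#' @param groups_per_stimulus one of 2, 4, 6, 10, 20
#' @param probability one of 1/2, 1/3, 1/5, 1/10, 1/20
#' @param n_e,n_i numbers of excitatory and inhibitory target cells
#' @param seed integer seed
#' @param w0 initial mean synaptic weight
#' @param homogeneous if TRUE every group connects to every cell
#'   (the homogeneous-inputs regime)
#' @param allow_nonstandard accept grid values outside the stated sets
#' @return list of class `input_ensemble` with the projection mask
#'   (groups x cells), initial weights, group-to-stimulus labels and the
#'   per-group rate
#' @export
build_input_ensemble <- function(groups_per_stimulus, probability,
                                 n_e = 320, n_i = 80, seed = 1L,
                                 w0 = 0.05, homogeneous = FALSE,
                                 allow_nonstandard = FALSE) {
  if (!allow_nonstandard) {
    if (!groups_per_stimulus %in% .input_group_counts)
      stop("groups_per_stimulus must be one of 2, 4, 6, 10, 20",
           call. = FALSE)
    if (!any(abs(probability - .input_probabilities) < 1e-12))
      stop("probability must be one of 1/2, 1/3, 1/5, 1/10, 1/20",
           call. = FALSE)
  }
  g_total <- 4L * as.integer(groups_per_stimulus)
  n <- n_e + n_i
  set.seed(seed)
  mask <- if (homogeneous) matrix(TRUE, g_total, n)
          else .random_mask(g_total, n, probability)
  weights <- .init_weights(mask, w0)
  structure(list(
    stimuli = c("A", "B", "C", "D"),
    groups_per_stimulus = as.integer(groups_per_stimulus),
    group_stimulus = rep(c("A", "B", "C", "D"),
                         each = groups_per_stimulus),
    rate_per_group = 480 / groups_per_stimulus,
    input_probability = probability,
    mask = mask, weights = weights,
    n_e = n_e, n_i = n_i, seed = seed),
    class = "input_ensemble")
}

#' @export
print.input_ensemble <- function(x, ...) {
  cat(sprintf(
    "Input ensemble: 4 stimuli x %d groups at %.3g Hz/group (p = %.3g)\n",
    x$groups_per_stimulus, x$rate_per_group, x$input_probability))
  invisible(x)
}

#' Build an associative-layer network
#'
#' Assembles one random heterogeneous associative network from a
#' configuration: cell parameter tables, the input ensemble, and all
#' synapse blocks with their connectivity statistics --
#' excitatory-to-excitatory sparse-random at 10%,
#' inhibitory-to-excitatory random at 25%, inhibitory-to-inhibitory
#' all-to-all, and no excitatory-to-inhibitory connections (inhibition is
#' feedforward only) except in the recurrent-inhibition regime where
#' excitatory cells connect to inhibitory cells with probability 25%.
#' Initial weights are uniform within 50% of the effective mean `W0`.
#' Plasticity tags: E-to-E and input-to-E synapses are STDP-capable,
#' I-to-E synapses are LTPi-capable, everything else is static.
#'
#' @param config a [network_config()]
#' @return list of class `assoc_network`
#' @export
build_associative_network <- function(config) {
  stopifnot(inherits(config, "network_config"))
  n_e <- config$n_e; n_i <- config$n_i
  w0 <- config$w0_eff
  ms <- config$master_seed
  regime <- config$regime

  cells_e <- sample_cell_params(n_e, "excitatory", "associative",
                                seed = child_seed(ms, "cell_params"),
                                regime = regime)
  cells_i <- sample_cell_params(n_i, "inhibitory", "associative",
                                seed = .child_seed(ms, 21L),
                                regime = regime)
  cells <- rbind(cells_e, cells_i)

  set.seed(child_seed(ms, "structure"))
  m_ee <- .random_mask(n_e, n_e, 0.10, no_self = TRUE)
  if (identical(regime, "homogeneous_ee")) {
    m_ee <- matrix(TRUE, n_e, n_e); diag(m_ee) <- FALSE
  }
  m_ie <- .random_mask(n_i, n_e, 0.25)
  if (identical(regime, "homogeneous_ie")) m_ie <- matrix(TRUE, n_i, n_e)
  m_ii <- matrix(TRUE, n_i, n_i); diag(m_ii) <- FALSE
  m_ei <- if (identical(regime, "recurrent_inhibition"))
    .random_mask(n_e, n_i, 0.25) else matrix(FALSE, n_e, n_i)

  set.seed(child_seed(ms, "weights"))
  w_ee <- .init_weights(m_ee, w0)
  w_ie <- .init_weights(m_ie, w0)
  if (identical(regime, "inhibition_x4")) w_ie <- 4 * w_ie
  w_ii <- .init_weights(m_ii, w0)
  # recurrent-inhibition regime: fixed mean strength W0
  w_ei <- matrix(0, n_e, n_i); w_ei[m_ei] <- w0

  ensemble <- build_input_ensemble(
    config$groups_per_stimulus, config$input_probability,
    n_e = n_e, n_i = n_i, seed = .child_seed(ms, 22L),
    w0 = w0, homogeneous = identical(regime, "homogeneous_inputs"))

  set.seed(child_seed(ms, "goal_rates"))
  hc <- config$homeostasis
  goal_e <- runif(n_e, hc$r_goal_e, hc$r_goal_e + hc$goal_spread)
  goal_ie <- runif(n_e, hc$r_goal_ie, hc$r_goal_ie + hc$goal_spread)

  structure(list(
    config = config, n_e = n_e, n_i = n_i, cells = cells,
    ensemble = ensemble,
    masks = list(ee = m_ee, ie = m_ie, ii = m_ii, ei = m_ei),
    weights = list(ee = w_ee, ie = w_ie, ii = w_ii, ei = w_ei,
                   input = ensemble$weights),
    initial_weights = list(ee = w_ee, ie = w_ie,
                           input = ensemble$weights),
    plasticity_tags = list(ee = "stdp", input = "stdp", ie = "ltpi",
                           ii = "static", ei = "static"),
    goal_rates = list(e = goal_e, ie = goal_ie),
    w0_eff = w0,
    seeds = c(structure = child_seed(ms, "structure"),
              cell_params = child_seed(ms, "cell_params"),
              weights = child_seed(ms, "weights"))),
    class = "assoc_network")
}

#' @export
print.assoc_network <- function(x, ...) {
  cat(sprintf("Associative network: %d E + %d I cells (regime %s)\n",
              x$n_e, x$n_i, x$config$regime))
  cat(sprintf("  E->E density %.3f, I->E density %.3f, I->I all-to-all%s\n",
              mean(x$masks$ee), mean(x$masks$ie),
              if (any(x$masks$ei)) ", E->I recurrent" else
                " (feedforward inhibition)"))
  print(x$ensemble)
  invisible(x)
}

#' Build the winner-take-all decision network
#'
#' Two pools (Release and Hold) of 200 excitatory + 50 inhibitory cells
#' each (500 cells total, 4:1 E:I). Connections within each pool are
#' all-to-all at strength `W0 = 0.25`; cross-inhibition runs from each
#' pool's inhibitory cells to the opposing pool's excitatory cells.
#' Afferents from all associative excitatory cells are all-to-all onto
#' both excitatory pools at `DW0 = 0.075` in trained networks, or
#' `DW0 = 0.125` when testing untrained networks at the sparse input
#' probabilities (1/10, 1/20).
#'
#' @param config a [network_config()] (supplies the associative E count
#'   and the input probability used for the untrained-sparse exception)
#' @param trained logical; FALSE selects the untrained-network afferent
#'   strength rule
#' @return list of class `decision_network`
#' @export
build_decision_network <- function(config, trained = TRUE) {
  stopifnot(inherits(config, "network_config"))
  n_e_pool <- 200L; n_i_pool <- 50L
  n_e <- 2L * n_e_pool; n_i <- 2L * n_i_pool
  n <- n_e + n_i
  w0 <- 0.25
  dw0 <- if (!trained && config$input_probability <= 1/10 + 1e-12)
    0.125 else 0.075

  cells_e <- sample_cell_params(n_e, "excitatory", "decision")
  cells_i <- sample_cell_params(n_i, "inhibitory", "decision")
  cells <- rbind(cells_e, cells_i)

  # cell index layout: E pool1, E pool2, I pool1, I pool2
  pool <- c(rep(1L, n_e_pool), rep(2L, n_e_pool),
            rep(1L, n_i_pool), rep(2L, n_i_pool))
  mask <- matrix(FALSE, n, n)
  e1 <- 1:n_e_pool; e2 <- n_e_pool + 1:n_e_pool
  i1 <- n_e + 1:n_i_pool; i2 <- n_e + n_i_pool + 1:n_i_pool
  # within-pool all-to-all (E->E, E->I, I->I); inhibition onto
  # excitatory cells is cross-pool only, which is what generates the
  # winner-take-all competition
  for (idx in list(c(list(e1), list(e1)), c(list(e1), list(i1)),
                   c(list(i1), list(i1)),
                   c(list(e2), list(e2)), c(list(e2), list(i2)),
                   c(list(i2), list(i2))))
    mask[idx[[1]], idx[[2]]] <- TRUE
  # cross-inhibition: inhibitory pool -> opposing excitatory pool
  mask[i1, e2] <- TRUE
  mask[i2, e1] <- TRUE
  diag(mask) <- FALSE
  weights <- matrix(0, n, n)
  weights[mask] <- w0

  n_aff <- config$n_e
  afferents <- matrix(dw0, n_aff, n_e)

  structure(list(
    n_e = n_e, n_i = n_i, n_e_pool = n_e_pool, n_i_pool = n_i_pool,
    pool = pool, pool_names = c("Release", "Hold"),
    cells = cells, mask = mask, weights = weights, w0 = w0,
    afferents = afferents, dw0 = dw0, trained = trained,
    e1 = e1, e2 = e2, i1 = i1, i2 = i2),
    class = "decision_network")
}

#' @export
print.decision_network <- function(x, ...) {
  cat(sprintf(
    "Decision network: 2 pools of %d E + %d I (W0 = %.3g, DW0 = %.3g)\n",
    x$n_e_pool, x$n_i_pool, x$w0, x$dw0))
  invisible(x)
}

#' Enumerate the 5 x 5 grid of network configurations
#'
#' The Cartesian product of the five input connection probabilities and
#' the five input-group counts gives 25 variant networks per regime,
#' each with a child seed derived from the master seed.
#'
#' @param regime regime name
#' @param master_seed integer master seed
#' @param ... further arguments passed to [network_config()]
#' @return list of 25 `network_config` objects
#' @export
grid_configs <- function(regime = "standard", master_seed = 1L, ...) {
  regime <- match.arg(regime, .regimes)
  grid <- expand.grid(probability = .input_probabilities,
                      groups = .input_group_counts)
  lapply(seq_len(nrow(grid)), function(k)
    network_config(groups_per_stimulus = grid$groups[k],
                   input_probability = grid$probability[k],
                   regime = regime,
                   master_seed = .child_seed(master_seed, 100L + k),
                   ...))
}
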