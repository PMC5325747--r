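# Independent DerSimonian-Laird oracle on the raw-proportion scale, written
# directly from the closed-form estimator, used to cross-check the package's
# pooling (which shares no code with this).
dl_pool_oracle <- function(p, v) {
  w <- 1 / v
  mu_fe <- sum(w * p) / sum(w)
  q <- sum(w * (p - mu_fe)^2)
  k <- length(p)
  tau2 <- max(0, (q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (v + tau2)
  list(mean = sum(wr * p) / sum(wr), se = sqrt(1 / sum(wr)),
       tau2 = tau2, q = q)
}

# Random chance tree of at most `depth` further levels; terminals carry
# payoffs in [-10, 10].
random_tree <- function(depth) {
  if (depth == 0L || stats::runif(1) < 0.3) {
    return(terminal_node(stats::runif(1, -10, 10)))
  }
  nb <- sample(2:3, 1L)
  w <- stats::runif(nb)
  chance_node(w / sum(w), lapply(seq_len(nb), function(i) {
    random_tree(depth - 1L)
  }))
}

scale_payoffs <- function(node, c) {
  if (inherits(node, "tn_terminal")) {
    return(terminal_node(node$payoff * c, node$label))
  }
  chance_node(node$probs,
              lapply(node$children, scale_payoffs, c = c),
              node$labels, node$label)
}

terminal_payoffs <- function(node) {
  if (inherits(node, "tn_terminal")) return(node$payoff)
  unlist(lapply(node$children, terminal_payoffs))
}

collect_labels <- function(node) {
  if (inherits(node, "tn_terminal")) return(node$label)
  c(node$labels, unlist(lapply(node$children, collect_labels)))
}

# Arm parameters with every uncertainty removed (point-mass PSA inputs).
zero_sd_params <- function(params) {
  strip <- function(e) { e$sd <- 0; e }
  for (lvl in BNI_LEVELS) {
    params$bni_dist[[lvl]] <- strip(params$bni_dist[[lvl]])
    params$bni_utility[[lvl]] <- strip(params$bni_utility[[lvl]])
  }
  params$complication_rate <- strip(params$complication_rate)
  params$recurrence_rate_7y <- strip(params$recurrence_rate_7y)
  params$retreat_fraction <- strip(params$retreat_fraction)
  params$complications <- lapply(params$complications, function(e) {
    e$incidence <- strip(e$incidence); e$utility <- strip(e$utility); e
  })
  for (cat in names(params$medication$probs)) {
    params$medication$probs[[cat]] <- strip(params$medication$probs[[cat]])
    params$medication$utilities[[cat]] <- strip(params$medication$utilities[[cat]])
  }
  params
}

# One-outcome corpus spec for pooling calibration runs.
single_rate_spec <- function(rate, k, n, seed, slopes = NULL) {
  args <- list(
    n_studies = c(MVD = k, SRS = 1L),
    size_range = c(n, n),
    true_rates = list(MVD = c(recurrence = rate), SRS = c(recurrence = rate)),
    seed = seed)
  if (!is.null(slopes)) args$slopes <- slopes
  do.call(corpus_spec, args)
}
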