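#' Aggregate complication sub-model
#'
#' Individual procedure-related complications are assumed additive: the total
#' complication rate is the sum of the itemized incidences, and the expected
#' utility conditional on experiencing any complication is the
#' incidence-weighted mean of the entry utilities divided by the total rate.
#' An entry with a non-empty `compound_with` contributes the product of its
#' own utility and the utilities of the named entries (corneal keratitis
#' compounding with facial numbness and facial palsy in the default SRS
#' profile).
#'
#' @param entries list of [complication_entry()]s.
#' @return list with `total_rate` and `conditional_utility` (1.0 when
#'   `entries` is empty).
#' @export
complication_submodel <- function(entries) {
  if (length(entries) == 0L) {
    return(list(total_rate = 0, conditional_utility = 1.0))
  }
  inc <- vapply(entries, function(e) e$incidence$mean, 0)
  total <- sum(inc)
  if (total > 1 + PROB_TOL) {
    stop(sprintf("complication incidences sum to %.4g > 1", total))
  }
  u <- vapply(entries, function(e) compound_utility(e, entries), 0)
  list(total_rate = total, conditional_utility = sum(inc * u) / total)
}

compound_utility <- function(entry, entries) {
  u <- entry$utility$mean
  for (nm in entry$compound_with) {
    other <- Filter(function(e) e$name == nm, entries)
    if (length(other) != 1L) {
      stop("compound_with references unknown complication: ", nm)
    }
    u <- u * other[[1L]]$utility$mean
  }
  u
}

#' Complication sub-tree (conditional on any complication)
#'
#' The chance node over which complication occurred, given that one did:
#' branch probabilities are the itemized incidences normalized by the total
#' rate, terminal payoffs the (compounded) complication utilities.  Its
#' [rollback()] equals the `conditional_utility` of
#' [complication_submodel()].
#'
#' @inheritParams complication_submodel
#' @return a [chance_node()].
#' @export
build_complication_tree <- function(entries) {
  stopifnot(length(entries) >= 1L)
  inc <- vapply(entries, function(e) e$incidence$mean, 0)
  chance_node(
    probs = inc / sum(inc),
    children = lapply(entries, function(e) {
      terminal_node(compound_utility(e, entries), e$name)
    }),
    labels = vapply(entries, `[[`, "", "name"),
    label = "complication_type")
}

#' Expected utility of requiring maintenance medication
#'
#' Probability-weighted mean of the three medication side-effect category
#' utilities (categories renormalized to sum to one).  This direct weighted
#' mean of the source values is 0.874; the source analysis prints 0.881 for
#' the same sub-tree, a value not reproducible from the printed inputs.  Set
#' `pinned` to use the printed constant instead of the computed mean.
#'
#' @param model a [medication_model()].
#' @param pinned optional numeric: return this value instead of the computed
#'   weighted mean (e.g. `0.881` to pin the published constant).
#' @return expected utility of the medicated state.
#' @export
medication_submodel <- function(model, pinned = NULL) {
  stopifnot(inherits(model, "medication_model"))
  if (!is.null(pinned)) return(pinned)
  p <- vapply(model$probs, `[[`, 0, "mean")
  u <- vapply(model$utilities, `[[`, 0, "mean")
  sum(p * u) / sum(p)
}

#' Utility of a composite health state
#'
#' Coexisting outcomes combine multiplicatively: the utility of the BNI pain
#' level, times the complication multiplier (1 if none), times the medication
#' sub-model utility when the level requires medication (BNI III and IV-V),
#' times the re-treatment multiplier compounded per additional procedure.
#'
#' @param ctx list with `bni` (a level in [BNI_LEVELS]),
#'   `complication_multiplier` (default 1), and `retreat_depth` (default 0).
#' @param params a [treatment_params()] supplying the BNI utilities and
#'   medication model.
#' @param config a [model_config()] supplying the re-treatment multiplier.
#' @return utility in \[0, 1\].
#' @examples
#' state_utility(list(bni = "I"), default_parameters("MVD"), model_config())
#' @export
state_utility <- function(ctx, params, config = model_config()) {
  stopifnot(ctx$bni %in% BNI_LEVELS)
  cm <- if (is.null(ctx$complication_multiplier)) 1 else ctx$complication_multiplier
  depth <- if (is.null(ctx$retreat_depth)) 0L else ctx$retreat_depth
  stopifnot(depth <= config$max_additional_procedures)
  u <- params$bni_utility[[ctx$bni]]$mean * cm *
    config$retreat_utility_multiplier^depth
  if (bni_medicated(ctx$bni)) u <- u * medication_submodel(params$medication)
  u
}

#' Patient timeline and its QALY total
#'
#' A timeline is a set of contiguous health-state segments partitioning
#' `[0, horizon]`, each with a constant utility; its QALY total is the sum of
#' duration times utility (so 4 years at utility 0.25 is 1 QALY, and 7 years
#' in perfect health is 7).
#'
#' @param start,end,utility numeric vectors describing the segments.
#' @param events optional named list of event times (procedures,
#'   complication onset, recurrence).
#' @return `patient_timeline` returns an object of class `patient_timeline`;
#'   `timeline_qaly` its QALY total after checking that the segments tile
#'   `[0, horizon]` without gaps or overlaps.
#' @examples
#' timeline_qaly(patient_timeline(0, 4, 0.25))  # 1 QALY
#' @export
patient_timeline <- function(start, end, utility, events = list()) {
  stopifnot(length(start) == length(end), length(end) == length(utility))
  start <- as.numeric(start); end <- as.numeric(end)
  utility <- as.numeric(utility)
  if (is.unsorted(start)) {
    o <- order(start)
    start <- start[o]; end <- end[o]; utility <- utility[o]
  }
  structure(list(start = start, end = end, utility = utility, events = events),
            class = "patient_timeline")
}

#' @rdname patient_timeline
#' @param timeline a `patient_timeline`.
#' @export
timeline_qaly <- function(timeline) {
  stopifnot(inherits(timeline, "patient_timeline"))
  s <- timeline$start; e <- timeline$end
  if (length(s) == 0L) return(0)
  tol <- 1e-9
  if (abs(s[1]) > tol) stop("timeline does not start at 0")
  if (any(e <= s)) stop("timeline has an empty or inverted segment")
  if (length(s) > 1L && any(abs(s[-1] - e[-length(e)]) > tol)) {
    stop("timeline segments have gaps or overlaps")
  }
  if (any(timeline$utility < 0 | timeline$utility > 1)) {
    stop("segment utility outside [0, 1]")
  }
  sum((e - s) * timeline$utility)
}

# Resolve base-state segments plus permanent multiplicative effects (each a
# c(onset, factor) pair) into a flat piecewise-constant timeline on [0, H].
# `segs` is a list of c(start, end, base_utility) covering [0, H].
resolve_timeline <- function(segs, effects, horizon, events = list()) {
  sm <- do.call(rbind, segs)
  onsets <- if (length(effects)) vapply(effects, `[[`, 0, 1L) else numeric()
  breaks <- sort(unique(c(sm[, 1L], sm[, 2L],
                          onsets[onsets > 0 & onsets < horizon])))
  a <- breaks[-length(breaks)]
  b <- breaks[-1L]
  # base utility of the segment containing each atomic interval
  idx <- findInterval(a + 1e-12, sm[, 1L])
  u <- sm[idx, 3L]
  for (ef in effects) {
    if (ef[1L] < horizon) {
      hit <- a >= ef[1L] - 1e-12
      u[hit] <- u[hit] * ef[2L]
    }
  }
  patient_timeline(a, b, u, events)
}

add_seg <- function(segs, start, end, u) {
  if (end - start <= 1e-12) return(segs)
  c(segs, list(c(start, end, u)))
}

#' Assemble the treatment decision tree
#'
#' Builds the full chance tree for one primary procedure: complication
#' (yes/no, with the arm's pooled rate; the conditional utility multiplier
#' comes from the itemized complication sub-model and applies permanently
#' from complication onset), then the four-level BNI outcome.  Initial
#' failures (BNI IV-V) are re-treated with probability `retreat_fraction` at
#' the arm's re-treatment delay, by a modality drawn from
#' `retreat_modality_mix`, recursing with the next re-treatment depth until
#' the cap; unretreated failures persist in BNI IV-V.  Successes (BNI I-III)
#' may recur at `recurrence_time_years` after their procedure (when that
#' falls inside the horizon): re-treated recurrences enter a re-treatment
#' subtree at that time, untreated recurrences settle at the medicated
#' post-recurrence level for the remainder.  Each additional procedure
#' multiplies subsequent utility by `retreat_utility_multiplier`.  Terminal
#' payoffs are timeline QALYs over `[0, horizon]`.
#'
#' @param treatment `"MVD"` or `"SRS"`: the primary procedure.
#' @param params a [treatment_params()] for the primary arm.
#' @param config a [model_config()].
#' @param other_params parameters for the other modality, used when the
#'   re-treatment mix gives it positive weight; defaults to
#'   [default_parameters()] of the other arm.
#' @return a `tn_node` whose [rollback()] is the arm's expected QALYs.
#' @export
build_treatment_tree <- function(treatment = c("MVD", "SRS"),
                                 params = default_parameters(treatment),
                                 config = model_config(),
                                 other_params = NULL) {
  treatment <- match.arg(treatment)
  stopifnot(inherits(params, "treatment_params"),
            inherits(config, "model_config"))
  other <- setdiff(c("MVD", "SRS"), treatment)
  if (is.null(other_params)) other_params <- default_parameters(other)
  pl <- list()
  pl[[treatment]] <- params
  pl[[other]] <- other_params
  if (config$horizon_years == 0) return(terminal_node(0, "zero_horizon"))
  build_procedure(treatment, t0 = 0, depth = 0L, segs = list(),
                  effects = list(), pl = pl, config = config)
}

build_procedure <- function(mod, t0, depth, segs, effects, pl, config) {
  P <- pl[[mod]]
  H <- config$horizon_years
  if (depth > 0L) {
    effects <- c(effects, list(c(t0, config$retreat_utility_multiplier)))
  }
  med_u <- medication_submodel(P$medication)
  u_level <- function(lvl) {
    u <- P$bni_utility[[lvl]]$mean
    if (bni_medicated(lvl)) u <- u * med_u
    u
  }
  pre_lvl <- config$post_recurrence_pre_treatment_level
  t_resp <- min(t0 + P$response_delay_months / 12, H)
  segs <- add_seg(segs, t0, t_resp, u_level(pre_lvl))
  t_comp <- t0 + P$complication_onset_months / 12
  cs <- complication_submodel(P$complications)
  pc <- P$complication_rate$mean

  leaf <- function(segs, effects, label) {
    tl <- resolve_timeline(segs, effects, H)
    terminal_node(timeline_qaly(tl), label)
  }

  bni_subtree <- function(lvl, effects) {
    u_b <- u_level(lvl)
    if (lvl == "IV_V") {
      # initial failure of this procedure
      t_rt <- t0 + P$retreat_delay_months / 12
      persist <- function() {
        leaf(add_seg(segs, t_resp, H, u_b), effects, "persistent_IV_V")
      }
      if (depth >= config$max_additional_procedures || t_rt >= H) {
        return(persist())
      }
      retreat_node <- modality_mix_node(
        P$retreat_modality_mix,
        function(m) {
          build_procedure(m, t_rt, depth + 1L,
                          add_seg(segs, t_resp, t_rt, u_b), effects, pl, config)
        })
      chance_node(
        probs = c(P$retreat_fraction$mean, 1 - P$retreat_fraction$mean),
        children = list(retreat_node, persist()),
        labels = c("failure_retreat", "failure_no_retreat"),
        label = "failure_retreat_decision")
    } else {
      # success state: recurrence possible at a fixed time after the procedure
      t_rec <- t0 + config$recurrence_time_years
      stay <- function() {
        leaf(add_seg(segs, t_resp, H, u_b), effects, paste0("stay_BNI_", lvl))
      }
      if (t_rec >= H) return(stay())
      segs_rec <- add_seg(segs, t_resp, t_rec, u_b)
      untreated <- function() {
        u_rec <- u_level(config$post_recurrence_untreated_level)
        leaf(add_seg(segs_rec, t_rec, H, u_rec), effects,
             "untreated_recurrence")
      }
      rec_child <- if (depth >= config$max_additional_procedures) {
        untreated()
      } else {
        retreat_node <- modality_mix_node(
          P$retreat_modality_mix,
          function(m) {
            build_procedure(m, t_rec, depth + 1L, segs_rec, effects, pl, config)
          })
        chance_node(
          probs = c(P$retreat_fraction$mean, 1 - P$retreat_fraction$mean),
          children = list(retreat_node, untreated()),
          labels = c("recurrence_retreat", "recurrence_no_retreat"),
          label = "recurrence_retreat_decision")
      }
      chance_node(
        probs = c(P$recurrence_rate_7y$mean, 1 - P$recurrence_rate_7y$mean),
        children = list(rec_child, stay()),
        labels = c("recurrence", "no_recurrence"),
        label = "recurrence")
    }
  }

  bni_node <- function(effects) {
    p <- vapply(P$bni_dist, `[[`, 0, "mean")
    p <- p / sum(p)
    chance_node(
      probs = unname(p),
      children = lapply(BNI_LEVELS, bni_subtree, effects = effects),
      labels = paste0("BNI_", BNI_LEVELS),
      label = paste0(mod, "_outcome"))
  }

  chance_node(
    probs = c(pc, 1 - pc),
    children = list(
      bni_node(c(effects, list(c(t_comp, cs$conditional_utility)))),
      bni_node(effects)),
    labels = c("complication", "no_complication"),
    label = paste0(mod, "_complication"))
}

modality_mix_node <- function(mix, build) {
  pos <- names(mix)[mix > 0]
  if (length(pos) == 1L) return(build(pos))
  chance_node(
    probs = unname(mix[pos]),
    children = lapply(pos, build),
    labels = paste0("retreat_", pos),
    label = "retreat_modality")
}

#' Deterministic expected QALYs of a treatment strategy
#'
#' Rollback of the assembled treatment tree at point (mean) parameter
#' values.
#'
#' @inheritParams build_treatment_tree
#' @return expected QALYs over the horizon.
#' @examples
#' expected_qalys("MVD")
#' @export
expected_qalys <- function(treatment = c("MVD", "SRS"),
                           params = default_parameters(treatment),
                           config = model_config(),
                           other_params = NULL) {
  treatment <- match.arg(treatment)
  rollback(build_treatment_tree(treatment, params, config, other_params))
}

#' One-way deterministic sensitivity analysis
#'
#' Recomputes [expected_qalys()] across a grid of values for a single scalar
#' parameter, all else held at baseline; the baseline value and its QALYs
#' are included in the result.
#'
#' @inheritParams build_treatment_tree
#' @param parameter_id dotted path addressing one scalar mean, e.g.
#'   `"complication_rate"`, `"recurrence_rate_7y"`, `"retreat_fraction"`,
#'   `"bni_dist.I"`, `"bni_utility.III"`, `"medication.utilities.severe"`,
#'   `"complications.facial_numbness.incidence"`, or a config field as
#'   `"config.retreat_utility_multiplier"`.
#' @param values numeric vector of alternative values.
#' @return data.frame with columns `value`, `qalys`, `baseline` (logical).
#' @export
one_way_sensitivity <- function(treatment, params = default_parameters(treatment),
                                config = model_config(), parameter_id, values,
                                other_params = NULL) {
  base_val <- get_parameter(params, config, parameter_id)
  grid <- c(base_val, values)
  qalys <- vapply(grid, function(v) {
    pc <- set_parameter(params, config, parameter_id, v)
    expected_qalys(treatment, pc$params, pc$config, other_params)
  }, 0)
  out <- data.frame(value = grid, qalys = qalys,
                    baseline = c(TRUE, rep(FALSE, length(values))))
  out[order(out$value), , drop = FALSE]
}

parameter_slot <- function(params, config, id) {
  parts <- strsplit(id, ".", fixed = TRUE)[[1L]]
  if (parts[1L] == "config") {
    if (length(parts) != 2L || !parts[2L] %in% names(config)) {
      stop("unknown parameter id: ", id)
    }
    return(list(where = "config", field = parts[2L]))
  }
  ok <- switch(parts[1L],
    complication_rate = , recurrence_rate_7y = , retreat_fraction =
      length(parts) == 1L,
    bni_dist = , bni_utility =
      length(parts) == 2L && parts[2L] %in% BNI_LEVELS,
    medication =
      length(parts) == 3L && parts[2L] %in% c("probs", "utilities") &&
        parts[3L] %in% c("none", "mild_moderate", "severe"),
    complications =
      length(parts) == 3L && parts[3L] %in% c("incidence", "utility") &&
        any(vapply(params$complications, `[[`, "", "name") == parts[2L]),
    FALSE)
  if (!isTRUE(ok)) stop("unknown parameter id: ", id)
  list(where = "params", parts = parts)
}

get_parameter <- function(params, config, id) {
  slot <- parameter_slot(params, config, id)
  if (slot$where == "config") return(config[[slot$field]])
  parts <- slot$parts
  switch(parts[1L],
    complication_rate = params$complication_rate$mean,
    recurrence_rate_7y = params$recurrence_rate_7y$mean,
    retreat_fraction = params$retreat_fraction$mean,
    bni_dist = params$bni_dist[[parts[2L]]]$mean,
    bni_utility = params$bni_utility[[parts[2L]]]$mean,
    medication = params$medication[[parts[2L]]][[parts[3L]]]$mean,
    complications = {
      i <- which(vapply(params$complications, `[[`, "", "name") == parts[2L])
      params$complications[[i]][[parts[3L]]]$mean
    })
}

set_parameter <- function(params, config, id, value) {
  slot <- parameter_slot(params, config, id)
  if (slot$where == "config") {
    config[[slot$field]] <- value
    return(list(params = params, config = config))
  }
  parts <- slot$parts
  switch(parts[1L],
    complication_rate = params$complication_rate$mean <- value,
    recurrence_rate_7y = params$recurrence_rate_7y$mean <- value,
    retreat_fraction = params$retreat_fraction$mean <- value,
    bni_dist = params$bni_dist[[parts[2L]]]$mean <- value,
    bni_utility = params$bni_utility[[parts[2L]]]$mean <- value,
    medication = params$medication[[parts[2L]]][[parts[3L]]]$mean <- value,
    complications = {
      i <- which(vapply(params$complications, `[[`, "", "name") == parts[2L])
      params$complications[[i]][[parts[3L]]]$mean <- value
    })
  list(params = params, config = config)
}
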