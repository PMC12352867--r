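# The eleven 200 ms classification windows, each anchored to a behavioral
# event: "before" = [event - 200, event), "after" = [event, event + 200).
EPOCH_WINDOWS <- data.frame(
  window = sprintf("w%02d", 1:11),
  event = c("instruction_on", "instruction_on", "instruction_off",
            "instruction_off", "go", "go", "move_on", "move_on",
            "hold_on", "hold_on", "hold_off"),
  side = c("before", "after", "before", "after", "before", "after",
           "before", "after", "before", "after", "before"),
  stringsAsFactors = FALSE)

#' Per-trial spike counts in the eleven 200 ms task windows
#'
#' Windows: before/after instruction onset, before/after instruction
#' offset (delay begins), before/after the go cue (delay ends), before/
#' after movement onset, before/after hold onset (movement ends), and
#' before hold end. Half-open convention: a spike exactly at the event time
#' falls in the "after" window only.
#'
#' @param bundle A [session_bundle()].
#' @param unit A unit id present in the bundle.
#' @return `data.frame(trial_id, object, window, count)` over successful
#'   trials; trials whose windows exceed the trial bounds are dropped with
#'   a warning.
#' @export
epoch_counts <- function(bundle, unit) {
  if (!unit %in% bundle$units$unit_id) stop("unknown unit: ", unit)
  st <- bundle$spikes[[unit]]
  tr <- successful_trials(bundle)
  out <- vector("list", nrow(tr))
  for (k in seq_len(nrow(tr))) {
    lo <- ifelse(EPOCH_WINDOWS$side == "before",
                 as.numeric(tr[k, EPOCH_WINDOWS$event]) - 200,
                 as.numeric(tr[k, EPOCH_WINDOWS$event]))
    hi <- lo + 200
    if (any(lo < tr$start[k]) || any(hi > tr$end[k])) {
      warning(sprintf("trial '%s': classification window outside trial bounds; dropped",
                      tr$trial_id[k]))
      next
    }
    counts <- vapply(seq_len(11), function(w) sum(st >= lo[w] & st < hi[w]), 1L)
    out[[k]] <- data.frame(trial_id = tr$trial_id[k], object = tr$object[k],
                           window = EPOCH_WINDOWS$window, count = counts)
  }
  do.call(rbind, out)
}

# Two-way fixed-effects ANOVA with interaction on window counts for one
# context; returns the three p-values (object, period, interaction).
anova_pvals <- function(counts) {
  if (stats::var(counts$count) == 0) {
    warning("degenerate counts (zero variance); unit treated as unmodulated")
    return(c(object = 1, period = 1, interaction = 1))
  }
  fit <- stats::lm(count ~ object * window, data = counts)
  tab <- stats::anova(fit)
  p <- tab[["Pr(>F)"]]
  c(object = p[1], period = p[2], interaction = p[3])
}

#' Classify units as MN, AE, AO or NS
#'
#' For each unit and context, a two-way ANOVA on the eleven-window spike
#' counts with object (4 levels) and time period (11 levels) as crossed
#' factors, trials as replicates. A context counts as "modulated" if any of
#' the three p-values (object main effect, period main effect, interaction)
#' falls below `alpha` (default 0.0083, a Bonferroni correction of 0.05
#' over the six tests each unit gets across its two contexts). Modulated in
#' both contexts = MN (mirror neuron); execution only = AE; observation
#' only = AO; neither = NS.
#'
#' @param exec_bundle,obs_bundle The two contexts' [session_bundle()]s
#'   (same units).
#' @param alpha Significance criterion (default 0.0083).
#' @return `data.frame(unit_id, area, class, p_obj_exec, p_per_exec,
#'   p_int_exec, p_obj_obs, p_per_obs, p_int_obs)`.
#' @export
classify_units <- function(exec_bundle, obs_bundle, alpha = 0.0083) {
  if (!identical(exec_bundle$units$unit_id, obs_bundle$units$unit_id))
    stop("contexts disagree on the unit population")
  res <- lapply(exec_bundle$units$unit_id, function(u) {
    pe <- anova_pvals(epoch_counts(exec_bundle, u))
    po <- anova_pvals(epoch_counts(obs_bundle, u))
    mod_e <- any(pe < alpha); mod_o <- any(po < alpha)
    cls <- if (mod_e && mod_o) "MN" else if (mod_e) "AE" else if (mod_o) "AO" else "NS"
    data.frame(unit_id = u,
               area = exec_bundle$units$area[exec_bundle$units$unit_id == u],
               class = cls,
               p_obj_exec = pe[1], p_per_exec = pe[2], p_int_exec = pe[3],
               p_obj_obs = po[1], p_per_obs = po[2], p_int_obs = po[3],
               row.names = NULL)
  })
  out <- do.call(rbind, res)
  attr(out, "alpha") <- alpha
  out
}

#' Is a single context modulated?
#'
#' Applies the modulation rule to one context's bundle (used for the
#' type-I-error calibration of the classifier).
#'
#' @param bundle A [session_bundle()].
#' @param unit Unit id.
#' @param alpha Significance criterion.
#' @return Logical: any of the three ANOVA p-values below `alpha`.
#' @export
context_modulated <- function(bundle, unit, alpha = 0.0083) {
  any(anova_pvals(epoch_counts(bundle, unit)) < alpha)
}
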