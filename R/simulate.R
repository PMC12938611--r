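#' Simulate one session of the group foraging task
#'
#' Runs a discrete-event simulation of `condition$group_size` agents foraging
#' for `condition$session_length` seconds and returns the resulting event log
#' as a tibble. Each agent repeatedly chooses between three actions through a
#' softmax over utilities:
#'
#' * **produce** — travel to a patch without an active discovery (if needed),
#'   press for `search_cost` seconds; with probability `success_prob` the
#'   search succeeds and `food_per_patch` units appear. Utility:
#'   `baseline_logit + produce_signal - cost_sensitivity * search_cost`.
#' * **scrounge** — join another agent's discovery that still has
#'   uncollected units and is within its join window. Utility:
#'   `scrounge_opportunism - scrounge_cost_spillover * search_cost` (only
#'   available while a joinable discovery exists; a costly ecology suppresses
#'   chances to express either strategy).
#' * **idle** — wait `decision_pause` seconds. Utility 0.
#'
#' Agents attached to a discovery (its finder, plus any joiners) collect its
#' units one at a time, `collect_time` seconds per unit, interleaved in event
#' order — so the finder's share (the units the finder secures before joiners
#' arrive) is an emergent quantity, recoverable with
#' [estimate_finders_share()]. A patch holding an active discovery cannot be
#' searched again until the discovery is exhausted, so at most one discovery
#' is alive per patch and the log alone identifies which discovery every
#' `join`/`collect` refers to.
#'
#' The log is a valid event stream: times are nondecreasing within
#' `[0, session_length]`, every `join` refers to a patch holding an
#' uncollected discovery by another agent, and identical
#' `(condition, agents, seed)` reproduce the log exactly.
#'
#' @param condition A [gft_condition()].
#' @param agents Agent tibble from [generate_cohort()] or [agent_profile()];
#'   must have exactly `condition$group_size` rows.
#' @param seed Integer seed for this session's random stream.
#' @return A tibble with columns `session_id`, `condition`, `time_s`,
#'   `agent_id`, `event` (`search_start`, `search_success`, `search_fail`,
#'   `join`, `collect`), `patch_id`, `units` (1 for `collect`, NA otherwise).
#' @export
#' @examples
#' ag <- generate_cohort(4, seed = 1)
#' log <- simulate_session(condition_low_cost(), ag, seed = 42)
#' dplyr::count(log, event)
simulate_session <- function(condition, agents, seed) {
  if (!inherits(condition, "gft_condition")) {
    abort_validation("`condition` must be a `gft_condition`")
  }
  agents <- validate_agents(agents)
  if (nrow(agents) != condition$group_size) {
    abort_config(
      "condition `%s` needs %d agents, got %d",
      condition$name, condition$group_size, nrow(agents)
    )
  }
  check_number(seed, "seed", integer = TRUE)
  withr::with_seed(as.integer(seed), sim_engine(condition, agents))
}

validate_agents <- function(agents) {
  need <- c(
    "agent_id", "O", "C", "E", "A", "N",
    "baseline_logit", "produce_signal", "cost_sensitivity", "scrounge_opportunism",
    "scrounge_cost_spillover"
  )
  if (!is.data.frame(agents)) abort_validation("`agents` must be a data frame")
  miss <- setdiff(need, names(agents))
  if (length(miss)) {
    abort_validation("`agents` is missing columns: %s", paste(miss, collapse = ", "))
  }
  num <- setdiff(need, "agent_id")
  for (col in num) {
    if (!is.numeric(agents[[col]]) || any(!is.finite(agents[[col]]))) {
      abort_validation("agent column `%s` must be finite numeric", col)
    }
  }
  if (any(agents$cost_sensitivity < 0)) {
    abort_validation("`cost_sensitivity` must be >= 0")
  }
  if (anyDuplicated(agents$agent_id)) abort_validation("duplicate `agent_id`")
  tibble::as_tibble(agents)
}

# The event-driven engine. Runs inside withr::with_seed().
sim_engine <- function(cond, agents) {
  G <- nrow(cond_agents <- agents)
  len <- cond$session_length
  ids <- as.character(agents$agent_id)

  u_produce <- agents$baseline_logit + agents$produce_signal -
    agents$cost_sensitivity * cond$search_cost
  u_scrounge <- agents$scrounge_opportunism - agents$scrounge_cost_spillover * cond$search_cost

  t_free <- numeric(G) # next decision time per agent
  loc <- integer(G) # 0 = field, else patch id
  attached <- integer(G) # discovery index or 0
  collected <- numeric(G)

  d_patch <- integer(0)
  d_units <- integer(0)
  d_avail <- numeric(0) # the success event's time: invisible before it
  d_open_until <- numeric(0)
  d_busy_until <- numeric(0) # last scheduled collect; patch locked until then
  d_finder <- integer(0)
  pending_join <- integer(G)

  # event store, grown by doubling
  cap <- 512L
  n_ev <- 0L
  ev_time <- numeric(cap)
  ev_agent <- integer(cap)
  ev_type <- character(cap)
  ev_patch <- integer(cap)
  ev_units <- integer(cap)
  push <- function(time, agent, type, patch, units) {
    if (n_ev == cap) {
      cap <<- cap * 2L
      length(ev_time) <<- cap
      length(ev_agent) <<- cap
      length(ev_type) <<- cap
      length(ev_patch) <<- cap
      length(ev_units) <<- cap
    }
    n_ev <<- n_ev + 1L
    ev_time[n_ev] <<- time
    ev_agent[n_ev] <<- agent
    ev_type[n_ev] <<- type
    ev_patch[n_ev] <<- patch
    ev_units[n_ev] <<- units
  }

  repeat {
    i <- which.min(t_free)
    now <- t_free[i]
    if (now >= len) break
    if (is.finite(cond$stop_after_units) && all(collected >= cond$stop_after_units)) break

    # a join decided earlier resolves now, against the current patch state
    pj <- pending_join[i]
    if (pj > 0L) {
      pending_join[i] <- 0L
      loc[i] <- d_patch[pj]
      if (d_units[pj] > 0L) {
        push(now, i, "join", d_patch[pj], NA_integer_)
        attached[i] <- pj
      }
      next
    }

    a <- attached[i]
    if (a > 0L && d_units[a] > 0L) {
      tc <- now + cond$collect_time
      t_free[i] <- tc
      if (tc <= len) {
        d_units[a] <- d_units[a] - 1L
        collected[i] <- collected[i] + 1
        d_busy_until[a] <- max(d_busy_until[a], tc)
        push(tc, i, "collect", d_patch[a], 1L)
      }
      next
    }
    if (a > 0L) attached[i] <- 0L

    joinable <- which(d_avail <= now & d_units > 0L & d_open_until >= now & d_finder != i)
    u <- c(u_produce[i], if (length(joinable)) u_scrounge[i] else -Inf, 0)
    w <- exp(u - max(u))
    act <- sample.int(3L, 1L, prob = w)

    if (act == 1L) { # produce
      busy <- unique(d_patch[d_units > 0L | d_busy_until > now])
      open_patches <- setdiff(seq_len(cond$n_patches), busy)
      if (!length(open_patches)) {
        t_free[i] <- now + cond$decision_pause
        next
      }
      if (loc[i] %in% open_patches) {
        target <- loc[i]
        t0 <- now
      } else {
        target <- if (length(open_patches) == 1L) {
          open_patches
        } else {
          open_patches[sample.int(length(open_patches), 1L)]
        }
        t0 <- now + cond$travel_time
        loc[i] <- target
      }
      t1 <- t0 + cond$search_cost
      t_free[i] <- t1
      if (t0 > len) next
      push(t0, i, "search_start", target, NA_integer_)
      if (t1 > len) next # search cut off by session end
      if (stats::runif(1) < cond$success_prob) {
        push(t1, i, "search_success", target, NA_integer_)
        d_patch <- c(d_patch, target)
        d_units <- c(d_units, cond$food_per_patch)
        d_avail <- c(d_avail, t1)
        d_open_until <- c(d_open_until, t1 + cond$scrounger_join_window)
        d_busy_until <- c(d_busy_until, t1)
        d_finder <- c(d_finder, i)
        attached[i] <- length(d_patch)
      } else {
        push(t1, i, "search_fail", target, NA_integer_)
      }
    } else if (act == 2L) { # scrounge
      j <- joinable[which.max(d_units[joinable])]
      t_arr <- if (loc[i] == d_patch[j]) now else now + cond$travel_time
      t_free[i] <- max(t_arr, now + 1e-9)
      pending_join[i] <- j # resolved on arrival, if units remain
    } else { # idle
      t_free[i] <- now + cond$decision_pause
    }
  }

  ord <- order(ev_time[seq_len(n_ev)], seq_len(n_ev))
  out <- tibble::tibble(
    session_id = paste0("s", format(cond$search_cost), "-1"),
    condition = cond$name,
    time_s = ev_time[ord],
    agent_id = ids[ev_agent[ord]],
    event = ev_type[ord],
    patch_id = ev_patch[ord],
    units = ev_units[ord]
  )
  attr(out, "units_collected") <- stats::setNames(collected, ids)
  out
}

#' Estimate the realized finder's share from an event log
#'
#' The finder's share `a` of the rate-maximization model is the food a
#' producer secures from its own discovery before scroungers join. The task
#' never fixes it; in the simulation it emerges from collection timing. This
#' estimates it from a log as the mean, over discoveries, of the fraction of
#' collected units taken by the discovery's finder.
#'
#' @param log Event-log tibble (possibly several sessions).
#' @return A tibble with `session_id`, `n_discoveries`, `finders_share`
#'   (mean fraction) and `finders_units` (mean units the finder took).
#' @export
estimate_finders_share <- function(log) {
  validate_event_log(log)
  log |>
    dplyr::group_by(.data$session_id) |>
    dplyr::group_modify(~ finders_share_one(.x)) |>
    dplyr::ungroup()
}

finders_share_one <- function(log) {
  disc <- which(log$event == "search_success")
  if (!length(disc)) {
    return(tibble::tibble(n_discoveries = 0L, finders_share = NA_real_, finders_units = NA_real_))
  }
  frac <- units_f <- numeric(0)
  for (k in disc) {
    patch <- log$patch_id[k]
    later <- which(log$patch_id == patch & seq_len(nrow(log)) > k)
    nxt <- later[log$event[later] == "search_success"]
    stop_at <- if (length(nxt)) min(nxt) else nrow(log) + 1L
    coll <- later[log$event[later] == "collect" & later < stop_at]
    if (!length(coll)) next
    own <- sum(log$agent_id[coll] == log$agent_id[k])
    frac <- c(frac, own / length(coll))
    units_f <- c(units_f, own)
  }
  tibble::tibble(
    n_discoveries = length(disc),
    finders_share = if (length(frac)) mean(frac) else NA_real_,
    finders_units = if (length(units_f)) mean(units_f) else NA_real_
  )
}

validate_event_log <- function(log) {
  need <- c("session_id", "condition", "time_s", "agent_id", "event", "patch_id", "units")
  if (!is.data.frame(log)) abort_validation("event log must be a data frame")
  miss <- setdiff(need, names(log))
  if (length(miss)) {
    abort_validation("event log is missing columns: %s", paste(miss, collapse = ", "))
  }
  ok <- c("search_start", "search_success", "search_fail", "join", "collect")
  bad <- setdiff(unique(log$event), ok)
  if (length(bad)) abort_validation("unknown event types: %s", paste(bad, collapse = ", "))
  invisible(log)
}
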