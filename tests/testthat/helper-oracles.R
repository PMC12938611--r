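# Independent oracles and fixture generators. Everything here is written as
# plainly as possible (nested loops, direct enumeration) and never calls the
# package code paths it is used to check.

# --- random, structurally valid event logs -------------------------------

# Builds a log discovery-by-discovery: per patch a sequence of successful
# searches, each followed by joins and interleaved collects that respect the
# discovery's unit budget. Includes failed searches, joins and successes
# with no subsequent collection, and multiple discoveries per patch.
random_event_log <- function(seed) {
  set.seed(seed)
  agents <- paste0("a", seq_len(sample(2:4, 1)))
  n_patches <- sample(1:3, 1)
  rows <- list()
  t <- 0
  for (patch in seq_len(n_patches)) {
    for (d in seq_len(sample(1:4, 1))) {
      finder <- sample(agents, 1)
      t <- t + runif(1, 0.1, 2)
      rows[[length(rows) + 1L]] <- data.frame(
        time_s = t, agent_id = finder, event = "search_start", patch_id = patch,
        units = NA_integer_
      )
      if (runif(1) < 0.25) { # failed search
        t <- t + 0.1
        rows[[length(rows) + 1L]] <- data.frame(
          time_s = t, agent_id = finder, event = "search_fail", patch_id = patch,
          units = NA_integer_
        )
        next
      }
      t <- t + 0.1
      rows[[length(rows) + 1L]] <- data.frame(
        time_s = t, agent_id = finder, event = "search_success", patch_id = patch,
        units = NA_integer_
      )
      units <- sample(1:5, 1)
      joiners <- sample(setdiff(agents, finder), sample(0:min(2, length(agents) - 1), 1))
      collectors <- finder
      for (j in joiners) {
        t <- t + runif(1, 0.05, 0.5)
        rows[[length(rows) + 1L]] <- data.frame(
          time_s = t, agent_id = j, event = "join", patch_id = patch,
          units = NA_integer_
        )
        collectors <- c(collectors, j)
      }
      n_collect <- sample(0:units, 1)
      for (k in seq_len(n_collect)) {
        who <- sample(collectors, 1)
        t <- t + runif(1, 0.05, 0.5)
        rows[[length(rows) + 1L]] <- data.frame(
          time_s = t, agent_id = who, event = "collect", patch_id = patch,
          units = 1L
        )
      }
    }
  }
  log <- do.call(rbind, rows)
  log <- log[order(log$time_s), ]
  tibble::tibble(
    session_id = sprintf("rnd%04d", seed), condition = "rnd",
    time_s = log$time_s, agent_id = log$agent_id, event = log$event,
    patch_id = log$patch_id, units = log$units
  )
}

# Brute-force response tally: for every successful search, scan forward for
# collects/joins at that patch until the patch's next successful search.
oracle_tally <- function(log) {
  out <- list()
  for (sid in unique(log$session_id)) {
    L <- log[log$session_id == sid, ]
    L <- L[order(L$time_s), ]
    agents <- sort(unique(L$agent_id))
    p <- stats::setNames(integer(length(agents)), agents)
    s <- p
    u <- p
    n <- nrow(L)
    for (k in seq_len(n)) {
      if (L$event[k] != "search_success") next
      patch <- L$patch_id[k]
      finder <- L$agent_id[k]
      win <- integer(0)
      for (m in seq_len(n)) {
        if (m <= k || L$patch_id[m] != patch) next
        if (L$event[m] == "search_success") break
        win <- c(win, m)
      }
      finder_collected <- FALSE
      for (m in win) {
        if (L$event[m] == "collect" && L$agent_id[m] == finder) finder_collected <- TRUE
      }
      if (finder_collected) p[finder] <- p[finder] + 1L
      for (m in win) {
        if (L$event[m] != "join") next
        who <- L$agent_id[m]
        joined_collected <- FALSE
        for (q in win) {
          if (q > m && L$event[q] == "collect" && L$agent_id[q] == who) joined_collected <- TRUE
        }
        if (joined_collected) s[who] <- s[who] + 1L
      }
    }
    for (k in seq_len(n)) {
      if (L$event[k] == "collect") u[L$agent_id[k]] <- u[L$agent_id[k]] + L$units[k]
    }
    out[[sid]] <- tibble::tibble(
      session_id = sid, participant_id = agents,
      producer_responses = unname(p), scrounger_responses = unname(s),
      units_collected = unname(u)
    )
  }
  dplyr::bind_rows(out)
}

# --- rank-test oracles ---------------------------------------------------

# U by direct pair counting
oracle_u <- function(g1, g2) {
  sum(outer(g1, g2, ">")) + 0.5 * sum(outer(g1, g2, "=="))
}

# exact two-sided signed-rank p by looping over all 2^n sign patterns
oracle_signed_rank_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  mu <- sum(r) / 2
  obs <- sum(r[d > 0])
  hits <- 0L
  for (mask in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(mask))[seq_len(n)]
    w <- sum(r[bits == 1L])
    if (abs(w - mu) >= abs(obs - mu) - 1e-9) hits <- hits + 1L
  }
  hits / 2^n
}

# exact two-sided Mann-Whitney p by enumerating every group-1 subset
oracle_mw_exact_p <- function(g1, g2) {
  n1 <- length(g1)
  pooled <- c(g1, g2)
  r <- rank(pooled)
  obs_u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  center <- n1 * length(g2) / 2
  sets <- utils::combn(length(pooled), n1)
  hits <- 0L
  for (cix in seq_len(ncol(sets))) {
    u <- sum(r[sets[, cix]]) - n1 * (n1 + 1) / 2
    if (abs(u - center) >= abs(obs_u - center) - 1e-9) hits <- hits + 1L
  }
  hits / ncol(sets)
}

# --- misc fixtures -------------------------------------------------------

# Wide item table whose *scored* values equal the requested ones, built by
# inverting the reverse-keying by hand from the shipped keys.
items_from_scored <- function(participant_id, bfi_value = 3, apsd_value = 0) {
  bfi_key <- scoring_key("bfi")
  apsd_key <- scoring_key("apsd")
  bfi <- rep(bfi_value, length.out = 44)
  rev_b <- bfi_key$reverse # key rows are sorted by item number
  bfi[rev_b] <- 6 - bfi[rev_b]
  apsd <- rep(apsd_value, length.out = 20)
  rev_a <- apsd_key$reverse
  apsd[rev_a] <- 2 - apsd[rev_a]
  out <- c(list(participant_id = participant_id), as.list(bfi), as.list(apsd))
  names(out) <- c("participant_id", sprintf("bfi_%d", 1:44), sprintf("apsd_%d", 1:20))
  tibble::as_tibble(out)
}
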