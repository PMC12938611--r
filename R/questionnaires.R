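#' Generate item-level questionnaire responses from latent traits
#'
#' The inverse of the scoring step, so that latent-to-scored round trips are
#' testable: each agent's 44 BFI items (1-5) and 20 APSD items (0-2) are
#' produced from its latent traits and antisociality. An item on scale
#' `[lo, hi]` with latent value `L` is `clamp(round(L + e), lo, hi)` with
#' `e ~ N(0, noise_sd)`; reverse-keyed items are stored inverted
#' (`(lo + hi) - x`) at generation so that scoring recovers the latent value.
#'
#' With `noise_sd = 0` the generator is deterministic and emits, per trait,
#' the mix of `floor(L)` and `ceiling(L)` responses whose mean is the closest
#' grid point to `L` (exact when `L` sits on the trait's `1/k` grid, `k` the
#' number of items), so noise-free scored means reproduce the latents.
#'
#' @param agents Agent tibble from [generate_cohort()] (needs `agent_id`,
#'   `O`, `C`, `E`, `A`, `N`, `antisociality`).
#' @param noise_sd Item-level noise SD (response-scale points).
#' @param bfi_key,apsd_key Scoring keys, see [scoring_key()]; every item must
#'   be covered.
#' @param seed Integer seed.
#' @return Wide tibble: `participant_id`, `bfi_1` ... `bfi_44`,
#'   `apsd_1` ... `apsd_20`.
#' @export
#' @examples
#' ag <- generate_cohort(4, seed = 1)
#' qs <- generate_questionnaires(ag, noise_sd = 0.7, seed = 2)
#' score_bfi(qs)
generate_questionnaires <- function(agents, noise_sd = 0.7,
                                    bfi_key = scoring_key("bfi"),
                                    apsd_key = scoring_key("apsd"),
                                    seed = 1L) {
  need <- c("agent_id", "O", "C", "E", "A", "N", "antisociality")
  miss <- setdiff(need, names(agents))
  if (length(miss)) abort_validation("`agents` missing columns: %s", paste(miss, collapse = ", "))
  check_number(noise_sd, "noise_sd", lo = 0)
  n <- nrow(agents)

  bfi_scale <- bfi_key$scale[match(seq_len(44L), bfi_key$item)]
  apsd_rev <- apsd_key$reverse[match(seq_len(20L), apsd_key$item)]
  bfi_rev <- bfi_key$reverse[match(seq_len(44L), bfi_key$item)]
  if (any(is.na(bfi_scale)) || any(is.na(apsd_rev))) {
    abort_validation("scoring keys must cover every item")
  }

  withr::with_seed(as.integer(seed), {
    bfi <- matrix(NA_real_, n, 44L)
    for (tr in c("O", "C", "E", "A", "N")) {
      sel <- which(bfi_scale == tr)
      lat <- agents[[tr]]
      bfi[, sel] <- draw_items(lat, length(sel), noise_sd, 1, 5)
    }
    bfi[, bfi_rev] <- 6 - bfi[, bfi_rev]

    apsd <- draw_items(agents$antisociality, 20L, noise_sd, 0, 2)
    apsd[, apsd_rev] <- 2 - apsd[, apsd_rev]

    out <- tibble::tibble(participant_id = as.character(agents$agent_id))
    bfi_df <- as.data.frame(bfi)
    names(bfi_df) <- item_cols("bfi", 44L)
    apsd_df <- as.data.frame(apsd)
    names(apsd_df) <- item_cols("apsd", 20L)
    dplyr::bind_cols(out, bfi_df, apsd_df)
  })
}

# n_agents x k item draws around latent values `lat` on [lo, hi]
draw_items <- function(lat, k, noise_sd, lo, hi) {
  n <- length(lat)
  if (noise_sd == 0) {
    # deterministic floor/ceiling mix whose mean is the nearest 1/k grid point
    out <- matrix(NA_real_, n, k)
    for (i in seq_len(n)) {
      L <- clamp(lat[i], lo, hi)
      base <- floor(L)
      m <- round((L - base) * k)
      if (m == k) {
        base <- base + 1
        m <- 0
      }
      out[i, ] <- clamp(c(rep(base + 1, m), rep(base, k - m)), lo, hi)
    }
    return(out)
  }
  raw <- matrix(stats::rnorm(n * k, mean = rep(lat, k), sd = noise_sd), n, k)
  clamp(round(raw), lo, hi)
}
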