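## Scripted online-evaluation scenarios: streams assembled from generated
## recordings, with ground truth carried through for scoring.

#' Scenario: a recurring fall-confusable ADL with occasional real falls
#'
#' Builds a stream in which one impulsive ADL (clapping by default, with its
#' spike amplitude boosted into the fall range so the seed classifier
#' confuses it with a fall) recurs many times, interleaved with a few real
#' falls.  With a truthful feedback oracle the learning loop should drive the
#' false-positive rate down over the session.
#'
#' @param n_adl number of ADL repetitions (default 16).
#' @param n_falls number of real falls inserted (default 2).
#' @param adl_code impulsive ADL code (default `"D10"`, clapping).
#' @param boost multiplier on the ADL spike amplitude (default 1.6).
#' @param gap_s idle gap between recordings (s).
#' @param seed integer seed.
#' @return list with `stream` (a `sensor_stream`) and `recordings`.
#' @export
scenario_recurring_adl <- function(n_adl = 16, n_falls = 2, adl_code = "D10",
                                   boost = 1.6, gap_s = 2, seed = 1) {
  seeds <- derive_seeds(seed, n_adl + n_falls + 1)
  params <- adl_defaults(adl_code)
  params$spike_amp <- params$spike_amp * boost
  recs <- lapply(seq_len(n_adl), function(i) {
    generate_adl(adl_code, params, seed = seeds[i])
  })
  if (n_falls > 0) {
    fall_recs <- lapply(seq_len(n_falls), function(i) {
      generate_fall(
        FALL_CODES[1 + (i - 1) %% length(FALL_CODES)],
        seed = seeds[n_adl + i]
      )
    })
    # spread the falls evenly through the ADL repetitions
    pos <- round(seq(2, n_adl, length.out = n_falls))
    out <- list()
    fi <- 1
    for (i in seq_len(n_adl)) {
      out[[length(out) + 1]] <- recs[[i]]
      if (fi <= n_falls && i == pos[fi]) {
        out[[length(out) + 1]] <- fall_recs[[fi]]
        fi <- fi + 1
      }
    }
    recs <- out
  }
  list(
    stream = build_stream(recs, gap_s = gap_s, seed = seeds[n_adl + n_falls + 1]),
    recordings = recs
  )
}

#' Read a scenario description file
#'
#' Flat key-value text (`key: value` per line, `#` comments).  Recognised
#' keys: `adl_code`, `n_adl`, `n_falls`, `boost`, `gap_s`, `seed_users`,
#' `seed_fall_points`, `seed_adl_points`.
#'
#' @param path scenario file.
#' @return named list of scenario settings (numbers parsed).
#' @export
read_scenario <- function(path) {
  kv <- read_keyvalue(path)
  num <- c(
    "n_adl", "n_falls", "boost", "gap_s", "seed_users",
    "seed_fall_points", "seed_adl_points"
  )
  for (k in intersect(names(kv), num)) kv[[k]] <- as.numeric(kv[[k]])
  kv
}
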