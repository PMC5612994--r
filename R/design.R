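#' Experimental design specification
#'
#' Describes one slow event-related session: per run, 4 trials for each of 9
#' identities (4 personally familiar, 4 unfamiliar, self), 4 blank trials,
#' 4 oddball (catch) trials and 4 buffer trials (3 at run start, 1 at run
#' end), i.e. 48 trials per run; 11 runs per session. Each trial presents 3
#' head views (front and two 30-degree profiles) of one identity for 500 ms
#' each.
#'
#' @param n_runs number of functional runs (default 11).
#' @param n_familiar,n_unfamiliar number of familiar / unfamiliar identities.
#' @param include_self include the self-face condition (default TRUE).
#' @param trials_per_identity_per_run identity trials per run (default 4).
#' @param n_blank_per_run,n_oddball_per_run,n_buffer_per_run counts of the
#'   remaining trial types (defaults 4 each; buffers split 3 start + 1 end).
#' @param stim_duration_ms duration of each image (default 500).
#' @return object of class `design_spec`.
#' @export
design_spec <- function(n_runs = 11, n_familiar = 4, n_unfamiliar = 4,
                        include_self = TRUE, trials_per_identity_per_run = 4,
                        n_blank_per_run = 4, n_oddball_per_run = 4,
                        n_buffer_per_run = 4, stim_duration_ms = 500) {
  if (n_runs < 1 || trials_per_identity_per_run < 1)
    stop("n_runs and trials_per_identity_per_run must be positive")
  if (n_buffer_per_run < 2) stop("need at least 2 buffer trials (start + end)")
  identities <- c(
    if (n_familiar > 0) paste0("F", seq_len(n_familiar)),
    if (n_unfamiliar > 0) paste0("U", seq_len(n_unfamiliar)),
    if (include_self) "self")
  familiarity <- c(rep("familiar", n_familiar), rep("unfamiliar", n_unfamiliar),
                   if (include_self) "self")
  structure(list(
    n_runs = as.integer(n_runs),
    identities = identities,
    familiarity = setNames(familiarity, identities),
    trials_per_identity_per_run = as.integer(trials_per_identity_per_run),
    n_blank_per_run = as.integer(n_blank_per_run),
    n_oddball_per_run = as.integer(n_oddball_per_run),
    n_buffer_per_run = as.integer(n_buffer_per_run),
    views = c("front", "left30", "right30"),
    stim_duration_ms = stim_duration_ms
  ), class = "design_spec")
}

trials_per_run <- function(spec) {
  length(spec$identities) * spec$trials_per_identity_per_run +
    spec$n_blank_per_run + spec$n_oddball_per_run + spec$n_buffer_per_run
}

# Sum of squared deviations of the first-order transition-count matrix from a
# uniform matrix with the same total. `seq_cat` is the per-trial category
# sequence of one run's optimized segment.
transition_cost <- function(seq_cat, n_cat) {
  trans <- table(factor(seq_cat[-length(seq_cat)], levels = seq_len(n_cat)),
                 factor(seq_cat[-1], levels = seq_len(n_cat)))
  sum((trans - mean(trans))^2)
}

#' Generate a pseudo-randomized trial sequence
#'
#' Orders the non-buffer trials of each run with a seeded greedy search that
#' minimizes the deviation of the first-order transition-count matrix from
#' uniform (a deterministic surrogate for first-order counterbalancing
#' optimizers). Buffer trials are placed 3 at the start and the remainder at
#' the end of each run; the head-view order within each trial is randomized.
#'
#' @param spec a [design_spec()].
#' @param seed integer seed; the sequence is deterministic given the seed.
#' @param n_swaps greedy improvement attempts per run (default 300).
#' @return data.frame with columns `run`, `trial`, `trial_type`
#'   (`buffer`/`normal`/`blank`/`oddball`), `identity`, `familiarity`,
#'   `oddball_identity` and `view_order`.
#' @export
generate_design <- function(spec, seed, n_swaps = 300) {
  if (!inherits(spec, "design_spec")) stop("spec must be a design_spec")
  ids <- spec$identities
  n_id <- length(ids)
  with_seed(seed, {
    runs <- lapply(seq_len(spec$n_runs), function(r) {
      # categories of the optimized middle segment: identities, blank, oddball
      cats <- c(rep(seq_len(n_id), each = spec$trials_per_identity_per_run),
                rep(n_id + 1L, spec$n_blank_per_run),
                rep(n_id + 2L, spec$n_oddball_per_run))
      ord <- sample(length(cats))
      cur <- cats[ord]
      cost <- transition_cost(cur, n_id + 2L)
      for (it in seq_len(n_swaps)) {
        sw <- sample(length(cur), 2)
        cand <- cur
        cand[sw] <- cand[rev(sw)]
        cand_cost <- transition_cost(cand, n_id + 2L)
        if (cand_cost <= cost) {
          cur <- cand
          cost <- cand_cost
        }
      }
      n_start_buf <- min(3L, spec$n_buffer_per_run - 1L)
      n_end_buf <- spec$n_buffer_per_run - n_start_buf
      seq_types <- c(rep("buffer", n_start_buf),
                     ifelse(cur <= n_id, "normal",
                            ifelse(cur == n_id + 1L, "blank", "oddball")),
                     rep("buffer", n_end_buf))
      seq_ids <- c(sample(ids, n_start_buf, replace = TRUE),
                   ifelse(cur <= n_id, ids[pmin(cur, n_id)], NA),
                   sample(ids, n_end_buf, replace = TRUE))
      n_trials <- length(seq_types)
      odd_id <- rep(NA_character_, n_trials)
      is_odd <- seq_types == "oddball"
      seq_ids[is_odd] <- sample(ids, sum(is_odd), replace = TRUE)
      odd_id[is_odd] <- vapply(seq_ids[is_odd],
                               function(i) sample(setdiff(ids, i), 1), "")
      views <- vapply(seq_len(n_trials), function(i) {
        if (seq_types[i] == "blank") return(NA_character_)
        paste(sample(spec$views), collapse = "|")
      }, "")
      data.frame(run = r, trial = seq_len(n_trials), trial_type = seq_types,
                 identity = seq_ids,
                 familiarity = ifelse(is.na(seq_ids), NA,
                                      unname(spec$familiarity[seq_ids])),
                 oddball_identity = odd_id, view_order = views,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, runs)
    attr(out, "design_spec") <- spec
    out
  })
}

#' Write a trial table as TSV
#' @param design data.frame from [generate_design()].
#' @param path output path.
#' @export
write_trial_table <- function(design, path) {
  write.table(design, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trial table written by [write_trial_table()]
#' @param path TSV path.
#' @export
read_trial_table <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             na.strings = "NA")
}
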