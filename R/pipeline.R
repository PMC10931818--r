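#' Pool peri-event trials across sessions
#'
#' Stacks the trial matrices of several PETHs of the same neuron and event
#' (identical binning required) and recomputes the trial-averaged PETH.
#'
#' @param ps list of [build_peth()] objects.
#' @return A single `peth` object.
#' @export
combine_peths <- function(ps) {
  ps <- ps[!vapply(ps, is.null, logical(1))]
  if (!length(ps)) stop("no PETHs to combine")
  nb <- length(ps[[1]]$mean_peth)
  stopifnot(all(vapply(ps, function(p) length(p$mean_peth) == nb, logical(1))))
  tm <- do.call(rbind, lapply(ps, function(p) p$trial_matrix))
  out <- ps[[1]]
  out$trial_matrix <- tm
  out$mean_peth <- if (nrow(tm)) colMeans(tm) else rep(NA_real_, nb)
  out$n_dropped <- sum(vapply(ps, function(p) p$n_dropped, numeric(1)))
  out$empty <- nrow(tm) == 0L
  out
}

peths_for_session <- function(ztm, bouts, window = c(-8, 6), bin = 0.1,
                              condition = NA_character_) {
  press <- bouts$first_press
  lick <- bouts$lick_time[!is.na(bouts$lick_time)]
  lapply(seq_along(ztm$neuron_ids), function(i) {
    list(press = build_peth(ztm$values[i, ], press, ztm$sampling_rate,
                            window, bin, neuron_id = ztm$neuron_ids[i],
                            event_type = "first_press", condition = condition),
         lick = build_peth(ztm$values[i, ], lick, ztm$sampling_rate,
                           window, bin, neuron_id = ztm$neuron_ids[i],
                           event_type = "rewarded_lick", condition = condition))
  })
}

#' Run the full simulated-imaging analysis pipeline
#'
#' Orchestrates every stage on one synthetic cohort: behavior simulation,
#' trace simulation, per-session z-scoring, trial pooling across days,
#' neuron classification, population statistics (per-mouse proportions,
#' laterality of pre-press amplitude, movement/reward overlap vs chance,
#' reward and magazine-approach laterality, sequence-length coding), and
#' cross-day ROI matching with the functional-stability controls.
#'
#' @param cfg a [sim_config()].
#' @param pre_press_window window for the laterality peak (default
#'   `c(-2, 0)` s).
#' @param length_window window for the per-bout length-coding peak
#'   (default `c(-1, 0)` s).
#' @param run_matching run the (slower) matching/stability stage
#'   (default TRUE).
#' @return List with elements `config`, `truth`, `modtable`, `behavior`
#'   (per-session metrics), `population`, `length_coding`, `matching`,
#'   `stability`.
#' @export
run_pipeline <- function(cfg, pre_press_window = c(-2, 0),
                         length_window = c(-1, 0), run_matching = TRUE) {
  stopifnot(inherits(cfg, "sim_config"))
  sim <- simulate_behavior(cfg)
  tr <- simulate_traces(cfg, sim)
  ztr <- lapply(tr$traces, zscore_traces)
  roster <- tr$truth
  mice <- unique(roster$mouse_id)

  behavior <- dplyr::bind_rows(lapply(names(sim$logs), function(sid) {
    behavior_metrics(sim$logs[[sid]], segment_sequences(sim$logs[[sid]]))
  }))

  # --- pooled PETHs and classification per neuron x condition -------------
  modtable <- list(); length_rows <- list()
  peths_by_day <- list()  # mouse -> day -> neuron -> 4 event PETHs (wide window)
  for (m in mice) {
    sids <- names(sim$logs)[vapply(sim$logs, function(l) l$mouse_id == m, logical(1))]
    limb_of <- vapply(sids, function(s)
      limb_from_sides(sim$logs[[s]]$lever_side, sim$logs[[s]]$hemisphere), "")
    for (cond in c("contra", "ipsi")) {
      cs <- sids[limb_of == cond]
      per_day <- lapply(cs, function(s)
        peths_for_session(ztr[[s]], sim$bouts[sim$bouts$session_id == s, ],
                          condition = cond))
      nn <- ztr[[cs[1]]]$neuron_ids
      # bout lengths for the trials that survive the PETH window bounds,
      # in trial-matrix row order
      lens <- unlist(lapply(cs, function(s) {
        b <- sim$bouts[sim$bouts$session_id == s, ]
        t_last <- (ncol(ztr[[s]]$values) - 1) / ztr[[s]]$sampling_rate
        keep <- b$first_press - 8 >= -1e-9 & b$first_press + 6 <= t_last + 1e-9
        b$n_presses[keep]
      }))
      for (i in seq_along(nn)) {
        pp <- combine_peths(lapply(per_day, function(d) d[[i]]$press))
        pl <- combine_peths(lapply(per_day, function(d) d[[i]]$lick))
        row <- classify_neuron(pp, pl, pre_press_window = pre_press_window)
        row$mouse <- m
        modtable[[paste(m, cond, i)]] <- row
        if (row$is_movement) {
          # per-bout peak in the length window (trial rows align with lens)
          ok <- which(!apply(is.na(pp$trial_matrix), 1, any))
          act <- vapply(ok, function(tr_i)
            max_activity(pp, length_window, trial = tr_i), numeric(1))
          lm_row <- length_modulation(act, lens[ok])
          lm_row$neuron_id <- nn[i]; lm_row$condition <- cond; lm_row$mouse <- m
          length_rows[[paste(m, cond, i)]] <- lm_row
        }
      }
    }
    if (run_matching) {
      days <- sort(unique(vapply(sids, function(s) sim$logs[[s]]$day_index, 1L)))
      peths_by_day[[m]] <- lapply(days, function(d) {
        ds <- sids[vapply(sids, function(s) sim$logs[[s]]$day_index == d, logical(1))]
        per <- lapply(ds, function(s)
          peths_for_session(ztr[[s]], sim$bouts[sim$bouts$session_id == s, ],
                            window = c(-10, 6),
                            condition = limb_of[s]))
        nn <- ztr[[ds[1]]]$neuron_ids
        stats::setNames(lapply(seq_along(nn), function(i) {
          out <- list()
          for (k in seq_along(ds)) {
            cnd <- limb_of[ds[k]]
            # light smoothing stabilizes the rank correlation of noisy bins
            out[[paste0("press_", cnd)]] <- moving_average3(per[[k]][[i]]$press$mean_peth)
            out[[paste0("lick_", cnd)]] <- moving_average3(per[[k]][[i]]$lick$mean_peth)
          }
          out
        }), nn)
      })
    }
  }
  modtable <- dplyr::bind_rows(modtable)
  length_tbl <- dplyr::bind_rows(length_rows)

  # --- population statistics ---------------------------------------------
  frac <- modtable |>
    dplyr::group_by(mouse, condition) |>
    dplyr::summarise(pct_movement = 100 * mean(is_movement),
                     pct_reward = 100 * mean(is_reward),
                     pct_magazine = 100 * mean(is_magazine),
                     .groups = "drop")
  fw <- tidyr_pivot(frac[, c("mouse", "condition", "pct_movement")],
                    "condition", "pct_movement")
  prop_test <- proportion_contrast(fw$contra, fw$ipsi)
  mv_c <- modtable$max_pre_press[modtable$is_movement & modtable$condition == "contra"]
  mv_i <- modtable$max_pre_press[modtable$is_movement & modtable$condition == "ipsi"]
  amp_test <- amplitude_contrast(mv_c, mv_i)
  contra_rows <- modtable[modtable$condition == "contra", ]
  overlap <- overlap_analysis(contra_rows$is_movement, contra_rows$is_reward)
  rl <- reward_laterality(modtable)

  # --- length coding -----------------------------------------------------
  length_coding <- NULL
  if (nrow(length_tbl)) {
    gm_cols <- grep("^mean_", names(length_tbl), value = TRUE)
    trend <- lapply(c(contra = "contra", ipsi = "ipsi"), function(cond) {
      mm <- as.matrix(length_tbl[length_tbl$condition == cond, gm_cols])
      keep <- colSums(!is.na(mm)) > 0
      if (nrow(mm) >= 2 && sum(keep) >= 3) linear_trend_contrast(mm[, keep]) else NULL
    })
    n_mod <- function(cond) sum(length_tbl$positively_modulated[length_tbl$condition == cond])
    n_tot <- function(cond) sum(length_tbl$condition == cond)
    prop <- if (n_tot("contra") > 0 && n_tot("ipsi") > 0)
      length_proportion_contrast(n_mod("contra"), n_tot("contra"),
                                 n_mod("ipsi"), n_tot("ipsi")) else NULL
    length_coding <- list(table = length_tbl, trend = trend,
                          proportion_test = prop,
                          n_modulated = c(contra = n_mod("contra"), ipsi = n_mod("ipsi")),
                          n_neurons = c(contra = n_tot("contra"), ipsi = n_tot("ipsi")))
  }

  # --- cross-day matching and stability ----------------------------------
  matching <- NULL; stability <- NULL
  if (run_matching) {
    match_acc <- c(); track_counts <- c(); records <- list()
    for (m in mice) {
      sids <- names(tr$rois)[vapply(sim$logs, function(l) l$mouse_id == m, logical(1))]
      contra_sids <- sids[vapply(sids, function(s)
        limb_from_sides(sim$logs[[s]]$lever_side, sim$logs[[s]]$hemisphere) == "contra",
        logical(1))]
      maps <- stats::setNames(tr$rois[contra_sids],
                              paste0("day", seq_along(contra_sids)))
      tracks <- match_rois(maps, max_dist = 5)
      tc <- table(tracks$track_id)
      track_counts <- c(track_counts, as.integer(tc))
      # accuracy: within a track all rois share the true neuron identity
      acc <- tapply(tracks$roi, tracks$track_id,
                    function(r) length(unique(r)) == 1L)
      match_acc <- c(match_acc, acc[tc > 1])
      pbd <- peths_by_day[[m]]
      nn <- names(pbd[[1]])
      for (id in nn) {
        ref <- lapply(pbd, function(day) day[[id]])
        others <- lapply(setdiff(nn, id), function(o) lapply(pbd, function(day) day[[o]]))
        records[[paste(m, id, "matched")]] <-
          tibble::tibble(roi = id, group = "matched",
                         value = matched_correlation(ref))
        records[[paste(m, id, "shuffled")]] <-
          tibble::tibble(roi = id, group = "shuffled",
                         value = control_correlations(ref, mode = "shuffled"))
        records[[paste(m, id, "different")]] <-
          tibble::tibble(roi = id, group = "different",
                         value = control_correlations(ref, others, mode = "different"))
      }
    }
    records <- dplyr::bind_rows(records)
    matching <- list(accuracy = mean(match_acc),
                     summary = summarize_matches(
                       tibble::tibble(n_sessions_matched = track_counts),
                       n_sessions = cfg$n_days))
    stability <- stability_summary(records)
  }

  list(config = cfg, truth = roster, modtable = modtable, behavior = behavior,
       population = list(fractions = frac, proportion_test = prop_test,
                         amplitude_test = amp_test, overlap = overlap,
                         reward_laterality = rl,
                         mean_max_contra = mean(mv_c), mean_max_ipsi = mean(mv_i),
                         n_movement = c(contra = length(mv_c), ipsi = length(mv_i))),
       length_coding = length_coding,
       matching = matching, stability = stability)
}
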