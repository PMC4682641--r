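#' Simulate molecule state trajectories
#'
#' Event-driven (exact, Gillespie-style) stochastic simulation of independent
#' molecules jumping among the FREE, CHROM, and RNA states. Mobile molecules
#' are initialized from the stationary distribution of the rate matrix (or a
#' fixed state), chromatin-bound molecules are assigned to foci with
#' probability proportional to `focus_weights`, and immobile molecules sit
#' permanently at their focus. All molecules start fluorescent; fluorescence
#' changes only at bleach events (see [apply_bleach()]).
#'
#' @param config A [kinetic_config()].
#' @param geometry A [nucleus_geometry()].
#' @param duration Simulated time span in seconds.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param initial_state `"stationary"` or one of `"FREE"`, `"CHROM"`, `"RNA"`
#'   to start every mobile molecule in a fixed state (required when all rates
#'   are zero).
#' @return A `molecule_trajectory`: a tibble of events with columns
#'   `molecule`, `time`, `state`, `focus` (NA outside CHROM), carrying the
#'   configuration, fluorescence flags, and immobility flags as attributes.
#' @export
simulate_molecules <- function(config, geometry, duration, seed = NULL,
                               initial_state = "stationary") {
  stopifnot(inherits(config, "kinetic_config"), inherits(geometry, "nucleus_geometry"))
  if (duration <= 0) abort("`duration` must be > 0.")
  if (!is.null(seed)) withr::local_seed(seed)

  n <- config$n_molecules
  k_foci <- nrow(geometry$foci)
  w <- rep_len(config$focus_weights, k_foci)
  w <- w / sum(w)
  q <- config$rate_matrix
  exit_rate <- rowSums(q)

  n_imm <- n_immobile(config)
  n_mob <- n - n_imm
  imm_ids <- if (n_imm > 0) seq_len(n_imm) else integer(0)
  mob_ids <- setdiff(seq_len(n), imm_ids)

  # initial states
  if (identical(initial_state, "stationary")) {
    pi0 <- stationary_distribution(q)
    st0 <- sample.int(3, n_mob, replace = TRUE, prob = pi0)
  } else {
    st0 <- rep(match(match.arg(initial_state, KINETIC_STATES), KINETIC_STATES), n_mob)
  }
  sample_focus <- function(k) sample.int(k_foci, k, replace = TRUE, prob = w)
  f0 <- rep(NA_integer_, n_mob)
  f0[st0 == 2L] <- sample_focus(sum(st0 == 2L))
  imm_focus <- if (n_imm > 0) sample_focus(n_imm) else integer(0)

  events <- list(tibble(
    molecule = c(imm_ids, mob_ids),
    time = 0,
    state = c(rep(2L, n_imm), st0),
    focus = c(imm_focus, f0)
  ))

  # vectorized rounds: each round advances every still-active molecule by one jump
  id <- mob_ids
  st <- st0
  tm <- rep(0, n_mob)
  cum <- t(apply(q, 1, cumsum))
  repeat {
    rate <- exit_rate[st]
    active <- rate > 0 & tm < duration
    if (!any(active)) break
    idx <- which(active)
    tm[idx] <- tm[idx] + rexp(length(idx), rate[idx])
    live <- idx[tm[idx] <= duration]
    if (length(live) > 0) {
      u <- runif(length(live)) * exit_rate[st[live]]
      new_st <- 1L + rowSums(outer(u, rep(1, 3)) > cum[st[live], , drop = FALSE])
      new_focus <- rep(NA_integer_, length(live))
      is_chrom <- new_st == 2L
      new_focus[is_chrom] <- sample_focus(sum(is_chrom))
      st[live] <- new_st
      events[[length(events) + 1]] <- tibble(
        molecule = id[live], time = tm[live], state = new_st, focus = new_focus
      )
    }
    tm[idx[tm[idx] > duration]] <- Inf # done
  }

  ev <- dplyr::arrange(dplyr::bind_rows(events), .data$molecule, .data$time)
  ev$state <- factor(KINETIC_STATES[ev$state], levels = KINETIC_STATES)
  structure(
    ev,
    class = c("molecule_trajectory", class(ev)),
    n_molecules = n,
    duration = duration,
    config = config,
    geometry = geometry,
    immobile = c(rep(TRUE, n_imm), rep(FALSE, n_mob)),
    fluorescent = rep(TRUE, n),
    bleach_time = NA_real_
  )
}

traj_codes <- function(traj) {
  # integer state codes: 1 FREE, 2 RNA, 3..(2+K) CHROM at focus
  st <- as.integer(traj$state)
  code <- ifelse(st == 1L, 1L, ifelse(st == 3L, 2L, 2L + traj$focus))
  code
}

#' Per-molecule state codes at query times
#'
#' Returns an `n_molecules x length(times)` integer matrix of compartment
#' codes (1 = FREE, 2 = RNA, 2 + j = CHROM at focus j).
#' @keywords internal
state_code_matrix <- function(traj, times) {
  n <- attr(traj, "n_molecules")
  code <- traj_codes(traj)
  out <- matrix(NA_integer_, n, length(times))
  ev_t <- split(traj$time, traj$molecule)
  ev_c <- split(code, traj$molecule)
  ids <- as.integer(names(ev_t))
  for (i in seq_along(ids)) {
    k <- findInterval(times, ev_t[[i]])
    k[k < 1] <- 1L
    out[ids[i], ] <- ev_c[[i]][k]
  }
  out
}

#' Compartment occupancy counts over time
#'
#' Counts molecules per compartment (FREE, RNA, CHROM per focus) at the query
#' times, optionally restricted to fluorescent molecules.
#'
#' @param traj A `molecule_trajectory`.
#' @param times Query times, s.
#' @param fluorescent_only Count only fluorescent molecules (fluorescence is
#'   evaluated against the trajectory's bleach record).
#' @return Tibble with columns `time`, `FREE`, `RNA`, `CHROM_1` ... and
#'   `total`.
#' @export
occupancy_counts <- function(traj, times, fluorescent_only = FALSE) {
  k_foci <- nrow(attr(traj, "geometry")$foci)
  n_codes <- 2L + k_foci
  codes <- state_code_matrix(traj, times)
  keep <- rep(TRUE, attr(traj, "n_molecules"))
  if (fluorescent_only) {
    fl <- attr(traj, "fluorescent")
    bt <- attr(traj, "bleach_time")
    if (!is.na(bt)) {
      # bleached molecules count as fluorescent before the bleach time
      counts <- vapply(seq_along(times), function(j) {
        kp <- if (times[j] < bt) rep(TRUE, length(fl)) else fl
        tabulate(codes[kp, j], nbins = n_codes)
      }, integer(n_codes))
      return(occ_tibble(times, t(counts), k_foci))
    }
  }
  counts <- vapply(seq_along(times), function(j) {
    tabulate(codes[keep, j], nbins = n_codes)
  }, integer(n_codes))
  occ_tibble(times, t(counts), k_foci)
}

occ_tibble <- function(times, counts, k_foci) {
  colnames(counts) <- c("FREE", "RNA", paste0("CHROM_", seq_len(k_foci)))
  out <- as_tibble(counts)
  out$total <- rowSums(counts)
  dplyr::bind_cols(tibble(time = times), out)
}

#' Apply a bleach pulse to a trajectory
#'
#' Molecules whose position lies inside the bleach region at any point during
#' the bleach window `[bleach_time, bleach_time + bleach_duration]` lose
#' fluorescence with probability `bleach_efficiency`. Chromatin-bound
#' molecules sit at their focus centre; FREE and RNA-bound molecules are
#' well mixed and receive a uniformly sampled nucleoplasmic position. The
#' molecule count is unchanged; fluorescence, once lost, never returns.
#'
#' @param traj A `molecule_trajectory`.
#' @param geometry A [nucleus_geometry()].
#' @param imaging An [imaging_config()] (supplies the bleach radius/duration
#'   and, if set, the bleach centre).
#' @param bleach_time Start of the bleach window, s.
#' @param focus Focus the spot is centred on when `imaging$bleach_center` is
#'   `NULL`.
#' @param seed Optional integer seed.
#' @return The trajectory with updated fluorescence flags and a recorded
#'   bleach time.
#' @export
apply_bleach <- function(traj, geometry, imaging, bleach_time, focus = 1,
                         seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  dur <- attr(traj, "duration")
  if (bleach_time < 0 || bleach_time > dur) {
    abort("`bleach_time` must lie within the simulated duration.")
  }
  centre <- imaging$bleach_center %||%
    unlist(geometry$foci[focus, c("x", "y", "z")])
  if (sqrt(sum(centre^2)) + imaging$bleach_radius > geometry$nucleus_radius + 1e-9) {
    abort("Bleach region must lie inside the nucleus.")
  }
  t1 <- min(bleach_time + imaging$bleach_duration, dur)

  # foci whose centre falls inside the spot are bleached
  d_foci <- sqrt((geometry$foci$x - centre[1])^2 +
    (geometry$foci$y - centre[2])^2 +
    (geometry$foci$z - centre[3])^2)
  hit_foci <- which(d_foci <= imaging$bleach_radius)

  n <- attr(traj, "n_molecules")
  codes0 <- state_code_matrix(traj, bleach_time)[, 1]
  in_hit_focus <- codes0 %in% (2L + hit_foci)
  was_pool <- codes0 <= 2L

  # events inside the window can move molecules through the spot
  win <- traj$time > bleach_time & traj$time <= t1
  if (any(win)) {
    wcodes <- traj_codes(traj)[win]
    wmol <- traj$molecule[win]
    in_hit_focus[wmol[wcodes %in% (2L + hit_foci)]] <- TRUE
    was_pool[wmol[wcodes <= 2L]] <- TRUE
  }

  # pool molecules: uniform position in the nuclear sphere
  pool_ids <- which(was_pool)
  in_spot_pool <- logical(n)
  if (length(pool_ids) > 0) {
    m <- length(pool_ids)
    r <- geometry$nucleus_radius * runif(m)^(1 / 3)
    z <- runif(m, -1, 1)
    th <- runif(m, 0, 2 * pi)
    px <- r * sqrt(1 - z^2) * cos(th)
    py <- r * sqrt(1 - z^2) * sin(th)
    pz <- r * z
    d <- sqrt((px - centre[1])^2 + (py - centre[2])^2 + (pz - centre[3])^2)
    in_spot_pool[pool_ids] <- d <= imaging$bleach_radius
  }

  candidate <- in_hit_focus | in_spot_pool
  eff <- attr(traj, "config")$bleach_efficiency
  bleached <- candidate & runif(n) < eff

  fl <- attr(traj, "fluorescent")
  fl[bleached] <- FALSE
  attr(traj, "fluorescent") <- fl
  attr(traj, "bleach_time") <- bleach_time
  attr(traj, "bleach_end") <- t1
  attr(traj, "bleached_focus") <- if (length(hit_foci)) hit_foci else integer(0)
  traj
}

#' Export a trajectory as a plain event table
#'
#' @param traj A `molecule_trajectory`.
#' @return Tibble with columns `time`, `molecule`, `state`, `focus`,
#'   `fluorescent` (flag after any bleach), `immobile`.
#' @export
trajectory_table <- function(traj) {
  fl <- attr(traj, "fluorescent")
  imm <- attr(traj, "immobile")
  tibble(
    time = traj$time,
    molecule = traj$molecule,
    state = as.character(traj$state),
    focus = traj$focus,
    fluorescent = fl[traj$molecule],
    immobile = imm[traj$molecule]
  )
}
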